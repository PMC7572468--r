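Package: glycoquant
Title: Identification and Multiplexed Quantification of Intact N-Glycopeptides
    from Multi-Notch MS3 Data
Version: 0.1.0
Authors@R:
    person("glycoquant", "developers", email = "glycoquant@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for intact N-glycopeptide identification
    and isobaric-tag (TMT) quantification from multi-notch SPS-MS3 acquisitions.
    Merges high-resolution MS2 and MS3 fragments of the same precursor into
    pseudo-spectra, corrects monoisotopic precursor assignments, searches a
    peptide-glycan composition space with binomial-surprisal scoring and
    two-level (peptide and glycan) target-decoy FDR control, performs a
    two-step database search, extracts reporter-ion intensities, and
    propagates quantification to glycoform, glycosite, and glycan levels with
    proteome-median normalization and Z-score regulation calls. Includes a
    synthetic acquisition simulator with ground truth, covering SPS notch
    selection and co-isolation interference mixture designs, so every stage
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    xml2,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
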