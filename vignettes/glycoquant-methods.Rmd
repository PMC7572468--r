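---
title: "Methods: identification and multiplexed quantification of intact N-glycopeptides from multi-notch MS3 data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identification and multiplexed quantification of intact N-glycopeptides from multi-notch MS3 data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tandem-MS characterization of intact N-glycopeptides is caught between
incompatible collision-energy optima: glycosidic bonds break at low
normalized collision energy (NCE), producing the glycan Y-series (the
peptide backbone retaining progressively trimmed glycan remnants, down to
the bare peptide Y0); peptide backbone b/y ions need mid-range NCE; and
isobaric-tag (TMT) reporter ions need high NCE. A multi-notch SPS-MS3
acquisition resolves this: a low-NCE MS2 scan yields Y ions, the 10 most
abundant fragments in 700–2000 m/z are co-selected (synchronous precursor
selection) and re-fragmented at higher NCE, and the resulting MS3 scan
carries b/y ions plus reporters. Reading reporters from MS3 also strips
most co-isolation interference, because contaminant precursor fragments
are rarely co-selected into the notches.

`glycoquant` implements the data-processing side of this design as a
self-contained pipeline: spectra I/O and the MS3→MS2 scan linkage,
MS2+MS3 pseudo-spectrum merging with monoisotopic precursor correction,
a glycopeptide search engine with two-level (peptide and glycan)
target–decoy FDR control and a two-step database search, reporter-ion
quantification propagated to glycoform (protein–site–glycan, "P-N-G"),
glycosite (P-N), and glycan levels, and a synthetic acquisition simulator
with ground truth that makes every stage testable at desk scale.

## Pseudo-spectrum merging

Both MS2 and MS3 scans are acquired at high resolution, so fragments of
the same precursor can be pooled: peaks within a **1 ppm** merge tolerance
(default, `merge_config()`) are combined into one peak. The combined m/z
is the intensity-weighted mean of the contributors; intensities are
summed (`combine_rule = "sum"`) because MS2 and MS3 sample the same
fragment population — total intensity is conserved exactly, and the
result is independent of the order in which MS3 scans are supplied.
Near-tolerance chains are resolved by single-linkage clustering on the
sorted peak list, which is deterministic for pathological inputs. A
`"max"` rule is available for sensitivity analyses. MS2 scans without an
MS3 partner pass through unmerged (flagged) and are searched identically,
which is what supports plain-MS2 acquisitions.

Reporter-region peaks (m/z < 135) are carried into the pseudo-spectrum
but flagged and excluded from identification scoring and SPS selection;
they are quantification-only signals.

**Precursor correction.** Instruments often isolate a higher isotope of
the precursor. The correction walks the isotope envelope (spacing
1.0033548/z) in the preceding MS1 scan across integer offsets −2..+2 and
moves the precursor to the envelope start, defined as the leftmost chain
member whose left neighbour is absent or below 20% of its intensity and
which has a right neighbour (the envelope must rise then fall). Unknown
charges (MGF frequently omits them) are inferred first from the spacing
that yields the longest consistent chain. When no envelope is found the
precursor is left unchanged with a warning recorded — a deliberate
simplification of full isotope-cluster deconvolution, which the source
tools delegate to closed-source software.

## The search space

Proteins are digested fully specifically with trypsin (cleavage after
K/R unless P follows), up to 2 missed cleavages, minimum length 4.
Peptides are kept when they carry at least one N-X-S/T sequon (X ≠ P),
evaluated on the parent protein so boundary sequons (S/T beyond the
C-terminus) are found. Fixed modifications: carbamidomethyl-C
(+57.02146 Da) and one isobaric label on the N-terminus plus one per
lysine (TMT6 229.16293 Da, TMT0 224.15248 Da). Variable modification:
oxidation-M (+15.99492 Da), at most 3 per peptide, expanded as separate
candidate entries with oxidations placed on the first methionines (a
declared positional convention — composition-level scores are unaffected,
b/y placement is deterministic).

Glycans are handled as compositions (Hex, HexNAc, NeuAc, Fuc counts);
the default library is all compositions with Hex 3–12, HexNAc 2–7,
NeuAc 0–4, Fuc 0–3 and at most 18 residues (~900 entries, shipped as an
editable TSV), spanning the 8–14-monosaccharide range that dominates
biological N-glycans. The theoretical Y series of a candidate contains
one ion per sub-composition satisfying the attachment rules — at least
one HexNAc whenever any other residue is present (the reducing-end
residue is a HexNAc), and NeuAc requires a Hex to sit on — plus Y0.

**Decoys.** Peptide decoys reverse the sequence keeping the C-terminal
K/R (mass-preserving, tryptic); sequons are recomputed on the reversed
sequence, and colliding decoys are dropped. Glycan decoys add a fixed
+17.00274 Da to every glycan-containing mass (precursor and Y ions, but
never Y0), keeping target and decoy Y-ion counts identical so scores are
comparable. The search space is the full 2×2 cross — `target`,
`pep_decoy`, `gly_decoy`, `both` — indexed together by neutral mass.

## Scoring and FDR

Candidates within 10 ppm of the observed neutral precursor mass are
scored against the pseudo-spectrum at 20 ppm fragment tolerance. b/y ions
are considered at 1+ and 2+ (bounded by the precursor charge), Y ions at
1+ up to the precursor charge; theoretical ions outside the instrument
scan range (default 120–2000 m/z) are not counted as observable, and the
match-count ratios (`PepIonRatio`, `GlyIonRatio`) are defined over these
observable (ion, charge) pairs.

The subscores use a binomial surprisal: with n theoretical ions, k
matched, and p̂ the probability that a uniformly placed peak falls into
one of the n tolerance windows (summed window widths divided by the
spectrum span, floored at 1e-6 and capped at 0.5),

  score = −log10 P(X ≥ k), X ~ Binomial(n, p̂),

zero when k = 0 and strictly increasing in k. This functional form is a
declared replacement for the unpublished scoring of the delegated search
engine: it is deterministic, testable against a closed-form oracle, and
behaves sensibly under the spectrum sizes the simulator produces.
`TotalScore = w_pep·PepScore + w_gly·GlyScore` with default weights 1/1.
Only the rank-1 candidate per spectrum is reported (ties broken by
smaller precursor-mass delta, then candidate id).

FDR is controlled on both levels: at score threshold s,
FDR_p(s) = #(peptide-decoy GPSMs ≥ s)/#(targets ≥ s) (counting `both`),
FDR_g(s) analogously, and total FDR = FDR_p + FDR_g − FDR_p·FDR_g —
the inclusion–exclusion combination, declared because the source only
names a "total FDR". q-values are the running minimum of total FDR over
descending score. The default threshold is **2%**; the small-database
preset (`preset = "igm"`) additionally requires PepScore > 7 and
GlyScore > 8.

**Two-step search.** Round 1 searches the full database at 2% total FDR;
round 2 re-searches all spectra against exactly the proteins with an
accepted round-1 GPSM, again at 2%. The smaller round-2 decoy space
rescues low-stoichiometry glycoforms on already-identified proteins. FDR
is controlled per round (not jointly), matching the per-round thresholds
the method describes; both rounds are reported, along with glycoform keys
gained and lost.

## Quantification

Reporter intensities (6-plex channels 126–131; standard monoisotopic
m/z values, editable table) are extracted as the most intense peak within
0.003 Th of each channel from the MS3 scan(s) linked to the identified
MS2 scan, summed channel-wise when several MS3 scans exist, and read from
the MS2 scan itself in plain-MS2 mode. Propagation sums channel
intensities of all GPSMs of a glycoform (missed-cleavage, modification,
and charge variants), then of all glycoforms of a glycosite, and of all
glycoforms carrying a glycan — sums are conserved exactly at every level.
We sum intensities rather than average ratios when combining (the source
says only "combined"); summation conserves signal and weights ratios by
abundance. Ratios are taken against a configurable reference channel,
normalized by the per-channel median ratio of a matched proteomics
analysis, and regulation is called per channel on log2 normalized ratios:
z = (log2 r − mean)/SD across entries, regulated when z > 2 or z < −2.
Conditions with fewer than 3 finite entries or zero SD are flagged, not
called. No isotope-impurity correction is applied (declared non-goal).

## The simulator: what it emulates, and what it does not

`simulate_run()` generates a full scan hierarchy per analyte — an MS1
context scan with an averagine-like isotope envelope (by default 20% of
precursors are mis-reported one isotope up, exercising the correction), a
low-NCE MS2, SPS notch selection (top 10 in 700–2000 m/z, never reporter
peaks), and an MS3 with b/y ions (uniform-random 60–95% coverage) and the
reporter cluster. The stated world:

* **Y ions in MS2, b/y in MS3** — fragment classes separated by scan
  type as the acquisition design intends. The MS2 Y series is the
  stepwise trimming ladder (core HexNAc2Hex3 first, branches, NeuAc,
  Fuc last; one rung per lost residue, core rungs most intense), not the
  combinatorial sub-composition lattice: real low-NCE spectra show a
  sparse ladder, and emitting the full lattice would make every
  lattice-translated candidate score as well as the truth.
* **Channel design** — the six-channel mixing vector defaults to
  10:4:1:1:4:10; the contaminant design to 1:1:1:0:0:0 with total signal
  matched 1:1 to the analyte. Reporter channel c of a contaminated
  spectrum receives A·r_c + f·α·B·s_c, with f the co-isolated
  contaminant fraction and α the SPS carry-through (1 in MS2 mode,
  default 0.2 in MS3 mode, reflecting strong but imperfect
  purification).
* **Noise** — multiplicative log-normal with 10% CV on reporter
  intensities (additive floor available, off by default). Fragment
  intensities are always drawn randomly (log-normal); they carry no
  quantitative meaning.
* **Redundancy** — each simulated glycoform is observed as 6 GPSMs
  (charge states 2–4 and repeated sampling), the redundancy that makes
  glycoform-level summation meaningful; typical real datasets carry a
  handful of GPSMs per glycoform.
* **Scale realism** — true analytes are single-sequon tryptic peptides
  of ≤ 30 residues (multi-sequon peptides stay in the search space but
  are not simulated as truth, keeping the rank-1 answer unambiguous);
  precursors are isolated only at charges placing them within 400–1950
  m/z; fragments outside the 120–2000 m/z scan range are not recorded
  (b/y ions fall back to 2+ before being dropped).
* **Impostors** — for FDR benchmarking, spectra of analytes absent from
  any database: interior-shuffled peptides (mass-preserving) with glycan
  masses shifted by a continuous 5–50 Da offset, fragmented with their
  own consistent ion series. Because the peptide mass is preserved,
  impostors frequently land within precursor tolerance of real
  candidates with lattice-consistent Y alignments — a deliberately hard
  null for the decoy machinery.

Not emulated: chromatography and peak shapes, fragment isotope
envelopes and charge-state deconvolution, ion optics, isotope-impurity
cross-talk between channels, and the instrument's real co-isolation
statistics. A green end-to-end test therefore establishes that the
*processing* recovers what the *stated acquisition model* put in — it
says nothing about raw-file decoding or detector physics.

`simulate_interference_mixture()` wraps the six-channel design: two
synthetic carrier proteins (stand-ins for an IgM-like digest, generated,
not copied from any real sequence), contaminant interference confined to
channels 126–128, and two runs over the same analytes — SPS-MS3 mode and
plain-MS2 mode — so the interference attenuation can be compared
directly. With f = 0 and noise off the recovered median fold changes are
exactly 10 (131/129), 4 (130/129), and 2.5 (131/130).

## Numerical and design choices

* Masses are full-precision standard monoisotopic values; all mass
  arithmetic is checked against an independent summation oracle at
  1e-6 Da.
* Exact-duplicate peak m/z values are summed on load (canonical sorted
  representation); peak ties in SPS selection break by m/z.
* The candidate index is a binary search over the sorted neutral-mass
  vector (R's `findInterval` revalidates its arguments on every call,
  which dominates runtime on multi-million-row indexes).
* Score ties in FDR estimation share the cumulative decoy/target counts
  at the end of their score group.
* Config files are JSON (`jsonlite`), not YAML: the pipeline's contract
  (nested config, presets by name, flag overrides) does not depend on
  the markup language, and JSON support is part of the declared
  dependency set.
* `sample()`-based draws are all governed by a single seed per
  simulation; a fixed seed reproduces output files byte-identically.

## Known limitations

* The scoring function is not the delegated engine's unpublished
  formula; absolute score values are not comparable to that tool, only
  the FDR-controlled accepted sets are designed to be.
* Peptide decoys that lose their sequon upon reversal contribute no
  candidates, so the peptide-decoy space is smaller than the target
  space; the glycan-decoy space is size-matched, and the combined
  estimator remains conservative in the simulations shipped here.
* Site localization within multi-sequon peptides rests on rank-1
  enumeration of each site as a separate candidate; sites of equal
  evidence tie-break deterministically (lowest candidate id).
* mzML support covers centroided spectra with the standard CV terms
  (32/64-bit, zlib or plain); vendor raw files and profile data are out
  of scope.
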