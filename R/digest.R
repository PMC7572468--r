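#' Read a protein FASTA database
#'
#' Accession is the first whitespace-delimited token after `>`.
#'
#' @param path FASTA file.
#' @return A `data.table` with columns `accession`, `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("read_fasta: empty database: ", path)
  data.table::data.table(
    accession = vapply(strsplit(names(aa), "[ \t]"), `[[`, "", 1L),
    sequence = toupper(as.character(aa))
  )
}

#' Write a protein table as FASTA
#'
#' @param proteins `data.table` with `accession`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- proteins$accession
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @noRd
.check_protein <- function(sequence, accession = "?") {
  if (!nzchar(sequence))
    stop("protein ", accession, ": empty sequence")
  bad <- setdiff(strsplit(sequence, "")[[1]], names(mass_table()$residues))
  if (length(bad))
    stop("protein ", accession, ": non-standard residues: ",
         paste(unique(bad), collapse = ""))
  invisible(TRUE)
}

#' Fully specific tryptic digestion
#'
#' Cleaves after K/R except when followed by P, emitting all peptides with
#' up to `max_missed` missed cleavages and length >= `min_len`.
#' Deterministic order: by start position, then by missed-cleavage count.
#'
#' @param sequence protein sequence (uppercase one-letter amino acids).
#' @param accession protein accession carried into the output.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_len minimum peptide length (default 4).
#' @return A `data.table` with columns `peptide`, `protein`, `start_pos`
#'   (1-based residue index in the protein), `missed_cleavages`.
#' @export
tryptic_digest <- function(sequence, accession = "protein",
                           max_missed = 2L, min_len = 4L) {
  .check_protein(sequence, accession)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  # cut points: positions i such that cleavage occurs between i and i+1
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts < n & aa[cuts + 1L] != "P" | cuts == n]
  bounds <- c(0L, cuts[cuts < n], n)  # segment boundaries
  bounds <- sort(unique(bounds))
  nseg <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nseg)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nseg) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      if (end - start + 1L < min_len) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        peptide = substr(sequence, start, end), protein = accession,
        start_pos = start, missed_cleavages = m)
    }
  }
  if (!length(rows))
    return(data.table::data.table(peptide = character(), protein = character(),
                                  start_pos = integer(),
                                  missed_cleavages = integer()))
  dt <- data.table::rbindlist(rows)
  data.table::setorder(dt, start_pos, missed_cleavages)
  dt[]
}

#' Find N-glycosylation sequons in a peptide
#'
#' Returns 1-based positions within the peptide where the N-X-S/T motif
#' (X != P) holds. The motif is evaluated on the parent protein so sequons
#' whose S/T falls beyond the peptide's C-terminus are still detected.
#'
#' @param peptide peptide sequence.
#' @param protein_sequence full protein sequence containing the peptide.
#' @param start_pos 1-based position of the peptide in the protein; if NA
#'   the first occurrence is located (error when absent).
#' @return Integer vector of sequon positions within the peptide.
#' @export
find_sequons <- function(peptide, protein_sequence, start_pos = NA_integer_) {
  if (is.na(start_pos)) {
    start_pos <- regexpr(peptide, protein_sequence, fixed = TRUE)[1]
    if (start_pos < 0)
      stop("find_sequons: peptide '", peptide, "' not found in protein")
  }
  if (substr(protein_sequence, start_pos, start_pos + nchar(peptide) - 1L) != peptide)
    stop("find_sequons: peptide '", peptide, "' does not match protein at ",
         start_pos)
  aa <- strsplit(protein_sequence, "")[[1]]
  pos <- integer()
  for (k in seq_len(nchar(peptide))) {
    i <- start_pos + k - 1L          # protein coordinate of this residue
    if (aa[i] != "N") next
    if (i + 2L > length(aa)) next
    if (aa[i + 1L] != "P" && aa[i + 2L] %in% c("S", "T")) pos <- c(pos, k)
  }
  pos
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water, fixed carbamidomethyl on every C, one
#' isobaric label on the N-terminus plus one per lysine, and `n_ox`
#' oxidations (+15.99492 each) on methionine.
#'
#' @param peptide peptide sequence.
#' @param masses a [mass_table()].
#' @param label `"TMT6"`, `"TMT0"` or `"none"`.
#' @param n_ox number of oxidized methionines (0-3, must not exceed the
#'   number of M residues).
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(peptide, masses = mass_table(),
                         label = c("TMT6", "TMT0", "none"), n_ox = 0L) {
  label <- match.arg(label)
  aa <- strsplit(peptide, "")[[1]]
  if (!all(aa %in% names(masses$residues)))
    stop("peptide_mass: unknown residues in '", peptide, "'")
  if (n_ox > sum(aa == "M"))
    stop("peptide_mass: n_ox exceeds methionine count in '", peptide, "'")
  sum(masses$residues[aa]) + masses$water +
    sum(aa == "C") * masses$mods[["carbamidomethyl"]] +
    n_ox * masses$mods[["oxidation"]] +
    masses$labels[[label]] * (1 + sum(aa == "K"))
}

#' Enumerate b/y backbone fragment ions
#'
#' All b_k and y_k for k = 1..len-1, as neutral masses. Fixed
#' carbamidomethyl follows its cysteine; the N-terminal label contributes
#' to every b ion; lysine labels travel with the fragment containing the
#' K; oxidations are placed on the first `n_ox` methionines (N-terminal
#' placement convention, documented in the methods vignette).
#'
#' Convention: neutral(b_k) + neutral(y_{n-k}) = neutral peptide mass.
#'
#' @inheritParams peptide_mass
#' @return A `data.table` with columns `ion` (e.g. "b2", "y3"), `neutral`
#'   (Da).
#' @export
enumerate_by_ions <- function(peptide, masses = mass_table(),
                              label = c("TMT6", "TMT0", "none"), n_ox = 0L) {
  label <- match.arg(label)
  aa <- strsplit(peptide, "")[[1]]
  n <- length(aa)
  if (n < 2L) stop("enumerate_by_ions: peptide length must be >= 2")
  res <- masses$residues[aa]
  res <- res + (aa == "C") * masses$mods[["carbamidomethyl"]] +
    (aa == "K") * masses$labels[[label]]
  if (n_ox > 0L) {
    mpos <- which(aa == "M")
    if (n_ox > length(mpos))
      stop("enumerate_by_ions: n_ox exceeds methionine count")
    res[mpos[seq_len(n_ox)]] <- res[mpos[seq_len(n_ox)]] + masses$mods[["oxidation"]]
  }
  cum <- cumsum(res)
  total <- cum[n]
  b <- cum[seq_len(n - 1L)] + masses$labels[[label]]      # N-terminal label
  y <- total - cum[seq_len(n - 1L)] + masses$water
  data.table::data.table(
    ion = c(paste0("b", seq_len(n - 1L)), paste0("y", seq_len(n - 1L))),
    neutral = c(b, rev(y))
  )
}
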