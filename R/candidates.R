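#' Digest a protein database into sequon-bearing peptide entries
#'
#' Tryptic digestion of every protein, keeping peptides that contain at
#' least one N-X-S/T (X != P) sequon. Each retained (peptide, sequon)
#' pair becomes one row; oxidation variants (0..`max_ox` oxidized
#' methionines, bounded by the methionine count) are expanded as separate
#' entries so the candidate space covers the variable modification.
#'
#' @param proteins `data.table` with `accession`, `sequence` (see
#'   [read_fasta()]).
#' @param max_missed,min_len digestion parameters (defaults 2, 4).
#' @param max_ox maximum oxidized methionines per peptide (default 3).
#' @param masses a [mass_table()].
#' @param label isobaric label applied as fixed modification.
#' @return A `data.table` with one row per (peptide, site, n_ox):
#'   `peptide`, `protein`, `start_pos`, `missed_cleavages`, `site`
#'   (1-based within peptide), `site_protein` (1-based protein residue),
#'   `n_ox`, `pep_mass`, `pep_decoy` (FALSE).
#' @export
digest_proteome <- function(proteins, max_missed = 2L, min_len = 4L,
                            max_ox = 3L, masses = mass_table(),
                            label = "TMT6") {
  peps <- data.table::rbindlist(lapply(seq_len(nrow(proteins)), function(i) {
    tryptic_digest(proteins$sequence[i], proteins$accession[i],
                   max_missed, min_len)
  }))
  if (!nrow(peps)) return(.empty_peptide_entries())
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  rows <- vector("list", nrow(peps))
  for (i in seq_len(nrow(peps))) {
    sites <- find_sequons(peps$peptide[i], seqs[[peps$protein[i]]],
                          peps$start_pos[i])
    if (!length(sites)) next
    n_m <- lengths(regmatches(peps$peptide[i], gregexpr("M", peps$peptide[i])))
    rows[[i]] <- data.table::CJ(site = sites, n_ox = 0:min(max_ox, n_m))[
      , `:=`(peptide = peps$peptide[i], protein = peps$protein[i],
             start_pos = peps$start_pos[i],
             missed_cleavages = peps$missed_cleavages[i])]
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(.empty_peptide_entries())
  dt <- data.table::rbindlist(rows)
  dt[, site_protein := start_pos + site - 1L]
  dt[, pep_decoy := FALSE]
  # peptide mass per unique (peptide, n_ox)
  um <- unique(dt[, .(peptide, n_ox)])
  um[, pep_mass := vapply(seq_len(.N), function(j)
    peptide_mass(peptide[j], masses, label, n_ox[j]), 0)]
  dt <- um[dt, on = c("peptide", "n_ox")]
  data.table::setcolorder(dt, c("peptide", "protein", "start_pos",
                                "missed_cleavages", "site", "site_protein",
                                "n_ox", "pep_mass", "pep_decoy"))
  unique(dt)
}

#' @noRd
.empty_peptide_entries <- function() {
  data.table::data.table(peptide = character(), protein = character(),
                         start_pos = integer(), missed_cleavages = integer(),
                         site = integer(), site_protein = integer(),
                         n_ox = integer(), pep_mass = numeric(),
                         pep_decoy = logical())
}

#' @noRd
.reverse_keep_cterm <- function(p) {
  n <- nchar(p)
  if (n <= 2L) return(p)
  paste0(paste(rev(strsplit(substr(p, 1L, n - 1L), "")[[1]]), collapse = ""),
         substr(p, n, n))
}

#' Peptide-level decoys by sequence reversal
#'
#' One decoy per target entry: the sequence is reversed keeping the
#' C-terminal K/R in place (preserving tryptic character and mass), the
#' protein accession is prefixed `DECOY_`, and sequons are recomputed on
#' the reversed sequence (within-peptide motif; decoys without a sequon
#' produce no glycopeptide candidates). Decoys whose sequence collides
#' with any target peptide are dropped.
#'
#' @param peptide_entries output of [digest_proteome()].
#' @param masses a [mass_table()].
#' @param label isobaric label.
#' @return Decoy entries in the same layout, `pep_decoy = TRUE`.
#' @export
make_peptide_decoys <- function(peptide_entries, masses = mass_table(),
                                label = "TMT6") {
  targets <- unique(peptide_entries[, .(peptide, protein, start_pos,
                                        missed_cleavages)])
  target_seqs <- unique(peptide_entries$peptide)
  rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    dec <- .reverse_keep_cterm(targets$peptide[i])
    if (dec %in% target_seqs) next  # palindromic or colliding decoy
    sites <- .peptide_sequons(dec)
    if (!length(sites)) next
    n_m <- lengths(regmatches(dec, gregexpr("M", dec)))
    rows[[i]] <- data.table::CJ(site = sites, n_ox = 0:min(3L, n_m))[
      , `:=`(peptide = dec, protein = paste0("DECOY_", targets$protein[i]),
             start_pos = targets$start_pos[i],
             missed_cleavages = targets$missed_cleavages[i])]
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(.empty_peptide_entries())
  dt <- data.table::rbindlist(rows)
  dt[, site_protein := start_pos + site - 1L]
  dt[, pep_decoy := TRUE]
  um <- unique(dt[, .(peptide, n_ox)])
  um[, pep_mass := vapply(seq_len(.N), function(j)
    peptide_mass(peptide[j], masses, label, n_ox[j]), 0)]
  dt <- um[dt, on = c("peptide", "n_ox")]
  data.table::setcolorder(dt, names(.empty_peptide_entries()))
  unique(dt)
}

# within-peptide sequon motif (no protein context available for decoys)
#' @noRd
.peptide_sequons <- function(pep) {
  aa <- strsplit(pep, "")[[1]]
  n <- length(aa)
  which(aa == "N" & seq_along(aa) <= n - 2L &
          c(aa[-1], "") != "P" & c(aa[-(1:2)], "", "") %in% c("S", "T"))
}

#' Glycan-level decoys by fixed mass offset
#'
#' One decoy per library glycan, with all glycan-containing masses
#' (precursor and Y ions, but never Y0) shifted by `shift` Da. The shift
#' keeps the Y-ion count of a decoy identical to its target, so target
#' and decoy scores are comparable.
#'
#' @param glycans a glycan library table ([default_glycan_library()]).
#' @param shift decoy mass offset in Da (default +17.00274).
#' @return The library with `gly_mass` shifted and `gly_decoy = TRUE`.
#' @export
make_glycan_decoys <- function(glycans, shift = 17.00274) {
  dec <- data.table::copy(glycans)
  dec[, gly_mass := gly_mass + shift]
  dec[, gly_decoy := TRUE]
  dec[]
}

#' Build the glycopeptide candidate search space
#'
#' Cross product of peptide entries (targets + reversal decoys) and
#' glycan library (targets + mass-shift decoys), yielding the four decoy
#' classes `target`, `pep_decoy`, `gly_decoy`, `both`. Candidate neutral
#' mass = peptide mass + glycan mass (+ decoy shift for glycan decoys).
#'
#' @param proteins protein `data.table` (see [read_fasta()]).
#' @param glycans glycan library (default [default_glycan_library()]).
#' @param masses a [mass_table()].
#' @param label isobaric label (default `"TMT6"`).
#' @param max_missed,min_len,max_ox digestion/modification bounds.
#' @param decoy_shift glycan decoy offset (Da).
#' @param decoys include decoy classes (TRUE for searching; FALSE gives a
#'   target-only space).
#' @return A `data.table` of candidates with columns `cand_id`, peptide
#'   entry fields, glycan fields, `pep_decoy`, `gly_decoy`, `decoy_class`,
#'   `gly_shift`, `neutral_mass`.
#' @export
build_search_space <- function(proteins, glycans = default_glycan_library(),
                               masses = mass_table(), label = "TMT6",
                               max_missed = 2L, min_len = 4L, max_ox = 3L,
                               decoy_shift = 17.00274, decoys = TRUE) {
  tpep <- digest_proteome(proteins, max_missed, min_len, max_ox, masses, label)
  if (!nrow(tpep)) stop("build_search_space: no sequon-bearing peptides in database")
  peps <- if (decoys) {
    data.table::rbindlist(list(tpep, make_peptide_decoys(tpep, masses, label)))
  } else tpep
  gl <- data.table::copy(glycans)[, `:=`(gly_decoy = FALSE, gly_shift = 0)]
  if (decoys) {
    gd <- make_glycan_decoys(glycans, decoy_shift)[, gly_shift := decoy_shift]
    gl <- data.table::rbindlist(list(gl, gd), use.names = TRUE)
  }
  cand <- data.table::CJ(pi = seq_len(nrow(peps)), gi = seq_len(nrow(gl)))
  out <- cbind(peps[cand$pi], gl[cand$gi])
  out[, neutral_mass := pep_mass + gly_mass]
  out[, decoy_class := data.table::fcase(
    !pep_decoy & !gly_decoy, "target",
    pep_decoy & !gly_decoy, "pep_decoy",
    !pep_decoy & gly_decoy, "gly_decoy",
    default = "both")]
  data.table::setorder(out, neutral_mass, peptide, site, glycan, n_ox, decoy_class)
  out[, cand_id := .I]
  out[]
}

#' Candidate index for precursor-mass queries
#'
#' Binary-search index over candidate neutral masses. Querying at
#' tolerance t ppm returns exactly the candidates with |dm|/m <= t*1e-6
#' (set-equal to a linear scan).
#'
#' @param candidates output of [build_search_space()].
#' @return An object of class `CandidateIndex`.
#' @export
build_candidate_index <- function(candidates) {
  if (!nrow(candidates)) stop("build_candidate_index: empty candidate set")
  stopifnot(!is.unsorted(candidates$neutral_mass))
  structure(list(candidates = candidates, mass = candidates$neutral_mass),
            class = "CandidateIndex")
}

#' @rdname build_candidate_index
#' @param index a `CandidateIndex`.
#' @param neutral_mass query neutral mass (Da).
#' @param tol_ppm precursor tolerance in ppm.
#' @return `query_candidates()`: the matching candidate rows.
#' @export
query_candidates <- function(index, neutral_mass, tol_ppm) {
  r <- .mass_window(index$mass, neutral_mass, tol_ppm)
  if (r[2] < r[1]) return(index$candidates[0])
  index$candidates[r[1]:r[2]]
}

# binary search bounds on a sorted vector without findInterval's per-call
# NA/sortedness validation (the index holds millions of masses)
#' @noRd
.bsearch_le <- function(v, x) {
  lo <- 0L; hi <- length(v)
  while (lo < hi) {               # count of elements <= x
    mid <- (lo + hi + 1L) %/% 2L
    if (v[mid] <= x) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' @noRd
.bsearch_lt <- function(v, x) {
  lo <- 0L; hi <- length(v)
  while (lo < hi) {               # count of elements < x
    mid <- (lo + hi + 1L) %/% 2L
    if (v[mid] < x) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' @noRd
.mass_window <- function(mass, neutral_mass, tol_ppm) {
  tol <- neutral_mass * tol_ppm * 1e-6
  c(.bsearch_lt(mass, neutral_mass - tol) + 1L,
    .bsearch_le(mass, neutral_mass + tol))
}
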