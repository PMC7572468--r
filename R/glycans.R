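#' Glycan composition helpers
#'
#' Glycans are handled at the composition level: counts of hexose (Hex),
#' N-acetylhexosamine (HexNAc), sialic acid (NeuAc) and fucose (Fuc).
#' The canonical string form `"Hex(h)HexNAc(n)NeuAc(s)Fuc(f)"` is used in
#' all outputs.
#'
#' @param hex,hexnac,neuac,fuc monosaccharide counts (>= 0, not all zero).
#' @return `glycan_composition()`: a named integer vector of class
#'   `GlycanComposition`.
#' @export
glycan_composition <- function(hex = 0L, hexnac = 0L, neuac = 0L, fuc = 0L) {
  g <- c(hex = as.integer(hex), hexnac = as.integer(hexnac),
         neuac = as.integer(neuac), fuc = as.integer(fuc))
  if (any(g < 0)) stop("glycan_composition: negative counts")
  if (all(g == 0)) stop("glycan_composition: empty composition")
  structure(g, class = "GlycanComposition")
}

#' @rdname glycan_composition
#' @param g a composition (named vector or `GlycanComposition`).
#' @export
glycan_string <- function(g) {
  sprintf("Hex(%d)HexNAc(%d)NeuAc(%d)Fuc(%d)",
          g[["hex"]], g[["hexnac"]], g[["neuac"]], g[["fuc"]])
}

#' @rdname glycan_composition
#' @param masses a [mass_table()].
#' @export
glycan_mass <- function(g, masses = mass_table()) {
  sum(masses$mono * as.numeric(g[c("hex", "hexnac", "neuac", "fuc")]))
}

#' Default glycan composition library
#'
#' All compositions with Hex 3-12, HexNAc 2-7, NeuAc 0-4, Fuc 0-3 whose
#' total residue count is at most 18 — spanning the small paucimannose to
#' large sialylated N-glycans (most biological N-glycans carry 8-14
#' monosaccharides). Shipped as an editable TSV with columns hex, hexnac,
#' neuac, fuc (see `system.file("extdata", "glycans_default.tsv",
#' package = "glycoquant")`).
#'
#' @param max_total maximum total monosaccharide count (default 18).
#' @return A `data.table` with columns `hex`, `hexnac`, `neuac`, `fuc`,
#'   `glycan` (canonical string), `gly_mass` (Da).
#' @export
default_glycan_library <- function(max_total = 18L) {
  dt <- data.table::CJ(hex = 3:12, hexnac = 2:7, neuac = 0:4, fuc = 0:3)
  dt <- dt[hex + hexnac + neuac + fuc <= max_total]
  .finish_glycan_library(dt)
}

#' @noRd
.finish_glycan_library <- function(dt) {
  masses <- mass_table()
  dt[, glycan := sprintf("Hex(%d)HexNAc(%d)NeuAc(%d)Fuc(%d)", hex, hexnac, neuac, fuc)]
  dt[, gly_mass := hex * masses$mono[["hex"]] + hexnac * masses$mono[["hexnac"]] +
       neuac * masses$mono[["neuac"]] + fuc * masses$mono[["fuc"]]]
  data.table::setorder(dt, gly_mass)
  dt[]
}

#' Read / write a glycan library TSV
#'
#' @param path TSV with columns `hex`, `hexnac`, `neuac`, `fuc`.
#' @return A glycan library `data.table` (as [default_glycan_library()]).
#' @export
read_glycan_library <- function(path) {
  dt <- data.table::fread(path)
  need <- c("hex", "hexnac", "neuac", "fuc")
  if (!all(need %in% names(dt)))
    stop("read_glycan_library: columns required: ", paste(need, collapse = ", "))
  .finish_glycan_library(dt[, .(hex = as.integer(hex), hexnac = as.integer(hexnac),
                                neuac = as.integer(neuac), fuc = as.integer(fuc))])
}

#' @rdname read_glycan_library
#' @param lib a glycan library table.
#' @export
write_glycan_library <- function(lib, path) {
  data.table::fwrite(lib[, .(hex, hexnac, neuac, fuc)], path, sep = "\t")
  invisible(path)
}

# Sub-compositions g' <= g (component-wise) satisfying glycan attachment:
# the reducing-end residue is a HexNAc, so hexnac' >= 1 whenever anything
# else is present, and a sialic acid requires at least one hexose to sit
# on (neuac' > 0 => hex' >= 1). Includes the empty composition (= Y0).
#' @noRd
.sub_compositions <- function(g) {
  dt <- data.table::CJ(hex = 0:g[["hex"]], hexnac = 0:g[["hexnac"]],
                       neuac = 0:g[["neuac"]], fuc = 0:g[["fuc"]])
  dt[(hexnac >= 1 | (hex == 0 & neuac == 0 & fuc == 0)) &
       (neuac == 0 | hex >= 1)]
}

#' Enumerate the glycan Y-ion series of a candidate
#'
#' Y ions retain the intact peptide backbone plus a glycan remnant; Y0 is
#' the bare (labelled, modified) peptide. The series contains one ion per
#' attachment-rule-satisfying sub-composition of the glycan (see the
#' methods vignette), deduplicated by mass and sorted ascending.
#'
#' For glycan-decoy candidates the decoy mass offset is added to every
#' glycan-containing ion but never to Y0.
#'
#' @param pep_mass neutral peptide mass (Da), e.g. from [peptide_mass()].
#' @param glycan named counts (`hex`, `hexnac`, `neuac`, `fuc`).
#' @param masses a [mass_table()].
#' @param decoy_shift mass offset (Da) applied to glycan-containing ions
#'   (0 for targets).
#' @return A `data.table` with columns `ion` (canonical remnant string,
#'   "Y0" for the bare peptide), `neutral` (Da).
#' @export
enumerate_y_ions <- function(pep_mass, glycan, masses = mass_table(),
                             decoy_shift = 0) {
  sub <- .sub_compositions(glycan)
  delta <- sub$hex * masses$mono[["hex"]] + sub$hexnac * masses$mono[["hexnac"]] +
    sub$neuac * masses$mono[["neuac"]] + sub$fuc * masses$mono[["fuc"]]
  lab <- ifelse(delta == 0, "Y0",
                sprintf("Y-Hex(%d)HexNAc(%d)NeuAc(%d)Fuc(%d)",
                        sub$hex, sub$hexnac, sub$neuac, sub$fuc))
  neutral <- pep_mass + delta + ifelse(delta == 0, 0, decoy_shift)
  dt <- data.table::data.table(ion = lab, neutral = neutral)
  dt <- dt[!duplicated(signif(neutral, 12))]
  data.table::setorder(dt, neutral)
  dt[]
}
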