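#' Monoisotopic mass table
#'
#' Builds the table of constants used by every mass computation in the
#' package: amino-acid residue masses, water and proton masses, the
#' monosaccharide residue masses that define glycan compositions, fixed and
#' variable modification masses, and the isobaric-label masses added to
#' peptide N-termini and lysine side chains.
#'
#' All values are standard monoisotopic masses in Dalton. Carbamidomethyl
#' (+57.02146) is applied as a fixed modification on cysteine; oxidation
#' (+15.99492) is the variable modification on methionine.
#'
#' @return A list with components `residues` (named numeric, one per
#'   amino-acid letter), `water`, `proton`, `c13` (the 13C-12C mass
#'   difference used for isotope spacing), `mono` (named numeric: `hex`,
#'   `hexnac`, `neuac`, `fuc`), `mods` (named numeric: `carbamidomethyl`,
#'   `oxidation`), and `labels` (named numeric: `TMT6`, `TMT0`, `none`).
#' @export
#' @examples
#' mt <- mass_table()
#' mt$residues[["G"]] + mt$water  # neutral mass of glycine
mass_table <- function() {
  residues <- c(
    G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276385,
    V = 99.06841391, T = 101.04767846, C = 103.00918496, L = 113.08406398,
    I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
    K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
    F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
  )
  list(
    residues = residues,
    water  = 18.010564684,
    proton = 1.007276467,
    c13    = 1.0033548,
    mono   = c(hex = 162.05282, hexnac = 203.07937,
               neuac = 291.09542, fuc = 146.05791),
    mods   = c(carbamidomethyl = 57.02146, oxidation = 15.99492),
    labels = c(TMT6 = 229.16293, TMT0 = 224.15248, none = 0)
  )
}

#' @noRd
.ppm <- function(a, b) abs(a - b) / b * 1e6

#' Parts-per-million distance helpers
#'
#' `ppm_diff()` returns the absolute relative difference between two m/z
#' values in parts per million (denominator `b`); `within_ppm()` tests it
#' against a tolerance.
#'
#' @param a,b m/z values (Th).
#' @param tol_ppm tolerance in parts per million.
#' @return Numeric ppm distance, or logical.
#' @export
ppm_diff <- function(a, b) .ppm(a, b)

#' @rdname ppm_diff
#' @export
within_ppm <- function(a, b, tol_ppm) .ppm(a, b) <= tol_ppm
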