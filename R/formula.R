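# Elemental formula from composition counts. The scaffold bases are the fully
# saturated unsubstituted skeletons: Cn acid = CnH(2n-8)O2 (e.g. C24H40O2,
# cholanoic acid), C27 alcohol = C27H48O (cholestanol, terminal hydroxyl
# included in the base). Each extra hydroxyl adds O; each oxo adds O and
# removes 2 H; each double bond removes 2 H. Only the final substituent set
# matters (an oxo derived from a hydroxyl is not distinguished from one added
# de novo).
.CONJUGATE_ADDITIONS <- list(
  none = c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L),
  glycine = c(C = 2L, H = 3L, N = 1L, O = 1L, S = 0L),  # amide, -H2O
  taurine = c(C = 2L, H = 5L, N = 1L, O = 2L, S = 1L),  # amide, -H2O
  sulfate = c(C = 0L, H = 0L, N = 0L, O = 3L, S = 1L)   # ester, -H2O
)

formula_from_counts <- function(carbon_count, terminal_group, n_hydroxyl,
                                n_oxo, n_double_bond, conjugation) {
  if (!carbon_count %in% c(23L, 24L, 27L)) {
    stop("unsupported scaffold size: C", carbon_count)
  }
  if (terminal_group == "acid") {
    f <- c(C = carbon_count, H = 2L * carbon_count - 8L, N = 0L, O = 2L, S = 0L)
  } else {
    if (carbon_count != 27L) stop("bile alcohols are C27 only")
    f <- c(C = carbon_count, H = 2L * carbon_count - 6L, N = 0L, O = 1L, S = 0L)
  }
  f["O"] <- f["O"] + n_hydroxyl + n_oxo
  f["H"] <- f["H"] - 2L * (n_oxo + n_double_bond)
  f <- f + .CONJUGATE_ADDITIONS[[conjugation]]
  if (f["H"] < 0L) stop("impossible composition: negative hydrogen count")
  f
}

#' Elemental formula of a bile salt
#'
#' Builds the molecular formula by arithmetic from the saturated scaffold base
#' (C24 acid C24H40O2; C27 acid C27H46O2; C27 alcohol C27H48O, terminal
#' hydroxyl included), adding O per hydroxyl, O and -2H per oxo, -2H per
#' double bond, and the conjugate residue (glycine amide +C2H3NO, taurine
#' amide +C2H5NO2S, sulfate ester +SO3).
#'
#' @param d A [bile_salt()] descriptor.
#' @return Named integer vector with elements `C`, `H`, `N`, `O`, `S`
#'   (zero counts retained).
#' @examples
#' molecular_formula(parse_bile_salt_name("cholic acid")) # C24 H40 O5
#' @export
molecular_formula <- function(d) {
  stopifnot(inherits(d, "bile_salt"))
  n_oh <- nrow(d$hydroxyls)
  if (d$terminal_group == "alcohol") n_oh <- n_oh - 1L  # terminal OH is in the base
  formula_from_counts(d$carbon_count, d$terminal_group, n_oh,
                      length(d$oxo), length(d$double_bonds), d$conjugation)
}

#' Format an elemental formula as a Hill-style string
#'
#' @param formula Named integer vector as from [molecular_formula()].
#' @return String such as `"C24H40O5"`.
#' @export
format_formula <- function(formula) {
  keep <- formula[formula > 0]
  keep <- keep[order(match(names(keep), c("C", "H", "N", "O", "S")))]
  paste0(names(keep), ifelse(keep > 1, keep, ""), collapse = "")
}

#' Monoisotopic m/z of the deprotonated molecular ion
#'
#' The [M-H]- ion observed in negative-mode electrospray: monoisotopic mass of
#' the molecular formula minus one proton (1.007276 u).
#'
#' @param d A [bile_salt()] descriptor.
#' @return m/z in Th (Dalton per unit charge).
#' @examples
#' mz_mh_minus(parse_bile_salt_name("cholic acid")) # 407.2803
#' @export
mz_mh_minus <- function(d) {
  formula_mass(molecular_formula(d)) - .PROTON_MASS
}
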