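# Monoisotopic atomic masses (u), single embedded table so that every mass in
# the package derives from one source. Values to 6 decimals.
.MONOISOTOPIC <- c(
  C = 12.000000,
  H = 1.007825,
  N = 14.003074,
  O = 15.994915,
  S = 31.972071
)

# Mass of a proton; subtracted for the [M-H]- ion.
.PROTON_MASS <- 1.007276

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Named integer vector of element counts with names among
#'   `C`, `H`, `N`, `O`, `S` (as returned by [molecular_formula()]).
#' @return Monoisotopic mass in u.
#' @examples
#' formula_mass(c(C = 24, H = 40, O = 5)) # cholic acid
#' @export
formula_mass <- function(formula) {
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  bad <- setdiff(names(formula), names(.MONOISOTOPIC))
  if (length(bad)) {
    stop("unknown element(s) in formula: ", paste(bad, collapse = ", "))
  }
  sum(formula * .MONOISOTOPIC[names(formula)])
}
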