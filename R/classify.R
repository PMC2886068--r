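#' Broad compound type of a bile salt
#'
#' Assigns one of the three broad types used throughout comparative bile-salt
#' work — C27 bile alcohols, C27 bile acids, C24 bile acids — from skeleton
#' size and side-chain terminal group. Everything else (notably C23 acids) is
#' `"other"`.
#'
#' @param d A [bile_salt()] descriptor.
#' @return One of `"C27_alcohol"`, `"C27_acid"`, `"C24_acid"`, `"other"`.
#' @examples
#' classify_type(parse_bile_salt_name("cholic acid")) # "C24_acid"
#' @export
classify_type <- function(d) {
  stopifnot(inherits(d, "bile_salt"))
  if (d$carbon_count == 27L && d$terminal_group == "alcohol") return("C27_alcohol")
  if (d$carbon_count == 27L && d$terminal_group == "acid") return("C27_acid")
  if (d$carbon_count == 24L && d$terminal_group == "acid") return("C24_acid")
  "other"
}

.COMPOUND_TYPES <- c("C27_alcohol", "C27_acid", "C24_acid")

has_oh <- function(d, position, orientation = NULL) {
  i <- which(d$hydroxyls$position == position)
  if (!length(i)) return(FALSE)
  if (is.null(orientation)) return(TRUE)
  d$hydroxyls$orientation[i] == orientation
}

#' Flag unusual structural modifications
#'
#' Returns the set of rare-modification flags whose structural predicate holds
#' for a descriptor: the 5-alpha ("allo") ring junction, hydroxylation at
#' unusual positions (1, 6, 15, 16, 22 on C27 skeletons, 23R, 25), the
#' 7-beta hydroxyl of ursodeoxycholic acid, a 7-oxo group, Delta-22
#' unsaturation, and 7-deoxy bile salts (no hydroxyl and no oxo at C-7, a
#' pattern normally produced only by gut bacteria, not by the liver).
#'
#' @param d A [bile_salt()] descriptor.
#' @return Character vector (possibly empty) of flags among `allo_5a`,
#'   `oh_1a`, `oh_1b`, `oh_6a`, `oh_6b`, `oxo_7`, `oh_15a`, `oh_16a`,
#'   `udca_7b`, `delta22`, `oh_22_C27`, `oh_23R`, `deoxy_7`, `oh_25`.
#' @examples
#' flag_unusual(parse_bile_salt_name("pythocholic acid")) # deoxy_7, oh_16a
#' @export
flag_unusual <- function(d) {
  stopifnot(inherits(d, "bile_salt"))
  flags <- character()
  if (d$junction == "5a") flags <- c(flags, "allo_5a")
  if (has_oh(d, 1L, "a")) flags <- c(flags, "oh_1a")
  if (has_oh(d, 1L, "b")) flags <- c(flags, "oh_1b")
  if (has_oh(d, 6L, "a")) flags <- c(flags, "oh_6a")
  if (has_oh(d, 6L, "b")) flags <- c(flags, "oh_6b")
  if (7L %in% d$oxo) flags <- c(flags, "oxo_7")
  if (has_oh(d, 15L, "a")) flags <- c(flags, "oh_15a")
  if (has_oh(d, 16L, "a")) flags <- c(flags, "oh_16a")
  if (has_oh(d, 7L, "b")) flags <- c(flags, "udca_7b")
  if (22L %in% d$double_bonds) flags <- c(flags, "delta22")
  if (d$carbon_count == 27L && has_oh(d, 22L)) flags <- c(flags, "oh_22_C27")
  if (has_oh(d, 23L, "R")) flags <- c(flags, "oh_23R")
  if (!has_oh(d, 7L) && !(7L %in% d$oxo)) flags <- c(flags, "deoxy_7")
  if (has_oh(d, 25L)) flags <- c(flags, "oh_25")
  flags
}
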