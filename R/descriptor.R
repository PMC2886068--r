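#' Structural descriptor for a bile salt
#'
#' A `bile_salt` object captures the structural features of one bile alcohol or
#' bile acid that matter for classification and mass computation: skeleton size
#' (total carbons), terminal group of the side chain, A/B ring-junction
#' stereochemistry, hydroxyl substituents with orientation, oxo groups,
#' side-chain/nuclear double bonds, and conjugation state.
#'
#' Nuclear hydroxyl orientations are given as `a` (alpha, below the ring plane)
#' or `b` (beta, above); side-chain stereocentres use `R`/`S` as conventional
#' for positions 22-25; an empty string means unspecified (used for the
#' terminal hydroxyl of bile alcohols). For bile alcohols the hydroxyl at the
#' terminal carbon is part of the definition and is always present in
#' `hydroxyls`.
#'
#' @param carbon_count Total skeleton carbons: 23, 24 or 27.
#' @param terminal_group `"acid"` (side chain ends in -COOH) or `"alcohol"`
#'   (ends in -CH2OH).
#' @param junction A/B ring junction: `"5a"` (trans/allo), `"5b"` (cis) or
#'   `"unknown"`.
#' @param hydroxyls Character vector of position+orientation tokens, e.g.
#'   `c("3a", "7a", "12a")`, `"24R"`, or `"27"` (unspecified orientation).
#' @param oxo Integer vector of oxo (ketone) positions.
#' @param double_bonds Integer vector of double-bond positions (the lower
#'   carbon, e.g. `22` for a Delta-22 bond).
#' @param conjugation `"none"`, `"glycine"`, `"taurine"` or `"sulfate"`.
#' @param trivial_name Optional trivial name (e.g. `"cholic acid"`); ignored
#'   when descriptors are compared.
#' @return An object of class `bile_salt`.
#' @examples
#' bile_salt(24, "acid", "5b", c("3a", "7a", "12a"), trivial_name = "cholic acid")
#' @seealso [parse_bile_salt_name()], [render_bile_salt_name()]
#' @export
bile_salt <- function(carbon_count,
                      terminal_group = c("acid", "alcohol"),
                      junction = c("5b", "5a", "unknown"),
                      hydroxyls = character(),
                      oxo = integer(),
                      double_bonds = integer(),
                      conjugation = c("none", "glycine", "taurine", "sulfate"),
                      trivial_name = NA_character_) {
  terminal_group <- match.arg(terminal_group)
  junction <- match.arg(junction)
  conjugation <- match.arg(conjugation)
  carbon_count <- as.integer(carbon_count)

  oh <- parse_hydroxyl_tokens(hydroxyls)
  oxo <- sort(unique(as.integer(oxo)))
  double_bonds <- sort(unique(as.integer(double_bonds)))

  if (terminal_group == "alcohol" && !carbon_count %in% oh$position) {
    # terminal hydroxyl is implied by the alcohol terminal group
    oh <- rbind(oh, data.frame(position = carbon_count, orientation = "",
                               stringsAsFactors = FALSE))
  }
  oh <- oh[order(oh$position), , drop = FALSE]
  rownames(oh) <- NULL

  d <- structure(
    list(
      carbon_count = carbon_count,
      terminal_group = terminal_group,
      junction = junction,
      hydroxyls = oh,
      oxo = oxo,
      double_bonds = double_bonds,
      conjugation = conjugation,
      trivial_name = trivial_name
    ),
    class = "bile_salt"
  )
  validate_bile_salt(d)
  d
}

# "3a" -> (3, "a"); "24R" -> (24, "R"); "27" -> (27, "")
parse_hydroxyl_tokens <- function(tokens) {
  tokens <- as.character(tokens)
  if (!length(tokens)) {
    return(data.frame(position = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(tokens, regexec("^([0-9]+)([abRS]?)$", tokens))
  bad <- tokens[vapply(m, length, 1L) == 0L]
  if (length(bad)) {
    stop("invalid hydroxyl token(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    position = as.integer(vapply(m, `[`, "", 2L)),
    orientation = vapply(m, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$position)) {
    stop("duplicate hydroxyl position(s): ",
         paste(out$position[duplicated(out$position)], collapse = ", "))
  }
  out
}

validate_bile_salt <- function(d) {
  if (!d$carbon_count %in% c(23L, 24L, 27L)) {
    stop("unsupported scaffold size: C", d$carbon_count,
         " (supported: C23, C24, C27)")
  }
  pos <- c(d$hydroxyls$position, d$oxo, d$double_bonds)
  if (length(pos) && (any(pos < 1L) || any(pos > d$carbon_count))) {
    stop("substituent position outside 1..", d$carbon_count, ": ",
         paste(pos[pos < 1L | pos > d$carbon_count], collapse = ", "))
  }
  clash <- intersect(d$hydroxyls$position, d$oxo)
  if (length(clash)) {
    stop("position(s) both hydroxylated and oxo: ",
         paste(clash, collapse = ", "))
  }
  if (d$carbon_count %in% c(23L, 24L) && d$terminal_group != "acid") {
    stop("C", d$carbon_count, " bile salts must be acids ",
         "(bile alcohols retain the full C27 skeleton)")
  }
  invisible(d)
}

#' Canonical name for a bile-salt descriptor
#'
#' Renders the ASCII canonical systematic name: Greek orientations as `a`/`b`,
#' conjugation as a `glyco-`/`tauro-` prefix or ` sulfate` suffix, double bonds
#' as leading `deltaN` tokens, and the C23 skeleton as `norcholan`. The output
#' re-parses to an equal descriptor ([parse_bile_salt_name()] round trip).
#'
#' @param d A [bile_salt()] descriptor.
#' @return A single string.
#' @examples
#' render_bile_salt_name(bile_salt(24, "acid", "5b", c("3a", "7a")))
#' @export
render_bile_salt_name <- function(d) {
  stopifnot(inherits(d, "bile_salt"))
  mult <- c("", "di", "tri", "tetra", "penta", "hexa", "hepta", "octa")
  parts <- character()
  for (p in d$double_bonds) parts <- c(parts, paste0("delta", p))
  if (nrow(d$hydroxyls)) {
    toks <- paste0(d$hydroxyls$position, d$hydroxyls$orientation)
    parts <- c(parts, paste(toks, collapse = ","),
               paste0(mult[nrow(d$hydroxyls)], "hydroxy"))
  }
  if (length(d$oxo)) {
    parts <- c(parts, paste(d$oxo, collapse = ","),
               paste0(mult[length(d$oxo)], "oxo"))
  }
  if (d$junction != "unknown") parts <- c(parts, d$junction)
  skeleton <- switch(as.character(d$carbon_count),
                     "23" = "norcholan", "24" = "cholan", "27" = "cholestan")
  parts <- c(parts, skeleton)
  name <- paste(parts, collapse = "-")
  if (d$terminal_group == "acid") {
    name <- paste0(name, "-", d$carbon_count, "-oic acid")
  }
  prefix <- switch(d$conjugation, glycine = "glyco-", taurine = "tauro-", "")
  suffix <- if (d$conjugation == "sulfate") " sulfate" else ""
  paste0(prefix, name, suffix)
}

#' @export
print.bile_salt <- function(x, ...) {
  type <- classify_type(x)
  cat("<bile_salt> ", render_bile_salt_name(x), "\n", sep = "")
  if (!is.na(x$trivial_name)) cat("  trivial name: ", x$trivial_name, "\n", sep = "")
  cat("  type: ", type, "\n", sep = "")
  invisible(x)
}

# Canonical identity string; trivial_name excluded so equality is structural.
descriptor_key <- function(d) {
  render_bile_salt_name(d)
}

#' Structural equality of two descriptors
#'
#' Compares everything except the trivial name.
#'
#' @param a,b [bile_salt()] descriptors.
#' @return Logical scalar.
#' @export
same_bile_salt <- function(a, b) {
  descriptor_key(a) == descriptor_key(b)
}

# The aglycone: same structure with conjugation stripped. Profile-class
# aggregation is aglycone-based (a glycine- and a taurine-conjugate of the
# same acid are the same compound for classification).
unconjugated <- function(d) {
  if (d$conjugation == "none") return(d)
  d$conjugation <- "none"
  d
}
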