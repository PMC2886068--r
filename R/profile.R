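#' A species' biliary bile-salt composition
#'
#' Bundles one species' bile-salt profile: the component descriptors with
#' their percent of the total biliary pool, plus taxonomy and diet. Percents
#' are of total biliary bile salts; they may sum to less than 100 (the
#' remainder is unidentified material) but not materially more.
#'
#' @param species Binomial species name.
#' @param components List of [bile_salt()] descriptors.
#' @param percents Numeric vector (same length), each in \[0, 100\].
#' @param family,order_group Taxonomy labels.
#' @param diet `"carnivore"`, `"herbivore"`, `"omnivore"` or `NA` (unknown).
#' @param approximate Logical vector flagging percents transcribed as
#'   approximate (`~100`); defaults to all `FALSE`.
#' @param check_total If `TRUE` (default), error when percents sum above
#'   100 + 0.5.
#' @return Object of class `species_profile`.
#' @export
species_profile <- function(species, components, percents,
                            family = NA_character_,
                            order_group = NA_character_,
                            diet = NA_character_,
                            approximate = NULL,
                            check_total = TRUE) {
  stopifnot(is.list(components),
            all(vapply(components, inherits, TRUE, "bile_salt")),
            length(components) == length(percents))
  percents <- as.numeric(percents)
  if (any(percents < 0 | percents > 100)) {
    stop("component percents must lie in [0, 100] (species ", species, ")")
  }
  if (check_total && sum(percents) > 100.5) {
    stop("component percents sum to ", round(sum(percents), 1),
         " > 100 for species ", species)
  }
  keys <- vapply(components, descriptor_key, "")
  if (anyDuplicated(keys)) {
    stop("duplicate bile-salt component(s) in profile of ", species, ": ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  }
  if (is.null(approximate)) approximate <- rep(FALSE, length(percents))
  diet <- if (length(diet) != 1 || is.na(diet)) NA_character_ else as.character(diet)
  if (!is.na(diet) && !diet %in% c("carnivore", "herbivore", "omnivore")) {
    stop("unknown diet label: ", diet)
  }
  structure(
    list(species = species, family = family, order_group = order_group,
         diet = diet, components = components, percents = percents,
         approximate = approximate),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile> ", x$species,
      if (!is.na(x$family)) paste0(" (", x$family, ")"), "\n", sep = "")
  for (i in seq_along(x$components)) {
    nm <- x$components[[i]]$trivial_name
    if (is.na(nm)) nm <- render_bile_salt_name(x$components[[i]])
    cat(sprintf("  %5.1f%%  %s\n", x$percents[i], nm))
  }
  invisible(x)
}

#' Aggregate percent per broad compound type
#'
#' Sums component percents by [classify_type()], ignoring conjugation state
#' (a glycine- and a taurine-conjugate of the same acid count toward the same
#' aglycone type) and ignoring `"other"` compounds for the three named types.
#'
#' @param p A [species_profile()].
#' @return Named numeric vector over `C27_alcohol`, `C27_acid`, `C24_acid`,
#'   `other`.
#' @export
type_aggregates <- function(p) {
  stopifnot(inherits(p, "species_profile"))
  agg <- c(C27_alcohol = 0, C27_acid = 0, C24_acid = 0, other = 0)
  for (i in seq_along(p$components)) {
    t <- classify_type(p$components[[i]])
    agg[t] <- agg[t] + p$percents[i]
  }
  agg
}

# The class rule as a pure function of the three type aggregates (percents of
# the total pool; the 10% threshold is inclusive and absolute).
class_from_aggregates <- function(alcohol, c27_acid, c24_acid) {
  present <- c(alcohol >= 10, c27_acid >= 10, c24_acid >= 10)
  key <- paste(ifelse(present, "1", "0"), collapse = "")
  switch(key,
         "100" = "I", "110" = "II", "101" = "III",
         "010" = "IV", "011" = "V", "001" = "VI",
         "111" = "mixed",
         NA_character_)
}

#' Profile class (I-VI) of a species
#'
#' Classifies a species by which of the three broad compound types reach 10%
#' or more of the biliary pool: I = C27 alcohols only; II = alcohols + C27
#' acids; III = alcohols + C24 acids; IV = C27 acids only; V = C27 + C24
#' acids; VI = C24 acids only. Profiles where all three types reach 10% get
#' the extra label `"mixed"` (the one-or-two-types scheme does not cover
#' them). Reported percents are used as-is, with no renormalization for
#' unidentified material.
#'
#' @param p A [species_profile()] with at least one positive component.
#' @return One of `"I"` ... `"VI"`, `"mixed"`.
#' @export
assign_class <- function(p) {
  stopifnot(inherits(p, "species_profile"))
  if (!length(p$components) || all(p$percents <= 0)) {
    stop("profile of ", p$species, " has no positive component")
  }
  agg <- type_aggregates(p)
  cls <- class_from_aggregates(agg["C27_alcohol"], agg["C27_acid"], agg["C24_acid"])
  if (is.na(cls)) {
    stop("profile of ", p$species,
         " cannot be classified: no compound type reaches 10% of the pool")
  }
  cls
}

#' Is a bile-salt profile complex?
#'
#' A profile is complex when it includes two (or more) of the broad compound
#' types at >= 10% each, and/or three or more individual bile salts each at
#' >= 10% of total biliary bile salts.
#'
#' @param p A [species_profile()].
#' @return Logical scalar.
#' @export
is_complex <- function(p) {
  stopifnot(inherits(p, "species_profile"))
  agg <- type_aggregates(p)[.COMPOUND_TYPES]
  sum(agg >= 10) >= 2 || sum(p$percents >= 10) >= 3
}

#' Major / minor / trace partition of profile components
#'
#' Major bile salts constitute more than 50% of total biliary bile salts;
#' minor ones more than 10% but at most 50%; the rest are trace. At most one
#' component can be major (ties at exactly 50% are all minor).
#'
#' @param p A [species_profile()].
#' @return List with elements `major`, `minor`, `trace`, each an integer
#'   vector of component indices into `p$components`.
#' @export
major_minor <- function(p) {
  stopifnot(inherits(p, "species_profile"))
  list(
    major = which(p$percents > 50),
    minor = which(p$percents > 10 & p$percents <= 50),
    trace = which(p$percents <= 10)
  )
}
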