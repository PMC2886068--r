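#' Diet category from raw diet fractions
#'
#' Carnivore when the diet is more than 90% meat, herbivore when more than
#' 90% plant matter, omnivore otherwise.
#'
#' @param percent_meat,percent_plant Percents in \[0, 100\], summing to at
#'   most 100.
#' @return `"carnivore"`, `"herbivore"` or `"omnivore"`.
#' @examples
#' assign_diet(95, 5)  # carnivore
#' assign_diet(50, 50) # omnivore
#' @export
assign_diet <- function(percent_meat, percent_plant) {
  if (!is.numeric(percent_meat) || !is.numeric(percent_plant) ||
      any(c(percent_meat, percent_plant) < 0) ||
      any(c(percent_meat, percent_plant) > 100)) {
    stop("diet percents must lie in [0, 100]")
  }
  if (percent_meat + percent_plant > 100 + 1e-9) {
    stop("diet percents sum above 100")
  }
  if (percent_meat > 90) return("carnivore")
  if (percent_plant > 90) return("herbivore")
  "omnivore"
}

# round half-up at `digits` decimals (matches printed percentages)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

major_aglycone_name <- function(p) {
  mm <- major_minor(p)
  if (!length(mm$major)) return(NA_character_)
  i <- mm$major[1]
  descriptor_key(unconjugated(p$components[[i]]))
}

#' Diet by bile-salt-profile cross-tabulation
#'
#' For each diet group, counts species and computes the percent with a
#' complex profile ([is_complex()]), the percent whose major (> 50%) bile
#' salt is cholic acid, chenodeoxycholic acid, or another C24 acid, and the
#' percent whose profile is primarily C27 bile acids. "Primarily" is
#' operationalized as an aggregate C27-bile-acid percent above 50 (conjugation
#' ignored). Percentages are half-up rounded to one decimal; numerators and
#' denominators are reported alongside.
#'
#' @param profiles List of [species_profile()] objects; profiles with `NA`
#'   diet are excluded with a warning.
#' @return Data frame with one row per diet group present, columns `diet`,
#'   `n`, `pct_complex`, `n_complex`, `pct_major_CA`, `n_major_CA`,
#'   `pct_major_CDCA`, `n_major_CDCA`, `pct_major_other_C24`,
#'   `n_major_other_C24`, `pct_primarily_C27_acids`, `n_primarily_C27_acids`.
#' @export
diet_crosstab <- function(profiles) {
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, TRUE, "species_profile")))
  if (!length(profiles)) stop("empty cohort: no profiles to cross-tabulate")
  diets <- vapply(profiles, function(p) p$diet, "")
  if (anyNA(diets)) {
    warning(sum(is.na(diets)), " profile(s) without a diet label excluded")
    profiles <- profiles[!is.na(diets)]
    diets <- diets[!is.na(diets)]
  }
  if (!length(profiles)) stop("empty cohort: no diet-labeled profiles")

  ca_key <- descriptor_key(registry_get()[["cholic acid"]])
  cdca_key <- descriptor_key(registry_get()[["chenodeoxycholic acid"]])

  rows <- lapply(intersect(c("carnivore", "herbivore", "omnivore"),
                           unique(diets)), function(g) {
    ps <- profiles[diets == g]
    n <- length(ps)
    complex <- vapply(ps, is_complex, TRUE)
    major <- vapply(ps, major_aglycone_name, "")
    major_c24 <- vapply(ps, function(p) {
      mm <- major_minor(p)
      length(mm$major) > 0 &&
        classify_type(p$components[[mm$major[1]]]) == "C24_acid"
    }, TRUE)
    c27_primary <- vapply(ps, function(p) {
      type_aggregates(p)["C27_acid"] > 50
    }, TRUE)
    pct <- function(k) round_half_up(100 * k / n, 1)
    data.frame(
      diet = g, n = n,
      pct_complex = pct(sum(complex)), n_complex = sum(complex),
      pct_major_CA = pct(sum(major == ca_key, na.rm = TRUE)),
      n_major_CA = sum(major == ca_key, na.rm = TRUE),
      pct_major_CDCA = pct(sum(major == cdca_key, na.rm = TRUE)),
      n_major_CDCA = sum(major == cdca_key, na.rm = TRUE),
      pct_major_other_C24 = pct(sum(major_c24 & major != ca_key &
                                      major != cdca_key, na.rm = TRUE)),
      n_major_other_C24 = sum(major_c24 & major != ca_key &
                                major != cdca_key, na.rm = TRUE),
      pct_primarily_C27_acids = pct(sum(c27_primary)),
      n_primarily_C27_acids = sum(c27_primary),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
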