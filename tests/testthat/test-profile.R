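# representative compounds, one per broad type, plus extra C24 acids
P_ALC <- "5b-cyprinol"
P_C27 <- "3a,7a,12a-trihydroxy-5b-cholestan-27-oic acid"
P_C24 <- "cholic acid"

make_profile <- function(compounds, percents, species = "sp", diet = NA,
                         check_total = TRUE) {
  species_profile(species,
                  lapply(compounds, parse_bile_salt_name),
                  percents, family = "fam", diet = diet,
                  check_total = check_total)
}

test_that("profile classes follow the one-or-two-types-at-10-percent rule", {
  # approximately 100% cholic acid, the pit-viper pattern
  expect_equal(assign_class(make_profile(P_C24, 100)), "VI")
  # all-bile-alcohol profile (elephants, manatees, hyrax)
  expect_equal(assign_class(make_profile(P_ALC, 98)), "I")
  expect_equal(assign_class(make_profile(c(P_ALC, P_C27), c(60, 40))), "II")
  expect_equal(assign_class(make_profile(c(P_ALC, P_C24), c(55, 45))), "III")
  expect_equal(assign_class(make_profile(P_C27, 95)), "IV")
  expect_equal(assign_class(make_profile(c(P_C27, P_C24), c(50, 50))), "V")
  # all three types over threshold fall outside the six classes
  expect_equal(assign_class(make_profile(c(P_ALC, P_C27, P_C24),
                                         c(40, 35, 25))), "mixed")
  # the 10% threshold is inclusive
  expect_equal(assign_class(make_profile(c(P_ALC, P_C24), c(90, 10))), "III")
  expect_equal(assign_class(make_profile(c(P_ALC, P_C24), c(90.5, 9.5))), "I")
})

test_that("degenerate profiles are refused with the species named", {
  expect_error(assign_class(make_profile(P_C24, 5, species = "degenerate_sp")),
               "degenerate_sp")
  expect_error(assign_class(make_profile(P_C24, 0)), "no positive component")
})

test_that("conjugation is ignored when aggregating types", {
  p <- make_profile(c("glycocholic acid", "taurocholic acid",
                      "taurochenodeoxycholic acid"), c(50, 30, 20))
  expect_equal(assign_class(p), "VI")
  agg <- type_aggregates(p)
  expect_equal(unname(agg["C24_acid"]), 100)
})

test_that("complexity requires two types or three >=10% components", {
  expect_true(is_complex(make_profile(
    c("cholic acid", "chenodeoxycholic acid", "deoxycholic acid"),
    c(50, 30, 15))))
  expect_false(is_complex(make_profile(P_C24, 100)))
  expect_true(is_complex(make_profile(c(P_ALC, P_C24), c(55, 45))))
  # three components but only two over 10%
  expect_false(is_complex(make_profile(
    c("cholic acid", "chenodeoxycholic acid", "deoxycholic acid"),
    c(60, 31, 9))))
})

test_that("adding a >=10% component never makes a complex profile simple", {
  set.seed(21)
  menu <- c("cholic acid", "chenodeoxycholic acid", "deoxycholic acid",
            "lithocholic acid", P_C27, P_ALC)
  for (i in 1:30) {
    k <- sample(1:4, 1)
    picks <- sample(menu, k)
    pct <- as.numeric(rmultinom(1, 80, rep(1, k)))
    keep <- pct > 0
    p <- make_profile(picks[keep], pct[keep], check_total = FALSE)
    before <- is_complex(p)
    extra <- setdiff(menu, picks)[1]
    p2 <- make_profile(c(picks[keep], extra), c(pct[keep], 15),
                       check_total = FALSE)
    expect_true(!before || is_complex(p2))
  }
})

test_that("major/minor/trace partition respects the 50% and 10% boundaries", {
  p <- make_profile(c("cholic acid", "chenodeoxycholic acid",
                      "deoxycholic acid"), c(85, 12, 3))
  mm <- major_minor(p)
  expect_equal(mm$major, 1L)
  expect_equal(mm$minor, 2L)
  expect_equal(mm$trace, 3L)

  # a 100% single bile salt is major
  expect_equal(major_minor(make_profile("varanic acid", 100))$major, 1L)

  # 50/50 tie: neither is major, both are minor
  tie <- major_minor(make_profile(c("cholic acid", "chenodeoxycholic acid"),
                                  c(50, 50)))
  expect_length(tie$major, 0L)
  expect_equal(tie$minor, c(1L, 2L))

  # exactly 10% is trace for the label, though it counts for classification
  edge <- major_minor(make_profile(c("cholic acid", "chenodeoxycholic acid"),
                                   c(90, 10)))
  expect_equal(edge$trace, 2L)
})

test_that("classification is invariant to component order", {
  comps <- c(P_ALC, P_C27, P_C24)
  pct <- c(45, 35, 20)
  base <- assign_class(make_profile(comps, pct))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(assign_class(make_profile(comps[perm], pct[perm])), base)
  }
})

test_that("profile invariants are enforced", {
  expect_error(make_profile(c(P_C24, P_C24), c(50, 50)), "duplicate")
  expect_error(make_profile(P_C24, 120), "\\[0, 100\\]")
  expect_error(make_profile(c(P_C24, P_ALC), c(80, 60)), "sum")
  expect_silent(make_profile(c(P_C24, P_ALC), c(80, 60), check_total = FALSE))
})
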