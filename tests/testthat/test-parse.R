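test_that("systematic names parse to the expected descriptors", {
  cdca <- parse_bile_salt_name("3α,7α-dihydroxy-5β-cholan-24-oic acid")
  expect_equal(cdca$carbon_count, 24L)
  expect_equal(cdca$terminal_group, "acid")
  expect_equal(cdca$junction, "5b")
  expect_equal(cdca$hydroxyls$position, c(3L, 7L))
  expect_equal(cdca$hydroxyls$orientation, c("a", "a"))
  expect_true(same_bile_salt(cdca, bile_salt_registry()[["chenodeoxycholic acid"]]))

  varanic <- parse_bile_salt_name("3α,7α,12α,24R-tetrahydroxy-5β-cholestan-27-oic acid")
  expect_equal(varanic$carbon_count, 27L)
  expect_equal(varanic$hydroxyls$position, c(3L, 7L, 12L, 24L))
  expect_equal(varanic$hydroxyls$orientation[4], "R")
  expect_true(same_bile_salt(varanic, bile_salt_registry()[["varanic acid"]]))

  oxo_lca <- parse_bile_salt_name("3α-hydroxy-12-oxo-5β-cholan-24-oic acid")
  expect_equal(oxo_lca$hydroxyls$position, 3L)
  expect_equal(oxo_lca$oxo, 12L)
})

test_that("Greek, ASCII and spelled-out orientation letters are equivalent", {
  variants <- c("3α,7α-dihydroxy-5β-cholan-24-oic acid",
                "3a,7a-dihydroxy-5b-cholan-24-oic acid",
                "3alpha,7alpha-dihydroxy-5beta-cholan-24-oic acid")
  keys <- vapply(variants, function(v)
    render_bile_salt_name(parse_bile_salt_name(v)), "")
  expect_length(unique(keys), 1L)
})

# strip conjugation for aglycone comparison in this file
unclass_conj <- function(d) { d$conjugation <- "none"; d }

test_that("conjugation prefixes, fused names and sulfate suffix are captured", {
  expect_equal(parse_bile_salt_name("glycocholic acid")$conjugation, "glycine")
  expect_equal(parse_bile_salt_name("taurochenodeoxycholic acid")$conjugation, "taurine")
  gc <- parse_bile_salt_name("glyco-3a,7a,12a-trihydroxy-5b-cholan-24-oic acid")
  expect_equal(gc$conjugation, "glycine")
  expect_true(same_bile_salt(unclass_conj(gc),
                             bile_salt_registry()[["cholic acid"]]))
  alc <- parse_bile_salt_name("5b-cyprinol sulfate")
  expect_equal(alc$conjugation, "sulfate")
  expect_equal(classify_type(alc), "C27_alcohol")
})

test_that("names without an -oic acid suffix are bile alcohols", {
  alc <- parse_bile_salt_name("3α,7α,27-trihydroxy-5β-cholestan")
  expect_equal(alc$terminal_group, "alcohol")
  expect_equal(classify_type(alc), "C27_alcohol")
  # terminal hydroxyl implied even when not written
  alc2 <- parse_bile_salt_name("3a,7a,12a,25-tetrahydroxy-5b-cholestan")
  expect_true(27L %in% alc2$hydroxyls$position)
})

test_that("every registry descriptor round-trips through render and parse", {
  reg <- bile_salt_registry()
  for (nm in names(reg)) {
    d <- reg[[nm]]
    for (conj in c("none", "glycine", "taurine", "sulfate")) {
      d$conjugation <- conj
      back <- parse_bile_salt_name(render_bile_salt_name(d))
      expect_true(same_bile_salt(d, back), label = paste(nm, conj))
      expect_equal(back$conjugation, conj)
    }
  }
})

test_that("random descriptors round-trip through render and parse", {
  set.seed(71)
  for (i in 1:50) {
    d <- random_descriptor()
    back <- parse_bile_salt_name(render_bile_salt_name(d))
    expect_true(same_bile_salt(d, back),
                label = render_bile_salt_name(d))
  }
})

test_that("parse errors name the offending fragment; conflicts are refused", {
  expect_error(parse_bile_salt_name("not-a-bile-acid"), "fragment|skeleton",
               class = "biliphy_parse_error")
  err <- tryCatch(parse_bile_salt_name("3a,7a-dihydroxy-5b-wibblestan-24-oic acid"),
                  error = identity)
  expect_match(conditionMessage(err), "wibblestan")
  expect_error(parse_bile_salt_name(""), "non-empty")
  # hydroxyl and oxo on the same carbon
  expect_error(parse_bile_salt_name("3a-hydroxy-3-oxo-5b-cholan-24-oic acid"),
               "both hydroxylated and oxo")
  # multiplier inconsistent with the position list
  expect_error(parse_bile_salt_name("3a,7a-trihydroxy-5b-cholan-24-oic acid"),
               "multiplier")
  # a C24 skeleton cannot be a bile alcohol
  expect_error(parse_bile_salt_name("3a,7a-dihydroxy-5b-cholan"),
               "alcohols")
  # terminal carbon must match the skeleton
  expect_error(parse_bile_salt_name("3a-hydroxy-5b-cholan-27-oic acid"),
               "terminal carbon")
})

test_that("the C23 (24-nor) skeleton is recognized", {
  d <- parse_bile_salt_name("3a,12a-dihydroxy-5b-24-norcholan-23-oic acid")
  expect_equal(d$carbon_count, 23L)
  expect_equal(classify_type(d), "other")
  expect_true(same_bile_salt(
    d, parse_bile_salt_name("3a,12a-dihydroxy-5b-norcholan-23-oic acid")))
})
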