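test_that("identical seed and config give identical output", {
  cfg <- sim_config(n_families = 8, species_per_family = 2, seed = 42)
  s1 <- simulate_tree_and_characters(cfg)
  s2 <- simulate_tree_and_characters(cfg)
  expect_identical(s1$characters, s2$characters)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  p1 <- generate_profile_table(cfg, s1)
  p2 <- generate_profile_table(cfg, s2)
  expect_identical(p1, p2)
})

test_that("a rate-zero character leaves every tip in the root state", {
  cfg <- sim_config(n_families = 12, species_per_family = 3, char_rate = 0,
                    class_states = c("I", "IV", "VI"), root_state = 2,
                    seed = 7)
  sim <- simulate_tree_and_characters(cfg)
  expect_true(all(sim$characters$class_state == "IV"))
  expect_equal(sim$root_state, "IV")
  # and conservation is perfect: zero heterogeneous families
  profs <- generate_profile_table(cfg, sim)
  rep <- conservation_report(profs, "family")
  expect_false(any(rep$heterogeneous))
})

test_that("at saturating rates tip states approach the uniform distribution", {
  cfg <- sim_config(n_families = 1000, species_per_family = 1,
                    char_rate = 50, class_states = c("I", "IV", "VI"),
                    seed = 99)
  sim <- simulate_tree_and_characters(cfg)
  tab <- table(factor(sim$characters$class_state,
                      levels = c("I", "IV", "VI")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("generated profiles obey the class label and profile invariants", {
  set.seed(5)
  cfg <- sim_config(n_families = 60, species_per_family = 1,
                    char_rate = 0.3, class_states = c("I", "IV", "V", "VI"),
                    dirichlet_conc = 50, seed = 5)
  sim <- simulate_tree_and_characters(cfg)
  profs <- generate_profile_table(cfg, sim)
  classes <- vapply(profs, assign_class, "")
  agree <- mean(classes == sim$characters$class_state)
  expect_gte(agree, 0.99)
  for (p in profs) {
    expect_true(all(p$percents >= 0 & p$percents <= 100))
    expect_lte(sum(p$percents), 100.5)
  }
})

test_that("generated tables round-trip through the writer and reader", {
  cfg <- sim_config(n_families = 10, species_per_family = 2,
                    class_states = c("I", "IV", "VI"), char_rate = 0.5,
                    seed = 13)
  sim <- simulate_tree_and_characters(cfg)
  profs <- generate_profile_table(cfg, sim)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_table(profs, path)
  back <- read_profile_table(path)
  expect_equal(length(back), length(profs))
  expect_equal(vapply(back, assign_class, ""), vapply(profs, assign_class, ""))
  expect_equal(vapply(back, function(p) sum(p$percents), 0),
               vapply(profs, function(p) sum(p$percents), 0),
               tolerance = 1e-6)
})

test_that("a degenerate single-compound draw is exactly 100% of one compound", {
  # concentration -> infinity limit emulated by the simple-profile branch
  p <- species_profile("sp", list(parse_bile_salt_name("cholic acid")), 100)
  expect_equal(assign_class(p), "VI")
  expect_false(is_complex(p))
})

test_that("peak lists from profiles carry one [M-H]- peak per component", {
  p <- species_profile("sp",
                       lapply(c("glycocholic acid", "glycodeoxycholic acid"),
                              parse_bile_salt_name),
                       c(70, 30))
  pk <- simulate_peak_list(p)
  expect_equal(nrow(pk), 2L)
  expect_equal(sort(pk$mz),
               sort(c(mz_mh_minus(parse_bile_salt_name("glycocholic acid")),
                      mz_mh_minus(parse_bile_salt_name("glycodeoxycholic acid")))))
  ann <- annotate_peaks(pk, tolerance = 0.01)
  expect_true(all(c("glycine-conjugated trihydroxy C24 bile acid",
                    "glycine-conjugated dihydroxy C24 bile acid") %in%
                    ann$candidate_label))
})

test_that("configs serialize to key=value text and restore equal", {
  cfg <- sim_config(n_families = 9, species_per_family = 4, birth_rate = 2,
                    char_rate = 0.2, within_family_flip = 0.05,
                    class_states = c("IV", "VI"), root_state = 2,
                    dirichlet_conc = 25,
                    complexity_q = c(carnivore = 0.1, herbivore = 0.9,
                                     omnivore = 0.5),
                    seed = 17)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$class_states, cfg$class_states)
  expect_equal(cfg2$complexity_q, cfg$complexity_q)
  expect_equal(cfg2$seed, cfg$seed)
  s1 <- simulate_tree_and_characters(cfg)
  s2 <- simulate_tree_and_characters(cfg2)
  expect_identical(s1$characters, s2$characters)
})
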