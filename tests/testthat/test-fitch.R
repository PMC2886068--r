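test_that("small reconstructions match hand-checked optima", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  fit <- fitch_ancestral(tr, c(A = "alcohol", B = "alcohol",
                               C = "acid", D = "acid"))
  expect_setequal(fit$root_states, c("alcohol", "acid"))
  expect_equal(fit$changes, 1L)

  tr2 <- ape::read.tree(text = "((A,B),C);")
  fit2 <- fitch_ancestral(tr2, c(A = "alcohol", B = "acid", C = "alcohol"))
  expect_equal(fit2$root_states, "alcohol")
  expect_equal(fit2$changes, 1L)

  tr3 <- ape::read.tree(text = "(A);")
  fit3 <- fitch_ancestral(tr3, c(A = "alcohol"))
  expect_equal(fit3$root_states, "alcohol")
  expect_equal(fit3$changes, 0L)

  # polytomy where naive pairwise intersection undercounts
  tr4 <- ape::read.tree(text = "(A,B,C,D);")
  fit4 <- fitch_ancestral(tr4, c(A = "x", B = "x", C = "y", D = "y"))
  expect_equal(fit4$changes, 2L)
  expect_setequal(fit4$root_states, c("x", "y"))
})

test_that("change counts equal exhaustive enumeration on random trees", {
  set.seed(31)
  alphabet <- c("s1", "s2", "s3")
  for (i in 1:200) {
    ntip <- sample(2:6, 1)
    tr <- random_polytomy_tree(ntip)
    states <- stats::setNames(sample(alphabet, ntip, replace = TRUE),
                              tr$tip.label)
    fit <- fitch_ancestral(tr, states)
    oracle <- oracle_parsimony(tr, states, alphabet)
    expect_equal(fit$changes, oracle$changes,
                 label = ape::write.tree(tr))
    expect_setequal(fit$root_states, oracle$root_states)
  }
})

test_that("reconstruction is invariant under tip relabeling and child order", {
  set.seed(32)
  for (i in 1:20) {
    tr <- random_polytomy_tree(6)
    states <- stats::setNames(sample(c("p", "q"), 6, replace = TRUE),
                              tr$tip.label)
    fit <- fitch_ancestral(tr, states)
    # bijective relabeling
    perm <- sample(tr$tip.label)
    tr2 <- tr
    tr2$tip.label <- perm
    states2 <- stats::setNames(states[tr$tip.label], perm)
    fit2 <- fitch_ancestral(tr2, states2)
    expect_equal(fit2$changes, fit$changes)
    # rotating children does not change the optimum
    tr3 <- ape::rotate(ape::read.tree(text = "((A,B),(C,D));"), 5)
    st <- c(A = "p", B = "q", C = "p", D = "q")
    expect_equal(fitch_ancestral(tr3, st)$changes,
                 fitch_ancestral(ape::read.tree(text = "((A,B),(C,D));"),
                                 st)$changes)
  }
})

test_that("missing tip states are pruned by default and refused on request", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  states <- c(A = "x", B = "x", C = NA, D = "y")
  fit <- fitch_ancestral(tr, states)
  expect_equal(sort(fit$tree$tip.label), c("A", "B", "D"))
  expect_equal(fit$changes, 1L)
  expect_error(fitch_ancestral(tr, states, missing = "error"), "without a state")
})

test_that("the amniote fixture reconstructs an alcohol-plus-C27-acid ancestor", {
  tree <- ape::read.tree(system.file("extdata", "amniote_tree.nwk",
                                     package = "biliphy"))
  cm <- read_character_matrix(system.file("extdata",
                                          "amniote_tip_codings.csv",
                                          package = "biliphy"))
  alc <- fitch_ancestral(tree, cm$C27_alcohol_present)
  acid <- fitch_ancestral(tree, cm$C27_acid_present)
  expect_true("present" %in% node_state_set(alc, "B"))
  expect_true("present" %in% node_state_set(acid, "B"))
  # node C (tuatara + squamates) retains C27 acids, per the lepidosaur pattern
  expect_equal(node_state_set(acid, "C"), "present")
  # the MRCA route to the same node agrees with the label route
  expect_equal(node_state_set(alc, c("Testudines", "Crocodylia", "Aves")),
               node_state_set(alc, "B"))
})

test_that("conservation report flags heterogeneous families and overlap", {
  mk <- function(sp, fam, compounds, percents) {
    species_profile(sp, lapply(compounds, parse_bile_salt_name), percents,
                    family = fam, diet = "carnivore")
  }
  profs <- list(
    mk("s1", "FamA", "cholic acid", 100),
    mk("s2", "FamA", "cholic acid", 95),
    # FamB heterogeneous but overlapping: VI vs V share the C24 type
    mk("s3", "FamB", "cholic acid", 90),
    mk("s4", "FamB", c("cholic acid", "varanic acid"), c(55, 45)),
    # FamC heterogeneous and non-overlapping
    mk("s5", "FamC", "5b-cyprinol", 95),
    mk("s6", "FamC", "cholic acid", 95)
  )
  rep <- conservation_report(profs, "family")
  expect_equal(rep$heterogeneous, c(FALSE, TRUE, TRUE))
  expect_equal(rep$overlap, c(TRUE, TRUE, FALSE))
  expect_equal(rep$classes[rep$group == "FamB"], "V,VI")
  expect_error(conservation_report(profs, "bogus"))
})
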