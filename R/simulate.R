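# One draw from a Dirichlet with parameter vector alpha.
rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate guard
  g / sum(g)
}

# Component menus per broad compound type; every name parses via
# parse_bile_salt_name() so generated tables round-trip through the reader.
.TYPE_MENUS <- list(
  C27_alcohol = c("5b-cyprinol",
                  "3a,7a,27-trihydroxy-5b-cholestan",
                  "3a,7a,12a,25,27-pentahydroxy-5b-cholestan"),
  C27_acid = c("3a,7a,12a-trihydroxy-5b-cholestan-27-oic acid",
               "varanic acid",
               "3a,7a-dihydroxy-5b-cholestan-27-oic acid"),
  C24_acid = c("cholic acid", "chenodeoxycholic acid", "deoxycholic acid",
               "ursodeoxycholic acid", "lithocholic acid")
)

.CLASS_TYPES <- list(
  I = "C27_alcohol",
  II = c("C27_alcohol", "C27_acid"),
  III = c("C27_alcohol", "C24_acid"),
  IV = "C27_acid",
  V = c("C27_acid", "C24_acid"),
  VI = "C24_acid"
)

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic cohort generator. Default
#' complexity targets per diet group are the observed mammalian rates
#' (carnivores 39.8%, herbivores 70.5%, omnivores 50.0%). Character evolution
#' uses a symmetric Mk process at `char_rate` expected changes per unit of
#' tree height on a Yule (pure-birth) family backbone; species inherit the
#' family state and flip to a random other state with probability
#' `within_family_flip`, mirroring the strong within-family conservation of
#' real profiles.
#'
#' @param n_families Number of families (backbone tips).
#' @param species_per_family Species per family (scalar, recycled).
#' @param birth_rate Yule birth rate for backbone and within-family subtrees.
#' @param char_rate Mk transition rate (expected changes per unit height).
#' @param within_family_flip Probability a species deviates from its family's
#'   character state.
#' @param class_states Alphabet of the profile-class character; subset of
#'   `I, II, III, IV, V, VI`.
#' @param root_state Index into `class_states` for the root state.
#' @param dirichlet_conc Dirichlet concentration for component percents.
#' @param diet_probs Probabilities of carnivore/herbivore/omnivore per family.
#' @param complexity_q Named probability of a complex profile per diet group
#'   (applies to single-type classes; two-type classes are complex by
#'   definition).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_families = 20L,
                       species_per_family = 5L,
                       birth_rate = 1,
                       char_rate = 0.05,
                       within_family_flip = 0,
                       class_states = c("I", "IV", "VI"),
                       root_state = 1L,
                       dirichlet_conc = 50,
                       diet_probs = c(carnivore = 0.4, herbivore = 0.4,
                                      omnivore = 0.2),
                       complexity_q = c(carnivore = 0.398, herbivore = 0.705,
                                        omnivore = 0.500),
                       seed = 1L) {
  stopifnot(n_families >= 1, species_per_family >= 1, birth_rate > 0,
            char_rate >= 0, within_family_flip >= 0, within_family_flip <= 1,
            all(class_states %in% names(.CLASS_TYPES)),
            length(class_states) >= 1,
            root_state >= 1, root_state <= length(class_states),
            dirichlet_conc > 0,
            all(diet_probs >= 0), sum(diet_probs) > 0,
            all(complexity_q >= 0 & complexity_q <= 1),
            all(c("carnivore", "herbivore", "omnivore") %in%
                  names(complexity_q)))
  structure(
    list(n_families = as.integer(n_families),
         species_per_family = as.integer(species_per_family),
         birth_rate = birth_rate, char_rate = char_rate,
         within_family_flip = within_family_flip,
         class_states = class_states, root_state = as.integer(root_state),
         dirichlet_conc = dirichlet_conc,
         diet_probs = diet_probs / sum(diet_probs),
         complexity_q = complexity_q,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

scale_tree_height <- function(tree, height = 1) {
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_along(tree$tip.label)])
  if (h > 0) tree$edge.length <- tree$edge.length * height / h
  tree
}

#' Simulate a phylogeny and discrete profile-class characters
#'
#' Draws a Yule family backbone scaled to unit height, evolves the
#' profile-class character by a symmetric Mk process (retaining the true
#' states at every internal node for recovery tests), grafts within-family
#' species subtrees (height 0.1), and assigns species states by inheritance
#' with an optional flip probability.
#'
#' @param cfg A [sim_config()].
#' @return List with `tree` (species-level `phylo`), `backbone` (family-level
#'   `phylo`), `characters` (data frame `species`, `family`, `class_state`),
#'   `ancestral_states` (true states at backbone internal nodes),
#'   `root_state`, and `family_states`.
#' @export
simulate_tree_and_characters <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_families < 1) stop("configuration error: zero families")
  set.seed(cfg$seed)

  nf <- cfg$n_families
  fam_names <- sprintf("fam%03d", seq_len(nf))
  if (nf >= 2) {
    backbone <- scale_tree_height(ape::rphylo(nf, cfg$birth_rate, 0))
    backbone$tip.label <- fam_names
    k <- length(cfg$class_states)
    if (k == 1 || cfg$char_rate == 0) {
      states <- rep(cfg$class_states[cfg$root_state],
                    nf + backbone$Nnode)
    } else {
      states <- as.character(ape::rTraitDisc(
        backbone, model = "ER", k = k, rate = cfg$char_rate,
        states = cfg$class_states, ancestor = TRUE,
        root.value = cfg$root_state))
    }
    fam_states <- states[seq_len(nf)]
    anc_states <- states[(nf + 1):(nf + backbone$Nnode)]
    root_state <- anc_states[1]
  } else {
    backbone <- NULL
    fam_states <- cfg$class_states[cfg$root_state]
    anc_states <- character()
    root_state <- fam_states
  }
  names(fam_states) <- fam_names

  nsp <- rep_len(cfg$species_per_family, nf)
  species <- character()
  family_of <- character()
  tree <- backbone
  for (i in seq_len(nf)) {
    sp <- sprintf("%s_sp%02d", fam_names[i], seq_len(nsp[i]))
    species <- c(species, sp)
    family_of <- c(family_of, rep(fam_names[i], nsp[i]))
    if (is.null(tree)) next
    if (nsp[i] == 1L) {
      tree$tip.label[tree$tip.label == fam_names[i]] <- sp
    } else {
      sub <- scale_tree_height(ape::rphylo(nsp[i], cfg$birth_rate, 0), 0.1)
      sub$tip.label <- sp
      tree <- ape::bind.tree(tree, sub,
                             where = which(tree$tip.label == fam_names[i]))
    }
  }

  sp_states <- fam_states[family_of]
  if (cfg$within_family_flip > 0 && length(cfg$class_states) > 1) {
    flip <- stats::runif(length(sp_states)) < cfg$within_family_flip
    for (j in which(flip)) {
      sp_states[j] <- sample(setdiff(cfg$class_states, sp_states[j]), 1)
    }
  }

  list(tree = tree, backbone = backbone,
       characters = data.frame(species = species, family = family_of,
                               class_state = unname(sp_states),
                               stringsAsFactors = FALSE),
       ancestral_states = anc_states,
       root_state = root_state,
       family_states = fam_states)
}

draw_components <- function(class_state, complex, conc) {
  types <- .CLASS_TYPES[[class_state]]
  if (length(types) == 1L) {
    menu <- .TYPE_MENUS[[types]]
    if (complex) {
      compounds <- sample(menu, 3L)
      percents <- 100 * rdirichlet_one(rep(conc / 3, 3L))
    } else {
      compounds <- sample(menu, 2L)
      percents <- 100 * rdirichlet_one(conc * c(0.95, 0.05))
    }
  } else {
    # one component per type, balanced: both types reach 10% almost surely
    compounds <- vapply(types, function(t) sample(.TYPE_MENUS[[t]], 1L), "")
    percents <- 100 * rdirichlet_one(rep(conc / 2, 2L))
  }
  list(compounds = unname(compounds), percents = percents)
}

#' Generate a synthetic species bile-salt profile table
#'
#' Per species: the profile class comes from the simulated character; diet is
#' drawn per family (or supplied explicitly); single-type classes are made
#' complex (three components, balanced Dirichlet) with the configured
#' per-diet probability and otherwise get one dominant plus one trace
#' component; two-type classes draw one component per type. Emitted profiles
#' round-trip through [write_profile_table()] / [read_profile_table()].
#'
#' @param cfg A [sim_config()].
#' @param sim Result of [simulate_tree_and_characters()] under the same config.
#' @param diets Optional named character vector (by family) fixing each
#'   family's diet instead of sampling from `cfg$diet_probs`.
#' @return List of [species_profile()] objects.
#' @export
generate_profile_table <- function(cfg, sim, diets = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  chars <- sim$characters
  set.seed(cfg$seed + 10007L)

  fams <- unique(chars$family)
  if (is.null(diets)) {
    diets <- sample(names(cfg$diet_probs), length(fams), replace = TRUE,
                    prob = cfg$diet_probs)
    names(diets) <- fams
  } else {
    if (!all(fams %in% names(diets))) {
      stop("diets must be named for every family")
    }
  }

  lapply(seq_len(nrow(chars)), function(i) {
    cls <- chars$class_state[i]
    if (is.null(.CLASS_TYPES[[cls]])) {
      stop("configuration error: no component menu for class ", cls)
    }
    diet <- diets[[chars$family[i]]]
    complex <- stats::runif(1) < cfg$complexity_q[[diet]]
    draw <- draw_components(cls, complex, cfg$dirichlet_conc)
    species_profile(
      species = chars$species[i],
      components = lapply(draw$compounds, parse_bile_salt_name),
      percents = draw$percents,
      family = chars$family[i],
      order_group = "synthetic",
      diet = diet
    )
  })
}

#' Simulate a negative-mode peak list from a profile
#'
#' One [M-H]- peak per component, intensity proportional to its percent of
#' the pool, with optional Gaussian m/z jitter.
#'
#' @param profile A [species_profile()].
#' @param mz_jitter Standard deviation of m/z noise in Da (0 = exact).
#' @param seed Optional seed applied when `mz_jitter > 0`.
#' @return Data frame with columns `mz`, `intensity`, sorted by m/z.
#' @export
simulate_peak_list <- function(profile, mz_jitter = 0, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  if (!is.null(seed)) set.seed(seed)
  mz <- vapply(profile$components, mz_mh_minus, 0)
  if (mz_jitter > 0) mz <- mz + stats::rnorm(length(mz), 0, mz_jitter)
  out <- data.frame(mz = mz, intensity = profile$percents)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
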