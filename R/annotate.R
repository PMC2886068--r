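.GREEK_COUNT <- c("non-hydroxylated", "monohydroxy", "dihydroxy", "trihydroxy",
                  "tetrahydroxy", "pentahydroxy", "hexahydroxy")

candidate_label <- function(scaffold, terminal, n_oh_total, n_oxo, n_db, conjugation) {
  parts <- character()
  parts <- c(parts, switch(conjugation,
                           none = NULL,
                           glycine = "glycine-conjugated",
                           taurine = "taurine-conjugated",
                           sulfate = "sulfated"))
  parts <- c(parts, .GREEK_COUNT[n_oh_total + 1L])
  if (n_oxo == 1L) parts <- c(parts, "mono-oxo")
  if (n_oxo == 2L) parts <- c(parts, "dioxo")
  if (n_db == 1L) parts <- c(parts, "singly-unsaturated")
  if (n_db == 2L) parts <- c(parts, "doubly-unsaturated")
  kind <- if (terminal == "alcohol") "bile alcohol" else "bile acid"
  paste(c(parts, paste0("C", scaffold), kind), collapse = " ")
}

#' Enumerate the bounded bile-salt search space
#'
#' Structural equivalence classes (position-agnostic, since m/z cannot
#' localize substituents) over scaffolds, hydroxyl/oxo/double-bond counts and
#' conjugation states, with theoretical formula and [M-H]- m/z for each.
#' For bile alcohols the hydroxyl count includes the terminal hydroxyl, so
#' `hydroxyls = 0:4` spans mono- to pentahydroxy alcohols.
#'
#' @param scaffolds Integer vector among 23, 24, 27 (C23/C24 acids; C27
#'   contributes both acids and alcohols).
#' @param hydroxyls Range of non-terminal hydroxyl counts (default `0:4`).
#' @param oxo Range of oxo counts (default `0:2`).
#' @param double_bonds Range of double-bond counts (default `0:2`).
#' @param conjugations Subset of `c("none", "glycine", "taurine", "sulfate")`.
#' @return Data frame with columns `scaffold`, `terminal`, `n_hydroxyl`,
#'   `n_oxo`, `n_double_bond`, `conjugation`, `candidate_label`, `formula`,
#'   `theoretical_mz`.
#' @export
enumerate_bile_salt_space <- function(scaffolds = c(23L, 24L, 27L),
                                      hydroxyls = 0:4,
                                      oxo = 0:2,
                                      double_bonds = 0:2,
                                      conjugations = c("none", "glycine",
                                                       "taurine", "sulfate")) {
  stopifnot(all(scaffolds %in% c(23L, 24L, 27L)),
            all(conjugations %in% c("none", "glycine", "taurine", "sulfate")))
  terminals <- function(s) if (s == 27L) c("acid", "alcohol") else "acid"
  rows <- list()
  for (s in as.integer(scaffolds)) for (term in terminals(s)) {
    grid <- expand.grid(n_oh = as.integer(hydroxyls), n_oxo = as.integer(oxo),
                        n_db = as.integer(double_bonds),
                        conj = conjugations, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      f <- formula_from_counts(s, term, g$n_oh, g$n_oxo, g$n_db, g$conj)
      n_oh_total <- g$n_oh + if (term == "alcohol") 1L else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = s, terminal = term, n_hydroxyl = g$n_oh, n_oxo = g$n_oxo,
        n_double_bond = g$n_db, conjugation = g$conj,
        candidate_label = candidate_label(s, term, n_oh_total, g$n_oxo,
                                          g$n_db, g$conj),
        formula = format_formula(f),
        theoretical_mz = formula_mass(f) - .PROTON_MASS,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate a negative-mode peak list with candidate bile salts
#'
#' Matches each observed m/z against the theoretical [M-H]- masses of the
#' bounded search space; every candidate within the mass window is reported,
#' sorted by absolute mass error within a peak. The default 0.5 Da window
#' suits unit-resolution quadrupole data; narrow it for high-resolution
#' inputs.
#'
#' @param peaks Data frame with columns `mz` (positive) and `intensity`, as
#'   read by [read_peak_list()].
#' @param tolerance Mass window in Da (> 0).
#' @param space Search space from [enumerate_bile_salt_space()].
#' @return Data frame with columns `peak_mz`, `intensity`, `candidate_label`,
#'   `formula`, `theoretical_mz`, `delta_mz`, `conjugation`; zero rows when
#'   nothing matches.
#' @examples
#' annotate_peaks(data.frame(mz = 464.30, intensity = 100), tolerance = 0.05)
#' @export
annotate_peaks <- function(peaks, tolerance = 0.5,
                           space = enumerate_bile_salt_space()) {
  if (!is.data.frame(peaks) || !all(c("mz", "intensity") %in% names(peaks))) {
    stop("peaks must be a data frame with columns mz and intensity")
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("tolerance must be a single positive mass window (Da)")
  }
  if (!nrow(space)) stop("empty search space")
  if (any(peaks$mz <= 0)) stop("peak m/z values must be positive")

  out <- list()
  for (i in seq_len(nrow(peaks))) {
    delta <- peaks$mz[i] - space$theoretical_mz
    hit <- which(abs(delta) <= tolerance)
    if (!length(hit)) next
    hit <- hit[order(abs(delta[hit]))]
    out[[length(out) + 1L]] <- data.frame(
      peak_mz = peaks$mz[i], intensity = peaks$intensity[i],
      candidate_label = space$candidate_label[hit],
      formula = space$formula[hit],
      theoretical_mz = space$theoretical_mz[hit],
      delta_mz = delta[hit],
      conjugation = space$conjugation[hit],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(peak_mz = numeric(), intensity = numeric(),
                      candidate_label = character(), formula = character(),
                      theoretical_mz = numeric(), delta_mz = numeric(),
                      conjugation = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
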