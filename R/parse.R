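parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("biliphy_parse_error", "error")))
}

# Accepts Greek letters, ASCII a/b, or spelled-out alpha/beta/delta, and the
# "24-nor" C23 skeleton prefix; collapses unicode dashes.
normalize_bile_salt_name <- function(name) {
  x <- trimws(name)
  x <- gsub("[‐-―−]", "-", x)
  x <- gsub("α|alpha", "a", x)
  x <- gsub("β|beta", "b", x)
  x <- gsub("Δ|∆", "delta", x)
  x <- gsub("24-nor-?cholan", "norcholan", x, ignore.case = TRUE)
  gsub("[[:space:]]+", " ", x)
}

.MULTIPLIER <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L)
names(.MULTIPLIER) <- c("", "di", "tri", "tetra", "penta", "hexa", "hepta", "octa")

#' Parse a systematic or trivial bile-salt name
#'
#' Understands the hydroxy/oxo substituent nomenclature used for steroids
#' (e.g. `"3a,7a-dihydroxy-5b-cholan-24-oic acid"`), trivial names and
#' abbreviations from [bile_salt_registry()], `glyco-`/`tauro-` conjugation
#' prefixes (including fused forms such as `"glycocholic acid"`), a trailing
#' `sulfate`, Greek or ASCII or spelled-out orientation letters, `deltaN`
#' double-bond tokens, and the `cholan` (C24) / `cholestan` (C27) /
#' `norcholan` (C23) skeletons. Names without an `-oic acid` suffix are bile
#' alcohols.
#'
#' @param name Non-empty character scalar.
#' @return A [bile_salt()] descriptor.
#' @examples
#' parse_bile_salt_name("3α,7α-dihydroxy-5β-cholan-24-oic acid")
#' parse_bile_salt_name("taurocholic acid")
#' @export
parse_bile_salt_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    parse_error("bile-salt name must be a non-empty string")
  }
  x <- normalize_bile_salt_name(name)

  conjugation <- "none"
  if (grepl("^glyco-?", x, ignore.case = TRUE)) {
    conjugation <- "glycine"
    x <- sub("^glyco-?", "", x, ignore.case = TRUE)
  } else if (grepl("^tauro-?", x, ignore.case = TRUE)) {
    conjugation <- "taurine"
    x <- sub("^tauro-?", "", x, ignore.case = TRUE)
  }
  if (grepl("[- ]sulfate$", x, ignore.case = TRUE)) {
    if (conjugation != "none") {
      parse_error(paste0("conflicting conjugation in '", name, "'"))
    }
    conjugation <- "sulfate"
    x <- sub("[- ]sulfate$", "", x, ignore.case = TRUE)
  }

  reg <- registry_get()
  hit <- reg[[tolower(x)]]
  if (!is.null(hit)) {
    hit$conjugation <- conjugation
    return(hit)
  }

  parse_systematic(x, conjugation, name)
}

parse_systematic <- function(x, conjugation, original) {
  terminal_group <- "alcohol"
  acid_terminal <- NA_integer_
  m <- regmatches(x, regexec("-([0-9]+)-oic acid$", x, ignore.case = TRUE))[[1]]
  if (length(m)) {
    terminal_group <- "acid"
    acid_terminal <- as.integer(m[2])
    x <- sub("-[0-9]+-oic acid$", "", x, ignore.case = TRUE)
  }

  tokens <- strsplit(x, "-", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) parse_error(paste0("cannot parse '", original, "'"))
  # lowercase everything except R/S stereocentre letters after digits
  tokens <- vapply(tokens, function(t) {
    if (grepl("[0-9][RSrs]", t)) gsub("r", "R", gsub("s", "S", tolower(t))) else tolower(t)
  }, "", USE.NAMES = FALSE)

  skeleton <- tokens[length(tokens)]
  carbon_count <- switch(sub("e$", "", skeleton),
                         "cholan" = 24L, "cholestan" = 27L, "norcholan" = 23L,
                         parse_error(paste0("unrecognized skeleton '", skeleton,
                                            "' in '", original, "'")))
  tokens <- tokens[-length(tokens)]
  if (terminal_group == "acid" && acid_terminal != carbon_count) {
    parse_error(paste0("acid terminal carbon ", acid_terminal,
                       " does not match the C", carbon_count, " skeleton in '",
                       original, "'"))
  }

  junction <- "unknown"
  if (length(tokens) && tokens[length(tokens)] %in% c("5a", "5b")) {
    junction <- tokens[length(tokens)]
    tokens <- tokens[-length(tokens)]
  }

  hydroxyls <- character()
  oxo <- integer()
  double_bonds <- integer()
  pending <- NULL
  for (tok in tokens) {
    if (grepl("^delta[0-9]+(,[0-9]+)*$", tok)) {
      double_bonds <- c(double_bonds,
                        as.integer(strsplit(sub("^delta", "", tok), ",")[[1]]))
    } else if (grepl("^[0-9]+[abRS]?(,[0-9]+[abRS]?)*$", tok)) {
      if (!is.null(pending)) {
        parse_error(paste0("dangling position list '", pending, "' in '",
                           original, "'"))
      }
      pending <- tok
    } else {
      g <- regmatches(tok, regexec("^(di|tri|tetra|penta|hexa|hepta|octa)?(hydroxy|oxo)$",
                                   tok))[[1]]
      if (!length(g)) {
        parse_error(paste0("cannot parse name fragment '", tok, "' in '",
                           original, "'"))
      }
      if (is.null(pending)) {
        parse_error(paste0("substituent '", tok, "' without positions in '",
                           original, "'"))
      }
      pieces <- strsplit(pending, ",", fixed = TRUE)[[1]]
      n_expected <- unname(.MULTIPLIER[match(g[2], names(.MULTIPLIER))])
      if (length(pieces) != n_expected) {
        parse_error(paste0("multiplier '", tok, "' does not match ",
                           length(pieces), " position(s) in '", original, "'"))
      }
      if (g[3] == "hydroxy") {
        hydroxyls <- c(hydroxyls, pieces)
      } else {
        if (any(grepl("[abRS]", pieces))) {
          parse_error(paste0("oxo positions cannot carry an orientation in '",
                             original, "'"))
        }
        oxo <- c(oxo, as.integer(pieces))
      }
      pending <- NULL
    }
  }
  if (!is.null(pending)) {
    parse_error(paste0("dangling position list '", pending, "' in '",
                       original, "'"))
  }

  bile_salt(carbon_count, terminal_group, junction, hydroxyls, oxo,
            double_bonds, conjugation)
}
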