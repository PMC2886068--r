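.PROFILE_COLUMNS <- c("species", "family", "order_group", "diet", "compound",
                      "percent")

# "~100", "approximately 100", "100%" -> value plus approximate flag
parse_percent <- function(x) {
  raw <- trimws(as.character(x))
  approx <- grepl("^~", raw) | grepl("^approximately", raw, ignore.case = TRUE)
  clean <- sub("^~", "", raw)
  clean <- sub("^approximately[[:space:]]*", "", clean, ignore.case = TRUE)
  clean <- sub("%$", "", clean)
  value <- suppressWarnings(as.numeric(clean))
  list(value = value, approximate = approx)
}

#' Read a species bile-salt profile table
#'
#' Long-format CSV, one row per species/compound, header
#' `species,family,order_group,diet,compound,percent` (UTF-8). Compound names
#' are parsed with [parse_bile_salt_name()]; rows whose compound cannot be
#' parsed are collected into an error report attached as attribute
#' `parse_errors` (a data frame with `row`, `species`, `compound`,
#' `message`), with a warning — never silently dropped. Percents may carry a
#' `~` / "approximately" prefix, recorded in the profile's `approximate`
#' flags. An empty diet field becomes `NA`.
#'
#' @param path CSV file path.
#' @return List of [species_profile()] objects (attribute `parse_errors`
#'   present when any row failed).
#' @export
read_profile_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(.PROFILE_COLUMNS, names(df))
  if (length(missing)) {
    stop("profile table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- duplicated(df[, c("species", "compound")])
  if (any(dup)) {
    stop("duplicate species+compound row(s) in ", path, ": rows ",
         paste(which(dup) + 1L, collapse = ", "))
  }

  pct <- parse_percent(df$percent)
  if (anyNA(pct$value)) {
    stop("unreadable percent value(s) in ", path, ": rows ",
         paste(which(is.na(pct$value)) + 1L, collapse = ", "))
  }

  parsed <- vector("list", nrow(df))
  errs <- list()
  for (i in seq_len(nrow(df))) {
    d <- tryCatch(parse_bile_salt_name(df$compound[i]), error = identity)
    if (inherits(d, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        row = i + 1L,  # header is line 1
        species = df$species[i], compound = df$compound[i],
        message = conditionMessage(d), stringsAsFactors = FALSE)
    } else {
      parsed[[i]] <- d
    }
  }
  ok <- !vapply(parsed, is.null, TRUE)

  profiles <- lapply(unique(df$species[ok]), function(sp) {
    idx <- which(ok & df$species == sp)
    diet <- df$diet[idx[1]]
    if (is.na(diet) || !nzchar(diet)) diet <- NA_character_
    species_profile(
      species = sp,
      components = parsed[idx],
      percents = pct$value[idx],
      family = df$family[idx[1]],
      order_group = df$order_group[idx[1]],
      diet = diet,
      approximate = pct$approximate[idx]
    )
  })
  if (length(errs)) {
    report <- do.call(rbind, errs)
    warning(nrow(report), " row(s) with unparseable compound names; ",
            "see attr(, 'parse_errors')")
    attr(profiles, "parse_errors") <- report
  }
  profiles
}

#' Write a species bile-salt profile table
#'
#' Inverse of [read_profile_table()]: canonical compound names via
#' [render_bile_salt_name()] (trivial name kept when known), approximate
#' percents re-prefixed with `~`. Deterministic row and column order.
#'
#' @param profiles List of [species_profile()] objects.
#' @param path Output CSV path.
#' @export
write_profile_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    compound <- vapply(seq_along(p$components), function(i) {
      d <- p$components[[i]]
      if (!is.na(d$trivial_name) && d$conjugation == "none") d$trivial_name
      else render_bile_salt_name(d)
    }, "")
    pctf <- formatC(p$percents, format = "fg", digits = 10)
    pctf <- ifelse(p$approximate, paste0("~", pctf), pctf)
    data.frame(species = p$species, family = p$family,
               order_group = p$order_group, diet = p$diet,
               compound = compound, percent = pctf,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a peak list
#'
#' Two-column CSV with header `mz,intensity`.
#'
#' @param path CSV file path.
#' @return Data frame with numeric `mz` and `intensity`.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("peak list ", path, " must have columns mz,intensity")
  }
  df$mz <- as.numeric(df$mz)
  df$intensity <- as.numeric(df$intensity)
  if (anyNA(df$mz) || any(df$mz <= 0)) {
    stop("peak list ", path, " contains non-positive or unreadable m/z")
  }
  df
}

#' Write a peak list
#' @param peaks Data frame with columns `mz`, `intensity`.
#' @param path Output CSV path.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.csv(peaks[, c("mz", "intensity")], path, row.names = FALSE)
  invisible(path)
}

#' Write a result table as CSV or aligned text
#'
#' Deterministic column order (as given); numeric columns are written at full
#' precision in CSV and with `digits` significant decimals in text mode.
#'
#' @param results A data frame.
#' @param path Output path.
#' @param format `"csv"` or `"text"`.
#' @param digits Decimal places for the text format.
#' @export
write_report <- function(results, path, format = c("csv", "text"), digits = 4) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE)
  } else {
    fmt <- results
    for (j in seq_along(fmt)) {
      if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]])) {
        fmt[[j]] <- formatC(fmt[[j]], format = "f", digits = digits)
      }
    }
    writeLines(utils::capture.output(print(fmt, row.names = FALSE)), path)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Flat key=value record of a pipeline run: command, parameters, input-file
#' MD5 digests, seed, timestamp and package version, for reproducibility
#' audits.
#'
#' @param path Output path.
#' @param command Short name of the step.
#' @param params Named list of parameter values.
#' @param inputs Character vector of input file paths (digested if present).
#' @param seed Integer seed used by the step (or `NA`).
#' @export
write_run_manifest <- function(path, command, params = list(),
                               inputs = character(), seed = NA_integer_) {
  lines <- c(paste0("command=", command),
             paste0("version=", as.character(utils::packageVersion("biliphy"))),
             paste0("seed=", seed),
             paste0("timestamp=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  for (nm in names(params)) {
    lines <- c(lines, paste0("param.", nm, "=",
                             paste(params[[nm]], collapse = ",")))
  }
  for (f in inputs) {
    digest <- if (file.exists(f)) unname(tools::md5sum(f)) else "missing"
    lines <- c(lines, paste0("input.", basename(f), "=", digest))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a discrete character matrix
#'
#' Long-format CSV with header `species,character,state`; missing data is an
#' empty state or `NA`.
#'
#' @param path CSV file path.
#' @return Named list, one named character vector of states per character.
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "character", "state")
  if (!all(need %in% names(df))) {
    stop("character matrix ", path, " must have columns species,character,state")
  }
  df$state[!nzchar(trimws(ifelse(is.na(df$state), "", df$state)))] <- NA
  out <- lapply(split(df, df$character), function(sub) {
    if (anyDuplicated(sub$species)) {
      stop("duplicate species in character '", sub$character[1], "'")
    }
    stats::setNames(sub$state, sub$species)
  })
  out[order(names(out))]
}

#' Serialize / restore a simulation configuration
#'
#' Flat `key=value` plain-text representation of a [sim_config()]; vectors
#' are comma-joined, named vectors as `name:value` pairs.
#'
#' @param cfg A [sim_config()].
#' @param path Output (or input) path.
#' @return `write_sim_config()` the path, invisibly; `read_sim_config()` a
#'   [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  fmt <- function(x) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      paste(paste0(names(x), ":", x), collapse = ",")
    } else {
      paste(x, collapse = ",")
    }
  }
  writeLines(paste0(names(cfg), "=", vapply(cfg, fmt, "")), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) paste(p[-1], collapse = "=")),
    vapply(kv, `[`, "", 1L)
  )
  unfmt <- function(s, numeric = TRUE) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (all(grepl(":", parts, fixed = TRUE))) {
      pieces <- strsplit(parts, ":", fixed = TRUE)
      out <- vapply(pieces, `[`, "", 2L)
      names(out) <- vapply(pieces, `[`, "", 1L)
    } else {
      out <- parts
    }
    if (numeric) {
      num <- suppressWarnings(as.numeric(out))
      if (!anyNA(num)) {
        names(num) <- names(out)
        return(num)
      }
    }
    out
  }
  sim_config(
    n_families = as.integer(vals$n_families),
    species_per_family = as.integer(unfmt(vals$species_per_family)),
    birth_rate = as.numeric(vals$birth_rate),
    char_rate = as.numeric(vals$char_rate),
    within_family_flip = as.numeric(vals$within_family_flip),
    class_states = unfmt(vals$class_states, numeric = FALSE),
    root_state = as.integer(vals$root_state),
    dirichlet_conc = as.numeric(vals$dirichlet_conc),
    diet_probs = unfmt(vals$diet_probs),
    complexity_q = unfmt(vals$complexity_q),
    seed = as.integer(vals$seed)
  )
}
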