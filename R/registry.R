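# Trivial-name registry. Keys are lowercase; abbreviations included.
# Side-chain stereocentres (23R, 24R) keep their R/S labels.
.registry_build <- function() {
  reg <- list(
    "cholic acid" = bile_salt(24, "acid", "5b", c("3a", "7a", "12a"),
                              trivial_name = "cholic acid"),
    "chenodeoxycholic acid" = bile_salt(24, "acid", "5b", c("3a", "7a"),
                                        trivial_name = "chenodeoxycholic acid"),
    "deoxycholic acid" = bile_salt(24, "acid", "5b", c("3a", "12a"),
                                   trivial_name = "deoxycholic acid"),
    "lithocholic acid" = bile_salt(24, "acid", "5b", "3a",
                                   trivial_name = "lithocholic acid"),
    "ursodeoxycholic acid" = bile_salt(24, "acid", "5b", c("3a", "7b"),
                                       trivial_name = "ursodeoxycholic acid"),
    "allocholic acid" = bile_salt(24, "acid", "5a", c("3a", "7a", "12a"),
                                  trivial_name = "allocholic acid"),
    "allochenodeoxycholic acid" = bile_salt(24, "acid", "5a", c("3a", "7a"),
                                            trivial_name = "allochenodeoxycholic acid"),
    "hyocholic acid" = bile_salt(24, "acid", "5b", c("3a", "6a", "7a"),
                                 trivial_name = "hyocholic acid"),
    "a-muricholic acid" = bile_salt(24, "acid", "5b", c("3a", "6b", "7a"),
                                    trivial_name = "a-muricholic acid"),
    "b-muricholic acid" = bile_salt(24, "acid", "5b", c("3a", "6b", "7b"),
                                    trivial_name = "b-muricholic acid"),
    "pythocholic acid" = bile_salt(24, "acid", "5b", c("3a", "12a", "16a"),
                                   trivial_name = "pythocholic acid"),
    "bitocholic acid" = bile_salt(24, "acid", "5b", c("3a", "12a", "23R"),
                                  trivial_name = "bitocholic acid"),
    "varanic acid" = bile_salt(27, "acid", "5b", c("3a", "7a", "12a", "24R"),
                               trivial_name = "varanic acid"),
    # C27 bile alcohols (terminal 27-OH implied by the alcohol terminal group)
    "5b-cyprinol" = bile_salt(27, "alcohol", "5b", c("3a", "7a", "12a", "26"),
                              trivial_name = "5b-cyprinol"),
    "5a-cyprinol" = bile_salt(27, "alcohol", "5a", c("3a", "7a", "12a", "26"),
                              trivial_name = "5a-cyprinol")
  )
  aliases <- c(
    "ca" = "cholic acid",
    "cdca" = "chenodeoxycholic acid",
    "dca" = "deoxycholic acid",
    "lca" = "lithocholic acid",
    "udca" = "ursodeoxycholic acid",
    "alloca" = "allocholic acid",
    "allo-cholic acid" = "allocholic acid",
    "5a-cholic acid" = "allocholic acid",
    "alpha-muricholic acid" = "a-muricholic acid",
    "beta-muricholic acid" = "b-muricholic acid",
    "pythoca" = "pythocholic acid"
  )
  for (a in names(aliases)) reg[[a]] <- reg[[aliases[[a]]]]
  reg
}

.registry_env <- new.env(parent = emptyenv())

registry_get <- function() {
  if (is.null(.registry_env$reg)) .registry_env$reg <- .registry_build()
  .registry_env$reg
}

#' Registry of trivial bile-salt names
#'
#' Trivial names and common abbreviations (CA, CDCA, DCA, LCA, UDCA, varanic
#' acid, pythocholic acid, bitocholic acid, hyocholic acid, the muricholic
#' acids, allocholic acid, cyprinols) mapped to structural descriptors.
#' [parse_bile_salt_name()] consults this registry before attempting a
#' systematic parse.
#'
#' @return Named list of [bile_salt()] descriptors (lowercase keys).
#' @examples
#' names(bile_salt_registry())
#' @export
bile_salt_registry <- function() {
  registry_get()
}
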