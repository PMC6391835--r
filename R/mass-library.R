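# Elemental masses per mass dialect. "nominal" uses the integer mass of the
# most abundant isotope, which is the arithmetic of the printed adduct tables.
.element_masses <- list(
  nominal      = c(H = 1, C = 12, N = 14, O = 16, Na = 23),
  monoisotopic = c(H = 1.00782503207, C = 12, N = 14.0030740048,
                   O = 15.9949146196, Na = 22.9897692809),
  average      = c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   Na = 22.98976928)
)

.electron_mass <- 0.00054858

.mass_modes <- c("nominal", "monoisotopic", "average")

match_mode <- function(mode) {
  rlang::arg_match0(mode, .mass_modes, arg_nm = "mode")
}

# Parse an elemental formula ("C6H12O6") into a named count vector.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) {
    return(c(H = 0, C = 0, N = 0, O = 0, Na = 0))
  }
  m <- stringr::str_match_all(formula, "([A-Z][a-z]?)(\\d*)")[[1]]
  m <- m[nzchar(m[, 1]), , drop = FALSE]
  counts <- c(H = 0, C = 0, N = 0, O = 0, Na = 0)
  for (i in seq_len(nrow(m))) {
    el <- m[i, 2]
    if (!el %in% names(counts)) {
      rlang::abort(paste0("unsupported element in formula: ", el))
    }
    n <- if (nzchar(m[i, 3])) as.integer(m[i, 3]) else 1L
    counts[el] <- counts[el] + n
  }
  counts
}

formula_mass <- function(formula, mode = "nominal") {
  mode <- match_mode(mode)
  counts <- parse_formula(formula)
  sum(counts * .element_masses[[mode]][names(counts)])
}

#' Built-in small-molecule mass library
#'
#' The closed set of neutral analytes, solvent/neutral adducts and charge
#' carriers used throughout the package, with masses in three dialects
#' (nominal integer, monoisotopic, average). Analytes are the seven
#' monosaccharide products of oxidative cellulose degradation (glucose and its
#' C1-, C6- and C1/C6-oxidized acids with their lactones) and the three forms
#' of the ascorbate reductant present in LPMO reaction mixtures. Charge-carrier
#' masses in monoisotopic mode account for the electron.
#'
#' @param extra Optional data frame (name, formula, class) or path to a JSON
#'   file of such records appended to the built-in entries; used to extend the
#'   analyte set without editing the package. JSON records may instead give
#'   explicit `nominal`/`monoisotopic`/`average` masses.
#' @return A `mass_library` tibble with columns `name`, `class`
#'   (analyte/adduct/carrier), `formula`, `nominal`, `monoisotopic`, `average`.
#' @examples
#' lib <- default_library()
#' library_mass(lib, "glucuronic acid")          # 194
#' library_mass(lib, "saccharic acid lactone")   # 192
#' @export
default_library <- function(extra = NULL) {
  base <- tibble::tribble(
    ~name,                           ~class,    ~formula,
    "glucose",                       "analyte", "C6H12O6",
    "gluconic acid",                 "analyte", "C6H12O7",
    "gluconic acid lactone",         "analyte", "C6H10O6",
    "glucuronic acid",               "analyte", "C6H10O7",
    "glucuronic acid lactone",       "analyte", "C6H8O6",
    "saccharic acid",                "analyte", "C6H10O8",
    "saccharic acid lactone",        "analyte", "C6H8O7",
    "reduced ascorbate",             "analyte", "C6H8O6",
    "oxidized ascorbate",            "analyte", "C6H6O6",
    "oxidized-dehydrated ascorbate", "analyte", "C6H4O5",
    "H2O",                           "adduct",  "H2O",
    "NH3",                           "adduct",  "NH3",
    "CH3OH",                         "adduct",  "CH4O",
    "HCOOH",                         "adduct",  "CH2O2",
    "CH3COOH",                       "adduct",  "C2H4O2"
  )
  base$nominal      <- vapply(base$formula, formula_mass, 0, mode = "nominal")
  base$monoisotopic <- vapply(base$formula, formula_mass, 0, mode = "monoisotopic")
  base$average      <- vapply(base$formula, formula_mass, 0, mode = "average")

  carriers <- tibble::tibble(
    name    = c("proton", "sodium", "ammonium", "deprotonation"),
    class   = "carrier",
    formula = c("H", "Na", "NH4", NA_character_),
    nominal = c(1, 23, 18, -1),
    monoisotopic = c(
      formula_mass("H", "monoisotopic") - .electron_mass,
      formula_mass("Na", "monoisotopic") - .electron_mass,
      formula_mass("NH4", "monoisotopic") - .electron_mass,
      -(formula_mass("H", "monoisotopic") - .electron_mass)
    ),
    average = c(1.007, 22.989, 18.038, -1.007)
  )

  lib <- dplyr::bind_rows(base, carriers)
  if (!is.null(extra)) {
    lib <- dplyr::bind_rows(lib, normalize_library_extra(extra))
  }
  if (anyDuplicated(lib$name)) {
    rlang::abort("duplicate names in mass library")
  }
  structure(lib, class = c("mass_library", class(lib)))
}

normalize_library_extra <- function(extra) {
  if (is.character(extra) && length(extra) == 1) {
    extra <- jsonlite::fromJSON(extra)
  }
  extra <- tibble::as_tibble(extra)
  if (!"name" %in% names(extra)) {
    rlang::abort("library extension needs a 'name' column")
  }
  if (!"class" %in% names(extra)) extra$class <- "analyte"
  if (!"formula" %in% names(extra)) extra$formula <- NA_character_
  for (mode in .mass_modes) {
    if (!mode %in% names(extra)) {
      extra[[mode]] <- vapply(extra$formula, formula_mass, 0, mode = mode)
    }
  }
  extra[, c("name", "class", "formula", .mass_modes)]
}

#' Look up masses in a mass library
#'
#' Unknown names are an error: the library is closed so that a typo cannot
#' silently shift an annotation.
#'
#' @param library A `mass_library` from [default_library()].
#' @param name Character vector of entry names.
#' @param mode Mass dialect: "nominal" (default), "monoisotopic" or "average".
#' @return Numeric vector of masses.
#' @export
library_mass <- function(library, name, mode = "nominal") {
  mode <- match_mode(mode)
  idx <- match(name, library$name)
  if (anyNA(idx)) {
    rlang::abort(paste0(
      "unknown species in mass library: ",
      paste(unique(name[is.na(idx)]), collapse = ", ")
    ))
  }
  unname(library[[mode]][idx])
}

library_entries <- function(library, class) {
  library$name[library$class == class]
}
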