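# Oxidized cello-oligosaccharides are modeled compositionally: an ordered
# chain of glucosyl residues (residue 1 = non-reducing end, last = reducing
# end), each carrying an oxidation state. Masses are 162*dp + 18 plus additive
# per-residue deltas, in the nominal dialect:
#   C1 carboxyl (aldonic acid, reducing end only)      +16
#   C4 ketone (ketoaldose)                              -2
#   C6 aldehyde (hexodialdose)                          -2
#   C6 carboxyl (uronic acid)                          +14
#   each lactone ring closure                          -18
#   4,5-unsaturation (lyase product, non-reducing end) -18
# The same deltas are expressed as elemental changes so that monoisotopic and
# average dialects stay consistent: +O, -H2, -H2, +O-H2, -H2O, -H2O.

.c6_states <- c("none", "aldehyde", "acid")

.delta_formula <- list(
  c1_acid   = c(H = 0, O = 1),
  c4_keto   = c(H = -2, O = 0),
  c6_ald    = c(H = -2, O = 0),
  c6_acid   = c(H = -2, O = 1),
  lactone   = c(H = -2, O = -1),
  unsat_4_5 = c(H = -2, O = -1)
)

delta_unit <- function(which, mode = "nominal") {
  mode <- match_mode(mode)
  el <- .element_masses[[mode]]
  f <- .delta_formula[[which]]
  sum(f * el[names(f)])
}

residue_tibble <- function(n) {
  tibble::tibble(
    c1_acid = rep(FALSE, n),
    c4_keto = rep(FALSE, n),
    c6 = rep("none", n),
    lactones = rep(0L, n),
    unsat_4_5 = rep(FALSE, n)
  )
}

#' Per-residue oxidation-state mass delta
#'
#' Vectorized over parallel state arguments. The delta is the mass difference
#' a residue's oxidation state contributes relative to an unmodified
#' anhydroglucosyl residue; deltas are additive within and across residues.
#'
#' @param c1_acid Logical; reducing-end aldehyde oxidized to carboxyl (+16).
#' @param c4_keto Logical; C4 ketone (-2).
#' @param c6 One of "none", "aldehyde" (-2), "acid" (+14).
#' @param lactones Integer count of intramolecular ester closures (-18 each);
#'   cannot exceed the number of carboxyl groups on the residue.
#' @param unsat_4_5 Logical; 4,5-ring unsaturation of a lyase-generated
#'   non-reducing end (-18).
#' @param mode Mass dialect (see [default_library()]).
#' @return Numeric vector of deltas.
#' @examples
#' residue_delta(c1_acid = TRUE)               # +16, aldonic acid
#' residue_delta(c6 = "acid")                  # +14, uronic acid
#' residue_delta(c1_acid = TRUE, c6 = "acid", lactones = 1)  # +12
#' @export
residue_delta <- function(c1_acid = FALSE, c4_keto = FALSE, c6 = "none",
                          lactones = 0L, unsat_4_5 = FALSE,
                          mode = "nominal") {
  n <- max(length(c1_acid), length(c4_keto), length(c6), length(lactones),
           length(unsat_4_5))
  c1_acid <- rep_len(as.logical(c1_acid), n)
  c4_keto <- rep_len(as.logical(c4_keto), n)
  c6 <- rep_len(as.character(c6), n)
  lactones <- rep_len(as.integer(lactones), n)
  unsat_4_5 <- rep_len(as.logical(unsat_4_5), n)
  if (!all(c6 %in% .c6_states)) {
    rlang::abort("c6 state must be one of none/aldehyde/acid")
  }
  acids <- c1_acid + (c6 == "acid")
  if (any(lactones < 0)) rlang::abort("lactone count must be >= 0")
  bad <- lactones > acids
  if (any(bad)) {
    rlang::abort(
      "invalid oxidation state: lactones exceed carboxyl groups (lactones <= c1_acid + (c6 == 'acid'))"
    )
  }
  c1_acid * delta_unit("c1_acid", mode) +
    c4_keto * delta_unit("c4_keto", mode) +
    (c6 == "aldehyde") * delta_unit("c6_ald", mode) +
    (c6 == "acid") * delta_unit("c6_acid", mode) +
    lactones * delta_unit("lactone", mode) +
    unsat_4_5 * delta_unit("unsat_4_5", mode)
}

#' Construct an oxidized cello-oligosaccharide
#'
#' Accepts either a chain length (an unmodified chain of that DP) or a compact
#' chain string, non-reducing end first, e.g. `"G-G(c6a)-G(c1)"`. Flags inside
#' the parentheses: `c1` C1 carboxyl, `c4k` C4 ketone, `c6d` C6 aldehyde,
#' `c6a` C6 carboxyl, `L` one lactone (repeat or prefix with a count, `2L`),
#' `u` 4,5-unsaturation.
#'
#' @param x Integer chain length, a chain string, a residue data frame with
#'   columns `c1_acid`, `c4_keto`, `c6`, `lactones`, `unsat_4_5`, or an
#'   existing `oligo`.
#' @return An `oligo` object.
#' @examples
#' oligo(3)                      # cellotriose, neutral nominal mass 504
#' oligo("G(c6d)-G-G")           # one C6 aldehyde: the m/z 525 sodiated DP3-2
#' oligo("G(c6a)-G-G(c1,c6a,L)")
#' @export
oligo <- function(x) {
  if (inherits(x, "oligo")) return(x)
  if (is.numeric(x) && length(x) == 1) {
    if (x < 1 || x != round(x)) rlang::abort("dp must be a positive integer")
    return(new_oligo(residue_tibble(as.integer(x))))
  }
  if (is.character(x) && length(x) == 1) {
    return(parse_oligo(x))
  }
  if (is.data.frame(x)) {
    need <- c("c1_acid", "c4_keto", "c6", "lactones", "unsat_4_5")
    missing <- setdiff(need, names(x))
    if (length(missing)) {
      rlang::abort(paste0("residue table lacks columns: ",
                          paste(missing, collapse = ", ")))
    }
    return(new_oligo(tibble::as_tibble(x[, need])))
  }
  rlang::abort("cannot interpret input as an oligosaccharide")
}

new_oligo <- function(residues) {
  res <- structure(list(residues = residues), class = "oligo")
  validate_oligo(res)
  res
}

validate_oligo <- function(x) {
  r <- x$residues
  n <- nrow(r)
  if (n < 1) rlang::abort("an oligosaccharide needs at least one residue")
  if (any(r$c1_acid & seq_len(n) != n)) {
    rlang::abort("c1_acid is only legal on the reducing-end residue")
  }
  if (any(r$unsat_4_5 & seq_len(n) != 1)) {
    rlang::abort("unsat_4_5 is only legal on the non-reducing-end residue")
  }
  # residue_delta re-checks the lactone/carboxyl invariant
  invisible(residue_delta(r$c1_acid, r$c4_keto, r$c6, r$lactones, r$unsat_4_5))
  invisible(x)
}

#' @export
dp <- function(x) UseMethod("dp")

#' Degree of polymerization
#' @param x An `oligo`.
#' @rdname dp
#' @export
dp.oligo <- function(x) nrow(x$residues)

parse_oligo <- function(spec) {
  spec <- gsub("\\s", "", spec)
  parts <- strsplit(spec, "-(?![^(]*\\))", perl = TRUE)[[1]]
  if (!length(parts)) rlang::abort("empty chain string")
  res <- residue_tibble(length(parts))
  for (i in seq_along(parts)) {
    m <- stringr::str_match(parts[i], "^G(?:\\(([^)]*)\\))?$")
    if (is.na(m[1, 1])) {
      rlang::abort(paste0("cannot parse residue '", parts[i], "'"))
    }
    flags <- m[1, 2]
    if (is.na(flags) || !nzchar(flags)) next
    for (flag in strsplit(flags, ",")[[1]]) {
      lm <- stringr::str_match(flag, "^(\\d*)L$")
      if (!is.na(lm[1, 1])) {
        k <- if (nzchar(lm[1, 2])) as.integer(lm[1, 2]) else 1L
        res$lactones[i] <- res$lactones[i] + k
      } else if (flag == "c1") {
        res$c1_acid[i] <- TRUE
      } else if (flag == "c4k") {
        res$c4_keto[i] <- TRUE
      } else if (flag == "c6d") {
        res$c6[i] <- "aldehyde"
      } else if (flag == "c6a") {
        res$c6[i] <- "acid"
      } else if (flag == "u") {
        res$unsat_4_5[i] <- TRUE
      } else {
        rlang::abort(paste0("unknown residue flag '", flag, "'"))
      }
    }
  }
  new_oligo(res)
}

#' @export
format.oligo <- function(x, ...) {
  r <- x$residues
  parts <- vapply(seq_len(nrow(r)), function(i) {
    flags <- c(
      if (r$c1_acid[i]) "c1",
      if (r$c4_keto[i]) "c4k",
      if (r$c6[i] == "aldehyde") "c6d",
      if (r$c6[i] == "acid") "c6a",
      if (r$lactones[i] == 1) "L"
      else if (r$lactones[i] > 1) paste0(r$lactones[i], "L"),
      if (r$unsat_4_5[i]) "u"
    )
    if (length(flags)) paste0("G(", paste(flags, collapse = ","), ")") else "G"
  }, character(1))
  paste(parts, collapse = "-")
}

#' @export
print.oligo <- function(x, ...) {
  cat("<oligo> ", format(x),
      "  dp=", dp(x),
      "  nominal mass=", oligo_mass(x),
      " (delta ", sprintf("%+d", delta_class(x)), ")\n", sep = "")
  invisible(x)
}

#' @export
as.character.oligo <- function(x, ...) format(x)

#' Neutral mass of an oligosaccharide
#'
#' In nominal mode this is exactly `162*dp + 18 + sum(residue deltas)`.
#'
#' @param x An `oligo` (or anything [oligo()] accepts).
#' @param mode Mass dialect.
#' @return Neutral mass (scalar).
#' @examples
#' oligo_mass(oligo(3))             # 504
#' oligo_mass(oligo("G(c6d)-G-G"))  # 502; sodiated ion 525
#' @export
oligo_mass <- function(x, mode = "nominal") {
  x <- oligo(x)
  mode <- match_mode(mode)
  el <- .element_masses[[mode]]
  residue <- 6 * el["C"] + 10 * el["H"] + 5 * el["O"]  # anhydroglucose
  water <- 2 * el["H"] + el["O"]
  r <- x$residues
  unname(residue * dp(x) + water +
    sum(residue_delta(r$c1_acid, r$c4_keto, r$c6, r$lactones, r$unsat_4_5,
                      mode = mode)))
}

#' Oxidation delta class
#'
#' Nominal neutral mass minus the mass of the unmodified chain of the same DP;
#' the class labels used on annotated MALDI spectra (+16, -2, +14, ...).
#'
#' @inheritParams oligo_mass
#' @return Integer delta.
#' @export
delta_class <- function(x) {
  x <- oligo(x)
  as.integer(round(oligo_mass(x, "nominal") - (162 * dp(x) + 18)))
}

#' Name the monosaccharide corresponding to a DP 1 species
#'
#' Maps single-residue oxidation states onto the monosaccharide standards
#' used to identify degradation end products: glucose, gluconic acid
#' (C1-oxidized), glucuronic acid (C6-oxidized), saccharic acid (C1- and
#' C6-oxidized), and their mono-lactones. States with a C4 ketone or a C6
#' aldehyde have no monosaccharide standard and return `NA` (not an error).
#'
#' @param x A DP 1 `oligo`.
#' @return Character scalar (a [default_library()] analyte name) or `NA`.
#' @examples
#' monosaccharide_identity(oligo("G(c6a)"))      # glucuronic acid
#' monosaccharide_identity(oligo("G(c1,c6a)"))   # saccharic acid
#' @export
monosaccharide_identity <- function(x) {
  x <- oligo(x)
  if (dp(x) != 1) rlang::abort("monosaccharide_identity needs dp == 1")
  r <- x$residues
  if (r$c4_keto[1] || r$c6[1] == "aldehyde" || r$unsat_4_5[1] ||
      r$lactones[1] > 1) {
    return(NA_character_)
  }
  base <- if (r$c1_acid[1] && r$c6[1] == "acid") "saccharic acid"
    else if (r$c1_acid[1]) "gluconic acid"
    else if (r$c6[1] == "acid") "glucuronic acid"
    else "glucose"
  if (r$lactones[1] == 1) paste(base, "lactone") else base
}
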