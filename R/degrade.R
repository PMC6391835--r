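# Exo-degradation of oxidized cello-oligosaccharides. Beta-glucosidase (BGL)
# releases an unmodified glucosyl unit from the non-reducing end;
# beta-glucuronidase (GUS) releases a glucuronosyl (C6-carboxyl) unit. The
# two alternate down a chain until a residue neither accepts (C4 ketone, C6
# aldehyde, lactone, 4,5-unsaturated end) stalls it or a monosaccharide is
# left. Every hydrolytic release consumes one water (+18 on the product
# ledger), which the census verifies.

nre_state <- function(r) {
  if (r$unsat_4_5[1] || r$lactones[1] > 0) return("blocked")
  if (r$c4_keto[1] || r$c6[1] == "aldehyde") return("blocked")
  if (r$c1_acid[1]) return("blocked")  # dp==1 handled before this
  if (r$c6[1] == "acid") "uronic" else "plain"
}

#' Exhaustive exo-digestion of an oligosaccharide pool
#'
#' Iterates non-reducing-end releases to a fixed point, deterministically.
#' The outcome per chain is independent of pool order; DP 1 species are
#' resolved by [monosaccharide_identity()].
#'
#' @param pool List of `oligo` objects (or chain strings).
#' @param enzymes Subset of `c("BGL", "GUS")`.
#' @param stall_policy What to do with a non-reducing-end residue neither
#'   enzyme accepts: "stall" (default) keeps the chain as a residual;
#'   "pass_through" removes the residue anyway (recorded under its state
#'   label) and continues down the chain.
#' @param library A [default_library()] for the mass ledger.
#' @return A `product_census`: released monosaccharide counts, residual
#'   chains, and a mass ledger proving
#'   `sum(products) == sum(parents) + 18 * cleavages`.
#' @examples
#' digest(list(oligo("G(c6a)-G-G")))              # glucuronic acid + 2 glucose
#' digest(list(oligo("G(c6a)-G-G(c1,c6a)")))      # the saccharic-acid pathway
#' @export
digest <- function(pool, enzymes = c("BGL", "GUS"),
                   stall_policy = c("stall", "pass_through"),
                   library = default_library()) {
  stall_policy <- rlang::arg_match(stall_policy)
  enzymes <- match.arg(enzymes, c("BGL", "GUS"), several.ok = TRUE)
  pool <- lapply(pool, oligo)
  parents_mass <- sum(vapply(pool, oligo_mass, 0))
  monomers <- character(0)
  unnamed <- character(0)
  residuals <- character(0)
  cleavages <- 0L

  for (chain in pool) {
    r <- chain$residues
    repeat {
      if (nrow(r) == 1) {
        id <- monosaccharide_identity(new_oligo(r))
        if (is.na(id)) {
          unnamed <- c(unnamed, format(new_oligo(r)))
        } else {
          monomers <- c(monomers, id)
        }
        break
      }
      state <- nre_state(r[1, ])
      released <- switch(
        state,
        plain = if ("BGL" %in% enzymes) "glucose" else NA_character_,
        uronic = if ("GUS" %in% enzymes) "glucuronic acid" else NA_character_,
        blocked = NA_character_
      )
      if (!is.na(released)) {
        monomers <- c(monomers, released)
        cleavages <- cleavages + 1L
        r <- r[-1, ]
      } else if (stall_policy == "pass_through") {
        unnamed <- c(unnamed, format(new_oligo(r[1, ])))
        cleavages <- cleavages + 1L
        r <- r[-1, ]
      } else {
        residuals <- c(residuals, format(new_oligo(r)))
        break
      }
    }
  }

  census <- new_product_census(monomers, unnamed, residuals, cleavages,
                               parents_mass, library)
  ledger <- census$mass_ledger
  stopifnot(abs(ledger$products - ledger$parents - 18 * ledger$cleavages) <
              1e-9)
  census
}

new_product_census <- function(monomers, unnamed, residuals, cleavages,
                               parents_mass, library) {
  mono_tbl <- if (length(monomers)) {
    dplyr::count(tibble::tibble(name = monomers), .data$name, name = "n")
  } else {
    tibble::tibble(name = character(0), n = integer(0))
  }
  mono_tbl$nominal_mass <- if (nrow(mono_tbl)) {
    library_mass(library, mono_tbl$name)
  } else numeric(0)
  unnamed_tbl <- if (length(unnamed)) {
    dplyr::count(tibble::tibble(spec = unnamed), .data$spec, name = "n")
  } else tibble::tibble(spec = character(0), n = integer(0))
  resid_tbl <- if (length(residuals)) {
    dplyr::count(tibble::tibble(spec = residuals), .data$spec, name = "n")
  } else tibble::tibble(spec = character(0), n = integer(0))
  resid_tbl$delta <- if (nrow(resid_tbl)) {
    vapply(resid_tbl$spec, function(s) delta_class(oligo(s)), 0L)
  } else integer(0)

  products_mass <- sum(mono_tbl$n * mono_tbl$nominal_mass) +
    sum(vapply(unnamed, function(s) oligo_mass(oligo(s)), 0)) +
    sum(vapply(residuals, function(s) oligo_mass(oligo(s)), 0))

  structure(
    list(
      monosaccharides = mono_tbl,
      unnamed = unnamed_tbl,
      residuals = resid_tbl,
      mass_ledger = list(parents = parents_mass, products = products_mass,
                         cleavages = cleavages)
    ),
    class = "product_census"
  )
}

#' @export
print.product_census <- function(x, ...) {
  cat("<product_census>\n")
  if (nrow(x$monosaccharides)) {
    cat("  released monosaccharides:\n")
    for (i in seq_len(nrow(x$monosaccharides))) {
      cat("    ", x$monosaccharides$name[i], " x", x$monosaccharides$n[i],
          "\n", sep = "")
    }
  }
  if (nrow(x$unnamed)) {
    cat("  unnamed DP1 species:", sum(x$unnamed$n), "\n")
  }
  if (nrow(x$residuals)) {
    cat("  stalled residual chains:", sum(x$residuals$n), "\n")
  }
  l <- x$mass_ledger
  cat("  mass ledger: parents ", l$parents, " + ", 18 * l$cleavages,
      " (", l$cleavages, " cleavages) = products ", l$products, "\n",
      sep = "")
  invisible(x)
}

#' Polysaccharide-lyase cleavage at a uronate residue
#'
#' Beta-elimination cleaves the glycosidic bond on the 4-side of a
#' C6-carboxyl residue: the fragment toward the non-reducing end gains a new
#' (ordinary) reducing end and the uronate becomes the 4,5-unsaturated
#' non-reducing end of the distal fragment. No water is consumed, so the two
#' fragment masses sum exactly to the parent mass.
#'
#' @param x An `oligo`.
#' @param site 1-based index (from the non-reducing end) of the uronate
#'   residue; must be in `2..dp` and carry a C6 carboxyl.
#' @return List of two `oligo`s: `proximal` (new reducing end) and `distal`
#'   (4,5-unsaturated uronate non-reducing end).
#' @examples
#' pl_cleave(oligo("G-G-G(c6a)-G"), site = 3)
#' @export
pl_cleave <- function(x, site) {
  x <- oligo(x)
  n <- dp(x)
  if (site < 2 || site > n) {
    rlang::abort("site must identify a non-terminal-NRE residue (2..dp)")
  }
  if (x$residues$c6[site] != "acid") {
    rlang::abort("lyase rule not applicable: residue at site lacks a C6 carboxyl")
  }
  proximal <- new_oligo(x$residues[seq_len(site - 1), ])
  distal_res <- x$residues[site:n, ]
  distal_res$unsat_4_5[1] <- TRUE
  distal <- new_oligo(distal_res)
  list(proximal = proximal, distal = distal)
}

#' Delta-class census of an oligosaccharide pool
#'
#' @param pool List of `oligo`s or chain strings.
#' @return Tibble (`delta`, `n`) of species counts per oxidation delta class.
#' @export
pool_census <- function(pool) {
  deltas <- vapply(lapply(pool, oligo), delta_class, 0L)
  dplyr::count(tibble::tibble(delta = deltas), .data$delta, name = "n")
}

#' Theoretical spectrum of a pool or digestion census
#'
#' Maps each species to its singly cationized m/z (the MALDI convention) and
#' sums counts per m/z.
#'
#' @param x A pool (list of `oligo`s) or a `product_census`.
#' @param cation Charge-carrier name (default "sodium").
#' @param library,mode Mass library and dialect.
#' @return A [peaklist()] with intensities equal to species counts.
#' @export
census_to_spectrum <- function(x, cation = "sodium",
                               library = default_library(),
                               mode = "nominal") {
  cat_mass <- library_mass(library, cation, mode)
  if (inherits(x, "product_census")) {
    masses <- c(
      rep(x$monosaccharides$nominal_mass, x$monosaccharides$n),
      rep(vapply(x$unnamed$spec, function(s) oligo_mass(oligo(s), mode), 0),
          x$unnamed$n),
      rep(vapply(x$residuals$spec, function(s) oligo_mass(oligo(s), mode), 0),
          x$residuals$n)
    )
  } else {
    masses <- vapply(lapply(x, oligo), oligo_mass, 0, mode = mode)
  }
  if (!length(masses)) {
    return(peaklist(numeric(0), numeric(0), "positive", "maldi"))
  }
  agg <- dplyr::count(tibble::tibble(mz = masses + cat_mass), .data$mz,
                      name = "intensity")
  peaklist(agg$mz, agg$intensity, "positive", "maldi")
}
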