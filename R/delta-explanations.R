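# Inverse problem for the delta classes read off annotated MALDI spectra:
# which combinations of oxidation events explain a given mass shift? Results
# are composition multisets, not positioned assignments, because an in-chain
# C6 oxidation is positionally degenerate on a spectrum (any of the dp
# glucosyl units could carry it).

#' Enumerate oxidation-state compositions explaining a mass delta
#'
#' Finds every multiset of per-residue oxidation events whose nominal deltas
#' sum to `delta` on a chain of length `dp`, subject to positional legality
#' (at most one C1 carboxyl, which sits on the reducing end; at most one
#' 4,5-unsaturation, on the non-reducing end; at most one C6 state per
#' residue) and to a cap on the total number of oxidation events. Lactones do
#' not count as oxidation events but cannot exceed the number of carboxyl
#' groups in the composition.
#'
#' @param delta Integer nominal mass shift relative to the unmodified chain.
#' @param dp Chain length (>= 1).
#' @param cap Maximum number of oxidation events (C1, C4 ketone, C6 aldehyde,
#'   C6 acid) per chain; default 3, the largest combination labeled on the
#'   spectra this model was built around.
#' @param include_unsaturated Also allow the lyase-type 4,5-unsaturated
#'   non-reducing end (default `FALSE`: it is a degradation product, not a
#'   monooxygenase product).
#' @param positions If `TRUE`, expand each composition into the distinct
#'   positioned residue assignments it represents (as chain strings).
#' @return A tibble with event counts (`n_c1_acid`, `n_c4_keto`,
#'   `n_c6_aldehyde`, `n_c6_acid`, `n_lactone`, `n_unsat_4_5`), the `delta`,
#'   and a human-readable `label`; with `positions = TRUE` also a list-column
#'   `chains`. Zero rows when no explanation exists within the cap.
#' @examples
#' delta_explanations(14, dp = 3)  # C1+C4 pair, C1+C6-aldehyde pair, or one uronate
#' delta_explanations(12, dp = 3)  # includes the C1/C6 dilactone-free lactone class
#' @export
delta_explanations <- function(delta, dp, cap = 3,
                               include_unsaturated = FALSE,
                               positions = FALSE) {
  if (dp < 1) rlang::abort("dp must be >= 1")
  max_c6 <- dp
  grid <- tidyr::expand_grid(
    n_c1_acid = 0:1,
    n_c4_keto = 0:min(cap, dp),
    n_c6_aldehyde = 0:min(cap, max_c6),
    n_c6_acid = 0:min(cap, max_c6),
    n_unsat_4_5 = if (include_unsaturated) 0:1 else 0L
  )
  grid <- dplyr::filter(
    grid,
    .data$n_c1_acid + .data$n_c4_keto + .data$n_c6_aldehyde +
      .data$n_c6_acid <= cap,
    .data$n_c6_aldehyde + .data$n_c6_acid <= max_c6
  )
  # lactones: 0 .. number of carboxyls in the composition
  grid <- tidyr::uncount(grid, .data$n_c1_acid + .data$n_c6_acid + 1,
                         .id = ".lac")
  grid$n_lactone <- as.integer(grid$.lac) - 1L
  grid$.lac <- NULL
  grid$delta <- 16L * grid$n_c1_acid - 2L * grid$n_c4_keto -
    2L * grid$n_c6_aldehyde + 14L * grid$n_c6_acid -
    18L * grid$n_lactone - 18L * grid$n_unsat_4_5
  out <- dplyr::filter(grid, .data$delta == !!as.integer(delta))
  out <- dplyr::filter(out, composition_fits(
    dp, .data$n_c1_acid, .data$n_c4_keto, .data$n_c6_aldehyde,
    .data$n_c6_acid, .data$n_unsat_4_5
  ))
  out <- out[, c("n_c1_acid", "n_c4_keto", "n_c6_aldehyde", "n_c6_acid",
                 "n_lactone", "n_unsat_4_5", "delta")]
  out <- dplyr::arrange(out, .data$n_c1_acid, .data$n_c4_keto,
                        .data$n_c6_aldehyde, .data$n_c6_acid,
                        .data$n_lactone, .data$n_unsat_4_5)
  out$label <- composition_label(out)
  if (positions) {
    out$chains <- purrr::pmap(
      out[, 1:6],
      function(n_c1_acid, n_c4_keto, n_c6_aldehyde, n_c6_acid, n_lactone,
               n_unsat_4_5) {
        expand_positions(dp, n_c1_acid, n_c4_keto, n_c6_aldehyde, n_c6_acid,
                         n_lactone, n_unsat_4_5)
      }
    )
  }
  out
}

# Can the event counts be placed on a chain of length dp? C4 ketones and C6
# states are independent flags, so a residue may carry one of each; the only
# capacity constraints are the per-flag ones.
composition_fits <- function(dp, n_c1, n_c4, n_c6d, n_c6a, n_u) {
  n_c1 <= 1 & n_u <= 1 & n_c4 <= dp & (n_c6d + n_c6a) <= dp
}

composition_label <- function(x) {
  purrr::pmap_chr(
    x[, c("n_c1_acid", "n_c4_keto", "n_c6_aldehyde", "n_c6_acid",
          "n_lactone", "n_unsat_4_5")],
    function(n_c1_acid, n_c4_keto, n_c6_aldehyde, n_c6_acid, n_lactone,
             n_unsat_4_5) {
      part <- function(n, txt) if (n > 0) paste0(if (n > 1) n, txt) else NULL
      bits <- c(
        part(n_c1_acid, "C1-acid"),
        part(n_c4_keto, "C4-keto"),
        part(n_c6_aldehyde, "C6-aldehyde"),
        part(n_c6_acid, "C6-acid"),
        part(n_lactone, "lactone"),
        part(n_unsat_4_5, "4,5-unsaturation")
      )
      if (is.null(bits)) "unmodified" else paste(bits, collapse = " + ")
    }
  )
}

# All distinct positioned assignments of a composition on a chain of length
# dp, as chain strings. Lactones are attached to carboxyl-bearing residues in
# every distinct way.
expand_positions <- function(dp, n_c1, n_c4, n_c6d, n_c6a, n_lac, n_u) {
  base <- residue_tibble(dp)
  states <- list(base)
  if (n_c1) states <- lapply(states, function(r) { r$c1_acid[dp] <- TRUE; r })
  if (n_u) states <- lapply(states, function(r) { r$unsat_4_5[1] <- TRUE; r })
  place_flags <- function(states, n, set) {
    if (n == 0) return(states)
    out <- list()
    for (r in states) {
      for (pos in utils::combn(dp, n, simplify = FALSE)) {
        out[[length(out) + 1]] <- set(r, pos)
      }
    }
    out
  }
  states <- place_flags(states, n_c4, function(r, pos) {
    r$c4_keto[pos] <- TRUE; r
  })
  # C6 states: choose positions for aldehydes and acids without overlap
  if (n_c6d + n_c6a > 0) {
    out <- list()
    for (r in states) {
      for (pos in utils::combn(dp, n_c6d + n_c6a, simplify = FALSE)) {
        if (n_c6d == 0 || n_c6a == 0) {
          r2 <- r
          r2$c6[pos] <- if (n_c6a > 0) "acid" else "aldehyde"
          out[[length(out) + 1]] <- r2
        } else {
          for (ald in utils::combn(pos, n_c6d, simplify = FALSE)) {
            r2 <- r
            r2$c6[ald] <- "aldehyde"
            r2$c6[setdiff(pos, ald)] <- "acid"
            out[[length(out) + 1]] <- r2
          }
        }
      }
    }
    states <- out
  }
  # lactones on carboxyl-bearing residues, respecting per-residue capacity
  if (n_lac > 0) {
    out <- list()
    for (r in states) {
      capacity <- r$c1_acid + (r$c6 == "acid")
      for (assign in lactone_assignments(capacity, n_lac)) {
        r2 <- r
        r2$lactones <- assign
        out[[length(out) + 1]] <- r2
      }
    }
    states <- out
  }
  chains <- unique(vapply(states, function(r) format(new_oligo(r)),
                          character(1)))
  sort(chains)
}

lactone_assignments <- function(capacity, total) {
  if (total == 0) return(list(rep(0L, length(capacity))))
  if (!length(capacity)) return(list())
  out <- list()
  recurse <- function(i, left, acc) {
    if (i > length(capacity)) {
      if (left == 0) out[[length(out) + 1]] <<- acc
      return()
    }
    for (k in 0:min(capacity[i], left)) {
      recurse(i + 1, left - k, c(acc, as.integer(k)))
    }
  }
  recurse(1, total, integer(0))
  out
}
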