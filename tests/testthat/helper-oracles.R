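# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (hardcoded nominal masses, naive nested enumeration)
# so they share no code path with the package internals they check.

# ---- cached ion tables (built once per test run) --------------------------

.table_cache <- new.env(parent = emptyenv())

cached_ion_table <- function(polarity) {
  key <- paste0("tab_", polarity)
  if (is.null(.table_cache[[key]])) {
    .table_cache[[key]] <- ion_table(annotation_config(polarity))
  }
  .table_cache[[key]]
}

# ---- naive adduct-ion enumeration oracle ----------------------------------

oracle_analyte_masses <- c(
  "glucose" = 180, "gluconic acid" = 196, "gluconic acid lactone" = 178,
  "glucuronic acid" = 194, "glucuronic acid lactone" = 176,
  "saccharic acid" = 210, "saccharic acid lactone" = 192,
  "reduced ascorbate" = 176, "oxidized ascorbate" = 174,
  "oxidized-dehydrated ascorbate" = 156
)
oracle_adduct_masses <- c(H2O = 18, NH3 = 17, CH3OH = 32, HCOOH = 46,
                          CH3COOH = 60)

# all multisets of up to `total` items over `types`, as count matrices
oracle_multisets <- function(n_types, total) {
  recurse <- function(i, left) {
    if (i > n_types) return(matrix(integer(0), nrow = 1, ncol = 0))
    do.call(rbind, lapply(0:left, function(k) {
      rest <- recurse(i + 1, left - k)
      cbind(rep(k, nrow(rest)), rest)
    }))
  }
  recurse(1, total)
}

# Full naive enumeration: returns a tibble (mz, signature) over the default
# bounds (<= 2 analytes, z <= 2, <= 6 neutral adducts, <= 1 Na exchange).
oracle_enumeration <- function(polarity) {
  a_names <- names(oracle_analyte_masses)
  analyte_sets <- list()
  for (i in seq_along(a_names)) {
    analyte_sets[[length(analyte_sets) + 1]] <- a_names[i]
    for (j in i:length(a_names)) {
      analyte_sets[[length(analyte_sets) + 1]] <- c(a_names[i], a_names[j])
    }
  }

  if (polarity == "positive") {
    c_types <- c("proton", "sodium", "ammonium")
    c_masses <- c(proton = 1, sodium = 23, ammonium = 18)
    carrier_sets <- list()
    for (z in 1:2) {
      cm <- oracle_multisets(3, z)
      cm <- cm[rowSums(cm) == z, , drop = FALSE]
      for (r in seq_len(nrow(cm))) {
        carrier_sets[[length(carrier_sets) + 1]] <-
          rep(c_types, times = cm[r, ])
      }
    }
    carrier_mass <- vapply(carrier_sets, function(s) sum(c_masses[s]), 0)
    carrier_z <- lengths(carrier_sets)
  } else {
    carrier_sets <- list()
    for (s in 0:1) for (z in 1:2) {
      carrier_sets[[length(carrier_sets) + 1]] <-
        c(rep("deprotonation", z + s), rep("sodium", s))
    }
    carrier_mass <- vapply(carrier_sets, function(set) {
      -sum(set == "deprotonation") + 23 * sum(set == "sodium")
    }, 0)
    carrier_z <- vapply(carrier_sets, function(set) {
      sum(set == "deprotonation") - sum(set == "sodium")
    }, 0)
  }

  ad_counts <- oracle_multisets(5, 6)
  ad_mass <- as.numeric(ad_counts %*% oracle_adduct_masses)
  ad_sig <- vapply(seq_len(nrow(ad_counts)), function(r) {
    paste(sort(rep(names(oracle_adduct_masses), times = ad_counts[r, ])),
          collapse = ",")
  }, character(1))

  pol3 <- substr(polarity, 1, 3)
  rows <- list()
  for (ai in seq_along(analyte_sets)) {
    a_mass <- sum(oracle_analyte_masses[analyte_sets[[ai]]])
    a_sig <- paste(sort(analyte_sets[[ai]]), collapse = ",")
    for (ci in seq_along(carrier_sets)) {
      c_sig <- paste(sort(carrier_sets[[ci]]), collapse = ",")
      z <- carrier_z[ci]
      rows[[length(rows) + 1]] <- tibble::tibble(
        mz = (a_mass + carrier_mass[ci] + ad_mass) / z,
        signature = paste0(pol3, "|z", z, "|A:", a_sig, "|C:", c_sig,
                           "|N:", ad_sig)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# ---- exhaustive positioned oxidation-state oracle -------------------------

# Every legal per-residue state assignment on a chain of length dp with at
# most `cap` oxidation events (no 4,5-unsaturation), tallied as composition
# multisets per delta. Returns a tibble of distinct compositions with delta.
oracle_state_census <- function(dp, cap) {
  res_states <- function(is_re) {
    out <- list()
    for (c1 in if (is_re) c(FALSE, TRUE) else FALSE) {
      for (c4 in c(FALSE, TRUE)) {
        for (c6 in c("none", "aldehyde", "acid")) {
          for (lac in 0:(c1 + (c6 == "acid"))) {
            out[[length(out) + 1]] <- list(c1 = c1, c4 = c4, c6 = c6,
                                           lac = lac)
          }
        }
      }
    }
    out
  }
  inner <- res_states(FALSE)
  re <- res_states(TRUE)
  combos <- list(list())
  for (i in seq_len(dp)) {
    pool <- if (i == dp) re else inner
    combos <- unlist(lapply(combos, function(acc) {
      lapply(pool, function(s) c(acc, list(s)))
    }), recursive = FALSE)
  }
  rows <- lapply(combos, function(chain) {
    n_c1 <- sum(vapply(chain, `[[`, TRUE, "c1"))
    n_c4 <- sum(vapply(chain, `[[`, TRUE, "c4"))
    c6s <- vapply(chain, `[[`, "", "c6")
    n_c6d <- sum(c6s == "aldehyde")
    n_c6a <- sum(c6s == "acid")
    n_lac <- sum(vapply(chain, `[[`, 0, "lac"))
    if (n_c1 + n_c4 + n_c6d + n_c6a > cap) return(NULL)
    tibble::tibble(n_c1_acid = n_c1, n_c4_keto = n_c4,
                   n_c6_aldehyde = n_c6d, n_c6_acid = n_c6a,
                   n_lactone = n_lac,
                   delta = 16 * n_c1 - 2 * n_c4 - 2 * n_c6d + 14 * n_c6a -
                     18 * n_lac)
  })
  dplyr::distinct(dplyr::bind_rows(rows))
}

# ---- random legal oligosaccharides ----------------------------------------

random_oligo <- function(dp = sample(1:6, 1), p_mod = 0.4,
                         allow_unsat = FALSE) {
  r <- tibble::tibble(
    c1_acid = c(rep(FALSE, dp - 1), stats::runif(1) < p_mod),
    c4_keto = stats::runif(dp) < p_mod / 2,
    c6 = sample(c("none", "aldehyde", "acid"), dp, replace = TRUE,
                prob = c(1 - p_mod, p_mod / 2, p_mod / 2)),
    lactones = 0L,
    unsat_4_5 = c(allow_unsat && stats::runif(1) < p_mod / 2,
                  rep(FALSE, dp - 1))
  )
  capacity <- r$c1_acid + (r$c6 == "acid")
  r$lactones <- vapply(capacity, function(k) {
    if (k == 0) 0L else sample(0:k, 1)
  }, 0L)
  oligo(r)
}
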