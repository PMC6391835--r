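# Candidate ion enumeration for full-scan ESI spectra of LPMO degradation
# products. The observable ions are clusters: one or two analyte molecules,
# cationized by H+/Na+/NH4+ (positive mode) or deprotonated with optional
# sodium-for-proton exchange (negative mode), solvated by the neutrals present
# in the reaction/LC solvent (H2O, NH3, CH3OH, HCOOH, CH3COOH). Enumeration
# is complete within the configured bounds -- no pruning -- so a golden table
# of printed decompositions can be checked for exact containment.

`%||%` <- function(a, b) if (is.null(a)) b else a

round_half_up <- function(x) floor(x + 0.5)

#' Annotation configuration
#'
#' Bounds and matching rules for candidate-ion enumeration. The defaults are
#' the smallest bounds that cover every decomposition in the package's golden
#' adduct tables (up to two analytes per cluster, net charge up to 2, up to
#' six neutral adduct molecules, at most one sodium-for-proton exchange in
#' negative mode).
#'
#' @param polarity "positive" or "negative".
#' @param instrument "esi" (adduct/cluster enumeration) or "maldi" (sodiated
#'   oligosaccharide series).
#' @param mode Mass dialect; "nominal" matches integers exactly after
#'   half-up rounding, other dialects use `tolerance`.
#' @param tolerance Mass window for non-nominal dialects (default 0.01).
#' @param max_analytes,max_z,max_neutral_adducts,max_sodium_exchange
#'   Enumeration bounds.
#' @param analytes,adducts Allowed species names; default: all library
#'   analytes / all library neutral adducts.
#' @param dp_range,delta_classes,cation MALDI series parameters (instrument
#'   "maldi" only).
#' @return An `annotation_config` list.
#' @export
annotation_config <- function(polarity = c("positive", "negative"),
                              instrument = c("esi", "maldi"),
                              mode = "nominal",
                              tolerance = NULL,
                              max_analytes = 2,
                              max_z = 2,
                              max_neutral_adducts = 6,
                              max_sodium_exchange = 1,
                              analytes = NULL,
                              adducts = NULL,
                              dp_range = 1:6,
                              delta_classes = c(0, -2, 12, 14, 16, 28),
                              cation = "sodium") {
  polarity <- rlang::arg_match(polarity)
  instrument <- rlang::arg_match(instrument)
  mode <- match_mode(mode)
  structure(
    list(
      polarity = polarity, instrument = instrument, mode = mode,
      tolerance = tolerance %||% if (mode == "nominal") 0 else 0.01,
      max_analytes = max_analytes, max_z = max_z,
      max_neutral_adducts = max_neutral_adducts,
      max_sodium_exchange = max_sodium_exchange,
      analytes = analytes, adducts = adducts,
      dp_range = dp_range, delta_classes = delta_classes, cation = cation
    ),
    class = "annotation_config"
  )
}

#' Construct a single ion species
#'
#' @param analytes Character vector (multiset) of 1-2 analyte names.
#' @param carriers Character multiset of charge carriers: "proton", "sodium",
#'   "ammonium" in positive mode; "deprotonation" and "sodium" (a
#'   sodium-for-proton exchange) in negative mode.
#' @param adducts Character multiset of neutral adduct names.
#' @param polarity "positive" or "negative".
#' @return An `ion_species` list with the derived net charge `z`.
#' @examples
#' ion_mz(ion_species("glucose", c("sodium", "proton")))             # 102
#' ion_mz(ion_species("oxidized ascorbate", "deprotonation",
#'                    polarity = "negative"))                        # 173
#' @export
ion_species <- function(analytes, carriers, adducts = character(),
                        polarity = c("positive", "negative")) {
  polarity <- rlang::arg_match(polarity)
  carriers <- as.character(carriers)
  if (polarity == "positive") {
    bad <- setdiff(carriers, c("proton", "sodium", "ammonium"))
    if (length(bad)) rlang::abort(paste0("not a positive-mode charge carrier: ",
                                         paste(bad, collapse = ", ")))
    z <- length(carriers)
  } else {
    bad <- setdiff(carriers, c("deprotonation", "sodium"))
    if (length(bad)) rlang::abort(paste0("not a negative-mode charge carrier: ",
                                         paste(bad, collapse = ", ")))
    z <- sum(carriers == "deprotonation") - sum(carriers == "sodium")
  }
  if (z < 1) rlang::abort("ion species must carry net charge >= 1")
  structure(
    list(analytes = sort(as.character(analytes)), carriers = sort(carriers),
         adducts = sort(as.character(adducts)), z = as.integer(z),
         polarity = polarity),
    class = "ion_species"
  )
}

#' m/z of an ion species
#'
#' Charge-normalized mass: the summed analyte, carrier and neutral-adduct
#' masses divided by the net charge. Negative-mode deprotonation carries mass
#' -1 (nominal), so the single formula covers both polarities.
#'
#' @param ion An [ion_species()].
#' @param library A [default_library()].
#' @param mode Mass dialect.
#' @return Numeric m/z.
#' @export
ion_mz <- function(ion, library = default_library(), mode = "nominal") {
  if (!inherits(ion, "ion_species")) rlang::abort("need an ion_species")
  total <- sum(library_mass(library, ion$analytes, mode)) +
    sum(library_mass(library, ion$carriers, mode)) +
    sum(library_mass(library, ion$adducts, mode))
  total / ion$z
}

# ---- component tables for full enumeration --------------------------------

multiset_counts <- function(k_max, n_types, total_max) {
  grid <- do.call(expand.grid, rep(list(0:k_max), n_types))
  grid[rowSums(grid) <= total_max, , drop = FALSE]
}

analyte_component <- function(config, library, mode) {
  names <- config$analytes %||% library_entries(library, "analyte")
  sets <- as.list(names)
  if (config$max_analytes >= 2) {
    idx <- which(upper.tri(diag(length(names)), diag = TRUE), arr.ind = TRUE)
    sets <- c(sets, lapply(seq_len(nrow(idx)), function(i) {
      names[c(idx[i, 1], idx[i, 2])]
    }))
  }
  tibble::tibble(
    analytes = sets,
    a_mass = vapply(sets, function(s) sum(library_mass(library, s, mode)), 0),
    a_label = vapply(sets, function(s) {
      paste(sort(library_mass(library, s, "nominal"), decreasing = TRUE),
            collapse = " + ")
    }, character(1)),
    a_sig = vapply(sets, function(s) paste(sort(s), collapse = ","),
                   character(1)),
    a_mass_sig = vapply(sets, function(s) {
      paste(sort(library_mass(library, s, "nominal")), collapse = ",")
    }, character(1)),
    n_analytes = lengths(sets)
  )
}

carrier_label <- function(set, polarity) {
  coeff <- function(n, sym) if (n > 1) paste0(n, sym) else sym
  if (polarity == "positive") {
    syms <- c(sodium = "Na+", ammonium = "NH4+", proton = "H+")
    out <- ""
    for (nm in names(syms)) {
      n <- sum(set == nm)
      if (n > 0) out <- paste0(out, " + ", coeff(n, syms[[nm]]))
    }
    out
  } else {
    d <- sum(set == "deprotonation")
    s <- sum(set == "sodium")
    paste0(" - ", coeff(d, "H+"), if (s > 0) paste0(" + ", coeff(s, "Na+")))
  }
}

carrier_component <- function(config, library, mode) {
  if (config$polarity == "positive") {
    types <- c("proton", "sodium", "ammonium")
    sets <- list()
    for (z in seq_len(config$max_z)) {
      counts <- multiset_counts(z, 3, z)
      counts <- counts[rowSums(counts) == z, , drop = FALSE]
      sets <- c(sets, lapply(seq_len(nrow(counts)), function(i) {
        rep(types, times = as.integer(counts[i, ]))
      }))
    }
  } else {
    sets <- list()
    for (s in 0:config$max_sodium_exchange) {
      for (z in seq_len(config$max_z)) {
        sets[[length(sets) + 1]] <- c(rep("deprotonation", z + s),
                                      rep("sodium", s))
      }
    }
  }
  tibble::tibble(
    carriers = sets,
    c_mass = vapply(sets, function(s) sum(library_mass(library, s, mode)), 0),
    z = vapply(sets, function(s) {
      if (config$polarity == "positive") length(s)
      else sum(s == "deprotonation") - sum(s == "sodium")
    }, 0),
    c_label = vapply(sets, carrier_label, character(1),
                     polarity = config$polarity),
    c_sig = vapply(sets, function(s) paste(sort(s), collapse = ","),
                   character(1)),
    n_carriers = lengths(sets)
  )
}

adduct_component <- function(config, library, mode) {
  names <- config$adducts %||% library_entries(library, "adduct")
  counts <- multiset_counts(config$max_neutral_adducts, length(names),
                            config$max_neutral_adducts)
  sets <- lapply(seq_len(nrow(counts)), function(i) {
    rep(names, times = as.integer(counts[i, ]))
  })
  canonical <- c("H2O", "NH3", "CH3OH", "HCOOH", "CH3COOH")
  tibble::tibble(
    adducts = sets,
    n_mass = vapply(sets, function(s) sum(library_mass(library, s, mode)), 0),
    n_label = vapply(sets, function(s) {
      out <- ""
      for (ad in canonical) {
        k <- sum(s == ad)
        if (k > 0) out <- paste0(out, " + ", if (k > 1) k, ad)
      }
      out
    }, character(1)),
    n_sig = vapply(sets, function(s) paste(sort(s), collapse = ","),
                   character(1)),
    n_adducts = lengths(sets)
  )
}

#' Full candidate-ion table for a configuration
#'
#' Materializes every ion species within the configuration bounds, with its
#' m/z. [annotate_peaklist()] and [enumerate_candidates()] filter this table;
#' computing it once and passing it through `table` avoids rebuilding it per
#' peak.
#'
#' @inheritParams enumerate_candidates
#' @return Tibble with list-columns `analytes`, `carriers`, `adducts`, plus
#'   `z`, `mz`, component counts, a display `label` in the style
#'   `"194 + 2NH4+ + CH3COOH/2"`, and a canonical `signature`.
#' @export
ion_table <- function(config, library = default_library()) {
  stopifnot(inherits(config, "annotation_config"))
  mode <- config$mode
  A <- analyte_component(config, library, mode)
  C <- carrier_component(config, library, mode)
  N <- adduct_component(config, library, mode)
  grid <- tidyr::expand_grid(ai = seq_len(nrow(A)), ci = seq_len(nrow(C)),
                             ni = seq_len(nrow(N)))
  out <- tibble::tibble(
    analytes = A$analytes[grid$ai],
    carriers = C$carriers[grid$ci],
    adducts = N$adducts[grid$ni],
    z = as.integer(C$z[grid$ci]),
    polarity = config$polarity,
    mz = (A$a_mass[grid$ai] + C$c_mass[grid$ci] + N$n_mass[grid$ni]) /
      C$z[grid$ci],
    n_analytes = A$n_analytes[grid$ai],
    n_components = A$n_analytes[grid$ai] + C$n_carriers[grid$ci] +
      N$n_adducts[grid$ni]
  )
  out$label <- paste0(A$a_label[grid$ai], C$c_label[grid$ci],
                      N$n_label[grid$ni],
                      ifelse(out$z > 1, paste0("/", out$z), ""))
  pol3 <- substr(config$polarity, 1, 3)
  out$signature <- paste0(pol3, "|z", out$z, "|A:", A$a_sig[grid$ai],
                          "|C:", C$c_sig[grid$ci], "|N:", N$n_sig[grid$ni])
  out$mass_signature <- paste0(pol3, "|z", out$z, "|A:",
                               A$a_mass_sig[grid$ai],
                               "|C:", C$c_sig[grid$ci],
                               "|N:", N$n_sig[grid$ni])
  out
}

# Canonical identity string used for set comparisons between independent
# enumerations; analytes by name (mass-degenerate analytes stay distinct).
ion_signature_vec <- function(analytes, carriers, adducts, z, polarity,
                              library) {
  paste0(
    substr(polarity, 1, 3), "|z", z,
    "|A:", vapply(analytes, function(s) paste(sort(s), collapse = ","),
                  character(1)),
    "|C:", vapply(carriers, function(s) paste(sort(s), collapse = ","),
                  character(1)),
    "|N:", vapply(adducts, function(s) paste(sort(s), collapse = ","),
                  character(1))
  )
}

# Mass-level signature: analytes identified by nominal mass, as in the
# printed tables (two analytes of equal mass are indistinguishable there).
ion_mass_signature_vec <- function(analytes, carriers, adducts, z, polarity,
                                   library) {
  paste0(
    substr(polarity, 1, 3), "|z", z,
    "|A:", vapply(analytes, function(s) {
      paste(sort(library_mass(library, s, "nominal")), collapse = ",")
    }, character(1)),
    "|C:", vapply(carriers, function(s) paste(sort(s), collapse = ","),
                  character(1)),
    "|N:", vapply(adducts, function(s) paste(sort(s), collapse = ","),
                  character(1))
  )
}

matches_target <- function(mz, target, config) {
  if (config$mode == "nominal") {
    round_half_up(mz) == round_half_up(target)
  } else {
    abs(mz - target) <= config$tolerance
  }
}

rank_candidates <- function(tbl) {
  tbl <- dplyr::arrange(tbl, .data$n_components, .data$n_analytes, .data$z,
                        .data$label)
  tbl$rank <- seq_len(nrow(tbl))
  tbl
}

#' Enumerate candidate ions for an observed m/z
#'
#' Complete (within the configured bounds) enumeration of ion species whose
#' m/z matches the target; ranked by parsimony (fewest total components, then
#' fewest analytes, then lowest charge, then label).
#'
#' @param target_mz Observed m/z.
#' @param config An [annotation_config()].
#' @param library A [default_library()].
#' @param table Optional precomputed [ion_table()] for this config.
#' @return Ranked tibble of candidates (possibly empty).
#' @examples
#' cfg <- annotation_config("positive")
#' enumerate_candidates(228, cfg)  # includes saccharic acid + NH4+
#' @export
enumerate_candidates <- function(target_mz, config,
                                 library = default_library(), table = NULL) {
  table <- table %||% ion_table(config, library)
  rank_candidates(table[matches_target(table$mz, target_mz, config), ])
}

# ---- MALDI series ---------------------------------------------------------

#' Theoretical MALDI series of cationized oligosaccharides
#'
#' For each chain length and oxidation delta class, the singly cationized
#' m/z `162*dp + 18 + delta + cation`, labeled the way annotated spectra
#' label their peaks ("DP3-2", "DP4+16", ...).
#'
#' @param dp Integer vector of chain lengths.
#' @param deltas Integer vector of delta classes.
#' @param cation Charge-carrier name (default "sodium").
#' @param library,mode Mass library and dialect.
#' @return Tibble (`dp`, `delta`, `label`, `mz`) sorted by m/z.
#' @examples
#' maldi_series(3, -2)  # the m/z 525 DP3-2 peak
#' @export
maldi_series <- function(dp, deltas, cation = "sodium",
                         library = default_library(), mode = "nominal") {
  if (!length(dp)) rlang::abort("dp range must be nonempty")
  cat_mass <- library_mass(library, cation, mode)
  el <- .element_masses[[mode]]
  residue <- 6 * el["C"] + 10 * el["H"] + 5 * el["O"]
  water <- 2 * el["H"] + el["O"]
  out <- tidyr::expand_grid(dp = as.integer(dp), delta = deltas)
  out$label <- paste0("DP", out$dp,
                      ifelse(out$delta < 0, out$delta,
                             paste0("+", out$delta)))
  out$mz <- unname(residue * out$dp + water + out$delta + cat_mass)
  dplyr::arrange(out, .data$mz)
}

# ---- fragment neutral losses ----------------------------------------------

#' Explain MS/MS fragments as neutral losses/gains from a parent ion
#'
#' Carbohydrate negative-mode fragmentation is dominated by losses of H, H2O,
#' CHO and COOH and occasional H gains; each fragment is explained as
#' `parent - sum(losses) + sum(gains)` with at most `max_steps` steps,
#' preferring the fewest steps.
#'
#' @param parent_mz Parent ion m/z.
#' @param fragments Numeric vector of fragment m/z values.
#' @param losses,gains Named numeric vectors of allowed neutral-loss / gain
#'   masses.
#' @param max_steps Maximum total losses + gains (default 3).
#' @param tolerance Matching window (default 0.5, i.e. nearest integer).
#' @return Tibble: `fragment_mz`, `explained`, `steps`, `path`, `expected_mz`,
#'   `error`.
#' @examples
#' explain_fragments(193, c(193, 175, 146.9))
#' @export
explain_fragments <- function(parent_mz, fragments,
                              losses = c(H = 1, H2O = 18, CHO = 29, COOH = 45),
                              gains = c(H = 1),
                              max_steps = 3, tolerance = 0.5) {
  steps_grid <- do.call(
    tidyr::expand_grid,
    c(
      stats::setNames(lapply(losses, function(x) 0:max_steps),
                      paste0("loss_", names(losses))),
      stats::setNames(lapply(gains, function(x) 0:max_steps),
                      paste0("gain_", names(gains)))
    )
  )
  total <- rowSums(steps_grid)
  steps_grid <- steps_grid[total <= max_steps, , drop = FALSE]
  loss_cols <- paste0("loss_", names(losses))
  gain_cols <- paste0("gain_", names(gains))
  shift <- as.matrix(steps_grid[loss_cols]) %*% (-losses) +
    as.matrix(steps_grid[gain_cols]) %*% gains
  expected <- parent_mz + as.numeric(shift)
  n_steps <- rowSums(steps_grid)
  path <- vapply(seq_len(nrow(steps_grid)), function(i) {
    bits <- character(0)
    for (j in seq_along(losses)) {
      k <- steps_grid[[loss_cols[j]]][i]
      if (k > 0) bits <- c(bits, paste0("-", if (k > 1) k, names(losses)[j]))
    }
    for (j in seq_along(gains)) {
      k <- steps_grid[[gain_cols[j]]][i]
      if (k > 0) bits <- c(bits, paste0("+", if (k > 1) k, names(gains)[j]))
    }
    if (length(bits)) paste(bits, collapse = "") else "parent"
  }, character(1))

  purrr::map_dfr(fragments, function(f) {
    ok <- abs(expected - f) <= tolerance
    if (!any(ok)) {
      return(tibble::tibble(fragment_mz = f, explained = FALSE,
                            steps = NA_integer_, path = NA_character_,
                            expected_mz = NA_real_, error = NA_real_))
    }
    best <- which(ok)[order(n_steps[ok], abs(expected[ok] - f))][1]
    tibble::tibble(fragment_mz = f, explained = TRUE,
                   steps = as.integer(n_steps[best]), path = path[best],
                   expected_mz = expected[best],
                   error = f - expected[best])
  })
}
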