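#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a peak annotation into one row per candidate
#'
#' @param x A `peak_annotation` from [annotate_peaklist()].
#' @param ... Unused.
#' @return Tibble: `peak_id`, `mz`, `intensity`, `rank`, `label`,
#'   `candidate_mz`, `z` (ESI only); unassigned peaks keep one row with `NA`
#'   candidate fields.
#' @method tidy peak_annotation
#' @export
tidy.peak_annotation <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    cand <- x$candidates[[i]]
    if (!nrow(cand)) {
      return(tibble::tibble(peak_id = x$peak_id[i], mz = x$mz[i],
                            intensity = x$intensity[i], rank = NA_integer_,
                            label = NA_character_, candidate_mz = NA_real_,
                            z = NA_integer_))
    }
    tibble::tibble(peak_id = x$peak_id[i], mz = x$mz[i],
                   intensity = x$intensity[i], rank = cand$rank,
                   label = cand$label, candidate_mz = cand$mz,
                   z = if ("z" %in% names(cand)) cand$z else 1L)
  })
}

#' Summarize a peak annotation
#'
#' @param x A `peak_annotation`.
#' @param ... Unused.
#' @return One-row tibble: peak counts, assignment rate, mean candidate
#'   multiplicity among assigned peaks.
#' @method glance peak_annotation
#' @export
glance.peak_annotation <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x),
    n_assigned = sum(x$assigned),
    assignment_rate = if (nrow(x)) mean(x$assigned) else NA_real_,
    mean_candidates = if (any(x$assigned)) {
      mean(x$n_candidates[x$assigned])
    } else NA_real_
  )
}

#' Tidy a product census into one row per species
#'
#' @param x A `product_census` from [digest()].
#' @param ... Unused.
#' @return Tibble: `kind` (monosaccharide / unnamed_dp1 / residual),
#'   `species`, `n`, `delta` (residuals only).
#' @method tidy product_census
#' @export
tidy.product_census <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(kind = "monosaccharide", species = x$monosaccharides$name,
                   n = x$monosaccharides$n, delta = NA_integer_),
    tibble::tibble(kind = "unnamed_dp1", species = x$unnamed$spec,
                   n = x$unnamed$n, delta = NA_integer_),
    tibble::tibble(kind = "residual", species = x$residuals$spec,
                   n = x$residuals$n, delta = x$residuals$delta)
  )
}

#' Summarize a product census
#'
#' @param x A `product_census`.
#' @param ... Unused.
#' @return One-row tibble with release counts, residuals and the mass ledger.
#' @method glance product_census
#' @export
glance.product_census <- function(x, ...) {
  l <- x$mass_ledger
  tibble::tibble(
    n_released = sum(x$monosaccharides$n) + sum(x$unnamed$n),
    n_residual = sum(x$residuals$n),
    cleavages = l$cleavages,
    parents_mass = l$parents,
    products_mass = l$products,
    mass_balanced = abs(l$products - l$parents - 18 * l$cleavages) < 1e-9
  )
}
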