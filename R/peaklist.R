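#' Construct a peak list
#'
#' A peak list is a tibble of (`mz`, `intensity`) sorted ascending by m/z,
#' carrying polarity and instrument dialect as attributes.
#'
#' @param mz,intensity Numeric vectors; m/z strictly positive, intensities
#'   non-negative.
#' @param polarity "positive" or "negative".
#' @param instrument "esi" or "maldi".
#' @param metadata Optional named list carried along unchanged.
#' @return A `peaklist` tibble.
#' @export
peaklist <- function(mz, intensity = rep(1, length(mz)),
                     polarity = c("positive", "negative"),
                     instrument = c("esi", "maldi"),
                     metadata = list()) {
  polarity <- rlang::arg_match(polarity)
  instrument <- rlang::arg_match(instrument)
  if (any(mz <= 0)) rlang::abort("m/z values must be strictly positive")
  if (any(intensity < 0)) rlang::abort("intensities must be non-negative")
  ord <- order(mz)
  structure(
    tibble::tibble(mz = as.numeric(mz)[ord],
                   intensity = as.numeric(intensity)[ord]),
    polarity = polarity, instrument = instrument, metadata = metadata,
    class = c("peaklist", class(tibble::tibble()))
  )
}

peaklist_polarity <- function(x) attr(x, "polarity") %||% "positive"
peaklist_instrument <- function(x) attr(x, "instrument") %||% "esi"

#' Read a peak list from CSV/TSV
#'
#' Expects a header with columns `mz` and `intensity` (an intensity of 1 is
#' assumed if the column is absent). Polarity and instrument may be given as
#' arguments or in a JSON sidecar (`<file>.json`) with fields `polarity` /
#' `instrument`.
#'
#' @param path File path; delimiter inferred from the extension
#'   (".tsv"/".txt" = tab, otherwise comma).
#' @param polarity,instrument Overrides for the sidecar values.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, polarity = NULL, instrument = NULL) {
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (!"mz" %in% names(df)) rlang::abort("peak file needs an 'mz' column")
  if (!"intensity" %in% names(df)) df$intensity <- 1
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else list()
  peaklist(df$mz, df$intensity,
           polarity = polarity %||% meta$polarity %||% "positive",
           instrument = instrument %||% meta$instrument %||% "esi",
           metadata = meta)
}

#' Write a peak list with its JSON metadata sidecar
#'
#' @param x A [peaklist()].
#' @param path Output CSV/TSV path; a `<path>.json` sidecar records polarity
#'   and instrument.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  readr::write_delim(tibble::as_tibble(x)[, c("mz", "intensity")], path,
                     delim = delim)
  jsonlite::write_json(
    c(list(polarity = peaklist_polarity(x),
           instrument = peaklist_instrument(x)),
      attr(x, "metadata")),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Annotate every peak of a peak list
#'
#' For ESI peak lists, candidates come from the complete adduct/cluster
#' enumeration ([ion_table()]); for MALDI, from the cationized
#' oligosaccharide series ([maldi_series()]) over the configured DP range and
#' delta classes. Peaks with no candidate within tolerance are flagged
#' unassigned.
#'
#' @param peaks A [peaklist()] (or a data frame with `mz` and `intensity`).
#' @param config An [annotation_config()]; its polarity must agree with the
#'   peak list's.
#' @param library A [default_library()].
#' @param table Optional precomputed candidate table ([ion_table()] for ESI,
#'   [maldi_series()] for MALDI) to avoid rebuilding it per call.
#' @return A `peak_annotation` tibble: `peak_id`, `mz`, `intensity`,
#'   `assigned`, `n_candidates`, `best` (top-ranked label), and a `candidates`
#'   list-column of ranked candidate tibbles.
#' @export
annotate_peaklist <- function(peaks, config, library = default_library(),
                              table = NULL) {
  if (!is.data.frame(peaks)) rlang::abort("peaks must be a data frame")
  if (inherits(peaks, "peaklist") &&
      peaklist_polarity(peaks) != config$polarity) {
    rlang::abort(paste0("polarity mismatch: peaks are ",
                        peaklist_polarity(peaks), ", config is ",
                        config$polarity))
  }
  if (!"intensity" %in% names(peaks)) peaks$intensity <- 1
  tab <- table %||% if (config$instrument == "esi") {
    ion_table(config, library)
  } else {
    maldi_series(config$dp_range, config$delta_classes, config$cation,
                 library, config$mode)
  }
  cands <- purrr::map(peaks$mz, function(m) {
    hit <- tab[matches_target(tab$mz, m, config), ]
    if (config$instrument == "esi") rank_candidates(hit)
    else dplyr::mutate(dplyr::arrange(hit, .data$mz), rank = dplyr::row_number())
  })
  out <- tibble::tibble(
    peak_id = seq_along(peaks$mz),
    mz = peaks$mz,
    intensity = peaks$intensity,
    n_candidates = vapply(cands, nrow, 0L),
    candidates = cands
  )
  out$assigned <- out$n_candidates > 0
  out$best <- vapply(cands, function(x) {
    if (nrow(x)) x$label[1] else NA_character_
  }, character(1))
  out <- out[, c("peak_id", "mz", "intensity", "assigned", "n_candidates",
                 "best", "candidates")]
  structure(out, config = config,
            run_id = attr(peaks, "metadata")$run_id,
            class = c("peak_annotation", class(tibble::tibble())))
}

#' Write annotations as TSV (flat) and JSON (nested)
#'
#' The TSV has one row per (peak, candidate) with the paper-style
#' decomposition label; unassigned peaks appear once with an empty label.
#'
#' @param x A `peak_annotation` from [annotate_peaklist()].
#' @param path Output path; ".json" writes nested JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  flat <- generics::tidy(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(flat, path)
  }
  invisible(path)
}
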