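# Seeded generators of synthetic inputs with the structure the annotation
# stages assume: oxidized-product pools (through the PMO event model) and
# noisy spectra with a ground-truth sidecar. The ground truth is returned
# alongside the peak list, keyed by a run id, and is never embedded in the
# peak list itself.

#' Spectrum noise model
#'
#' @param mz_jitter_sd Gaussian m/z jitter standard deviation, mass units
#'   (0 in nominal-mode work).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters
#'   for planted species (multiplied by species count). Log-normal intensity
#'   is the generic MS practice; defaults give a median single-copy intensity
#'   of ~1000 counts spread over roughly one decade.
#' @param n_noise Number of uniform noise peaks.
#' @param noise_range m/z range for noise peaks.
#' @param noise_intensity_meanlog,noise_intensity_sdlog Log-normal intensity
#'   parameters for noise peaks (defaults sit ~10x below planted species).
#' @param detection_threshold Minimum intensity retained.
#' @param seed Optional integer seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(mz_jitter_sd = 0,
                        intensity_meanlog = log(1000), intensity_sdlog = 0.5,
                        n_noise = 0, noise_range = c(150, 1200),
                        noise_intensity_meanlog = log(100),
                        noise_intensity_sdlog = 0.5,
                        detection_threshold = 0, seed = NULL) {
  if (mz_jitter_sd < 0 || intensity_sdlog < 0 || n_noise < 0) {
    rlang::abort("noise-model dispersions and counts must be >= 0")
  }
  structure(
    list(mz_jitter_sd = mz_jitter_sd,
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog,
         n_noise = as.integer(n_noise), noise_range = noise_range,
         noise_intensity_meanlog = noise_intensity_meanlog,
         noise_intensity_sdlog = noise_intensity_sdlog,
         detection_threshold = detection_threshold, seed = seed),
    class = "noise_model"
  )
}

#' Generate an oxidized-product pool under a named scenario
#'
#' Thin wrapper over [pmo_simulate()] with named study scenarios:
#' \describe{
#'   \item{"C1-only"}{Pure C1-oxidizing activity; every oxidized species
#'     falls in the +16 delta class.}
#'   \item{"C6-only"}{Pure C6 ladder (hydroxymethyl to aldehyde to acid); no
#'     cleavage, classes mix -2 and +14 per residue.}
#'   \item{"paper-like-mixed"}{Concurrent C1/C4 cleavage and the C6 oxidation
#'     ladder, sized so the pool populates the delta classes seen on annotated
#'     MALDI spectra of AA9 digests: 0, -2, +12, +14, +16 and +28.}
#' }
#'
#' @param scenario Scenario name, or "custom" with explicit `chains`, `rates`,
#'   `steps`.
#' @param seed Integer seed.
#' @param chains,rates,steps Overrides for "custom" runs.
#' @return A pool (list of `oligo`s) as from [pmo_simulate()], with the
#'   scenario recorded in attributes.
#' @export
generate_pool <- function(scenario = c("paper-like-mixed", "C1-only",
                                       "C6-only", "custom"),
                          seed = 1, chains = NULL, rates = NULL,
                          steps = NULL) {
  scenario <- rlang::arg_match(scenario)
  preset <- switch(
    scenario,
    "C1-only" = list(chains = rep(30L, 40), steps = 60,
                     rates = c(c1_cleavage = 0.004)),
    "C6-only" = list(chains = rep(30L, 40), steps = 60,
                     rates = c(c6_to_aldehyde = 0.006,
                               c6_aldehyde_to_acid = 0.003)),
    "paper-like-mixed" = list(
      chains = rep(15L, 150), steps = 80,
      rates = c(c1_cleavage = 0.004, c4_cleavage = 0.002,
                c6_to_aldehyde = 0.006, c6_aldehyde_to_acid = 0.003)
    ),
    "custom" = list(chains = chains, rates = rates, steps = steps)
  )
  if (scenario == "custom" &&
      (is.null(chains) || is.null(rates) || is.null(steps))) {
    rlang::abort("custom scenario needs chains, rates and steps")
  }
  pool <- pmo_simulate(preset$chains, preset$rates, preset$steps, seed = seed)
  attr(pool, "scenario") <- scenario
  attr(pool, "seed") <- seed
  pool
}

#' Render a synthetic spectrum from a pool, with ground truth
#'
#' Plants one peak per distinct pool species at its theoretical cationized
#' m/z (jittered under the noise model), with log-normal intensities scaled
#' by species count, plus uniform noise peaks; applies the detection
#' threshold last. The returned ground truth maps planted peaks to their
#' species labels and shares a `run_id` with the peak list so a benchmark can
#' refuse mismatched inputs.
#'
#' @param pool List of `oligo`s.
#' @param noise A [noise_model()].
#' @param cation Cationizing species (default "sodium").
#' @param library,mode Mass library and dialect.
#' @return List with `peaks` (a [peaklist()]) and `truth` (tibble:
#'   `species`, `dp`, `delta`, `true_mz`, `observed_mz`, `detected`).
#' @export
render_spectrum <- function(pool, noise = noise_model(), cation = "sodium",
                            library = default_library(), mode = "nominal") {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  base <- census_to_spectrum(pool, cation, library, mode)
  deltas <- vapply(lapply(pool, oligo), delta_class, 0L)
  dps <- vapply(lapply(pool, oligo), dp, 0L)
  cat_mass <- library_mass(library, cation, mode)
  species <- dplyr::distinct(
    tibble::tibble(dp = dps, delta = deltas,
                   true_mz = vapply(lapply(pool, oligo), oligo_mass, 0,
                                    mode = mode) + cat_mass)
  )
  species <- dplyr::arrange(species, .data$true_mz)
  counts <- dplyr::count(tibble::tibble(true_mz = vapply(
    lapply(pool, oligo), oligo_mass, 0, mode = mode) + cat_mass),
    .data$true_mz, name = "count")
  species <- dplyr::left_join(species, counts, by = "true_mz")
  species <- dplyr::distinct(species, .data$true_mz, .keep_all = TRUE)
  species$species <- paste0("DP", species$dp,
                            ifelse(species$delta < 0, species$delta,
                                   paste0("+", species$delta)))

  n_sp <- nrow(species)
  observed <- species$true_mz + stats::rnorm(n_sp, 0, noise$mz_jitter_sd)
  intens <- species$count * stats::rlnorm(n_sp, noise$intensity_meanlog,
                                          noise$intensity_sdlog)
  detected <- intens >= noise$detection_threshold

  noise_mz <- stats::runif(noise$n_noise, noise$noise_range[1],
                           noise$noise_range[2])
  noise_int <- stats::rlnorm(noise$n_noise, noise$noise_intensity_meanlog,
                             noise$noise_intensity_sdlog)
  keep_noise <- noise_int >= noise$detection_threshold

  run_id <- paste0("synth-", paste(sample(c(letters, 0:9), 8, TRUE),
                                   collapse = ""))
  peaks <- peaklist(
    c(observed[detected], noise_mz[keep_noise]),
    c(intens[detected], noise_int[keep_noise]),
    polarity = "positive", instrument = "maldi",
    metadata = list(run_id = run_id, synthetic = TRUE)
  )
  sp <- species
  truth <- tibble::tibble(
    species = sp$species, dp = sp$dp, delta = sp$delta,
    count = sp$count, true_mz = sp$true_mz,
    observed_mz = observed, detected = detected
  )
  attr(truth, "run_id") <- run_id
  list(peaks = peaks, truth = truth)
}

#' Write the ground truth of a synthetic run as a JSON sidecar
#'
#' @param truth The `truth` tibble from [render_spectrum()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(run_id = attr(truth, "run_id"),
         species = truth),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Recovery benchmark: planted species vs annotations
#'
#' Recall: fraction of detected planted species whose true label appears in
#' the candidate set of a peak matching the species within the annotation
#' tolerance. Precision: fraction of assigned peaks whose candidate set
#' contains the label of some detected planted species at that peak. Both
#' inputs must come from the same render run.
#'
#' @param truth The `truth` tibble from [render_spectrum()].
#' @param annotations A `peak_annotation` of the corresponding `peaks`.
#' @return One-row tibble: `n_planted`, `n_recovered`, `recall`,
#'   `n_assigned`, `n_true_assigned`, `precision`.
#' @export
recovery_benchmark <- function(truth, annotations) {
  truth_run <- attr(truth, "run_id")
  anno_run <- attr(annotations, "run_id")
  if (!is.null(truth_run) && !is.null(anno_run) &&
      !identical(truth_run, anno_run)) {
    rlang::abort("run identifiers differ: truth and annotations are from different renders")
  }
  planted <- truth[truth$detected, ]
  candidate_labels <- lapply(annotations$candidates, function(x) x$label)
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    near <- which(abs(annotations$mz - planted$observed_mz[i]) < 1e-9)
    any(vapply(near, function(j) {
      planted$species[i] %in% candidate_labels[[j]]
    }, logical(1)))
  }, logical(1))
  assigned <- which(annotations$assigned)
  true_assigned <- vapply(assigned, function(j) {
    near <- which(abs(planted$observed_mz - annotations$mz[j]) < 1e-9)
    any(planted$species[near] %in% candidate_labels[[j]])
  }, logical(1))
  tibble::tibble(
    n_planted = nrow(planted),
    n_recovered = sum(recovered),
    recall = if (nrow(planted)) mean(recovered) else NA_real_,
    n_assigned = length(assigned),
    n_true_assigned = sum(true_assigned),
    precision = if (length(assigned)) mean(true_assigned) else NA_real_
  )
}
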