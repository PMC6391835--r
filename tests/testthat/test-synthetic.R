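test_that("generator scenarios are reproducible and respect their construction", {
  a <- generate_pool("C1-only", seed = 7)
  b <- generate_pool("C1-only", seed = 7)
  expect_identical(vapply(a, format, ""), vapply(b, format, ""))
  expect_true(all(pool_census(a)$delta %in% c(0L, 16L)))
  inert <- generate_pool("custom", seed = 1, chains = rep(10, 3),
                         rates = c(c1_cleavage = 0), steps = 10)
  expect_true(all(pool_census(inert)$delta == 0))
  expect_error(generate_pool("custom", seed = 1), "needs chains")
})

test_that("the mixed scenario populates the spectrum delta classes and recounts exactly", {
  pool <- generate_pool("paper-like-mixed", seed = 1)
  cen <- pool_census(pool)
  for (cls in c(0L, -2L, 12L, 14L, 16L, 28L)) {
    expect_gt(cen$n[cen$delta == cls], 0)
  }
  # independent recount from raw residue flags
  recount <- table(vapply(pool, function(x) {
    r <- x$residues
    sum(16 * r$c1_acid - 2 * r$c4_keto - 2 * (r$c6 == "aldehyde") +
          14 * (r$c6 == "acid") - 18 * r$lactones - 18 * r$unsat_4_5)
  }, 0))
  expect_equal(cen$n, as.integer(recount[as.character(cen$delta)]),
               ignore_attr = TRUE)
})

test_that("degenerate noise reproduces the theoretical spectrum exactly", {
  pool <- list(oligo("G(c6d)-G-G"), oligo("G(c6d)-G-G"), oligo(3))
  syn <- render_spectrum(pool, noise_model(seed = 2))
  expect_setequal(syn$peaks$mz, census_to_spectrum(pool)$mz)
  expect_true(525 %in% syn$peaks$mz)  # the planted DP3-2 sodiated species
  expect_true(all(syn$truth$detected))
  a <- render_spectrum(pool, noise_model(n_noise = 15, seed = 9))
  b <- render_spectrum(pool, noise_model(n_noise = 15, seed = 9))
  expect_identical(a$peaks$mz, b$peaks$mz)
  expect_identical(a$peaks$intensity, b$peaks$intensity)
})

test_that("noise-free synthetic spectra are recovered with recall 1", {
  pool <- generate_pool("paper-like-mixed", seed = 3)
  pool <- pool[vapply(pool, dp, 0L) <= 6]
  syn <- render_spectrum(pool, noise_model(seed = 4))
  cfg <- annotation_config("positive", instrument = "maldi", dp_range = 1:6,
                           delta_classes = sort(unique(pool_census(pool)$delta)))
  ann <- annotate_peaklist(syn$peaks, cfg)
  bench <- recovery_benchmark(syn$truth, ann)
  expect_equal(bench$recall, 1)
  expect_equal(bench$precision, 1)
})

test_that("recall is zero against empty annotations and drops under m/z jitter", {
  pool <- lapply(2:6, function(n) oligo(n))
  syn <- render_spectrum(pool, noise_model(seed = 5))
  empty <- annotate_peaklist(syn$peaks[0, ],
                             annotation_config("positive",
                                               instrument = "maldi"))
  attr(empty, "run_id") <- attr(syn$truth, "run_id")
  expect_equal(recovery_benchmark(syn$truth, empty)$recall, 0)

  cfg <- annotation_config("positive", instrument = "maldi", dp_range = 1:8,
                           delta_classes = 0)
  recalls <- vapply(1:10, function(s) {
    jit <- render_spectrum(pool, noise_model(mz_jitter_sd = 0.3, seed = s))
    recovery_benchmark(jit$truth,
                       annotate_peaklist(jit$peaks, cfg))$recall
  }, 0)
  expect_lt(mean(recalls), 1)
})

test_that("benchmarks refuse annotations from a different render run", {
  pool <- list(oligo(3))
  syn1 <- render_spectrum(pool, noise_model(seed = 6))
  syn2 <- render_spectrum(pool, noise_model(seed = 7))
  cfg <- annotation_config("positive", instrument = "maldi")
  ann2 <- annotate_peaklist(syn2$peaks, cfg)
  expect_error(recovery_benchmark(syn1$truth, ann2), "run identifiers")
})

test_that("noise-model parameters are validated and the truth sidecar round-trips", {
  expect_error(noise_model(mz_jitter_sd = -1), ">= 0")
  pool <- list(oligo(2), oligo(3))
  syn <- render_spectrum(pool, noise_model(seed = 8))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_truth(syn$truth, tmp)
  back <- jsonlite::fromJSON(tmp)
  expect_identical(back$run_id, attr(syn$truth, "run_id"))
  expect_equal(back$species$true_mz, syn$truth$true_mz)
})
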