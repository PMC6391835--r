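released <- function(census) {
  m <- census$monosaccharides
  sort(rep(m$name, m$n))
}

test_that("the three canonical degradation pathways yield the printed monomer sets", {
  # C6 oxidation: glucuronosyl NRE released by GUS, rest by BGL
  expect_identical(released(digest(list(oligo("G(c6a)-G-G")))),
                   sort(c("glucuronic acid", "glucose", "glucose")))
  # C1 oxidation: chain walked down to the aldonic monosaccharide
  expect_identical(released(digest(list(oligo("G-G-G(c1)")))),
                   sort(c("glucose", "glucose", "gluconic acid")))
  # C6/C1: double oxidation leaves saccharic acid
  expect_identical(released(digest(list(oligo("G(c6a)-G-G(c1,c6a)")))),
                   sort(c("glucuronic acid", "glucose", "saccharic acid")))
})

test_that("unaccepted non-reducing ends stall or pass through by policy", {
  stalled <- digest(list(oligo("G(c6d)-G-G")))
  expect_equal(nrow(stalled$monosaccharides), 0)
  expect_equal(sum(stalled$residuals$n), 1)
  passed <- digest(list(oligo("G(c6d)-G-G")), stall_policy = "pass_through")
  expect_equal(sum(passed$residuals$n), 0)
  expect_identical(released(passed), c("glucose", "glucose"))
  expect_equal(sum(passed$unnamed$n), 1)  # the hexodialdose unit
  # enzyme subsets gate their own substrates
  gus_only <- digest(list(oligo("G(c6a)-G-G")), enzymes = "GUS")
  expect_identical(released(gus_only), "glucuronic acid")
  expect_equal(sum(gus_only$residuals$n), 1)
})

test_that("digestion conserves mass: products equal parents plus one water per cleavage", {
  set.seed(23)
  for (i in 1:1000) {
    pool <- lapply(seq_len(sample(1:3, 1)), function(j) {
      random_oligo(sample(1:6, 1))
    })
    g <- glance(digest(pool))
    expect_true(g$mass_balanced)
    expect_equal(g$products_mass, g$parents_mass + 18 * g$cleavages)
  }
})

test_that("digestion is order-independent over the pool", {
  set.seed(29)
  pool <- lapply(1:6, function(i) random_oligo(sample(2:5, 1)))
  a <- generics::tidy(digest(pool))
  b <- generics::tidy(digest(rev(pool)))
  key <- function(d) d[order(d$kind, d$species), ]
  expect_equal(key(a), key(b))
})

test_that("lyase cleavage splits at the uronate with an unsaturated distal end and no water", {
  parent <- oligo("G-G-G(c6a)-G")
  fr <- pl_cleave(parent, 3)
  expect_identical(format(fr$proximal), "G-G")
  expect_identical(format(fr$distal), "G(c6a,u)-G")
  expect_equal(oligo_mass(fr$proximal) + oligo_mass(fr$distal),
               oligo_mass(parent))
  # boundary: DP2 parent gives two DP1 fragments
  fr2 <- pl_cleave(oligo("G-G(c6a)"), 2)
  expect_equal(vapply(fr2, dp, 0L), c(proximal = 1L, distal = 1L))
  expect_error(pl_cleave(oligo("G-G-G"), 2), "not applicable")
  expect_error(pl_cleave(oligo("G(c6a)-G"), 1), "2..dp")
})

test_that("lyase fragments conserve mass for random uronate positions", {
  set.seed(37)
  for (i in 1:50) {
    n <- sample(3:7, 1)
    x <- random_oligo(n, p_mod = 0.3)
    site <- sample(2:n, 1)
    x$residues$c6[site] <- "acid"
    x <- oligo(x$residues)
    fr <- pl_cleave(x, site)
    expect_equal(oligo_mass(fr$proximal) + oligo_mass(fr$distal),
                 oligo_mass(x))
    expect_true(fr$distal$residues$unsat_4_5[1])
  }
})

test_that("the PMO simulator is seed-reproducible and inert at zero rates", {
  inert <- pmo_simulate(c(5, 8), rates = c(c1_cleavage = 0), steps = 50,
                        seed = 3)
  expect_identical(vapply(inert, format, ""), c("G-G-G-G-G",
                                                "G-G-G-G-G-G-G-G"))
  a <- pmo_simulate(rep(30, 5), steps = 40, seed = 17)
  b <- pmo_simulate(rep(30, 5), steps = 40, seed = 17)
  expect_identical(vapply(a, format, ""), vapply(b, format, ""))
})

test_that("pure C1 activity yields only the aldonic (+16) oxidized class", {
  pool <- pmo_simulate(rep(40, 10), rates = c(c1_cleavage = 0.01),
                       steps = 80, seed = 5)
  cen <- pool_census(pool)
  expect_setequal(cen$delta, c(0L, 16L))
  expect_gt(cen$n[cen$delta == 16], 0)
})

test_that("event counts track the per-site rates within 3 sigma", {
  rates <- c(c1_cleavage = 0.01, c4_cleavage = 0.01, c6_to_aldehyde = 0.02,
             c6_aldehyde_to_acid = 0.01)
  pool <- pmo_simulate(rep(100, 20), rates, steps = 200, seed = 1)
  log <- attr(pool, "event_log")
  agg <- dplyr::summarise(dplyr::group_by(log, .data$type),
                          sites = sum(.data$n_sites),
                          events = sum(.data$n_events))
  for (i in seq_len(nrow(agg))) {
    expected <- agg$sites[i] * rates[[agg$type[i]]]
    expect_lt(abs(agg$events[i] - expected), 3 * sqrt(expected) + 1)
  }
  # heavy oxidation populates the diagnostic classes
  cen <- pool_census(pool)
  for (cls in c(-2L, 14L, 16L)) expect_true(cls %in% cen$delta)
})

test_that("census spectra aggregate species counts at the cationized masses", {
  pool <- replicate(5, oligo("G(c6d)-G-G"), simplify = FALSE)
  spec <- census_to_spectrum(pool)
  expect_equal(spec$mz, 525)
  expect_equal(spec$intensity, 5)
  empty <- census_to_spectrum(list())
  expect_equal(nrow(empty), 0)
  mixed <- census_to_spectrum(c(pool, list(oligo(2), oligo(2))))
  expect_equal(mixed$mz, c(365, 525))
  expect_equal(mixed$intensity, c(2, 5))
  # a digestion census maps through the monosaccharide standards
  cen <- digest(list(oligo("G(c6a)-G-G")))
  spec2 <- census_to_spectrum(cen)
  expect_setequal(spec2$mz, c(180 + 23, 194 + 23))
})
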