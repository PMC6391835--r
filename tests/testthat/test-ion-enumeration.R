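test_that("single-ion m/z follows the charge-normalized adduct formula", {
  expect_equal(ion_mz(ion_species("glucose", c("sodium", "proton"))), 102)
  expect_equal(ion_mz(ion_species("glucuronic acid", "proton")), 195)
  expect_equal(ion_mz(ion_species("oxidized ascorbate", "deprotonation",
                                  polarity = "negative")), 173)
  expect_equal(ion_mz(ion_species("glucuronic acid",
                                  c("ammonium", "ammonium"), "CH3COOH")), 145)
  # negative-mode sodium exchange: [M - 2H + Na]-
  expect_equal(ion_mz(ion_species("saccharic acid lactone",
                                  c("deprotonation", "deprotonation",
                                    "sodium"),
                                  "HCOOH", polarity = "negative")), 259)
})

test_that("ion m/z is invariant to multiset ordering", {
  a <- ion_species(c("glucose", "oxidized ascorbate"), c("proton", "sodium"),
                   c("H2O", "HCOOH"))
  b <- ion_species(c("oxidized ascorbate", "glucose"), c("sodium", "proton"),
                   c("HCOOH", "H2O"))
  expect_equal(ion_mz(a), ion_mz(b))
})

test_that("invalid ion species are rejected", {
  expect_error(ion_species("glucose", character()), "net charge")
  expect_error(ion_species("glucose", "deprotonation"), "positive-mode")
  expect_error(ion_species("glucose", c("sodium", "sodium"),
                           polarity = "negative"), "net charge")
  expect_error(ion_mz(ion_species("sorbitol", "proton")), "unknown species")
})

test_that("candidate enumeration recovers the printed single-analyte adducts", {
  cfg <- annotation_config("positive")
  tab <- cached_ion_table("positive")
  c228 <- enumerate_candidates(228, cfg, table = tab)
  expect_true("210 + NH4+" %in% c228$label)
  c193 <- enumerate_candidates(193, cfg, table = tab)
  expect_true("192 + H+" %in% c193$label)
  expect_equal(nrow(enumerate_candidates(5, cfg, table = tab)), 0)
  # parsimony ranking puts the protonated molecule first
  expect_identical(enumerate_candidates(195, cfg, table = tab)$label[1],
                   "194 + H+")
})

test_that("any in-bounds ion is recovered when its own m/z is queried", {
  set.seed(31)
  tabs <- list(positive = cached_ion_table("positive"),
               negative = cached_ion_table("negative"))
  for (pol in c("positive", "negative")) {
    cfg <- annotation_config(pol)
    tab <- tabs[[pol]]
    for (i in 1:25) {
      row <- tab[sample(nrow(tab), 1), ]
      ion <- ion_species(row$analytes[[1]], row$carriers[[1]],
                         row$adducts[[1]], pol)
      got <- enumerate_candidates(ion_mz(ion), cfg, table = tab)
      expect_true(row$signature %in% got$signature)
    }
  }
})

test_that("enumeration is complete against a naive nested oracle over m/z 50-300", {
  for (pol in c("positive", "negative")) {
    oracle <- oracle_enumeration(pol)
    oracle$key <- floor(oracle$mz + 0.5)
    tab <- cached_ion_table(pol)
    tab_key <- floor(tab$mz + 0.5)
    for (target in 50:300) {
      want <- sort(unique(oracle$signature[oracle$key == target]))
      got <- sort(unique(tab$signature[tab_key == target]))
      expect_identical(got, want)
    }
  }
})

test_that("the MALDI sodiated series reproduces the annotated peak ladder", {
  s <- maldi_series(3, c(-2, 0), cation = "sodium")
  expect_equal(s$mz[s$label == "DP3-2"], 525)
  expect_equal(s$mz[s$label == "DP3+0"], 527)
  expect_equal(maldi_series(4, 16)$mz, 705)
  expect_error(maldi_series(integer(0), 0), "nonempty")
  expect_error(maldi_series(3, 0, cation = "cesium"), "unknown species")
})

test_that("fragment losses are explained by the smallest loss/gain path", {
  out <- explain_fragments(193, c(193, 175, 148, 183.2))
  expect_identical(out$path[out$fragment_mz == 193], "parent")
  expect_identical(out$path[out$fragment_mz == 175], "-H2O")
  expect_identical(out$path[out$fragment_mz == 148], "-COOH")
  # a -10 shift is not a sum of at most three allowed losses/gains
  expect_false(out$explained[out$fragment_mz == 183.2])
  out2 <- explain_fragments(191, 146)
  expect_identical(out2$path, "-COOH")
  # multi-step path within the cap
  out3 <- explain_fragments(194, 194 - 18 - 29)
  expect_identical(out3$path, "-H2O-CHO")
})
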