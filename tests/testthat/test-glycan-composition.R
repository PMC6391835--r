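test_that("per-residue oxidation deltas match the annotated class arithmetic", {
  expect_equal(residue_delta(c1_acid = TRUE), 16)
  expect_equal(residue_delta(c6 = "acid"), 14)
  expect_equal(residue_delta(c6 = "aldehyde"), -2)
  expect_equal(residue_delta(c4_keto = TRUE), -2)
  expect_equal(residue_delta(c1_acid = TRUE, c6 = "acid", lactones = 1), 12)
  expect_equal(residue_delta(), 0)
})

test_that("illegal oxidation states name the violated invariant", {
  expect_error(residue_delta(lactones = 1), "lactones exceed carboxyl")
  expect_error(oligo("G(c1)-G-G"), "reducing-end")
  expect_error(oligo("G-G(u)-G"), "non-reducing-end")
  expect_error(residue_delta(c6 = "ketone"), "none/aldehyde/acid")
})

test_that("neutral masses follow 162*dp + 18 plus deltas", {
  expect_equal(oligo_mass(oligo(3)), 504)
  expect_equal(oligo_mass(oligo("G(c6d)-G-G")), 502)  # sodiated: 525
  expect_equal(oligo_mass(oligo(1)), 180)
  expect_equal(delta_class(oligo("G(c6a)-G-G(c1)")), 30)
})

test_that("chain-string grammar round-trips random legal oligosaccharides", {
  set.seed(42)
  for (i in 1:50) {
    x <- random_oligo(sample(1:6, 1), allow_unsat = TRUE)
    s <- format(x)
    expect_identical(format(oligo(s)), s)
    expect_equal(oligo_mass(oligo(s)), oligo_mass(x))
  }
})

test_that("delta additivity holds for random oligosaccharides in every mass dialect", {
  set.seed(7)
  for (i in 1:40) {
    x <- random_oligo(sample(1:5, 1))
    n <- dp(x)
    for (mode in c("nominal", "monoisotopic", "average")) {
      r <- x$residues
      deltas <- residue_delta(r$c1_acid, r$c4_keto, r$c6, r$lactones,
                              r$unsat_4_5, mode = mode)
      expect_equal(oligo_mass(x, mode) - oligo_mass(oligo(n), mode),
                   sum(deltas), tolerance = 1e-9)
    }
  }
})

test_that("monosaccharide identities map to library standards with consistent masses", {
  lib <- default_library()
  cases <- list(
    "G" = "glucose", "G(c1)" = "gluconic acid",
    "G(c6a)" = "glucuronic acid", "G(c1,c6a)" = "saccharic acid",
    "G(c1,L)" = "gluconic acid lactone",
    "G(c6a,L)" = "glucuronic acid lactone",
    "G(c1,c6a,L)" = "saccharic acid lactone"
  )
  for (spec in names(cases)) {
    name <- monosaccharide_identity(oligo(spec))
    expect_identical(name, cases[[spec]])
    expect_equal(library_mass(lib, name), oligo_mass(oligo(spec)))
  }
  expect_true(is.na(monosaccharide_identity(oligo("G(c4k)"))))
  expect_true(is.na(monosaccharide_identity(oligo("G(c6d)"))))
  expect_error(monosaccharide_identity(oligo(2)), "dp == 1")
})

test_that("delta explanations contain the compositions annotated on the spectra", {
  e14 <- delta_explanations(14, dp = 3)
  expect_true("C6-acid" %in% e14$label)
  expect_true("C1-acid + C4-keto" %in% e14$label)
  e28 <- delta_explanations(28, dp = 3)
  expect_true("2C6-acid" %in% e28$label)
  expect_true("C1-acid + C4-keto + C6-acid" %in% e28$label)
  e0 <- delta_explanations(0, dp = 3)
  expect_true("unmodified" %in% e0$label)
  expect_equal(nrow(delta_explanations(1, dp = 3)), 0)
})

test_that("delta explanations agree with exhaustive positioned enumeration", {
  for (config in list(list(dp = 2, cap = 3), list(dp = 3, cap = 3),
                      list(dp = 4, cap = 3), list(dp = 3, cap = 2))) {
    census <- oracle_state_census(config$dp, config$cap)
    for (delta in -40:40) {
      got <- delta_explanations(delta, config$dp, cap = config$cap)
      want <- census[census$delta == delta, ]
      cols <- c("n_c1_acid", "n_c4_keto", "n_c6_aldehyde", "n_c6_acid",
                "n_lactone")
      key <- function(d) sort(do.call(paste, d[cols]))
      expect_identical(key(got), key(want))
    }
  }
})

test_that("positioned expansion yields distinct valid chains of the right delta", {
  e <- delta_explanations(14, dp = 3, positions = TRUE)
  uronate <- e[e$label == "C6-acid", ]
  expect_length(uronate$chains[[1]], 3)  # any of the three residues
  for (row in seq_len(nrow(e))) {
    for (chain in e$chains[[row]]) {
      expect_equal(delta_class(oligo(chain)), 14)
    }
    expect_false(anyDuplicated(e$chains[[row]]) > 0)
  }
})
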