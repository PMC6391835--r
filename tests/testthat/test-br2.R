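test_that("bromine oxidation maps the pre-treatment classes to the printed post classes", {
  expect_equal(delta_class(br2_transform(oligo("G(c6d)-G-G"))), 30)
  expect_equal(delta_class(br2_transform(oligo("G(c6d)-G(c6d)-G"))), 44)
  expect_equal(delta_class(br2_transform(oligo("G(c4k)-G-G"))), 14)
  expect_equal(delta_class(br2_transform(oligo("G(c6d)-G(c4k)-G"))), 28)
  expect_equal(delta_class(br2_transform(oligo(3))), 16)
  # an existing aldonic end is not oxidized twice
  expect_equal(delta_class(br2_transform(oligo("G-G-G(c1)"))), 16)
})

test_that("reducing-end oxidation can be disabled", {
  expect_equal(delta_class(br2_transform(oligo("G(c6d)-G-G"),
                                         oxidize_reducing_end = FALSE)), 14)
  expect_equal(delta_class(br2_transform(oligo(3),
                                         oxidize_reducing_end = FALSE)), 0)
})

test_that("lactone policies preserve, open, or return both", {
  x <- oligo("G(c6a,L)-G-G")
  expect_equal(delta_class(br2_transform(x)), 12)  # 14 - 18 + 16
  expect_equal(delta_class(br2_transform(x, lactone_policy = "open")), 30)
  both <- br2_transform(x, lactone_policy = "equilibrate_both")
  expect_length(both, 2)
  expect_setequal(vapply(both, delta_class, 0L), c(12L, 30L))
})

test_that("bromine oxidation is idempotent and adds exactly 16 per aldehyde", {
  set.seed(11)
  for (i in 1:40) {
    x <- random_oligo(sample(1:6, 1))
    n_ald <- sum(x$residues$c6 == "aldehyde") +
      as.integer(!x$residues$c1_acid[dp(x)])
    y <- br2_transform(x)
    expect_equal(oligo_mass(y) - oligo_mass(x), 16 * n_ald)
    expect_identical(format(br2_transform(y)), format(y))
  }
})

test_that("the delta map commutes with the transform on positioned chains", {
  set.seed(13)
  for (delta in c(-4, -2, 0, 12, 14, 16, 28)) {
    e <- delta_explanations(delta, dp = 3, positions = TRUE)
    for (row in seq_len(nrow(e))) {
      post <- br2_delta_map(delta, e[row, ])
      for (chain in e$chains[[row]]) {
        expect_equal(delta_class(br2_transform(oligo(chain))), post)
      }
    }
  }
})

test_that("the delta map rejects compositions inconsistent with the stated class", {
  expect_error(br2_delta_map(-2, c(n_c6_acid = 1)), "evaluates to delta")
  expect_equal(br2_delta_map(-2, c(n_c6_aldehyde = 1)), 30)
  expect_equal(br2_delta_map(-2, c(n_c4_keto = 1)), 14)
  expect_equal(br2_delta_map(-4, c(n_c6_aldehyde = 2)), 44)
})
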