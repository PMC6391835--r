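test_that("nominal masses of all monosaccharide and reductant standards match the footnote values", {
  lib <- default_library()
  expected <- c(
    "glucose" = 180, "gluconic acid" = 196, "gluconic acid lactone" = 178,
    "glucuronic acid" = 194, "glucuronic acid lactone" = 176,
    "saccharic acid" = 210, "saccharic acid lactone" = 192,
    "reduced ascorbate" = 176, "oxidized ascorbate" = 174,
    "oxidized-dehydrated ascorbate" = 156,
    "H2O" = 18, "NH3" = 17, "CH3OH" = 32, "HCOOH" = 46, "CH3COOH" = 60,
    "proton" = 1, "sodium" = 23, "ammonium" = 18, "deprotonation" = -1
  )
  expect_equal(library_mass(lib, names(expected)), unname(expected))
})

test_that("nominal masses are integers and monoisotopic masses track the formulas", {
  lib <- default_library()
  expect_true(all(lib$nominal == round(lib$nominal)))
  expect_equal(library_mass(lib, "glucose", "monoisotopic"), 180.0634,
               tolerance = 1e-6)
  expect_equal(library_mass(lib, "H2O", "monoisotopic"), 18.010565,
               tolerance = 1e-6)
  # proton/ammonium include the electron in monoisotopic mode
  expect_equal(library_mass(lib, "proton", "monoisotopic"), 1.007276,
               tolerance = 1e-5)
  expect_equal(library_mass(lib, "deprotonation", "monoisotopic"), -1.007276,
               tolerance = 1e-5)
})

test_that("library lookups fail loudly for unknown names and modes", {
  lib <- default_library()
  expect_error(library_mass(lib, "sorbitol"), "unknown species")
  expect_error(library_mass(lib, "glucose", mode = "exactish"))
})

test_that("the library can be extended from a record table or JSON", {
  lib <- default_library(extra = tibble::tibble(name = "xylose",
                                                formula = "C5H10O5"))
  expect_equal(library_mass(lib, "xylose"), 150)
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(list(name = "cellobiose", formula = "C12H22O11", class = "analyte")),
    tmp, auto_unbox = TRUE
  )
  lib2 <- default_library(extra = tmp)
  expect_equal(library_mass(lib2, "cellobiose"), 342)
  expect_error(default_library(extra = tibble::tibble(name = "glucose",
                                                      formula = "C6H12O6")),
               "duplicate")
})
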