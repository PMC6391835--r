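Package: oxocello
Title: Mass-Spectrometric Annotation of Oxidized Cello-Oligosaccharides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reasoning about lytic polysaccharide monooxygenase
    (LPMO, CAZy family AA9) oxidation products of cellulose at the mass
    spectrometer. Provides a compositional nominal/monoisotopic mass model for
    cello-oligosaccharides carrying C1, C4 and C6 oxidation states (aldonic
    acids, ketoaldoses, hexodialdoses, uronic acids, their lactones and
    4,5-unsaturated lyase products), an adduct and cluster-ion enumerator for
    ESI full-scan and sodiated MALDI-TOF peak lists, the bromine-water
    oxidation transform used to discriminate C4 from C6 oxidation, a
    rule-based simulator of exo-glycosidase (beta-glucosidase,
    beta-glucuronidase) and polysaccharide-lyase degradation, peptide m/z
    utilities, and seeded synthetic-spectrum generators with ground truth for
    benchmarking peak annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
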