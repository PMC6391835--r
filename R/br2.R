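# Bromine-water oxidation is the wet-chemistry disambiguator for the -2 delta
# class: Br2 oxidizes every free aldehyde -- in-chain C6 hexodialdose groups
# and the open-chain anomeric aldehyde of an unmodified reducing end -- to a
# carboxyl (+16 each), while ketones (C4) resist it. A C6 aldehyde (-2)
# therefore moves to +30 together with the new C1 acid, whereas a C4 ketone
# moves only to +14, separating the two interpretations on the spectrum.

#' Apply the bromine-water oxidation transform
#'
#' Every residue with a C6 aldehyde becomes a C6 carboxyl; if
#' `oxidize_reducing_end` is `TRUE` (the default: aldoses are Br2 substrates)
#' and the reducing-end residue is not already an aldonic acid, it gains a C1
#' carboxyl. C4 ketones are unchanged.
#'
#' @param x An `oligo` (or anything [oligo()] accepts).
#' @param oxidize_reducing_end Oxidize a free reducing end to the aldonic
#'   acid (default `TRUE`).
#' @param lactone_policy "preserve" keeps lactone counts as they are, "open"
#'   hydrolyzes all lactones, "equilibrate_both" returns both variants as a
#'   list.
#' @return The transformed `oligo`, or a list of two under
#'   "equilibrate_both".
#' @examples
#' delta_class(br2_transform(oligo("G(c6d)-G-G")))  # -2 -> +30
#' delta_class(br2_transform(oligo(3)))             #  0 -> +16
#' @export
br2_transform <- function(x, oxidize_reducing_end = TRUE,
                          lactone_policy = c("preserve", "open",
                                             "equilibrate_both")) {
  lactone_policy <- rlang::arg_match(lactone_policy)
  x <- oligo(x)
  r <- x$residues
  r$c6[r$c6 == "aldehyde"] <- "acid"
  n <- nrow(r)
  if (oxidize_reducing_end && !r$c1_acid[n]) r$c1_acid[n] <- TRUE
  preserved <- new_oligo(r)
  if (lactone_policy == "preserve") return(preserved)
  r_open <- r
  r_open$lactones <- 0L
  opened <- new_oligo(r_open)
  if (lactone_policy == "open") opened else list(preserved, opened)
}

#' Map a pre-Br2 delta class to its post-Br2 class for a given composition
#'
#' Given one composition explaining the pre-treatment delta class (a row of
#' [delta_explanations()] or equivalent named counts), the post-treatment
#' class is `pre + 16 * (number of aldehydes oxidized)`: every C6 aldehyde
#' plus the free reducing end (free unless the composition already contains
#' the C1 acid). Lactones are assumed preserved; ketones are inert.
#'
#' @param pre_delta Integer pre-treatment delta class.
#' @param composition One-row data frame or named vector with counts
#'   `n_c1_acid`, `n_c4_keto`, `n_c6_aldehyde`, `n_c6_acid`, `n_lactone`
#'   (missing counts default to 0). Must itself evaluate to `pre_delta`.
#' @param oxidize_reducing_end As in [br2_transform()].
#' @return Integer post-treatment delta class.
#' @examples
#' br2_delta_map(-2, c(n_c6_aldehyde = 1))  # +30
#' br2_delta_map(-2, c(n_c4_keto = 1))      # +14
#' @export
br2_delta_map <- function(pre_delta, composition, oxidize_reducing_end = TRUE) {
  comp <- as.list(composition)
  get <- function(nm) as.integer(comp[[nm]] %||% 0L)
  counts <- c(
    n_c1_acid = get("n_c1_acid"), n_c4_keto = get("n_c4_keto"),
    n_c6_aldehyde = get("n_c6_aldehyde"), n_c6_acid = get("n_c6_acid"),
    n_lactone = get("n_lactone"), n_unsat_4_5 = get("n_unsat_4_5")
  )
  implied <- 16L * counts["n_c1_acid"] - 2L * counts["n_c4_keto"] -
    2L * counts["n_c6_aldehyde"] + 14L * counts["n_c6_acid"] -
    18L * counts["n_lactone"] - 18L * counts["n_unsat_4_5"]
  if (implied != as.integer(pre_delta)) {
    rlang::abort(paste0("composition evaluates to delta ", implied,
                        ", not the stated pre-treatment delta ", pre_delta))
  }
  aldehydes <- counts[["n_c6_aldehyde"]] +
    as.integer(oxidize_reducing_end && counts[["n_c1_acid"]] == 0L)
  as.integer(pre_delta) + 16L * aldehydes
}
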