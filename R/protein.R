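# Peptide-level arithmetic used when verifying the processed N-terminus of a
# heterologously expressed enzyme: neutral peptide masses, multiply charged
# m/z, and the apparent-vs-calculated glycosylation percentage from SDS-PAGE.

# Standard amino-acid residue masses (peptide-bond residues, i.e. minus
# water). Monoisotopic values to 5 decimals; average to 4.
.residue_masses <- list(
  monoisotopic = c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  ),
  average = c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594,
    N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741,
    E = 129.1155, M = 131.1926, H = 137.1411, F = 147.1766,
    R = 156.1875, Y = 163.1760, W = 186.2132
  )
)

.proton_monoisotopic <- 1.00728

#' Neutral mass of a peptide
#'
#' Sum of standard residue masses plus one water; no modifications.
#'
#' @param sequence Peptide string over the 20 standard one-letter codes.
#' @param mode "monoisotopic" (default) or "average".
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("G")  # 75.032
#' peptide_mass("HGHVSHIIVNGVQYR")
#' @export
peptide_mass <- function(sequence, mode = c("monoisotopic", "average")) {
  mode <- rlang::arg_match(mode)
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    rlang::abort("sequence must be a nonempty string")
  }
  letters_vec <- strsplit(sequence, "")[[1]]
  masses <- .residue_masses[[mode]][letters_vec]
  if (anyNA(masses)) {
    bad <- unique(letters_vec[is.na(masses)])
    rlang::abort(paste0("not a standard amino-acid letter: ",
                        paste(bad, collapse = ", ")))
  }
  water <- if (mode == "monoisotopic") 18.010565 else 18.0153
  sum(masses) + water
}

#' m/z of a multiply protonated species
#'
#' @param mass Neutral mass.
#' @param z Positive integer charge.
#' @param mode "monoisotopic" (proton 1.00728) or "nominal" (proton 1).
#' @return `(mass + z * proton) / z`.
#' @examples
#' charged_mz(peptide_mass("HGHVSHIIVNGVQYR"), 3)  # ~572.64
#' @export
charged_mz <- function(mass, z, mode = c("monoisotopic", "nominal")) {
  mode <- rlang::arg_match(mode)
  if (any(z < 1) || any(z != round(z))) {
    rlang::abort("charge z must be a positive integer")
  }
  proton <- if (mode == "monoisotopic") .proton_monoisotopic else 1
  (mass + z * proton) / z
}

#' Apparent glycosylation percentage
#'
#' The SDS-PAGE convention: `100 * (apparent - calculated) / apparent`,
#' reported to one decimal.
#'
#' @param apparent_kda Apparent molecular mass (gel), kDa.
#' @param calculated_kda Sequence-calculated mass, kDa.
#' @return Percent glycosylation, rounded to one decimal.
#' @examples
#' glycosylation_percent(57.5, 34.89979)  # 39.3
#' @export
glycosylation_percent <- function(apparent_kda, calculated_kda) {
  if (any(calculated_kda <= 0) || any(apparent_kda < calculated_kda)) {
    rlang::abort("need apparent >= calculated > 0")
  }
  round(100 * (apparent_kda - calculated_kda) / apparent_kda, 1)
}
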