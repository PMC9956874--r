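#' Published dietary amino acid molar ratios
#'
#' The three chemically defined fly-diet amino acid compositions shipped
#' with the package: `FLYAA`, the exome-matched molar ratio; `MALEAA` and
#' `FEMALEAA`, the whole-body transcriptome-weighted ratios for male and
#' female flies. Values are the printed 3-decimal molar fractions,
#' renormalised so each profile sums to exactly one (the raw column sum is
#' kept in each profile's `raw_sum` attribute).
#'
#' @return A named list of three [aa_profile()] objects.
#' @export
#' @examples
#' diets <- diet_profiles()
#' aa_coverage(diets$FLYAA, diets$MALEAA)
diet_profiles <- function() {
  read_diet_ratios(system.file("extdata", "diet_aa_ratios.tsv",
                               package = "exomatch", mustWork = TRUE))
}
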