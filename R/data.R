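#' Example panel of modified 2'-deoxyribonucleoside ions
#'
#' Eleven precursor/product ion pairs of putative DNA adducts observed in
#' marine amphipod genomic DNA, with retention times, proposed neutral
#' elemental compositions (where determined), reported mass accuracies and
#' rings-plus-double-bonds values, and the direction of change between
#' contaminated and reference sites. Used as example screening targets and
#' as consistency anchors in the test suite. Every precursor/product pair
#' satisfies the 116.0473 Da deoxyribose neutral-loss criterion at 5 ppm
#' referenced to the precursor m/z.
#'
#' @return data.frame with columns `adduct_id`, `precursor_mz`,
#'   `product_mz`, `rt` (minutes), `formula`, `delta_ppm_reported`,
#'   `rdb_reported`, `direction`.
#' @export
example_adducts <- function() {
  utils::read.delim(system.file("extdata", "example_adducts.tsv",
                                package = "dnadduct"),
                    stringsAsFactors = FALSE)
}
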