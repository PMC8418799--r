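#' Bundled reference survey tables
#'
#' The package ships summary tables from a range-wide microsatellite survey
#' of the southern pine beetle (*Dendroctonus frontalis*) across the eastern
#' United States: 33 loci genotyped at 9 sampling sites (255 individuals).
#' They provide realistic inputs for the locus-screening workflow and are
#' used by the test suite as fixtures.
#'
#' * `spb_null_freqs()` — per locus and outbred population: estimated
#'   null-allele frequency (`r_hat`, Brookfield estimator 1) and whether the
#'   population showed a significant homozygote excess at that locus
#'   (`significant`). Seven outbred populations; two inbred sites were
#'   excluded from the scan.
#' * `spb_null_summary()` — per locus: published cumulative null burden
#'   (`r_cumulative`) and worst-to-best rank (`null_rank`).
#' * `spb_locus_annotations()` — per locus: repeat count and length (bp) of
#'   the one directly sequenced allele, the median allele length over all
#'   255 individuals, the published rescaled repeat count
#'   (`median_repeats_printed`) and homoplasy rank (`repeat_rank`).
#' * `spb_global_fst()` — per locus: global Weir-Cockerham F_ST across the
#'   nine sites and its descending rank.
#'
#' @return A data frame (see above).
#' @name spb_reference
NULL

spb_table <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "msatIBD",
                              mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname spb_reference
#' @export
spb_null_freqs <- function() spb_table("spb_null_freqs.csv")

#' @rdname spb_reference
#' @export
spb_null_summary <- function() spb_table("spb_null_summary.csv")

#' @rdname spb_reference
#' @export
spb_locus_annotations <- function() spb_table("spb_locus_annotations.csv")

#' @rdname spb_reference
#' @export
spb_global_fst <- function() spb_table("spb_global_fst.csv")
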