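#' Published legume TF/TAP repertoire counts (worked example)
#'
#' Per-family counts for the largest TF/TAP families of cowpea
#' (*Vigna unguiculata*), common bean (*Phaseolus vulgaris*) and soybean
#' (*Glycine max*), as published for the three-pipeline cowpea compendium,
#' together with the repertoire totals (cowpea: 5460 domains from 4416
#' sequences from 4408 genes) and each species' protein-coding transcript
#' totals. These serve as the worked-example inputs for
#' [family_share()], [percent_difference()], [halve_counts()] and
#' [compare_repertoires()]: e.g. C2H2 holds 511 of 4416 cowpea sequences
#' (11.57% of the repertoire), cowpea has ~31.7% fewer TF/TAP sequences
#' than common bean, and the halved soybean total is 6710.
#'
#' The `sequences` column counts gene models (per-frame translated
#' sequences); the `genes` column collapses models onto genes. Families
#' whose count at a granularity was not published carry `NA` there.
#'
#' @return named list of three [repertoire_table()]s: `cowpea`, `bean`,
#'   `soy`.
#' @export
legume_repertoire_counts <- function() {
  cowpea <- repertoire_table(
    data.frame(
      family = c("C2H2", "PcG_FIE", "MYB-HB-like", "bHLH", "CCHC_Zn",
                 "AP2-EREBP", "bZIP", "PHD", "NAC", "MYB-related"),
      sequences = c(511L, 462L, 311L, 214L, 167L,
                    180L, 165L, 184L, 120L, 156L),
      genes = c(416L, 307L, 240L, 155L, 155L,
                148L, 139L, 147L, NA, NA),
      stringsAsFactors = FALSE),
    species = "cowpea",
    protein_coding_total = 60838,
    totals = c(domains = 5460, sequences = 4416, genes = 4408))
  bean <- repertoire_table(
    data.frame(
      family = c("C2H2", "PcG_FIE", "MYB-HB-like"),
      sequences = c(974L, 489L, 468L),
      genes = c(699L, 315L, 322L),
      stringsAsFactors = FALSE),
    species = "bean",
    protein_coding_total = 36995,
    totals = c(domains = NA, sequences = 6468, genes = 5291))
  soy <- repertoire_table(
    data.frame(
      family = c("C2H2", "PcG_FIE", "MYB-HB-like"),
      sequences = c(2144L, 1208L, 1153L),
      genes = c(1253L, 632L, 654L),
      stringsAsFactors = FALSE),
    species = "soy",
    protein_coding_total = 88647,
    totals = c(domains = NA, sequences = 13419, genes = 11065))
  list(cowpea = cowpea, bean = bean, soy = soy)
}
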