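#' Reference summary of the white clover component and integrated maps
#'
#' Published per-linkage-group summary statistics for the white clover
#' integrated map (`IM`) and its two component parental-consensus maps: the
#' EST-SSR population (`MP1`, n = 92) and the GeneThresher-SSR population
#' (`MP2`, n = 184).  Sixteen linkage groups (eight homoeologous pairs,
#' labelled `1-1` ... `8-2` under Medicago-aligned nomenclature) with the
#' number of mapped marker loci, the observed Kosambi map length, and the
#' printed expected (Method-4) length.
#'
#' The printed expected lengths are carried for reference; `map_statistics()`
#' and the worked examples recompute expected lengths from the observed
#' columns with `method4_expected()`.  Two known quirks of the printed table
#' are documented here rather than reproduced: the IM and MP2 expected values
#' for groups 2-1/2-2 and 6-1/6-2 appear interchanged relative to a direct
#' Method-4 computation from the same rows, and the MP1 per-group expected
#' column is not recoverable from the MP1 observed column by Method 4 (only
#' its printed total, 1220.7 cM, is used downstream).
#'
#' @return A tibble with columns `group`, `map` (`"IM"`, `"MP2"`, `"MP1"`),
#'   `n_loci`, `length_obs` (cM), and `length_est_printed` (cM).
#' @examples
#' clover_map_summary() |>
#'   dplyr::group_by(map) |>
#'   dplyr::summarise(loci = sum(n_loci), length = sum(length_obs))
#' @export
clover_map_summary <- function() {
  group <- c("1-1", "1-2", "2-1", "2-2", "3-1", "3-2", "4-1", "4-2",
             "5-1", "5-2", "6-1", "6-2", "7-1", "7-2", "8-1", "8-2")
  im <- tibble(
    group = group, map = "IM",
    n_loci = c(66L, 87L, 42L, 48L, 77L, 85L, 98L, 78L,
               60L, 63L, 57L, 44L, 70L, 62L, 95L, 77L),
    length_obs = c(86.7, 92.8, 70.2, 71.4, 89.4, 88.1, 82.5, 80.0,
                   76.3, 72.7, 70.1, 66.5, 88.3, 72.9, 86.2, 79.6),
    length_est_printed = c(89.3, 94.9, 72.6, 69.6, 91.7, 90.2, 84.2, 82.1,
                           78.9, 75.0, 73.6, 74.5, 90.8, 75.3, 88.0, 81.7)
  )
  mp2 <- tibble(
    group = group, map = "MP2",
    n_loci = c(44L, 70L, 24L, 38L, 47L, 53L, 59L, 52L,
               50L, 46L, 41L, 22L, 41L, 47L, 59L, 40L),
    length_obs = c(84.9, 93.1, 63.2, 70.9, 92.4, 87.8, 76.9, 76.7,
                   62.3, 65.4, 68.5, 70.3, 94.8, 76.6, 93.8, 87.2),
    length_est_printed = c(88.9, 95.8, 72.0, 77.0, 96.4, 91.2, 79.5, 79.7,
                           64.9, 68.3, 68.7, 74.8, 99.5, 79.9, 97.1, 91.7)
  )
  mp1 <- tibble(
    group = group, map = "MP1",
    n_loci = c(31L, 27L, 22L, 18L, 35L, 38L, 52L, 47L,
               26L, 14L, 22L, 23L, 38L, 20L, 41L, 39L),
    length_obs = c(91.0, 72.0, 72.0, 76.0, 76.0, 77.0, 82.0, 94.0,
                   77.0, 28.0, 69.0, 60.0, 69.0, 62.0, 70.0, 69.0),
    length_est_printed = c(80.8, 81.8, 76.8, 80.8, 73.8, 66.8, 86.8, 98.8,
                           95.8, 76.8, 74.8, 73.8, 81.8, 32.8, 73.8, 64.8)
  )
  dplyr::bind_rows(im, mp2, mp1)
}

#' Reference inter-population homoeologue matching evidence
#'
#' Published per-linkage-group evidence counts used to match homoeologues
#' between the two white clover mapping populations: counts of single-locus
#' homoeologue-specific (SL-HS) joining loci in agreement (`slhs_match`) or at
#' variance (`slhs_mismatch`) with the accepted pairing, and counts of joining
#' loci whose allele sizes support (`size_match`), contradict
#' (`size_mismatch`) or fail to discriminate (`size_ambiguous`) the pairing.
#'
#' @return A tibble with one row per integrated linkage group.
#' @seealso [support_summary()] for the derived summary statistics.
#' @export
clover_integration_support <- function() {
  tibble(
    group = c("1-1", "1-2", "2-1", "2-2", "3-1", "3-2", "4-1", "4-2",
              "5-1", "5-2", "6-1", "6-2", "7-1", "7-2", "8-1", "8-2"),
    slhs_match     = c(3L, 4L, 1L, 2L, 3L, 2L, 2L, 1L, 1L, 0L, 2L, 0L, 2L, 1L, 4L, 2L),
    slhs_mismatch  = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    size_match     = c(2L, 3L, 1L, 5L, 3L, 1L, 4L, 7L, 7L, 2L, 2L, 2L, 3L, 3L, 2L, 0L),
    size_mismatch  = c(0L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 2L, 0L, 2L, 1L, 1L, 0L, 0L, 0L),
    size_ambiguous = c(2L, 2L, 3L, 4L, 1L, 0L, 2L, 2L, 5L, 3L, 3L, 0L, 2L, 4L, 1L, 2L)
  )
}
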