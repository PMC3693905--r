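#' Tidy a linkage map
#'
#' @param x A `clover_map`.
#' @param ... Unused.
#' @return The locus table as a tibble (`locus_id`, `group`, `pos_cM`, plus
#'   provenance columns where present).
#' @export
tidy.clover_map <- function(x, ...) {
  as_tibble(x$loci)
}

#' One-row summary of a linkage map
#'
#' @param x A `clover_map`.
#' @param ... Unused.
#' @return A one-row tibble: `n_loci`, `n_groups`, `length_obs`,
#'   `length_est`, `coverage`, `mean_density`.
#' @export
glance.clover_map <- function(x, ...) {
  s <- map_statistics(x)$summary
  val <- setNames(s$value, s$statistic)
  tibble(
    n_loci = unname(val["total_loci"]),
    n_groups = unname(val["n_groups"]),
    length_obs = unname(val["total_length_obs"]),
    length_est = unname(val["total_length_est"]),
    coverage = unname(val["coverage"]),
    mean_density = unname(val["mean_density"])
  )
}
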