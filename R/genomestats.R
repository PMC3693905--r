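#' Expected linkage-group length (Method 4)
#'
#' Inflate an observed linkage-group length to an expected chromosome length
#' under the assumption of randomly distributed markers:
#' \deqn{\hat L = L_{obs} \times \frac{m + 1}{m - 1}}
#' for a group of `m` mapped loci.  As `m` grows the inflation factor tends to
#' one and the estimate converges on the observed length.
#'
#' @param l_obs Observed group length(s), cM.
#' @param m Number of mapped loci per group (integer, `m >= 2`).
#'
#' @return Expected length(s), cM.  Vectorised over groups.
#' @examples
#' method4_expected(82.5, 98)  # 84.2
#' @export
method4_expected <- function(l_obs, m) {
  stopifnot(is.numeric(l_obs), is.numeric(m))
  if (any(!is.na(m) & m < 2)) {
    stop("Method-4 expected length needs at least 2 loci per group",
         call. = FALSE)
  }
  if (any(!is.na(l_obs) & l_obs < 0)) {
    stop("observed lengths must be non-negative", call. = FALSE)
  }
  l_obs * (m + 1) / (m - 1)
}

#' Genome coverage from observed and expected map length
#'
#' Coverage in the sense of Sekino and Hara: the summed observed map length as
#' a proportion of the summed expected genome length.
#'
#' @param g_obs Total observed map length, cM.
#' @param g_est Total expected genome length, cM (`> 0`).
#' @return Coverage proportion.
#' @examples
#' genome_coverage(1264.8, 1325.2)  # MP2-style coverage, 0.954
#' @export
genome_coverage <- function(g_obs, g_est) {
  stopifnot(is.numeric(g_obs), is.numeric(g_est))
  if (any(!is.na(g_est) & g_est <= 0)) {
    stop("expected genome length must be positive", call. = FALSE)
  }
  g_obs / g_est
}

#' Map saturation (Fishman)
#'
#' Proportion of a genome of length `g` cM expected to lie within `d` cM of at
#' least one of `n` randomly placed marker loci:
#' \deqn{c = 1 - e^{-2 d n / g}.}
#' Strictly increasing in both `d` and `n`, and tends to 1 as `d` grows.
#'
#' @param n Number of mapped loci (`>= 1`).
#' @param g Genome length, cM (`> 0`); use the Method-4 expected total.
#' @param d Distance from a locus, cM (`>= 0`).  Vectorised.
#' @return Proportion(s) in `[0, 1)`.
#' @examples
#' map_saturation(1109, 1312.5, 1)  # 0.815 -> "82% within 1 cM"
#' @export
map_saturation <- function(n, g, d) {
  stopifnot(is.numeric(n), is.numeric(g), is.numeric(d))
  if (any(n < 1) || any(g <= 0) || any(d < 0)) {
    stop("need n >= 1, g > 0 and d >= 0", call. = FALSE)
  }
  1 - exp(-2 * d * n / g)
}

#' Saturation curve over a range of distances
#'
#' @inheritParams map_saturation
#' @param d_max Largest distance evaluated, cM.
#' @param step Grid step, cM.
#' @return A tibble with columns `d` (cM) and `saturation`.
#' @export
saturation_curve <- function(n, g, d_max = 5, step = 0.1) {
  d <- seq(0, d_max, by = step)
  tibble(d = d, saturation = map_saturation(n, g, d))
}
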