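#' Kosambi mapping function
#'
#' Convert a recombination fraction to genetic distance, or back, under the
#' Kosambi mapping function, which allows partial crossover interference:
#' \deqn{d = 25\,\ln\!\frac{1 + 2r}{1 - 2r} \quad\textrm{cM}.}
#'
#' The inverse is \eqn{r = \tanh(2d/100)/2}.  The two functions are exact
#' inverses of each other (round trip to machine precision).
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Genetic distance(s) in centimorgans, `d >= 0`.
#'
#' @return `kosambi_d()` returns genetic distance in cM; `kosambi_r()` returns
#'   a recombination fraction.  Both are vectorised.
#'
#' @examples
#' kosambi_d(0.1)               # 10.137 cM
#' kosambi_r(kosambi_d(0.25))   # 0.25
#' @export
kosambi_d <- function(r) {
  stopifnot(is.numeric(r))
  if (any(!is.na(r) & (r < 0 | r >= 0.5))) {
    stop("recombination fractions must lie in [0, 0.5)", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_d
#' @export
kosambi_r <- function(d) {
  stopifnot(is.numeric(d))
  if (any(!is.na(d) & d < 0)) {
    stop("genetic distances must be non-negative", call. = FALSE)
  }
  tanh(2 * d / 100) / 2
}
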