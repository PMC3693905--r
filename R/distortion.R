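#' Chi-square test of a segregation ratio
#'
#' Goodness-of-fit of observed progeny class counts against an expected
#' ratio, with `classes - 1` degrees of freedom.  When any expected count
#' falls below 1 the chi-square approximation is unsafe and an exact
#' multinomial test is used instead (all outcomes with a chi-square statistic
#' at least as large as observed), falling back to a Monte-Carlo p-value for
#' sample sizes where enumeration is impractical.
#'
#' @param observed Integer vector of class counts.
#' @param ratio Expected ratio (e.g. `c(1, 1, 1, 1)`); normalised internally.
#' @return Tibble: `chi_square`, `df`, `p_value`, `method`.
#' @examples
#' segregation_chisq(c(60, 40), c(1, 1))  # chi-square 4, P = 0.0455
#' @export
segregation_chisq <- function(observed, ratio = rep(1, length(observed))) {
  stopifnot(length(observed) == length(ratio), all(observed >= 0))
  n <- sum(observed)
  p <- ratio / sum(ratio)
  expected <- n * p
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  if (all(expected >= 1)) {
    return(tibble(chi_square = stat, df = df,
                  p_value = pchisq(stat, df, lower.tail = FALSE),
                  method = "chi-square"))
  }
  if (n <= 40 && length(observed) <= 4) {
    outcomes <- compositions(n, length(observed))
    stats <- colSums((t(outcomes) - expected)^2 / expected)
    probs <- apply(outcomes, 1, function(x) stats::dmultinom(x, prob = p))
    pv <- sum(probs[stats >= stat - 1e-9])
    return(tibble(chi_square = stat, df = df, p_value = pv,
                  method = "exact multinomial"))
  }
  sim <- stats::rmultinom(2000, n, p)
  stats <- colSums((sim - expected)^2 / expected)
  tibble(chi_square = stat, df = df,
         p_value = mean(stats >= stat - 1e-9),
         method = "monte-carlo multinomial")
}

# all length-k compositions of n (rows)
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (i in 0:n) {
    sub <- compositions(n - i, k - 1)
    out[[length(out) + 1L]] <- cbind(i, sub)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Segregation-distortion scan of a mapped population
#'
#' Tests every mapped locus for distortion of the transmitted-allele ratio,
#' separately per parental origin: for each parent with informative meioses
#' at the locus, the two transmitted-allele counts are tested against 1:1.
#' Probabilities are reported on the signed log scale used for distortion
#' profiles: `-log10(P)` (a positive value) for female(maternal)-derived
#' alleles and `log10(P)` (a negative value) for male(paternal)-derived
#' alleles, so the sign encodes parental origin and the magnitude is always
#' `-log10(P)`.
#'
#' Loci with `P < p_threshold` are flagged `distorted`.  A flagged locus is
#' additionally marked `removable` when its distortion is incongruous with
#' its map neighbourhood: both flanking loci (same group and parent, by map
#' order) are non-distorted and its `|signed log10 P|` exceeds both flanks'
#' by more than 2.
#'
#' @param pop A `clover_population`.
#' @param map Optional map tibble (`locus_id`, `group`, `pos_cM`) used to
#'   attach groups, relative positions and the flanking-locus rule; without
#'   it, only the per-locus tests are returned.
#' @param p_threshold Flagging threshold (default 0.05).
#' @return Tibble: `locus_id`, `parental_origin` (`"female"`/`"male"`),
#'   `n`, `chi_square`, `df`, `p_value`, `signed_log10p`, `distorted`, and —
#'   when a map is supplied — `group`, `pos_cM`, `relative_position`,
#'   `removable`.
#' @export
distortion_scan <- function(pop, map = NULL, p_threshold = 0.05) {
  res <- list()
  for (parent in c("maternal", "paternal")) {
    tmat <- transmission_matrix(pop, parent)
    n1 <- colSums(tmat == 1L, na.rm = TRUE)
    n2 <- colSums(tmat == 2L, na.rm = TRUE)
    n <- n1 + n2
    keep <- n > 0
    if (!any(keep)) next
    stat <- (n1[keep] - n2[keep])^2 / n[keep]
    pv <- pchisq(stat, 1, lower.tail = FALSE)
    origin <- if (parent == "maternal") "female" else "male"
    sgn <- if (origin == "female") 1 else -1
    res[[parent]] <- tibble(
      locus_id = names(n)[keep],
      parental_origin = origin,
      n = as.integer(n[keep]),
      chi_square = stat,
      df = 1L,
      p_value = pv,
      signed_log10p = sgn * (-log10(pv)),
      distorted = pv < p_threshold
    )
  }
  out <- dplyr::bind_rows(res)
  if (is.null(map) || nrow(out) == 0) return(out)
  out <- dplyr::inner_join(out, map[, c("locus_id", "group", "pos_cM")],
                           by = "locus_id")
  out <- out %>%
    dplyr::group_by(.data$group) %>%
    dplyr::mutate(relative_position = proportional_position(.data$pos_cM)) %>%
    dplyr::group_by(.data$group, .data$parental_origin) %>%
    dplyr::arrange(.data$pos_cM, .by_group = TRUE) %>%
    dplyr::mutate(removable = flag_incongruous(.data$distorted,
                                               abs(.data$signed_log10p))) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$group, .data$pos_cM, .data$parental_origin)
  out
}

# distorted AND both flanks non-distorted AND magnitude exceeds flanks by > 2
flag_incongruous <- function(distorted, mag) {
  m <- length(distorted)
  out <- rep(FALSE, m)
  if (m < 3) return(out)
  for (i in 2:(m - 1)) {
    out[i] <- distorted[i] && !distorted[i - 1] && !distorted[i + 1] &&
      (mag[i] - mag[i - 1] > 2) && (mag[i] - mag[i + 1] > 2)
  }
  out
}
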