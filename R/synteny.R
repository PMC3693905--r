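#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses the conventional 12-column BLAST tabular format (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`).
#' Malformed rows are reported with their line numbers.
#'
#' @param path Path to a tab-separated hits file without header.
#' @return Tibble with the 12 standard columns, numeric where appropriate.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad)) {
    stop("malformed BLAST tabular rows at line(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  out <- tibble(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  if (anyNA(out$evalue) || anyNA(out$bitscore)) {
    stop("malformed numeric fields in BLAST tabular input", call. = FALSE)
  }
  out
}

#' Best-hit filtering of homology hits
#'
#' Per query: discard hits with E-value above the exclusion threshold, keep
#' at most `max_hits` by ascending E-value, and retain the single strongest
#' hit (lowest E-value; ties broken by higher bit score, then by first
#' occurrence in the input).  The result depends only on the set of
#' `(query, evalue, bitscore)` triples, not on input order.
#'
#' @param hits Tibble with at least `qseqid`, `evalue`, `bitscore` (e.g.
#'   from [read_blast_tab()]).
#' @param e_max E-value exclusion threshold (default 1e-20).
#' @param max_hits Cap on retained hits per query before choosing the best.
#' @return Tibble of one row per query that survives the threshold, ordered
#'   by `qseqid`.
#' @export
filter_hits <- function(hits, e_max = 1e-20, max_hits = 5) {
  hits %>%
    dplyr::filter(.data$evalue <= e_max) %>%
    dplyr::group_by(.data$qseqid) %>%
    dplyr::arrange(.data$evalue, -.data$bitscore, .by_group = TRUE) %>%
    dplyr::slice_head(n = max_hits) %>%
    dplyr::slice_head(n = 1) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$qseqid)
}

#' Conflate homoeologue pairs onto eight proportional axes
#'
#' Collapses a 16-group integrated map into eight homoeologous groups for
#' reference-genome alignment: each locus keeps its own homoeologue's frame
#' and is expressed as a proportion of distance along that homoeologue
#' (`pos / homoeologue length`), so homoeoloci of one marker contribute one
#' point per mapped locus and homoeologue disagreements stay visible.
#'
#' @param map A `clover_map` or tibble with `locus_id`, `group`, `pos_cM`,
#'   where groups follow the `"<pair>-<homoeologue>"` naming (e.g. `"3-1"`).
#' @return Tibble: `locus_id`, `tr_group` (integer 1-8), `homoeologue`,
#'   `tr_position` in `[0, 1]`.  Loci with unparsable group labels are
#'   dropped with a warning.
#' @export
conflate_homoeologues <- function(map) {
  loci <- if (inherits(map, "clover_map")) map$loci else map
  parsed <- stringr::str_match(loci$group, "^(\\d+)-(\\d+)$")
  bad <- is.na(parsed[, 1])
  if (any(bad)) {
    warning(sum(bad), " locus/loci without a parsable group label excluded",
            call. = FALSE)
  }
  out <- loci[!bad, , drop = FALSE]
  out$tr_group <- as.integer(parsed[!bad, 2])
  out$homoeologue <- as.integer(parsed[!bad, 3])
  out %>%
    dplyr::group_by(.data$group) %>%
    dplyr::mutate(tr_position = proportional_position(.data$pos_cM)) %>%
    dplyr::ungroup() %>%
    dplyr::select("locus_id", "tr_group", "homoeologue", "tr_position")
}

proportional_position <- function(pos) {
  mx <- max(pos)
  if (mx > 0) pos / mx else rep(0, length(pos))
}

#' Build normalized synteny records
#'
#' Joins conflated map positions with best homology hits and expresses the
#' reference position as the proportion of distance along its chromosome
#' (hit midpoint; strand kept as metadata only).
#'
#' @param conflated Output of [conflate_homoeologues()].
#' @param hits Best-hit tibble from [filter_hits()].
#' @param chrom_lengths Named numeric vector: reference chromosome lengths
#'   (bp), names matching `sseqid`.
#' @param by Name of the hit column matching `locus_id` (default
#'   `"qseqid"`).
#' @return Tibble: `locus_id`, `tr_group`, `tr_position`,
#'   `ref_chromosome`, `ref_position`, `e_value`, `strand`.
#' @export
synteny_records <- function(conflated, hits, chrom_lengths, by = "qseqid") {
  stopifnot(all(hits$sseqid %in% names(chrom_lengths)))
  h <- hits %>%
    dplyr::mutate(
      ref_chromosome = .data$sseqid,
      ref_position = (pmin(.data$sstart, .data$send) +
                        pmax(.data$sstart, .data$send)) / 2 /
        unname(chrom_lengths[.data$sseqid]),
      strand = ifelse(.data$send >= .data$sstart, "+", "-"),
      e_value = .data$evalue
    ) %>%
    dplyr::select(locus_id = dplyr::all_of(by), "ref_chromosome",
                  "ref_position", "e_value", "strand")
  dplyr::inner_join(conflated, h, by = "locus_id")
}

#' Hit-count matrix between map groups and reference chromosomes
#'
#' @param records Tibble from [synteny_records()] (needs `tr_group`,
#'   `ref_chromosome`; `tr_position`/`ref_position` carried through for
#'   plotting).
#' @return List: `counts` (tibble `tr_group`, `ref_chromosome`, `n`),
#'   `dominant` (tibble `tr_group`, `ref_chromosome`, `n`, `fraction`), and
#'   `dots` (the per-record plotting table).
#' @export
synteny_matrix <- function(records) {
  if (nrow(records) == 0) {
    empty <- tibble(tr_group = integer(), ref_chromosome = character(),
                    n = integer())
    return(list(counts = empty,
                dominant = dplyr::mutate(empty, fraction = double()),
                dots = records))
  }
  counts <- dplyr::count(records, .data$tr_group, .data$ref_chromosome)
  dominant <- counts %>%
    dplyr::group_by(.data$tr_group) %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n)) %>%
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  list(counts = counts, dominant = dominant, dots = records)
}

#' Robust line fit by repeated medians
#'
#' Siegel's repeated-median regression: the slope is the median over points
#' of the median pairwise slope through each point, and the intercept the
#' median residual offset.  Breakdown point 50%, so scattered off-trend hits
#' do not drag the macrosyntenic trend line.
#'
#' @param x,y Numeric vectors.
#' @return List `slope`, `intercept`, `residuals`.
#' @export
repeated_median_fit <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n)
  slope_i <- vapply(seq_len(n), function(i) {
    dx <- x[-i] - x[i]
    dy <- y[-i] - y[i]
    ok <- dx != 0
    if (!any(ok)) return(NA_real_)
    median(dy[ok] / dx[ok])
  }, double(1))
  slope <- median(slope_i, na.rm = TRUE)
  if (is.na(slope)) slope <- 0
  intercept <- median(y - slope * x)
  list(slope = slope, intercept = intercept,
       residuals = y - (intercept + slope * x))
}

#' Fraction of hits on the dominant macrosyntenic trend
#'
#' For each map group's dominant reference chromosome, fits a robust
#' (repeated-median) line to the normalized coordinates and counts a record
#' as co-linear when its absolute residual is at most `residual_threshold`
#' (in units of normalized length).  The overall fraction is co-linear
#' records over all records, so hits to non-dominant chromosomes and blocks
#' too small to evaluate (< 3 records) count against co-linearity.  Because
#' the fit is a line with free sign, the measure is invariant to reversing
#' either axis.
#'
#' @param records Tibble from [synteny_records()].
#' @param residual_threshold Residual band half-width (default 0.1).
#' @return List: `fraction`, `n_colinear`, `n_total`, and per-record detail
#'   `records` with `colinear` and `residual` columns.
#' @export
colinearity_fraction <- function(records, residual_threshold = 0.1) {
  if (nrow(records) == 0) {
    return(list(fraction = NA_real_, n_colinear = 0L, n_total = 0L,
                records = records))
  }
  dom <- synteny_matrix(records)$dominant
  records <- records %>%
    dplyr::left_join(dom %>%
                       dplyr::select("tr_group",
                                     dom_chrom = "ref_chromosome"),
                     by = "tr_group") %>%
    dplyr::mutate(residual = NA_real_, colinear = FALSE)
  for (g in unique(records$tr_group)) {
    i <- which(records$tr_group == g &
                 records$ref_chromosome == records$dom_chrom)
    if (length(i) < 3) next
    fit <- repeated_median_fit(records$tr_position[i],
                               records$ref_position[i])
    records$residual[i] <- fit$residuals
    records$colinear[i] <- abs(fit$residuals) <= residual_threshold
  }
  list(fraction = mean(records$colinear),
       n_colinear = sum(records$colinear),
       n_total = nrow(records),
       records = records)
}

#' Detect translocation-like segmentation of a map group
#'
#' Orders one conflated group's hits along the group and segments the
#' sequence of reference-chromosome labels with at most `max_breakpoints`
#' change points, minimising the number of hits not matching their segment's
#' majority chromosome (ties resolved toward fewer segments).  A segment
#' whose chromosome is not the group's dominant one must be supported by at
#' least `min_support` hits and be internally coherent (within-segment
#' majority share at least `min_purity`); otherwise it is merged into its
#' neighbour, so interleaved labels collapse to a single low-purity segment
#' rather than spurious breakpoints.
#' Breakpoints are reported at the midpoint between the flanking hits.
#'
#' @param records Records of one `tr_group` (columns `tr_position`,
#'   `ref_chromosome`).
#' @param max_breakpoints Maximum number of change points (default 3).
#' @param min_support Minimum hits for a secondary-chromosome segment.
#' @param min_purity Minimum within-segment majority share for a
#'   secondary-chromosome segment.
#' @return List: `segments` (tibble `start`, `end`, `ref_chromosome`,
#'   `n_support`, `n_miscalled`), `breakpoints`, `purity` (1 - overall
#'   misclassification rate).
#' @export
detect_translocation <- function(records, max_breakpoints = 3,
                                 min_support = 3, min_purity = 0.75) {
  stopifnot(nrow(records) >= 1)
  ord <- order(records$tr_position)
  pos <- records$tr_position[ord]
  lab <- records$ref_chromosome[ord]
  n <- length(lab)
  seg <- optimal_segmentation(lab, max_breakpoints)
  segs <- segment_summary(seg, pos, lab)
  dominant <- names(sort(-table(lab)))[1]
  # enforce minimum support for secondary-chromosome segments and collapse
  # adjacent segments that end up with the same majority chromosome
  repeat {
    same <- which(segs$ref_chromosome[-1] ==
                    segs$ref_chromosome[-nrow(segs)])
    seg_purity <- segs$n_support / (segs$n_support + segs$n_miscalled)
    weak <- which(segs$ref_chromosome != dominant &
                    (segs$n_support < min_support |
                       seg_purity < min_purity))
    if (nrow(segs) == 1 || (!length(weak) && !length(same))) break
    w <- if (length(same)) same[1] + 1L else weak[1]
    neighbour <- if (w > 1) w - 1L else w + 1L
    seg[seg == w] <- neighbour
    seg <- as.integer(factor(seg, levels = unique(seg)))
    segs <- segment_summary(seg, pos, lab)
  }
  mis <- sum(segs$n_miscalled)
  bks <- if (nrow(segs) > 1) segs$start[-1] else numeric(0)
  list(segments = segs, breakpoints = bks, purity = 1 - mis / n)
}

# dynamic programme: contiguous segmentation with <= k+1 segments minimising
# hits not matching their segment's majority label; among optima prefer
# fewer segments.  Returns integer segment id per position.
optimal_segmentation <- function(lab, max_breakpoints) {
  n <- length(lab)
  labs <- unique(lab)
  # cost[i, j]: misclassified count in window i..j
  cost <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    tab <- integer(length(labs))
    for (j in i:n) {
      tab[match(lab[j], labs)] <- tab[match(lab[j], labs)] + 1L
      cost[i, j] <- (j - i + 1L) - max(tab)
    }
  }
  kmax <- max_breakpoints + 1L
  best <- matrix(Inf, kmax, n)   # best[k, j]: cost of 1..j with k segments
  back <- matrix(NA_integer_, kmax, n)
  best[1, ] <- cost[1, ]
  if (kmax >= 2) {
    for (k in 2:kmax) {
      if (k > n) break
      for (j in k:n) {
        cand <- (k - 1):(j - 1)   # last index of the previous segment
        prev <- best[k - 1, cand] + cost[cand + 1L, j]
        b <- which.min(prev)
        best[k, j] <- prev[b]
        back[k, j] <- cand[b]
      }
    }
  }
  ks <- which(best[, n] == min(best[, n]))
  k <- ks[1]                       # fewest segments among optima
  seg <- integer(n)
  j <- n
  for (kk in k:1) {
    i <- if (kk == 1) 1L else back[kk, j] + 1L
    seg[i:j] <- kk
    j <- i - 1L
  }
  seg
}

segment_summary <- function(seg, pos, lab) {
  out <- lapply(unique(seg), function(s) {
    i <- which(seg == s)
    tab <- sort(-table(lab[i]))
    maj <- names(tab)[1]
    lo <- if (min(i) == 1) 0 else mean(pos[c(min(i) - 1, min(i))])
    hi <- if (max(i) == length(pos)) 1 else mean(pos[c(max(i), max(i) + 1)])
    tibble(start = lo, end = hi, ref_chromosome = maj,
           n_support = sum(lab[i] == maj),
           n_miscalled = sum(lab[i] != maj))
  })
  dplyr::bind_rows(out)
}

#' Simulate synteny records with known structure
#'
#' Generates normalized dot-plot records for testing and illustration: each
#' map group aligns to one reference chromosome along a linear trend (with
#' optional inversion), a fraction of hits is scattered uniformly at random
#' over the genome, and one group can carry a translocated terminal segment.
#'
#' @param n_groups Number of map groups (and reference chromosomes).
#' @param hits_per_group Records per group.
#' @param scatter Fraction of hits scattered off-trend.
#' @param noise SD of on-trend residuals (normalized units).
#' @param translocation `NULL`, or a list with `group`, `to` (chromosome
#'   index), `from_position` (tr break in `[0,1]`).
#' @param seed RNG seed.
#' @return Tibble shaped like [synteny_records()] output, with truth columns
#'   `true_scattered`, `true_translocated`.
#' @export
simulate_synteny_records <- function(n_groups = 8, hits_per_group = 40,
                                     scatter = 0.1, noise = 0.02,
                                     translocation = NULL, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in seq_len(n_groups)) {
    x <- sort(runif(hits_per_group))
    y <- pmin(pmax(x + stats::rnorm(hits_per_group, 0, noise), 0), 1)
    chrom <- rep(paste0("chr", g), hits_per_group)
    sc <- runif(hits_per_group) < scatter
    chrom[sc] <- paste0("chr", sample.int(n_groups, sum(sc), replace = TRUE))
    y[sc] <- runif(sum(sc))
    tr <- rep(FALSE, hits_per_group)
    if (!is.null(translocation) && g == translocation$group) {
      tr <- x >= translocation$from_position & !sc
      chrom[tr] <- paste0("chr", translocation$to)
      y[tr] <- pmin(pmax(x[tr] - translocation$from_position +
                           stats::rnorm(sum(tr), 0, noise), 0), 1)
    }
    rows[[g]] <- tibble(
      locus_id = sprintf("g%d_l%02d", g, seq_len(hits_per_group)),
      tr_group = g, tr_position = x,
      ref_chromosome = chrom, ref_position = y,
      e_value = 10^runif(hits_per_group, -40, -21),
      strand = sample(c("+", "-"), hits_per_group, replace = TRUE),
      true_scattered = sc, true_translocated = tr
    )
  }
  dplyr::bind_rows(rows)
}
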