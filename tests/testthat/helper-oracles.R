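# Independent brute-force oracles used to check the implementation.

# exhaustive SSR scan: every (start, period) candidate, maximal perfect
# stretches, primitive motifs only, class thresholds
brute_ssr <- function(seq, min_repeats = c(di = 6L, tri = 5L, tetra = 5L,
                                           penta = 5L, hexa = 5L)) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  ok <- ch %in% c("A", "C", "G", "T")
  classes <- c("di", "tri", "tetra", "penta", "hexa")
  rows <- list()
  for (p in 2:6) {
    thr <- min_repeats[[classes[p - 1]]]
    i <- 1L
    while (i + p - 1 <= n) {
      # maximal-left: position i-1 must not continue the period
      left_ext <- i > 1 && i + p - 1 <= n && ok[i - 1] && ok[i + p - 1] &&
        ch[i - 1] == ch[i + p - 1]
      if (!left_ext && all(ok[i:(i + p - 1)])) {
        j <- i + p
        while (j <= n && ok[j] && ch[j] == ch[j - p]) j <- j + 1
        region_len <- j - i
        reps <- region_len %/% p
        motif <- paste(ch[i:(i + p - 1)], collapse = "")
        primitive <- TRUE
        for (q in seq_len(p - 1)) {
          if (p %% q == 0 &&
              strrep(substr(motif, 1, q), p / q) == motif) {
            primitive <- FALSE
            break
          }
        }
        if (reps >= thr && primitive && region_len >= 2 * p) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = i - 1L, end = i - 1L + reps * p, motif = motif,
            repeats = reps, stringsAsFactors = FALSE
          )
        }
      }
      i <- i + 1L
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), repeats = integer()))
  }
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

# brute-force primer feasibility: enumerate primer lengths and offsets
brute_feasibility <- function(start, end, seq_len,
                              amp = c(95, 395), primer = c(20, 27)) {
  left <- start; right <- seq_len - end
  if (left < primer[2] || right < primer[2]) return(FALSE)
  for (el in primer[1]:left) {
    for (er in primer[1]:right) {
      len <- (end - start) + el + er
      if (len >= amp[1] && len <= amp[2]) return(TRUE)
    }
  }
  FALSE
}

# brute-force best-hit filter
brute_filter_hits <- function(hits, e_max = 1e-20, max_hits = 5) {
  hits$.row <- seq_len(nrow(hits))
  out <- lapply(split(hits, hits$qseqid), function(h) {
    h <- h[h$evalue <= e_max, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    h <- h[order(h$evalue, -h$bitscore, h$.row), , drop = FALSE]
    h <- head(h, max_hits)
    h[1, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(hits[0, setdiff(names(hits), ".row")])
  out <- out[order(out$qseqid), , drop = FALSE]
  out$.row <- NULL
  rownames(out) <- NULL
  out
}

# exhaustive label segmentation: all segmentations with <= kmax breakpoints,
# minimal misclassification vs per-segment majority label
brute_segmentation_cost <- function(lab, kmax = 3) {
  n <- length(lab)
  mis <- function(idx) length(idx) - max(table(lab[idx]))
  best <- Inf
  cuts_list <- list(integer(0))
  if (kmax >= 1 && n >= 2) {
    for (k in 1:min(kmax, n - 1)) {
      cmb <- utils::combn(n - 1, k)
      for (ci in seq_len(ncol(cmb))) {
        cuts_list[[length(cuts_list) + 1L]] <- cmb[, ci]
      }
    }
  }
  for (cuts in cuts_list) {
    b <- c(0, cuts, n)
    tot <- 0
    for (s in seq_len(length(b) - 1)) {
      tot <- tot + mis((b[s] + 1):b[s + 1])
    }
    best <- min(best, tot)
  }
  best
}

# Monte-Carlo saturation: drop n loci on a circle of length g, measure the
# fraction of the circle within d of a locus
mc_saturation <- function(n, g, d, reps = 200, grid = 2000) {
  covered <- vapply(seq_len(reps), function(i) {
    loci <- runif(n, 0, g)
    pts <- seq(0, g, length.out = grid + 1)[-1]
    dist <- vapply(pts, function(p) {
      dd <- abs(p - loci)
      min(pmin(dd, g - dd))
    }, double(1))
    mean(dist <= d)
  }, double(1))
  mean(covered)
}

# small default simulation config for fast tests (overridable defaults)
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosome_pairs = 2L, markers_per_group = 8L,
         population_sizes = c(60L, 100L), panel_size = 10L),
    list(...)
  )
  do.call(sim_config, args)
}
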