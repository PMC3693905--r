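#' Merge two matched linkage groups through their joining loci
#'
#' Integrates two maps of the same chromosome (from two populations, or the
#' two parents of one population) via the loci they share.  The procedure:
#'
#' 1. Joining (anchor) loci are the loci present in both maps; at least two
#'    are required.
#' 2. If the joining loci run in exactly opposite order in the two maps, map
#'    B is flipped (group orientation is arbitrary); any remaining order
#'    conflict is an error naming the offending loci.
#' 3. Consensus anchor positions start at the weight-averaged raw positions
#'    and are refined by alternating least-squares: each map is affinely
#'    regressed onto the consensus frame, then the consensus is recomputed
#'    as the weighted mean of the fitted positions (a 1-D Procrustes fit;
#'    with two anchors, or identical maps, this reproduces the plain
#'    weighted mean).
#' 4. Non-joining loci are carried into the consensus frame by piecewise
#'    linear interpolation between their flanking anchors; beyond the
#'    terminal anchors the source map's overall affine slope extrapolates
#'    (a terminal-segment slope is numerically fragile when two anchors sit
#'    close together).
#' 5. The merged group is re-anchored to start at 0 and its orientation
#'    canonicalised (lexicographically smaller terminal locus first), which
#'    makes the merge symmetric in its two arguments.
#'
#' Because each source is carried by a monotone map, the relative order of
#' any two loci co-occurring in a source is preserved in the output.
#'
#' @param group_a,group_b Tibbles with `locus_id`, `pos_cM` for one linkage
#'   group each.
#' @param weights Length-2 positive weights (typically the population
#'   sizes).
#' @param on_conflict What to do when joining loci disagree in order after
#'   orientation is fixed: `"error"` (default) stops and names the loci;
#'   `"demote"` keeps the largest order-consistent anchor subset and places
#'   the remaining joining loci like ordinary loci (at the weighted mean of
#'   their two interpolated positions), with a warning.  Estimated maps
#'   carry ordering noise, so pipeline-level callers use `"demote"`.
#' @return Tibble `locus_id`, `pos_cM`, `provenance` (`"A only"`,
#'   `"B only"`, `"joining"`), ordered by position.
#' @examples
#' a <- tibble::tibble(locus_id = c("j1", "j2"), pos_cM = c(0, 10))
#' b <- tibble::tibble(locus_id = c("j1", "j2"), pos_cM = c(0, 20))
#' combine_groups(a, b)  # anchors at 0 and 15
#' @export
combine_groups <- function(group_a, group_b, weights = c(1, 1),
                           on_conflict = c("error", "demote")) {
  on_conflict <- match.arg(on_conflict)
  stopifnot(all(c("locus_id", "pos_cM") %in% names(group_a)),
            all(c("locus_id", "pos_cM") %in% names(group_b)),
            length(weights) == 2, all(weights > 0))
  joining <- intersect(group_a$locus_id, group_b$locus_id)
  if (length(joining) < 2) {
    stop("cannot integrate: fewer than 2 joining loci", call. = FALSE)
  }
  a <- setNames(group_a$pos_cM, group_a$locus_id)
  b <- setNames(group_b$pos_cM, group_b$locus_id)
  ja <- a[joining]; jb <- b[joining]
  ord <- order(ja, jb)
  ja <- ja[ord]; jb <- jb[ord]; joining <- joining[ord]
  # orientation of a group is arbitrary: flip B if the anchors run backwards
  if (length(joining) >= 2 && stats::var(jb) > 0 && stats::var(ja) > 0 &&
      cor(ja, jb, method = "spearman") < 0) {
    b <- max(b) - b
    jb <- b[joining]
  }
  demoted <- character(0)
  conflicts <- which(diff(rank(jb)) < 0)
  if (length(conflicts)) {
    bad <- unique(c(joining[conflicts], joining[conflicts + 1]))
    if (on_conflict == "error") {
      stop("conflicting joining-locus order: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    keep <- longest_monotone_subset(jb)
    demoted <- joining[-keep]
    warning(length(demoted), " joining locus/loci demoted to interpolated ",
            "placement (order conflict): ",
            paste(head(demoted, 8), collapse = ", "), call. = FALSE)
    joining <- joining[keep]; ja <- ja[keep]; jb <- jb[keep]
    if (length(joining) < 2) {
      stop("cannot integrate: fewer than 2 order-consistent joining loci",
           call. = FALSE)
    }
  }
  w <- weights / sum(weights)
  cons <- w[1] * ja + w[2] * jb
  for (it in 1:10) {
    fa <- affine_fit(ja, cons)
    fb <- affine_fit(jb, cons)
    new_cons <- w[1] * fa(ja) + w[2] * fb(jb)
    if (max(abs(new_cons - cons)) < 1e-10) { cons <- new_cons; break }
    cons <- new_cons
  }
  slope_of <- function(x, y) {
    if (length(x) < 2 || stats::var(x) == 0) return(1)
    abs(stats::cov(x, y) / stats::var(x))
  }
  place <- function(pos, anchors_src, anchors_cons) {
    piecewise_map(pos, anchors_src, anchors_cons,
                  ext_slope = slope_of(anchors_src, anchors_cons))
  }
  a_only <- setdiff(group_a$locus_id, c(joining, demoted))
  b_only <- setdiff(group_b$locus_id, c(joining, demoted))
  w2 <- weights / sum(weights)
  out <- dplyr::bind_rows(
    tibble(locus_id = joining, pos_cM = unname(cons), provenance = "joining"),
    tibble(locus_id = a_only, pos_cM = place(unname(a[a_only]), ja, cons),
           provenance = "A only"),
    tibble(locus_id = b_only, pos_cM = place(unname(b[b_only]), jb, cons),
           provenance = "B only"),
    tibble(locus_id = demoted,
           pos_cM = w2[1] * place(unname(a[demoted]), ja, cons) +
             w2[2] * place(unname(b[demoted]), jb, cons),
           provenance = rep("joining", length(demoted)))
  )
  out <- dplyr::arrange(out, .data$pos_cM, .data$locus_id)
  out$pos_cM <- out$pos_cM - min(out$pos_cM)
  # canonical orientation
  if (out$locus_id[nrow(out)] < out$locus_id[1]) {
    out$pos_cM <- max(out$pos_cM) - out$pos_cM
    out <- dplyr::arrange(out, .data$pos_cM, .data$locus_id)
  }
  out
}

# indices of the longest non-decreasing subsequence (O(n^2), n small)
longest_monotone_subset <- function(x) {
  n <- length(x)
  len <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] <= x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  out <- integer(0)
  while (!is.na(i)) { out <- c(i, out); i <- prev[i] }
  out
}

affine_fit <- function(x, y) {
  if (length(x) < 2 || stats::var(x) == 0) {
    off <- mean(y) - mean(x)
    return(function(z) z + off)
  }
  beta <- stats::cov(x, y) / stats::var(x)
  alpha <- mean(y) - beta * mean(x)
  function(z) alpha + beta * z
}

# monotone piecewise-linear map through (anchors_src[i], anchors_cons[i]);
# beyond the terminal anchors the overall affine slope extrapolates
piecewise_map <- function(pos, anchors_src, anchors_cons, ext_slope = NULL) {
  if (length(pos) == 0) return(double(0))
  ord <- order(anchors_src)
  xs <- anchors_src[ord]; ys <- anchors_cons[ord]
  # collapse duplicate source anchors
  keep <- !duplicated(xs)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) == 1) return(pos - xs[1] + ys[1])
  if (is.null(ext_slope)) {
    ext_slope <- (ys[length(ys)] - ys[1]) / (xs[length(xs)] - xs[1])
  }
  if (!is.finite(ext_slope)) ext_slope <- 1
  rev_axis <- ys[1] > ys[length(ys)]
  slopes <- diff(ys) / diff(xs)
  vapply(pos, function(p) {
    if (p < xs[1]) {
      return(ys[1] + (p - xs[1]) * (if (rev_axis) -ext_slope else ext_slope))
    }
    if (p > xs[length(xs)]) {
      return(ys[length(ys)] + (p - xs[length(xs)]) *
               (if (rev_axis) -ext_slope else ext_slope))
    }
    i <- findInterval(p, xs, all.inside = TRUE)
    s <- slopes[i]
    if (!is.finite(s)) s <- 1
    ys[i] + (p - xs[i]) * s
  }, double(1))
}

#' Integrate two full maps over accepted homoeologue pairings
#'
#' Applies [combine_groups()] to every accepted pairing of linkage groups
#' between two populations' maps; unresolved pairings are skipped with a
#' warning and their source groups passed through unchanged.  Homoeoloci of
#' multi-locus markers are cross-referenced via `marker_id` when a lookup is
#' supplied, which is what connects homoeologous loci across the two groups
#' of a pair.
#'
#' Loci assayed in two populations usually carry population-specific
#' configuration suffixes, so cross-population anchors are matched by marker
#' identity: a joining marker with exactly one locus in each of the two
#' paired groups anchors them, and its merged row is reported under the
#' marker name.  Supply `lookup_a`/`lookup_b` to enable this; without them
#' anchors are matched by shared `locus_id` (appropriate when merging maps
#' that name loci identically, e.g. the two parents of one population).
#'
#' @param map_a,map_b Map tibbles (`locus_id`, `group`, `pos_cM`).
#' @param assignments Tibble from [assign_pairing()] /
#'   [pair_homoeologues()]: columns `group_a`, `group_b`, `status`.
#' @param weights Length-2 weights, typically the two population sizes.
#' @param lookup_a,lookup_b Optional tibbles `locus_id`, `marker_id` for the
#'   two maps, used to match joining loci across populations.
#' @param on_conflict Joining-locus order-conflict policy passed to
#'   [combine_groups()]; estimated maps default to `"demote"`.
#' @return An object of class `clover_map` whose `loci` carry `group`
#'   (`"IG1"`, ...), `pos_cM` and `provenance`.
#' @export
integrate_maps <- function(map_a, map_b, assignments,
                           weights = c(1, 1), lookup_a = NULL,
                           lookup_b = NULL, on_conflict = "demote") {
  out <- list(); gi <- 0L
  accepted <- assignments[assignments$status %in%
                            c("accepted", "accepted_single_slhs"), ,
                          drop = FALSE]
  unres <- assignments[!assignments$status %in%
                         c("accepted", "accepted_single_slhs"), ,
                       drop = FALSE]
  for (i in seq_len(nrow(accepted))) {
    gi <- gi + 1L
    ga <- map_a[map_a$group == accepted$group_a[i], c("locus_id", "pos_cM")]
    gb <- map_b[map_b$group == accepted$group_b[i], c("locus_id", "pos_cM")]
    if (!is.null(lookup_a) && !is.null(lookup_b)) {
      ga$locus_id <- anchor_names(ga$locus_id, gb$locus_id,
                                  lookup_a, lookup_b)
      gb$locus_id <- anchor_names(gb$locus_id, ga$locus_id,
                                  lookup_b, lookup_a)
    }
    cg <- tryCatch(
      combine_groups(ga, gb, weights, on_conflict = on_conflict),
      error = function(e) e
    )
    if (inherits(cg, "error")) {
      # too few usable anchors: emit the source groups side by side
      warning("pairing ", accepted$group_a[i], " / ", accepted$group_b[i],
              " not integrable (", conditionMessage(cg),
              "); groups emitted side by side", call. = FALSE)
      out[[gi]] <- tibble(locus_id = ga$locus_id,
                          pos_cM = ga$pos_cM - min(ga$pos_cM),
                          provenance = "A only",
                          group = paste0("IG", gi))
      gi <- gi + 1L
      out[[gi]] <- tibble(locus_id = gb$locus_id,
                          pos_cM = gb$pos_cM - min(gb$pos_cM),
                          provenance = "B only",
                          group = paste0("IG", gi))
    } else {
      out[[gi]] <- dplyr::mutate(cg, group = paste0("IG", gi))
    }
  }
  if (nrow(unres)) {
    warning(nrow(unres), " pairing(s) unresolved; source groups passed through",
            call. = FALSE)
    for (i in seq_len(nrow(unres))) {
      for (side in c("a", "b")) {
        g <- unres[[paste0("group_", side)]][i]
        mp <- if (side == "a") map_a else map_b
        sel <- mp[mp$group == g, , drop = FALSE]
        if (!nrow(sel)) next
        gi <- gi + 1L
        out[[gi]] <- tibble(locus_id = sel$locus_id,
                            pos_cM = sel$pos_cM - min(sel$pos_cM),
                            provenance = paste(toupper(side), "only"),
                            group = paste0("IG", gi))
      }
    }
  }
  loci <- dplyr::bind_rows(out) %>%
    dplyr::select("locus_id", "group", "pos_cM", "provenance")
  structure(list(loci = loci, assignments = assignments),
            class = "clover_map")
}

# rename loci that anchor this group pair to their marker id: a marker with
# exactly one locus on each side of the pair identifies one merged locus
anchor_names <- function(ids_self, ids_other, lookup_self, lookup_other) {
  mk_self <- lookup_self$marker_id[match(ids_self, lookup_self$locus_id)]
  # the other side may already be renamed to marker ids
  mk_other <- lookup_other$marker_id[match(ids_other, lookup_other$locus_id)]
  mk_other <- ifelse(is.na(mk_other), ids_other, mk_other)
  single_self <- names(which(table(mk_self) == 1))
  single_other <- names(which(table(mk_other) == 1))
  anchors <- intersect(single_self, single_other)
  ifelse(!is.na(mk_self) & mk_self %in% anchors, mk_self, ids_self)
}

#' Per-group map statistics
#'
#' The classic map-summary block: per linkage group the locus count `m`, the
#' observed length (largest position), the Method-4 expected length
#' `L_obs (m+1)/(m-1)`, and the marker density `L_obs / m`; plus totals,
#' means and standard errors over groups, genome coverage
#' (`total observed / total expected`), and overall density reported both as
#' the mean of per-group densities and as total length over total loci.
#'
#' @param map A `clover_map`, or a tibble with `locus_id`, `group`,
#'   `pos_cM`.
#' @return List with `groups` (tibble: `group`, `m`, `length_obs`,
#'   `length_est`, `density`), and `summary` (tibble of `statistic`,
#'   `value`).  Groups with fewer than 2 loci are excluded from the expected
#'   length (with a warning) but still counted in totals.
#' @export
map_statistics <- function(map) {
  loci <- if (inherits(map, "clover_map")) map$loci else map
  stopifnot(all(c("locus_id", "group", "pos_cM") %in% names(loci)))
  g <- loci %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(m = dplyr::n(),
                     length_obs = max(.data$pos_cM) - min(.data$pos_cM),
                     .groups = "drop")
  if (any(g$m < 2)) {
    warning(sum(g$m < 2), " group(s) with fewer than 2 loci excluded from ",
            "expected length", call. = FALSE)
  }
  g <- g %>%
    dplyr::mutate(
      length_est = ifelse(.data$m >= 2,
                          method4_expected(.data$length_obs, pmax(.data$m, 2)),
                          NA_real_),
      density = .data$length_obs / .data$m
    )
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  est_tot <- sum(g$length_est, na.rm = TRUE)
  cov <- if (est_tot > 0) {
    genome_coverage(sum(g$length_obs[g$m >= 2]), est_tot)
  } else {
    NA_real_
  }
  summary <- tibble(
    statistic = c("n_groups", "total_loci", "total_length_obs",
                  "total_length_est", "coverage",
                  "mean_loci", "sem_loci", "mean_length_obs",
                  "sem_length_obs", "mean_density", "sem_density",
                  "overall_density"),
    value = c(nrow(g), sum(g$m), sum(g$length_obs), est_tot, cov,
              mean(g$m), sem(g$m), mean(g$length_obs), sem(g$length_obs),
              mean(g$density), sem(g$density),
              sum(g$length_obs) / sum(g$m))
  )
  list(groups = g, summary = summary)
}

#' Per-group statistics from printed summary columns
#'
#' Convenience wrapper computing Method-4 expected lengths, density, totals
#' and coverage directly from per-group locus counts and observed lengths
#' (e.g. a published map-summary table).
#'
#' @param m Integer vector of per-group locus counts.
#' @param length_obs Numeric vector of per-group observed lengths, cM.
#' @return Tibble: `m`, `length_obs`, `length_est`, `density`, plus
#'   attributes-free totals available by summing.
#' @export
group_stats <- function(m, length_obs) {
  tibble(
    m = m, length_obs = length_obs,
    length_est = method4_expected(length_obs, m),
    density = length_obs / m
  )
}
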