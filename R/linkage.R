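#' Classify the segregation configuration of a locus
#'
#' Given the two parents' allele sizes at a co-dominant locus (null alleles
#' coded 0), derives the cross configuration and the expected observable
#' progeny classes by enumerating the four equally likely gamete unions and
#' collapsing unions that produce the same visible allele pattern (nulls are
#' invisible, so they collapse classes).
#'
#' Configurations follow the standard CP naming: `abxcd` (both parents
#' heterozygous, four alleles; `abxcd+null` when a null allele is involved),
#' `abxac` (three alleles), `abxab` (shared heterozygote, 1:2:1), `abxaa` /
#' `aaxab` (single-parent informative).  A locus whose four gamete unions are
#' observationally identical (e.g. both parents homozygous) is uninformative.
#'
#' @param p1,p2 Numeric length-2: maternal and paternal allele sizes (0 =
#'   null allele).
#' @return A list with `type` (character), `informative` (logical), and
#'   `classes`: a tibble of expected observable classes (`pattern` — visible
#'   sizes joined by `/`, `""` for no amplification — and `prob`).
#' @examples
#' classify_segregation(c(120, 124), c(128, 132))  # abxcd, 1:1:1:1
#' classify_segregation(c(120, 124), c(120, 128))  # abxac
#' @export
classify_segregation <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2)
  het1 <- p1[1] != p1[2]
  het2 <- p2[1] != p2[2]
  n_all <- length(unique(c(p1, p2)))
  any_null <- any(c(p1, p2) == 0)
  type <- if (!het1 && !het2) {
    "uninformative"
  } else if (het1 && het2) {
    if (n_all == 4) {
      if (any_null) "abxcd+null" else "abxcd"
    } else if (n_all == 3) "abxac" else "abxab"
  } else if (het1) "abxaa" else "aaxab"

  pat <- character(4)
  k <- 0L
  for (i in 1:2) {
    for (j in 1:2) {
      k <- k + 1L
      vis <- sort(c(p1[i], p2[j]))
      vis <- vis[vis > 0]
      pat[k] <- paste(vis, collapse = "/")
    }
  }
  classes <- tibble(pattern = pat) %>%
    dplyr::count(.data$pattern, name = "prob") %>%
    dplyr::mutate(prob = .data$prob / 4)
  informative <- nrow(classes) > 1 && type != "uninformative"
  if (!informative) type <- "uninformative"
  list(type = type, informative = informative, classes = classes)
}

#' Transmission matrix for one parent
#'
#' For every locus and progeny, infers which of the focal parent's two
#' alleles was transmitted, by matching the observed visible allele pattern
#' against the four enumerated gamete unions.  The inference is `NA` when the
#' call is missing or when both of the parent's alleles are compatible with
#' the observation (e.g. the heterozygous class of an ab×ab locus).  Allele
#' indices are relative to the parent's recorded allele order, not to linkage
#' phase — phase is resolved pair-by-pair in [estimate_rf()].
#'
#' @param pop A `clover_population` from [simulate_population()], or any list
#'   with `loci` (incl. `locus_id`, `p1_a1`..`p2_a2`) and `calls`
#'   (`locus_id`, `indiv`, `a1`, `a2`).
#' @param parent `"maternal"` (parent 1) or `"paternal"` (parent 2).
#' @return An `n_progeny x n_loci` integer matrix (values 1, 2, `NA`) with
#'   progeny ids as rownames and locus ids as colnames.
#' @export
transmission_matrix <- function(pop, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  loci <- pop$loci
  calls <- pop$calls
  inds <- sort(unique(calls$indiv))
  out <- matrix(NA_integer_, length(inds), nrow(loci),
                dimnames = list(inds, loci$locus_id))
  obs_pat <- ifelse(is.na(calls$a1), NA_character_,
                    ifelse(is.na(calls$a2), as.character(calls$a1),
                           paste(calls$a1, calls$a2, sep = "/")))
  for (li in seq_len(nrow(loci))) {
    if (parent == "maternal") {
      p <- c(loci$p1_a1[li], loci$p1_a2[li])
      q <- c(loci$p2_a1[li], loci$p2_a2[li])
    } else {
      p <- c(loci$p2_a1[li], loci$p2_a2[li])
      q <- c(loci$p1_a1[li], loci$p1_a2[li])
    }
    # pattern -> transmitted focal allele index (NA if ambiguous)
    pats <- character(4); idx <- integer(4)
    k <- 0L
    for (i in 1:2) {
      for (j in 1:2) {
        k <- k + 1L
        vis <- sort(c(p[i], q[j]))
        vis <- vis[vis > 0]
        pats[k] <- paste(vis, collapse = "/")
        idx[k] <- i
      }
    }
    lookup <- tapply(idx, pats, function(v) {
      u <- unique(v)
      if (length(u) == 1) u else NA_integer_
    })
    rows <- which(calls$locus_id == loci$locus_id[li])
    op <- obs_pat[rows]
    val <- rep(NA_integer_, length(rows))
    known <- !is.na(op) & op %in% names(lookup) & op != ""
    val[known] <- lookup[op[known]]
    out[cbind(match(calls$indiv[rows], inds),
              rep(li, length(rows)))] <- val
  }
  out
}

#' Two-point recombination fraction and LOD
#'
#' Maximum-likelihood two-point linkage estimate from the transmitted-allele
#' indicators of two loci in one parent's meioses.  With phase unknown, both
#' phase assignments are evaluated and the one with the higher likelihood is
#' kept (ties broken toward coupling); for fully informative ab×cd pairs this
#' reduces to recombinant counting.  With `n` informative meioses of which
#' `k` are recombinant, `r = k/n` and
#' `LOD = (n-k) log10(2(1-r)) + k log10(2r)` against independence (r = 0.5).
#'
#' @param ta,tb Integer vectors (values 1, 2, `NA`): transmitted-allele
#'   indices at the two loci for the same meioses (see
#'   [transmission_matrix()]).
#' @param min_informative Pairs with fewer shared informative meioses are
#'   flagged `low_confidence` (excluded from grouping by default).
#' @return One-row tibble: `n_informative`, `n_recombinant`, `r`, `lod`,
#'   `phase`, `low_confidence`.
#' @examples
#' ta <- rep(c(1L, 2L), each = 50)
#' tb <- ta; tb[1:5] <- 3L - tb[1:5]; tb[51:55] <- 3L - tb[51:55]
#' estimate_rf(ta, tb)  # r = 0.10, LOD = 15.98
#' @export
estimate_rf <- function(ta, tb, min_informative = 10) {
  ok <- !is.na(ta) & !is.na(tb)
  n <- sum(ok)
  if (n == 0) {
    return(tibble(n_informative = 0L, n_recombinant = NA_integer_,
                  r = NA_real_, lod = NA_real_, phase = NA_character_,
                  low_confidence = TRUE))
  }
  k <- sum(ta[ok] != tb[ok])
  phase <- if (k <= n - k) "coupling" else "repulsion"
  kk <- min(k, n - k)
  tibble(
    n_informative = n,
    n_recombinant = as.integer(kk),
    r = kk / n,
    lod = two_point_lod(n, kk),
    phase = phase,
    low_confidence = n < min_informative
  )
}

two_point_lod <- function(n, k) {
  r <- k / n
  term <- function(count, x) ifelse(count == 0, 0, count * log10(x))
  term(n - k, 2 * (1 - r)) + term(k, 2 * r)
}

#' All-pairs two-point linkage for one parent
#'
#' Vectorised two-point analysis over every locus pair of a transmission
#' matrix.  Loci with no informative meioses at all are dropped.
#'
#' @param tmat Matrix from [transmission_matrix()].
#' @inheritParams estimate_rf
#' @return Tibble: `locus_a`, `locus_b`, `n_informative`, `r`, `lod`,
#'   `low_confidence` (one row per unordered pair).
#' @export
pairwise_linkage <- function(tmat, min_informative = 10) {
  keep <- colSums(!is.na(tmat)) > 0
  tmat <- tmat[, keep, drop = FALSE]
  m <- ncol(tmat)
  if (m < 2) {
    return(tibble(locus_a = character(), locus_b = character(),
                  n_informative = integer(), r = double(), lod = double(),
                  low_confidence = logical()))
  }
  M <- (!is.na(tmat)) * 1
  X <- (!is.na(tmat) & tmat == 1L) * 1
  Y <- (!is.na(tmat) & tmat == 2L) * 1
  N <- crossprod(M)
  K <- crossprod(X, Y) + crossprod(Y, X)
  KK <- pmin(K, N - K)
  ut <- upper.tri(N)
  n <- N[ut]; k <- KK[ut]
  r <- ifelse(n > 0, k / n, NA_real_)
  lod <- ifelse(n > 0, two_point_lod(pmax(n, 1), k), NA_real_)
  ij <- which(ut, arr.ind = TRUE)
  tibble(
    locus_a = colnames(tmat)[ij[, 1]],
    locus_b = colnames(tmat)[ij[, 2]],
    n_informative = as.integer(n),
    r = r,
    lod = lod,
    low_confidence = n < min_informative
  )
}

#' Group loci at a LOD threshold
#'
#' Linkage groups are the connected components of the graph whose edges are
#' locus pairs with LOD at or above the threshold (default 8); low-confidence
#' pairs are excluded from the graph.
#'
#' @param pairwise Tibble from [pairwise_linkage()] (one or several parents'
#'   tables row-bound together).
#' @param loci Character vector of the locus universe (singletons are
#'   reported too); defaults to the loci present in `pairwise`.
#' @param lod Grouping threshold.
#' @param drop_low_confidence Exclude flagged pairs from the graph.
#' @return Tibble `locus_id`, `group_est` (`"LG1"`, ... numbered by
#'   decreasing group size).
#' @export
group_loci <- function(pairwise, loci = NULL, lod = 8,
                       drop_low_confidence = TRUE) {
  if (is.null(loci)) {
    loci <- sort(unique(c(pairwise$locus_a, pairwise$locus_b)))
  }
  lod_threshold <- lod
  edges <- pairwise %>%
    dplyr::filter(!is.na(.data$lod), .data$lod >= lod_threshold,
                  !(drop_low_confidence & .data$low_confidence))
  g <- igraph::graph_from_data_frame(
    edges[, c("locus_a", "locus_b")], directed = FALSE,
    vertices = data.frame(name = loci)
  )
  comp <- igraph::components(g)
  ord <- order(-comp$csize, seq_along(comp$csize))
  relabel <- match(seq_along(comp$csize), ord)
  tibble(
    locus_id = names(comp$membership),
    group_est = paste0("LG", relabel[comp$membership])
  )
}

#' Order the loci of one linkage group
#'
#' Heuristic seriation: the pair with the highest LOD seeds the order; each
#' remaining locus (taken in order of total LOD connectivity to the placed
#' set) is inserted at the slot minimising the LOD-weighted squared error
#' between its pairwise Kosambi distances and the path distances implied by
#' the candidate order.  The order is then polished by adjacent swaps until
#' locally optimal, positions are the cumulative adjacent Kosambi distances,
#' and orientation is canonicalised by placing the lexicographically smaller
#' terminal locus first.
#'
#' Internally the seriation cost uses Haldane distances, which are additive
#' under a no-interference crossover model, with weights zeroed below a
#' minimum LOD and recombination capped just below 0.5 so that noisy
#' distant pairs cannot outvote local structure; the reported cumulative
#' positions are Kosambi, the field's reporting convention (the two agree
#' closely at the adjacent distances that define positions).
#'
#' @param locus_ids Loci of one group.
#' @param pairwise Two-point table covering these loci.
#' @param max_sweeps Cap on adjacent-swap polish sweeps.
#' @param min_lod_order Pairs below this LOD carry no weight in the
#'   seriation cost.
#' @return Tibble `locus_id`, `pos_cM` in map order.
#' @export
order_group <- function(locus_ids, pairwise, max_sweeps = 20,
                        min_lod_order = 3) {
  m <- length(locus_ids)
  if (m == 1) return(tibble(locus_id = locus_ids, pos_cM = 0))
  mats <- pair_matrices(locus_ids, pairwise, min_lod_order)
  D <- mats$D; W <- mats$W
  if (m == 2) {
    ord <- locus_ids
  } else {
    candidates <- list(greedy_order(D, W))
    mds <- mds_order(D)
    if (!is.null(mds)) candidates <- c(candidates, list(mds))
    candidates <- lapply(candidates, polish_order, D = D, W = W,
                         max_sweeps = max_sweeps)
    costs <- vapply(candidates, order_cost, 0, D = D, W = W)
    ord_i <- candidates[[which.min(costs)]]
    ord <- locus_ids[ord_i]
  }
  if (ord[length(ord)] < ord[1]) ord <- rev(ord)
  ord_i <- match(ord, locus_ids)
  pos <- path_positions(ord_i, mats$Dpos)
  tibble(locus_id = ord, pos_cM = pos)
}

haldane_d <- function(r) -50 * log(1 - 2 * r)

# greedy seriation: seed with the strongest pair, insert each next locus
# (by LOD connectivity) at the slot minimising the weighted cost
greedy_order <- function(D, W) {
  m <- nrow(D)
  seed <- which(W == max(W, na.rm = TRUE), arr.ind = TRUE)[1, ]
  ord_i <- as.integer(seed)
  rest <- setdiff(seq_len(m), ord_i)
  while (length(rest)) {
    conn <- vapply(rest, function(i) sum(W[i, ord_i], na.rm = TRUE), 0)
    if (max(conn) == 0) {
      stop("ordering evidence is disconnected within this group",
           call. = FALSE)
    }
    nxt <- rest[which.max(conn)]
    best_cost <- Inf; best_slot <- 0L
    for (slot in 0:length(ord_i)) {
      cand <- append(ord_i, nxt, after = slot)
      cost <- order_cost(cand, D, W)
      if (cost < best_cost - 1e-9) { best_cost <- cost; best_slot <- slot }
    }
    ord_i <- append(ord_i, nxt, after = best_slot)
    rest <- setdiff(rest, nxt)
  }
  ord_i
}

# alternative global seriation: order along the first principal coordinate
# of the (capped) distance matrix; robust to locally weak linkage evidence
mds_order <- function(D) {
  Dc <- pmin(D, 80)
  if (any(!is.finite(Dc))) return(NULL)
  pc <- tryCatch(stats::cmdscale(stats::as.dist(Dc), k = 1),
                 error = function(e) NULL)
  if (is.null(pc)) return(NULL)
  order(pc[, 1])
}

# local search: adjacent swaps, single-locus relocation and segment
# reversal (ripple), repeated until no move improves the weighted cost.
# Segment reversal is what rescues a weakly linked chromosome arm whose
# internal order is right but whose orientation flipped.
polish_order <- function(ord_i, D, W, max_sweeps = 20) {
  best <- order_cost(ord_i, D, W)
  m <- length(ord_i)
  for (s in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(m - 1)) {
      cand <- ord_i
      cand[c(i, i + 1)] <- cand[c(i + 1, i)]
      cost <- order_cost(cand, D, W)
      if (cost < best - 1e-12) {
        ord_i <- cand; best <- cost; improved <- TRUE
      }
    }
    for (i in seq_len(m)) {
      for (slot in 0:(m - 1)) {
        if (slot == i - 1 || slot == i) next
        cand <- append(ord_i[-i], ord_i[i],
                       after = if (slot > i - 1) slot - 1 else slot)
        cost <- order_cost(cand, D, W)
        if (cost < best - 1e-12) {
          ord_i <- cand; best <- cost; improved <- TRUE
          break
        }
      }
    }
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        cand <- ord_i
        cand[i:j] <- rev(cand[i:j])
        cost <- order_cost(cand, D, W)
        if (cost < best - 1e-12) {
          ord_i <- cand; best <- cost; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord_i
}

pair_matrices <- function(locus_ids, pairwise, min_lod_order = 3) {
  m <- length(locus_ids)
  D <- matrix(NA_real_, m, m); W <- matrix(0, m, m)
  Dpos <- matrix(NA_real_, m, m)
  pw <- pairwise %>%
    dplyr::filter(.data$locus_a %in% locus_ids, .data$locus_b %in% locus_ids,
                  !is.na(.data$r))
  ia <- match(pw$locus_a, locus_ids); ib <- match(pw$locus_b, locus_ids)
  d <- haldane_d(pmin(pw$r, 0.45))
  D[cbind(ia, ib)] <- d; D[cbind(ib, ia)] <- d
  dk <- kosambi_d(pmin(pw$r, 0.4999))
  Dpos[cbind(ia, ib)] <- dk; Dpos[cbind(ib, ia)] <- dk
  w <- pmax(pw$lod, 0)
  w[w < min_lod_order] <- 0
  W[cbind(ia, ib)] <- w; W[cbind(ib, ia)] <- w
  # complete missing distances along the best available path
  if (any(is.na(D[upper.tri(D)]))) {
    ed <- which(!is.na(D) & upper.tri(D), arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed[, 1], to = ed[, 2], weight = D[ed]),
      directed = FALSE, vertices = data.frame(name = seq_len(m))
    )
    sp <- igraph::distances(g)
    sp <- sp[order(as.integer(rownames(sp))), order(as.integer(colnames(sp)))]
    D[is.na(D)] <- sp[is.na(D)]
  }
  diag(D) <- 0
  Dpos[is.na(Dpos)] <- D[is.na(Dpos)]
  diag(Dpos) <- 0
  list(D = D, W = W, Dpos = Dpos)
}

path_positions <- function(ord_i, D) {
  adj <- D[cbind(ord_i[-length(ord_i)], ord_i[-1])]
  cumsum(c(0, adj))
}

# LOD-weighted squared error between pairwise distances and path distances,
# over the loci present in the candidate order
order_cost <- function(ord_i, D, W) {
  pos <- path_positions(ord_i, D)
  Dsub <- D[ord_i, ord_i, drop = FALSE]
  Wsub <- W[ord_i, ord_i, drop = FALSE]
  E <- abs(outer(pos, pos, "-"))
  sum(Wsub * (Dsub - E)^2, na.rm = TRUE) / 2
}

#' Single-parent map for one population
#'
#' Runs the two-point pipeline for one parent: transmission inference,
#' all-pairs linkage, LOD grouping, and per-group ordering.
#'
#' @param pop A `clover_population`.
#' @inheritParams transmission_matrix
#' @inheritParams group_loci
#' @inheritParams estimate_rf
#' @return List with `map` (tibble `locus_id`, `group`, `pos_cM`; singleton
#'   groups dropped), `pairwise`, and `tmat`.
#' @export
build_parent_map <- function(pop, parent = c("maternal", "paternal"),
                             lod = 8, min_informative = 10) {
  parent <- match.arg(parent)
  tmat <- transmission_matrix(pop, parent)
  informative <- colSums(!is.na(tmat)) > 0
  tmat <- tmat[, informative, drop = FALSE]
  pw <- pairwise_linkage(tmat, min_informative)
  grp <- group_loci(pw, loci = colnames(tmat), lod = lod)
  maps <- grp %>%
    dplyr::group_by(.data$group_est) %>%
    dplyr::filter(dplyr::n() >= 2) %>%
    dplyr::group_map(function(d, key) {
      order_group(d$locus_id, pw) %>%
        dplyr::mutate(group = key$group_est[1])
    }) %>%
    dplyr::bind_rows()
  if (nrow(maps) == 0) {
    maps <- tibble(locus_id = character(), pos_cM = double(),
                   group = character())
  }
  list(map = dplyr::select(maps, "locus_id", "group", "pos_cM"),
       pairwise = pw, tmat = tmat)
}

#' Bi-parental consensus map for one population
#'
#' Estimates the maternal and paternal single-parent maps, matches their
#' linkage groups through bridge loci (loci segregating through both parents
#' and hence mapped in both), and merges each matched pair of groups with
#' [combine_groups()] at equal weight.  Groups with fewer than two bridge
#' loci are passed through unmerged with a warning.
#'
#' @param pop A `clover_population`.
#' @inheritParams build_parent_map
#' @return An object of class `clover_map`: list with `loci` (tibble
#'   `locus_id`, `group`, `pos_cM`, `provenance`), `population`, and the two
#'   single-parent fits.
#' @export
build_linkage_map <- function(pop, lod = 8, min_informative = 10) {
  mm <- build_parent_map(pop, "maternal", lod, min_informative)
  pm <- build_parent_map(pop, "paternal", lod, min_informative)
  merged <- merge_group_sets(mm$map, pm$map, weights = c(1, 1),
                             label_prefix = "LG")
  structure(list(
    loci = merged$map,
    unmerged = merged$unmerged,
    population = pop$population,
    maternal = mm, paternal = pm
  ), class = "clover_map")
}

# Merge two maps' groups via shared (bridge) loci.  Works agglomeratively:
# starting from all groups of both maps, any two groups sharing at least two
# bridge loci are combined (largest bridge count first), and merging repeats
# so that a group split in one parent can be reunited through the other.
# Returns $map (locus_id, group, pos_cM, provenance) and $unmerged (groups
# that never found a partner).
merge_group_sets <- function(map_a, map_b, weights, label_prefix = "LG") {
  sets <- c(
    lapply(split(map_a, map_a$group), function(d) {
      tibble(locus_id = d$locus_id, pos_cM = d$pos_cM, provenance = "A only")
    }),
    lapply(split(map_b, map_b$group), function(d) {
      tibble(locus_id = d$locus_id, pos_cM = d$pos_cM, provenance = "B only")
    })
  )
  names(sets) <- NULL
  merged_any <- rep(FALSE, length(sets))
  repeat {
    best <- NULL; best_n <- 1L
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (j <= i) next
        n_shared <- length(intersect(sets[[i]]$locus_id,
                                     sets[[j]]$locus_id))
        if (n_shared > best_n) { best <- c(i, j); best_n <- n_shared }
      }
    }
    if (is.null(best)) break
    cg <- combine_groups(sets[[best[1]]][, c("locus_id", "pos_cM")],
                         sets[[best[2]]][, c("locus_id", "pos_cM")],
                         weights = weights, on_conflict = "demote")
    prov_a <- setNames(sets[[best[1]]]$provenance, sets[[best[1]]]$locus_id)
    prov_b <- setNames(sets[[best[2]]]$provenance, sets[[best[2]]]$locus_id)
    cg$provenance <- ifelse(
      cg$locus_id %in% names(prov_a) & cg$locus_id %in% names(prov_b),
      "joining",
      ifelse(cg$locus_id %in% names(prov_a),
             unname(prov_a[cg$locus_id]), unname(prov_b[cg$locus_id]))
    )
    sets[[best[1]]] <- cg
    merged_any[best[1]] <- TRUE
    sets <- sets[-best[2]]
    merged_any <- merged_any[-best[2]]
  }
  ord <- order(-vapply(sets, nrow, 0L))
  sets <- sets[ord]; merged_any <- merged_any[ord]
  # a locus bridging two sets that never merged (single shared locus) would
  # otherwise appear twice: keep it in the largest set only
  seen <- character(0)
  for (i in seq_along(sets)) {
    keep <- !sets[[i]]$locus_id %in% seen
    sets[[i]] <- sets[[i]][keep, , drop = FALSE]
    seen <- c(seen, sets[[i]]$locus_id)
  }
  nonempty <- vapply(sets, nrow, 0L) > 0
  sets <- sets[nonempty]; merged_any <- merged_any[nonempty]
  if (any(!merged_any)) {
    warning(sum(!merged_any),
            " group(s) had no usable bridge loci and were passed through",
            call. = FALSE)
  }
  out <- purrr::imap(sets, function(d, i) {
    d$pos_cM <- d$pos_cM - min(d$pos_cM)
    d$group <- paste0(label_prefix, i)
    d
  })
  map <- dplyr::bind_rows(out) %>%
    dplyr::select("locus_id", "group", "pos_cM", "provenance")
  list(map = map,
       unmerged = paste0(label_prefix, which(!merged_any)))
}

#' Bi-parental consensus from two single-parent maps
#'
#' Joining-locus merge of a maternal and a paternal map (the same algorithm
#' as inter-population integration, with the two parents playing the role of
#' the two populations).  Bridge loci are loci present in both maps.
#'
#' @param maternal,paternal Map tibbles (`locus_id`, `group`, `pos_cM`).
#' @param weights Relative weights of the two maps.
#' @return List with `map` and `unmerged` as in [build_linkage_map()].
#' @export
build_parental_consensus <- function(maternal, paternal, weights = c(1, 1)) {
  merge_group_sets(maternal, paternal, weights)
}

#' @export
print.clover_map <- function(x, ...) {
  cat("<clover_map>", nrow(x$loci), "loci in",
      length(unique(x$loci$group)), "groups\n")
  invisible(x)
}
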