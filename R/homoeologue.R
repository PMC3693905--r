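#' Designate single-locus homoeologue-specific (SL-HS) markers
#'
#' A marker showing single-locus segregation is designated SL-HS when it
#' amplifies a maximum of two alleles per individual across the whole
#' diversity panel — an individual with three or more alleles betrays a
#' second (homoeologous or paralogous) locus.  A marker with no amplification
#' in a panel individual contributes zero alleles for that individual.
#'
#' @param panel Long tibble of panel genotypes: `marker_id`, `indiv`,
#'   `allele` (one row per distinct visible allele size); see
#'   [build_panel()].
#' @param markers Optional character vector restricting the markers tested;
#'   defaults to all markers in the panel.
#' @return Tibble: `marker_id`, `max_alleles`, `slhs` (logical).
#' @export
designate_slhs <- function(panel, markers = NULL) {
  if (nrow(panel) == 0 || length(unique(panel$indiv)) == 0) {
    stop("insufficient evidence: empty diversity panel", call. = FALSE)
  }
  if (is.null(markers)) markers <- unique(panel$marker_id)
  counts <- panel %>%
    dplyr::filter(.data$marker_id %in% markers) %>%
    dplyr::distinct(.data$marker_id, .data$indiv, .data$allele) %>%
    dplyr::count(.data$marker_id, .data$indiv) %>%
    dplyr::group_by(.data$marker_id) %>%
    dplyr::summarise(max_alleles = max(.data$n), .groups = "drop")
  tibble(marker_id = markers) %>%
    dplyr::left_join(counts, by = "marker_id") %>%
    dplyr::mutate(max_alleles = dplyr::coalesce(.data$max_alleles, 0L),
                  slhs = .data$max_alleles <= 2L)
}

#' Allele-size evidence for a candidate homoeologue pairing
#'
#' Classifies one joining locus's allele sizes in the two populations
#' against the marker's two homoeolocus size ranges.  If the two ranges
#' overlap they cannot discriminate homoeologues and the locus is
#' `ambiguous`; otherwise the locus is a `match` when both populations'
#' alleles fall in the same range, a `mismatch` when they fall in different
#' ranges, and `ambiguous` when either population's alleles fall in both or
#' neither range (or when sizes are missing, with a warning).
#'
#' @param sizes_a,sizes_b Numeric vectors of observed allele sizes for the
#'   locus in populations A and B.
#' @param range_paired Length-2 numeric, the size range of the homoeolocus
#'   implied by the candidate pairing.
#' @param range_alternative Length-2 numeric, the other homoeolocus's range.
#' @return `"match"`, `"mismatch"` or `"ambiguous"`.
#' @examples
#' allele_size_evidence(c(120, 126), c(122, 124), c(118, 128), c(150, 160))
#' @export
allele_size_evidence <- function(sizes_a, sizes_b,
                                 range_paired, range_alternative) {
  if (length(sizes_a) == 0 || length(sizes_b) == 0 ||
      anyNA(sizes_a) || anyNA(sizes_b)) {
    warning("missing allele sizes; evidence classed ambiguous", call. = FALSE)
    return("ambiguous")
  }
  if (ranges_overlap(range_paired, range_alternative)) return("ambiguous")
  side <- function(sizes) {
    in_p <- all(sizes >= range_paired[1] & sizes <= range_paired[2])
    in_a <- all(sizes >= range_alternative[1] & sizes <= range_alternative[2])
    if (in_p && !in_a) "paired" else if (in_a && !in_p) "alt" else "neither"
  }
  sa <- side(sizes_a); sb <- side(sizes_b)
  if (sa == "neither" || sb == "neither") return("ambiguous")
  if (sa == sb) "match" else "mismatch"
}

ranges_overlap <- function(r1, r2) {
  max(r1[1], r2[1]) <= min(r1[2], r2[2])
}

#' Decide a homoeologue pairing from joining-locus evidence
#'
#' Chooses between the two possible pairings of a homoeologous group pair
#' across two populations.  SL-HS evidence takes precedence: joining SL-HS
#' markers mapping to a single homoeologue in both populations directly
#' nominate a pairing, and any internal SL-HS conflict (markers nominating
#' both pairings) leaves the pair `unresolved`.  Otherwise the pairing
#' maximising `size matches - size mismatches` is taken; a tie with no SL-HS
#' support, a contradiction between the SL-HS and net allele-size verdicts,
#' or a complete absence of joining loci is `unresolved`.  An accepted
#' pairing resting on exactly one SL-HS locus is flagged
#' `accepted_single_slhs`.  Matching one inter-population pair fixes the
#' sister groups' pairing by elimination, so the decision is made once per
#' homoeologous pair.
#'
#' @param evidence Tibble with one row per joining-locus evidence item:
#'   `locus_id`, `kind` (`"slhs"` or `"size"`), and `class` — the evidence
#'   class (`"match"`, `"mismatch"`, `"ambiguous"`) evaluated against
#'   pairing 1 (`group_a1` with `group_b1`).
#' @param group_a1,group_a2,group_b1,group_b2 Group labels of the candidate
#'   quadruple.
#' @return Tibble with two rows (one per A group) and columns `group_a`,
#'   `group_b`, `slhs_support`, `slhs_conflicts`, `size_matches`,
#'   `size_mismatches`, `size_ambiguous`, `status` (`accepted`,
#'   `accepted_single_slhs`, `unresolved`).
#' @export
assign_pairing <- function(evidence, group_a1 = "A1", group_a2 = "A2",
                           group_b1 = "B1", group_b2 = "B2") {
  stopifnot(all(c("kind", "class") %in% names(evidence)))
  s1 <- sum(evidence$kind == "slhs" & evidence$class == "match")
  s2 <- sum(evidence$kind == "slhs" & evidence$class == "mismatch")
  m1 <- sum(evidence$kind == "size" & evidence$class == "match")
  mm1 <- sum(evidence$kind == "size" & evidence$class == "mismatch")
  amb <- sum(evidence$class == "ambiguous")
  net <- m1 - mm1

  chosen <- NA_integer_
  status <- "unresolved"
  if (nrow(evidence) == 0) {
    status <- "unresolved"
  } else if (s1 > 0 && s2 > 0) {
    status <- "unresolved"                      # SL-HS internal conflict
  } else if (s1 > 0 || s2 > 0) {
    cand <- if (s1 > 0) 1L else 2L
    signed_net <- if (cand == 1L) net else -net
    if (signed_net < 0) {
      status <- "unresolved"                    # SL-HS vs allele-size conflict
    } else {
      chosen <- cand
      status <- if (max(s1, s2) == 1L) "accepted_single_slhs" else "accepted"
    }
  } else if (net != 0) {
    chosen <- if (net > 0) 1L else 2L
    status <- "accepted"
  }

  if (is.na(chosen)) chosen <- 1L  # report counts in pairing-1 orientation
  sup <- if (status == "unresolved") {
    list(s = c(s1, s2), m = m1, mm = mm1)
  } else if (chosen == 1L) {
    list(s = c(s1, s2), m = m1, mm = mm1)
  } else {
    list(s = c(s2, s1), m = mm1, mm = m1)
  }
  gb <- if (chosen == 1L) c(group_b1, group_b2) else c(group_b2, group_b1)
  tibble(
    group_a = c(group_a1, group_a2),
    group_b = gb,
    slhs_support = sup$s[1],
    slhs_conflicts = sup$s[2],
    size_matches = sup$m,
    size_mismatches = sup$mm,
    size_ambiguous = amb,
    status = status
  )
}

#' Match homoeologues between two mapped populations
#'
#' Full inter-population homoeologue matching: identifies joining markers
#' (mapped in both populations), designates SL-HS markers from the diversity
#' panel, reconstructs homoeologous group pairs within each population from
#' dual-locus markers, evaluates both candidate pairings for every pair with
#' SL-HS and allele-size evidence, and decides each with [assign_pairing()].
#'
#' Allele-size evidence uses each homoeolocus's observed size range
#' (`[min, max]` of the parental alleles per population): a dual joining
#' marker supports the pairing under which same-homoeolocus ranges from the
#' two populations unite into disjoint hulls, contradicts it when only the
#' alternative pairing does, and is ambiguous when both or neither do.
#'
#' @param map_a,map_b Map tibbles (`locus_id`, `group`, `pos_cM`).
#' @param loci_a,loci_b Locus truth/annotation tibbles carrying `locus_id`,
#'   `marker_id` and parental allele columns (`p1_a1`..`p2_a2`), as in
#'   `clover_population$loci`.
#' @param panel Diversity-panel genotypes (see [build_panel()]).
#' @param max_anchor_spacing Warn when a group's joining-locus density is
#'   sparser than this many cM per joining locus (default 50).
#' @return Tibble of per-group assignments as returned by [assign_pairing()],
#'   plus `pair_id` and the evidence available via `attr(x, "evidence")`.
#' @export
pair_homoeologues <- function(map_a, map_b, loci_a, loci_b, panel,
                              max_anchor_spacing = 50) {
  ann_a <- annotate_map(map_a, loci_a)
  ann_b <- annotate_map(map_b, loci_b)
  joining <- intersect(unique(ann_a$marker_id), unique(ann_b$marker_id))
  single_a <- marker_locus_count(ann_a)
  single_b <- marker_locus_count(ann_b)
  slhs_tbl <- designate_slhs(panel, markers = joining)
  slhs_markers <- joining[
    single_a[joining] == 1 & single_b[joining] == 1 &
      slhs_tbl$slhs[match(joining, slhs_tbl$marker_id)]
  ]
  dual_markers <- joining[single_a[joining] == 2 & single_b[joining] == 2]

  pairs_a <- homoeologous_pairs(ann_a)
  out <- list(); evid_all <- list()
  for (pi in seq_len(nrow(pairs_a))) {
    ga1 <- pairs_a$g1[pi]; ga2 <- pairs_a$g2[pi]
    # candidate B groups: where this pair's joining markers land
    mk <- unique(ann_a$marker_id[ann_a$group %in% c(ga1, ga2) &
                                   ann_a$marker_id %in% joining])
    gb <- unique(ann_b$group[ann_b$marker_id %in% mk])
    if (length(gb) != 2) next
    gb1 <- gb[1]; gb2 <- gb[2]
    ev <- build_pair_evidence(ann_a, ann_b, ga1, ga2, gb1, gb2,
                              slhs_markers, dual_markers)
    res <- assign_pairing(ev, ga1, ga2, gb1, gb2) %>%
      dplyr::mutate(pair_id = pi)
    out[[length(out) + 1L]] <- res
    evid_all[[length(evid_all) + 1L]] <- dplyr::mutate(ev, pair_id = pi)
  }
  res <- dplyr::bind_rows(out)
  check_anchor_density(map_a, ann_a, joining, max_anchor_spacing)
  attr(res, "evidence") <- dplyr::bind_rows(evid_all)
  res
}

annotate_map <- function(map, loci) {
  dplyr::inner_join(
    map,
    loci[, c("locus_id", "marker_id", "p1_a1", "p1_a2", "p2_a1", "p2_a2")],
    by = "locus_id"
  )
}

marker_locus_count <- function(ann) {
  tab <- table(unique(ann[, c("marker_id", "locus_id")])$marker_id)
  setNames(as.integer(tab), names(tab))
}

# homoeologous group pairs within one map, linked by dual-locus markers;
# at least two independent dual markers must support a pair, which keeps
# small unmerged fragments from masquerading as homoeologues
homoeologous_pairs <- function(ann, min_links = 2) {
  dual <- ann %>%
    dplyr::group_by(.data$marker_id) %>%
    dplyr::filter(dplyr::n_distinct(.data$group) == 2) %>%
    dplyr::summarise(g1 = min(.data$group), g2 = max(.data$group),
                     .groups = "drop") %>%
    dplyr::count(.data$g1, .data$g2) %>%
    dplyr::filter(.data$n >= min_links) %>%
    dplyr::arrange(-.data$n)
  used <- character(); keep <- logical(nrow(dual))
  for (i in seq_len(nrow(dual))) {
    if (dual$g1[i] %in% used || dual$g2[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, dual$g1[i], dual$g2[i])
  }
  dual[keep, c("g1", "g2")]
}

locus_sizes <- function(ann, locus) {
  row <- ann[ann$locus_id == locus, ][1, ]
  s <- c(row$p1_a1, row$p1_a2, row$p2_a1, row$p2_a2)
  s[!is.na(s) & s > 0]
}

build_pair_evidence <- function(ann_a, ann_b, ga1, ga2, gb1, gb2,
                                slhs_markers, dual_markers) {
  rows <- list()
  in_groups <- function(ann, groups) ann[ann$group %in% groups, , drop = FALSE]
  aa <- in_groups(ann_a, c(ga1, ga2)); bb <- in_groups(ann_b, c(gb1, gb2))
  for (m in intersect(slhs_markers, intersect(aa$marker_id, bb$marker_id))) {
    g_in_a <- aa$group[aa$marker_id == m][1]
    g_in_b <- bb$group[bb$marker_id == m][1]
    consistent <- (g_in_a == ga1 && g_in_b == gb1) ||
      (g_in_a == ga2 && g_in_b == gb2)
    rows[[length(rows) + 1L]] <- tibble(
      locus_id = aa$locus_id[aa$marker_id == m][1], kind = "slhs",
      class = if (consistent) "match" else "mismatch",
      group_a = g_in_a
    )
  }
  for (m in intersect(dual_markers, intersect(aa$marker_id, bb$marker_id))) {
    ra1 <- size_hull(aa, m, ga1); ra2 <- size_hull(aa, m, ga2)
    rb1 <- size_hull(bb, m, gb1); rb2 <- size_hull(bb, m, gb2)
    if (anyNA(c(ra1, ra2, rb1, rb2))) next
    p1_ok <- !ranges_overlap(range_hull(ra1, rb1), range_hull(ra2, rb2))
    p2_ok <- !ranges_overlap(range_hull(ra1, rb2), range_hull(ra2, rb1))
    cls <- if (p1_ok && !p2_ok) "match" else
      if (p2_ok && !p1_ok) "mismatch" else "ambiguous"
    # a dual marker anchors a locus in each group of the pair
    for (g in c(ga1, ga2)) {
      rows[[length(rows) + 1L]] <- tibble(
        locus_id = aa$locus_id[aa$marker_id == m & aa$group == g][1],
        kind = "size", class = cls, group_a = g
      )
    }
  }
  if (!length(rows)) {
    return(tibble(locus_id = character(), kind = character(),
                  class = character(), group_a = character()))
  }
  dplyr::bind_rows(rows)
}

size_hull <- function(ann, marker, group) {
  sel <- ann[ann$marker_id == marker & ann$group == group, , drop = FALSE]
  if (!nrow(sel)) return(c(NA_real_, NA_real_))
  s <- c(sel$p1_a1, sel$p1_a2, sel$p2_a1, sel$p2_a2)
  s <- s[!is.na(s) & s > 0]
  if (!length(s)) return(c(NA_real_, NA_real_))
  range(s)
}

range_hull <- function(r1, r2) c(min(r1[1], r2[1]), max(r1[2], r2[2]))

check_anchor_density <- function(map_a, ann_a, joining, max_anchor_spacing) {
  dens <- ann_a %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      len = max(.data$pos_cM),
      n_join = sum(unique(.data$marker_id) %in% joining),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_join == 0 | .data$len / pmax(.data$n_join, 1) >
                    max_anchor_spacing)
  if (nrow(dens)) {
    warning("joining-locus density sparser than ", max_anchor_spacing,
            " cM per locus in group(s): ",
            paste(dens$group, collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

#' Per-group homoeologue-matching support table
#'
#' Reshapes a set of pairing assignments into the classic support table: one
#' row per linkage group with counts of SL-HS joining loci in agreement or
#' at variance with the accepted pairing and of allele-size matches,
#' mismatches and ambiguous loci.
#'
#' @param assignments Output of [pair_homoeologues()] (needs the attached
#'   evidence) or any tibble already shaped like the support table.
#' @return Tibble: `group`, `slhs_match`, `slhs_mismatch`, `size_match`,
#'   `size_mismatch`, `size_ambiguous`.
#' @export
support_table <- function(assignments) {
  if (all(c("slhs_match", "size_match") %in% names(assignments))) {
    return(assignments)
  }
  ev <- attr(assignments, "evidence")
  if (is.null(ev) || nrow(ev) == 0) {
    return(tibble(group = character(), slhs_match = integer(),
                  slhs_mismatch = integer(), size_match = integer(),
                  size_mismatch = integer(), size_ambiguous = integer()))
  }
  ev %>%
    dplyr::group_by(group = .data$group_a) %>%
    dplyr::summarise(
      slhs_match = sum(.data$kind == "slhs" & .data$class == "match"),
      slhs_mismatch = sum(.data$kind == "slhs" & .data$class == "mismatch"),
      size_match = sum(.data$kind == "size" & .data$class == "match"),
      size_mismatch = sum(.data$kind == "size" & .data$class == "mismatch"),
      size_ambiguous = sum(.data$kind == "size" & .data$class == "ambiguous"),
      .groups = "drop"
    )
}

#' Summary statistics of a homoeologue-matching support table
#'
#' @param tbl A support table (see [support_table()] or
#'   [clover_integration_support()]).
#' @return Tibble with `mean_joining_loci` (mean count of joining loci per
#'   group over all five evidence classes) and `n_multi_slhs` (groups whose
#'   pairing is supported by at least two SL-HS loci).
#' @export
support_summary <- function(tbl) {
  totals <- tbl$slhs_match + tbl$slhs_mismatch + tbl$size_match +
    tbl$size_mismatch + tbl$size_ambiguous
  tibble(
    n_groups = nrow(tbl),
    mean_joining_loci = mean(totals),
    n_multi_slhs = sum(tbl$slhs_match >= 2)
  )
}
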