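#' Configuration for the synthetic allotetraploid cross
#'
#' Builds and validates the parameter set for the synthetic white-clover-like
#' mapping experiment: a strict allotetraploid (2n = 4x = 32, eight
#' homoeologous chromosome pairs, disomic inheritance) genotyped with SSR-like
#' co-dominant markers in two unrelated double pseudo-testcross F1
#' populations that share a subset of joining markers, plus a small diversity
#' panel.
#'
#' Markers amplify one homoeolocus, or (with probability
#' `dual_homoeolocus_probability`) both homoeoloci of a pair at homologous
#' positions.  Each homoeolocus owns an allele-size range: the second
#' homoeologue's range is shifted by `homoeologue_size_offset` bp, so ranges
#' are disjoint when the offset exceeds `allele_size_spread` and deliberately
#' overlapping otherwise.  Null (non-amplifying) alleles arise per parental
#' allele with probability `null_allele_probability`; whole genotype calls go
#' missing at `missing_data_rate`.  Localised gametic selection is modelled by
#' `distortion_loci`: viability weights applied to a parent's two haplotypes
#' at a chromosome position, enforced by rejection sampling of gametes, which
#' produces a distortion signal that decays with map distance.
#'
#' @param seed Integer RNG seed; a fixed seed makes every generated object
#'   bitwise reproducible.
#' @param n_chromosome_pairs Number of homoeologous chromosome pairs.
#' @param chromosome_length Length in cM of each homoeologue (recycled).
#' @param markers_per_group Loci genotyped per linkage group in each
#'   population.
#' @param population_sizes Integer vector of two F1 family sizes.
#' @param joining_marker_fraction Fraction of each population's markers that
#'   are also typed in the other population (joining/anchor markers).
#' @param dual_homoeolocus_probability Chance a marker amplifies both
#'   homoeoloci of its pair.
#' @param allele_size_base,allele_size_range Base pairs: marker amplicon
#'   sizes are drawn from `allele_size_base + U(0, allele_size_range)`.
#' @param homoeologue_size_offset Shift in bp between the two homoeoloci's
#'   allele-size ranges.
#' @param allele_size_spread Width in bp of one homoeolocus's allele-size
#'   range (alleles sit on 2-bp steps within it).
#' @param null_allele_probability Per-parental-allele chance of a null.
#' @param missing_data_rate Per-genotype-call chance of missing data.
#' @param seg_type_probs Named probabilities for the nominal segregation
#'   configuration drawn at each locus (`abxcd`, `abxac`, `abxab`, `abxaa`,
#'   `aaxab`); normalised to sum to one.
#' @param distortion_loci `NULL`, or a tibble with columns `population`
#'   (1 or 2), `parent` (`"maternal"`/`"paternal"`), `group`, `homoeologue`,
#'   `pos_cM`, `w1`, `w2` (relative viability of the parent's haplotype 1/2
#'   gametes at that position).
#' @param panel_size Number of unrelated genotypes in the diversity panel.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosome_pairs = 8L,
                       chromosome_length = 80,
                       markers_per_group = 20L,
                       population_sizes = c(92L, 184L),
                       joining_marker_fraction = 0.25,
                       dual_homoeolocus_probability = 0.35,
                       allele_size_base = 100,
                       allele_size_range = 150,
                       homoeologue_size_offset = 40,
                       allele_size_spread = 12,
                       null_allele_probability = 0.03,
                       missing_data_rate = 0.02,
                       seg_type_probs = c(abxcd = 0.18, abxac = 0.15,
                                          abxab = 0.12, abxaa = 0.28,
                                          aaxab = 0.27),
                       distortion_loci = NULL,
                       panel_size = 16L) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosome_pairs = as.integer(n_chromosome_pairs),
    chromosome_length = rep_len(chromosome_length, n_chromosome_pairs),
    markers_per_group = as.integer(markers_per_group),
    population_sizes = as.integer(population_sizes),
    joining_marker_fraction = joining_marker_fraction,
    dual_homoeolocus_probability = dual_homoeolocus_probability,
    allele_size_base = allele_size_base,
    allele_size_range = allele_size_range,
    homoeologue_size_offset = homoeologue_size_offset,
    allele_size_spread = allele_size_spread,
    null_allele_probability = null_allele_probability,
    missing_data_rate = missing_data_rate,
    seg_type_probs = seg_type_probs / sum(seg_type_probs),
    distortion_loci = distortion_loci,
    panel_size = as.integer(panel_size)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$joining_marker_fraction, cfg$dual_homoeolocus_probability,
             cfg$null_allele_probability, cfg$missing_data_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$chromosome_length < 0)) {
    stop("chromosome lengths must be non-negative", call. = FALSE)
  }
  if (length(cfg$population_sizes) != 2 || any(cfg$population_sizes < 2)) {
    stop("need two population sizes, each >= 2", call. = FALSE)
  }
  if (cfg$markers_per_group < 1 || cfg$n_chromosome_pairs < 1) {
    stop("need at least one group and one marker per group", call. = FALSE)
  }
  if (cfg$panel_size < 0) stop("panel_size must be >= 0", call. = FALSE)
  seg <- c("abxcd", "abxac", "abxab", "abxaa", "aaxab")
  if (!all(seg %in% names(cfg$seg_type_probs))) {
    stop("seg_type_probs must name all of ", paste(seg, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

# -- marker scaffold ---------------------------------------------------------

# One row per homoeolocus.  Joining markers are typed in both populations;
# the remainder split evenly so each population sees markers_per_group loci
# per linkage group.
build_marker_scaffold <- function(cfg) {
  M <- cfg$markers_per_group
  n_join <- round(cfg$joining_marker_fraction * M)
  n_excl <- M - n_join
  rows <- list()
  for (g in seq_len(cfg$n_chromosome_pairs)) {
    L <- cfg$chromosome_length[g]
    n_sites <- n_join + 2L * n_excl
    pos <- sort(runif(n_sites, 0, L))
    role <- sample(rep(c("both", "pop1", "pop2"),
                       c(n_join, n_excl, n_excl)))
    dual <- runif(n_sites) < cfg$dual_homoeolocus_probability
    base <- cfg$allele_size_base + round(runif(n_sites, 0, cfg$allele_size_range))
    for (s in seq_len(n_sites)) {
      mk <- function(marker_id, hom) {
        lo <- base[s] + (hom - 1L) * cfg$homoeologue_size_offset
        tibble(marker_id = marker_id, group = g, homoeologue = hom,
               pos_cM = pos[s],
               range_lo = lo, range_hi = lo + cfg$allele_size_spread,
               dual = dual[s],
               in_pop1 = role[s] %in% c("both", "pop1"),
               in_pop2 = role[s] %in% c("both", "pop2"),
               joining = role[s] == "both")
      }
      if (dual[s]) {
        id <- sprintf("g%dm%02d", g, s)
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(mk(id, 1L), mk(id, 2L))
      } else {
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(
          mk(sprintf("g%dm%02da", g, s), 1L),
          mk(sprintf("g%dm%02db", g, s), 2L)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# -- parents -----------------------------------------------------------------

#' Build phased parents for one synthetic population
#'
#' Draws, for every homoeolocus typed in the population, a nominal
#' segregation configuration, parental allele sizes from the homoeolocus's
#' size range, null alleles, and a random linkage phase (which of the
#' parent's two homologues carries which allele).  Null alleles are encoded
#' as size 0.
#'
#' @param config A [sim_config()].
#' @param population Which population (1 or 2).
#' @param scaffold Optional pre-built marker scaffold (internal use); when
#'   omitted the RNG seed is set from `config` and the scaffold is drawn
#'   first, so repeated calls are reproducible.
#' @return A tibble of phased parental genotypes, one row per locus, with
#'   allele columns `p1_a1 ... p2_a2` and phase columns `p1_hap1 ... p2_hap2`
#'   (`p1` is the maternal parent).
#' @export
build_parents <- function(config, population = 1L, scaffold = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(scaffold)) {
    set.seed(config$seed)
    scaffold <- build_marker_scaffold(config)
  }
  keep <- if (population == 1L) scaffold$in_pop1 else scaffold$in_pop2
  loci <- scaffold[keep, , drop = FALSE]
  n <- nrow(loci)
  types <- sample(names(config$seg_type_probs), n, replace = TRUE,
                  prob = config$seg_type_probs)
  al <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    pool <- seq(loci$range_lo[i], loci$range_hi[i], by = 2)
    al[i, ] <- draw_seg_alleles(types[i], pool)
  }
  # null injection per parental allele
  nulls <- matrix(runif(4L * n) < config$null_allele_probability, n, 4)
  al[nulls] <- 0
  # random phase per parent
  flip1 <- runif(n) < 0.5
  flip2 <- runif(n) < 0.5
  loci %>%
    dplyr::mutate(
      seg_type = types,
      p1_a1 = al[, 1], p1_a2 = al[, 2], p2_a1 = al[, 3], p2_a2 = al[, 4],
      p1_hap1 = ifelse(flip1, .data$p1_a2, .data$p1_a1),
      p1_hap2 = ifelse(flip1, .data$p1_a1, .data$p1_a2),
      p2_hap1 = ifelse(flip2, .data$p2_a2, .data$p2_a1),
      p2_hap2 = ifelse(flip2, .data$p2_a1, .data$p2_a2),
      has_null = rowSums(nulls) > 0
    )
}

# allele draw for one locus: returns c(p1_a1, p1_a2, p2_a1, p2_a2)
draw_seg_alleles <- function(type, pool) {
  s <- sample(pool, min(4, length(pool)))
  switch(type,
    abxcd = c(s[1], s[2], s[3], s[4]),
    abxac = c(s[1], s[2], s[1], s[3]),
    abxab = c(s[1], s[2], s[1], s[2]),
    abxaa = c(s[1], s[2], s[1], s[1]),
    aaxab = c(s[1], s[1], s[1], s[2]),
    stop("unknown segregation type: ", type, call. = FALSE)
  )
}

# -- meiosis -----------------------------------------------------------------

#' Simulate gamete haplotype phases along one chromosome
#'
#' Meiosis under a no-interference (Poisson) crossover model with strict
#' disomic inheritance: the expected crossover count is `length_cM / 100`,
#' crossover positions are uniform, the starting homologue is random, and
#' homoeologues never pair.  At 0 cM apart two loci always co-segregate; at
#' map distance d the recombinant fraction follows Haldane's function
#' `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param positions Numeric vector of locus positions, cM.
#' @param length_cM Chromosome length, cM.
#' @param n Number of gametes.
#' @return An `n x length(positions)` integer matrix of homologue indices
#'   (1 or 2).
#' @examples
#' ph <- sim_gamete_phases(c(0, 10), 100, 1000)
#' mean(ph[, 1] != ph[, 2])  # about (1 - exp(-0.2)) / 2 = 0.0906
#' @export
sim_gamete_phases <- function(positions, length_cM, n) {
  m <- length(positions)
  out <- matrix(1L, n, m)
  lambda <- length_cM / 100
  k <- if (lambda > 0) rpois(n, lambda) else integer(n)
  start <- sample(c(1L, 2L), n, replace = TRUE)
  for (i in seq_len(n)) {
    if (k[i] == 0) {
      out[i, ] <- start[i]
    } else {
      xo <- sort(runif(k[i], 0, length_cM))
      out[i, ] <- 1L + (start[i] - 1L + findInterval(positions, xo)) %% 2L
    }
  }
  out
}

# Gametes for one parent on one chromosome, honouring gametic-selection
# loci by rejection sampling.  dist: tibble rows with pos_cM, w1, w2.
sim_gametes_selected <- function(positions, length_cM, n, dist,
                                 max_tries = 1000L) {
  if (is.null(dist) || nrow(dist) == 0) {
    return(sim_gamete_phases(positions, length_cM, n))
  }
  allpos <- c(positions, dist$pos_cM)
  m <- length(positions)
  wmax <- pmax(dist$w1, dist$w2)
  if (any(wmax <= 0)) stop("viability weights must have a positive maximum",
                           call. = FALSE)
  acc <- matrix(NA_integer_, n, m)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("rejection sampling failed: infeasible viability weights",
           call. = FALSE)
    }
    batch <- sim_gamete_phases(allpos, length_cM, max(2L * (n - got), 16L))
    dphase <- batch[, m + seq_len(nrow(dist)), drop = FALSE]
    p_acc <- rep(1, nrow(batch))
    for (j in seq_len(nrow(dist))) {
      w <- c(dist$w1[j], dist$w2[j]) / wmax[j]
      p_acc <- p_acc * w[dphase[, j]]
    }
    keep <- which(runif(nrow(batch)) < p_acc)
    take <- head(keep, n - got)
    if (length(take)) {
      acc[got + seq_along(take), ] <- batch[take, seq_len(m), drop = FALSE]
      got <- got + length(take)
    }
  }
  acc
}

# -- population --------------------------------------------------------------

#' Simulate one F1 mapping population
#'
#' Builds parents (see [build_parents()]) and generates F1 progeny, each the
#' union of one maternal and one paternal gamete; applies gametic-selection
#' distortion by rejection sampling, hides null alleles, and deletes calls at
#' the configured missing-data rate.  Analyst-facing locus names follow the
#' field's suffix convention: `x` for ab×cd, `xn` for ab×cd with at least one
#' null parental allele, `y` for ab×ac, `z` for ab×ab, and letters `a`, `b`,
#' ... for single-parent configurations, with a numeric disambiguator when a
#' marker yields two loci of the same configuration.
#'
#' @inheritParams build_parents
#' @return An object of class `clover_population`: a list with elements
#'   `population`, `n`, `loci` (truth table: `locus_id`, `marker_id`,
#'   `group`, `homoeologue`, `pos_cM`, `joining`, `dual`, size range, nominal
#'   `seg_type`, parental alleles and phases), and `calls` (long tibble:
#'   `locus_id`, `indiv`, `a1`, `a2`; `NA` = not observed).
#' @export
simulate_population <- function(config, population = 1L, scaffold = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(scaffold)) {
    set.seed(config$seed + (population - 1L))
    scaffold <- build_marker_scaffold(config)
  }
  loci <- build_parents(config, population, scaffold = scaffold)
  loci$locus_id <- locus_names(loci)
  n <- config$population_sizes[population]
  dist_all <- config$distortion_loci
  calls <- vector("list", 0L)
  mat_hap <- list()  # per chromosome: transmitted haplotype matrices (truth)
  for (g in unique(loci$group)) {
    for (h in 1:2) {
      idx <- which(loci$group == g & loci$homoeologue == h)
      if (!length(idx)) next
      idx <- idx[order(loci$pos_cM[idx])]
      pos <- loci$pos_cM[idx]
      L <- config$chromosome_length[g]
      dist_m <- dist_sel(dist_all, population, "maternal", g, h)
      dist_p <- dist_sel(dist_all, population, "paternal", g, h)
      ph_m <- sim_gametes_selected(pos, L, n, dist_m)
      ph_p <- sim_gametes_selected(pos, L, n, dist_p)
      a_m <- allele_from_phase(ph_m, loci$p1_hap1[idx], loci$p1_hap2[idx])
      a_p <- allele_from_phase(ph_p, loci$p2_hap1[idx], loci$p2_hap2[idx])
      cnt <- (a_m > 0) + (a_p > 0)
      a1 <- ifelse(cnt == 2, pmin(a_m, a_p), ifelse(cnt == 1, pmax(a_m, a_p), NA))
      a2 <- ifelse(cnt == 2, pmax(a_m, a_p), NA)
      miss <- matrix(runif(length(a1)) < config$missing_data_rate, nrow(a1))
      a1[miss] <- NA
      a2[miss] <- NA
      calls[[length(calls) + 1L]] <- tibble(
        locus_id = rep(loci$locus_id[idx], each = n),
        indiv = rep(sprintf("F1_%03d", seq_len(n)), length(idx)),
        a1 = as.vector(a1), a2 = as.vector(a2)
      )
      mat_hap[[paste0(g, "-", h)]] <- list(locus_id = loci$locus_id[idx],
                                           maternal = ph_m, paternal = ph_p)
    }
  }
  structure(list(
    population = population,
    n = n,
    loci = loci,
    calls = dplyr::bind_rows(calls),
    gametes = mat_hap
  ), class = "clover_population")
}

dist_sel <- function(dist, population, parent, group, hom) {
  if (is.null(dist)) return(NULL)
  dist[dist$population == population & dist$parent == parent &
         dist$group == group & dist$homoeologue == hom, , drop = FALSE]
}

allele_from_phase <- function(phase, hap1, hap2) {
  n <- nrow(phase)
  h1 <- matrix(hap1, n, length(hap1), byrow = TRUE)
  h2 <- matrix(hap2, n, length(hap2), byrow = TRUE)
  ifelse(phase == 1L, h1, h2)
}

# suffix convention for analyst-facing locus names
locus_names <- function(loci) {
  base <- dplyr::case_when(
    loci$seg_type == "abxcd" & loci$has_null ~ "xn",
    loci$seg_type == "abxcd" ~ "x",
    loci$seg_type == "abxac" ~ "y",
    loci$seg_type == "abxab" ~ "z",
    TRUE ~ NA_character_
  )
  out <- character(nrow(loci))
  for (m in unique(loci$marker_id)) {
    i <- which(loci$marker_id == m)
    suf <- base[i]
    letters_needed <- which(is.na(suf))
    suf[letters_needed] <- letters[seq_along(letters_needed)]
    dup <- duplicated(suf) | duplicated(suf, fromLast = TRUE)
    suf[dup] <- paste0(suf[dup], seq_along(suf)[dup])
    out[i] <- paste0(m, "_", suf)
  }
  out
}

# -- panel -------------------------------------------------------------------

#' Simulate a diversity panel
#'
#' Draws unrelated genotypes from the same allele-frequency model as the
#' mapping parents (uniform over each homoeolocus's allele pool, with null
#' alleles).  Panel individuals report the union of visible allele sizes per
#' marker — a marker amplifying both homoeoloci can therefore show up to four
#' alleles in one individual, which is exactly the signal the single-locus
#' homoeologue-specific (SL-HS) screen keys on.
#'
#' @inheritParams build_parents
#' @return A long tibble: `marker_id`, `indiv`, `allele` (one row per
#'   distinct visible allele size).  Empty when `panel_size` is 0.
#' @export
build_panel <- function(config, scaffold = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(scaffold)) {
    set.seed(config$seed + 1000L)
    scaffold <- build_marker_scaffold(config)
  }
  if (config$panel_size == 0) {
    return(tibble(marker_id = character(), indiv = character(),
                  allele = double()))
  }
  inds <- sprintf("PAN_%02d", seq_len(config$panel_size))
  rows <- list()
  for (m in unique(scaffold$marker_id)) {
    hl <- scaffold[scaffold$marker_id == m, , drop = FALSE]
    for (ind in inds) {
      vis <- double(0)
      for (j in seq_len(nrow(hl))) {
        pool <- seq(hl$range_lo[j], hl$range_hi[j], by = 2)
        a <- sample(pool, 2, replace = TRUE)
        a[runif(2) < config$null_allele_probability] <- 0
        vis <- c(vis, a[a > 0])
      }
      vis <- unique(vis)
      if (length(vis)) {
        rows[[length(rows) + 1L]] <- tibble(marker_id = m, indiv = ind,
                                            allele = vis)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# -- full experiment ---------------------------------------------------------

#' Simulate the full two-population mapping experiment
#'
#' Generates the shared marker scaffold, both F1 populations, and the
#' diversity panel under a single RNG seed, so the whole object is bitwise
#' reproducible from the configuration alone.
#'
#' @param config A [sim_config()].
#' @return An object of class `clover_cross`: list with `config`, `scaffold`
#'   (truth marker table), `populations` (list of two `clover_population`
#'   objects), and `panel`.
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  scaffold <- build_marker_scaffold(config)
  pops <- lapply(1:2, function(p) simulate_population(config, p, scaffold))
  panel <- build_panel(config, scaffold = scaffold)
  structure(list(config = config, scaffold = scaffold,
                 populations = pops, panel = panel),
            class = "clover_cross")
}

#' @export
print.clover_population <- function(x, ...) {
  cat("<clover_population> population", x$population,
      "-", x$n, "progeny,", nrow(x$loci), "loci\n")
  invisible(x)
}

#' @export
print.clover_cross <- function(x, ...) {
  cat("<clover_cross>", x$config$n_chromosome_pairs, "homoeologous pairs;",
      "populations n =", paste(x$config$population_sizes, collapse = ", "),
      "; panel", x$config$panel_size, "\n")
  invisible(x)
}
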