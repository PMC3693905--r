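test_that("configuration validation enforces the documented invariants", {
  expect_error(sim_config(null_allele_probability = 1.5), "probabilities")
  expect_error(sim_config(population_sizes = c(1, 50)), ">= 2")
  expect_error(sim_config(chromosome_length = -5), "lengths")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$population_sizes, c(92L, 184L))
  expect_equal(cfg$n_chromosome_pairs, 8L)
  expect_equal(cfg$panel_size, 16L)
})

test_that("a fixed seed makes the whole experiment bitwise reproducible", {
  c1 <- simulate_cross(small_config(seed = 5))
  c2 <- simulate_cross(small_config(seed = 5))
  expect_identical(c1$scaffold, c2$scaffold)
  expect_identical(c1$populations[[1]]$loci, c2$populations[[1]]$loci)
  expect_identical(c1$populations[[2]]$calls, c2$populations[[2]]$calls)
  expect_identical(c1$panel, c2$panel)
  p1 <- build_parents(small_config(seed = 9))
  p2 <- build_parents(small_config(seed = 9))
  expect_identical(p1, p2)
})

test_that("dual-homoeolocus probability 0 gives single-locus markers only", {
  cfg <- small_config(seed = 2, dual_homoeolocus_probability = 0)
  cross <- simulate_cross(cfg)
  per_marker <- table(cross$scaffold$marker_id)
  expect_true(all(per_marker == 1))
})

test_that("no nulls plus forced heterozygosity gives only bi-parental types", {
  cfg <- small_config(seed = 3, null_allele_probability = 0,
                      seg_type_probs = c(abxcd = 1, abxac = 1, abxab = 1,
                                         abxaa = 0, aaxab = 0))
  parents <- build_parents(cfg)
  expect_true(all(parents$seg_type %in% c("abxcd", "abxac", "abxab")))
  expect_false(any(parents$has_null))
  # every parent heterozygous at every locus
  expect_true(all(parents$p1_a1 != parents$p1_a2))
  expect_true(all(parents$p2_a1 != parents$p2_a2))
})

test_that("meiosis recombination matches Haldane's expectation", {
  set.seed(21)
  # two markers 10 cM apart on a 100 cM chromosome
  ph <- sim_gamete_phases(c(20, 30), 100, 10000)
  rf <- mean(ph[, 1] != ph[, 2])
  r_expected <- (1 - exp(-0.2)) / 2
  tol <- 3 * sqrt(r_expected * (1 - r_expected) / 10000)
  expect_lt(abs(rf - r_expected), tol)
  # zero-length chromosome: full parental haplotype, no recombinants
  ph0 <- sim_gamete_phases(c(0, 0, 0), 0, 500)
  expect_true(all(ph0 == ph0[, 1]))
  # different chromosomes assort independently
  a <- sim_gamete_phases(5, 80, 8000)
  b <- sim_gamete_phases(5, 80, 8000)
  rf_ind <- mean(a[, 1] != b[, 1])
  expect_lt(abs(rf_ind - 0.5), 3 * sqrt(0.25 / 8000))
})

test_that("an undistorted fully informative locus segregates 1:1:1:1", {
  # chi-square at P > 0.001 in nearly all seeds
  pass <- vapply(1:25, function(seed) {
    cfg <- sim_config(seed = seed, n_chromosome_pairs = 1L,
                      markers_per_group = 2L, population_sizes = c(10L, 184L),
                      null_allele_probability = 0, missing_data_rate = 0,
                      seg_type_probs = c(abxcd = 1, abxac = 0, abxab = 0,
                                         abxaa = 0, aaxab = 0),
                      panel_size = 0L)
    pop <- simulate_population(cfg, 2L)
    locus <- pop$loci$locus_id[1]
    counts <- table(paste(pop$calls$a1[pop$calls$locus_id == locus],
                          pop$calls$a2[pop$calls$locus_id == locus]))
    segregation_chisq(as.integer(counts))$p_value > 0.001
  }, logical(1))
  expect_gte(mean(pass), 24 / 25)
})

test_that("Mendelian conservation: parental alleles reach half the progeny", {
  cfg <- sim_config(seed = 13, n_chromosome_pairs = 1L,
                    markers_per_group = 4L, population_sizes = c(10L, 184L),
                    null_allele_probability = 0, missing_data_rate = 0,
                    seg_type_probs = c(abxcd = 1, abxac = 0, abxab = 0,
                                       abxaa = 0, aaxab = 0),
                    panel_size = 0L)
  pop <- simulate_population(cfg, 2L)
  tol <- 3 * sqrt(0.25 / 184)
  for (li in seq_len(nrow(pop$loci))) {
    lrow <- pop$loci[li, ]
    calls <- pop$calls[pop$calls$locus_id == lrow$locus_id, ]
    for (al in c(lrow$p1_a1, lrow$p1_a2, lrow$p2_a1, lrow$p2_a2)) {
      frac <- mean(calls$a1 == al | calls$a2 == al)
      expect_lt(abs(frac - 0.5), tol)
    }
  }
})

test_that("a zero viability weight removes the haplotype from all gametes", {
  set.seed(4)
  dist <- tibble::tibble(pos_cM = 0, w1 = 0, w2 = 1)
  ph <- clovermap:::sim_gametes_selected(c(0, 15, 40), 80, 400, dist)
  # at the selected position the lethal haplotype never appears
  expect_true(all(ph[, 1] == 2L))
  # nearby loci remain strongly depleted, distant ones recover
  expect_lt(mean(ph[, 2] == 1L), 0.25)
  expect_gt(mean(ph[, 3] == 1L), 0.25)
})

test_that("distortion signal is local and decays along the chromosome", {
  cfg <- sim_config(
    seed = 6, n_chromosome_pairs = 2L, markers_per_group = 10L,
    population_sizes = c(10L, 184L), null_allele_probability = 0,
    missing_data_rate = 0,
    seg_type_probs = c(abxcd = 1, abxac = 0, abxab = 0, abxaa = 0, aaxab = 0),
    panel_size = 0L,
    distortion_loci = tibble::tibble(population = 2L, parent = "maternal",
                                     group = 1L, homoeologue = 1L,
                                     pos_cM = 0, w1 = 0.1, w2 = 1)
  )
  pops <- lapply(1:10, function(s) {
    cfg$seed <- s
    simulate_population(cfg, 2L)
  })
  stat_by <- function(pop, group, hom) {
    loci <- pop$loci[pop$loci$group == group & pop$loci$homoeologue == hom, ]
    tm <- transmission_matrix(pop, "maternal")[, loci$locus_id, drop = FALSE]
    n1 <- colSums(tm == 1L, na.rm = TRUE)
    n2 <- colSums(tm == 2L, na.rm = TRUE)
    data.frame(pos = loci$pos_cM, chi = (n1 - n2)^2 / (n1 + n2))
  }
  target <- do.call(rbind, lapply(pops, stat_by, group = 1L, hom = 1L))
  other <- do.call(rbind, lapply(pops, stat_by, group = 2L, hom = 1L))
  near <- target$chi[target$pos < 20]
  far <- target$chi[target$pos > 60]
  expect_gt(mean(near), mean(far))          # decay along the chromosome
  expect_gt(mean(near), 3 * mean(other$chi))  # unlinked groups untouched
  # unlinked type-I rate stays near nominal
  expect_lt(mean(other$chi > qchisq(0.95, 1)), 0.15)
})

test_that("infeasible viability weights fail loudly", {
  expect_error(
    clovermap:::sim_gametes_selected(c(0, 10), 80, 20,
                                     tibble::tibble(pos_cM = 0, w1 = 0,
                                                    w2 = 0)),
    "positive")
})

test_that("missing-data rate one blanks every call", {
  cfg <- small_config(seed = 8, missing_data_rate = 1)
  pop <- simulate_population(cfg, 1L)
  expect_true(all(is.na(pop$calls$a1)))
  expect_true(all(is.na(pop$calls$a2)))
})

test_that("every progeny allele traces to a parental allele", {
  cfg <- small_config(seed = 12, missing_data_rate = 0)
  pop <- simulate_population(cfg, 2L)
  joined <- dplyr::inner_join(pop$calls, pop$loci, by = "locus_id")
  ok1 <- is.na(joined$a1) | joined$a1 == joined$p1_a1 |
    joined$a1 == joined$p1_a2 | joined$a1 == joined$p2_a1 |
    joined$a1 == joined$p2_a2
  ok2 <- is.na(joined$a2) | joined$a2 == joined$p1_a1 |
    joined$a2 == joined$p1_a2 | joined$a2 == joined$p2_a1 |
    joined$a2 == joined$p2_a2
  expect_true(all(ok1) && all(ok2))
  # truth positions lie within the chromosome
  expect_true(all(pop$loci$pos_cM >= 0 &
                    pop$loci$pos_cM <= max(cfg$chromosome_length)))
})

test_that("joining markers are genotyped in both populations", {
  cross <- simulate_cross(small_config(seed = 14))
  joining <- unique(cross$scaffold$marker_id[cross$scaffold$joining])
  m1 <- unique(cross$populations[[1]]$loci$marker_id)
  m2 <- unique(cross$populations[[2]]$loci$marker_id)
  expect_true(all(joining %in% m1))
  expect_true(all(joining %in% m2))
  # non-joining markers are split between the populations
  expect_equal(intersect(setdiff(m1, joining), setdiff(m2, joining)),
               character(0))
})

test_that("the panel respects truth labels and feeds the SL-HS screen", {
  cfg <- small_config(seed = 15, null_allele_probability = 0)
  cross <- simulate_cross(cfg)
  panel <- cross$panel
  sl <- designate_slhs(panel)
  per_marker <- table(cross$scaffold$marker_id)
  singles <- names(per_marker[per_marker == 1])
  duals <- names(per_marker[per_marker == 2])
  # truth single-homoeolocus markers can never show > 2 alleles
  expect_true(all(sl$slhs[sl$marker_id %in% singles]))
  # with disjoint ranges, no nulls and a 10-genotype panel, most dual
  # markers reveal themselves with > 2 alleles in someone
  expect_gt(mean(!sl$slhs[sl$marker_id %in% duals]), 0.8)
  # empty panel is an error
  expect_error(designate_slhs(panel[0, ]), "insufficient")
  expect_error(build_panel(small_config(panel_size = 0)) |> designate_slhs(),
               "insufficient")
})
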