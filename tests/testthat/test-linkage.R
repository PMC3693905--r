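test_that("segregation classification covers the standard CP configurations", {
  r1 <- classify_segregation(c(120, 124), c(128, 132))
  expect_equal(r1$type, "abxcd")
  expect_equal(nrow(r1$classes), 4)
  expect_true(all(r1$classes$prob == 0.25))
  r2 <- classify_segregation(c(120, 124), c(120, 128))
  expect_equal(r2$type, "abxac")
  expect_equal(nrow(r2$classes), 4)
  r3 <- classify_segregation(c(120, 124), c(120, 124))
  expect_equal(r3$type, "abxab")
  expect_equal(sort(r3$classes$prob), c(0.25, 0.25, 0.5))
  r4 <- classify_segregation(c(120, 120), c(120, 120))
  expect_equal(r4$type, "uninformative")
  expect_false(r4$informative)
  # aa x bb: progeny monomorphic, hence uninformative
  r5 <- classify_segregation(c(120, 120), c(130, 130))
  expect_false(r5$informative)
})

test_that("null alleles collapse classes exactly as gamete enumeration says", {
  res <- classify_segregation(c(120, 0), c(120, 124))
  # enumeration: gametes {120,0} x {120,124} ->
  # 120/120, 120/124, 120 (null+120), 124 (null+124)
  expect_equal(res$type, "abxac")
  pats <- sort(res$classes$pattern)
  expect_equal(pats, sort(c("120/120", "120/124", "120", "124")))
  expect_true(all(res$classes$prob == 0.25))
  # null x null parent side: no amplification class appears
  res2 <- classify_segregation(c(0, 124), c(0, 0))
  expect_true("" %in% res2$classes$pattern || res2$informative)
})

test_that("two-point estimates reduce to recombinant counting with LOD", {
  ta <- rep(c(1L, 2L), each = 50)
  tb <- ta
  flip <- c(1:5, 51:55)
  tb[flip] <- 3L - tb[flip]
  est <- estimate_rf(ta, tb)
  expect_equal(est$r, 0.1)
  expect_equal(est$lod, 90 * log10(1.8) + 10 * log10(0.2), tolerance = 1e-10)
  expect_equal(round(est$lod, 2), 15.98)
  expect_equal(est$phase, "coupling")
  # 90 informative meioses, 9 recombinant
  est2 <- estimate_rf(rep(c(1L, 2L), 45), c(rep(c(2L, 1L), 4), rep(c(1L, 2L), 41)))
  expect_equal(est2$n_informative, 90L)
  # complete linkage gives r = 0 and the maximal LOD n*log10(2)
  est3 <- estimate_rf(ta, ta)
  expect_equal(est3$r, 0)
  expect_equal(est3$lod, 100 * log10(2))
  # repulsion phase is chosen by likelihood
  est4 <- estimate_rf(ta, 3L - ta)
  expect_equal(est4$r, 0)
  expect_equal(est4$phase, "repulsion")
  # low-information flagging
  expect_true(estimate_rf(c(1L, 2L, 1L), c(1L, 2L, 2L))$low_confidence)
})

test_that("pairwise linkage matrix agrees with per-pair estimation", {
  set.seed(31)
  tmat <- matrix(sample(c(1L, 2L, NA), 300, replace = TRUE,
                        prob = c(0.45, 0.45, 0.1)), 50, 6,
                 dimnames = list(NULL, paste0("L", 1:6)))
  pw <- pairwise_linkage(tmat, min_informative = 10)
  for (row in sample(nrow(pw), 5)) {
    a <- tmat[, pw$locus_a[row]]
    b <- tmat[, pw$locus_b[row]]
    ref <- estimate_rf(a, b)
    expect_equal(pw$r[row], ref$r)
    expect_equal(pw$lod[row], ref$lod)
    expect_equal(pw$n_informative[row], ref$n_informative)
  }
})

test_that("LOD grouping is transitive and leaves weak pairs apart", {
  pw <- tibble::tibble(
    locus_a = c("A", "B", "A"), locus_b = c("B", "C", "C"),
    n_informative = 100L, r = c(0.05, 0.05, 0.4),
    lod = c(10, 9, 0.5), low_confidence = FALSE
  )
  g <- group_loci(pw, lod = 8)
  expect_equal(length(unique(g$group_est)), 1)
  pw$lod <- c(2, 3, 0.5)
  g2 <- group_loci(pw, lod = 8)
  expect_equal(length(unique(g2$group_est)), 3)
})

test_that("three-locus ordering places the largest distance at the ends", {
  pw <- tibble::tibble(
    locus_a = c("P", "P", "Q"), locus_b = c("Q", "R", "R"),
    n_informative = 184L, r = c(0.05, 0.15, 0.10),
    lod = clovermap:::two_point_lod(184, round(184 * c(0.05, 0.15, 0.10))),
    low_confidence = FALSE
  )
  og <- order_group(c("P", "Q", "R"), pw)
  expect_equal(og$locus_id[2], "Q")  # P-R is the largest distance
  expect_equal(og$pos_cM[1], 0)
  expect_true(all(diff(og$pos_cM) > 0))
})

test_that("ordering recovers a simulated order and canonicalises orientation", {
  set.seed(17)
  pos <- sort(runif(12, 0, 80))
  ids <- sprintf("L%02d", sample(12))
  grid <- expand.grid(i = 1:12, j = 1:12)
  grid <- grid[grid$i < grid$j, ]
  r <- (1 - exp(-2 * abs(pos[grid$i] - pos[grid$j]) / 100)) / 2
  pw <- tibble::tibble(
    locus_a = ids[grid$i], locus_b = ids[grid$j], n_informative = 184L,
    r = r, lod = clovermap:::two_point_lod(184, round(184 * r)),
    low_confidence = FALSE
  )
  og <- order_group(ids, pw)
  tp <- pos[match(og$locus_id, ids)]
  expect_gte(abs(cor(seq_along(tp), tp, method = "spearman")), 0.99)
  # a reversed map is equivalent; orientation fixed by the terminal tie-break
  expect_true(og$locus_id[1] < og$locus_id[nrow(og)])
  # disconnected evidence is flagged
  pw_cut <- pw[pw$locus_a %in% ids[1:3] & pw$locus_b %in% ids[1:3], ]
  expect_error(order_group(ids[1:6], pw_cut), "disconnected")
})

test_that("distortion chi-square values match their closed forms", {
  even <- segregation_chisq(c(46, 46, 46, 46))
  expect_equal(even$chi_square, 0)
  expect_equal(even$p_value, 1)
  skew <- segregation_chisq(c(60, 40))
  expect_equal(skew$chi_square, 4)
  expect_equal(skew$p_value, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(round(skew$p_value, 4), 0.0455)
  # exact fallback engages when expected counts drop below 1
  tiny <- segregation_chisq(c(3, 0, 0, 0))
  expect_equal(tiny$method, "exact multinomial")
  expect_equal(tiny$p_value, 4 * 0.25^3, tolerance = 1e-9)
})

test_that("distortion scan signs follow the parental-origin convention", {
  cfg <- sim_config(seed = 23, n_chromosome_pairs = 1L,
                    markers_per_group = 6L, population_sizes = c(10L, 150L),
                    null_allele_probability = 0, missing_data_rate = 0,
                    panel_size = 0L,
                    distortion_loci = tibble::tibble(
                      population = 2L, parent = "paternal", group = 1L,
                      homoeologue = 1L, pos_cM = 0, w1 = 0.15, w2 = 1))
  pop <- simulate_population(cfg, 2L)
  scan <- distortion_scan(pop)
  expect_true(all(scan$signed_log10p[scan$parental_origin == "female"] >= 0))
  expect_true(all(scan$signed_log10p[scan$parental_origin == "male"] <= 0))
  expect_equal(abs(scan$signed_log10p), -log10(scan$p_value))
  # male-derived distortion with P = 0.01 maps to -2
  male <- scan[scan$parental_origin == "male", ]
  expect_equal(male$signed_log10p, log10(male$p_value))
  # the planted paternal distortion is detected
  g1 <- pop$loci$locus_id[pop$loci$group == 1 & pop$loci$homoeologue == 1]
  flagged <- male$distorted[male$locus_id %in% g1]
  expect_gt(mean(flagged), 0.5)
})

test_that("distortion test holds its type-I error rate under the null", {
  rates <- vapply(1:25, function(seed) {
    cfg <- sim_config(seed = seed, n_chromosome_pairs = 1L,
                      markers_per_group = 10L,
                      population_sizes = c(10L, 184L),
                      null_allele_probability = 0, missing_data_rate = 0,
                      panel_size = 0L)
    scan <- distortion_scan(simulate_population(cfg, 2L))
    mean(scan$distorted)
  }, double(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("parental consensus merging preserves and reunites groups", {
  maternal <- tibble::tibble(
    locus_id = c("a", "b", "c", "d"), group = "M1",
    pos_cM = c(0, 10, 20, 30)
  )
  paternal <- tibble::tibble(
    locus_id = c("a", "b", "c", "e"), group = "P1",
    pos_cM = c(0, 10, 20, 25)
  )
  cons <- build_parental_consensus(maternal, paternal)
  expect_equal(length(unique(cons$map$group)), 1)
  expect_equal(sort(cons$map$locus_id), c("a", "b", "c", "d", "e"))
  # identical maps: consensus equals the input
  same <- build_parental_consensus(maternal,
                                   dplyr::mutate(maternal, group = "P1"))
  expect_equal(same$map$pos_cM[match(maternal$locus_id, same$map$locus_id)],
               maternal$pos_cM)
  # no bridge loci: both groups pass through with a warning
  disjoint <- tibble::tibble(locus_id = c("x", "y"), group = "P1",
                             pos_cM = c(0, 12))
  expect_warning(res <- build_parental_consensus(maternal, disjoint),
                 "bridge")
  expect_equal(length(unique(res$map$group)), 2)
})

test_that("genotype table round-trips through the delimited format", {
  pop <- simulate_population(small_config(seed = 19), 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(pop, path)
  back <- read_genotype_table(path)
  expect_equal(back$loci$locus_id, pop$loci$locus_id)
  expect_equal(back$loci$p1_a1, pop$loci$p1_a1)
  merged <- dplyr::inner_join(back$calls, pop$calls,
                              by = c("locus_id", "indiv"))
  expect_equal(merged$a1.x, merged$a1.y)
  expect_equal(merged$a2.x, merged$a2.y)
  # transmission matrices agree between original and round-tripped data
  t_orig <- transmission_matrix(pop, "maternal")
  t_back <- transmission_matrix(back, "maternal")
  expect_equal(t_back[, colnames(t_orig)], t_orig)
})

test_that("the JoinMap CP coding reader understands the classic codes", {
  path <- withr::local_tempfile(fileext = ".loc")
  writeLines(c(
    "m1 <abxcd> ac ad bc bd ac --",
    "m2 <lmxll> lm ll lm ll ll lm",
    "m3 <hkxhk> hh hk kk hk . hh"
  ), path)
  res <- read_joinmap_loc(path)
  expect_equal(res$loci$seg_type, c("abxcd", "abxaa", "abxab"))
  expect_equal(nrow(res$calls), 18)
  expect_equal(sum(is.na(res$calls$a1)), 2)
  tm <- transmission_matrix(res, "maternal")
  expect_equal(dim(tm), c(6L, 3L))
  # ac -> maternal transmitted allele a (index 1)
  expect_equal(unname(tm[1, "m1"]), 1L)
  expect_equal(unname(tm[3, "m1"]), 2L)
})
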