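make_hits <- function(n, queries = paste0("q", seq_len(n)), seed = 1) {
  set.seed(seed)
  tibble::tibble(
    qseqid = queries,
    sseqid = sample(paste0("chr", 1:4), n, replace = TRUE),
    pident = runif(n, 80, 100), length = sample(100:400, n, replace = TRUE),
    mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 200L,
    sstart = sample.int(4e6, n), send = sample.int(4e6, n),
    evalue = 10^runif(n, -45, -5), bitscore = runif(n, 50, 400)
  )
}

test_that("best-hit filtering keeps the strongest qualifying hit per query", {
  hits <- tibble::tibble(
    qseqid = c("q1", "q1", "q2"),
    sseqid = "chr1", pident = 95, length = 200, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
    evalue = c(1e-25, 1e-22, 1e-10), bitscore = c(100, 90, 80)
  )
  out <- filter_hits(hits)
  expect_equal(nrow(out), 1)
  expect_equal(out$qseqid, "q1")
  expect_equal(out$evalue, 1e-25)   # q2 fails the 1e-20 threshold entirely
})

test_that("filtering equals the brute-force oracle and ignores input order", {
  hits <- make_hits(120, queries = sample(paste0("q", 1:30), 120,
                                          replace = TRUE), seed = 5)
  got <- filter_hits(hits)
  exp <- brute_filter_hits(as.data.frame(hits))
  expect_equal(as.data.frame(got), exp, ignore_attr = TRUE)
  shuffled <- hits[sample(nrow(hits)), ]
  got2 <- filter_hits(shuffled)
  expect_equal(got2$qseqid, got$qseqid)
  expect_equal(got2$evalue, got$evalue)
  # ties on E-value resolved by bit score
  tied <- hits[1:2, ]
  tied$qseqid <- "t"; tied$evalue <- 1e-30; tied$bitscore <- c(100, 300)
  expect_equal(filter_hits(tied)$bitscore, 300)
})

test_that("BLAST tabular parsing reports malformed rows by line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  good <- paste(c("q1", "chr1", "98.5", "200", "1", "0", "1", "200",
                  "1000", "1200", "1e-30", "250"), collapse = "\t")
  writeLines(c(good, "broken\trow"), path)
  expect_error(read_blast_tab(path), "line")
  writeLines(c(good, good), path)
  parsed <- read_blast_tab(path)
  expect_equal(nrow(parsed), 2)
  expect_equal(parsed$evalue[1], 1e-30)
})

test_that("conflation normalises each homoeologue to proportional distance", {
  map <- tibble::tibble(
    locus_id = c("a", "b", "c", "d", "e"),
    group = c("3-1", "3-1", "3-1", "3-2", "bad"),
    pos_cM = c(0, 43.35, 86.7, 50, 10)
  )
  expect_warning(con <- conflate_homoeologues(map), "excluded")
  expect_equal(nrow(con), 4)
  expect_equal(con$tr_position[con$locus_id == "b"], 0.5)
  expect_equal(con$tr_position[con$locus_id == "c"], 1.0)
  expect_equal(unique(con$tr_group), 3L)
  expect_setequal(con$homoeologue, c(1L, 2L))
})

test_that("synteny records join map and reference proportional frames", {
  con <- tibble::tibble(locus_id = c("a", "b"), tr_group = 1L,
                        homoeologue = 1L, tr_position = c(0.2, 0.8))
  hits <- make_hits(2, queries = c("a", "b"), seed = 3)
  hits$sseqid <- "chr1"; hits$sstart <- c(100L, 300L); hits$send <- c(200L, 250L)
  rec <- synteny_records(con, hits, c(chr1 = 1000))
  expect_equal(rec$ref_position, c(150, 275) / 1000)
  expect_equal(rec$strand, c("+", "-"))
})

test_that("dot matrix counts find the dominant chromosome per group", {
  expect_equal(nrow(synteny_matrix(
    simulate_synteny_records(1, 0))$counts), 0)
  rec <- simulate_synteny_records(n_groups = 4, hits_per_group = 30,
                                  scatter = 0, noise = 0, seed = 2)
  sm <- synteny_matrix(rec)
  expect_equal(sm$dominant$fraction, rep(1, 4))
  expect_equal(sm$dominant$ref_chromosome, paste0("chr", 1:4))
  rec2 <- simulate_synteny_records(n_groups = 6, hits_per_group = 60,
                                   scatter = 0.1, seed = 3)
  sm2 <- synteny_matrix(rec2)
  expect_true(all(abs(sm2$dominant$fraction - 0.9) < 0.12))
})

test_that("co-linearity fraction is exact on a line and orientation-blind", {
  rec <- simulate_synteny_records(n_groups = 3, hits_per_group = 25,
                                  scatter = 0, noise = 0, seed = 4)
  cf <- colinearity_fraction(rec)
  expect_equal(cf$fraction, 1)
  flipped <- dplyr::mutate(rec, tr_position = 1 - tr_position)
  expect_equal(colinearity_fraction(flipped)$fraction, 1)
  flipped2 <- dplyr::mutate(rec, ref_position = 1 - ref_position)
  expect_equal(colinearity_fraction(flipped2)$fraction, 1)
  # repeated-median slope recovers an inverted trend's sign
  fit <- repeated_median_fit(rec$tr_position[rec$tr_group == 1],
                             1 - rec$ref_position[rec$tr_group == 1])
  expect_lt(fit$slope, 0)
})

test_that("scattered hits lower the co-linear fraction by about their share", {
  frac <- vapply(1:6, function(s) {
    rec <- simulate_synteny_records(n_groups = 8, hits_per_group = 40,
                                    scatter = 0.5, noise = 0.01, seed = s)
    colinearity_fraction(rec)$fraction
  }, double(1))
  # half the points permuted: brute-force residual counting says the
  # fraction sits near 0.5 plus the share of scattered points that land
  # inside the band (~0.1 of them times twice the band width)
  expect_lt(abs(mean(frac) - 0.6), 0.08)
})

test_that("translocation segmentation matches the exhaustive search", {
  # clean six-hit split breaks at 0.5
  rec <- tibble::tibble(
    tr_position = seq(0, 1, length.out = 6),
    ref_chromosome = rep(c("A", "B"), each = 3)
  )
  res <- detect_translocation(rec)
  expect_equal(nrow(res$segments), 2)
  expect_equal(res$breakpoints, 0.5)
  expect_equal(res$purity, 1)
  # interleaved labels: no confident breakpoint, single low-purity segment
  rec2 <- tibble::tibble(tr_position = seq(0, 1, length.out = 8),
                         ref_chromosome = rep(c("A", "B"), 4))
  res2 <- detect_translocation(rec2)
  expect_equal(nrow(res2$segments), 1)
  expect_lt(res2$purity, 0.8)
  # random label sequences: DP cost equals brute-force enumeration
  set.seed(9)
  for (i in 1:12) {
    n <- sample(8:30, 1)
    lab <- sample(c("A", "B", "C"), n, replace = TRUE)
    seg <- clovermap:::optimal_segmentation(lab, 3)
    dp_cost <- sum(vapply(unique(seg), function(s) {
      idx <- which(seg == s)
      length(idx) - max(table(lab[idx]))
    }, double(1)))
    expect_equal(dp_cost, brute_segmentation_cost(lab, 3))
  }
})

test_that("simulated 70/30 translocations are located within 0.05", {
  hits <- 40
  err <- vapply(1:20, function(s) {
    rec <- simulate_synteny_records(
      n_groups = 2, hits_per_group = hits, scatter = 0, noise = 0.01,
      translocation = list(group = 2, to = 1, from_position = 0.7), seed = s)
    g2 <- rec[rec$tr_group == 2, ]
    res <- detect_translocation(g2)
    if (length(res$breakpoints) == 0) return(NA_real_)
    min(abs(res$breakpoints - 0.7))
  }, double(1))
  expect_true(all(!is.na(err)))
  expect_true(mean(err <= 0.05) >= 0.9)
  # secondary segments below the support floor are not called
  rec3 <- tibble::tibble(tr_position = seq(0, 1, length.out = 12),
                         ref_chromosome = c(rep("A", 10), "B", "B"))
  res3 <- detect_translocation(rec3, min_support = 3)
  expect_equal(nrow(res3$segments), 1)
  expect_equal(res3$segments$ref_chromosome, "A")
})
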