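test_that("pwm construction validates and consensus PWMs score as expected", {
  expect_error(pwm(matrix(1, 3, 6)), "4 rows")
  expect_error(pwm(matrix(0.3, 4, 6)), "sum to 1")
  expect_error(pwm_from_consensus("ACGX"), "ACGTN")
  p <- pwm_from_consensus("ACGTAC")
  expect_equal(p$length, 6)
  expect_equal(colSums(p$matrix), rep(1, 6), ignore_attr = TRUE)
})

test_that("scan_pwm equals the naive position-by-position oracle", {
  p <- pwm_from_consensus("TCAAGT", mismatch_prob = 0.05)
  for (seed in 1:4) {
    s <- with_seed_test(seed, paste(
      sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = ""))
    thr <- 4
    got <- scan_pwm(s, p, threshold = thr)
    orc <- oracle_scan(s, p$matrix, thr)
    expect_equal(got$position, orc$position)
    expect_equal(got$strand, orc$strand)
    expect_equal(got$score, orc$score, tolerance = 1e-9)
  }
})

test_that("planted exact consensus sites are all found at consensus score", {
  cons <- "TCAAGTTTCA"
  p <- pwm_from_consensus(cons)
  g <- toy_genome(5e4)
  ps <- random_peaks(30, "F", len = 5e4, seed = 21)
  seqs <- with_seed_test(3, Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 5e4, replace = TRUE), collapse = ""))))
  pl <- plant_motifs(seqs, ps, cons, plant_prob = 1, positional_sd = 10,
                     seed = 9)
  consensus_score <- sum(log2(apply(p$matrix, 2, max) / 0.25))
  occ <- scan_pwm(pl$sequences, p, threshold = consensus_score - 1e-9)
  planted_pos <- pl$truth$position[pl$truth$planted]
  expect_true(all(planted_pos %in% occ$position))
})

test_that("region-restricted scans honor bounds and reject bad regions", {
  p <- pwm_from_consensus("ACGTAC")
  s <- strrep("ACGTAC", 100)
  occ_all <- scan_pwm(s, p, threshold = 5)
  occ_reg <- scan_pwm(s, p, threshold = 5,
                      regions = genomic_intervals("seq1", 0, 60))
  expect_true(all(occ_reg$position < 60))
  expect_gt(nrow(occ_all), nrow(occ_reg))
  expect_error(
    scan_pwm(s, p, regions = genomic_intervals("chrZ", 0, 10)),
    "absent")
})

test_that("p-value to score threshold matches the exact null by enumeration", {
  # small motif: enumerate all 4^5 windows directly as the oracle
  p <- pwm_from_consensus("ACGTA", mismatch_prob = 0.05)
  lo <- log2(pmax(p$matrix, 1e-6) / 0.25)
  grid <- expand.grid(rep(list(1:4), 5))
  scores <- apply(grid, 1, function(w)
    sum(lo[cbind(w, 1:5)]))
  for (pv in c(0.05, 0.01, 1e-3)) {
    thr <- pwm_threshold_from_pvalue(p, pv)
    expect_lte(mean(scores >= thr), pv + 1e-12)
    # the next achievable threshold below would exceed pv
    below <- max(scores[scores < thr - 1e-9], -Inf)
    if (is.finite(below))
      expect_gt(mean(scores >= below - 1e-9), pv)
  }
})

test_that("matched random peaks preserve the signed TSS-distance multiset", {
  g <- toy_genome(1e6)
  genes <- toy_genes(40, len = 1e6, seed = 5)
  # single gene, single peak: placement at the same signed distance
  g1 <- gene_annotation(data.frame(gene_id = "g1", chrom = "chr1",
                                   strand = "-", tss = 5e5,
                                   exonic_bp = 1000))
  pk1 <- peak_set(genomic_intervals("chr1", 400000, 400200), "F")
  m1 <- matched_random_peaks(pk1, g1, g, seed = 1)
  d_obs <- cistromics:::nearest_tss_distance(pk1, g1)$distance
  d_new <- cistromics:::nearest_tss_distance(m1, g1)$distance
  expect_equal(d_new, d_obs)
  # 200 peaks: exact multiset equality and consistent geometry, several seeds
  pk <- random_peaks(200, "F", len = 1e6, seed = 8)
  nt <- cistromics:::nearest_tss_distance(pk, genes)
  d0 <- sort(nt$distance)
  for (seed in 1:5) {
    m <- matched_random_peaks(pk, genes, g, seed = seed)
    expect_equal(n_peaks(m), n_peaks(pk))
    asn <- attr(m, "assignment")
    # exact multiset equality of carried signed distances
    expect_identical(sort(asn$distance), d0)
    # the gene list is a permutation of the observed nearest-gene list
    expect_identical(sort(asn$gene_id), sort(nt$gene_id))
    # geometry: each matched center sits at the carried signed distance
    # from its assigned gene's TSS, oriented by that gene's strand
    gm <- genes[match(asn$gene_id, genes$gene_id), ]
    ctr <- interval_center(m)
    expect_equal(ifelse(gm$strand == "+", ctr - gm$tss, gm$tss - ctr),
                 asn$distance)
  }
  # different seeds give different permutations
  m1 <- matched_random_peaks(pk, genes, g, seed = 1)
  m2 <- matched_random_peaks(pk, genes, g, seed = 2)
  expect_false(identical(attr(m1, "assignment")$gene_id,
                         attr(m2, "assignment")$gene_id))
})

test_that("motif_enrichment matches the exact binomial oracle on toys", {
  g <- toy_genome(1e5)
  pk <- random_peaks(20, "F", len = 1e5, seed = 30)
  occ <- with_seed_test(4, data.frame(
    chrom = "chr1", position = sort(sample.int(99000, 150)),
    strand = "+", score = 8))
  class(occ) <- c("motif_occurrences", "data.frame")
  matched <- lapply(1:3, function(i)
    random_peaks(20, "M", len = 1e5, seed = 300 + i))
  me <- motif_enrichment(pk, occ, matched)
  n_am <- sum(vapply(seq_len(nrow(occ)), function(i)
    any(abs(occ$position[i] - interval_center(pk)) <= 150), TRUE))
  expect_equal(me$n_am, n_am)
  n_m <- mean(vapply(matched, function(m)
    sum(vapply(seq_len(nrow(occ)), function(i)
      any(abs(occ$position[i] - interval_center(m)) <= 150), TRUE)), 0))
  expect_equal(me$n_m, n_m)
  orc <- oracle_binom_upper(me$n_am, 20, min(1, n_m / (300 * 20)))
  expect_equal(me$p_value, orc$p, tolerance = 1e-10)
  # no occurrences anywhere: N_Am = 0, p = 1
  empty <- occ[0, , drop = FALSE]
  me0 <- motif_enrichment(pk, empty, matched)
  expect_equal(me0$n_am, 0)
  expect_equal(me0$p_value, 1)
  expect_equal(me0$coverage, 0)
  expect_error(motif_enrichment(pk[0, ], occ, matched), "empty")
})

test_that("coverage saturates at 1 when every peak holds a motif", {
  pk <- random_peaks(25, "F", len = 5e4, seed = 31)
  occ <- data.frame(chrom = "chr1", position = interval_center(pk),
                    strand = "+", score = 10)
  me <- motif_enrichment(pk, occ, list(random_peaks(25, "M", len = 5e4,
                                                    seed = 32)))
  expect_equal(me$coverage, 1)
})

test_that("motif distance profiles are centered, normalized, and flag empties", {
  pk <- random_peaks(40, "F", len = 1e5, seed = 33)
  occ0 <- data.frame(chrom = "chr1", position = interval_center(pk),
                     strand = "+", score = 1)
  pr <- motif_distance_profile(pk, occ0)
  expect_false(pr$empty)
  expect_equal(pr$x[which.max(pr$density)], 0, tolerance = 5)
  step <- diff(pr$x[1:2])
  expect_equal(sum(pr$density * step), 1, tolerance = 1e-6)
  pr0 <- motif_distance_profile(pk, occ0[0, , drop = FALSE])
  expect_true(pr0$empty)
  # uniform placements: flat profile, KS test does not reject
  occu <- with_seed_test(6, data.frame(
    chrom = "chr1",
    position = rep(interval_center(pk), each = 20) +
      sample(-300:300, 800, replace = TRUE),
    strand = "+", score = 1))
  pru <- motif_distance_profile(pk, occu, bandwidth = 40)
  ks <- suppressWarnings(stats::ks.test(pru$distances, "punif", -300, 300))
  expect_gt(ks$p.value, 0.01)
})

test_that("MEME minimal and TSV PWM files round-trip", {
  p <- pwm_from_consensus("TCAAGT", mismatch_prob = 0.02, name = "toy")
  f <- withr::local_tempfile(fileext = ".meme")
  write_pwms(p, f)
  back <- read_pwms(f)
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$name, "toy")
  expect_equal(back[[1]]$matrix, p$matrix, tolerance = 1e-5)
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(p$matrix, ftsv, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  b2 <- read_pwms(ftsv)[[1]]
  expect_equal(b2$matrix, p$matrix, tolerance = 1e-9, ignore_attr = TRUE)
})
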