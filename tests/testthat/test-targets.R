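test_that("flank domains are exact and clipped at chromosome edges", {
  g <- toy_genome(2e6)
  genes <- gene_annotation(data.frame(
    gene_id = c("mid", "edge"), chrom = "chr1", strand = "+",
    tss = c(1e6, 1e4), exonic_bp = 1000), genome = g)
  d <- build_domains(genes, g, mode = "flank_500kb")
  dm <- d$domains
  expect_equal(dm$end[dm$gene_id == "mid"] - dm$start[dm$gene_id == "mid"],
               1e6)
  expect_lt(dm$end[dm$gene_id == "edge"] - dm$start[dm$gene_id == "edge"],
            1e6)
  expect_equal(dm$start[dm$gene_id == "edge"], 0)
  expect_error(build_domains(genes, g, mode = "nope"), "arg")
})

test_that("single-nearest domains partition at midpoints (bitmap oracle)", {
  g <- toy_genome(2e4)
  genes <- gene_annotation(data.frame(
    gene_id = c("L", "R"), chrom = "chr1", strand = c("+", "-"),
    tss = c(9000, 11000), exonic_bp = 1000), genome = g)
  d <- build_domains(genes, g, mode = "great_single_nearest",
                     extension = 5e5)
  dm <- d$domains
  # midpoint 10000; equidistant base goes left
  expect_equal(dm$end[dm$gene_id == "L"], 10001)
  expect_equal(dm$start[dm$gene_id == "R"], 10001)
  # per-base nearest-TSS bitmap on random layouts
  for (seed in 1:4) {
    genes_r <- toy_genes(8, len = 2e4, seed = seed)
    dr <- build_domains(genes_r, g, mode = "great_single_nearest",
                        extension = 3000)$domains
    owner <- rep(NA_character_, 2e4)
    for (b in 0:(2e4 - 1)) {
      dd <- abs(genes_r$tss - b)
      cand <- which(dd == min(dd))
      j <- cand[which.min(genes_r$tss[cand])]
      # half-open extension cap: [tss - ext, tss + ext)
      if (b - genes_r$tss[j] >= -3000 && b - genes_r$tss[j] < 3000)
        owner[b + 1] <- genes_r$gene_id[j]
    }
    for (k in seq_len(nrow(dr))) {
      span <- (dr$start[k] + 1):dr$end[k]
      expect_true(all(owner[span] == dr$gene_id[k]),
                  info = paste("seed", seed, dr$gene_id[k]))
    }
    # complete: every owned base is covered by exactly one domain
    covered <- sum(dr$end - dr$start)
    expect_equal(covered, sum(!is.na(owner)))
  }
})

test_that("basal-plus-extension respects basal floors and neighbor caps", {
  g <- toy_genome(2e6)
  genes <- gene_annotation(data.frame(
    gene_id = c("a", "b"), chrom = "chr1", strand = "+",
    tss = c(1e6, 1.05e6), exonic_bp = 1000), genome = g)
  d <- build_domains(genes, g, mode = "great_basal_extension")$domains
  # a extends right only up to b's basal start (b tss - 5 kb); b extends
  # left to a's basal end, so the intergenic span is claimed by both
  expect_equal(d$end[d$gene_id == "a"], 1.05e6 - 5000)
  expect_equal(d$start[d$gene_id == "b"], 1e6 + 1000)
  # a extends left the full 500 kb (no left neighbor)
  expect_equal(d$start[d$gene_id == "a"], 1e6 - 5e5)
  # basal never truncated: very close genes keep their basal spans
  close_genes <- gene_annotation(data.frame(
    gene_id = c("p", "q"), chrom = "chr1", strand = "+",
    tss = c(1e6, 1.001e6), exonic_bp = 1000), genome = g)
  dc <- build_domains(close_genes, g, mode = "great_basal_extension")$domains
  expect_gte(dc$end[dc$gene_id == "p"], 1e6 + 1000)
  expect_lte(dc$start[dc$gene_id == "q"], 1.001e6 - 5000)
})

test_that("assign_targets matches the linear nearest-TSS scan oracle", {
  g <- toy_genome(1e6)
  genes <- toy_genes(20, len = 1e6, seed = 77)
  d <- build_domains(genes, g, mode = "great_single_nearest",
                     extension = 5e5)
  # peak centered on a TSS is assigned to that gene
  on_tss <- peak_set(genomic_intervals("chr1", genes$tss[3] - 100,
                                       genes$tss[3] + 100), "P")
  a <- assign_targets(on_tss, d)
  expect_equal(a$assignments$gene_id, genes$gene_id[3])
  # peak 600 kb beyond the only gene is unassigned
  lone <- gene_annotation(data.frame(gene_id = "solo", chrom = "chr1",
                                     strand = "+", tss = 1e5,
                                     exonic_bp = 500), genome = g)
  d_lone <- build_domains(lone, g, mode = "great_single_nearest",
                          extension = 5e5)
  far <- peak_set(genomic_intervals("chr1", 7e5, 7e5 + 200), "P")
  expect_equal(nrow(assign_targets(far, d_lone)$assignments), 0)
  # random peaks vs oracle; single-nearest gives <= 1 gene per peak
  for (seed in 1:4) {
    pk <- random_peaks(100, "P", len = 1e6, seed = seed)
    asn <- assign_targets(pk, d, genes)$assignments
    expect_lte(max(table(factor(asn$peak_id, levels = pk$peak_id))), 1)
    orc <- oracle_assign_nearest(pk, genes, cap = 5e5)
    got <- asn$gene_id[match(pk$peak_id, asn$peak_id)]
    expect_equal(got, orc, info = paste("seed", seed))
  }
})

test_that("assign_targets annotates strand-oriented TSS distances", {
  g <- toy_genome(1e6)
  genes <- gene_annotation(data.frame(
    gene_id = c("plus", "minus"), chrom = "chr1", strand = c("+", "-"),
    tss = c(2e5, 8e5), exonic_bp = 1000), genome = g)
  d <- build_domains(genes, g, mode = "great_single_nearest")
  pk <- peak_set(genomic_intervals("chr1", c(190000, 810000) - 100,
                                   c(190000, 810000) + 100), "P")
  asn <- assign_targets(pk, d, genes)$assignments
  # 10 kb upstream of each TSS in its gene's orientation
  expect_equal(sort(asn$tss_distance), c(-10000, -10000))
})

test_that("region_enrichment matches the exact binomial oracle", {
  g <- toy_genome(1e6)
  genes <- toy_genes(30, len = 1e6, seed = 50)
  pk <- random_peaks(80, "P", len = 1e6, seed = 51)
  d <- build_domains(genes, g, mode = "flank_500kb", flank = 2e4)
  re <- region_enrichment(pk, genes$gene_id[1:6], genes, g, domains = d,
                          n_random = 20, seed = 4)
  # recount observed hits and sizes independently
  sub <- d$domains[d$domains$gene_id %in% genes$gene_id[1:6], ]
  merged <- merge_intervals(genomic_intervals(sub$chrom, sub$start, sub$end))
  ctr <- interval_center(pk)
  n_ax <- sum(vapply(ctr, function(cc)
    any(cc >= merged$start & cc < merged$end), TRUE))
  expect_equal(re$n_ax, n_ax)
  expect_equal(re$p_x, sum(interval_length(merged)) / 1e6)
  orc <- oracle_binom_upper(re$n_ax, re$n_a, min(1, re$p_x * re$r_ax))
  expect_equal(re$p_value, orc$p, tolerance = 1e-10)
  expect_equal(re$fold, re$n_ax / (re$n_a * re$p_x * re$r_ax))
})

test_that("region_enrichment saturates and validates inputs", {
  g <- toy_genome(1e5)
  genes <- toy_genes(10, len = 1e5, seed = 60)
  pk <- random_peaks(30, "P", len = 1e5, seed = 61)
  # domains covering the whole genome: p_x = 1, p = 1
  re <- region_enrichment(pk, genes$gene_id, genes, g, n_random = 2,
                          seed = 1, mode = "flank_500kb", flank = 5e5)
  expect_equal(re$p_x, 1)
  expect_equal(re$p_value, 1)
  expect_error(region_enrichment(pk, "ghost", genes, g), "absent")
  expect_error(region_enrichment(pk, character(0), genes, g), "empty")
})

test_that("r_Ax approaches 1 for uniform peaks and planted signal is found", {
  g <- toy_genome(2e6)
  genes <- toy_genes(60, len = 2e6, seed = 70)
  d <- build_domains(genes, g, mode = "flank_500kb", flank = 1e4)
  pk <- random_peaks(300, "P", len = 2e6, seed = 71)
  re <- region_enrichment(pk, genes$gene_id[1:10], genes, g, domains = d,
                          n_random = 50, seed = 5)
  spread <- stats::sd(re$random_ratios) / sqrt(re$n_random)
  expect_lt(abs(re$r_ax - 1), 4 * spread + 0.05)
  # peaks planted only inside the target domains are detected strongly
  sub <- d$domains[d$domains$gene_id %in% genes$gene_id[1:10], ]
  ctr <- with_seed_test(8, {
    row <- sample(nrow(sub), 200, replace = TRUE)
    floor(sub$start[row] + stats::runif(200) * (sub$end[row] - sub$start[row]))
  })
  planted <- peak_set(genomic_intervals("chr1", pmax(0, ctr - 100),
                                        ctr + 100), "planted")
  rp <- region_enrichment(planted, genes$gene_id[1:10], genes, g,
                          domains = d, n_random = 20, seed = 6)
  expect_lt(rp$p_value, 1e-6)
})

test_that("category_enrichment_table runs per cell with BH annotation", {
  g <- toy_genome(1e6)
  genes <- toy_genes(40, len = 1e6, seed = 80)
  sets <- list(F1 = random_peaks(50, "F1", len = 1e6, seed = 81),
               F2 = random_peaks(50, "F2", len = 1e6, seed = 82))
  cats <- list(all = genes$gene_id, some = genes$gene_id[1:8])
  tab <- category_enrichment_table(sets, cats, genes, g, n_random = 3,
                                   seed = 2, mode = "flank_500kb",
                                   flank = 2e4)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("fold", "p_value", "q") %in% names(tab)))
  # q is a BH adjustment of the p column, never a replacement
  expect_equal(tab$q, stats::p.adjust(tab$p_value, "BH"))
  expect_error(
    category_enrichment_table(sets, list(bad = character(0)), genes, g),
    "empty")
})
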