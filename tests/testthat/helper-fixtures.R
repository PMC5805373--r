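# Shared toy data builders. Everything is generated in code; nothing is
# read from disk unless a test writes it first.

toy_genome <- function(len = 1e5, chroms = "chr1") {
  genome_model(stats::setNames(rep(len, length(chroms)), chroms))
}

toy_genes <- function(n = 10, len = 1e5, chrom = "chr1", seed = 42) {
  with_seed_test(seed, {
    tss <- sort(sample.int(len - 200, n) + 100)
    gene_annotation(data.frame(
      gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
      strand = sample(c("+", "-"), n, replace = TRUE), tss = tss,
      exonic_bp = sample(500:3000, n, replace = TRUE),
      stringsAsFactors = FALSE))
  })
}

random_peaks <- function(n, name, len = 1e5, chrom = "chr1", width = 200,
                         seed = 7) {
  with_seed_test(seed, {
    s <- sort(sample.int(len - width - 1, n))
    peak_set(genomic_intervals(chrom, s, s + width,
                               score = round(stats::runif(n, 1, 10), 3)),
             name)
  })
}

# test-local seed scoping (mirrors the package-internal helper without
# depending on it being exported)
with_seed_test <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
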