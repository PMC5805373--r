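# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and R's pbinom) so that agreement is informative.

# upper-tail binomial P(X >= k) by direct term summation in log space
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(list(p = 1, neg_log10_p = 0))
  if (p <= 0) return(list(p = 0, neg_log10_p = Inf))
  if (p >= 1) return(list(p = 1, neg_log10_p = 0))
  ks <- k:n
  lt <- lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)
  m <- max(lt)
  lse <- m + log(sum(exp(lt - m)))
  list(p = exp(lse), neg_log10_p = -lse / log(10))
}

# per-base occupancy bitmap on toy chromosomes
oracle_coverage_bitmap <- function(ivs, chrom_len = 10000) {
  total <- 0
  for (ch in unique(ivs$chrom)) {
    bit <- logical(chrom_len)
    d <- ivs[ivs$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d)))
      bit[(d$start[i] + 1):d$end[i]] <- TRUE
    total <- total + sum(bit)
  }
  total
}

# all-pairs O(N^2) count of A peaks with a B center strictly closer than d
oracle_pairwise_overlap <- function(A, B, d = 150) {
  ca <- floor((A$start + A$end) / 2)
  cb <- floor((B$start + B$end) / 2)
  n <- 0L
  for (i in seq_along(ca)) {
    same <- B$chrom == A$chrom[i]
    if (any(same & abs(cb - ca[i]) < d)) n <- n + 1L
  }
  n
}

# greedy hotspot selection over exhaustively enumerated one-per-factor
# cliques: repeatedly take the clique whose leftmost member is smallest
# (ties: per-factor leftmost members), remove its peaks, repeat.
oracle_hotspots <- function(peak_sets, window = 1000,
                            min_factors = length(peak_sets)) {
  pool <- do.call(rbind, lapply(sort(names(peak_sets)), function(f) {
    ps <- peak_sets[[f]]
    data.frame(factor = f, peak_id = ps$peak_id, chrom = ps$chrom,
               center = floor((ps$start + ps$end) / 2),
               stringsAsFactors = FALSE)
  }))
  pool <- pool[order(pool$chrom, pool$center, pool$factor, pool$peak_id), ]
  avail <- rep(TRUE, nrow(pool))
  groups <- list()
  repeat {
    best <- NULL
    # candidate anchors in order; first that forms a clique wins
    for (i in seq_len(nrow(pool))) {
      if (!avail[i]) next
      members <- i
      for (f in setdiff(sort(unique(pool$factor)), pool$factor[i])) {
        j <- which(avail & pool$factor == f & pool$chrom == pool$chrom[i] &
                   pool$center >= pool$center[i] &
                   pool$center <= pool$center[i] + window)
        if (length(j)) members <- c(members, j[1])
      }
      if (length(members) >= min_factors &&
          !anyDuplicated(pool$factor[members])) {
        # verify clique: all pairwise distances <= window
        cs <- pool$center[members]
        if (max(cs) - min(cs) <= window) { best <- members; break }
      }
    }
    if (is.null(best)) break
    avail[best] <- FALSE
    groups[[length(groups) + 1]] <-
      sort(pool$peak_id[best])
  }
  groups
}

# position-by-position naive PWM scan of one sequence string, both strands
oracle_scan <- function(seq_str, mat, threshold, floor_prob = 1e-6) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lo <- log2(pmax(mat, floor_prob) / 0.25)
  rownames(lo) <- c("A", "C", "G", "T")
  L <- ncol(lo)
  chars <- strsplit(seq_str, "")[[1]]
  hits <- list()
  for (pos in seq_len(length(chars) - L + 1)) {
    win <- chars[pos:(pos + L - 1)]
    s_plus <- sum(vapply(seq_len(L), function(j) lo[win[j], j], 0))
    rc <- rev(unname(comp[win]))
    s_minus <- sum(vapply(seq_len(L), function(j) lo[rc[j], j], 0))
    if (s_plus >= threshold)
      hits[[length(hits) + 1]] <- data.frame(position = pos - 1,
                                             strand = "+", score = s_plus)
    if (s_minus >= threshold)
      hits[[length(hits) + 1]] <- data.frame(position = pos - 1,
                                             strand = "-", score = s_minus)
  }
  if (!length(hits))
    return(data.frame(position = numeric(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), ]
}

# per-peak linear scan: nearest TSS within `cap` of the peak center
oracle_assign_nearest <- function(peaks, genes, cap = 5e5) {
  ctr <- floor((peaks$start + peaks$end) / 2)
  res <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    same <- which(genes$chrom == peaks$chrom[i])
    if (!length(same)) { res[i] <- NA_character_; next }
    d <- abs(genes$tss[same] - ctr[i])
    j <- same[order(d, genes$tss[same])][1]
    best_d <- abs(genes$tss[j] - ctr[i])
    res[i] <- if (best_d < cap ||
                  (best_d == cap && ctr[i] < genes$tss[j]))
      genes$gene_id[j] else NA_character_
  }
  res
}

# independent re-implementation of the differential filter chain
oracle_enriched_filter <- function(tpm, sa, sb, fold = 3, min_tpm = 5,
                                   alpha = 0.05, pseudo = 0.01) {
  sel <- logical(nrow(tpm))
  for (g in seq_len(nrow(tpm))) {
    a <- tpm[g, sa]; b <- tpm[g, sb]
    fc <- (mean(a) + pseudo) / (mean(b) + pseudo)
    la <- log2(a + 1); lb <- log2(b + 1)
    p <- if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
      if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
    } else tryCatch(stats::t.test(la, lb)$p.value, error = function(e) 1)
    sel[g] <- mean(a) > min_tpm && fc > fold && p < alpha
  }
  rownames(tpm)[sel]
}
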