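# Upper-tail binomial P(X >= k), X ~ Binom(n, p), computed in log space so
# -log10 p stays finite far below double underflow (the co-binding tests
# routinely reach the 10^-300..10^-400 range).
binom_upper_tail <- function(k, n, p) {
  stopifnot(k >= 0, n >= 0, p >= 0, p <= 1)
  if (k == 0) return(list(p_value = 1, log_p = 0, neg_log10_p = 0))
  if (k > n) stop("observed count exceeds trial count")
  log_p <- stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE)
  list(p_value = exp(log_p), log_p = log_p, neg_log10_p = -log_p / log(10))
}

#' Accessible chromatin model
#'
#' The merged open-chromatin territory that the co-binding null confines
#' random peaks to. Normally built from ATAC-seq peaks via
#' [build_accessible()]; the constructor is exported for pre-merged inputs.
#'
#' @param regions disjoint `genomic_intervals` (merged internally if not).
#' @return object of class `accessible_chromatin`: list with `regions`
#'   (merged, sorted) and `total_size` (bp).
#' @export
accessible_chromatin <- function(regions) {
  if (nrow(regions) == 0) stop("accessible chromatin must be non-empty")
  merged <- merge_intervals(regions)
  structure(list(regions = merged,
                 total_size = sum(interval_length(merged))),
            class = "accessible_chromatin")
}

#' @export
print.accessible_chromatin <- function(x, ...) {
  cat(sprintf("<accessible_chromatin: %d regions, %.0f bp>\n",
              nrow(x$regions), x$total_size))
  invisible(x)
}

#' Build the accessible-chromatin null territory from ATAC-seq peaks
#'
#' ATAC peak coordinates are extended by `extend` bp on both sides, clipped
#' to chromosome bounds, and merged; the total size of the result is the
#' denominator of the per-peak overlap probability in [overlap_pvalue()].
#'
#' @param atac_peaks `peak_set` of ATAC-seq peaks.
#' @param genome `genome_model` used for clipping.
#' @param extend bp added to each side before merging (default 150, half
#'   the overlap window).
#' @return an [accessible_chromatin()] object.
#' @export
build_accessible <- function(atac_peaks, genome, extend = 150) {
  if (nrow(atac_peaks) == 0)
    stop("empty ATAC peak set: accessible-chromatin null undefined")
  ext <- genomic_intervals(atac_peaks$chrom,
                           pmax(0, atac_peaks$start - extend),
                           atac_peaks$end + extend)
  ext <- clip_to_genome(ext, genome)
  accessible_chromatin(ext)
}

# index of nearest value in sorted vector `sorted` for each x
nearest_sorted <- function(x, sorted) {
  i <- findInterval(x, sorted)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(sorted))
  ifelse(abs(x - sorted[lo]) <= abs(sorted[hi] - x), lo, hi)
}

#' Count peaks of A whose center lies near a peak of B
#'
#' Overlap between two peak sets is defined on peak centers: an A peak
#' overlaps B when some B peak center is strictly closer than
#' `max_center_dist` bp. The count is asymmetric — it is taken in A's frame
#' (`N_AB <= N_A`), so `pairwise_overlap(A, B)` and `pairwise_overlap(B, A)`
#' generally differ.
#'
#' @param A,B `peak_set`s.
#' @param max_center_dist strict center-distance threshold in bp
#'   (default 150; centers exactly 150 apart do not overlap).
#' @return list with `n_ab` (count of A peaks overlapping B), and `pairs`,
#'   a data frame of (`peak_a`, `peak_b`, `dist`) matching each overlapping
#'   A peak to its nearest B center.
#' @export
pairwise_overlap <- function(A, B, max_center_dist = 150) {
  ca <- interval_center(A)
  cb <- interval_center(B)
  hits <- logical(nrow(A))
  peak_b <- character(nrow(A))
  dist <- rep(NA_real_, nrow(A))
  for (ch in unique(A$chrom)) {
    ia <- which(A$chrom == ch)
    ib <- which(B$chrom == ch)
    if (!length(ib)) next
    o <- order(cb[ib]); ib <- ib[o]
    j <- nearest_sorted(ca[ia], cb[ib])
    d <- abs(ca[ia] - cb[ib][j])
    ok <- d < max_center_dist
    hits[ia] <- ok
    peak_b[ia[ok]] <- B$peak_id[ib][j[ok]]
    dist[ia[ok]] <- (ca[ia] - cb[ib][j])[ok]
  }
  list(n_ab = sum(hits),
       pairs = data.frame(peak_a = A$peak_id[hits],
                          peak_b = peak_b[hits],
                          dist = dist[hits],
                          stringsAsFactors = FALSE))
}

#' Binomial significance of peak-set overlap on the accessible-chromatin null
#'
#' Tests `N_AB ~ Binom(N_A, p_B)` against the null that A's peaks fall
#' uniformly into accessible chromatin, where
#' `p_B = window * N_B / accessible_size` is the chance that a random
#' accessible position lands within the overlap window of some B peak. The
#' window defaults to 300 bp, i.e. twice the 150 bp center-distance
#' threshold of [pairwise_overlap()]; changing the overlap threshold should
#' change the null consistently. The p-value is the upper tail
#' `P(X >= N_AB)` computed in log space, so `neg_log10_p` is exact even in
#' the 10^-300 regime where `p_value` itself underflows.
#'
#' @param n_a number of peaks in A (trials).
#' @param n_ab number of A peaks overlapping B (successes).
#' @param n_b number of peaks in B.
#' @param accessible_size total accessible chromatin, bp.
#' @param window overlap window length in bp (2 x max center distance).
#' @return object of class `overlap_test`: list with fields `n_a`, `n_b`,
#'   `n_ab`, `p_b`, `expected` (`n_a * p_b`), `fold`, `p_value`,
#'   `neg_log10_p`.
#' @export
overlap_pvalue <- function(n_a, n_ab, n_b, accessible_size, window = 300) {
  if (accessible_size <= 0) stop("accessible_size must be positive")
  if (n_ab > n_a) stop("n_ab cannot exceed n_a")
  if (n_a <= 0) stop("n_a must be positive")
  p_b <- window * n_b / accessible_size
  if (p_b > 1) {
    warning("p_B exceeds 1; capped (accessible chromatin saturated by B)")
    p_b <- 1
  }
  tail <- binom_upper_tail(n_ab, n_a, p_b)
  structure(list(n_a = n_a, n_b = n_b, n_ab = n_ab, p_b = p_b,
                 expected = n_a * p_b,
                 fold = if (p_b > 0) n_ab / (n_a * p_b) else NA_real_,
                 p_value = tail$p_value, neg_log10_p = tail$neg_log10_p,
                 window = window),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test: N_A=%d N_B=%d N_AB=%d p_B=%.3g expected=%.1f fold=%.2f -log10p=%.1f>\n",
    x$n_a, x$n_b, x$n_ab, x$p_b, x$expected, x$fold, x$neg_log10_p))
  invisible(x)
}

#' All-pairs overlap significance table
#'
#' Runs [pairwise_overlap()] and [overlap_pvalue()] for every ordered pair
#' of factors. Asymmetric: row (A, B) counts in A's frame.
#'
#' @param peak_sets named list of `peak_set`.
#' @param accessible `accessible_chromatin`.
#' @param max_center_dist strict center-distance threshold, bp.
#' @return data frame with one row per ordered factor pair.
#' @export
overlap_table <- function(peak_sets, accessible, max_center_dist = 150) {
  stopifnot(length(peak_sets) >= 2)
  nm <- names(peak_sets)
  rows <- list()
  for (a in nm) for (b in setdiff(nm, a)) {
    ov <- pairwise_overlap(peak_sets[[a]], peak_sets[[b]], max_center_dist)
    t <- overlap_pvalue(n_peaks(peak_sets[[a]]), ov$n_ab,
                        n_peaks(peak_sets[[b]]), accessible$total_size,
                        window = 2 * max_center_dist)
    rows[[paste(a, b)]] <- data.frame(
      set_a = a, set_b = b, n_a = t$n_a, n_b = t$n_b, n_ab = t$n_ab,
      p_b = t$p_b, expected = t$expected, fold = t$fold,
      p_value = t$p_value, neg_log10_p = t$neg_log10_p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find multi-factor regulatory hotspots
#'
#' A hotspot is a site where (at least) `min_factors` of the profiled
#' factors bind within `window` bp of each other: one peak per factor, all
#' pairwise center distances at most `window` (a clique rule, not a chained
#' rule). Groups are resolved by a greedy left-to-right sweep over pooled
#' sorted centers: the leftmost unused peak anchors a candidate window
#' `[c, c + window]`; every factor with an unused peak in that window
#' contributes its leftmost such peak; the group is emitted when enough
#' factors are present. Each peak joins at most one hotspot. The result is
#' invariant to input ordering and factor relabeling.
#'
#' @param peak_sets named list of `peak_set` (>= 2 factors).
#' @param window maximum pairwise center distance, bp (default 1000).
#' @param min_factors number of distinct factors required; defaults to all.
#' @return data frame of class `hotspots`: one row per hotspot with
#'   `chrom`, `start`, `end` (spanning member centers, half-open),
#'   `n_factors`, `members` (comma-separated peak ids) and one
#'   `peak_<factor>` column per factor (peak id or NA).
#' @export
find_hotspots <- function(peak_sets, window = 1000,
                          min_factors = length(peak_sets)) {
  if (length(peak_sets) < 2) stop("need at least 2 factors")
  if (min_factors < 2 || min_factors > length(peak_sets))
    stop("min_factors must be between 2 and the number of factors")
  factors <- sort(names(peak_sets))
  pool <- do.call(rbind, lapply(factors, function(f) {
    ps <- peak_sets[[f]]
    data.frame(factor = f, peak_id = ps$peak_id, chrom = ps$chrom,
               center = interval_center(ps), stringsAsFactors = FALSE)
  }))
  # deterministic order: chrom, center, then factor/peak id for exact ties
  pool <- pool[order(pool$chrom, pool$center, pool$factor, pool$peak_id), ]
  rownames(pool) <- NULL
  used <- logical(nrow(pool))
  out <- list()
  for (i in seq_len(nrow(pool))) {
    if (used[i]) next
    in_win <- which(!used & pool$chrom == pool$chrom[i] &
                    pool$center >= pool$center[i] &
                    pool$center <= pool$center[i] + window)
    # leftmost unused peak per factor inside the window (pool is sorted)
    first <- in_win[!duplicated(pool$factor[in_win])]
    if (length(first) < min_factors) next
    used[first] <- TRUE
    g <- pool[first, , drop = FALSE]
    row <- data.frame(chrom = g$chrom[1],
                      start = min(g$center), end = max(g$center) + 1,
                      n_factors = nrow(g),
                      members = paste(g$peak_id[order(g$factor)],
                                      collapse = ","),
                      stringsAsFactors = FALSE)
    for (f in factors)
      row[[paste0("peak_", f)]] <-
        if (f %in% g$factor) g$peak_id[g$factor == f] else NA_character_
    out[[length(out) + 1]] <- row
  }
  res <- if (length(out)) do.call(rbind, out)
         else {
    res0 <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), n_factors = integer(0),
                       members = character(0), stringsAsFactors = FALSE)
    for (f in factors) res0[[paste0("peak_", f)]] <- character(0)
    res0
  }
  rownames(res) <- NULL
  attr(res, "window") <- window
  attr(res, "min_factors") <- min_factors
  attr(res, "grouping_rule") <- "clique_greedy_leftmost"
  class(res) <- c("hotspots", "data.frame")
  res
}

#' Hotspots as a peak set
#'
#' Wraps hotspot spans as a `peak_set` so hotspots can enter the same
#' domain-enrichment machinery as single-factor peaks.
#'
#' @param hs result of [find_hotspots()].
#' @param name label (default "hotspots").
#' @return a [peak_set()].
#' @export
hotspots_as_peaks <- function(hs, name = "hotspots") {
  if (nrow(hs) == 0) stop("no hotspots to convert")
  peak_set(genomic_intervals(hs$chrom, hs$start, hs$end), name)
}

#' Asymmetric overlap ratio between target gene sets
#'
#' `|A intersect B| / |A|`, in A's frame.
#'
#' @param targets_a,targets_b character vectors of gene ids; A non-empty.
#' @return ratio in `[0, 1]`.
#' @export
target_set_overlap_ratio <- function(targets_a, targets_b) {
  targets_a <- unique(targets_a); targets_b <- unique(targets_b)
  if (length(targets_a) == 0) stop("set A must be non-empty")
  length(intersect(targets_a, targets_b)) / length(targets_a)
}

#' Core targets: genes targeted by every factor
#'
#' Exact n-way intersection of per-factor target gene sets. A gene
#' qualifies through any of its peaks — the factors' peaks need not be at
#' a shared site.
#'
#' @param target_sets list (>= 2) of character vectors of gene ids.
#' @return character vector of genes present in every set.
#' @export
core_targets <- function(target_sets) {
  if (length(target_sets) < 2) stop("need at least 2 target sets")
  sort(Reduce(intersect, lapply(target_sets, unique)))
}

#' Partition one factor's peaks by which other factors co-bind
#'
#' Splits a scored reference peak set (e.g. Six2) by the exact combination
#' of other factors bound at each peak under the center-distance overlap
#' rule, and summarizes the score distribution per combination — the
#' "co-binding strengthens binding" analysis.
#'
#' @param ref `peak_set` carrying scores.
#' @param others named list of other factors' `peak_set`s (may be empty).
#' @param max_center_dist strict center-distance threshold, bp.
#' @return list with `assignment` (per-peak combination label) and
#'   `summary` (per-combination n, mean, median score; combinations sorted
#'   by number of co-bound factors).
#' @export
strength_by_combination <- function(ref, others, max_center_dist = 150) {
  if (any(is.nan(ref$score)))
    stop("reference peaks must carry scores")
  combo <- rep("", nrow(ref))
  for (f in sort(names(others))) {
    ov <- pairwise_overlap(ref, others[[f]], max_center_dist)
    hit <- ref$peak_id %in% ov$pairs$peak_a
    combo[hit] <- paste0(combo[hit], ifelse(nzchar(combo[hit]), "+", ""), f)
  }
  combo[!nzchar(combo)] <- "none"
  assignment <- data.frame(peak_id = ref$peak_id, score = ref$score,
                           combination = combo, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(assignment, assignment$combination),
    function(d) data.frame(combination = d$combination[1], n = nrow(d),
                           mean_score = mean(d$score),
                           median_score = stats::median(d$score),
                           n_cofactors = if (d$combination[1] == "none") 0L
                                         else lengths(strsplit(d$combination[1], "+", fixed = TRUE)),
                           stringsAsFactors = FALSE)))
  agg <- agg[order(-agg$n_cofactors, agg$combination), ]
  rownames(agg) <- NULL
  list(assignment = assignment, summary = agg)
}
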