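#' Position weight matrix
#'
#' Column-stochastic 4 x L matrix over A, C, G, T. Occurrences are scored
#' by log2 odds against a uniform background; the detection threshold is a
#' score, derivable from a scan p-value via [pwm_threshold_from_pvalue()].
#'
#' @param matrix 4 x L numeric matrix, rows A/C/G/T, columns summing to 1.
#' @param name motif label.
#' @param threshold log2-odds detection threshold (default `-Inf`, i.e.
#'   report everything; set one before scanning real data).
#' @return object of class `pwm`.
#' @export
pwm <- function(matrix, name = "motif", threshold = -Inf) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4) stop("PWM must have length >= 4")
  if (any(abs(colSums(matrix) - 1) > 1e-9))
    stop("PWM columns must sum to 1")
  dimnames(matrix) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(matrix = matrix, name = name, threshold = threshold,
                 length = ncol(matrix)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm '%s': length %d, threshold %.3g>\n",
              x$name, x$length, x$threshold))
  invisible(x)
}

#' Build a PWM from a consensus sequence
#'
#' Each position puts probability `1 - 3 * mismatch_prob` on the consensus
#' base; `N` means uniform. Convenient for planting and recovering known
#' sites in simulations.
#'
#' @param consensus string over `ACGTN`.
#' @param mismatch_prob per-alternative-base probability (default 0.01).
#' @param name motif label (default: the consensus itself).
#' @return a [pwm()].
#' @export
pwm_from_consensus <- function(consensus, mismatch_prob = 0.01,
                               name = consensus) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T", "N")))
    stop("consensus must be over ACGTN")
  m <- vapply(bases, function(b) {
    if (b == "N") rep(0.25, 4)
    else {
      p <- rep(mismatch_prob, 4)
      p[match(b, c("A", "C", "G", "T"))] <- 1 - 3 * mismatch_prob
      p
    }
  }, numeric(4))
  pwm(m, name = name)
}

# log2-odds score matrix against uniform background, with a floor so that
# zero-probability cells stay finite
pwm_logodds <- function(x, floor_prob = 1e-6) {
  log2(pmax(x$matrix, floor_prob) / 0.25)
}

#' Map a scan p-value to a log-odds score threshold
#'
#' Computes the exact null distribution of the PWM log-odds score for a
#' random uniform-background window by dynamic programming over columns
#' (scores discretized to `digits` decimals), then returns the smallest
#' score `s` with `P(S >= s) <= pvalue` under that null.
#'
#' @param x a [pwm()].
#' @param pvalue per-window type-I rate, e.g. `2e-4`.
#' @param digits score discretization for the DP (default 4).
#' @return numeric score threshold.
#' @export
pwm_threshold_from_pvalue <- function(x, pvalue, digits = 4) {
  lo <- round(pwm_logodds(x), digits)
  dist <- c("0" = 1)  # score -> probability
  for (j in seq_len(ncol(lo))) {
    s <- as.numeric(names(dist))
    new_s <- as.vector(outer(lo[, j], s, `+`))
    new_p <- as.vector(outer(rep(0.25, 4), dist, `*`))
    key <- sprintf("%.*f", digits, new_s)
    dist <- vapply(split(new_p, key), sum, 0)
  }
  s <- as.numeric(names(dist))
  o <- order(s, decreasing = TRUE)
  tail_p <- cumsum(dist[o])
  ok <- which(tail_p <= pvalue + 1e-12)
  if (!length(ok)) return(max(s) + 10^(-digits))  # nothing passes
  s[o][max(ok)]
}

#' Read PWMs from MEME minimal format or a 4 x L TSV
#'
#' MEME minimal files may contain several motifs (all are returned); a TSV
#' holds one motif as four rows (A, C, G, T) of probabilities, optionally
#' with row names in the first column.
#'
#' @param path motif file.
#' @param format `"meme"` or `"tsv"`; guessed from content by default.
#' @return list of [pwm()] objects (length one for TSV).
#' @export
read_pwms <- function(path, format = c("auto", "meme", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(grepl("^MOTIF", lines))) "meme" else "tsv"
  if (format == "tsv") {
    dt <- data.table::fread(path, header = FALSE)
    if (is.character(dt[[1]])) dt <- dt[, -1]
    m <- as.matrix(dt)
    if (nrow(m) != 4 && ncol(m) == 4) m <- t(m)
    return(list(pwm(m, name = sub("\\.[^.]+$", "", basename(path)))))
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop(path, ": no MOTIF entries")
  lapply(starts, function(i) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[i])), "\\s+")[[1]][1]
    j <- i + 1
    while (j <= length(lines) && !grepl("^letter-probability", lines[j]))
      j <- j + 1
    if (j > length(lines)) stop(path, ": motif without probability matrix")
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[j]))
    rows <- lines[(j + 1):(j + w)]
    m <- t(vapply(rows,
                  function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(4)))
    # MEME rows are positions; renormalize away rounding in the file
    p <- pwm(apply(t(m), 2, function(cl) cl / sum(cl)), name = name)
    p
  })
}

#' Write a PWM in MEME minimal format
#'
#' @param x a [pwm()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(x, path) {
  if (inherits(x, "pwm")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in x) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      p$length), con)
    writeLines(apply(p$matrix, 2,
                     function(cl) paste(sprintf("%.6f", cl), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

# integer codes 1..4 for ACGT, NA otherwise
seq_to_codes <- function(s) {
  match(strsplit(as.character(s), "")[[1]], c("A", "C", "G", "T"))
}

revcomp_pwm_logodds <- function(lo) {
  lo[4:1, ncol(lo):1, drop = FALSE]
}

# score every window start on one coded strand with one log-odds matrix;
# returns numeric vector of window scores (NA where the window held non-ACGT)
score_windows <- function(codes, lo) {
  L <- ncol(lo)
  n <- length(codes) - L + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- lo[, j][codes[j:(j + n - 1)]]
    sc <- sc + v
  }
  sc
}

#' Scan sequences for PWM occurrences
#'
#' Scores every window on both strands by log2 odds against a uniform
#' background and reports windows at or above the threshold. The minus
#' strand is scanned with the reverse-complemented matrix, so a reported
#' minus-strand occurrence at `position` means the motif's reverse
#' complement starts there on the plus strand. Deterministic.
#'
#' @param seqs `DNAStringSet` (names are chromosome names) or a single
#'   character string.
#' @param x a [pwm()].
#' @param regions optional `genomic_intervals` restricting the scan;
#'   windows are kept when they start inside a region. `NULL` scans
#'   everything.
#' @param threshold score cutoff; defaults to the PWM's own threshold.
#' @return data frame of class `motif_occurrences`: `chrom`, `position`
#'   (0-based window start), `strand`, `score`.
#' @export
scan_pwm <- function(seqs, x, regions = NULL, threshold = x$threshold) {
  if (is.character(seqs))
    seqs <- Biostrings::DNAStringSet(c(seq1 = seqs))
  lo <- pwm_logodds(x)
  lo_rc <- revcomp_pwm_logodds(lo)
  out <- list()
  for (ch in names(seqs)) {
    codes <- match(strsplit(as.character(seqs[[ch]]), "")[[1]],
                   c("A", "C", "G", "T"))
    for (str in c("+", "-")) {
      sc <- score_windows(codes, if (str == "+") lo else lo_rc)
      hit <- which(!is.na(sc) & sc >= threshold)
      if (length(hit))
        out[[paste(ch, str)]] <- data.frame(
          chrom = ch, position = hit - 1, strand = str, score = sc[hit],
          stringsAsFactors = FALSE)
    }
  }
  occ <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(0), position = numeric(0),
                         strand = character(0), score = numeric(0),
                         stringsAsFactors = FALSE)
  if (!is.null(regions) && nrow(occ)) {
    bad_chr <- setdiff(unique(regions$chrom), names(seqs))
    if (length(bad_chr))
      stop("region chromosome(s) absent from sequence: ",
           paste(bad_chr, collapse = ", "))
    keep <- logical(nrow(occ))
    for (i in seq_len(nrow(regions)))
      keep <- keep | (occ$chrom == regions$chrom[i] &
                      occ$position >= regions$start[i] &
                      occ$position < regions$end[i])
    occ <- occ[keep, , drop = FALSE]
  } else if (!is.null(regions)) {
    bad_chr <- setdiff(unique(regions$chrom), names(seqs))
    if (length(bad_chr))
      stop("region chromosome(s) absent from sequence: ",
           paste(bad_chr, collapse = ", "))
  }
  occ <- occ[order(occ$chrom, occ$position, occ$strand), , drop = FALSE]
  rownames(occ) <- NULL
  class(occ) <- c("motif_occurrences", "data.frame")
  occ
}

# signed distance from each peak center to its nearest TSS, oriented by the
# gene's strand: negative = upstream of the TSS, positive = downstream
nearest_tss_distance <- function(peaks, genes) {
  ctr <- interval_center(peaks)
  gene_idx <- integer(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    ip <- which(peaks$chrom == ch)
    ig <- which(genes$chrom == ch)
    if (!length(ig)) stop("no gene on chromosome ", ch)
    o <- order(genes$tss[ig]); ig <- ig[o]
    gene_idx[ip] <- ig[nearest_sorted(ctr[ip], genes$tss[ig])]
  }
  raw <- ctr - genes$tss[gene_idx]
  signed <- ifelse(genes$strand[gene_idx] == "+", raw, -raw)
  data.frame(peak_id = peaks$peak_id, gene_id = genes$gene_id[gene_idx],
             distance = signed, stringsAsFactors = FALSE)
}

#' Matched random peak set preserving TSS distances
#'
#' Builds a null peak set with the same number of peaks as the input, in
#' which every observed peak's signed distance to its nearest TSS (oriented
#' by gene strand; negative = upstream) is preserved exactly, but the gene
#' each distance is attached to is a uniform random permutation of the
#' observed nearest-gene list. This keeps the promoter-proximity profile of
#' the observed set while scrambling which genes are hit — the background
#' used by [motif_enrichment()]. Peak widths are carried over with their
#' distances. If any permuted placement falls off its chromosome, a fresh
#' permutation is drawn (up to `max_retries`); the retry count is recorded
#' in attribute `retries`.
#'
#' @param peaks observed `peak_set`.
#' @param genes `gene_annotation`.
#' @param genome `genome_model`.
#' @param seed integer seed.
#' @param max_retries permutation redraws before giving up.
#' @return a `peak_set` named `<name>_matched`, with attribute
#'   `assignment` (data frame `peak_id`, `gene_id`, `distance`,
#'   `source_peak`) recording the permuted gene and carried distance per
#'   matched peak, and attribute `retries`.
#' @export
matched_random_peaks <- function(peaks, genes, genome, seed,
                                 max_retries = 100) {
  nt <- nearest_tss_distance(peaks, genes)
  widths <- interval_length(peaks)
  n <- nrow(nt)
  # validity of pairing peak i (its distance and width) with gene row gi
  pair_ok <- function(i, gi) {
    ctr <- if (genes$strand[gi] == "+") genes$tss[gi] + nt$distance[i]
           else genes$tss[gi] - nt$distance[i]
    s <- ctr - floor(widths[i] / 2)
    s >= 0 && s + widths[i] <= genome$chrom_sizes[[genes$chrom[gi]]]
  }
  gene_rows <- match(nt$gene_id, genes$gene_id)
  with_seed(seed, {
    for (try in 0:max_retries) {
      perm <- sample.int(n)
      # repair off-chromosome pairings by swapping permutation entries,
      # which preserves both multisets exactly
      for (pass in 1:10) {
        invalid <- which(!vapply(seq_len(n), function(i)
          pair_ok(i, gene_rows[perm[i]]), TRUE))
        if (!length(invalid)) break
        for (i in invalid) {
          js <- sample.int(n, min(n, 50))
          for (j in js) {
            if (pair_ok(i, gene_rows[perm[j]]) &&
                pair_ok(j, gene_rows[perm[i]])) {
              perm[c(i, j)] <- perm[c(j, i)]
              break
            }
          }
        }
      }
      invalid <- which(!vapply(seq_len(n), function(i)
        pair_ok(i, gene_rows[perm[i]]), TRUE))
      if (length(invalid)) next  # full redraw
      g <- genes[gene_rows[perm], , drop = FALSE]
      ctr <- ifelse(g$strand == "+", g$tss + nt$distance,
                    g$tss - nt$distance)
      start <- ctr - floor(widths / 2)
      end <- start + widths
      o <- order(g$chrom, start, end)  # mirror peak_set() sorting
      out <- peak_set(genomic_intervals(g$chrom[o], start[o], end[o]),
                      paste0(peak_set_name(peaks), "_matched"))
      attr(out, "retries") <- try
      attr(out, "assignment") <- data.frame(
        peak_id = out$peak_id, gene_id = g$gene_id[o],
        distance = nt$distance[o],
        source_peak = nt$peak_id[o], stringsAsFactors = FALSE)
      return(out)
    }
    stop("could not place matched random peaks after ", max_retries,
         " permutation redraws")
  })
}

# count occurrences whose position falls within +/- window of any center
count_occurrences_near <- function(occurrences, peaks, window = 150) {
  if (nrow(occurrences) == 0) return(0L)
  ctr <- interval_center(peaks)
  n <- 0L
  for (ch in unique(occurrences$chrom)) {
    io <- which(occurrences$chrom == ch)
    ic <- which(peaks$chrom == ch)
    if (!length(ic)) next
    cc <- sort(ctr[ic])
    j <- nearest_sorted(occurrences$position[io], cc)
    n <- n + sum(abs(occurrences$position[io] - cc[j]) <= window)
  }
  n
}

#' Motif enrichment against matched random backgrounds
#'
#' Tests `N_Am ~ Binom(N_A, p_m)` where `N_Am` is the number of motif
#' occurrences within `window` bp of observed peak centers, `N_m` the mean
#' of the same count over TSS-distance-matched random peak sets, and
#' `p_m = N_m / (2 * window * N_A)`, capped at 1. The statistic treats the
#' per-bp background rate as a per-peak success probability over `N_A`
#' trials; that is the convention implemented here. A dimensionally
#' conventional alternative using `2 * window * N_A` Bernoulli trials is
#' available with `per_bp_trials = TRUE`. When no occurrence is seen near
#' any matched set, `N_m` is floored at one occurrence spread over all
#' matched sets so the p-value stays positive (documented conservative
#' floor).
#'
#' @param peaks observed `peak_set` (`N_A` > 0).
#' @param occurrences genome-wide [scan_pwm()] output.
#' @param matched_sets list (>= 1) of matched random `peak_set`s, e.g. from
#'   [matched_random_peaks()] with distinct seeds.
#' @param window half-window around peak centers, bp (default 150).
#' @param per_bp_trials use `2 * window * N_A` trials instead of `N_A`.
#' @return object of class `motif_enrichment_test` with fields `n_a`,
#'   `n_am`, `n_m`, `p_m`, `p_value`, `neg_log10_p`, `coverage` (fraction
#'   of peaks with at least one occurrence in the window), `n_matched_sets`.
#' @export
motif_enrichment <- function(peaks, occurrences, matched_sets,
                             window = 150, per_bp_trials = FALSE) {
  if (n_peaks(peaks) == 0) stop("empty peak set")
  if (length(matched_sets) < 1) stop("need at least one matched set")
  n_a <- n_peaks(peaks)
  n_am <- count_occurrences_near(occurrences, peaks, window)
  n_m <- mean(vapply(matched_sets,
                     function(m) count_occurrences_near(occurrences, m, window),
                     0L))
  n_m_floored <- max(n_m, 1 / length(matched_sets))
  trials <- if (per_bp_trials) 2 * window * n_a else n_a
  p_m <- min(1, n_m_floored / (2 * window * n_a))
  if (n_am > trials) {
    warning("observed occurrence count exceeds trial count; ",
            "upper tail is empty (p reported as 0)")
    tail <- list(p_value = 0, neg_log10_p = Inf)
  } else {
    tail <- binom_upper_tail(n_am, trials, p_m)
  }
  ctr_cov <- covered_peak_fraction(peaks, occurrences, window)
  structure(list(n_a = n_a, n_am = n_am, n_m = n_m, p_m = p_m,
                 trials = trials, per_bp_trials = per_bp_trials,
                 p_value = tail$p_value, neg_log10_p = tail$neg_log10_p,
                 coverage = ctr_cov, n_matched_sets = length(matched_sets),
                 window = window),
            class = "motif_enrichment_test")
}

covered_peak_fraction <- function(peaks, occurrences, window) {
  if (nrow(occurrences) == 0) return(0)
  ctr <- interval_center(peaks)
  cov <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    ic <- which(peaks$chrom == ch)
    io <- which(occurrences$chrom == ch)
    if (!length(io)) next
    pos <- sort(occurrences$position[io])
    j <- nearest_sorted(ctr[ic], pos)
    cov[ic] <- abs(ctr[ic] - pos[j]) <= window
  }
  mean(cov)
}

#' @export
print.motif_enrichment_test <- function(x, ...) {
  cat(sprintf(
    "<motif_enrichment: N_A=%d N_Am=%d N_m=%.2f p_m=%.3g coverage=%.1f%% -log10p=%.1f>\n",
    x$n_a, x$n_am, x$n_m, x$p_m, 100 * x$coverage, x$neg_log10_p))
  invisible(x)
}

#' Smoothed motif-to-peak-center distance profile
#'
#' Signed distances from each occurrence to its nearest peak center,
#' restricted to `[-window, window]`, smoothed with a Gaussian kernel.
#' Integrates to 1 when any occurrence falls in the window.
#'
#' @param peaks `peak_set`.
#' @param occurrences [scan_pwm()] output.
#' @param window half-window, bp (default 300).
#' @param bandwidth Gaussian kernel sd, bp (default 25).
#' @return list of class `motif_distance_profile` with `x`, `density`,
#'   `distances`, `n`, `empty`.
#' @export
motif_distance_profile <- function(peaks, occurrences, window = 300,
                                   bandwidth = 25) {
  ctr <- interval_center(peaks)
  d <- numeric(0)
  for (ch in unique(occurrences$chrom)) {
    io <- which(occurrences$chrom == ch)
    ic <- which(peaks$chrom == ch)
    if (!length(ic)) next
    cc <- sort(ctr[ic])
    j <- nearest_sorted(occurrences$position[io], cc)
    d <- c(d, (occurrences$position[io] - cc[j]))
  }
  d <- d[abs(d) <= window]
  if (!length(d)) {
    return(structure(list(x = numeric(0), density = numeric(0),
                          distances = d, n = 0L, empty = TRUE),
                     class = "motif_distance_profile"))
  }
  dens <- stats::density(d, bw = bandwidth, from = -window, to = window,
                         n = 512)
  # renormalize to unit mass on the window
  step <- diff(dens$x[1:2])
  y <- dens$y / sum(dens$y * step)
  structure(list(x = dens$x, density = y, distances = d,
                 n = length(d), empty = FALSE),
            class = "motif_distance_profile")
}
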