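#' Co-binding simulation specification
#'
#' The stated world for the peak generator: a set of factors sharing
#' `n_anchors` hotspot anchors inside accessible chromatin. Each factor
#' binds each anchor independently with its probability from
#' `cobinding_matrix`; bound anchors receive a peak whose center is the
#' anchor position plus Gaussian jitter. Each factor additionally gets
#' `n_specific` factor-private peaks at uniform accessible positions.
#'
#' @param factors character vector of factor names.
#' @param n_anchors number of shared anchors.
#' @param n_specific factor-specific peak count, recycled per factor.
#' @param jitter_sd center jitter sd in bp (>= 0), recycled per factor.
#' @param width_range length-2 numeric, min/max peak width in bp.
#' @param cobinding_matrix per-factor anchor-binding probability: scalar,
#'   per-factor vector, or factors x anchors matrix; values in `[0, 1]`.
#' @param accessible_fraction fraction of the genome that is accessible,
#'   in `(0, 1]`.
#' @param region_width typical accessible-region width, bp (regions are
#'   tiled at this width until the fraction is met).
#' @param anchor_min_spacing minimum distance between anchors; default
#'   `max(2 * max width, window-safety 2000 bp)` so distinct anchors give
#'   distinct hotspots.
#' @param score_bonus additive peak-score bonus per co-binding factor at
#'   anchor-derived peaks (emulates stronger binding at co-bound sites).
#' @return list of class `cobinding_spec`.
#' @export
cobinding_spec <- function(factors, n_anchors = 100, n_specific = 100,
                           jitter_sd = 50, width_range = c(150, 400),
                           cobinding_matrix = 1, accessible_fraction = 0.25,
                           region_width = 2000,
                           anchor_min_spacing = NULL, score_bonus = 2) {
  stopifnot(length(factors) >= 1, n_anchors >= 0,
            all(jitter_sd >= 0), all(width_range > 0),
            accessible_fraction > 0, accessible_fraction <= 1)
  n_specific <- rep_len(n_specific, length(factors))
  jitter_sd <- rep_len(jitter_sd, length(factors))
  if (is.matrix(cobinding_matrix)) {
    if (nrow(cobinding_matrix) != length(factors) ||
        ncol(cobinding_matrix) != n_anchors)
      stop("cobinding_matrix must be factors x anchors")
    cb <- cobinding_matrix
  } else {
    cb <- matrix(rep_len(cobinding_matrix, length(factors)),
                 nrow = length(factors), ncol = max(n_anchors, 1))
  }
  if (any(cb < 0 | cb > 1)) stop("binding probabilities must be in [0, 1]")
  if (is.null(anchor_min_spacing))
    anchor_min_spacing <- max(2 * max(width_range), 2000)
  structure(list(factors = factors, n_anchors = n_anchors,
                 n_specific = stats::setNames(n_specific, factors),
                 jitter_sd = stats::setNames(jitter_sd, factors),
                 width_range = width_range, cobinding_matrix = cb,
                 accessible_fraction = accessible_fraction,
                 region_width = region_width,
                 anchor_min_spacing = anchor_min_spacing,
                 score_bonus = score_bonus),
            class = "cobinding_spec")
}

#' Simulate a genome with gene annotation and sequence
#'
#' Chromosomes of equal length, TSS placed uniformly (with a collision
#' guard) and random strand, i.i.d. uniform ACGT sequence. Deterministic
#' per seed. Exonic lengths are log-normal around 1.5 kb, the scale of a
#' typical mammalian mRNA.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length, bp (>= 10 kb).
#' @param n_genes total gene count (>= 1); at most one gene per kb.
#' @param seed integer seed.
#' @param sequence emit sequence (`DNAStringSet`)? Turn off to speed up
#'   simulations that never touch sequence.
#' @return list with `genome` (`genome_model`), `genes`
#'   (`gene_annotation`) and `sequences` (`DNAStringSet` or NULL).
#' @export
simulate_genome <- function(n_chroms = 1, chrom_len = 1e6, n_genes = 50,
                            seed = 1, sequence = TRUE) {
  if (chrom_len < 1e4) stop("chrom_len must be >= 10 kb")
  if (n_genes < 1) stop("n_genes must be >= 1")
  total <- n_chroms * chrom_len
  if (n_genes > total / 1000)
    stop("overconstrained placement: more than one gene per kb")
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  genome <- genome_model(stats::setNames(rep(chrom_len, n_chroms), chroms))
  with_seed(seed, {
    per_chrom <- tabulate(sample.int(n_chroms, n_genes, replace = TRUE),
                          nbins = n_chroms)
    gene_rows <- list()
    gi <- 0
    for (k in seq_len(n_chroms)) {
      ng <- per_chrom[k]
      if (!ng) next
      # uniform placement with a guaranteed >= 200 bp TSS spacing: sample
      # on the axis shrunken by the total spacing, then re-expand (exact,
      # no rejection loop; equivalent to conditioning on the spacing)
      spacing <- 200
      span <- chrom_len - 200 - (ng - 1) * spacing
      if (span <= ng) stop("overconstrained placement: genes too dense")
      tss <- sort(floor(stats::runif(ng, 0, span))) +
        100 + (seq_len(ng) - 1) * spacing
      gene_rows[[k]] <- data.frame(
        gene_id = sprintf("gene%04d", gi + seq_len(ng)),
        chrom = chroms[k],
        strand = sample(c("+", "-"), ng, replace = TRUE),
        tss = tss,
        exonic_bp = pmax(200, round(stats::rlnorm(ng, log(1500), 0.6))),
        stringsAsFactors = FALSE)
      gi <- gi + ng
    }
    genes <- gene_annotation(do.call(rbind, gene_rows), genome = genome)
    seqs <- NULL
    if (sequence) {
      # intToUtf8 over ASCII codes is orders of magnitude faster than
      # paste(collapse =) at megabase scale
      seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
        intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4, chrom_len,
                                                   replace = TRUE)]), ""))
      names(seqs) <- chroms
    }
    list(genome = genome, genes = genes, sequences = seqs)
  })
}

# tile disjoint accessible regions until the requested fraction is covered
simulate_accessible <- function(genome, fraction, region_width) {
  regions <- list()
  for (ch in names(genome$chrom_sizes)) {
    len <- genome$chrom_sizes[[ch]]
    target <- fraction * len
    n_regions <- max(1, round(target / region_width))
    # evenly spaced slots with the region placed at a jittered offset
    slot <- len / n_regions
    off <- stats::runif(n_regions, 0, pmax(1, slot - region_width))
    s <- floor((seq_len(n_regions) - 1) * slot + off)
    e <- pmin(len, s + region_width)
    regions[[ch]] <- genomic_intervals(ch, s, e)
  }
  accessible_chromatin(do.call(rbind, regions))
}

# sample n positions uniformly over the accessible base pairs. Uniformity
# over ALL accessible bp (no interior margin) is what keeps the generator
# consistent with the binomial null, whose per-peak probability is a rate
# over the total accessible size; peak intervals are clipped to their
# region instead of centers being pushed inward.
sample_accessible_positions <- function(accessible, n, margin = 0) {
  r <- accessible$regions
  s <- r$start + margin
  e <- r$end - margin
  ok <- which(e > s)
  if (!length(ok)) stop("no accessible region wide enough")
  w <- (e - s)[ok]
  pick <- sample.int(length(ok), n, replace = TRUE, prob = w)
  i <- ok[pick]
  pos <- floor(s[ok][pick] + stats::runif(n) * w[pick])
  data.frame(chrom = r$chrom[i], pos = pos, region = i,
             stringsAsFactors = FALSE)
}

# greedy spacing-respecting anchor placement: oversample candidate
# positions, accept each candidate at least `spacing` from every accepted
# anchor, refreshing candidates until n are placed or retries exhaust
place_anchors <- function(accessible, n, spacing, max_rounds = 50) {
  acc_chrom <- character(0); acc_pos <- numeric(0); acc_region <- integer(0)
  for (round in seq_len(max_rounds)) {
    cand <- sample_accessible_positions(accessible, n * 10)
    for (k in seq_len(nrow(cand))) {
      same <- acc_chrom == cand$chrom[k]
      if (!any(same & abs(acc_pos - cand$pos[k]) < spacing)) {
        acc_chrom <- c(acc_chrom, cand$chrom[k])
        acc_pos <- c(acc_pos, cand$pos[k])
        acc_region <- c(acc_region, cand$region[k])
        if (length(acc_pos) == n)
          return(data.frame(chrom = acc_chrom, pos = acc_pos,
                            region = acc_region, stringsAsFactors = FALSE))
      }
    }
  }
  stop("could not place ", n, " anchors with spacing ", spacing,
       " after bounded retries")
}

#' Simulate co-bound peak sets inside accessible chromatin
#'
#' Generates accessible chromatin first, then places shared anchors and
#' factor peaks inside it, reflecting the modeling assumption that only
#' open chromatin is available to any DNA-binding factor. Anchors are
#' sampled with a minimum spacing (`spec$anchor_min_spacing`); if spacing
#' cannot be achieved after bounded retries an error is raised. Every
#' emitted peak lies within an accessible region. Peak scores are
#' `N(5, 1)` plus `spec$score_bonus` for each co-binding factor at the
#' peak's anchor, so anchor peaks are systematically stronger.
#'
#' @param spec [cobinding_spec()].
#' @param genome `genome_model`.
#' @param seed integer seed.
#' @return list with `peaks` (named list of `peak_set`), `accessible`
#'   (`accessible_chromatin`), `anchors` (data frame `anchor_id`, `chrom`,
#'   `pos`, `n_factors_bound`) and `truth` (per-peak data frame: `factor`,
#'   `peak_id`, `anchor_id` (NA for specific peaks), `center`).
#' @export
simulate_peaks <- function(spec, genome, seed = 1) {
  max_w <- max(spec$width_range)
  with_seed(seed, {
    accessible <- simulate_accessible(genome, spec$accessible_fraction,
                                      spec$region_width)
    # anchors with minimum spacing (greedy spacing-aware placement)
    if (spec$n_anchors > 0) {
      anchors <- place_anchors(accessible, spec$n_anchors,
                               spec$anchor_min_spacing)
      o <- order(anchors$chrom, anchors$pos)
      anchors <- anchors[o, , drop = FALSE]
      anchors$anchor_id <- sprintf("anchor%04d", seq_len(nrow(anchors)))
    } else {
      anchors <- data.frame(chrom = character(0), pos = numeric(0),
                            region = integer(0), anchor_id = character(0),
                            stringsAsFactors = FALSE)
    }
    bound <- matrix(FALSE, nrow = length(spec$factors), ncol = nrow(anchors))
    if (nrow(anchors) > 0)
      for (fi in seq_along(spec$factors))
        bound[fi, ] <- stats::runif(nrow(anchors)) <
          spec$cobinding_matrix[fi, seq_len(nrow(anchors))]
    n_cobound <- if (ncol(bound)) colSums(bound) else integer(0)
    peaks <- list()
    truth <- list()
    for (fi in seq_along(spec$factors)) {
      f <- spec$factors[fi]
      rows <- list()
      if (nrow(anchors) > 0 && any(bound[fi, ])) {
        ia <- which(bound[fi, ])
        jit <- round(stats::rnorm(length(ia), 0, spec$jitter_sd[[f]]))
        ctr <- anchors$pos[ia] + jit
        w <- round(stats::runif(length(ia), spec$width_range[1],
                                spec$width_range[2]))
        reg <- accessible$regions[anchors$region[ia], , drop = FALSE]
        # clamp jittered centers into the region, then trim symmetrically
        # so the realized center equals the clamped jittered position
        ctr <- pmin(pmax(ctr, reg$start), reg$end - 1)
        half_l <- floor(w / 2); half_r <- w - half_l
        t <- pmax(0, reg$start - (ctr - half_l), (ctr + half_r) - reg$end)
        s <- ctr - half_l + t
        e <- pmax(ctr + half_r - t, s + 1)
        score <- stats::rnorm(length(ia), 5, 1) +
          spec$score_bonus * n_cobound[ia]
        rows$anchor <- data.frame(chrom = anchors$chrom[ia], start = s,
                                  end = e, score = score,
                                  anchor_id = anchors$anchor_id[ia],
                                  stringsAsFactors = FALSE)
      }
      ns <- spec$n_specific[[f]]
      if (ns > 0) {
        p <- sample_accessible_positions(accessible, ns)
        w <- round(stats::runif(ns, spec$width_range[1],
                                spec$width_range[2]))
        reg <- accessible$regions[p$region, , drop = FALSE]
        # symmetric trim against the region edges so the drawn center is
        # preserved exactly (center uniformity is what the null assumes)
        half_l <- floor(w / 2); half_r <- w - half_l
        t <- pmax(0, reg$start - (p$pos - half_l),
                  (p$pos + half_r) - reg$end)
        s <- p$pos - half_l + t
        e <- pmax(p$pos + half_r - t, s + 1)
        rows$specific <- data.frame(chrom = p$chrom, start = s, end = e,
                                    score = stats::rnorm(ns, 5, 1),
                                    anchor_id = NA_character_,
                                    stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, rows)
      if (is.null(df) || !nrow(df)) {
        peaks[[f]] <- NULL
        next
      }
      ps <- peak_set(genomic_intervals(df$chrom, df$start, df$end,
                                       score = df$score), f)
      # recover anchor ids after peak_set sorting via coordinate match
      key <- paste(df$chrom, df$start, df$end, round(df$score, 9))
      key_sorted <- paste(ps$chrom, ps$start, ps$end, round(ps$score, 9))
      anchor_of <- df$anchor_id[match(key_sorted, key)]
      peaks[[f]] <- ps
      truth[[f]] <- data.frame(factor = f, peak_id = ps$peak_id,
                               anchor_id = anchor_of,
                               center = interval_center(ps),
                               stringsAsFactors = FALSE)
    }
    anchors_out <- data.frame(anchor_id = anchors$anchor_id,
                              chrom = anchors$chrom, pos = anchors$pos,
                              n_factors_bound = n_cobound,
                              stringsAsFactors = FALSE)
    truth_df <- if (length(truth))
      do.call(rbind, c(truth, list(make.row.names = FALSE))) else NULL
    list(peaks = peaks, accessible = accessible, anchors = anchors_out,
         truth = truth_df)
  })
}

#' Plant motif instances near peak centers
#'
#' With probability `plant_prob` per peak, writes the consensus (or its
#' reverse complement, random strand) into the sequence so that the motif
#' start sits at `center - floor(L/2) + round(N(0, positional_sd))`.
#' Plants that would leave the peak's chromosome, or a consensus longer
#' than the peak, are skipped with a warning and recorded as such.
#'
#' @param seqs `DNAStringSet`.
#' @param peaks `peak_set`.
#' @param consensus string over ACGT.
#' @param plant_prob per-peak planting probability.
#' @param positional_sd Gaussian sd of the offset from peak center, bp.
#' @param seed integer seed.
#' @return list with `sequences` (modified `DNAStringSet`) and `truth`
#'   (data frame `peak_id`, `planted`, `chrom`, `position`, `strand`,
#'   `skipped`).
#' @export
plant_motifs <- function(seqs, peaks, consensus, plant_prob = 0.5,
                         positional_sd = 20, seed = 1) {
  consensus <- toupper(consensus)
  if (!grepl("^[ACGT]+$", consensus)) stop("consensus must be over ACGT")
  if (plant_prob < 0 || plant_prob > 1) stop("plant_prob must be in [0,1]")
  L <- nchar(consensus)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus)))
  with_seed(seed, {
    char_seqs <- lapply(seqs, as.character)
    plant <- stats::runif(nrow(peaks)) < plant_prob
    strand <- sample(c("+", "-"), nrow(peaks), replace = TRUE)
    off <- round(stats::rnorm(nrow(peaks), 0, positional_sd))
    ctr <- interval_center(peaks)
    pos <- ctr - floor(L / 2) + off
    skipped <- logical(nrow(peaks))
    n_skip <- 0
    for (i in which(plant)) {
      ch <- peaks$chrom[i]
      too_long <- L > interval_length(peaks[i, , drop = FALSE])
      out_of_seq <- pos[i] < 0 || pos[i] + L > nchar(char_seqs[[ch]])
      if (too_long || out_of_seq) {
        skipped[i] <- TRUE
        n_skip <- n_skip + 1
        next
      }
      ins <- if (strand[i] == "+") consensus else rc
      substr(char_seqs[[ch]], pos[i] + 1, pos[i] + L) <- ins
    }
    if (n_skip)
      warning(n_skip, " plant(s) skipped (consensus longer than peak or ",
              "outside sequence)")
    truth <- data.frame(peak_id = peaks$peak_id, planted = plant & !skipped,
                        chrom = peaks$chrom,
                        position = ifelse(plant & !skipped, pos, NA),
                        strand = ifelse(plant & !skipped, strand, NA),
                        skipped = skipped, stringsAsFactors = FALSE)
    out <- Biostrings::DNAStringSet(unlist(char_seqs))
    names(out) <- names(seqs)
    list(sequences = out, truth = truth)
  })
}

#' Expression simulation specification
#'
#' The stated world for the expression generator: log-normal baseline TPM
#' shared across populations, with designated planted gene sets scaled up
#' by a fold effect in one population, log-normal replicate noise, and
#' counts derived from TPM through the library metadata so the TPM
#' round-trip through [compute_tpm()] is exercised.
#'
#' @param populations character vector of population names.
#' @param n_genes total genes (must match the annotation used).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline TPM
#'   parameters (defaults give a median of ~20 TPM with a long right
#'   tail).
#' @param planted named list (by population): list with `n` (gene count)
#'   and `fold` (> 1) and optionally `baseline_tpm` (fixed baseline for
#'   planted genes, default 50 so planted genes clear detection floors).
#' @param replicates replicates per population (>= 2).
#' @param dispersion sd of the log-normal replicate noise on log scale
#'   (0 = noiseless).
#' @param total_mapped per-sample library depth (default 2e7).
#' @param exonic_ratio per-sample exonic mapping ratio (default 0.7).
#' @return list of class `expression_spec`.
#' @export
expression_spec <- function(populations, n_genes = 2000,
                            baseline_meanlog = 3, baseline_sdlog = 1,
                            planted = list(), replicates = 3,
                            dispersion = 0.3, total_mapped = 2e7,
                            exonic_ratio = 0.7) {
  if (replicates < 2) stop("need >= 2 replicates per population")
  for (p in names(planted)) {
    if (!p %in% populations) stop("planted population not in populations")
    if (planted[[p]]$fold <= 1) stop("planted fold effect must exceed 1")
  }
  if (length(planted) &&
      sum(vapply(planted, `[[`, 0, "n")) > n_genes)
    stop("planted gene sets exceed n_genes")
  structure(list(populations = populations, n_genes = n_genes,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, planted = planted,
                 replicates = replicates, dispersion = dispersion,
                 total_mapped = total_mapped, exonic_ratio = exonic_ratio),
            class = "expression_spec")
}

#' Simulate an expression table with planted enriched gene sets
#'
#' @param spec [expression_spec()].
#' @param genes `gene_annotation` with at least `spec$n_genes` genes; the
#'   first `n_genes` are used.
#' @param seed integer seed.
#' @return list with `expr` (`expression_table`) and `truth` (named list:
#'   population -> planted gene ids).
#' @export
simulate_expression <- function(spec, genes, seed = 1) {
  if (nrow(genes) < spec$n_genes)
    stop("annotation has fewer genes than spec$n_genes")
  g <- genes[seq_len(spec$n_genes), , drop = FALSE]
  with_seed(seed, {
    base <- stats::rlnorm(nrow(g), spec$baseline_meanlog,
                          spec$baseline_sdlog)
    truth <- list()
    pop_mean <- matrix(rep(base, length(spec$populations)),
                       ncol = length(spec$populations),
                       dimnames = list(g$gene_id, spec$populations))
    avail <- seq_len(nrow(g))
    for (p in names(spec$planted)) {
      pl <- spec$planted[[p]]
      pick <- sample(avail, pl$n)
      avail <- setdiff(avail, pick)
      b0 <- if (is.null(pl$baseline_tpm)) base[pick] else pl$baseline_tpm
      pop_mean[pick, ] <- matrix(rep(b0, length(spec$populations)),
                                 ncol = length(spec$populations))
      pop_mean[pick, p] <- b0 * pl$fold
      truth[[p]] <- g$gene_id[pick]
    }
    samples <- character(0)
    pops <- character(0)
    tpm <- NULL
    for (p in spec$populations) for (r in seq_len(spec$replicates)) {
      noise <- if (spec$dispersion > 0)
        exp(stats::rnorm(nrow(g), 0, spec$dispersion)) else 1
      tpm <- cbind(tpm, pop_mean[, p] * noise)
      samples <- c(samples, sprintf("%s_rep%d", p, r))
      pops <- c(pops, p)
    }
    colnames(tpm) <- samples
    # back out integer counts so the table round-trips through compute_tpm
    ratio <- rep(spec$exonic_ratio, length(samples))
    depth <- rep(spec$total_mapped, length(samples))
    names(ratio) <- names(depth) <- samples
    kb <- g$exonic_bp / 1000
    counts <- round(tpm * (kb %o% (depth * ratio / 1e6)))
    storage.mode(counts) <- "double"
    rownames(counts) <- g$gene_id
    expr <- expression_table(counts, stats::setNames(pops, samples),
                             depth, ratio, g)
    list(expr = expr, truth = truth)
  })
}
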