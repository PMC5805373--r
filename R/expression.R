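#' Expression table
#'
#' Raw counts with the library metadata needed for the TPM convention used
#' throughout: RPKM is computed from counts, exon length and library depth,
#' and TPM is RPKM divided by the library's exonic mapping ratio (the
#' fraction of mapped reads falling in exons). Note this is a specific
#' historical TPM convention, not the transcript-fraction TPM of modern
#' quantifiers.
#'
#' @param counts genes x samples numeric matrix (row names = gene ids).
#' @param populations named character vector: sample -> population label.
#' @param total_mapped named numeric: per-sample total mapped reads.
#' @param exonic_ratio named numeric in (0, 1]: per-sample exonic mapping
#'   ratio.
#' @param genes `gene_annotation` providing `exonic_bp` per gene.
#' @return object of class `expression_table`: list with `counts`, `rpkm`,
#'   `tpm`, `populations`, `total_mapped`, `exonic_ratio`, `genes`.
#' @export
expression_table <- function(counts, populations, total_mapped,
                             exonic_ratio, genes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts need gene ids as row names")
  if (any(counts < 0)) stop("counts must be non-negative")
  samples <- colnames(counts)
  if (is.null(samples)) stop("counts need sample names as column names")
  if (!all(samples %in% names(populations)))
    stop("every sample needs a population label")
  if (!all(samples %in% names(total_mapped)) ||
      !all(samples %in% names(exonic_ratio)))
    stop("every sample needs total_mapped and exonic_ratio")
  miss <- setdiff(rownames(counts), genes$gene_id)
  if (length(miss))
    stop("genes absent from annotation: ",
         paste(utils::head(miss, 3), collapse = ", "))
  tpm <- compute_tpm(counts,
                     genes$exonic_bp[match(rownames(counts), genes$gene_id)],
                     total_mapped[samples], exonic_ratio[samples])
  structure(list(counts = counts, rpkm = attr(tpm, "rpkm"),
                 tpm = unname_attr(tpm), populations = populations[samples],
                 total_mapped = total_mapped[samples],
                 exonic_ratio = exonic_ratio[samples], genes = genes),
            class = "expression_table")
}

unname_attr <- function(x) { attr(x, "rpkm") <- NULL; x }

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table: %d genes x %d samples, populations: %s>\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$populations), collapse = ", ")))
  invisible(x)
}

#' Counts to TPM via the exonic-mapping-ratio convention
#'
#' `RPKM = count / (exonic_kb * mapped_millions)`;
#' `TPM = RPKM / exonic_ratio`. Scaling all counts of a sample together
#' with its total leaves TPM unchanged (depth invariance).
#'
#' @param counts genes x samples matrix (or vector for one sample).
#' @param exonic_bp per-gene total exon length, bp (> 0).
#' @param total_mapped per-sample total mapped reads (> 0).
#' @param exonic_ratio per-sample exonic mapping ratio in (0, 1].
#' @return TPM matrix with the RPKM matrix attached as attribute `rpkm`.
#' @export
compute_tpm <- function(counts, exonic_bp, total_mapped, exonic_ratio) {
  counts <- as.matrix(counts)
  if (any(exonic_bp <= 0)) stop("exonic_bp must be positive")
  if (any(total_mapped <= 0)) stop("total mapped reads must be positive")
  if (any(exonic_ratio <= 0 | exonic_ratio > 1))
    stop("exonic_ratio must be in (0, 1]")
  kb <- exonic_bp / 1000
  millions <- total_mapped / 1e6
  rpkm <- sweep(counts / kb, 2, millions, `/`)
  tpm <- sweep(rpkm, 2, exonic_ratio, `/`)
  attr(tpm, "rpkm") <- rpkm
  tpm
}

# Welch's t-test p-values, vectorized over genes (rows); returns 1 where
# both groups are constant and equal, 0 where constant and different
welch_p <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  p <- rep(NA_real_, length(ma))
  zero <- se2 == 0
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  i <- !zero
  t <- (ma[i] - mb[i]) / sqrt(se2[i])
  df <- se2[i]^2 / ((va[i] / na)^2 / (na - 1) + (vb[i] / nb)^2 / (nb - 1))
  p[i] <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p
}

#' Differentially enriched gene sets between two populations
#'
#' A gene is enriched in population A when (i) its mean TPM in A exceeds
#' `min_tpm`, (ii) the fold difference of population means (with a small
#' pseudo-count) exceeds `fold`, and (iii) a Welch two-sample test on
#' `log2(TPM + 1)` across replicates gives `p < alpha`. Symmetric for B;
#' the A- and B-enriched sets are disjoint by construction. With a single
#' replicate per population the p-value filter is skipped with a warning.
#' All thresholds are strict.
#'
#' @param expr `expression_table`.
#' @param pop_a,pop_b population labels present in `expr$populations`.
#' @param fold fold-difference threshold on population mean TPM (default 3).
#' @param min_tpm minimum mean TPM in the enriched population (default 5).
#' @param alpha p-value threshold (default 0.05).
#' @param pseudo pseudo-count added to both means for the fold ratio
#'   (default 0.01).
#' @param min_tpm_both require the TPM floor in both populations instead of
#'   only the enriched one (default FALSE).
#' @return list of class `enriched_gene_sets` with elements `a` and `b`,
#'   each a data frame (`gene_id`, `mean_a`, `mean_b`, `fold`, `p_value`)
#'   of class `enriched_gene_set` carrying the comparison and thresholds as
#'   attributes, plus `stats`, the full per-gene table.
#' @export
select_enriched_genes <- function(expr, pop_a, pop_b, fold = 3, min_tpm = 5,
                                  alpha = 0.05, pseudo = 0.01,
                                  min_tpm_both = FALSE) {
  sa <- names(expr$populations)[expr$populations == pop_a]
  sb <- names(expr$populations)[expr$populations == pop_b]
  if (!length(sa) || !length(sb))
    stop("unknown population label(s): ",
         paste(setdiff(c(pop_a, pop_b), expr$populations), collapse = ", "))
  ta <- expr$tpm[, sa, drop = FALSE]
  tb <- expr$tpm[, sb, drop = FALSE]
  ma <- rowMeans(ta); mb <- rowMeans(tb)
  fc_a <- (ma + pseudo) / (mb + pseudo)
  if (length(sa) >= 2 && length(sb) >= 2) {
    p <- welch_p(log2(ta + 1), log2(tb + 1))
    p_ok <- p < alpha
  } else {
    warning("single replicate: p-value filter skipped ",
            "(fold and TPM filters only)")
    p <- rep(NA_real_, length(ma))
    p_ok <- rep(TRUE, length(ma))
  }
  tpm_ok_a <- if (min_tpm_both) ma > min_tpm & mb > min_tpm else ma > min_tpm
  tpm_ok_b <- if (min_tpm_both) ma > min_tpm & mb > min_tpm else mb > min_tpm
  in_a <- tpm_ok_a & fc_a > fold & p_ok
  in_b <- tpm_ok_b & (1 / fc_a) > fold & p_ok
  stats_df <- data.frame(gene_id = rownames(expr$tpm), mean_a = ma,
                         mean_b = mb, fold_a_over_b = fc_a, p_value = p,
                         stringsAsFactors = FALSE)
  rownames(stats_df) <- NULL
  mk <- function(sel, which_pop) {
    d <- stats_df[sel, , drop = FALSE]
    rownames(d) <- NULL
    structure(d, comparison = c(pop_a, pop_b), enriched_in = which_pop,
              thresholds = list(fold = fold, min_tpm = min_tpm,
                                alpha = alpha, pseudo = pseudo,
                                min_tpm_both = min_tpm_both,
                                test = "welch_log2_tpm_plus_1"),
              class = c("enriched_gene_set", "data.frame"))
  }
  structure(list(a = mk(in_a, pop_a), b = mk(in_b, pop_b), stats = stats_df),
            class = "enriched_gene_sets")
}

#' @export
print.enriched_gene_sets <- function(x, ...) {
  cmp <- attr(x$a, "comparison")
  cat(sprintf("<enriched_gene_sets %s vs %s: %d / %d genes>\n",
              cmp[1], cmp[2], nrow(x$a), nrow(x$b)))
  invisible(x)
}

#' Threshold-defined population gene sets
#'
#' Builds one gene list per named comparison using the simple rule
#' "TPM above `min_tpm` in the high population and fold change above
#' `fold` versus the low population" (population means, strict
#' inequalities, no replicate test). This is the rule used for the
#' progenitor / self-renewing / differentiating set construction.
#'
#' @param expr `expression_table`.
#' @param comparisons named list, each element `c(high, low)` population
#'   labels; all referenced populations must exist.
#' @param min_tpm TPM floor in the high population (default 10).
#' @param fold fold-change threshold (default 2); exactly `fold` is
#'   excluded.
#' @param pseudo pseudo-count for the ratio (default 0.01).
#' @return named list of character vectors of gene ids.
#' @export
threshold_gene_sets <- function(expr, comparisons, min_tpm = 10, fold = 2,
                                pseudo = 0.01) {
  pops <- unique(unlist(comparisons))
  missing_pops <- setdiff(pops, expr$populations)
  if (length(missing_pops))
    stop("population(s) absent from table: ",
         paste(missing_pops, collapse = ", "))
  pop_mean <- function(p) {
    s <- names(expr$populations)[expr$populations == p]
    rowMeans(expr$tpm[, s, drop = FALSE])
  }
  lapply(comparisons, function(cmp) {
    hi <- pop_mean(cmp[1]); lo <- pop_mean(cmp[2])
    sel <- hi > min_tpm & (hi + pseudo) / (lo + pseudo) > fold
    rownames(expr$tpm)[sel]
  })
}

#' Fraction of target genes falling in each category
#'
#' For each factor combination's target gene set, the percentage of its
#' genes that belong to each category list, with a whole-transcriptome
#' baseline row for comparison. Empty target sets are reported with a
#' zero-denominator flag rather than dropped.
#'
#' @param target_sets named list of gene-id vectors (per factor
#'   combination).
#' @param categories named list of gene-id vectors.
#' @param transcriptome character vector of all annotated gene ids.
#' @return data frame: `set`, `n_genes`, one percentage column per
#'   category, `zero_denominator` flag. The first row is the transcriptome
#'   baseline.
#' @export
category_fraction <- function(target_sets, categories, transcriptome) {
  transcriptome <- unique(transcriptome)
  all_sets <- c(list(transcriptome = transcriptome),
                lapply(target_sets, unique))
  rows <- lapply(names(all_sets), function(nm) {
    s <- all_sets[[nm]]
    row <- data.frame(set = nm, n_genes = length(s),
                      stringsAsFactors = FALSE)
    for (cat in names(categories)) {
      row[[paste0("pct_", cat)]] <-
        if (length(s) == 0) NA_real_
        else 100 * length(intersect(s, categories[[cat]])) / length(s)
    }
    row$zero_denominator <- length(s) == 0
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unique targets per factor combination
#'
#' Partitions the union of all factors' target genes by the exact set of
#' factors targeting each gene, e.g. `"Six2"`, `"Six2+Wt1"`, matching the
#' per-combination bars of category-fraction analyses.
#'
#' @param per_factor_targets named list: factor -> character vector of
#'   target gene ids.
#' @return named list: combination label (factors joined by `+`, sorted)
#'   -> gene ids targeted by exactly that combination.
#' @export
unique_targets_by_combination <- function(per_factor_targets) {
  factors <- sort(names(per_factor_targets))
  genes <- sort(unique(unlist(per_factor_targets)))
  if (!length(genes)) return(list())
  member <- vapply(factors,
                   function(f) genes %in% per_factor_targets[[f]],
                   logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, factors))
  label <- apply(member, 1, function(r) paste(factors[r], collapse = "+"))
  split(genes, label)
}
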