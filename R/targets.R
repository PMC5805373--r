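#' Build per-gene regulatory domains
#'
#' Three conventions for the genomic span attributed to a gene:
#' \describe{
#'   \item{`flank_500kb`}{symmetric flank: `[tss - flank, tss + flank)`,
#'     clipped to the chromosome. Domains of nearby genes overlap; the
#'     merged coverage is what enters the enrichment null.}
#'   \item{`great_single_nearest`}{every base belongs to its nearest TSS up
#'     to `extension` bp; adjacent genes split at the midpoint, so domains
#'     partition the covered territory (ties go to the upstream gene).}
#'   \item{`great_basal_extension`}{strand-aware basal domain
#'     (`basal_up` bp upstream, `basal_down` bp downstream of the TSS)
#'     extended in both directions up to `extension` bp but stopping at the
#'     neighboring gene's basal domain.}
#' }
#'
#' @param genes `gene_annotation`.
#' @param genome `genome_model` (domains clipped to chromosomes).
#' @param mode domain convention, one of the three above. Mandatory: the
#'   choice changes every downstream number and is recorded in all outputs.
#' @param flank half-width for `flank_500kb` (default 5e5 bp).
#' @param basal_up,basal_down basal promoter span for
#'   `great_basal_extension` (defaults 5000 / 1000 bp).
#' @param extension maximum reach from the TSS (default 5e5 bp).
#' @return object of class `regulatory_domains`: list with `mode`,
#'   `domains` (data frame `gene_id`, `chrom`, `start`, `end`),
#'   `merged_size` (bp after merging), `params`.
#' @export
build_domains <- function(genes, genome,
                          mode = c("flank_500kb", "great_single_nearest",
                                   "great_basal_extension"),
                          flank = 5e5, basal_up = 5000, basal_down = 1000,
                          extension = 5e5) {
  mode <- match.arg(mode)
  lim <- genome$chrom_sizes[genes$chrom]
  if (any(is.na(lim))) stop("gene on chromosome absent from genome model")
  tss <- genes$tss
  if (mode == "flank_500kb") {
    s <- pmax(0, tss - flank)
    e <- pmin(lim, tss + flank)
  } else if (mode == "great_single_nearest") {
    s <- pmax(0, tss - extension)
    e <- pmin(lim, tss + extension)
    # split at midpoints between TSS-adjacent genes on the same chromosome;
    # a base equidistant from two TSS goes with the left (smaller-tss) gene
    for (ch in unique(genes$chrom)) {
      i <- which(genes$chrom == ch)
      i <- i[order(tss[i])]
      if (length(i) < 2) next
      for (k in seq_len(length(i) - 1)) {
        cut <- floor((tss[i[k]] + tss[i[k + 1]]) / 2) + 1
        e[i[k]] <- min(e[i[k]], cut)
        s[i[k + 1]] <- max(s[i[k + 1]], cut)
      }
    }
  } else {
    up <- ifelse(genes$strand == "+", basal_up, basal_down)
    dn <- ifelse(genes$strand == "+", basal_down, basal_up)
    bs <- pmax(0, tss - up)
    be <- pmin(lim, tss + dn)
    s <- pmax(0, tss - extension)
    e <- pmin(lim, tss + extension)
    for (ch in unique(genes$chrom)) {
      i <- which(genes$chrom == ch)
      i <- i[order(tss[i])]
      if (length(i) >= 2) {
        for (k in seq_len(length(i) - 1)) {
          # extension stops at the neighbor's basal domain (but a basal
          # domain is never truncated, even when neighbors interleave)
          e[i[k]] <- min(e[i[k]], max(be[i[k]], bs[i[k + 1]]))
          s[i[k + 1]] <- max(s[i[k + 1]], min(bs[i[k + 1]], be[i[k]]))
        }
      }
    }
    s <- pmin(s, bs)
    e <- pmax(e, be)
  }
  dom <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = s, end = e, stringsAsFactors = FALSE)
  dom <- dom[dom$start < dom$end, , drop = FALSE]
  merged_size <- coverage_size(
    genomic_intervals(dom$chrom, dom$start, dom$end))
  structure(list(mode = mode, domains = dom, merged_size = merged_size,
                 params = list(flank = flank, basal_up = basal_up,
                               basal_down = basal_down,
                               extension = extension)),
            class = "regulatory_domains")
}

#' @export
print.regulatory_domains <- function(x, ...) {
  cat(sprintf("<regulatory_domains: %d genes, mode '%s', merged %.0f bp>\n",
              nrow(x$domains), x$mode, x$merged_size))
  invisible(x)
}

#' Export domains as a BED table
#'
#' @param domains `regulatory_domains`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_domains <- function(domains, path) {
  d <- domains$domains
  dt <- data.table::data.table(d$chrom,
                               format(d$start, scientific = FALSE, trim = TRUE),
                               format(d$end, scientific = FALSE, trim = TRUE),
                               d$gene_id)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign peaks to target genes by domain membership
#'
#' A peak belongs to a gene when the peak center lies inside the gene's
#' regulatory domain — the same center convention as the overlap
#' statistics. In `great_single_nearest` mode domains are disjoint, so
#' every peak receives at most one gene; in `flank_500kb` mode a peak may
#' sit in several genes' domains and all assignments are reported.
#'
#' @param peaks `peak_set`.
#' @param domains `regulatory_domains`.
#' @param genes optional `gene_annotation`; when supplied, each assignment
#'   is annotated with the signed strand-oriented distance from peak center
#'   to the gene's TSS (negative = upstream).
#' @return list with `assignments` (data frame `peak_id`, `gene_id`,
#'   `tss_distance`), and `target_sets` (named list: gene id -> character
#'   vector of peak ids, plus the reverse view `genes_of_peak`).
#' @export
assign_targets <- function(peaks, domains, genes = NULL) {
  ctr <- interval_center(peaks)
  d <- domains$domains
  rows <- list()
  for (ch in unique(d$chrom)) {
    id <- which(d$chrom == ch)
    ip <- which(peaks$chrom == ch)
    if (!length(ip)) next
    o <- order(ctr[ip]); ip <- ip[o]
    cc <- ctr[ip]
    for (k in id) {
      lo <- findInterval(d$start[k] - 0.5, cc) + 1
      hi <- findInterval(d$end[k] - 0.5, cc)
      if (lo <= hi)
        rows[[length(rows) + 1]] <- data.frame(
          peak_id = peaks$peak_id[ip[lo:hi]],
          gene_id = d$gene_id[k],
          peak_center = cc[lo:hi],
          stringsAsFactors = FALSE)
    }
  }
  asn <- if (length(rows)) do.call(rbind, rows)
         else data.frame(peak_id = character(0), gene_id = character(0),
                         peak_center = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(asn)) {
    g <- genes[match(asn$gene_id, genes$gene_id), , drop = FALSE]
    raw <- asn$peak_center - g$tss
    asn$tss_distance <- ifelse(g$strand == "+", raw, -raw)
  } else {
    asn$tss_distance <- rep(NA_real_, nrow(asn))
  }
  asn$peak_center <- NULL
  asn <- asn[order(asn$peak_id, asn$gene_id), , drop = FALSE]
  rownames(asn) <- NULL
  list(assignments = asn,
       target_genes = sort(unique(asn$gene_id)),
       peaks_of_gene = split(asn$peak_id, asn$gene_id),
       genes_of_peak = split(asn$gene_id, asn$peak_id))
}

# count peaks whose center falls in the merged domains of a gene subset
count_peaks_in_domains <- function(peaks, domains, gene_ids) {
  d <- domains$domains[domains$domains$gene_id %in% gene_ids, , drop = FALSE]
  if (!nrow(d)) return(list(count = 0L, p = 0))
  merged <- merge_intervals(genomic_intervals(d$chrom, d$start, d$end))
  ctr <- interval_center(peaks)
  n <- 0L
  for (ch in unique(merged$chrom)) {
    im <- which(merged$chrom == ch)
    ip <- which(peaks$chrom == ch)
    if (!length(ip)) next
    cc <- ctr[ip]
    for (k in im)
      n <- n + sum(cc >= merged$start[k] & cc < merged$end[k])
  }
  list(count = n, size = sum(interval_length(merged)))
}

#' Background-normalized regulatory-domain enrichment
#'
#' Tests whether peaks concentrate in the regulatory domains of a gene list
#' `G_x`. Under the primary null each peak falls uniformly anywhere in the
#' genome, so the domain-hit probability is
#' `p_x = merged_size(domains(G_x)) / genome_size`. Because real peak sets
#' land in *any* gene's domains more often than uniform (peaks track genes),
#' the test is normalized by a background ratio: for `n_random` uniformly
#' drawn gene lists of the same size, `r_Ax` is the mean of
#' `N_Ax_ri / (N_A * p_x_ri)`; the final model is
#' `N_Ax ~ Binom(N_A, p_x * r_Ax)` (capped at 1 with a warning).
#'
#' @param peaks `peak_set`.
#' @param gene_list character vector of gene ids (`G_x`), subset of
#'   `all_genes$gene_id`.
#' @param all_genes `gene_annotation` (sampling frame for random lists).
#' @param genome `genome_model`.
#' @param domains optional prebuilt `regulatory_domains` over `all_genes`;
#'   built with `mode` and `...` passed to [build_domains()] otherwise.
#' @param n_random number of random gene lists for `r_Ax` (default 10).
#' @param seed integer seed for the random lists.
#' @param mode,... forwarded to [build_domains()] when `domains` is NULL.
#' @return object of class `region_enrichment_test` with fields `n_a`,
#'   `n_ax`, `p_x`, `r_ax`, `expected` (`n_a * p_x * r_ax`), `fold`,
#'   `p_value`, `neg_log10_p`, `n_random`, `mode`.
#' @export
region_enrichment <- function(peaks, gene_list, all_genes, genome,
                              domains = NULL, n_random = 10, seed = 1,
                              mode = "flank_500kb", ...) {
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% all_genes$gene_id))
    stop("gene_list contains ids absent from the annotation")
  if (length(gene_list) == 0) stop("empty gene list")
  if (length(gene_list) > nrow(all_genes))
    stop("gene list larger than the annotation")
  if (n_random < 1) stop("n_random must be >= 1")
  if (is.null(domains))
    domains <- build_domains(all_genes, genome, mode = mode, ...)
  n_a <- n_peaks(peaks)
  obs <- count_peaks_in_domains(peaks, domains, gene_list)
  p_x <- obs$size / genome$genome_size
  ratios <- with_seed(seed, vapply(seq_len(n_random), function(i) {
    gl <- sample(all_genes$gene_id, length(gene_list))
    ri <- count_peaks_in_domains(peaks, domains, gl)
    p_ri <- ri$size / genome$genome_size
    ri$count / (n_a * p_ri)
  }, 0))
  r_ax <- mean(ratios)
  if (r_ax == 0) {
    warning("no peak fell in any random domain set; r_Ax set to 1 ",
            "(unnormalized null)")
    r_ax <- 1
  }
  p_null <- p_x * r_ax
  if (p_null > 1) {
    warning("p_x * r_Ax exceeds 1; capped")
    p_null <- 1
  }
  tail <- binom_upper_tail(obs$count, n_a, p_null)
  structure(list(n_a = n_a, n_ax = obs$count, p_x = p_x, r_ax = r_ax,
                 expected = n_a * p_null,
                 fold = if (p_null > 0) obs$count / (n_a * p_null) else NA_real_,
                 p_value = tail$p_value, neg_log10_p = tail$neg_log10_p,
                 n_random = n_random, mode = domains$mode,
                 random_ratios = ratios),
            class = "region_enrichment_test")
}

#' @export
print.region_enrichment_test <- function(x, ...) {
  cat(sprintf(
    "<region_enrichment (%s): N_A=%d N_Ax=%d p_x=%.3g r_Ax=%.2f fold=%.2f -log10p=%.1f>\n",
    x$mode, x$n_a, x$n_ax, x$p_x, x$r_ax, x$fold, x$neg_log10_p))
  invisible(x)
}

#' Domain enrichment of several peak sets against several gene categories
#'
#' One [region_enrichment()] per (peak set, category) cell, with
#' Benjamini-Hochberg adjustment across the whole table. Raw p-values are
#' never replaced; `q` is an additional column.
#'
#' @param peak_sets named list of `peak_set` (hotspot spans can be included
#'   via [hotspots_as_peaks()]).
#' @param categories named list of gene-id vectors; empty category is an
#'   error.
#' @param all_genes,genome,domains,n_random,seed,mode,... as in
#'   [region_enrichment()].
#' @return data frame, one row per (set, category):
#'   `set`, `category`, `n_a`, `n_ax`, `p_x`, `r_ax`, `expected`, `fold`,
#'   `p_value`, `neg_log10_p`, `q`.
#' @export
category_enrichment_table <- function(peak_sets, categories, all_genes,
                                      genome, domains = NULL, n_random = 10,
                                      seed = 1, mode = "flank_500kb", ...) {
  if (any(vapply(categories, length, 0L) == 0))
    stop("empty gene category")
  if (is.null(domains))
    domains <- build_domains(all_genes, genome, mode = mode, ...)
  rows <- list()
  for (s in names(peak_sets)) for (cat in names(categories)) {
    t <- region_enrichment(peak_sets[[s]], categories[[cat]], all_genes,
                           genome, domains = domains, n_random = n_random,
                           seed = derive_seed(seed, paste(s, cat)))
    rows[[paste(s, cat)]] <- data.frame(
      set = s, category = cat, n_a = t$n_a, n_ax = t$n_ax, p_x = t$p_x,
      r_ax = t$r_ax, expected = t$expected, fold = t$fold,
      p_value = t$p_value, neg_log10_p = t$neg_log10_p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  attr(out, "mode") <- domains$mode
  out
}
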