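#' Read a peak set from BED / narrowPeak
#'
#' BED is parsed as 0-based half-open. Columns beyond the first three are
#' optional: column 4 is the peak name, column 5 the score. narrowPeak files
#' (10 columns) additionally carry signalValue in column 7, which is used as
#' the score since the BED score column is capped at 1000 by convention.
#' Files written with 1-based inclusive coordinates can be declared as such
#' with `convention = "paper_inclusive"` and are shifted on read.
#'
#' @param path BED/narrowPeak file.
#' @param name factor label; defaults to the file base name.
#' @param genome optional `genome_model`; if given, coordinates are
#'   validated against it and unknown chromosomes are an error.
#' @param convention coordinate convention of the file.
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, name = NULL, genome = NULL,
                       convention = c("bed_half_open", "paper_inclusive")) {
  convention <- match.arg(convention)
  if (is.null(name))
    name <- sub("\\.(bed|narrowPeak)$", "", basename(path))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop("failed to read ", path, ": ", conditionMessage(e))
  )
  if (ncol(dt) < 3) stop(path, ": BED needs at least 3 columns")
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(path, ": malformed coordinates at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (convention == "paper_inclusive") start <- start - 1
  score <- if (ncol(dt) >= 10) as.numeric(dt[[7]])   # narrowPeak signalValue
           else if (ncol(dt) >= 5) as.numeric(dt[[5]])
           else NaN
  strand <- if (ncol(dt) >= 6) ifelse(dt[[6]] %in% c("+", "-"), dt[[6]], "*")
            else "*"
  iv <- genomic_intervals(dt[[1]], start, end, strand = strand, score = score)
  if (!is.null(genome)) validate_against_genome(iv, genome)
  peak_set(iv, name, source_convention = convention)
}

#' Write a peak set (or plain intervals) as BED
#'
#' Coordinates are emitted half-open. Missing scores (`NaN`) are written as
#' `.` so they round-trip as missing, never as 0.
#'
#' @param x `peak_set` or `genomic_intervals`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path) {
  nm <- if (!is.null(x$peak_id)) x$peak_id
        else sprintf("iv_%d", seq_len(nrow(x)))
  sc <- ifelse(is.nan(x$score) | is.na(x$score), ".",
               format(x$score, trim = TRUE, scientific = FALSE))
  strand <- if (is.null(x$strand)) "*" else x$strand
  strand <- ifelse(strand == "*", ".", strand)
  dt <- data.table::data.table(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                               format(x$end, scientific = FALSE, trim = TRUE),
                               nm, sc, strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a gene annotation table
#'
#' Tab-delimited with header: `gene_id`, `chrom`, `strand`, `tss`,
#' `exonic_bp` (and optionally `symbol`). `tss` is a 0-based position.
#' `exonic_bp` is the total exon length used for expression normalization.
#'
#' @param path TSV file.
#' @param genome optional `genome_model` for validation.
#' @return `data.frame` of class `gene_annotation`.
#' @export
read_gene_table <- function(path, genome = NULL) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("gene_id", "chrom", "strand", "tss", "exonic_bp")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  gene_annotation(as.data.frame(dt), genome = genome)
}

#' @rdname read_gene_table
#' @param genes a `gene_annotation`.
#' @export
write_gene_table <- function(genes, path) {
  data.table::fwrite(as.data.frame(genes), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Gene annotation
#'
#' @param df data frame with columns `gene_id`, `chrom`, `strand` (+/-),
#'   `tss` (0-based bp), `exonic_bp` (> 0), optional `symbol`.
#' @param genome optional `genome_model`; TSS positions validated if given.
#' @return `gene_annotation` data frame.
#' @export
gene_annotation <- function(df, genome = NULL) {
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(df$exonic_bp <= 0)) stop("exonic_bp must be positive")
  if (any(df$tss < 0)) stop("tss must be >= 0")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(df$chrom), names(genome$chrom_sizes))
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(df$tss >= genome$chrom_sizes[df$chrom]))
      stop("tss beyond chromosome end")
  }
  df <- df[order(df$chrom, df$tss), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around Biostrings; sequences are `DNAStringSet` keyed by
#' chromosome name.
#'
#' @param path FASTA file.
#' @return `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
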