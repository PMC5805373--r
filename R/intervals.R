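#' Genomic intervals
#'
#' Constructs a validated table of genomic intervals. All coordinates inside
#' the package are 0-based, half-open: an interval covers bases
#' `start, start+1, ..., end-1`. This is the BED convention; coordinate
#' strings in the literature (`"chr17:85414584-85419213"`) are 1-based
#' inclusive and are converted on parse (see [parse_genomic_coordinate()]).
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer-valued start positions, 0-based.
#' @param end integer-valued end positions, exclusive; must satisfy
#'   `start < end` (empty intervals are rejected).
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded), recycled.
#' @param score optional numeric score; `NaN` when absent (never silently 0).
#'
#' @return A `data.frame` of class `genomic_intervals` with columns
#'   `chrom`, `start`, `end`, `strand`, `score`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", score = NaN) {
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  score <- rep_len(as.numeric(score), n)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty strings")
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must not be NA")
  if (any(start < 0))
    stop("start must be >= 0 (0-based half-open convention)")
  if (any(start >= end))
    stop("empty or inverted intervals forbidden: need start < end")
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    strand = strand, score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' @export
print.genomic_intervals <- function(x, ...) {
  cat(sprintf("<genomic_intervals: %d interval(s) on %d chromosome(s)>\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

as_genomic_intervals <- function(df) {
  genomic_intervals(df$chrom, df$start, df$end,
                    strand = if (is.null(df$strand)) "*" else df$strand,
                    score = if (is.null(df$score)) NaN else df$score)
}

#' Parse a 1-based inclusive coordinate string
#'
#' Literature-style coordinates such as `"chr17:85414584-85419213"` use
#' 1-based endpoints with both endpoints included, so that string denotes
#' 4,630 bases. Both the ASCII hyphen and the en dash separator are accepted.
#' The result is converted to the internal 0-based half-open convention:
#' `[start - 1, end)`.
#'
#' @param text coordinate string(s) `chrom:start-end` (1-based inclusive).
#' @return `genomic_intervals` with one row per input string.
#' @seealso [format_genomic_coordinate()] for the inverse.
#' @examples
#' iv <- parse_genomic_coordinate("chr17:85414584-85419213")
#' interval_length(iv)  # 4630
#' @export
parse_genomic_coordinate <- function(text) {
  text <- as.character(text)
  # en dash (U+2013), minus sign (U+2212) or hyphen all seen in print
  norm <- gsub("–|−", "-", text)
  norm <- gsub(",", "", norm)
  m <- regmatches(norm, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", norm))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop("malformed coordinate string: ", paste(text[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  s1 <- as.numeric(vapply(m, `[`, "", 3L))
  e1 <- as.numeric(vapply(m, `[`, "", 4L))
  if (any(s1 < 1)) stop("1-based coordinates must be >= 1")
  if (any(s1 > e1)) stop("start > end in coordinate string")
  genomic_intervals(chrom, s1 - 1, e1)
}

#' Format intervals as 1-based inclusive coordinate strings
#'
#' Inverse of [parse_genomic_coordinate()]: round-trips exactly.
#'
#' @param iv `genomic_intervals`.
#' @param dash separator to emit; default plain hyphen.
#' @return character vector `chrom:start-end` with 1-based inclusive ends.
#' @export
format_genomic_coordinate <- function(iv, dash = "-") {
  sprintf("%s:%.0f%s%.0f", iv$chrom, iv$start + 1, dash, iv$end)
}

#' Interval lengths in bp
#'
#' @param iv `genomic_intervals` (or any data frame with `start`, `end`).
#' @return numeric vector `end - start`.
#' @export
interval_length <- function(iv) iv$end - iv$start

#' Interval center positions
#'
#' The peak-center used throughout the overlap and motif statistics.
#' For odd-length intervals the center is `floor((start + end) / 2)`.
#'
#' @param iv `genomic_intervals`.
#' @return numeric vector of 0-based center positions.
#' @export
interval_center <- function(iv) floor((iv$start + iv$end) / 2)

#' Merge overlapping or bookended intervals
#'
#' Returns the minimal set of disjoint intervals with identical base
#' coverage. Strand and score are dropped (merged regions are unstranded).
#' Idempotent; total covered bp is conserved.
#'
#' @param ivs `genomic_intervals`.
#' @return `genomic_intervals`, sorted by (chrom, start), pairwise disjoint.
#' @export
merge_intervals <- function(ivs) {
  if (nrow(ivs) == 0) return(ivs)
  o <- order(ivs$chrom, ivs$start, ivs$end)
  chrom <- ivs$chrom[o]; start <- ivs$start[o]; end <- ivs$end[o]
  keep_chrom <- character(0); keep_start <- numeric(0); keep_end <- numeric(0)
  cur_c <- chrom[1]; cur_s <- start[1]; cur_e <- end[1]
  n <- length(start)
  if (n > 1) {
    for (i in 2:n) {
      if (chrom[i] == cur_c && start[i] <= cur_e) {
        cur_e <- max(cur_e, end[i])
      } else {
        keep_chrom <- c(keep_chrom, cur_c)
        keep_start <- c(keep_start, cur_s)
        keep_end <- c(keep_end, cur_e)
        cur_c <- chrom[i]; cur_s <- start[i]; cur_e <- end[i]
      }
    }
  }
  genomic_intervals(c(keep_chrom, cur_c), c(keep_start, cur_s),
                    c(keep_end, cur_e))
}

#' Total base coverage of an interval set
#'
#' Merges first, so overlapping input intervals are not double counted.
#'
#' @param ivs `genomic_intervals`.
#' @return total covered bp.
#' @export
coverage_size <- function(ivs) {
  if (nrow(ivs) == 0) return(0)
  sum(interval_length(merge_intervals(ivs)))
}

#' Peak set
#'
#' A named set of peaks for one factor. The peak count `N_A = n_peaks(x)`
#' is the number of binomial trials in every enrichment statistic, so the
#' set, not the individual peak, is the unit of analysis.
#'
#' @param intervals `genomic_intervals` (or coercible data frame).
#' @param name factor label, e.g. `"Six2"`.
#' @param source_convention provenance of the coordinates:
#'   `"bed_half_open"` (default) or `"paper_inclusive"` (1-based inclusive
#'   input that was shifted on read). Recorded, not acted on.
#' @return object of class `peak_set`: the interval table with attributes
#'   `name` and `source_convention`, sorted by (chrom, start) with
#'   stable peak ids in `peak_id`.
#' @export
peak_set <- function(intervals, name,
                     source_convention = c("bed_half_open", "paper_inclusive")) {
  source_convention <- match.arg(source_convention)
  iv <- as_genomic_intervals(as.data.frame(intervals))
  o <- order(iv$chrom, iv$start, iv$end)
  iv <- iv[o, , drop = FALSE]
  rownames(iv) <- NULL
  iv$peak_id <- sprintf("%s_%d", name, seq_len(nrow(iv)))
  attr(iv, "name") <- name
  attr(iv, "source_convention") <- source_convention
  class(iv) <- c("peak_set", "genomic_intervals", "data.frame")
  iv
}

#' @rdname peak_set
#' @param x a `peak_set`.
#' @export
n_peaks <- function(x) nrow(x)

#' @rdname peak_set
#' @export
peak_set_name <- function(x) attr(x, "name")

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set '%s': %d peaks (%s)>\n", attr(x, "name"), nrow(x),
              attr(x, "source_convention")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Genome model
#'
#' Chromosome sizes and the derived total genome size used as the
#' denominator of the uniform-genome null in regulatory-domain enrichment.
#'
#' @param chrom_sizes named numeric vector, chromosome name to length (bp).
#' @return object of class `genome_model`: list with `chrom_sizes` and
#'   `genome_size`.
#' @export
genome_model <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  structure(list(chrom_sizes = chrom_sizes,
                 genome_size = sum(chrom_sizes)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model: %d chromosome(s), %.0f bp>\n",
              length(x$chrom_sizes), x$genome_size))
  invisible(x)
}

#' Check that intervals lie within a genome model
#'
#' @param ivs `genomic_intervals`.
#' @param genome `genome_model`.
#' @return invisibly `TRUE`; errors on unknown chromosome or out-of-bounds.
#' @export
validate_against_genome <- function(ivs, genome) {
  unknown <- setdiff(unique(ivs$chrom), names(genome$chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  lim <- genome$chrom_sizes[ivs$chrom]
  if (any(ivs$end > lim))
    stop("interval(s) extend beyond chromosome end")
  invisible(TRUE)
}

# clip intervals to chromosome bounds, dropping those that vanish
clip_to_genome <- function(ivs, genome) {
  lim <- genome$chrom_sizes[ivs$chrom]
  s <- pmax(ivs$start, 0)
  e <- pmin(ivs$end, lim)
  keep <- s < e
  genomic_intervals(ivs$chrom[keep], s[keep], e[keep],
                    strand = ivs$strand[keep], score = ivs$score[keep])
}
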