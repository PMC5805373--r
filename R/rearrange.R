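#' Annotated locus features
#'
#' @param name feature labels (unique).
#' @param kind one of `"enhancer"`, `"promoter_tss"`, `"boundary"`,
#'   `"gene_body"`, `"other"`, recycled.
#' @param chrom,start,end,strand interval fields (0-based half-open).
#' @return data frame of class `locus_features`.
#' @export
locus_features <- function(name, kind, chrom, start, end, strand = "*") {
  kinds <- c("enhancer", "promoter_tss", "boundary", "gene_body", "other")
  if (!all(kind %in% kinds))
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  if (anyDuplicated(name)) stop("feature names must be unique")
  iv <- genomic_intervals(chrom, start, end, strand = strand)
  out <- data.frame(name = as.character(name),
                    kind = rep_len(kind, length(name)),
                    chrom = iv$chrom, start = iv$start, end = iv$end,
                    strand = iv$strand, stringsAsFactors = FALSE)
  class(out) <- c("locus_features", "data.frame")
  out
}

#' Rearrangement plan: one inversion plus deletions
#'
#' Models a structural allele as a single inversion and a set of disjoint
#' deletions on one chromosome, all specified in original reference
#' coordinates. `order` fixes how the two are composed: with
#' `"deletions_first"` (default) the deletions are removed and the
#' inversion then acts on the shrunken axis; with `"inversion_first"` the
#' axis is inverted and the deletion intervals (mapped through the
#' inversion) are then removed. The composed position map is bijective on
#' surviving (non-deleted) bases either way.
#'
#' @param inversion one-row `genomic_intervals` (or NULL for
#'   deletions-only plans).
#' @param deletions `genomic_intervals` of disjoint deletions (or NULL).
#' @param order composition order.
#' @return object of class `rearrangement_plan`.
#' @export
rearrangement_plan <- function(inversion = NULL, deletions = NULL,
                               order = c("deletions_first",
                                         "inversion_first")) {
  order <- match.arg(order)
  chroms <- character(0)
  if (!is.null(inversion)) {
    if (nrow(inversion) != 1) stop("exactly one inversion interval")
    chroms <- c(chroms, inversion$chrom)
  }
  if (!is.null(deletions) && nrow(deletions) > 0) {
    m <- merge_intervals(deletions)
    if (nrow(m) != nrow(deletions) ||
        coverage_size(deletions) != sum(interval_length(deletions)))
      stop("deletions must be disjoint")
    deletions <- deletions[order(deletions$start), , drop = FALSE]
    chroms <- c(chroms, deletions$chrom)
  } else {
    deletions <- NULL
  }
  if (length(unique(chroms)) > 1)
    stop("plan intervals must be on a single chromosome")
  if (order == "inversion_first" && !is.null(inversion) &&
      !is.null(deletions)) {
    s <- inversion$start; e <- inversion$end
    straddle <- (deletions$start < s & deletions$end > s) |
                (deletions$start < e & deletions$end > e)
    if (any(straddle))
      stop("with inversion_first, deletions must not straddle an ",
           "inversion breakpoint")
  }
  structure(list(inversion = inversion, deletions = deletions,
                 order = order,
                 chrom = if (length(chroms)) chroms[1] else NA_character_),
            class = "rearrangement_plan")
}

#' @export
print.rearrangement_plan <- function(x, ...) {
  cat(sprintf("<rearrangement_plan on %s: %s inversion, %d deletion(s), %s>\n",
              x$chrom,
              if (is.null(x$inversion)) "no" else
                sprintf("%.0f bp", interval_length(x$inversion)),
              if (is.null(x$deletions)) 0L else nrow(x$deletions),
              x$order))
  invisible(x)
}

# monotone coordinate shift that removes deleted bp; positions inside a
# deletion return NA (strict = TRUE) or collapse to the deletion's image
# (strict = FALSE, used for interval endpoints)
deletion_shift <- function(pos, deletions, strict = TRUE) {
  if (is.null(deletions) || nrow(deletions) == 0) return(pos)
  ds <- deletions$start; de <- deletions$end
  out <- pos
  removed <- vapply(pos, function(p) sum(pmax(0, pmin(de, p) - ds)), 0)
  out <- pos - removed
  if (strict) {
    inside <- vapply(pos, function(p) any(p >= ds & p < de), FALSE)
    out[inside] <- NA_real_
  }
  out
}

# the inversion interval expressed on the axis the inversion acts on
effective_inversion <- function(plan) {
  if (is.null(plan$inversion)) return(NULL)
  s <- plan$inversion$start; e <- plan$inversion$end
  if (plan$order == "deletions_first") {
    s <- deletion_shift(s, plan$deletions, strict = FALSE)
    e <- deletion_shift(e, plan$deletions, strict = FALSE)
  }
  if (s >= e) return(NULL)  # inversion entirely deleted
  c(start = s, end = e)
}

invert_pos <- function(pos, inv) {
  if (is.null(inv)) return(pos)
  inside <- !is.na(pos) & pos >= inv["start"] & pos < inv["end"]
  pos[inside] <- inv["start"] + (inv["end"] - 1 - pos[inside])
  pos
}

#' Map reference positions through a rearrangement plan
#'
#' Deleted positions map to `NA`; every surviving base maps to a unique
#' new position (the restriction to survivors is a bijection). Positions
#' inside the inversion are mirrored (`pos -> inv_start + inv_end - 1 -
#' pos` on the acting axis); positions downstream of deletions shift left
#' by the deleted bp.
#'
#' @param pos numeric vector of 0-based positions on the plan's
#'   chromosome.
#' @param plan `rearrangement_plan`.
#' @return numeric vector of mapped positions, `NA` where deleted.
#' @export
map_position <- function(pos, plan) {
  if (plan$order == "deletions_first") {
    p <- deletion_shift(pos, plan$deletions, strict = TRUE)
    invert_pos(p, effective_inversion(plan))
  } else {
    p <- invert_pos(pos, effective_inversion(plan))
    del_mapped <- plan$deletions
    if (!is.null(del_mapped)) {
      inv <- effective_inversion(plan)
      s2 <- invert_pos(del_mapped$start, inv)
      e2 <- invert_pos(del_mapped$end - 1, inv)
      del_mapped <- genomic_intervals(del_mapped$chrom,
                                      pmin(s2, e2), pmax(s2, e2) + 1)
      del_mapped <- del_mapped[order(del_mapped$start), , drop = FALSE]
    }
    deletion_shift(p, del_mapped, strict = TRUE)
  }
}

#' Inverse of [map_position()] on surviving bases
#'
#' For a position on the rearranged axis, returns the reference position
#' that maps there. `map_position(invert_position_map(q, plan), plan) == q`
#' for every `q` in the image.
#'
#' @param pos positions on the rearranged axis.
#' @param plan `rearrangement_plan`.
#' @return reference positions.
#' @export
invert_position_map <- function(pos, plan) {
  # the map is a permutation composed of monotone pieces; invert by search
  # on each piece: undo inversion, then re-insert deletions
  if (plan$order == "deletions_first") {
    p <- invert_pos(pos, effective_inversion(plan))
    undo_deletion_shift(p, plan$deletions)
  } else {
    del_mapped <- plan$deletions
    inv <- effective_inversion(plan)
    if (!is.null(del_mapped)) {
      s2 <- invert_pos(del_mapped$start, inv)
      e2 <- invert_pos(del_mapped$end - 1, inv)
      del_mapped <- genomic_intervals(del_mapped$chrom,
                                      pmin(s2, e2), pmax(s2, e2) + 1)
      del_mapped <- del_mapped[order(del_mapped$start), , drop = FALSE]
    }
    p <- undo_deletion_shift(pos, del_mapped)
    invert_pos(p, inv)
  }
}

# inverse of deletion_shift on surviving bases
undo_deletion_shift <- function(pos, deletions) {
  if (is.null(deletions) || nrow(deletions) == 0) return(pos)
  ds <- deletions$start; de <- deletions$end
  len <- de - ds
  shifted_start <- ds - c(0, cumsum(len))[seq_along(ds)]
  vapply(pos, function(q) {
    if (is.na(q)) return(NA_real_)
    k <- sum(shifted_start <= q)
    q + if (k > 0) sum(len[seq_len(k)]) else 0
  }, 0)
}

#' Remap annotated features through a rearrangement
#'
#' Features fully outside the rearranged elements are untouched; features
#' fully inside the inversion are mirrored intact with flipped strand
#' (unstranded stays unstranded). A feature crossing an inversion
#' breakpoint is split into flagged parts; bases falling in deletions are
#' lost (a feature entirely within a deletion is dropped). Total feature
#' bp is conserved minus deleted bp. The report also records, for every
#' non-boundary feature and every boundary feature, whether their relative
#' order changed.
#'
#' @param features `locus_features`.
#' @param plan `rearrangement_plan`.
#' @return list of class `rearranged_locus`: `features` (remapped
#'   `locus_features`, split parts suffixed `_part1`, `_part2`, ...),
#'   `report` (per input feature: `status` in intact/split/truncated/
#'   dropped, `bp_in`, `bp_out`), `order_changes` (feature x boundary side
#'   flips).
#' @export
apply_rearrangement <- function(features, plan) {
  out <- list(); rep_rows <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    # atomic pieces: feature minus deletions, split at inversion edges
    cuts <- sort(unique(c(
      f$start, f$end,
      if (!is.null(plan$inversion))
        pmin(pmax(c(plan$inversion$start, plan$inversion$end), f$start),
             f$end),
      if (!is.null(plan$deletions))
        pmin(pmax(c(plan$deletions$start, plan$deletions$end), f$start),
             f$end))))
    pieces <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
    pieces <- pieces[pieces$start < pieces$end, , drop = FALSE]
    mapped <- list()
    for (k in seq_len(nrow(pieces))) {
      a <- map_position(pieces$start[k], plan)
      b <- map_position(pieces$end[k] - 1, plan)
      if (is.na(a) || is.na(b)) next  # deleted piece
      inverted <- b < a
      strand <- f$strand
      if (inverted && strand %in% c("+", "-"))
        strand <- if (strand == "+") "-" else "+"
      mapped[[length(mapped) + 1]] <- data.frame(
        start = min(a, b), end = max(a, b) + 1, strand = strand,
        inverted = inverted, stringsAsFactors = FALSE)
    }
    bp_in <- f$end - f$start
    if (!length(mapped)) {
      rep_rows[[i]] <- data.frame(name = f$name, status = "dropped",
                                  bp_in = bp_in, bp_out = 0,
                                  stringsAsFactors = FALSE)
      next
    }
    md <- do.call(rbind, mapped)
    # merge adjacent images with the same orientation (e.g. across an
    # excised internal deletion)
    md <- md[order(md$start), , drop = FALSE]
    merged <- md[1, , drop = FALSE]
    if (nrow(md) > 1) {
      for (k in 2:nrow(md)) {
        last <- nrow(merged)
        if (md$start[k] <= merged$end[last] &&
            md$inverted[k] == merged$inverted[last] &&
            md$strand[k] == merged$strand[last]) {
          merged$end[last] <- max(merged$end[last], md$end[k])
        } else merged <- rbind(merged, md[k, , drop = FALSE])
      }
    }
    bp_out <- sum(merged$end - merged$start)
    status <- if (nrow(merged) > 1) "split"
              else if (bp_out < bp_in) "truncated" else "intact"
    nm <- if (nrow(merged) > 1)
      sprintf("%s_part%d", f$name, seq_len(nrow(merged))) else f$name
    out[[i]] <- data.frame(name = nm, kind = f$kind, chrom = f$chrom,
                           start = merged$start, end = merged$end,
                           strand = merged$strand,
                           stringsAsFactors = FALSE)
    rep_rows[[i]] <- data.frame(name = f$name, status = status,
                                bp_in = bp_in, bp_out = bp_out,
                                stringsAsFactors = FALSE)
  }
  new_feat <- do.call(rbind, out)
  if (!is.null(new_feat)) {
    class(new_feat) <- c("locus_features", "data.frame")
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  structure(list(features = new_feat, report = report,
                 order_changes = order_changes(features, new_feat)),
            class = "rearranged_locus")
}

# side of each non-boundary feature relative to each boundary, before and
# after remapping (by feature midpoints; split parts use part 1)
order_changes <- function(before, after) {
  if (is.null(after)) return(NULL)
  mid <- function(d) (d$start + d$end) / 2
  b_bound <- before[before$kind == "boundary", , drop = FALSE]
  if (!nrow(b_bound)) return(NULL)
  base_of <- sub("_part[0-9]+$", "", after$name)
  rows <- list()
  for (j in seq_len(nrow(b_bound))) {
    bname <- b_bound$name[j]
    a_b <- after[base_of == bname, , drop = FALSE]
    if (!nrow(a_b)) next
    for (i in seq_len(nrow(before))) {
      f <- before[i, , drop = FALSE]
      if (f$kind == "boundary") next
      a_f <- after[base_of == f$name, , drop = FALSE]
      if (!nrow(a_f)) next
      side_before <- sign(mid(f) - mid(b_bound[j, , drop = FALSE]))
      side_after <- sign(mid(a_f[1, , drop = FALSE]) -
                         mid(a_b[1, , drop = FALSE]))
      rows[[length(rows) + 1]] <- data.frame(
        feature = f$name, boundary = bname,
        side_before = side_before, side_after = side_after,
        flipped = side_before != side_after, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Predict boundary-constrained enhancer-promoter contacts
#'
#' An enhancer may contact a promoter iff no boundary element lies
#' strictly between them on the current coordinate axis and their
#' separation does not exceed `max_range`. Blocking requires the
#' boundary's full interval strictly inside the open interval between the
#' enhancer center and the promoter position — touching either end does
#' not block. Distance alone never decides blocking: a long-range pair
#' with no intervening boundary is allowed while a shorter pair across a
#' boundary is blocked.
#'
#' @param features `locus_features` with at least one enhancer and one
#'   promoter (`promoter_tss`).
#' @param max_range maximum separation in bp (default `Inf`).
#' @return data frame of class `contact_predictions`: `enhancer`,
#'   `promoter`, `separation`, `blocking` (comma-joined boundary names,
#'   "" if none), `allowed`.
#' @export
predict_contacts <- function(features, max_range = Inf) {
  enh <- features[features$kind == "enhancer", , drop = FALSE]
  prom <- features[features$kind == "promoter_tss", , drop = FALSE]
  bound <- features[features$kind == "boundary", , drop = FALSE]
  if (!nrow(enh) || !nrow(prom))
    stop("need at least one enhancer and one promoter")
  enh <- enh[order(enh$name), , drop = FALSE]
  prom <- prom[order(prom$name), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(enh))) for (j in seq_len(nrow(prom))) {
    e_pos <- floor((enh$start[i] + enh$end[i]) / 2)
    p_pos <- floor((prom$start[j] + prom$end[j]) / 2)
    lo <- min(e_pos, p_pos); hi <- max(e_pos, p_pos)
    blocking <- character(0)
    if (nrow(bound) && enh$chrom[i] == prom$chrom[j]) {
      inb <- bound$chrom == enh$chrom[i] &
        bound$start > lo & (bound$end - 1) < hi
      blocking <- sort(bound$name[inb])
    }
    sep <- if (enh$chrom[i] == prom$chrom[j]) hi - lo else Inf
    rows[[length(rows) + 1]] <- data.frame(
      enhancer = enh$name[i], promoter = prom$name[j], separation = sep,
      blocking = paste(blocking, collapse = ","),
      allowed = length(blocking) == 0 && sep <= max_range,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contact_predictions", "data.frame")
  out
}

#' Size table of a rearrangement plan
#'
#' @param plan `rearrangement_plan`.
#' @return data frame `element`, `length_bp` (empty for an empty plan).
#' @export
plan_summary <- function(plan) {
  rows <- list()
  if (!is.null(plan$inversion))
    rows$inv <- data.frame(element = "inversion",
                           length_bp = interval_length(plan$inversion),
                           stringsAsFactors = FALSE)
  if (!is.null(plan$deletions))
    rows$del <- data.frame(
      element = sprintf("deletion_%d", seq_len(nrow(plan$deletions))),
      length_bp = interval_length(plan$deletions),
      stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(element = character(0), length_bp = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write rearrangement plans as JSON
#'
#' Plans are stored with 1-based inclusive coordinate strings (the
#' convention of printed locus coordinates), e.g.
#' `{"chrom": "chr17", "inversion": "chr17:1000-2000",
#'   "deletions": ["chr17:100-104"], "order": "deletions_first"}`.
#'
#' @param path JSON file.
#' @return `rearrangement_plan`.
#' @export
read_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  inv <- if (!is.null(j$inversion) && length(j$inversion))
    parse_genomic_coordinate(j$inversion) else NULL
  del <- if (!is.null(j$deletions) && length(j$deletions))
    parse_genomic_coordinate(unlist(j$deletions)) else NULL
  rearrangement_plan(inv, del,
                     order = if (is.null(j$order)) "deletions_first"
                             else j$order)
}

#' @rdname read_plan
#' @param plan `rearrangement_plan`.
#' @export
write_plan <- function(plan, path) {
  j <- list(
    chrom = plan$chrom,
    inversion = if (is.null(plan$inversion)) NULL
                else format_genomic_coordinate(plan$inversion),
    deletions = if (is.null(plan$deletions)) list()
                else as.list(format_genomic_coordinate(plan$deletions)),
    order = plan$order)
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write locus features (JSON or BED6 with kind in the name field)
#'
#' In BED form the name column is `kind:name`; JSON holds an array of
#' objects with `name`, `kind`, `chrom`, `start`, `end`, `strand`
#' (half-open coordinates).
#'
#' @param path file (`.json` or `.bed`).
#' @return `locus_features`.
#' @export
read_features <- function(path) {
  if (grepl("\\.json$", path)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(locus_features(j$name, j$kind, j$chrom, j$start, j$end,
                          if (is.null(j$strand)) "*" else j$strand))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 4) stop("feature BED needs kind:name in column 4")
  kn <- strsplit(dt[[4]], ":", fixed = TRUE)
  locus_features(vapply(kn, `[`, "", 2L), vapply(kn, `[`, "", 1L),
                 dt[[1]], dt[[2]], dt[[3]],
                 if (ncol(dt) >= 6) ifelse(dt[[6]] %in% c("+", "-"),
                                           dt[[6]], "*") else "*")
}

#' @rdname read_features
#' @param features `locus_features`.
#' @export
write_features <- function(features, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(features), path, pretty = TRUE)
  } else {
    dt <- data.table::data.table(
      features$chrom, format(features$start, scientific = FALSE, trim = TRUE),
      format(features$end, scientific = FALSE, trim = TRUE),
      paste(features$kind, features$name, sep = ":"), ".",
      ifelse(features$strand == "*", ".", features$strand))
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
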