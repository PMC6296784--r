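#' Interval tibbles
#'
#' All overlap machinery in rloopstat works on plain tibbles with at least the
#' columns `chrom` (character), `start` and `end` (integer base positions).
#' Coordinates are 0-based, half-open — the BED convention — so an interval
#' covers bases `start, start + 1, ..., end - 1` and two intervals that merely
#' abut do not overlap.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param arg Name used in error messages.
#' @return `as_intervals()` returns a validated tibble sorted by
#'   `(chrom, start, end)`.
#' @examples
#' as_intervals(data.frame(chrom = "chrI", start = 100, end = 200))
#' @export
as_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals.", arg))
  }
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing interval column(s): %s.",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  out <- as_tibble(x)
  out$chrom <- as.character(out$chrom)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  bad <- which(!is.finite(out$start) | !is.finite(out$end) |
    out$start < 0L | out$start >= out$end)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` has invalid interval(s) at row(s) %s: need 0 <= start < end.",
      arg, paste(head(bad, 5), collapse = ", ")
    ))
  }
  sort_intervals(out)
}

#' @rdname as_intervals
#' @export
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end, method = "radix"), , drop = FALSE]
}

#' Read and write BED interval files
#'
#' `read_bed()` parses a BED file into an interval tibble; `write_bed()`
#' writes one back out as sorted BED3. Coordinates stay 0-based half-open on
#' both sides of the round trip. `browser`, `track`, `#` comment and blank
#' lines are skipped on read; columns beyond the third are ignored on read
#' and dropped on write.
#'
#' @param path Path to a BED file.
#' @return `read_bed()` returns an interval tibble with columns `chrom`,
#'   `start`, `end`, sorted by position.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' write_bed(tibble::tibble(chrom = "chrI", start = 0L, end = 10L), tf)
#' read_bed(tf)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("BED file does not exist: '%s'.", path))
  }
  lines <- readr::read_lines(path)
  skip <- grepl("^(browser|track)(\\s|$)", lines) | grepl("^#", lines) |
    !nzchar(trimws(lines))
  keep_idx <- which(!skip)
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  if (length(keep_idx) == 0) {
    return(empty)
  }
  # BED is ragged by design (3-12 columns); take the first three fields
  fields <- strsplit(lines[keep_idx], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf(
      "BED file '%s' has fewer than 3 columns at line(s) %s.",
      path, paste(head(keep_idx[short], 5), collapse = ", ")
    ))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed BED coordinates in '%s' at line(s) %s (need integer start < end).",
      path, paste(head(keep_idx[bad], 5), collapse = ", ")
    ))
  }
  sort_intervals(tibble(chrom = chrom, start = start, end = end))
}

#' @rdname read_bed
#' @param x An interval tibble (see [as_intervals()]).
#' @return `write_bed()` invisibly returns `path`.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  readr::write_tsv(x[, c("chrom", "start", "end")], path, col_names = FALSE,
    progress = FALSE)
  invisible(path)
}

#' Pairwise interval overlap predicate
#'
#' Two intervals overlap when they are on the same chromosome and share at
#' least one base: `max(start_a, start_b) < min(end_a, end_b)`. Vectorised
#' over rows; a length-1 side is recycled.
#'
#' @param a,b Interval tibbles with the same number of rows (or one row).
#' @return A logical vector.
#' @examples
#' a <- tibble::tibble(chrom = "chrI", start = 0L, end = 10L)
#' b <- tibble::tibble(chrom = "chrI", start = c(9L, 10L), end = c(20L, 20L))
#' interval_overlaps(a, b) # TRUE FALSE: half-open intervals that abut miss
#' @export
interval_overlaps <- function(a, b) {
  a <- as_tibble(a)
  b <- as_tibble(b)
  a$chrom == b$chrom & pmax(a$start, b$start) < pmin(a$end, b$end)
}

#' Which query intervals overlap any target interval?
#'
#' Any-overlap semantics (>= 1 shared base), per chromosome, strand-ignorant.
#' Queries are matched against targets with `IRanges::overlapsAny()` after
#' converting the half-open coordinates to 1-based closed form.
#'
#' @param query,targets Interval tibbles.
#' @return A logical vector with one element per row of `query`.
#' @export
overlaps_any <- function(query, targets) {
  query <- as_tibble(query)
  targets <- as_tibble(targets)
  hit <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(targets) == 0) {
    return(hit)
  }
  for (ch in intersect(unique(query$chrom), unique(targets$chrom))) {
    qi <- which(query$chrom == ch)
    ti <- which(targets$chrom == ch)
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    tr <- IRanges::IRanges(start = targets$start[ti] + 1L, end = targets$end[ti])
    hit[qi] <- IRanges::overlapsAny(qr, tr)
  }
  hit
}

# TSV writer that preserves doubles bit-exactly across a write/read round
# trip: 17 significant digits are enough to reproduce any IEEE double.
write_tsv_exact <- function(df, path, col_names = TRUE) {
  is_dbl <- vapply(df, is.double, logical(1))
  df[is_dbl] <- lapply(df[is_dbl], function(x) sprintf("%.17g", x))
  readr::write_tsv(df, path, col_names = col_names, progress = FALSE)
  invisible(path)
}

# Incidence structure: for each target row, the indices of query rows it
# overlaps. Lets a permutation loop score thousands of resampled target
# subsets without re-running interval queries.
overlap_incidence <- function(query, targets) {
  query <- as_tibble(query)
  targets <- as_tibble(targets)
  by_target <- vector("list", nrow(targets))
  for (ch in intersect(unique(query$chrom), unique(targets$chrom))) {
    qi <- which(query$chrom == ch)
    ti <- which(targets$chrom == ch)
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    tr <- IRanges::IRanges(start = targets$start[ti] + 1L, end = targets$end[ti])
    hits <- IRanges::findOverlaps(qr, tr)
    from <- qi[S4Vectors::queryHits(hits)]
    to <- ti[S4Vectors::subjectHits(hits)]
    sp <- split(from, to)
    by_target[as.integer(names(sp))] <- sp
  }
  by_target
}

#' Remove peaks that overlap a control set
#'
#' Drops every peak that overlaps at least one interval of a control set —
#' the standard cleanup that removes no-antibody (bead control) artifact
#' peaks from a ChIP-seq peak set. A peak is removed on any overlap; no
#' reciprocal-fraction threshold is applied.
#'
#' @param peaks,control Interval tibbles.
#' @return The rows of `peaks` that overlap no `control` interval, input
#'   order preserved.
#' @examples
#' peaks <- tibble::tibble(chrom = "chrI", start = c(0L, 50L), end = c(10L, 60L))
#' ctrl <- tibble::tibble(chrom = "chrI", start = 5L, end = 8L)
#' filter_against_control(peaks, ctrl)
#' @export
filter_against_control <- function(peaks, control) {
  peaks <- as_tibble(peaks)
  control <- as_tibble(control)
  peaks[!overlaps_any(peaks, control), , drop = FALSE]
}

#' Select the top fraction of genes by expression
#'
#' Orders genes by expression (descending, ties broken by `gene_id`
#' ascending so the cut is deterministic), drops blacklisted identifiers
#' first, and keeps the first `floor(fraction * n_remaining)` records — e.g.
#' the top 10% of transcribed genes with rDNA loci excluded.
#'
#' @param genes A gene tibble with columns `gene_id`, `chrom`, `start`,
#'   `end`, `expression`.
#' @param fraction Fraction of (non-blacklisted) genes to keep, in (0, 1].
#' @param blacklist Character vector of `gene_id`s to exclude before the
#'   cut is computed. Note that with `floor()` the result can be empty when
#'   `fraction * n_remaining < 1`.
#' @return A tibble of the selected gene records, highest expression first.
#' @export
top_fraction_genes <- function(genes, fraction = 0.1, blacklist = character()) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) {
    abort("`genes` must be non-empty.")
  }
  if (!is.numeric(fraction) || length(fraction) != 1 ||
    is.na(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single number in (0, 1].")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("`genes$gene_id` must be unique.")
  }
  kept <- genes[!(genes$gene_id %in% blacklist), , drop = FALSE]
  k <- floor(fraction * nrow(kept))
  ord <- order(-kept$expression, kept$gene_id, method = "radix")
  kept[head(ord, k), , drop = FALSE]
}

#' Read and write gene annotation tables
#'
#' Tab-separated with header `gene_id  chrom  start  end  expression`;
#' coordinates 0-based half-open, expression in arbitrary transcription
#' units (non-negative).
#'
#' @param path Path to a TSV file.
#' @return `read_gene_table()` returns a gene tibble.
#' @export
read_gene_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    expression = readr::col_character()
  ), progress = FALSE)
  # strtod via as.numeric: correctly rounded, so TSV round trips bit-exactly
  out$expression <- as.numeric(out$expression)
  if (any(out$expression < 0)) {
    abort(sprintf("Negative expression value(s) in '%s'.", path))
  }
  if (anyDuplicated(out$gene_id)) {
    abort(sprintf("Duplicate gene_id(s) in '%s'.", path))
  }
  out
}

#' @rdname read_gene_table
#' @param genes A gene tibble.
#' @export
write_gene_table <- function(genes, path) {
  write_tsv_exact(
    genes[, c("gene_id", "chrom", "start", "end", "expression")], path
  )
}
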