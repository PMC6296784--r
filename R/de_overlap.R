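#' Top genes of a ranked differential-expression table
#'
#' Returns the `n` genes with the smallest differential-expression
#' p-values; ties at the boundary are broken by `gene_id` ascending so the
#' selection is deterministic across runs.
#'
#' @param table A ranked-gene tibble with columns `gene_id`, `chrom`,
#'   `start`, `end`, `p_value`, `direction`.
#' @param n Number of genes to keep (default 100); must not exceed the
#'   table size.
#' @return A tibble of `n` rows, smallest p-value first.
#' @export
top_ranked <- function(table, n = 100) {
  table <- as_tibble(table)
  if (n < 1 || n > nrow(table)) {
    abort(sprintf("`n` (%d) must be between 1 and the table size (%d).",
      n, nrow(table)))
  }
  ord <- order(table$p_value, table$gene_id, method = "radix")
  table[head(ord, n), , drop = FALSE]
}

#' Overlap enrichment of top differentially expressed genes with peaks
#'
#' Tests whether the genes showing the most evidence of differential
#' expression overlap a set of peak regions (e.g. R-loop prone regions
#' from DRIPc-seq) more often than randomly chosen genes. The observed
#' statistic is the fraction of the top `n_top` genes (by p-value) whose
#' gene body overlaps at least one peak; the null resamples `n_top` genes
#' uniformly without replacement from the full tested table — equivalent
#' to re-taking the top after randomly permuting the p-values — and the
#' permutation p-value carries a 99% confidence interval.
#'
#' @param table A ranked-gene tibble (see [top_ranked()]).
#' @param peaks An interval tibble of peak regions.
#' @param n_top Size of the top gene set (default 100).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the resampling.
#' @param ci_level Confidence level on the permutation p-value.
#' @return An `enrich_result` (see [permutation_test()]).
#' @export
de_peak_enrichment <- function(table, peaks, n_top = 100, n_perm = 1000,
                               seed = 1, ci_level = 0.99) {
  table <- as_tibble(table)
  if (n_top < 1 || n_top > nrow(table)) {
    abort(sprintf("`n_top` (%d) must be between 1 and the table size (%d).",
      n_top, nrow(table)))
  }
  # each gene's overlap status is fixed, so resampling reduces to drawing
  # from a precomputed indicator vector
  gene_hit <- overlaps_any(table, peaks)
  top_idx <- head(order(table$p_value, table$gene_id, method = "radix"), n_top)
  observed <- mean(gene_hit[top_idx])
  n_genes <- nrow(table)
  fractions <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mean(gene_hit[sample.int(n_genes, n_top)])
    }, numeric(1))
  })
  null <- structure(
    list(fractions = fractions, n_perm = as.integer(n_perm),
      k = as.integer(n_top), seed = as.integer(seed)),
    class = "null_dist"
  )
  permutation_test(observed, null, tail = "greater", ci_level = ci_level)
}

#' Summarise altered transcripts
#'
#' Counts transcripts altered in either direction and expresses them as a
#' percentage of all quantified transcripts.
#'
#' @param up,down Character vectors (or counts) of up- and down-regulated
#'   gene identifiers; when identifiers are given the two sets must be
#'   disjoint.
#' @param total_quantified Total number of transcripts quantified.
#' @return A one-row tibble: `n_up`, `n_down`, `altered`,
#'   `percent_altered` (exact) and `percent_altered_rounded` (nearest
#'   integer).
#' @examples
#' de_summary(2578, 2435, 30769)
#' @export
de_summary <- function(up, down, total_quantified) {
  if (is.character(up) || is.character(down)) {
    if (length(intersect(up, down)) > 0) {
      abort("`up` and `down` gene sets must be disjoint.")
    }
    n_up <- length(unique(up))
    n_down <- length(unique(down))
  } else {
    n_up <- as.integer(up)
    n_down <- as.integer(down)
  }
  if (total_quantified < 1 || n_up + n_down > total_quantified) {
    abort("`total_quantified` must be >= |up| + |down|.")
  }
  altered <- n_up + n_down
  tibble(
    n_up = n_up,
    n_down = n_down,
    altered = altered,
    percent_altered = 100 * altered / total_quantified,
    percent_altered_rounded = round(100 * altered / total_quantified)
  )
}

#' Read and write ranked differential-expression tables
#'
#' Tab-separated with header `gene_id  chrom  start  end  p_value
#' direction`; `direction` is `up`, `down` or `unchanged`.
#'
#' @param path Path to a TSV file.
#' @return `read_ranked_table()` returns a ranked-gene tibble.
#' @export
read_ranked_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    p_value = readr::col_character(),
    direction = readr::col_character()
  ), progress = FALSE)
  # correctly rounded double parsing for bit-exact round trips
  out$p_value <- as.numeric(out$p_value)
  if (any(out$p_value < 0 | out$p_value > 1)) {
    abort(sprintf("p_value out of [0, 1] in '%s'.", path))
  }
  if (anyDuplicated(out$gene_id)) {
    abort(sprintf("Duplicate gene_id(s) in '%s'.", path))
  }
  out
}

#' @rdname read_ranked_table
#' @param table A ranked-gene tibble.
#' @export
write_ranked_table <- function(table, path) {
  write_tsv_exact(
    table[, c("gene_id", "chrom", "start", "end", "p_value", "direction")],
    path
  )
}
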