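#' Fraction of query intervals overlapping a target set
#'
#' The overlap statistic of the permutation test: the fraction of query
#' intervals (e.g. ChIP-seq peaks) for which at least one overlap with the
#' target set was detected. A query interval overlapping several targets
#' counts once.
#'
#' @param query Non-empty interval tibble whose rows are counted.
#' @param targets Interval tibble overlapped against.
#' @return A single number in \[0, 1\].
#' @examples
#' peaks <- tibble::tibble(chrom = "chrI", start = c(0L, 100L), end = c(10L, 120L))
#' genes <- tibble::tibble(chrom = "chrI", start = 5L, end = 50L)
#' observed_overlap_fraction(peaks, genes) # 0.5
#' @export
observed_overlap_fraction <- function(query, targets) {
  query <- as_tibble(query)
  if (nrow(query) == 0) {
    abort("`query` must be non-empty: the overlap fraction is undefined.")
  }
  mean(overlaps_any(query, targets))
}

#' Null distribution of overlap fractions under gene-set resampling
#'
#' Estimates the background distribution of the overlap statistic by
#' repeatedly drawing `k` genes uniformly without replacement from the
#' annotation universe and recording the fraction of query intervals that
#' overlap the sampled gene bodies — equivalent to re-selecting the gene
#' set of interest after randomly permuting the genes. Sampled sets are
#' matched to the real set in count only, not in length or chromosome
#' composition.
#'
#' @param query Non-empty interval tibble (the fixed peak set).
#' @param universe Gene tibble to resample from (columns `gene_id`, `chrom`,
#'   `start`, `end`).
#' @param k Number of genes per draw; must not exceed `nrow(universe)`.
#' @param n_perm Number of permutations (draws).
#' @param seed Integer seed; the same seed reproduces the draw exactly.
#' @return An object of class `null_dist`: a list with `fractions` (length
#'   `n_perm`), `n_perm`, `k` and `seed`.
#' @export
sample_null <- function(query, universe, k, n_perm = 1000, seed = 1) {
  query <- as_tibble(query)
  universe <- as_tibble(universe)
  if (nrow(query) == 0) {
    abort("`query` must be non-empty.")
  }
  if (k < 1 || k > nrow(universe)) {
    abort(sprintf(
      "`k` (%d) must be between 1 and the universe size (%d).",
      k, nrow(universe)
    ))
  }
  if (n_perm < 1) {
    abort("`n_perm` must be >= 1.")
  }
  hits_by_gene <- overlap_incidence(query, universe)
  n_query <- nrow(query)
  n_genes <- nrow(universe)
  fractions <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n_genes, k)
      hit <- unlist(hits_by_gene[idx], use.names = FALSE)
      length(unique(hit)) / n_query
    }, numeric(1))
  })
  structure(
    list(fractions = fractions, n_perm = as.integer(n_perm),
      k = as.integer(k), seed = as.integer(seed)),
    class = "null_dist"
  )
}

#' Permutation test with an exact CI on the p-value
#'
#' Compares an observed overlap fraction with a resampled null
#' distribution. The p-value uses the add-one estimator
#' `(r + 1) / (n_perm + 1)`, where `r` counts null fractions at least as
#' extreme as the observation (ties count as exceedances). Because `r` is a
#' binomial count, a Monte-Carlo confidence interval for the p-value is
#' obtained from the exact Clopper-Pearson interval for the proportion
#' `r / n_perm`, mapped endpoint-wise through the same add-one rule; an
#' observation is called enriched when even the interval's upper end is
#' small.
#'
#' @param observed Observed overlap fraction.
#' @param null A `null_dist` from [sample_null()], or a numeric vector of
#'   null fractions.
#' @param tail `"greater"` (enrichment, the default) or `"less"`.
#' @param ci_level Confidence level for the p-value interval (default 0.99).
#' @param add_one Use the add-one estimator (default). With `FALSE` the raw
#'   proportion `r / n_perm` is reported (may be 0) and the interval is the
#'   unshifted Clopper-Pearson interval.
#' @return An object of class `enrich_result`; see [tidy.enrich_result()].
#' @export
permutation_test <- function(observed, null, tail = c("greater", "less"),
                             ci_level = 0.99, add_one = TRUE) {
  tail <- match.arg(tail)
  fractions <- if (inherits(null, "null_dist")) null$fractions else as.numeric(null)
  n <- length(fractions)
  if (n == 0) {
    abort("`null` must contain at least one permutation fraction.")
  }
  if (ci_level <= 0 || ci_level >= 1) {
    abort("`ci_level` must be in (0, 1).")
  }
  r <- if (tail == "greater") sum(fractions >= observed) else sum(fractions <= observed)
  ci_raw <- stats::binom.test(r, n, conf.level = ci_level)$conf.int
  if (add_one) {
    p_value <- (r + 1) / (n + 1)
    ci <- (ci_raw * n + 1) / (n + 1)
  } else {
    p_value <- r / n
    ci <- ci_raw
  }
  structure(
    list(
      observed_fraction = observed,
      null_mean = mean(fractions),
      null_sd = sd(fractions),
      p_value = p_value,
      ci_low = ci[[1]],
      ci_high = ci[[2]],
      ci_level = ci_level,
      n_perm = as.integer(n),
      n_exceed = as.integer(r),
      tail = tail,
      add_one = add_one,
      seed = if (inherits(null, "null_dist")) null$seed else NA_integer_,
      null_fractions = fractions
    ),
    class = "enrich_result"
  )
}

#' Overlap enrichment of a peak set for a gene set
#'
#' One-call composition of the permutation machinery: computes the fraction
#' of `query` intervals overlapping the feature gene bodies, builds the
#' resampling null by drawing `|feature_set|` genes at random from
#' `universe` (`n_perm` times, default 1000), and tests for enrichment
#' (upper tail) with a 99% confidence interval on the permutation p-value.
#'
#' @inheritParams sample_null
#' @param feature_set Gene tibble of the set of interest; its `gene_id`s
#'   must all be present in `universe`.
#' @param ci_level,tail,add_one Passed to [permutation_test()].
#' @return An `enrich_result`.
#' @examples
#' cfg <- synthetic_config(n_genes = 80, n_peaks = 30, enrichment_theta = 0.9, seed = 4)
#' ann <- generate_annotation(cfg)
#' pk <- generate_peaks(ann$genes, ann$truth, cfg, seed = 5)
#' top <- top_fraction_genes(ann$genes, 0.1)
#' enrich(pk$peaks, ann$genes, top, n_perm = 200, seed = 6)
#' @export
enrich <- function(query, universe, feature_set, n_perm = 1000, seed = 1,
                   ci_level = 0.99, tail = "greater", add_one = TRUE) {
  universe <- as_tibble(universe)
  feature_set <- as_tibble(feature_set)
  if (!all(feature_set$gene_id %in% universe$gene_id)) {
    abort("Every `feature_set` gene_id must be present in `universe`.")
  }
  observed <- observed_overlap_fraction(query, feature_set)
  null <- sample_null(query, universe, k = nrow(feature_set),
    n_perm = n_perm, seed = seed)
  permutation_test(observed, null, tail = tail, ci_level = ci_level,
    add_one = add_one)
}

#' @export
print.enrich_result <- function(x, ...) {
  cat("Permutation overlap enrichment\n")
  cat(sprintf("  observed fraction : %.4f\n", x$observed_fraction))
  cat(sprintf("  null mean (sd)    : %.4f (%.4f), %d permutations\n",
    x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  p-value (%s)  : %.4g  [%g%% CI %.4g, %.4g]\n",
    x$tail, x$p_value, 100 * x$ci_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Tidy an enrichment result
#'
#' @param x An `enrich_result`.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble with the observed fraction,
#'   null summary, p-value and its confidence interval; `glance()` returns
#'   a one-row tibble of test metadata.
#' @export
tidy.enrich_result <- function(x, ...) {
  tibble(
    observed_fraction = x$observed_fraction,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    p_value = x$p_value,
    ci_low = x$ci_low,
    ci_high = x$ci_high
  )
}

#' @rdname tidy.enrich_result
#' @export
glance.enrich_result <- function(x, ...) {
  tibble(
    n_perm = x$n_perm,
    n_exceed = x$n_exceed,
    ci_level = x$ci_level,
    tail = x$tail,
    add_one = x$add_one,
    seed = x$seed
  )
}

#' Plot the permutation null against the observed fraction
#'
#' Histogram of the resampled null overlap fractions with the observed
#' fraction marked; the standard picture for a region-set randomization
#' test.
#'
#' @param object An `enrich_result`.
#' @param ... Unused.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
autoplot.enrich_result <- function(object, ..., bins = 30) {
  df <- tibble(fraction = object$null_fractions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$observed_fraction,
      colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "null overlap fraction",
      y = "permutations",
      title = sprintf("Observed %.3f vs %d-permutation null (p = %.3g)",
        object$observed_fraction, object$n_perm, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Serialise an enrichment result to JSON
#'
#' @param x An `enrich_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrich_json <- function(x, path) {
  payload <- list(
    observed_fraction = x$observed_fraction,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    p_value = x$p_value,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    ci_level = x$ci_level,
    n_perm = x$n_perm,
    tail = x$tail,
    seed = x$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
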