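# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (O(n*m) loops, closed forms) so they check the fast
# implementation rather than mirror it.

brute_pair_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && max(s1, s2) < min(e1, e2)
}

brute_overlaps_any <- function(query, targets) {
  vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(targets)), function(j) {
      brute_pair_overlap(
        query$chrom[i], query$start[i], query$end[i],
        targets$chrom[j], targets$start[j], targets$end[j]
      )
    }, logical(1)))
  }, logical(1))
}

brute_overlap_fraction <- function(query, targets) {
  mean(brute_overlaps_any(query, targets))
}

brute_filter_control <- function(peaks, control) {
  peaks[!brute_overlaps_any(peaks, control), , drop = FALSE]
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 5000,
                             max_len = 200) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}

random_genes <- function(n, chroms = c("chrA", "chrB"), max_pos = 5000) {
  iv <- random_intervals(n, chroms, max_pos)
  iv$gene_id <- sprintf("g%03d", seq_len(n))
  iv$expression <- stats::rlnorm(n, 3, 1)
  iv[, c("gene_id", "chrom", "start", "end", "expression")]
}

# Exact Clopper-Pearson interval from the beta closed form, independent of
# stats::binom.test.
clopper_pearson <- function(r, n, level) {
  alpha <- 1 - level
  lo <- if (r == 0) 0 else stats::qbeta(alpha / 2, r, n - r + 1)
  hi <- if (r == n) 1 else stats::qbeta(1 - alpha / 2, r + 1, n - r)
  c(lo, hi)
}

# 45-peak fixture in which exactly 9 peaks overlap the target set: peaks at
# 1 kb spacing, targets covering the first 9.
worked_example_peaks <- function() {
  tibble::tibble(
    chrom = "chrI",
    start = seq(0L, by = 1000L, length.out = 45L),
    end = seq(0L, by = 1000L, length.out = 45L) + 200L
  )
}

worked_example_targets <- function() {
  tibble::tibble(
    chrom = "chrI",
    start = seq(0L, by = 1000L, length.out = 9L) + 100L,
    end = seq(0L, by = 1000L, length.out = 9L) + 400L
  )
}
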