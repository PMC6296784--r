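#' Configuration for the synthetic-data generators
#'
#' The generators produce every input the pipeline consumes — a genome
#' annotation with per-gene expression, peak sets with a tunable
#' probability of landing in highly expressed genes, Ct plate tables
#' derived from known true enrichments, and ranked differential-expression
#' tables with known peak-overlap structure — all pure functions of
#' (config, seed), so every stage can be tested against ground truth
#' without external downloads.
#'
#' The default genome is 3 chromosomes of 300 kb carrying 600
#' non-overlapping genes (mean length 800 bp, a yeast-like density) and
#' 150 peaks of 300 bp (narrow ChIP peaks), with log-normal expression.
#'
#' @param n_chroms,chrom_length Number of chromosomes and their common
#'   length in bases.
#' @param n_genes,gene_length_mean Gene count and mean gene length (bases).
#' @param expression_mu,expression_sigma Log-scale mean and sd of the
#'   log-normal expression model.
#' @param n_peaks,peak_length Peak count and fixed peak length (bases).
#' @param enrichment_theta Probability in \[0, 1\] that a peak is placed
#'   inside a uniformly chosen top-fraction gene rather than uniformly on
#'   the genome; 0 gives a null genome, values near 1 a strongly enriched
#'   one.
#' @param top_fraction Expression quantile defining the "top" gene set
#'   (default 0.1, the top 10% of transcribed genes).
#' @param ct_noise_sd Gaussian noise sd on the Ct (cycle) scale — the
#'   conventional qPCR error model (default 0.2 cycles).
#' @param true_folds Named positive vector, locus -> true enrichment: the
#'   fold over input for `drip`, the mock-subtracted percent enrichment
#'   for `chip`, and the fold change for `ddct` simulation designs.
#' @param mock_percent True mock (no-antibody) percent-of-input background
#'   used by the `chip` design.
#' @param base_ct Input-sample Ct around which the plate is built.
#' @param dilution Dilution factor carried on simulated Ct records.
#' @param n_replicates Technical replicates per Ct measurement.
#' @param seed Default integer seed for the generators.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chroms = 3, chrom_length = 300000L,
                             n_genes = 600, gene_length_mean = 800,
                             expression_mu = 3, expression_sigma = 1,
                             n_peaks = 150, peak_length = 300,
                             enrichment_theta = 0, top_fraction = 0.1,
                             ct_noise_sd = 0.2,
                             true_folds = c("ADH1-2" = 4, "ENO2-3" = 2,
                               "FBA1-2" = 8),
                             mock_percent = 0.5, base_ct = 18,
                             dilution = 10, n_replicates = 3, seed = 1) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes), gene_length_mean = gene_length_mean,
    expression_mu = expression_mu, expression_sigma = expression_sigma,
    n_peaks = as.integer(n_peaks), peak_length = as.integer(peak_length),
    enrichment_theta = enrichment_theta, top_fraction = top_fraction,
    ct_noise_sd = ct_noise_sd, true_folds = true_folds,
    mock_percent = mock_percent, base_ct = base_ct, dilution = dilution,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  )
  if (any(c(cfg$n_chroms, cfg$chrom_length, cfg$n_genes, cfg$n_peaks,
    cfg$peak_length, cfg$n_replicates) < 1)) {
    abort("All synthetic counts and lengths must be positive.")
  }
  if (cfg$enrichment_theta < 0 || cfg$enrichment_theta > 1) {
    abort("`enrichment_theta` must be in [0, 1].")
  }
  if (cfg$ct_noise_sd < 0) {
    abort("`ct_noise_sd` must be non-negative.")
  }
  if (is.null(names(cfg$true_folds)) || any(cfg$true_folds <= 0)) {
    abort("`true_folds` must be a named vector of positive values.")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes on the configured chromosomes (genes are
#' dealt round-robin across chromosomes; the slack on each chromosome is
#' split into random inter-genic gaps) and draws expression levels from the
#' configured log-normal. Reproducible: the same (config, seed) yields the
#' same annotation.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with `genes` (a gene tibble) and `truth` (a list
#'   retaining the config, the realised top-fraction `top_gene_ids`, the
#'   configured `true_folds`, and a `peak_in_top_count` slot filled in by
#'   [generate_peaks()]).
#' @export
generate_annotation <- function(config, seed = config$seed) {
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  genes <- withr::with_seed(seed, {
    len <- pmax(200L, as.integer(round(rlnorm(config$n_genes,
      meanlog = log(config$gene_length_mean) - 0.35^2 / 2, sdlog = 0.35))))
    chrom_idx <- rep_len(seq_len(config$n_chroms), config$n_genes)
    expr <- rlnorm(config$n_genes, config$expression_mu, config$expression_sigma)
    starts <- integer(config$n_genes)
    for (ci in seq_len(config$n_chroms)) {
      on_chrom <- which(chrom_idx == ci)
      n_c <- length(on_chrom)
      free <- config$chrom_length - sum(len[on_chrom])
      if (free < 0) {
        abort(sprintf(
          "Infeasible gene density: %d genes of total length %d exceed chromosome length %d.",
          n_c, sum(len[on_chrom]), config$chrom_length
        ))
      }
      w <- rexp(n_c + 1)
      gaps <- floor(free * w / sum(w))
      starts[on_chrom] <- cumsum(c(0L, len[on_chrom][-n_c])) +
        cumsum(gaps[seq_len(n_c)])
    }
    tibble(
      gene_id = sprintf("g%04d", seq_len(config$n_genes)),
      chrom = chrom_names[chrom_idx],
      start = as.integer(starts),
      end = as.integer(starts + len),
      expression = expr
    )
  })
  truth <- list(
    config = config,
    top_gene_ids = top_fraction_genes(genes, config$top_fraction)$gene_id,
    true_folds = config$true_folds,
    peak_in_top_count = NA_integer_
  )
  list(genes = genes, truth = truth)
}

#' Generate a synthetic peak set with tunable gene-set enrichment
#'
#' Each peak is placed independently: with probability
#' `config$enrichment_theta` it is dropped uniformly inside a uniformly
#' chosen top-fraction gene (clipped to the gene body so enrichment is
#' exact by construction), otherwise uniformly on the genome. The realised
#' number of in-top placements is recorded in the returned truth.
#'
#' @param genes A gene tibble from [generate_annotation()].
#' @param truth The matching truth list.
#' @param config The [synthetic_config()] used to generate the annotation.
#' @param seed Integer seed (defaults to `config$seed + 1` so peak
#'   placement is decoupled from gene placement).
#' @return A list with `peaks` (a sorted interval tibble) and the updated
#'   `truth`.
#' @export
generate_peaks <- function(genes, truth, config, seed = config$seed + 1L) {
  top <- genes[genes$gene_id %in% truth$top_gene_ids, , drop = FALSE]
  if (config$enrichment_theta > 0 && nrow(top) == 0) {
    abort("enrichment_theta > 0 requires a non-empty top gene set.")
  }
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  pk_len <- config$peak_length
  drawn <- withr::with_seed(seed, {
    in_top <- runif(config$n_peaks) < config$enrichment_theta
    chrom <- character(config$n_peaks)
    start <- integer(config$n_peaks)
    end <- integer(config$n_peaks)
    for (i in seq_len(config$n_peaks)) {
      if (in_top[i]) {
        g <- top[sample.int(nrow(top), 1), ]
        s <- as.integer(floor(runif(1, g$start, max(g$start, g$end - pk_len) + 1)))
        chrom[i] <- g$chrom
        start[i] <- s
        end[i] <- min(s + pk_len, g$end)
      } else {
        ci <- sample.int(config$n_chroms, 1)
        s <- as.integer(floor(runif(1, 0, config$chrom_length - pk_len + 1)))
        chrom[i] <- chrom_names[ci]
        start[i] <- s
        end[i] <- s + pk_len
      }
    }
    list(peaks = tibble(chrom = chrom, start = start, end = end),
      n_in_top = sum(in_top))
  })
  truth$peak_in_top_count <- drawn$n_in_top
  list(peaks = sort_intervals(drawn$peaks), truth = truth)
}

#' Simulate a Ct plate table from known true enrichments
#'
#' Inverts the quantitation formulas: for the `drip` design each drip-role
#' Ct is `base_ct - log2(dilution) - log2(F) + e` with
#' `e ~ Normal(0, ct_noise_sd)`, so [quantify_qpcr()] recovers the true
#' fold `F` exactly at zero noise. The `chip` design analogously encodes a
#' true mock-subtracted percent on top of a `mock_percent` background, and
#' `ddct` encodes a fold change of a `treated` sample over a `control`
#' sample against a shared reference amplicon (locus `"REF"`). Replicates
#' receive independent noise.
#'
#' @param design `"drip"`, `"chip"` or `"ddct"`.
#' @param config A [synthetic_config()]; `config$true_folds` names the loci
#'   and their true values.
#' @param seed Integer seed (defaults to `config$seed + 2`).
#' @return A Ct tibble (`sample`, `locus`, `role`, `dilution`, `ct`,
#'   `replicate`).
#' @export
simulate_ct <- function(design = c("drip", "chip", "ddct"), config,
                        seed = config$seed + 2L) {
  design <- match.arg(design)
  folds <- config$true_folds
  n_rep <- config$n_replicates
  d <- config$dilution
  base <- config$base_ct
  noise <- function(n) rnorm(n, 0, config$ct_noise_sd)
  withr::with_seed(seed, {
    rows <- purrr::imap(folds, function(f, locus) {
      reps <- seq_len(n_rep)
      switch(design,
        drip = dplyr::bind_rows(
          tibble(sample = "S1", locus = locus, role = "input",
            dilution = d, ct = rep(base, n_rep), replicate = reps),
          tibble(sample = "S1", locus = locus, role = "drip", dilution = d,
            ct = base - log2(d) - log2(f) + noise(n_rep), replicate = reps)
        ),
        chip = {
          raw_pct <- f + config$mock_percent
          dplyr::bind_rows(
            tibble(sample = "S1", locus = locus, role = "input",
              dilution = d, ct = rep(base, n_rep), replicate = reps),
            tibble(sample = "S1", locus = locus, role = "ip", dilution = d,
              ct = base - log2(d) - log2(raw_pct / 100) + noise(n_rep),
              replicate = reps),
            tibble(sample = "S1", locus = locus, role = "mock", dilution = d,
              ct = base - log2(d) - log2(config$mock_percent / 100) +
                noise(n_rep), replicate = reps)
          )
        },
        ddct = dplyr::bind_rows(
          tibble(sample = "control", locus = locus, role = "ip",
            dilution = 1, ct = base + 4 + noise(n_rep), replicate = reps),
          tibble(sample = "treated", locus = locus, role = "ip",
            dilution = 1, ct = base + 4 - log2(f) + noise(n_rep),
            replicate = reps)
        )
      )
    })
    out <- dplyr::bind_rows(rows)
    if (design == "ddct") {
      reps <- seq_len(n_rep)
      out <- dplyr::bind_rows(out,
        tibble(sample = "control", locus = "REF", role = "reference",
          dilution = 1, ct = base + 2 + noise(n_rep), replicate = reps),
        tibble(sample = "treated", locus = "REF", role = "reference",
          dilution = 1, ct = base + 2 + noise(n_rep), replicate = reps)
      )
    }
    out
  })
}

#' Generate a ranked DE table with known peak-overlap structure
#'
#' Builds a ranked differential-expression table in which a chosen set of
#' `n_top_true` genes receives the smallest p-values, and synthesises a
#' matching peak set: each top gene carries a peak inside its body with
#' probability `p_top`, each background gene with probability
#' `p_background` (peaks are clipped to the gene body, so overlap
#' probabilities are exact and independent across genes). With
#' `p_top == p_background` overlap is independent of rank and
#' [de_peak_enrichment()] p-values are calibrated; the defaults (0.60 vs
#' 0.35) mirror a strongly R-loop-associated DE signature over a ~35%
#' background overlap rate.
#'
#' @param genes A gene tibble (e.g. from [generate_annotation()]).
#' @param p_top,p_background Per-gene peak-overlap probabilities for top
#'   and background genes.
#' @param n_top_true Number of truly differential genes.
#' @param peak_length Maximum peak length in bases (clipped to the gene).
#' @param prop_up Probability that a truly differential gene is
#'   up-regulated (default 0.514, slightly more increases than decreases);
#'   background genes are `unchanged`.
#' @param seed Integer seed.
#' @return A list with `ranked` (a ranked-gene tibble), `peaks` (an
#'   interval tibble) and `truth` (top gene ids and per-gene overlap
#'   indicator).
#' @export
generate_ranked_table <- function(genes, p_top = 0.6, p_background = 0.35,
                                  n_top_true = 100, peak_length = 300,
                                  prop_up = 0.514, seed = 1) {
  genes <- as_tibble(genes)
  n <- nrow(genes)
  if (n_top_true < 1 || n_top_true > n) {
    abort(sprintf("`n_top_true` (%d) must be between 1 and %d.", n_top_true, n))
  }
  if (any(c(p_top, p_background) < 0) || any(c(p_top, p_background) > 1)) {
    abort("`p_top` and `p_background` must be probabilities.")
  }
  withr::with_seed(seed, {
    top_idx <- sample.int(n, n_top_true)
    is_top <- seq_len(n) %in% top_idx
    hit <- runif(n) < ifelse(is_top, p_top, p_background)
    p_value <- runif(n, 1e-3, 1)
    p_value[is_top] <- runif(n_top_true, 0, 1e-6)
    direction <- rep("unchanged", n)
    direction[is_top] <- ifelse(runif(n_top_true) < prop_up, "up", "down")
    pk <- genes[hit, , drop = FALSE]
    pk_start <- as.integer(floor(runif(nrow(pk), pk$start,
      pmax(pk$start, pk$end - peak_length) + 1)))
    peaks <- tibble(
      chrom = pk$chrom,
      start = pk_start,
      end = pmin(pk_start + as.integer(peak_length), pk$end)
    )
    list(
      ranked = tibble(
        gene_id = genes$gene_id, chrom = genes$chrom, start = genes$start,
        end = genes$end, p_value = p_value, direction = direction
      ),
      peaks = sort_intervals(peaks),
      truth = list(
        top_gene_ids = genes$gene_id[top_idx],
        overlap = setNames(hit, genes$gene_id),
        p_top = p_top, p_background = p_background
      )
    )
  })
}
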