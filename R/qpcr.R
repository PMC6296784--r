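#' Ct-based quantitation formulas
#'
#' Scalar (vectorised) forms of the cycle-threshold quantitation models.
#' Each qPCR cycle corresponds to a twofold difference in starting
#' template, so all formulas are powers of two in Ct differences, with the
#' dilution factor of the measured template entering as `log2(dilution)`.
#'
#' `chip_percent_enrichment()` is the ChIP percent-of-input model:
#' `100 * 2^(ct_input - ct_ip - log2(dilution))`, minus the same quantity
#' evaluated at the mock (no-antibody) IP's Ct when one is supplied, so
#' non-specific background is subtracted on the percent scale. A negative
#' result means the IP recovered less than the mock and is reported as-is
#' (not clipped); table-level drivers flag it as below background.
#'
#' `drip_fold_enrichment()` is the DRIP fold-over-input model:
#' `2^(ct_input - log2(dilution) - ct_drip)`.
#'
#' `ddct_fold()` is the comparative-Ct (2^-ddCt) model:
#' `2^-((ct_target_treated - ct_ref_treated) - (ct_target_control -
#' ct_ref_control))`.
#'
#' @param ct_input,ct_ip,ct_mock,ct_drip Cycle-threshold values (finite).
#'   `ct_mock = NULL` skips mock subtraction.
#' @param dilution Dilution factor of the measured template relative to the
#'   IP/input split; must be positive.
#' @return A numeric vector: percent enrichment, fold enrichment, or fold
#'   change respectively.
#' @examples
#' chip_percent_enrichment(ct_input = 20, ct_ip = 24, ct_mock = 28, dilution = 10)
#' drip_fold_enrichment(ct_input = 18, ct_drip = 15, dilution = 1) # 8
#' ddct_fold(21, 20, 22, 20) # 2
#' @export
chip_percent_enrichment <- function(ct_input, ct_ip, ct_mock = NULL,
                                    dilution = 1) {
  check_ct(ct_input, "ct_input")
  check_ct(ct_ip, "ct_ip")
  check_dilution(dilution)
  out <- 100 * 2^(ct_input - ct_ip - log2(dilution))
  if (!is.null(ct_mock)) {
    check_ct(ct_mock, "ct_mock")
    out <- out - 100 * 2^(ct_input - ct_mock - log2(dilution))
  }
  out
}

#' @rdname chip_percent_enrichment
#' @export
drip_fold_enrichment <- function(ct_input, ct_drip, dilution = 1) {
  check_ct(ct_input, "ct_input")
  check_ct(ct_drip, "ct_drip")
  check_dilution(dilution)
  2^(ct_input - log2(dilution) - ct_drip)
}

#' @rdname chip_percent_enrichment
#' @param ct_target_treated,ct_ref_treated Cts of the target and reference
#'   amplicon in the treated (or test) sample.
#' @param ct_target_control,ct_ref_control Cts of the target and reference
#'   amplicon in the control sample.
#' @export
ddct_fold <- function(ct_target_treated, ct_ref_treated,
                      ct_target_control, ct_ref_control) {
  check_ct(ct_target_treated, "ct_target_treated")
  check_ct(ct_ref_treated, "ct_ref_treated")
  check_ct(ct_target_control, "ct_target_control")
  check_ct(ct_ref_control, "ct_ref_control")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

check_ct <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric Ct value(s).", name))
  }
  invisible(x)
}

check_dilution <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort("`dilution` must be positive and finite.")
  }
  invisible(x)
}

#' Subtract a mock-IP quantitation from a raw one
#'
#' DRIP experiments carry a mock IP (empty beads) per sample whose
#' enrichment is computed with the same formula; the reported value is the
#' raw enrichment minus the mock's. Both arguments are one-row quant
#' tibbles as produced by [quantify_qpcr()]; they must agree on `sample`
#' and `locus`.
#'
#' @param raw,mock One-row tibbles with columns `sample`, `locus`, `kind`,
#'   `value`.
#' @return A one-row tibble like `raw` with `value = raw$value -
#'   mock$value`; a `flags` column carries `"below_background"` when the
#'   corrected value is <= 0.
#' @export
mock_corrected_drip <- function(raw, mock) {
  raw <- as_tibble(raw)
  mock <- as_tibble(mock)
  if (nrow(raw) != 1 || nrow(mock) != 1) {
    abort("`raw` and `mock` must each be a single quantitation row.")
  }
  if (raw$sample != mock$sample || raw$locus != mock$locus) {
    abort(sprintf(
      "Sample/locus mismatch: raw is %s/%s, mock is %s/%s.",
      raw$sample, raw$locus, mock$sample, mock$locus
    ))
  }
  raw$value <- raw$value - mock$value
  raw$flags <- if (raw$value <= 0) "below_background" else ""
  raw
}

#' Normalise quantitations to a reference sample, per locus
#'
#' Divides every value by the reference sample's value at the same locus
#' (e.g. expressing ChIP percent enrichment relative to untreated wild-type
#' cells); the reference sample's own rows become 1. The result kind is
#' `"relative_fold"`.
#'
#' @param results A quant tibble (`sample`, `locus`, `kind`, `value`, and
#'   optionally `sd`).
#' @param reference_sample Sample label to normalise to; must have a
#'   positive value at every locus present.
#' @return A tibble like `results` with rescaled `value` (and `sd`).
#' @export
relative_normalize <- function(results, reference_sample) {
  results <- as_tibble(results)
  ref <- results[results$sample == reference_sample, , drop = FALSE]
  for (loc in unique(results$locus)) {
    ref_val <- ref$value[ref$locus == loc]
    if (length(ref_val) != 1 || !is.finite(ref_val) || ref_val <= 0) {
      abort(sprintf(
        "Reference sample '%s' has no positive value at locus '%s'.",
        reference_sample, loc
      ))
    }
    sel <- results$locus == loc
    results$value[sel] <- results$value[sel] / ref_val
    if ("sd" %in% names(results)) {
      results$sd[sel] <- results$sd[sel] / ref_val
    }
  }
  results$kind <- "relative_fold"
  results
}

#' Pick the dilution whose Ct sits in the linear range
#'
#' qPCR templates are measured at several dilution factors and the one
#' whose Ct falls in the assay's linear range is used for quantitation.
#' Within each (sample, locus, role) group this returns the record whose Ct
#' (averaged over replicates at the same dilution) lies inside `ct_window`;
#' among several qualifying dilutions, the one nearest the window midpoint
#' wins. If none qualifies the nearest-to-window record is returned with an
#' `out_of_range` flag.
#'
#' @param records A Ct tibble (`sample`, `locus`, `role`, `dilution`, `ct`,
#'   optionally `replicate`).
#' @param ct_window Length-2 numeric: the inclusive linear-range Ct window.
#'   The default (15, 32) spans the usual usable range of a 40-cycle run.
#' @return One row per (sample, locus, role) with columns `sample`,
#'   `locus`, `role`, `dilution`, `ct` (replicate-mean) and `flags`.
#' @export
select_linear_dilution <- function(records, ct_window = c(15, 32)) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    abort("`records` must be non-empty.")
  }
  if (length(ct_window) != 2 || ct_window[1] >= ct_window[2]) {
    abort("`ct_window` must be an increasing pair of Ct values.")
  }
  mid <- mean(ct_window)
  records |>
    dplyr::group_by(.data$sample, .data$locus, .data$role, .data$dilution) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    dplyr::group_by(.data$sample, .data$locus, .data$role) |>
    dplyr::group_modify(function(g, key) {
      inside <- g$ct >= ct_window[1] & g$ct <= ct_window[2]
      if (any(inside)) {
        cand <- g[inside, , drop = FALSE]
        pick <- cand[which.min(abs(cand$ct - mid)), , drop = FALSE]
        pick$flags <- ""
      } else {
        dist <- pmax(ct_window[1] - g$ct, g$ct - ct_window[2], 0)
        pick <- g[which.min(dist), , drop = FALSE]
        pick$flags <- "out_of_range"
      }
      pick
    }) |>
    dplyr::ungroup()
}

#' Read and write Ct plate tables
#'
#' Tab-separated with header `sample  locus  role  dilution  ct  replicate`.
#' `role` is one of `input`, `ip`, `mock`, `drip`, `reference`.
#'
#' @param path Path to a TSV file.
#' @return `read_ct_table()` returns a Ct tibble.
#' @export
read_ct_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    locus = readr::col_character(),
    role = readr::col_character(),
    dilution = readr::col_character(),
    ct = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  # correctly rounded double parsing for bit-exact round trips
  out$dilution <- as.numeric(out$dilution)
  out$ct <- as.numeric(out$ct)
  bad_role <- setdiff(unique(out$role), c("input", "ip", "mock", "drip", "reference"))
  if (length(bad_role) > 0) {
    abort(sprintf("Unknown Ct role(s) in '%s': %s.", path,
      paste(bad_role, collapse = ", ")))
  }
  if (any(out$dilution <= 0)) {
    abort(sprintf("Non-positive dilution factor(s) in '%s'.", path))
  }
  out
}

#' @rdname read_ct_table
#' @param records A Ct tibble.
#' @export
write_ct_table <- function(records, path) {
  write_tsv_exact(
    records[, c("sample", "locus", "role", "dilution", "ct", "replicate")],
    path
  )
}

#' Quantify a Ct table
#'
#' Table-level driver over the Ct formulas. Within each (sample, locus,
#' role) group, replicate Cts are averaged before the formula is evaluated
#' (`average = "ct"`, the default); the reported `sd` is the standard
#' deviation of replicate-wise formula evaluations, pairing replicates
#' across roles by their `replicate` index (a role missing a replicate
#' contributes its mean Ct). With `average = "value"` the formula is
#' instead evaluated per replicate and the values averaged.
#'
#' Modes:
#' \describe{
#'   \item{`"chip"`}{roles `input`, `ip` and optionally `mock`; value is
#'     mock-subtracted percent enrichment of IP over input
#'     (kind `percent_enrichment`).}
#'   \item{`"drip"`}{roles `input`, `drip` and optionally `mock`; value is
#'     fold enrichment over input, with the mock IP's fold (computed the
#'     same way) subtracted when present (kind `fold_over_input`).}
#'   \item{`"ddct"`}{roles `ip` (target amplicons) and `reference` (the
#'     reference amplicon) per sample; values are 2^-ddCt fold changes of
#'     each sample relative to `reference_sample` (kind `ddct_fold`).}
#' }
#'
#' The dilution factor used in each formula is the one carried on the
#' measured (ip/drip) records of the group.
#'
#' @param records A Ct tibble (see [read_ct_table()]).
#' @param mode `"chip"`, `"drip"` or `"ddct"`.
#' @param reference_sample For `mode = "ddct"`, the control sample label;
#'   for other modes, when non-`NULL` the result is additionally passed
#'   through [relative_normalize()].
#' @param average Replicate-combination rule, `"ct"` or `"value"`.
#' @return A quant tibble: `sample`, `locus`, `kind`, `value`, `sd`,
#'   `flags`.
#' @examples
#' cfg <- synthetic_config(ct_noise_sd = 0, true_folds = c(LOC1 = 8), seed = 2)
#' ct <- simulate_ct(design = "drip", config = cfg)
#' quantify_qpcr(ct, mode = "drip") # recovers fold 8 exactly
#' @export
quantify_qpcr <- function(records, mode = c("chip", "drip", "ddct"),
                          reference_sample = NULL,
                          average = c("ct", "value")) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  records <- as_tibble(records)
  if (!"replicate" %in% names(records)) {
    records$replicate <- 1L
  }
  out <- switch(mode,
    chip = quantify_ratio_mode(records, numerator_role = "ip",
      value_fun = chip_percent_enrichment, kind = "percent_enrichment",
      average = average),
    drip = quantify_ratio_mode(records, numerator_role = "drip",
      value_fun = NULL, kind = "fold_over_input", average = average),
    ddct = quantify_ddct_mode(records, reference_sample, average)
  )
  if (mode != "ddct" && !is.null(reference_sample)) {
    out <- relative_normalize(out, reference_sample)
  }
  out
}

# Shared driver for chip (percent, mock on percent scale) and drip (fold,
# mock as an independently computed fold). Evaluates the formula once on
# replicate-mean Cts and once per replicate for the sd.
quantify_ratio_mode <- function(records, numerator_role, value_fun, kind,
                                average) {
  groups <- dplyr::distinct(records, .data$sample, .data$locus)
  purrr::pmap_dfr(groups, function(sample, locus) {
    g <- records[records$sample == sample & records$locus == locus, ]
    roles <- split(g, g$role)
    for (need in c("input", numerator_role)) {
      if (is.null(roles[[need]])) {
        abort(sprintf("Sample '%s', locus '%s': missing role '%s'.",
          sample, locus, need))
      }
    }
    dilution <- roles[[numerator_role]]$dilution[1]
    eval_one <- function(ct_of) {
      if (kind == "percent_enrichment") {
        chip_percent_enrichment(ct_of("input"), ct_of("ip"),
          ct_mock = ct_of("mock"), dilution = dilution)
      } else {
        raw <- drip_fold_enrichment(ct_of("input"), ct_of("drip"), dilution)
        if (!is.null(roles[["mock"]])) {
          raw - drip_fold_enrichment(ct_of("input"), ct_of("mock"), dilution)
        } else {
          raw
        }
      }
    }
    mean_ct <- function(role) {
      if (is.null(roles[[role]])) NULL else mean(roles[[role]]$ct)
    }
    rep_ids <- sort(unique(g$replicate))
    per_rep <- vapply(rep_ids, function(r) {
      ct_of <- function(role) {
        rr <- roles[[role]]
        if (is.null(rr)) return(NULL)
        hit <- rr$ct[rr$replicate == r]
        if (length(hit) > 0) mean(hit) else mean(rr$ct)
      }
      eval_one(ct_of)
    }, numeric(1))
    value <- if (average == "ct") eval_one(mean_ct) else mean(per_rep)
    tibble(
      sample = sample, locus = locus, kind = kind, value = value,
      sd = if (length(per_rep) > 1) sd(per_rep) else NA_real_,
      flags = if (value <= 0 &&
        (!is.null(roles[["mock"]]))) "below_background" else ""
    )
  })
}

quantify_ddct_mode <- function(records, reference_sample, average) {
  if (is.null(reference_sample)) {
    abort("`reference_sample` is required for mode = \"ddct\".")
  }
  if (!reference_sample %in% records$sample) {
    abort(sprintf("Reference sample '%s' not found in the Ct table.",
      reference_sample))
  }
  target <- records[records$role == "ip", , drop = FALSE]
  ref <- records[records$role == "reference", , drop = FALSE]
  if (nrow(target) == 0 || nrow(ref) == 0) {
    abort("ddct mode needs both 'ip' (target) and 'reference' roles.")
  }
  groups <- dplyr::distinct(target, .data$sample, .data$locus)
  purrr::pmap_dfr(groups, function(sample, locus) {
    tt <- target$ct[target$sample == sample & target$locus == locus]
    rt <- ref$ct[ref$sample == sample]
    tc <- target$ct[target$sample == reference_sample & target$locus == locus]
    rc <- ref$ct[ref$sample == reference_sample]
    if (length(tt) == 0 || length(rt) == 0 || length(tc) == 0 || length(rc) == 0) {
      abort(sprintf(
        "Sample '%s', locus '%s': incomplete target/reference Ct quartet.",
        sample, locus
      ))
    }
    n_rep <- max(length(tt), length(rt), length(tc), length(rc))
    pad <- function(x) if (length(x) >= n_rep) x[seq_len(n_rep)] else
      rep(mean(x), n_rep)
    per_rep <- ddct_fold(pad(tt), pad(rt), pad(tc), pad(rc))
    value <- if (average == "ct") {
      ddct_fold(mean(tt), mean(rt), mean(tc), mean(rc))
    } else {
      mean(per_rep)
    }
    tibble(
      sample = sample, locus = locus, kind = "ddct_fold", value = value,
      sd = if (n_rep > 1) sd(per_rep) else NA_real_, flags = ""
    )
  })
}

#' Write a quant table
#'
#' Tab-separated output with columns `sample  locus  kind  value  sd
#' flags`.
#'
#' @param results A quant tibble from [quantify_qpcr()].
#' @param path Output path.
#' @export
write_quant_table <- function(results, path) {
  readr::write_tsv(
    results[, c("sample", "locus", "kind", "value", "sd", "flags")],
    path, progress = FALSE
  )
  invisible(path)
}
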