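#' Pair normal-tissue heteroplasmies with their tumour counterparts
#'
#' For every heteroplasmic constitutional call, recomputes the variant
#' allele fraction (VAF) and heteroplasmic fraction (HF, minor allele count
#' over total read count, i.e. `min(vaf, 1 - vaf)`) in the matched tumour
#' directly from the raw tumour counts with no calling thresholds applied:
#' tracking loss of heteroplasmy requires observing tumour fractions below
#' the calling floor, so a variant allele absent from the tumour yields a
#' tumour VAF of 0 rather than a missing value. HF is defined on the
#' biallelic (ref, alt) pair; third alleles at the site are ignored (a
#' warning is issued when they exceed 1 percent of tumour depth).
#'
#' @param normal_calls variant-call data.frame; only rows with
#'   `zygosity == "heteroplasmy"` are paired.
#' @param tumour_sites site-count data.frame for the matched tumour.
#' @param min_depth tumour positions below this depth are retained but
#'   flagged `low_confidence`.
#' @param pair_id identifier attached to the emitted records.
#' @return data.frame with columns `pair_id`, `pos`, `ref`, `alt`,
#'   `normal_vaf`, `tumour_vaf`, `normal_hf`, `tumour_hf`, `delta_hf`
#'   (`normal_hf - tumour_hf`; positive = loss of heteroplasmy),
#'   `delta_vaf` (`tumour_vaf - normal_vaf`), `tumour_depth`,
#'   `low_confidence`.
#' @export
pair_heteroplasmies <- function(normal_calls, tumour_sites,
                                min_depth = 100L, pair_id = "pair") {
  het <- normal_calls[normal_calls$zygosity == "heteroplasmy", , drop = FALSE]
  tumour_sites <- validate_site_counts(tumour_sites)
  if (nrow(het) == 0L) {
    return(data.frame(pair_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      normal_vaf = numeric(0), tumour_vaf = numeric(0),
                      normal_hf = numeric(0), tumour_hf = numeric(0),
                      delta_hf = numeric(0), delta_vaf = numeric(0),
                      tumour_depth = integer(0), low_confidence = logical(0),
                      stringsAsFactors = FALSE))
  }
  m <- match(het$pos, tumour_sites$pos)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " heteroplasmic positions missing from tumour ",
            "counts were dropped")
    het <- het[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  t_depth <- tumour_sites$depth[m]
  t_vac <- vapply(seq_along(m), function(i) {
    tumour_sites[[paste0(het$alt[i], "_fwd")]][m[i]] +
      tumour_sites[[paste0(het$alt[i], "_rev")]][m[i]]
  }, numeric(1))
  ref_vac <- vapply(seq_along(m), function(i) {
    tumour_sites[[paste0(het$ref[i], "_fwd")]][m[i]] +
      tumour_sites[[paste0(het$ref[i], "_rev")]][m[i]]
  }, numeric(1))
  third <- t_depth - t_vac - ref_vac
  if (any(third > 0.01 * t_depth)) {
    warning(sum(third > 0.01 * t_depth), " paired sites carry a third ",
            "allele above 1% of tumour depth; HF uses the (ref, alt) pair only")
  }
  tumour_vaf <- ifelse(t_depth > 0, t_vac / t_depth, 0)
  out <- data.frame(
    pair_id = pair_id, pos = het$pos, ref = het$ref, alt = het$alt,
    normal_vaf = het$vaf, tumour_vaf = tumour_vaf,
    normal_hf = pmin(het$vaf, 1 - het$vaf),
    tumour_hf = pmin(tumour_vaf, 1 - tumour_vaf),
    tumour_depth = t_depth,
    low_confidence = t_depth < min_depth,
    stringsAsFactors = FALSE)
  out$delta_hf <- out$normal_hf - out$tumour_hf
  out$delta_vaf <- out$tumour_vaf - out$normal_vaf
  out
}

#' Paired t-test
#'
#' Two-tailed paired t-test `t = mean(d) / (sd(d) / sqrt(n))` on the
#' pairwise differences `d = a - b`, with `n - 1` degrees of freedom.
#'
#' @param a,b equal-length numeric vectors of paired observations.
#' @return list with `t`, `p` (two-tailed), `n`, `mean_diff`, `df`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) stop("zero variance of paired differences; ",
                              "t statistic undefined")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, n = length(a),
       mean_diff = unname(ht$estimate), df = unname(ht$parameter))
}

safe_paired_t <- function(a, b) {
  tryCatch(c(paired_t_test(a, b), degenerate = FALSE),
           error = function(e) list(t = NA_real_, p = NA_real_,
                                    n = length(a),
                                    mean_diff = mean(a - b),
                                    df = length(a) - 1L, degenerate = TRUE))
}

#' Heteroplasmy-shift summary
#'
#' Tests for directional shifts of heteroplasmies between normal and tumour
#' tissue: a paired t-test on heteroplasmic fractions (positive t = loss of
#' heteroplasmy, i.e. drift of the minor allele towards fixation or loss)
#' and a paired t-test on variant allele fractions (a significant result
#' means the variant allele specifically is preferentially amplified or
#' lost). Also counts pairs crossing the fixation (`tumour_vaf >
#' het_upper`) and loss (`tumour_vaf < het_lower`) boundaries.
#'
#' @param pairs output of [pair_heteroplasmies()] (rows from several pairs
#'   may be concatenated).
#' @param het_lower,het_upper heteroplasmy band used for the fixation/loss
#'   counts.
#' @return `shift_report` object: `hf_test` and `vaf_test` (each a list
#'   with t, p, n, mean_diff; `degenerate = TRUE` when the differences have
#'   zero variance), `n_fixed`, `n_lost`, `n_pairs`.
#' @export
shift_report <- function(pairs, het_lower = 0.02, het_upper = 0.98) {
  if (nrow(pairs) < 2L) stop("need at least 2 heteroplasmy pairs")
  structure(list(
    hf_test = safe_paired_t(pairs$normal_hf, pairs$tumour_hf),
    vaf_test = safe_paired_t(pairs$tumour_vaf, pairs$normal_vaf),
    n_fixed = sum(pairs$tumour_vaf > het_upper),
    n_lost = sum(pairs$tumour_vaf < het_lower),
    n_pairs = nrow(pairs)), class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat("<shift_report> ", x$n_pairs, " heteroplasmy pairs\n", sep = "")
  fmt <- function(tt, label) {
    if (isTRUE(tt$degenerate)) {
      cat(sprintf("  %s: degenerate (zero variance), mean diff %.4f\n",
                  label, tt$mean_diff))
    } else {
      cat(sprintf("  %s: t = %.3f, p = %.3g, mean diff = %.4f (n = %d)\n",
                  label, tt$t, tt$p, tt$mean_diff, tt$n))
    }
  }
  fmt(x$hf_test, "HF shift (normal - tumour)")
  fmt(x$vaf_test, "VAF shift (tumour - normal)")
  cat("  fixation crossings:", x$n_fixed, " loss crossings:", x$n_lost, "\n")
  invisible(x)
}
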