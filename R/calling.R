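#' Variant-calling thresholds
#'
#' The filter cascade applied to every candidate allele: minimum base
#' quality (applied at pileup parsing), minimum mapping quality (upstream
#' contract of pileup generation), minimum read depth, minimum variant
#' allele fraction and count, the confidence level of the exact binomial
#' interval filter, and the per-strand minimum variant count. Somatic calls
#' additionally require tumour-normal differences of at least
#' `somatic_min_vac_diff` in allele count and `somatic_min_vaf_diff` in
#' allele fraction. The heteroplasmy band `[het_lower, het_upper]`
#' (inclusive) separates heteroplasmies from homoplasmies; the upper bound
#' mirrors the 0.02 calling floor symmetrically.
#'
#' @param min_baq,min_mq Phred quality floors (defaults 20).
#' @param min_depth minimum read depth (default 100).
#' @param min_vaf minimum variant allele fraction (default 0.02).
#' @param min_vac minimum variant allele count (default 10).
#' @param ci_confidence binomial-interval confidence (default 0.99999).
#' @param min_per_strand minimum variant alleles on each strand (default 5).
#' @param somatic_min_vac_diff,somatic_min_vaf_diff tumour-normal
#'   difference floors (defaults 10 and 0.02).
#' @param het_lower,het_upper heteroplasmy band (defaults 0.02, 0.98).
#' @return classed list of thresholds.
#' @export
calling_thresholds <- function(min_baq = 20L, min_mq = 20L, min_depth = 100L,
                               min_vaf = 0.02, min_vac = 10L,
                               ci_confidence = 0.99999, min_per_strand = 5L,
                               somatic_min_vac_diff = 10,
                               somatic_min_vaf_diff = 0.02,
                               het_lower = 0.02, het_upper = 0.98) {
  t <- list(min_baq = min_baq, min_mq = min_mq, min_depth = min_depth,
            min_vaf = min_vaf, min_vac = min_vac,
            ci_confidence = ci_confidence, min_per_strand = min_per_strand,
            somatic_min_vac_diff = somatic_min_vac_diff,
            somatic_min_vaf_diff = somatic_min_vaf_diff,
            het_lower = het_lower, het_upper = het_upper)
  stopifnot(all(vapply(t, function(x) is.numeric(x) && length(x) == 1L &&
                         !is.na(x), logical(1))),
            t$ci_confidence > 0, t$ci_confidence < 1,
            t$min_depth > 0, t$min_vaf > 0, t$min_vac > 0,
            t$min_per_strand >= 0,
            t$het_lower <= t$het_upper)
  structure(t, class = "calling_thresholds")
}

#' @export
print.calling_thresholds <- function(x, ...) {
  cat("<calling_thresholds>\n")
  for (n in names(x)) cat(" ", n, "=", format(x[[n]]), "\n")
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided exact interval for an underlying proportion given `count`
#' successes in `depth` trials, used by the calling cascade at confidence
#' 0.99999. The lower bound is exactly 0 when `count` is 0 and the upper
#' bound exactly 1 when `count` equals `depth`.
#'
#' @param count,depth non-negative integers (vectorized), `depth > 0`.
#' @param confidence interval confidence level in (0, 1).
#' @return data.frame with columns `lower`, `upper`.
#' @export
binomial_interval <- function(count, depth, confidence = 0.99999) {
  if (any(depth <= 0)) stop("depth must be positive")
  if (any(count < 0 | count > depth)) stop("count must be in [0, depth]")
  alpha <- 1 - confidence
  lower <- ifelse(count == 0, 0,
                  stats::qbeta(alpha / 2, count, depth - count + 1))
  upper <- ifelse(count == depth, 1,
                  stats::qbeta(1 - alpha / 2, count + 1, depth - count))
  data.frame(lower = lower, upper = upper)
}

#' Heteroplasmy / homoplasmy classification
#'
#' @param vaf variant allele fractions (vectorized).
#' @param het_lower,het_upper inclusive heteroplasmy band.
#' @return character vector "heteroplasmy"/"homoplasmy".
#' @export
classify_zygosity <- function(vaf, het_lower = 0.02, het_upper = 0.98) {
  ifelse(vaf >= het_lower - 1e-12 & vaf <= het_upper + 1e-12,
         "heteroplasmy", "homoplasmy")
}

# Long-format candidate table: one row per (site, non-reference allele with
# at least one supporting read). Carries the per-predicate filter columns so
# callers can report filter attrition.
candidate_alleles <- function(sites) {
  sites <- validate_site_counts(sites)
  out <- vector("list", 4L)
  for (k in seq_along(.BASES)) {
    b <- .BASES[k]
    fwd <- sites[[paste0(b, "_fwd")]]
    rev <- sites[[paste0(b, "_rev")]]
    keep <- sites$ref != b & (fwd + rev) > 0L
    out[[k]] <- data.frame(
      sample = sites$sample[keep], pos = sites$pos[keep],
      ref = sites$ref[keep], alt = rep(b, sum(keep)),
      fwd_vac = fwd[keep], rev_vac = rev[keep],
      depth = sites$depth[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$pos, res$alt), , drop = FALSE]
  res$vac <- res$fwd_vac + res$rev_vac
  res$vaf <- ifelse(res$depth > 0, res$vac / res$depth, 0)
  rownames(res) <- NULL
  res
}

constitutional_predicates <- function(cand, t) {
  ci_lower <- binomial_interval(cand$vac, pmax(cand$depth, 1L),
                                t$ci_confidence)$lower
  data.frame(
    pass_depth = cand$depth >= t$min_depth,
    pass_vaf = ge_frac(cand$vac, cand$depth, t$min_vaf),
    pass_vac = cand$vac >= t$min_vac,
    pass_ci = ci_lower > 0,
    pass_strand = cand$fwd_vac >= t$min_per_strand &
                  cand$rev_vac >= t$min_per_strand)
}

finish_calls <- function(cand, tissue, origin, t) {
  if (nrow(cand) == 0L) return(empty_variant_calls())
  data.frame(
    sample = cand$sample, tissue = tissue, pos = cand$pos, ref = cand$ref,
    alt = cand$alt, vac = cand$vac, depth = cand$depth, vaf = cand$vaf,
    fwd_vac = cand$fwd_vac, rev_vac = cand$rev_vac,
    zygosity = classify_zygosity(cand$vaf, t$het_lower, t$het_upper),
    origin = origin, stringsAsFactors = FALSE)
}

empty_variant_calls <- function() {
  data.frame(sample = character(0), tissue = character(0), pos = integer(0),
             ref = character(0), alt = character(0), vac = integer(0),
             depth = integer(0), vaf = numeric(0), fwd_vac = integer(0),
             rev_vac = integer(0), zygosity = character(0),
             origin = character(0), stringsAsFactors = FALSE)
}

#' Call constitutional variants from normal-tissue site counts
#'
#' A non-reference allele is called iff depth >= `min_depth`, VAF >=
#' `min_vaf`, VAC >= `min_vac`, the lower bound of the exact binomial
#' interval on the variant fraction excludes zero, and at least
#' `min_per_strand` variant reads are present on each strand. Multiple
#' alternative alleles at one site are filtered independently (VAF
#' denominators use total site depth).
#'
#' @param sites site-count data.frame (one sample's normal tissue).
#' @param thresholds [calling_thresholds()].
#' @param tissue tissue label for the emitted calls.
#' @return variant-call data.frame (columns sample, tissue, pos, ref, alt,
#'   vac, depth, vaf, fwd_vac, rev_vac, zygosity, origin). Attribute
#'   `attrition` tabulates how many candidates each predicate removed.
#' @export
call_constitutional <- function(sites, thresholds = calling_thresholds(),
                                tissue = "normal") {
  cand <- candidate_alleles(sites)
  if (nrow(cand) == 0L) return(empty_variant_calls())
  pred <- constitutional_predicates(cand, thresholds)
  pass <- Reduce(`&`, pred)
  calls <- finish_calls(cand[pass, , drop = FALSE], tissue,
                        "constitutional", thresholds)
  attr(calls, "attrition") <- colSums(!pred)
  calls
}

#' Call somatic mutations from matched tumour and normal site counts
#'
#' A tumour allele is somatic iff it passes every constitutional-style
#' filter in the tumour, the matched normal position has depth >=
#' `min_depth`, the tumour-normal difference in variant alleles is at least
#' `somatic_min_vac_diff` in count and `somatic_min_vaf_diff` in fraction,
#' and the normal VAF lies outside the exact binomial interval of the
#' tumour variant count. The count difference is computed by default with
#' the normal count rescaled to tumour depth (`normal_vaf * tumour_depth`)
#' so unequal depths do not bias the comparison; `vac_diff = "raw"` uses the
#' unscaled difference.
#'
#' @param tumour_sites,normal_sites site-count data.frames for one pair.
#' @param thresholds [calling_thresholds()].
#' @param vac_diff "normalized" (default) or "raw".
#' @return variant-call data.frame (origin "somatic", tissue "tumour") with
#'   added columns `normal_vaf`, `normal_vac`. Attribute `n_unmatched`
#'   counts tumour positions lacking a matched normal row.
#' @export
call_somatic <- function(tumour_sites, normal_sites,
                         thresholds = calling_thresholds(),
                         vac_diff = c("normalized", "raw")) {
  vac_diff <- match.arg(vac_diff)
  t <- thresholds
  cand <- candidate_alleles(tumour_sites)
  if (nrow(cand) == 0L) return(empty_variant_calls())
  normal_sites <- validate_site_counts(normal_sites)
  m <- match(cand$pos, normal_sites$pos)
  unmatched <- is.na(m)
  if (any(unmatched)) {
    warning(sum(unmatched), " unmatched tumour positions (no normal ",
            "counts) were skipped")
    cand <- cand[!unmatched, , drop = FALSE]
    m <- m[!unmatched]
  }
  if (nrow(cand) == 0L) return(empty_variant_calls())
  n_fwd <- mapply(function(i, b) normal_sites[[paste0(b, "_fwd")]][i],
                  m, cand$alt)
  n_rev <- mapply(function(i, b) normal_sites[[paste0(b, "_rev")]][i],
                  m, cand$alt)
  normal_vac <- as.integer(n_fwd + n_rev)
  normal_depth <- normal_sites$depth[m]
  normal_vaf <- ifelse(normal_depth > 0, normal_vac / normal_depth, 0)

  pred <- constitutional_predicates(cand, t)
  pred$pass_normal_depth <- normal_depth >= t$min_depth
  scaled_normal_vac <- if (vac_diff == "normalized") {
    normal_vaf * cand$depth
  } else {
    normal_vac
  }
  pred$pass_vac_diff <- cand$vac - scaled_normal_vac >=
    t$somatic_min_vac_diff - 1e-9
  pred$pass_vaf_diff <- cand$vaf - normal_vaf >= t$somatic_min_vaf_diff - 1e-9
  ci <- binomial_interval(cand$vac, cand$depth, t$ci_confidence)
  pred$pass_ci_normal <- normal_vaf < ci$lower | normal_vaf > ci$upper

  pass <- Reduce(`&`, pred)
  calls <- finish_calls(cand[pass, , drop = FALSE], "tumour", "somatic", t)
  calls$normal_vaf <- normal_vaf[pass]
  calls$normal_vac <- normal_vac[pass]
  attr(calls, "attrition") <- colSums(!pred)
  attr(calls, "n_unmatched") <- sum(unmatched)
  calls
}

#' Flag read-linked artefact variant pairs
#'
#' Tests whether two candidate variants co-occur on the same reads more
#' often than `cooccurrence_min`: among reads covering both positions, the
#' fraction carrying both alternative alleles out of reads carrying either
#' must reach the threshold, and the partner allele must be absent from
#' co-covering reads lacking the first allele. Pairs with no co-covering
#' reads are reported as untestable.
#'
#' @param observations data.frame of read-level observations with columns
#'   `read_id`, `pos`, `allele` (one row per read-base).
#' @param candidate_pairs data.frame with columns `pos1`, `alt1`, `pos2`,
#'   `alt2`.
#' @param cooccurrence_min flagging threshold (default 0.95).
#' @return `candidate_pairs` with added columns `n_covering`, `n_both`,
#'   `n_either`, `fraction`, `partner_absent`, `testable`, `flagged`.
#' @export
flag_linked_artefacts <- function(observations, candidate_pairs,
                                  cooccurrence_min = 0.95) {
  stopifnot(all(c("read_id", "pos", "allele") %in% names(observations)),
            all(c("pos1", "alt1", "pos2", "alt2") %in% names(candidate_pairs)))
  if (anyDuplicated(observations[c("read_id", "pos")])) {
    stop("duplicate (read_id, pos) observations")
  }
  out <- candidate_pairs
  out$n_covering <- out$n_both <- out$n_either <- 0L
  out$fraction <- 0
  out$partner_absent <- NA
  out$testable <- FALSE
  out$flagged <- FALSE
  for (i in seq_len(nrow(out))) {
    o1 <- observations[observations$pos == out$pos1[i], , drop = FALSE]
    o2 <- observations[observations$pos == out$pos2[i], , drop = FALSE]
    shared <- intersect(o1$read_id, o2$read_id)
    out$n_covering[i] <- length(shared)
    if (length(shared) == 0L) next
    a1 <- o1$allele[match(shared, o1$read_id)] == out$alt1[i]
    a2 <- o2$allele[match(shared, o2$read_id)] == out$alt2[i]
    out$n_both[i] <- sum(a1 & a2)
    out$n_either[i] <- sum(a1 | a2)
    out$fraction[i] <- if (out$n_either[i] > 0) {
      out$n_both[i] / out$n_either[i]
    } else 0
    out$partner_absent[i] <- !any(!a1 & a2)
    out$testable[i] <- TRUE
    out$flagged[i] <- out$n_either[i] > 0L &&
      out$fraction[i] >= cooccurrence_min && out$partner_absent[i]
  }
  out
}
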