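#' Cohort-level variant summary
#'
#' Tabulates, for each variant class — all constitutional variants, private
#' constitutional variants, heteroplasmic constitutional variants and
#' somatic mutations — the total variant count, the number of unique
#' variants (distinct position/ref/alt), the number of samples carrying at
#' least one, and the mean and standard deviation of read depth at the
#' called variants.
#'
#' @param all_calls variant-call data.frame with columns `sample`,
#'   `origin`, `zygosity`, `depth`, `pos`, `ref`, `alt` and (optionally)
#'   `private_class` from [derive_private()].
#' @param cohort_size number of pairs in the cohort; defaults to the number
#'   of distinct samples contributing constitutional calls.
#' @return `cohort_summary` data.frame with one row per class.
#' @export
summarize_cohort <- function(all_calls, cohort_size = NULL) {
  const <- all_calls[all_calls$origin == "constitutional", , drop = FALSE]
  classes <- list(
    total_constitutional = const,
    private_constitutional = if ("private_class" %in% names(const)) {
      const[const$private_class %in% "private", , drop = FALSE]
    } else const[0L, , drop = FALSE],
    heteroplasmic_constitutional =
      const[const$zygosity == "heteroplasmy", , drop = FALSE],
    somatic = all_calls[all_calls$origin == "somatic", , drop = FALSE])
  rows <- lapply(names(classes), function(nm) {
    d <- classes[[nm]]
    data.frame(
      class = nm,
      total_variants = nrow(d),
      unique_variants = nrow(unique(d[c("pos", "ref", "alt")])),
      n_samples = length(unique(d$sample)),
      depth_mean = if (nrow(d)) mean(d$depth) else NA_real_,
      depth_sd = if (nrow(d) > 1L) stats::sd(d$depth) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cohort_size") <- if (is.null(cohort_size)) {
    length(unique(const$sample))
  } else cohort_size
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> cohort size ", attr(x, "cohort_size"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Chi-square test of variant distribution across functional regions
#'
#' Goodness-of-fit test of the observed variant counts in the seven
#' functional regions against the proportions expected from region lengths
#' alone: `chi^2 = sum (O - E)^2 / E` with `E = n * length / genome_length`
#' and 6 degrees of freedom. Variants in overlapping genes count towards
#' their primary (most severe consequence) gene's region. Regions with
#' expected counts below 5 are flagged.
#'
#' @param variants data.frame with a `region` column (from
#'   [annotate_variants()]).
#' @param map `region_map`.
#' @return `region_distribution` object with `observed`, `expected`,
#'   `proportions_expected`, `chisq`, `df`, `p`, `low_expected`.
#' @export
region_distribution_test <- function(variants, map) {
  if (nrow(variants) < 1L) stop("need at least one variant")
  region_names <- names(map$lengths)
  if (!all(variants$region %in% region_names)) {
    stop("unknown region labels: ",
         paste(setdiff(unique(variants$region), region_names), collapse = ", "))
  }
  observed <- table(factor(variants$region, levels = region_names))
  p_exp <- map$lengths / map$genome_length
  ht <- suppressWarnings(stats::chisq.test(as.integer(observed), p = p_exp))
  structure(list(
    observed = stats::setNames(as.integer(observed), region_names),
    expected = unname(ht$expected), proportions_expected = unname(p_exp),
    chisq = unname(ht$statistic), df = as.integer(ht$parameter),
    p = ht$p.value,
    low_expected = region_names[ht$expected < 5]), class = "region_distribution")
}

#' @export
print.region_distribution <- function(x, ...) {
  cat("<region_distribution>\n")
  print(data.frame(region = names(x$observed), observed = x$observed,
                   expected = round(x$expected, 2), row.names = NULL))
  cat(sprintf("  chi-square = %.3f, df = %d, p = %.3g\n", x$chisq, x$df, x$p))
  if (length(x$low_expected)) {
    cat("  note: expected < 5 in", paste(x$low_expected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Two-sample chi-square homogeneity test of region distributions
#'
#' Compares the regional distributions of two variant sets (e.g. somatic vs
#' private constitutional) with a standard contingency-table chi-square
#' test.
#'
#' @param variants_a,variants_b data.frames with `region` columns.
#' @param map `region_map`.
#' @return `htest` from [stats::chisq.test()].
#' @export
region_homogeneity_test <- function(variants_a, variants_b, map) {
  region_names <- names(map$lengths)
  ta <- table(factor(variants_a$region, levels = region_names))
  tb <- table(factor(variants_b$region, levels = region_names))
  keep <- (ta + tb) > 0
  suppressWarnings(stats::chisq.test(rbind(as.integer(ta[keep]),
                                           as.integer(tb[keep]))))
}

#' Association screen between mutational burden and clinical phenotypes
#'
#' For each phenotype column: binary phenotypes are tested with a
#' two-sample t-test of burden between groups, continuous phenotypes with a
#' Pearson correlation test. Raw p-values are always reported;
#' Benjamini-Hochberg adjusted p-values are added across the screened
#' phenotypes.
#'
#' @param per_sample_burden data.frame with columns `sample`, `burden`.
#' @param phenotype_table data.frame with a `sample` column plus one column
#'   per phenotype.
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return data.frame with one row per phenotype: `phenotype`, `type`,
#'   `statistic`, `estimate`, `p`, `p_adj`, `note`.
#' @export
burden_association <- function(per_sample_burden, phenotype_table,
                               var_equal = TRUE) {
  m <- match(phenotype_table$sample, per_sample_burden$sample)
  burden <- per_sample_burden$burden[m]
  pheno_cols <- setdiff(names(phenotype_table), "sample")
  rows <- lapply(pheno_cols, function(pc) {
    x <- phenotype_table[[pc]]
    ok <- !is.na(x) & !is.na(burden)
    xv <- x[ok]; bv <- burden[ok]
    lv <- unique(xv)
    out <- data.frame(phenotype = pc, type = NA_character_,
                      statistic = NA_real_, estimate = NA_real_,
                      p = NA_real_, note = "", stringsAsFactors = FALSE)
    if (length(lv) == 2L) {
      out$type <- "binary"
      g1 <- bv[xv == lv[1L]]; g2 <- bv[xv == lv[2L]]
      if (length(g1) < 2L || length(g2) < 2L) {
        out$note <- "skipped: a group has fewer than 2 samples"
      } else if (stats::sd(bv) == 0) {
        out$statistic <- 0; out$estimate <- 0; out$p <- 1
      } else {
        ht <- stats::t.test(g1, g2, var.equal = var_equal)
        out$statistic <- unname(ht$statistic)
        out$estimate <- mean(g1) - mean(g2)
        out$p <- ht$p.value
      }
    } else if (is.numeric(xv) && length(lv) > 2L) {
      out$type <- "continuous"
      if (stats::sd(xv) == 0 || stats::sd(bv) == 0) {
        out$note <- "skipped: zero variance"
      } else {
        ht <- stats::cor.test(bv, xv)
        out$statistic <- unname(ht$statistic)
        out$estimate <- unname(ht$estimate)
        out$p <- ht$p.value
      }
    } else {
      out$note <- "skipped: not binary or continuous"
    }
    out
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[c("phenotype", "type", "statistic", "estimate", "p", "p_adj", "note")]
}
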