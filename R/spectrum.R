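.PYR_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.ALL_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                  "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

complement_class <- function(cls) {
  parts <- strsplit(cls, ">", fixed = TRUE)
  vapply(parts, function(p) {
    paste0(complement_base(p[1L]), ">", complement_base(p[2L]))
  }, character(1))
}

#' The 96 pyrimidine-collapsed trinucleotide bins
#' @return character vector of bin labels like `"A[C>T]G"`, ordered by
#'   substitution class, then 5' base, then 3' base.
#' @export
spectrum_bins <- function() {
  bins <- character(0)
  for (cls in .PYR_CLASSES) for (p5 in .BASES) for (p3 in .BASES) {
    bins <- c(bins, paste0(p5, "[", cls, "]", p3))
  }
  bins
}

#' Collapse substitutions to the pyrimidine-centred convention
#'
#' Substitutions with a purine reference are complemented (both the
#' substitution and its trinucleotide context are reverse complemented) so
#' every SNV is expressed with a C or T reference; this yields the 96-bin
#' convention of mutational-signature analysis.
#'
#' @param ref,alt,context equal-length vectors; `context` is the
#'   forward-strand 3-mer around each variant.
#' @return data.frame with `class` (one of the six pyrimidine classes),
#'   `context` (collapsed 3-mer) and `bin` (96-bin label).
#' @export
pyrimidine_collapse <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  if (any(substr(context, 2L, 2L) != ref)) {
    stop("context centre base must equal ref")
  }
  purine <- ref %in% c("A", "G")
  cls <- paste0(ref, ">", alt)
  cls[purine] <- complement_class(cls[purine])
  context[purine] <- vapply(context[purine], function(x) {
    reverse_complement(x)
  }, character(1), USE.NAMES = FALSE)
  data.frame(class = cls, context = context,
             bin = paste0(substr(context, 1L, 1L), "[", cls, "]",
                          substr(context, 3L, 3L)),
             stringsAsFactors = FALSE)
}

#' Canonical strand-spectrum cell of a strand-labelled substitution class
#'
#' Every single-nucleotide substitution is a pyrimidine substitution on
#' exactly one strand, so a strand-labelled class like `"H:A>G"` (A>G as
#' read on the heavy strand) has a canonical cell in the
#' [build_strand_spectrum()] matrix: A>G on the H strand is T>C on the L
#' strand, giving cell (L, T>C).
#'
#' @param label class like `"H:C>T"` or `"L:A>G"`.
#' @return character vector `c(strand, class)` indexing the
#'   `strand_spectrum` counts/frequencies matrix.
#' @export
strand_label_cell <- function(label) {
  strand <- substr(label, 1L, 1L)
  cls <- substr(label, 3L, nchar(label))
  if (!strand %in% c("L", "H") || !cls %in% .ALL_CLASSES) {
    stop("malformed strand label: ", label)
  }
  if (substr(cls, 1L, 1L) %in% c("A", "G")) {
    strand <- if (strand == "L") "H" else "L"
    cls <- complement_class(cls)
  }
  c(strand, cls)
}

new_spectrum_matrix <- function(counts, set_label) {
  total <- sum(counts)
  freq <- if (total > 0) counts / total else rep(NA_real_, length(counts))
  structure(list(counts = counts, frequencies = freq, total = total,
                 set_label = set_label, empty = total == 0),
            class = "spectrum_matrix")
}

#' Build a 96-context mutational spectrum
#'
#' Counts single-nucleotide variants into the 96 pyrimidine-collapsed
#' trinucleotide bins, taking contexts from the circular genome.
#'
#' @param variants data.frame with columns `pos`, `ref`, `alt`. If a
#'   `context` column is present it is used directly (nuclear variants with
#'   precomputed contexts); otherwise contexts are read from `genome`.
#' @param genome `mito_genome` (default the packaged reference).
#' @param set_label label stored with the spectrum.
#' @return `spectrum_matrix`: named 96-vector of counts, frequencies
#'   normalised to sum 1 (NA and flagged `empty` when there are no
#'   variants), total count and label.
#' @export
build_96_spectrum <- function(variants, genome = NULL,
                              set_label = "variants") {
  if (nrow(variants) == 0L) {
    return(new_spectrum_matrix(
      stats::setNames(integer(96L), spectrum_bins()), set_label))
  }
  if (!"context" %in% names(variants)) {
    if (is.null(genome)) genome <- mito_genome()
    gref <- genome_base(genome, variants$pos)
    bad <- gref != toupper(variants$ref)
    if (any(bad)) stop("reference mismatch with genome at position(s) ",
                       paste(variants$pos[bad], collapse = ", "))
    variants$context <- trinucleotide_context(variants$pos, genome)
  }
  pc <- pyrimidine_collapse(variants$ref, variants$alt, variants$context)
  counts <- table(factor(pc$bin, levels = spectrum_bins()))
  new_spectrum_matrix(stats::setNames(as.integer(counts), spectrum_bins()),
                      set_label)
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat("<spectrum_matrix> '", x$set_label, "': ", x$total, " variants\n",
      sep = "")
  if (!x$empty) {
    cls <- vapply(strsplit(names(x$counts), "[][]"), `[`, character(1), 2L)
    print(round(tapply(x$frequencies, cls, sum)[.PYR_CLASSES], 3))
  } else cat("  (empty: frequencies undefined)\n")
  invisible(x)
}

#' @export
plot.spectrum_matrix <- function(x, ...) {
  cls <- vapply(strsplit(names(x$counts), "[][]"), `[`, character(1), 2L)
  cols <- c("C>A" = "skyblue3", "C>G" = "black", "C>T" = "firebrick",
            "T>A" = "grey60", "T>C" = "olivedrab", "T>G" = "rosybrown")
  graphics::barplot(x$counts, col = cols[cls], border = NA, las = 2,
                    cex.names = 0.4, main = x$set_label,
                    ylab = "count", ...)
  invisible(x)
}

#' Strand-resolved substitution spectrum
#'
#' Tallies each variant's substitution as read on the light strand (the
#' forward rCRS sequence, i.e. as recorded) and on the heavy strand (its
#' complement). The headline `frequencies` matrix gives, for each strand,
#' the fraction of all variants that are pyrimidine substitutions of each
#' of the six classes *on that strand*: a forward G>A variant is a C>T
#' substitution on the heavy strand. Each variant is a pyrimidine
#' substitution on exactly one strand, so the matrix sums to 1.
#'
#' @param variants data.frame with columns `ref`, `alt`.
#' @return `strand_spectrum`: `l_tally`/`h_tally` (12-class counts per
#'   strand reading), `counts`/`frequencies` (2 x 6 strand-by-class
#'   pyrimidine view), `n`.
#' @export
build_strand_spectrum <- function(variants) {
  sc <- strand_class(variants$ref, variants$alt)
  l_tally <- table(factor(sc$l_class, levels = .ALL_CLASSES))
  h_tally <- table(factor(sc$h_class, levels = .ALL_CLASSES))
  pyr_on_l <- toupper(variants$ref) %in% c("C", "T")
  counts <- matrix(0L, nrow = 2L, ncol = 6L,
                   dimnames = list(c("L", "H"), .PYR_CLASSES))
  tl <- table(factor(sc$l_class[pyr_on_l], levels = .PYR_CLASSES))
  th <- table(factor(sc$h_class[!pyr_on_l], levels = .PYR_CLASSES))
  counts["L", ] <- as.integer(tl)
  counts["H", ] <- as.integer(th)
  n <- nrow(variants)
  structure(list(l_tally = stats::setNames(as.integer(l_tally), .ALL_CLASSES),
                 h_tally = stats::setNames(as.integer(h_tally), .ALL_CLASSES),
                 counts = counts,
                 frequencies = if (n > 0) counts / n else counts * NA_real_,
                 n = n),
            class = "strand_spectrum")
}

#' @export
print.strand_spectrum <- function(x, ...) {
  cat("<strand_spectrum> ", x$n, " variants\n", sep = "")
  print(round(x$frequencies, 3))
  invisible(x)
}

#' @export
plot.strand_spectrum <- function(x, ...) {
  graphics::barplot(x$counts, beside = TRUE, col = c("grey40", "firebrick"),
                    legend.text = c("L-strand", "H-strand"),
                    ylab = "count", ...)
  invisible(x)
}

#' Two-sample t-test on group values
#'
#' Pooled-variance two-sample t-test by default (Welch optional), two
#' tailed; used for comparing population frequencies or pathogenicity
#' scores between variant groups.
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @param var_equal pooled variance (default TRUE); FALSE gives Welch.
#' @param log10_transform apply log10 to both groups first (for
#'   frequency-scale comparisons); non-positive values are rejected.
#' @return list with `t`, `p`, `df`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
frequency_group_test <- function(values_a, values_b, var_equal = TRUE,
                                 log10_transform = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("need at least 2 values per group")
  }
  if (log10_transform) {
    if (any(values_a <= 0) || any(values_b <= 0)) {
      stop("log10 transform requires positive values")
    }
    values_a <- log10(values_a); values_b <- log10(values_b)
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(list(t = 0, p = 1, df = length(values_a) + length(values_b) - 2L,
                  n_a = length(values_a), n_b = length(values_b),
                  mean_a = mean(values_a), mean_b = mean(values_b)))
    }
    stop("degenerate variance in both groups")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       n_a = length(values_a), n_b = length(values_b),
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Strand asymmetry of variant consequences and pathogenicity
#'
#' Compares C>T and A>G substitutions as read on the heavy strand (forward
#' G>A / T>C) against the same classes on the light strand (forward C>T /
#' A>G): the proportions of non-coding, synonymous and amino-acid-changing
#' variants per strand group, and a two-tailed two-sample t-test on the
#' pathogenicity scores of the amino-acid-changing members. tRNA and rRNA
#' variants count as non-coding for this tabulation; stop-gains count as
#' non-synonymous. The strand groups contain different variants, so the
#' score comparison is a two-sample test (pooled by default, Welch
#' optional), not a paired one.
#'
#' @param annotated_variants output of [annotate_variants()]; transversions
#'   (no C>T/A>G reading on either strand) are excluded.
#' @param scores optional data.frame (`pos`, `ref`, `alt`, `score`) of
#'   pathogenicity scores joined exactly; alternatively a `score` column on
#'   `annotated_variants` is used.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return `strand_asymmetry` object: `table` (2 x 3 counts),
#'   `proportions`, per-strand score summaries, `score_test` (NULL with a
#'   `note` when a group has fewer than 2 scored variants).
#' @export
strand_asymmetry_analysis <- function(annotated_variants, scores = NULL,
                                      var_equal = TRUE) {
  av <- annotated_variants[!is.na(annotated_variants$strand_group), ,
                           drop = FALSE]
  if (!is.null(scores)) {
    key <- function(d) paste(d$pos, d$ref, d$alt)
    av$score <- scores$score[match(key(av), key(scores))]
  }
  if (!"score" %in% names(av)) av$score <- rep(NA_real_, nrow(av))
  category <- ifelse(av$consequence %in% c("non-coding", "tRNA", "rRNA"),
                     "non-coding",
                     ifelse(av$consequence == "synonymous", "synonymous",
                            "non-synonymous"))
  tab <- table(factor(av$strand_group, levels = c("L", "H")),
               factor(category,
                      levels = c("non-coding", "synonymous",
                                 "non-synonymous")))
  props <- prop.table(tab, margin = 1L)
  ns <- av[category == "non-synonymous" & !is.na(av$score), , drop = FALSE]
  sl <- ns$score[ns$strand_group == "L"]
  sh <- ns$score[ns$strand_group == "H"]
  score_test <- NULL
  note <- NULL
  if (length(sl) >= 2L && length(sh) >= 2L) {
    score_test <- frequency_group_test(sh, sl, var_equal = var_equal)
  } else {
    note <- "score test skipped: fewer than 2 scored non-synonymous variants in a strand group"
  }
  structure(list(table = unclass(tab), proportions = unclass(props),
                 score_summary = data.frame(
                   strand = c("L", "H"),
                   n_scored = c(length(sl), length(sh)),
                   mean = c(mean(sl), mean(sh)),
                   median = c(stats::median(sl), stats::median(sh))),
                 score_test = score_test, note = note,
                 n = nrow(av)), class = "strand_asymmetry")
}

#' @export
print.strand_asymmetry <- function(x, ...) {
  cat("<strand_asymmetry> ", x$n, " C>T / A>G variants\n", sep = "")
  print(round(x$proportions, 3))
  if (!is.null(x$score_test)) {
    cat(sprintf("  pathogenicity (H vs L): t = %.3f, p = %.3g\n",
                x$score_test$t, x$score_test$p))
  } else if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Annotate nuclear variants with trinucleotide contexts
#'
#' Extracts the 5' and 3' flanking bases for variants on linear nuclear
#' contigs from a reference FASTA; variants at contig edges (no flanking
#' base) are dropped with a notice. Contexts feed [build_96_spectrum()] via
#' its `context` column.
#'
#' @param variant_table data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param reference_fasta path to a FASTA, or a `Biostrings::DNAStringSet`.
#' @return variant table with an added `context` column, edge variants
#'   removed (count reported via attribute `n_dropped`).
#' @export
nuclear_context_annotation <- function(variant_table, reference_fasta) {
  ref <- if (inherits(reference_fasta, "DNAStringSet")) reference_fasta
         else Biostrings::readDNAStringSet(reference_fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  miss <- setdiff(unique(variant_table$chrom), names(ref))
  if (length(miss)) stop("chromosome(s) absent from reference: ",
                         paste(miss, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(ref), names(ref))
  at_edge <- variant_table$pos <= 1L |
    variant_table$pos >= lens[variant_table$chrom]
  if (any(at_edge)) {
    message(sum(at_edge), " variant(s) at contig edges dropped ",
            "(no flanking base)")
  }
  vt <- variant_table[!at_edge, , drop = FALSE]
  vt$context <- vapply(seq_len(nrow(vt)), function(i) {
    toupper(as.character(Biostrings::subseq(ref[[vt$chrom[i]]],
                                            vt$pos[i] - 1L, vt$pos[i] + 1L)))
  }, character(1))
  bad <- substr(vt$context, 2L, 2L) != toupper(vt$ref)
  if (any(bad)) stop("reference mismatch at ",
                     paste0(vt$chrom[bad], ":", vt$pos[bad], collapse = ", "))
  attr(vt, "n_dropped") <- sum(at_edge)
  vt
}
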