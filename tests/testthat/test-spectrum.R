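test_that("pyrimidine collapse complements purine-reference substitutions", {
  pc <- pyrimidine_collapse("G", "A", "AGC")
  expect_identical(pc$class, "C>T")
  expect_identical(pc$context, "GCT")
  expect_identical(pc$bin, "G[C>T]T")
  # pyrimidine references pass through
  pc <- pyrimidine_collapse("C", "A", "ACG")
  expect_identical(pc$bin, "A[C>A]G")
  expect_error(pyrimidine_collapse("C", "A", "AAG"), "centre")
})

test_that("collapse is involution-consistent under complementation", {
  with_seed(6, {
    for (rep in 1:40) {
      ref <- sample(c("A", "C", "G", "T"), 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      ctx <- paste0(sample(c("A", "C", "G", "T"), 1L), ref,
                    sample(c("A", "C", "G", "T"), 1L))
      b1 <- pyrimidine_collapse(ref, alt, ctx)$bin
      b2 <- pyrimidine_collapse(complement_base(ref), complement_base(alt),
                                reverse_complement(ctx))$bin
      expect_identical(b1, b2)
    }
  })
})

test_that("96-bin spectrum counts, normalises and flags emptiness", {
  # one variant per bin via precomputed contexts
  bins <- spectrum_bins()
  v <- data.frame(
    pos = seq_along(bins),
    ref = substr(sub(".*\\[", "", bins), 1L, 1L),
    alt = substr(sub(".*>", "", bins), 1L, 1L),
    context = paste0(substr(bins, 1L, 1L), substr(bins, 3L, 3L),
                     substr(bins, 7L, 7L)),
    stringsAsFactors = FALSE)
  sp <- build_96_spectrum(v)
  expect_identical(unname(sp$counts), rep(1L, 96L))
  expect_equal(sum(sp$frequencies), 1, tolerance = 1e-12)
  expect_equal(unname(sp$frequencies), rep(1 / 96, 96L))
  empty <- build_96_spectrum(v[0L, ])
  expect_true(empty$empty)
  expect_true(all(is.na(empty$frequencies)))
})

test_that("spectrum from the genome honours circular context and ref checks", {
  g <- mito_genome()
  pos <- c(1L, 16569L, 5000L)
  v <- data.frame(pos = pos, ref = genome_base(g, pos), alt = NA)
  v$alt <- vapply(v$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1L], "")
  sp <- build_96_spectrum(v, g)
  expect_identical(sp$total, 3L)
  expect_equal(sum(sp$frequencies), 1, tolerance = 1e-12)
  v$ref[1] <- setdiff(c("A", "C", "G", "T"), v$ref[1])[1L]
  expect_error(build_96_spectrum(v, g), "mismatch")
})

test_that("strand spectrum maps complements between L and H readings", {
  v <- data.frame(ref = c("G", "G", "T"), alt = c("A", "A", "C"))
  ss <- build_strand_spectrum(v)
  expect_equal(ss$frequencies["H", "C>T"], 2 / 3)
  # the remaining T>C variant is a pyrimidine substitution on the L strand
  # (equivalently A>G on the H strand)
  expect_equal(ss$frequencies["L", "T>C"], 1 / 3)
  expect_identical(unname(ss$h_tally["A>G"]), 1L)
  expect_equal(sum(ss$frequencies), 1)
  v2 <- data.frame(ref = rep("C", 3), alt = rep("T", 3))
  ss2 <- build_strand_spectrum(v2)
  expect_equal(ss2$frequencies["L", "C>T"], 1)
  expect_identical(unname(ss2$h_tally["G>A"]), 3L)
  # exact complement identity on random variant sets
  with_seed(19, {
    for (rep in 1:10) {
      n <- sample(5:80, 1L)
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
      ss <- build_strand_spectrum(data.frame(ref = ref, alt = alt))
      for (cls in names(ss$l_tally)) {
        comp <- mitovar:::complement_class(cls)
        expect_identical(ss$h_tally[[cls]], ss$l_tally[[comp]])
      }
      expect_identical(sum(ss$l_tally), n)
      expect_identical(sum(ss$h_tally), n)
    }
  })
})

test_that("two-sample test matches the pooled closed form", {
  res <- frequency_group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.6742346, tolerance = 1e-6)
  # hand check: pooled sd 1, se = sqrt(2/3)
  expect_equal(res$t, (2 - 5) / sqrt(2 / 3), tolerance = 1e-10)
  same <- frequency_group_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  welch <- frequency_group_test(c(1, 2, 3), c(4, 5, 60), var_equal = FALSE)
  expect_lt(abs(welch$t), abs(frequency_group_test(c(1, 2, 3),
                                                   c(4, 5, 60))$t) + 10)
  lg <- frequency_group_test(c(1, 10, 100), c(10, 100, 1000),
                             log10_transform = TRUE)
  expect_equal(lg$t, frequency_group_test(log10(c(1, 10, 100)),
                                          log10(c(10, 100, 1000)))$t)
  expect_error(frequency_group_test(c(-1, 2), c(1, 2), log10_transform = TRUE))
  expect_error(frequency_group_test(1, c(1, 2)), "2 values")
})

test_that("strand asymmetry groups transitions and compares pathogenicity", {
  g <- mito_genome()
  # forward G>A variants inside protein genes -> all H group
  pos <- which(g$bases == "G")
  pos <- pos[pos > 3400 & pos < 4200][1:6]   # inside ND1
  v <- data.frame(pos = pos, ref = "G", alt = "A", stringsAsFactors = FALSE)
  av <- annotate_variants(v)
  expect_true(all(av$strand_group == "H"))
  sa <- strand_asymmetry_analysis(av)
  expect_identical(sum(sa$table["L", ]), 0L)
  expect_identical(sum(sa$table["H", ]), 6L)
  expect_null(sa$score_test)
  expect_match(sa$note, "skipped")
  # identical score vectors in both groups: t = 0, p = 1
  av2 <- av
  av2$strand_group <- rep(c("H", "L"), 3L)
  av2$consequence <- "non-synonymous"
  av2$score <- rep(c(0.5, 0.7, 0.9), each = 2L)
  sa2 <- strand_asymmetry_analysis(av2)
  expect_equal(sa2$score_test$t, 0)
  expect_equal(sa2$score_test$p, 1)
  # tRNA/rRNA fold into the non-coding category
  av3 <- av
  av3$consequence <- c("tRNA", "rRNA", "non-coding", "synonymous",
                       "non-synonymous", "stop-gain")
  sa3 <- strand_asymmetry_analysis(av3)
  expect_identical(unname(sa3$table["H", "non-coding"]), 3L)
  expect_identical(unname(sa3$table["H", "non-synonymous"]), 2L)
})

test_that("planted asymmetric consequences are recovered in ordering", {
  # simulate variants where the H group is enriched for amino-acid changes
  with_seed(55, {
    hits <- 0L
    for (rep in 1:20) {
      n <- 60L
      grp <- sample(c("H", "L"), n, replace = TRUE)
      cons <- ifelse(runif(n) < ifelse(grp == "H", 0.7, 0.3),
                     "non-synonymous", "synonymous")
      av <- data.frame(strand_group = grp, consequence = cons,
                       stringsAsFactors = FALSE)
      sa <- strand_asymmetry_analysis(av)
      if (sa$proportions["H", "non-synonymous"] >
          sa$proportions["L", "non-synonymous"]) hits <- hits + 1L
    }
    expect_gte(hits, 19L)
  })
})

test_that("nuclear contexts come from the reference with edge dropping", {
  fa <- Biostrings::DNAStringSet(c(chr1 = "ACGT", chr2 = "TTACGTT"))
  v <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  pos = c(2L, 1L, 4L),
                  ref = c("C", "A", "C"), alt = c("T", "G", "A"),
                  stringsAsFactors = FALSE)
  expect_message(out <- nuclear_context_annotation(v, fa), "dropped")
  expect_identical(out$context, c("ACG", "ACG"))
  expect_identical(attr(out, "n_dropped"), 1L)
  expect_error(nuclear_context_annotation(
    data.frame(chrom = "chrX", pos = 2L, ref = "A", alt = "C"), fa),
    "absent")
  # collapse of the toy variant matches the mitochondrial binning
  bin_nuc <- pyrimidine_collapse(out$ref[1], out$alt[1], out$context[1])$bin
  sp <- build_96_spectrum(out[1L, ])
  expect_identical(unname(sp$counts[bin_nuc]), 1L)
})
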