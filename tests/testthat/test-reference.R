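test_that("packaged gene table yields the seven-region partition", {
  map <- build_region_map(mito_genes())
  expect_identical(sum(map$lengths), 16569L)
  expect_identical(unname(map$lengths["complex I"]), 6356L)
  expect_identical(nrow(map$genes), 37L)
  expect_identical(sum(map$genes$kind == "protein"), 13L)
  expect_identical(sum(map$genes$kind == "tRNA"), 22L)
  expect_identical(sum(map$genes$kind == "rRNA"), 2L)
})

test_that("build_region_map arithmetic and validation on toy inputs", {
  g <- data.frame(name = "G1", start = 10L, end = 39L, kind = "protein",
                  orientation = "forward", complex = "I",
                  stringsAsFactors = FALSE)
  map <- build_region_map(g, 100L)
  expect_identical(unname(map$lengths["complex I"]), 30L)
  expect_identical(unname(map$lengths["non-coding"]), 70L)
  expect_error(build_region_map(rbind(g, g), 100L), "duplicate")
  bad <- g; bad$end <- 200L
  expect_error(build_region_map(bad, 100L), "outside")
})

test_that("locate resolves genes, overlaps and the control region", {
  map <- build_region_map(mito_genes())
  expect_identical(locate(11711, map),
                   data.frame(region = "complex I", gene = "ND4",
                              stringsAsFactors = FALSE))
  expect_identical(locate(16519, map)$region, "non-coding")
  atp <- locate(8530, map)          # inside the ATP8/ATP6 overlap
  expect_setequal(atp$gene, c("ATP8", "ATP6"))
  nd <- locate(10762, map)          # inside the ND4L/ND4 overlap
  expect_setequal(nd$gene, c("ND4L", "ND4"))
  expect_error(locate(0, map))
  expect_error(locate(16570, map))
})

test_that("locate is total over the genome", {
  map <- build_region_map(mito_genes())
  positions <- with_seed(11, sample.int(16569L, 400L))
  positions <- c(positions, 1L, 576L, 577L, 16023L, 16024L, 16569L)
  for (p in positions) {
    loc <- locate(p, map)
    expect_gte(nrow(loc), 1L)
    expect_true(all(loc$region %in% names(map$lengths)))
  }
})

test_that("trinucleotide context wraps circularly", {
  g <- mito_genome()
  expect_identical(trinucleotide_context(1, g),
                   paste0(g$bases[16569], g$bases[1], g$bases[2]))
  expect_identical(trinucleotide_context(16569, g),
                   paste0(g$bases[16568], g$bases[16569], g$bases[1]))
  expect_identical(trinucleotide_context(2, g), "GAT")
  expect_error(trinucleotide_context(0, g), "range")
})

test_that("vertebrate mitochondrial code has its signature reassignments", {
  code <- mito_genetic_code()
  expect_length(code, 64L)
  expect_identical(unname(code[c("TGA", "AGA", "AGG", "ATA")]),
                   c("W", "*", "*", "M"))
})

test_that("consequence classifies substitutions in a forward protein gene", {
  g <- toy_protein_genome(); map <- toy_map()
  # codon AAA (13-15): first-position A>G -> Glu
  expect_identical(consequence(13, "A", "G", map, g)$consequence,
                   "non-synonymous")
  expect_identical(consequence(13, "A", "G", map, g)$codon_pos, 1L)
  # third-position AAA>AAG stays Lys
  expect_identical(consequence(15, "A", "G", map, g)$consequence,
                   "synonymous")
  # AGC>AGA is a stop-gain under the mitochondrial code
  expect_identical(consequence(12, "C", "A", map, g)$consequence,
                   "stop-gain")
  # TCA>TGA is Trp (not stop) under the mitochondrial code
  expect_identical(consequence(8, "C", "G", map, g)$consequence,
                   "non-synonymous")
  # outside any gene
  expect_identical(consequence(1, "T", "A", map, g)$consequence,
                   "non-coding")
  expect_error(consequence(13, "C", "G", map, g), "mismatch")
})

test_that("ATA>ATG is synonymous (both Met)", {
  g <- mito_genome_from_string("TTTATGATAAAATAATT")
  genes <- data.frame(name = "G", start = 4L, end = 15L, kind = "protein",
                      orientation = "forward", complex = "I",
                      stringsAsFactors = FALSE)
  map <- build_region_map(genes, g$length)
  expect_identical(consequence(9, "A", "G", map, g)$consequence, "synonymous")
})

test_that("reverse-orientation genes are read on the reverse complement", {
  g <- toy_protein_genome(); map <- toy_map()
  # REV codon 2 is GAT (Asp); genome position 30 holds its third base
  cs <- consequence(30, "A", "C", map, g)     # GAT>GAG, Asp>Glu
  expect_identical(cs$consequence, "non-synonymous")
  expect_identical(cs$gene, "REV")
  expect_identical(cs$codon_pos, 3L)
  expect_identical(consequence(30, "A", "G", map, g)$consequence,
                   "synonymous")              # GAT>GAC stays Asp
})

test_that("reverse-gene consequences match the forward-strand oracle", {
  # oracle: the same coding sequence laid out as a forward gene must give
  # the same consequence for the mirrored substitution
  rev_cds <- "ATGGATCCCTGGTAA"
  fwd_genome <- mito_genome_from_string(paste0("TT", rev_cds, "TT"))
  fwd_map <- build_region_map(
    data.frame(name = "F", start = 3L, end = 17L, kind = "protein",
               orientation = "forward", complex = "I",
               stringsAsFactors = FALSE), fwd_genome$length)
  g <- toy_protein_genome(); map <- toy_map()
  for (cds_off in with_seed(5, sample(0:14, 8L))) {
    rev_pos <- 35L - cds_off                 # REV spans 21..35 reversed
    fwd_pos <- 3L + cds_off
    ref_rev <- genome_base(g, rev_pos)
    ref_fwd <- genome_base(fwd_genome, fwd_pos)
    expect_identical(complement_base(ref_rev), ref_fwd)
    for (alt_fwd in setdiff(c("A", "C", "G", "T"), ref_fwd)) {
      alt_rev <- complement_base(alt_fwd)
      expect_identical(
        consequence(rev_pos, ref_rev, alt_rev, map, g)$consequence,
        consequence(fwd_pos, ref_fwd, alt_fwd, fwd_map,
                    fwd_genome)$consequence)
    }
  }
})

test_that("incomplete terminal codons are padded with A", {
  g <- mito_genome_from_string("TTTATGTCATATTT")   # gene 4..11: ATG TCA TA
  genes <- data.frame(name = "G", start = 4L, end = 11L, kind = "protein",
                      orientation = "forward", complex = "I",
                      stringsAsFactors = FALSE)
  map <- build_region_map(genes, g$length)
  cs <- consequence(11, "A", "G", map, g)  # padded codon TAA -> TGA (Trp)
  expect_identical(cs$codon_pos, 2L)
  expect_identical(cs$consequence, "non-synonymous")
})

test_that("overlap positions report both genes with the most severe primary", {
  map <- build_region_map(mito_genes())
  g <- mito_genome()
  p <- 8530L
  cs <- consequence(p, genome_base(g, p),
                    setdiff(c("A", "C", "G", "T"), genome_base(g, p))[1L],
                    map, g)
  expect_identical(nrow(cs$per_gene), 2L)
  expect_setequal(cs$per_gene$gene, c("ATP8", "ATP6"))
  sev <- match(cs$per_gene$consequence, mitovar:::.CONSEQUENCE_LEVELS)
  expect_identical(match(cs$consequence, mitovar:::.CONSEQUENCE_LEVELS),
                   min(sev))
})

test_that("strand labels complement and are an involution", {
  expect_identical(strand_class("G", "A")$h_class, "C>T")
  expect_identical(strand_class("T", "C")$h_class, "A>G")
  expect_identical(strand_class("C", "A")$h_class, "G>T")
  for (ref in c("A", "C", "G", "T")) {
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      sc <- strand_class(ref, alt)
      flipped <- strand_class(complement_base(ref), complement_base(alt))
      expect_identical(flipped$l_class, sc$h_class)
      expect_identical(flipped$h_class, sc$l_class)
    }
  }
  expect_error(strand_class("A", "A"))
  expect_error(strand_class("A", "X"))
})

test_that("annotate_variants attaches region, consequence and strand group", {
  v <- data.frame(pos = c(11711L, 16519L), ref = c("G", genome_base(mito_genome(), 16519L)),
                  alt = c("A", NA), stringsAsFactors = FALSE)
  v$alt[2] <- setdiff(c("A", "C", "G", "T"), v$ref[2])[1L]
  av <- annotate_variants(v)
  expect_identical(av$gene[1], "ND4")
  expect_identical(av$consequence[1], "non-synonymous")
  expect_identical(av$region[2], "non-coding")
  expect_identical(av$strand_group[1], "H")   # G>A reads C>T on the H strand
})

test_that("packaged synthetic reference is reproducible and ORF-clean", {
  g <- mito_genome()
  expect_identical(g$length, 16569L)
  regen <- synthetic_mito_genome()
  expect_identical(regen$bases, g$bases)
  code <- mito_genetic_code()
  prot <- mito_genes()
  prot <- prot[prot$kind == "protein", ]
  for (i in seq_len(nrow(prot))) {
    gene <- prot[i, ]
    ncod <- (gene$end - gene$start + 1L) %/% 3L
    expect_identical(unname(code[mitovar:::codon_at(g, gene, 0L)]), "M")
    internal <- vapply(seq_len(ncod - 2L), function(ci) {
      unname(code[mitovar:::codon_at(g, gene, ci)])
    }, character(1))
    expect_false(any(internal == "*"))
  }
})
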