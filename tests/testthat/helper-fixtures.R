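# Toy genome with a fully controlled forward protein gene:
#   positions 1-3   TTT        (non-coding)
#   positions 4-15  ATG TCA AGC AAA   gene "FWD" (protein, complex I)
#   positions 16-18 TAA        (its stop, kept outside for clarity? no --
# the gene includes its stop codon: redefine below)
# Gene FWD spans 4..18: ATG TCA AGC AAA TAA (5 codons incl. stop).
# Gene REV spans 21..35 on the reverse strand; its coding sequence is
# ATG GAT CCC TGG TAA, so the genome carries the reverse complement.
toy_protein_genome <- function() {
  fwd_cds <- "ATGTCAAGCAAATAA"
  rev_cds <- "ATGGATCCCTGGTAA"
  seq <- paste0("TTT", fwd_cds, "GG",
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(rev_cds))),
                "ACGTA")
  mito_genome_from_string(seq, "toy")
}

toy_protein_genes <- function() {
  data.frame(
    name = c("FWD", "REV"),
    start = c(4L, 21L), end = c(18L, 35L),
    kind = "protein", orientation = c("forward", "reverse"),
    complex = c("I", "IV"), stringsAsFactors = FALSE)
}

toy_map <- function() {
  g <- toy_protein_genome()
  build_region_map(toy_protein_genes(), g$length)
}

# One-row site-count builder
site_row <- function(pos, ref, depth, alt = NULL, alt_fwd = 0L, alt_rev = 0L,
                     sample = "s1") {
  row <- data.frame(sample = sample, pos = as.integer(pos), ref = ref,
                    A_fwd = 0L, A_rev = 0L, C_fwd = 0L, C_rev = 0L,
                    G_fwd = 0L, G_rev = 0L, T_fwd = 0L, T_rev = 0L,
                    stringsAsFactors = FALSE)
  nalt <- alt_fwd + alt_rev
  ref_n <- depth - nalt
  rf <- ref_n %/% 2L; rr <- ref_n - rf
  row[[paste0(ref, "_fwd")]] <- rf
  row[[paste0(ref, "_rev")]] <- rr
  if (!is.null(alt)) {
    row[[paste0(alt, "_fwd")]] <- row[[paste0(alt, "_fwd")]] + as.integer(alt_fwd)
    row[[paste0(alt, "_rev")]] <- row[[paste0(alt, "_rev")]] + as.integer(alt_rev)
  }
  row$depth <- as.integer(depth)
  row
}

site_table <- function(...) do.call(rbind, list(...))

# Random site-count table used by the oracle-equivalence tests
random_sites <- function(n, seed, max_depth = 3000L, sample = "s1") {
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      ref <- sample(c("A", "C", "G", "T"), 1L)
      depth <- sample.int(max_depth, 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      vac <- rbinom(1L, depth, runif(1L, 0, 0.2))
      fwd <- rbinom(1L, vac, runif(1L, 0.2, 0.8))
      site_row(i, ref, depth, alt, fwd, vac - fwd, sample = sample)
    })
    do.call(rbind, rows)
  })
}

with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Plain restatement of the constitutional filter cascade, applied one
# (site, allele) at a time -- the brute-force oracle the vectorized caller
# is checked against.
brute_constitutional <- function(sites, t) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    for (alt in setdiff(c("A", "C", "G", "T"), s$ref)) {
      fwd <- s[[paste0(alt, "_fwd")]]; rev <- s[[paste0(alt, "_rev")]]
      vac <- fwd + rev
      if (vac == 0) next
      vaf <- vac / s$depth
      ci_low <- qbeta((1 - t$ci_confidence) / 2, vac, s$depth - vac + 1)
      if (vac == 0) ci_low <- 0
      if (s$depth >= t$min_depth && vac >= t$min_vac &&
          vac >= t$min_vaf * s$depth - 1e-9 && ci_low > 0 &&
          fwd >= t$min_per_strand && rev >= t$min_per_strand) {
        out[[length(out) + 1L]] <- data.frame(pos = s$pos, alt = alt,
                                              vac = vac, vaf = vaf)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(0), alt = character(0), vac = integer(0),
               vaf = numeric(0))
}

brute_somatic <- function(tumour, normal, t, normalized = TRUE) {
  out <- list()
  for (i in seq_len(nrow(tumour))) {
    s <- tumour[i, ]
    j <- which(normal$pos == s$pos)
    if (length(j) != 1L) next
    nrm <- normal[j, ]
    for (alt in setdiff(c("A", "C", "G", "T"), s$ref)) {
      fwd <- s[[paste0(alt, "_fwd")]]; rev <- s[[paste0(alt, "_rev")]]
      vac <- fwd + rev
      if (vac == 0) next
      vaf <- vac / s$depth
      n_vac <- nrm[[paste0(alt, "_fwd")]] + nrm[[paste0(alt, "_rev")]]
      n_vaf <- if (nrm$depth > 0) n_vac / nrm$depth else 0
      ci_low <- qbeta((1 - t$ci_confidence) / 2, vac, s$depth - vac + 1)
      ci_up <- if (vac == s$depth) 1 else
        qbeta(1 - (1 - t$ci_confidence) / 2, vac + 1, s$depth - vac)
      n_vac_cmp <- if (normalized) n_vaf * s$depth else n_vac
      if (s$depth >= t$min_depth && vac >= t$min_vac &&
          vac >= t$min_vaf * s$depth - 1e-9 && ci_low > 0 &&
          fwd >= t$min_per_strand && rev >= t$min_per_strand &&
          nrm$depth >= t$min_depth &&
          vac - n_vac_cmp >= t$somatic_min_vac_diff - 1e-9 &&
          vaf - n_vaf >= t$somatic_min_vaf_diff - 1e-9 &&
          (n_vaf < ci_low || n_vaf > ci_up)) {
        out[[length(out) + 1L]] <- data.frame(pos = s$pos, alt = alt,
                                              vac = vac, vaf = vaf)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(0), alt = character(0), vac = integer(0),
               vaf = numeric(0))
}

call_key <- function(d) sort(paste(d$pos, d$alt))
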