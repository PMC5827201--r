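#' Construct a synthetic rCRS-like mitochondrial reference genome
#'
#' Builds a deterministic 16,569 bp circular genome that carries the real
#' rCRS gene coordinates ([mito_genes()]) but a constructed sequence: this is
#' a labelled synthetic stand-in for the revised Cambridge Reference
#' Sequence, used as the packaged test reference. The sequence is drawn with
#' the light strand's characteristic base composition and then constrained so
#' that every protein gene is a coherent open reading frame in the
#' vertebrate mitochondrial code:
#'
#' * codon 1 of each protein gene is ATG;
#' * internal codons contain no in-frame stop codons (including across the
#'   ATP8/ATP6 and ND4L/ND4 overlaps, where both reading frames are
#'   repaired jointly);
#' * genes whose length is not a multiple of 3 end in the incomplete stop
#'   T / TA completed by polyadenylation, complete genes end in TAA;
#' * the recurrent DLBCL mutation site 11711 is occupied by a GTA (Val)
#'   codon starting at 11711, so the G11711A substitution is a
#'   non-synonymous ND4 variant as on the real rCRS.
#'
#' @param seed integer seed fixing the construction (default gives the
#'   packaged reference).
#' @param genes gene table (default packaged rCRS coordinates).
#' @param genome_length total length (default 16569).
#' @return `mito_genome` named `rcrs_synthetic`.
#' @export
synthetic_mito_genome <- function(seed = 20180226L, genes = mito_genes(),
                                  genome_length = 16569L) {
  code <- mito_genetic_code()
  sense <- names(code)[code != "*"]
  with_local_seed(seed, {
    bases <- sample(.BASES, genome_length, replace = TRUE,
                    prob = c(0.309, 0.313, 0.131, 0.247))
    if (genome_length >= 7L) bases[1:7] <- c("G","A","T","C","A","C","A")

    prot <- genes[genes$kind == "protein", , drop = FALSE]
    write_codon <- function(g, ci, codon) {
      # ci 0-based codon index; trailing bases beyond the gene are dropped
      cb <- strsplit(codon, "")[[1L]]
      if (g$orientation == "forward") {
        pos <- g$start + 3L * ci + 0:2
        keep <- pos <= g$end
        bases[pos[keep]] <<- cb[keep]
      } else {
        pos <- g$end - 3L * ci - 0:2
        keep <- pos >= g$start
        bases[pos[keep]] <<- complement_base(cb)[keep]
      }
    }
    for (i in seq_len(nrow(prot))) {
      g <- prot[i, ]
      len <- g$end - g$start + 1L
      ncod <- len %/% 3L
      rem <- len %% 3L
      write_codon(g, 0L, "ATG")
      for (ci in seq_len(ncod - 1L)) {
        write_codon(g, ci, sample(sense, 1L))
      }
      if (rem == 0L) write_codon(g, ncod - 1L, "TAA")
      else write_codon(g, ncod, "TAA")  # trailing T or TA kept, rest dropped
    }

    # joint repair: overlapping frames can re-introduce internal stops;
    # resample offending codons with random sense codons until clean
    genome <- new_mito_genome(bases, "rcrs_synthetic")
    for (iter in 1:500) {
      dirty <- FALSE
      for (i in seq_len(nrow(prot))) {
        g <- prot[i, ]
        ncod <- (g$end - g$start + 1L) %/% 3L
        for (ci in seq_len(ncod - 2L)) {  # internal codons only
          if (unname(code[codon_at(genome, g, ci)]) == "*") {
            write_codon(g, ci, sample(sense, 1L))
            genome <- new_mito_genome(bases, "rcrs_synthetic")
            dirty <- TRUE
          }
        }
      }
      if (!dirty) break
    }
    if (dirty) stop("internal: ORF repair did not converge")

    # anchor: ND4 codon at 11711..11713 = GTA so that G11711A -> Val>Met
    nd4 <- prot[prot$name == "ND4", ]
    if (nrow(nd4) == 1L && nd4$start <= 11711L - 3L && nd4$end >= 11713L &&
        (11711L - nd4$start) %% 3L == 0L) {
      bases[11711:11713] <- c("G", "T", "A")
    }
    new_mito_genome(bases, "rcrs_synthetic")
  })
}
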