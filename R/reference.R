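# Severity ranking shared by consequence() and primary-region assignment.
.CONSEQUENCE_LEVELS <- c("stop-gain", "non-synonymous", "synonymous",
                         "tRNA", "rRNA", "non-coding")

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Complement nucleotide bases
#'
#' @param x character vector of single bases (A/C/G/T/N).
#' @return complemented bases.
#' @export
complement_base <- function(x) {
  out <- .COMPLEMENT[toupper(x)]
  if (anyNA(out)) stop("non-nucleotide base: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Reverse complement of a base vector or string
#' @param x character vector of bases, or a single string.
#' @return same shape as input, reverse complemented.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  } else {
    rev(complement_base(x))
  }
}

#' Vertebrate mitochondrial genetic code
#'
#' The NCBI translation table 2 used by the 13 mtDNA-encoded proteins:
#' relative to the standard code, TGA encodes Trp, AGA and AGG are stop
#' codons, and ATA encodes Met.
#'
#' @return named character vector mapping all 64 codons (DNA alphabet) to
#'   one-letter amino acids, with "*" for stop.
#' @export
mito_genetic_code <- function() {
  code <- Biostrings::getGeneticCode("2")
  code[seq_along(code)]
}

#' Load a mitochondrial gene annotation table
#'
#' Columns: name, start, end (1-based inclusive), kind (protein/tRNA/rRNA),
#' orientation (forward/reverse relative to the forward rCRS sequence, which
#' is the light strand), complex (I/III/IV/V/none). The packaged default
#' carries the standard rCRS coordinates of the 37 mitochondrial genes.
#'
#' @param path TSV file; default the packaged rCRS table.
#' @return validated data.frame of gene records.
#' @export
mito_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rcrs_genes.tsv", package = "mitovar",
                        mustWork = TRUE)
  }
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "start", "end", "kind", "orientation", "complex")
  if (!all(required %in% names(g))) {
    stop("gene table must have columns: ", paste(required, collapse = ", "))
  }
  g <- g[required]
  if (!all(g$kind %in% c("protein", "tRNA", "rRNA"))) {
    stop("gene kind must be protein/tRNA/rRNA")
  }
  if (!all(g$orientation %in% c("forward", "reverse"))) {
    stop("gene orientation must be forward/reverse")
  }
  if (!all(g$complex %in% c("I", "III", "IV", "V", "none"))) {
    stop("gene complex must be I/III/IV/V/none")
  }
  if (any(g$kind == "protein" & g$complex == "none")) {
    stop("protein genes must be assigned an OxPhos complex")
  }
  g
}

#' Read a mitochondrial genome from FASTA
#'
#' @param path single-record FASTA.
#' @return `mito_genome` object: list with `name`, `bases` (character vector),
#'   and `length`.
#' @export
read_mito_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected a single-record FASTA, got ", length(ss))
  seq <- toupper(as.character(ss[[1L]]))
  new_mito_genome(strsplit(seq, "", fixed = TRUE)[[1L]], names(ss)[1L])
}

#' Write a mitochondrial genome to FASTA
#' @param genome `mito_genome`.
#' @param path output path.
#' @export
write_mito_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(paste(genome$bases, collapse = ""))
  names(ss) <- genome$name
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Build a mitochondrial genome object from a sequence string
#'
#' Mainly useful for constructing small toy genomes in examples and tests;
#' the packaged reference comes from [mito_genome()].
#'
#' @param sequence nucleotide string (A/C/G/T/N).
#' @param name genome identifier.
#' @return `mito_genome`.
#' @export
mito_genome_from_string <- function(sequence, name = "toy") {
  new_mito_genome(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]], name)
}

new_mito_genome <- function(bases, name) {
  if (!all(bases %in% c(.BASES, "N"))) {
    stop("genome alphabet must be A/C/G/T/N")
  }
  structure(list(name = name, bases = bases, length = length(bases)),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$name, ": ", x$length, " bp, circular\n", sep = "")
  invisible(x)
}

#' Packaged mitochondrial reference genome
#'
#' Loads the packaged synthetic rCRS-like reference: a 16,569 bp circular
#' genome carrying the real rCRS gene coordinates but a constructed sequence
#' (see [synthetic_mito_genome()]). Supply the real rCRS FASTA via `path`
#' for analyses of real data.
#'
#' @param path optional FASTA overriding the packaged reference.
#' @return `mito_genome`.
#' @export
mito_genome <- function(path = NULL) {
  if (!is.null(path)) return(read_mito_fasta(path))
  cached <- get0(".genome_cache", envir = .mitovar_cache)
  if (!is.null(cached)) return(cached)
  fa <- system.file("extdata", "rcrs_synthetic.fa", package = "mitovar",
                    mustWork = TRUE)
  g <- read_mito_fasta(fa)
  assign(".genome_cache", g, envir = .mitovar_cache)
  g
}

.mitovar_cache <- new.env(parent = emptyenv())

#' Bases at genome positions (circular)
#'
#' @param genome `mito_genome`.
#' @param positions integer vector; wrapped circularly so 0 maps to the last
#'   base and length+1 maps to the first.
#' @return character vector of bases.
#' @export
genome_base <- function(genome, positions) {
  idx <- ((as.integer(positions) - 1L) %% genome$length) + 1L
  genome$bases[idx]
}

#' Trinucleotide context around a position
#'
#' Returns the 5'-base, reference base and 3'-base as a 3-mer on the forward
#' (light) strand, with circular wrap-around at the genome ends.
#'
#' @param positions 1-based positions (vectorized).
#' @param genome `mito_genome`.
#' @return character vector of 3-mers.
#' @export
trinucleotide_context <- function(positions, genome) {
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > genome$length)) {
    stop("position out of range 1..", genome$length)
  }
  paste0(genome_base(genome, positions - 1L),
         genome_base(genome, positions),
         genome_base(genome, positions + 1L))
}

#' Build the seven-region functional partition of the mitochondrial genome
#'
#' Partitions the genome into non-coding, rRNA, tRNA and OxPhos complex
#' I/III/IV/V classes. Region lengths are the summed gene span lengths per
#' class; the non-coding length is the remainder `genome_length - sum(gene
#' lengths)`, so the short ATP8/ATP6- and ND4L/ND4-style gene overlaps are
#' absorbed into the remainder rather than double counted.
#'
#' @param genes gene table as from [mito_genes()].
#' @param genome_length total genome length (default 16569).
#' @return `region_map` object with `lengths` (named 7-vector), `genes`, and
#'   `genome_length`.
#' @export
build_region_map <- function(genes, genome_length = 16569L) {
  if (any(genes$start < 1L | genes$end > genome_length |
          genes$start > genes$end)) {
    stop("gene outside [1, ", genome_length, "] or start > end")
  }
  key <- paste(genes$name, genes$start, genes$end)
  if (anyDuplicated(key)) stop("duplicate gene records: ",
                               paste(unique(key[duplicated(key)]), collapse = "; "))
  genes$region <- gene_region(genes)
  genes$length <- genes$end - genes$start + 1L
  # identically-classed exact-span duplicates already rejected above; also
  # reject same-name overlapping re-entries, which indicate a malformed table
  for (r in unique(genes$region)) {
    sub <- genes[genes$region == r, , drop = FALSE]
    if (anyDuplicated(sub$name)) stop("duplicate gene name within region ", r)
  }
  region_names <- c("non-coding", "rRNA", "tRNA",
                    "complex I", "complex III", "complex IV", "complex V")
  lens <- stats::setNames(integer(7L), region_names)
  coding <- tapply(genes$length, genes$region, sum)
  lens[names(coding)] <- coding
  lens["non-coding"] <- genome_length - sum(genes$length)
  if (lens["non-coding"] < 0L) stop("gene lengths exceed genome length")
  structure(list(lengths = lens, genes = genes,
                 genome_length = as.integer(genome_length)),
            class = "region_map")
}

gene_region <- function(genes) {
  ifelse(genes$kind == "rRNA", "rRNA",
         ifelse(genes$kind == "tRNA", "tRNA",
                paste0("complex ", genes$complex)))
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map> ", x$genome_length, " bp, ", nrow(x$genes),
      " genes\n", sep = "")
  print(x$lengths)
  invisible(x)
}

#' Region and gene membership of a genome position
#'
#' @param position single 1-based position.
#' @param map `region_map`.
#' @return data.frame with one row per covering gene (columns `region`,
#'   `gene`); positions outside all genes return a single
#'   (`non-coding`, `NA`) row.
#' @export
locate <- function(position, map) {
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > map$genome_length) {
    stop("position must be a single integer in 1..", map$genome_length)
  }
  hit <- map$genes$start <= position & map$genes$end >= position
  if (!any(hit)) {
    return(data.frame(region = "non-coding", gene = NA_character_,
                      stringsAsFactors = FALSE))
  }
  data.frame(region = map$genes$region[hit], gene = map$genes$name[hit],
             stringsAsFactors = FALSE)
}

#' Strand-resolved substitution labels
#'
#' Variants are recorded on the forward rCRS sequence, which is the light
#' (L) strand; the heavy (H) strand is its reverse complement. A forward
#' G>A substitution is therefore a C>T substitution on the H-strand.
#'
#' @param ref,alt nucleotide vectors (equal length).
#' @return data.frame with columns `l_class` (substitution as recorded on
#'   the forward/light strand) and `h_class` (its complement, the
#'   heavy-strand reading).
#' @export
strand_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(ref %in% .BASES) || !all(alt %in% .BASES)) {
    stop("alleles must be A/C/G/T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  data.frame(l_class = paste0(ref, ">", alt),
             h_class = paste0(complement_base(ref), ">", complement_base(alt)),
             stringsAsFactors = FALSE)
}

codon_at <- function(genome, gene, codon_index) {
  # codon_index is 0-based within the gene reading frame; incomplete terminal
  # codons (genes ending in T or TA completed by polyadenylation) are padded
  # with A
  if (gene$orientation == "forward") {
    pos <- gene$start + 3L * codon_index + 0:2
    bases <- ifelse(pos > gene$end, "A", genome_base(genome, pos))
  } else {
    pos <- gene$end - 3L * codon_index - 0:2
    bases <- ifelse(pos < gene$start, "A",
                    complement_base(genome_base(genome, pos)))
  }
  paste(bases, collapse = "")
}

consequence_in_gene <- function(position, ref, alt, gene, genome, code) {
  if (gene$kind == "tRNA") {
    return(list(consequence = "tRNA", codon_pos = NA_integer_,
                ref_aa = NA_character_, alt_aa = NA_character_))
  }
  if (gene$kind == "rRNA") {
    return(list(consequence = "rRNA", codon_pos = NA_integer_,
                ref_aa = NA_character_, alt_aa = NA_character_))
  }
  if (gene$orientation == "forward") {
    off <- position - gene$start
    gref <- ref; galt <- alt
  } else {
    off <- gene$end - position
    gref <- complement_base(ref); galt <- complement_base(alt)
  }
  ci <- as.integer(off %/% 3)
  cpos <- as.integer(off %% 3 + 1)
  codon <- codon_at(genome, gene, ci)
  if (substr(codon, cpos, cpos) != gref) {
    stop("internal: codon base disagrees with reference at position ", position)
  }
  alt_codon <- codon
  substr(alt_codon, cpos, cpos) <- galt
  ref_aa <- unname(code[codon])
  alt_aa <- unname(code[alt_codon])
  cons <- if (ref_aa == alt_aa) "synonymous"
          else if (alt_aa == "*") "stop-gain"
          else "non-synonymous"
  list(consequence = cons, codon_pos = cpos, ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Functional consequence of a single-nucleotide substitution
#'
#' Classifies a substitution as non-coding, tRNA, rRNA, synonymous,
#' non-synonymous or stop-gain using the vertebrate mitochondrial genetic
#' code. Reverse-orientation genes are read on the reverse complement.
#' Positions inside overlapping genes are evaluated against each gene; the
#' most severe consequence (stop-gain > non-synonymous > synonymous > tRNA >
#' rRNA > non-coding) is reported as primary with all per-gene calls
#' retained.
#'
#' @param position 1-based position.
#' @param ref,alt single nucleotides; `ref` must match the genome.
#' @param map `region_map`.
#' @param genome `mito_genome`.
#' @param code genetic code, default [mito_genetic_code()].
#' @return list with `consequence`, `gene`, `region`, `codon_pos` (primary
#'   call) and `per_gene` (data.frame of all gene-level calls).
#' @export
consequence <- function(position, ref, alt, map, genome,
                        code = mito_genetic_code()) {
  ref <- toupper(ref); alt <- toupper(alt)
  gref <- genome_base(genome, position)
  if (gref != ref) {
    stop("reference mismatch at position ", position, ": genome has ", gref,
         ", variant says ", ref)
  }
  if (!alt %in% .BASES || alt == ref) stop("alt must be a nucleotide != ref")
  loc <- locate(position, map)
  rows <- lapply(seq_len(nrow(loc)), function(i) {
    if (is.na(loc$gene[i])) {
      return(data.frame(gene = NA_character_, region = "non-coding",
                        consequence = "non-coding", codon_pos = NA_integer_,
                        ref_aa = NA_character_, alt_aa = NA_character_,
                        stringsAsFactors = FALSE))
    }
    gene <- map$genes[map$genes$name == loc$gene[i], , drop = FALSE][1L, ]
    cg <- consequence_in_gene(position, ref, alt, gene, genome, code)
    data.frame(gene = gene$name, region = gene$region,
               consequence = cg$consequence, codon_pos = cg$codon_pos,
               ref_aa = if (is.null(cg$ref_aa)) NA_character_ else cg$ref_aa,
               alt_aa = if (is.null(cg$alt_aa)) NA_character_ else cg$alt_aa,
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  sev <- match(per_gene$consequence, .CONSEQUENCE_LEVELS)
  primary <- which.min(sev)
  list(consequence = per_gene$consequence[primary],
       gene = per_gene$gene[primary],
       region = per_gene$region[primary],
       codon_pos = per_gene$codon_pos[primary],
       per_gene = per_gene)
}

#' Annotate a variant table with consequence, region and strand classes
#'
#' @param variants data.frame with columns `pos`, `ref`, `alt` (additional
#'   columns are carried through).
#' @param map `region_map`.
#' @param genome `mito_genome`.
#' @param code genetic code.
#' @return input with added columns `gene`, `region`, `consequence`,
#'   `codon_pos`, `context` (forward-strand 3-mer), `l_class`, `h_class`,
#'   and `strand_group` ("H" for forward G>A / T>C, i.e. heavy-strand C>T /
#'   A>G; "L" for forward C>T / A>G; NA otherwise).
#' @export
annotate_variants <- function(variants, map = NULL, genome = NULL,
                              code = mito_genetic_code()) {
  if (is.null(genome)) genome <- mito_genome()
  if (is.null(map)) map <- build_region_map(mito_genes(), genome$length)
  n <- nrow(variants)
  if (n == 0L) {
    for (col in c("gene", "region", "consequence")) {
      variants[[col]] <- character(0)
    }
    variants$codon_pos <- integer(0)
    for (col in c("context", "l_class", "h_class", "strand_group")) {
      variants[[col]] <- character(0)
    }
    return(variants)
  }
  ann <- lapply(seq_len(n), function(i) {
    consequence(variants$pos[i], variants$ref[i], variants$alt[i],
                map, genome, code)
  })
  variants$gene <- vapply(ann, function(a) a$gene, character(1))
  variants$region <- vapply(ann, function(a) a$region, character(1))
  variants$consequence <- vapply(ann, function(a) a$consequence, character(1))
  variants$codon_pos <- vapply(ann, function(a)
    if (is.na(a$codon_pos)) NA_integer_ else as.integer(a$codon_pos),
    integer(1))
  variants$context <- trinucleotide_context(variants$pos, genome)
  sc <- strand_class(variants$ref, variants$alt)
  variants$l_class <- sc$l_class
  variants$h_class <- sc$h_class
  variants$strand_group <- ifelse(sc$h_class %in% c("C>T", "A>G"), "H",
                           ifelse(sc$l_class %in% c("C>T", "A>G"), "L",
                                  NA_character_))
  variants
}
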