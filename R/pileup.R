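#' Parse a text pileup into strand-aware site counts
#'
#' Parses the standard mpileup text dialect (columns chrom / pos / ref /
#' depth / bases / qualities) into per-position strand-split allele counts.
#' Base symbols: `.` and `,` are reference matches on the forward and
#' reverse strand; upper/lowercase A/C/G/T are forward/reverse mismatches;
#' `^X` (read start with mapping quality) and `$` (read end) are consumed
#' without counting; `+n`/`-n` indel runs are skipped; `*`/`#` deletion
#' placeholders and `>`/`<` reference skips consume a quality character but
#' are excluded from counts and depth; N bases are dropped. Bases whose
#' Phred base quality is below `min_baq` are removed from both counts and
#' depth. Mapping quality cannot be re-checked from a plain pileup; MQ
#' filtering is the documented contract of pileup generation upstream.
#'
#' @param lines character vector of pileup lines (or a connection/file path).
#' @param min_baq minimum Phred base (alignment) quality to retain a base.
#' @param sample sample identifier attached to every site.
#' @return site-count data.frame with columns `sample`, `pos`, `ref`,
#'   `A_fwd`, `A_rev`, `C_fwd`, `C_rev`, `G_fwd`, `G_rev`, `T_fwd`, `T_rev`,
#'   `depth` (depth equals the sum of the eight allele counts).
#' @export
parse_pileup <- function(lines, min_baq = 20L, sample = "sample") {
  if (length(lines) == 1L && !grepl("\t", lines) && file.exists(lines)) {
    lines <- readLines(lines)
  }
  rows <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L) stop("pileup line ", li, ": fewer than 4 columns")
    pos <- as.integer(f[2L]); ref <- toupper(f[3L])
    counts <- matrix(0L, nrow = 2L, ncol = 4L,
                     dimnames = list(c("fwd", "rev"), .BASES))
    if (length(f) >= 6L && nzchar(f[5L]) &&
        !grepl("[^.,ACGTNacgtn]", f[5L])) {
      # fast path: no read-start/end, indel or placeholder symbols, so base
      # and quality characters align one-to-one
      bs <- strsplit(f[5L], "", fixed = TRUE)[[1L]]
      q <- utf8ToInt(f[6L]) - 33L
      if (length(bs) != length(q)) {
        stop("pileup line ", li, ": base/quality string length mismatch")
      }
      bs <- bs[q >= min_baq]
      syms <- c(".", ",", .BASES, tolower(.BASES))
      tallies <- table(factor(bs, levels = c(syms, "N", "n")))
      if (ref %in% .BASES) {
        counts["fwd", ref] <- counts["fwd", ref] + tallies[["."]]
        counts["rev", ref] <- counts["rev", ref] + tallies[[","]]
      }
      for (b in .BASES) {
        counts["fwd", b] <- counts["fwd", b] + tallies[[b]]
        counts["rev", b] <- counts["rev", b] + tallies[[tolower(b)]]
      }
    } else if (length(f) >= 6L && nzchar(f[5L])) {
      bs <- strsplit(f[5L], "", fixed = TRUE)[[1L]]
      qs <- strsplit(f[6L], "", fixed = TRUE)[[1L]]
      i <- 1L; qi <- 1L
      take_qual <- function() {
        if (qi > length(qs)) stop("pileup line ", li,
                                  ": base/quality string length mismatch")
        q <- utf8ToInt(qs[qi]) - 33L
        qi <<- qi + 1L
        q
      }
      while (i <= length(bs)) {
        ch <- bs[i]
        if (ch == "^") {
          i <- i + 2L            # caret plus mapping-quality char
        } else if (ch == "$") {
          i <- i + 1L
        } else if (ch == "+" || ch == "-") {
          j <- i + 1L
          while (j <= length(bs) && grepl("[0-9]", bs[j])) j <- j + 1L
          nrun <- as.integer(paste(bs[(i + 1L):(j - 1L)], collapse = ""))
          i <- j + nrun          # indel sequence carries no qualities
        } else if (ch %in% c("*", "#", ">", "<")) {
          take_qual()            # placeholder: consumes quality, not counted
          i <- i + 1L
        } else if (ch == "." || ch == ",") {
          q <- take_qual()
          if (q >= min_baq && ref %in% .BASES) {
            strand <- if (ch == ".") "fwd" else "rev"
            counts[strand, ref] <- counts[strand, ref] + 1L
          }
          i <- i + 1L
        } else if (toupper(ch) %in% c(.BASES, "N")) {
          q <- take_qual()
          b <- toupper(ch)
          if (q >= min_baq && b != "N") {
            strand <- if (ch == toupper(ch)) "fwd" else "rev"
            counts[strand, b] <- counts[strand, b] + 1L
          }
          i <- i + 1L
        } else {
          stop("pileup line ", li, ": unexpected symbol '", ch, "'")
        }
      }
      if (qi != length(qs) + 1L) {
        stop("pileup line ", li, ": base/quality string length mismatch")
      }
    }
    rows[[li]] <- data.frame(
      sample = sample, pos = pos, ref = ref,
      A_fwd = counts["fwd", "A"], A_rev = counts["rev", "A"],
      C_fwd = counts["fwd", "C"], C_rev = counts["rev", "C"],
      G_fwd = counts["fwd", "G"], G_rev = counts["rev", "G"],
      T_fwd = counts["fwd", "T"], T_rev = counts["rev", "T"],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_site_counts()
  out$depth <- as.integer(rowSums(out[count_columns()]))
  validate_site_counts(out)
}

count_columns <- function() {
  c("A_fwd", "A_rev", "C_fwd", "C_rev", "G_fwd", "G_rev", "T_fwd", "T_rev")
}

empty_site_counts <- function() {
  out <- data.frame(sample = character(0), pos = integer(0),
                    ref = character(0), stringsAsFactors = FALSE)
  for (cc in count_columns()) out[[cc]] <- integer(0)
  out$depth <- integer(0)
  out
}

#' Validate a strand-aware site-count table
#'
#' @param sites data.frame in the site-count schema (see [parse_pileup()]).
#' @return the validated table (depth recomputed if absent).
#' @export
validate_site_counts <- function(sites) {
  need <- c("sample", "pos", "ref", count_columns())
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("site counts missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(sites)) {
    cm <- as.matrix(sites[count_columns()])
    if (any(cm < 0L)) stop("negative allele counts")
    if (!"depth" %in% names(sites)) sites$depth <- rowSums(cm)
    if (any(sites$depth != rowSums(cm))) {
      stop("depth must equal the sum of strand-split allele counts")
    }
    if (!all(sites$ref %in% c(.BASES, "N"))) stop("ref must be A/C/G/T/N")
  } else if (!"depth" %in% names(sites)) sites$depth <- integer(0)
  sites
}

#' Read a site-count TSV
#'
#' Count-table alternative to the pileup input: columns sample, pos, ref and
#' strand-split counts A_fwd..T_rev. No quality filtering applies to this
#' path (counts are taken as already filtered upstream).
#'
#' @param path TSV file.
#' @return validated site-count data.frame.
#' @export
read_site_counts <- function(path) {
  validate_site_counts(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a site-count TSV
#' @param sites site-count data.frame.
#' @param path output path.
#' @export
write_site_counts <- function(sites, path) {
  utils::write.table(validate_site_counts(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render site counts as pileup text
#'
#' Inverse of [parse_pileup()] for testing both input paths: emits one
#' pileup line per site with all base qualities set to `qual` (Phred).
#'
#' @param sites site-count data.frame.
#' @param qual Phred quality written for every base (default 40).
#' @param chrom contig name.
#' @return character vector of pileup lines.
#' @export
format_pileup <- function(sites, qual = 40L, chrom = "chrM") {
  sites <- validate_site_counts(sites)
  qc <- intToUtf8(qual + 33L)
  vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    parts <- character(0)
    for (b in .BASES) {
      fwd <- s[[paste0(b, "_fwd")]]; rev <- s[[paste0(b, "_rev")]]
      sym_f <- if (b == s$ref) "." else b
      sym_r <- if (b == s$ref) "," else tolower(b)
      parts <- c(parts, strrep(sym_f, fwd), strrep(sym_r, rev))
    }
    bases <- paste(parts, collapse = "")
    paste(chrom, s$pos, s$ref, s$depth, bases,
          strrep(qc, s$depth), sep = "\t")
  }, character(1))
}
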