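#' Mutational super-hotspot positions
#'
#' Highly recurrent control-region polymorphisms that are frequent in the
#' general population without being haplogroup-informative; excluded from
#' the private-variant set. Matching is exact on (position, alt allele).
#'
#' @return data.frame with columns `pos`, `ref`, `alt`.
#' @export
default_hotspots <- function() {
  data.frame(pos = c(16182L, 16183L, 16519L),
             ref = c("A", "A", "T"),
             alt = c("C", "C", "C"), stringsAsFactors = FALSE)
}

parse_variant_token <- function(tok) {
  m <- regmatches(tok, regexec("^([ACGT])([0-9]+)([ACGT])$", toupper(tok)))[[1L]]
  if (length(m) != 4L) stop("malformed variant token: ", tok)
  data.frame(pos = as.integer(m[3L]), ref = m[2L], alt = m[4L],
             stringsAsFactors = FALSE)
}

#' Read a phylotree-style haplogroup table
#'
#' TSV with columns `haplogroup`, `parent` (empty for the root) and
#' `defining_variants` (comma-separated tokens like `T16519C`, possibly
#' empty). The packaged toy tree is a small synthetic fixture for testing;
#' a full phylotree-format table in the same schema can be supplied.
#'
#' @param path TSV file; default the packaged toy tree.
#' @return `phylotree` object: node table plus per-node root-to-node path
#'   variant sets.
#' @export
read_phylotree <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "toy_phylotree.tsv", package = "mitovar",
                        mustWork = TRUE)
  }
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  stopifnot(all(c("haplogroup", "parent", "defining_variants") %in% names(tb)))
  tb$parent[tb$parent == ""] <- NA_character_
  if (sum(is.na(tb$parent)) != 1L) stop("tree must have exactly one root")
  if (anyDuplicated(tb$haplogroup)) stop("duplicate haplogroup labels")
  if (!all(tb$parent[!is.na(tb$parent)] %in% tb$haplogroup)) {
    stop("parent labels missing from the table")
  }
  defining <- lapply(tb$defining_variants, function(s) {
    toks <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
    toks <- toks[nzchar(toks)]
    if (!length(toks)) {
      return(data.frame(pos = integer(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(toks, parse_variant_token))
  })
  # accumulate root-to-node paths; also detects cycles
  paths <- vector("list", nrow(tb))
  depth <- integer(nrow(tb))
  path_of <- function(i, seen = character(0)) {
    if (!is.null(paths[[i]])) return(paths[[i]])
    if (tb$haplogroup[i] %in% seen) stop("cycle in haplogroup tree at ",
                                         tb$haplogroup[i])
    if (is.na(tb$parent[i])) {
      res <- defining[[i]]
    } else {
      j <- match(tb$parent[i], tb$haplogroup)
      res <- rbind(path_of(j, c(seen, tb$haplogroup[i])), defining[[i]])
    }
    paths[[i]] <<- unique(res)
    paths[[i]]
  }
  for (i in seq_len(nrow(tb))) path_of(i)
  for (i in seq_len(nrow(tb))) {
    depth[i] <- 0L
    j <- i
    while (!is.na(tb$parent[j])) {
      j <- match(tb$parent[j], tb$haplogroup)
      depth[i] <- depth[i] + 1L
    }
  }
  structure(list(nodes = tb$haplogroup, parent = tb$parent,
                 defining = defining, paths = paths, depth = depth),
            class = "phylotree")
}

#' @export
print.phylotree <- function(x, ...) {
  cat("<phylotree> ", length(x$nodes), " nodes, root ",
      x$nodes[x$depth == 0L], "\n", sep = "")
  invisible(x)
}

variant_key <- function(v) {
  if (NROW(v) == 0L) return(character(0))
  paste0(v$pos, ":", v$alt)
}

#' Assign a haplogroup from constitutional variants
#'
#' Scores every node of the tree as (path variants matched in the sample)
#' minus (path variants absent from the sample) and returns the maximum;
#' ties are broken by the deeper node, then by lexicographic label. This is
#' a deliberately simple match-minus-mismatch matcher without rank
#' weighting; externally produced haplogroup calls can be supplied to the
#' pipeline instead via a sample-to-haplogroup table.
#'
#' @param constitutional_variants data.frame with columns `pos`, `alt`.
#' @param tree `phylotree`.
#' @return list with `haplogroup`, `score`, `path_variants` (data.frame),
#'   and `scores` (per-node score table).
#' @export
assign_haplogroup <- function(constitutional_variants, tree) {
  if (!inherits(tree, "phylotree")) stop("tree must be a phylotree")
  sample_keys <- unique(variant_key(constitutional_variants))
  score <- vapply(tree$paths, function(p) {
    pk <- variant_key(p)
    length(intersect(pk, sample_keys)) - length(setdiff(pk, sample_keys))
  }, numeric(1))
  ord <- order(-score, -tree$depth, tree$nodes)
  best <- ord[1L]
  list(haplogroup = tree$nodes[best], score = score[best],
       path_variants = tree$paths[[best]],
       scores = data.frame(haplogroup = tree$nodes, score = score,
                           depth = tree$depth, stringsAsFactors = FALSE))
}

#' Derive private constitutional variants
#'
#' Removes from the constitutional set the variants accounted for by the
#' assigned haplogroup (the root-to-node path) and the mutational
#' super-hotspots, both matched exactly on (position, alt allele). A
#' variant at a path or hotspot position but with a different alternative
#' allele is retained. For reporting, hotspot membership takes precedence
#' over path membership.
#'
#' @param constitutional_variants data.frame with columns `pos`, `alt` (and
#'   anything else, carried through).
#' @param haplogroup_call result of [assign_haplogroup()], or a data.frame
#'   of path variants (`pos`, `alt`).
#' @param hotspots hotspot table (default [default_hotspots()]).
#' @return input data.frame with an added `private_class` column
#'   ("private" / "global" / "hotspot"); the private subset is the rows
#'   with `private_class == "private"`.
#' @export
derive_private <- function(constitutional_variants, haplogroup_call,
                           hotspots = default_hotspots()) {
  path <- if (is.data.frame(haplogroup_call)) haplogroup_call
          else haplogroup_call$path_variants
  keys <- variant_key(constitutional_variants)
  cls <- rep("private", length(keys))
  cls[keys %in% variant_key(path)] <- "global"
  cls[keys %in% variant_key(hotspots)] <- "hotspot"  # hotspot precedence
  constitutional_variants$private_class <- cls
  constitutional_variants
}
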