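#' Write variant calls to VCF
#'
#' Minimal VCF 4.2 writer for mitochondrial calls: contig chrM with the
#' genome length, one record per call, sorted by position, with INFO keys
#' SAMPLE, TISSUE, VAC, VAF, FVAC, RVAC, ORIGIN, ZYG and, when present on
#' the input, GENE, REGION, CSQ and PRIV. Duplicate (sample, pos, ref,
#' alt) records are rejected.
#'
#' @param calls variant-call data.frame.
#' @param path output path.
#' @param genome_length contig length written to the header.
#' @return the path, invisibly.
#' @export
write_vcf <- function(calls, path, genome_length = 16569L) {
  key <- paste(calls$sample, calls$pos, calls$ref, calls$alt)
  if (anyDuplicated(key)) stop("duplicate call records: ",
                               paste(unique(key[duplicated(key)]),
                                     collapse = "; "))
  calls <- calls[order(calls$pos, calls$sample, calls$alt), , drop = FALSE]
  info_defs <- c(
    '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Sample identifier">',
    '##INFO=<ID=TISSUE,Number=1,Type=String,Description="Tissue (normal/tumour)">',
    '##INFO=<ID=VAC,Number=1,Type=Integer,Description="Variant allele count">',
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Variant allele fraction">',
    '##INFO=<ID=FVAC,Number=1,Type=Integer,Description="Forward-strand variant count">',
    '##INFO=<ID=RVAC,Number=1,Type=Integer,Description="Reverse-strand variant count">',
    '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="constitutional/somatic">',
    '##INFO=<ID=ZYG,Number=1,Type=String,Description="heteroplasmy/homoplasmy">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Primary gene">',
    '##INFO=<ID=REGION,Number=1,Type=String,Description="Functional region">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=PRIV,Number=1,Type=String,Description="private/global/hotspot">')
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=chrM,length=", genome_length, ">"),
              info_defs,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  esc <- function(x) gsub("[;=[:space:]]", "_", x)
  fmt_info <- function(i) {
    kv <- c(SAMPLE = esc(calls$sample[i]), TISSUE = calls$tissue[i],
            VAC = calls$vac[i], VAF = sprintf("%.6g", calls$vaf[i]),
            FVAC = calls$fwd_vac[i], RVAC = calls$rev_vac[i],
            ORIGIN = calls$origin[i], ZYG = calls$zygosity[i])
    extra <- c(GENE = "gene", REGION = "region", CSQ = "consequence",
               PRIV = "private_class")
    for (k in names(extra)) {
      if (extra[[k]] %in% names(calls) && !is.na(calls[[extra[[k]]]][i])) {
        kv[k] <- esc(calls[[extra[[k]]]][i])
      }
    }
    paste(paste0(names(kv), "=", kv), collapse = ";")
  }
  records <- vapply(seq_len(nrow(calls)), function(i) {
    paste("chrM", calls$pos[i], ".", calls$ref[i], calls$alt[i], ".",
          "PASS", fmt_info(i), sep = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read variant calls back from a package-written VCF
#'
#' Round-trip reader for [write_vcf()] output.
#'
#' @param path VCF file.
#' @return variant-call data.frame.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(empty_variant_calls())
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else NA_character_,
                   character(1))
    unname(vals[match(key, keys)])
  }
  rows <- lapply(f, function(x) {
    info <- x[8L]
    g <- function(k) info_get(info, k)
    data.frame(sample = g("SAMPLE"), tissue = g("TISSUE"),
               pos = as.integer(x[2L]), ref = x[4L], alt = x[5L],
               vac = as.integer(g("VAC")),
               depth = NA_integer_, vaf = as.numeric(g("VAF")),
               fwd_vac = as.integer(g("FVAC")),
               rev_vac = as.integer(g("RVAC")),
               zygosity = g("ZYG"), origin = g("ORIGIN"),
               gene = g("GENE"), region = g("REGION"),
               consequence = g("CSQ"), private_class = g("PRIV"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$depth <- as.integer(round(out$vac / out$vaf))
  out
}

#' Run the end-to-end tumour-normal mitochondrial analysis
#'
#' Executes the full pipeline on a cohort: constitutional calling per
#' normal sample, somatic calling per pair, haplogroup assignment and
#' private-variant derivation, heteroplasmy pairing and shift tests,
#' functional annotation, strand-resolved spectra for somatic and private
#' variant sets, region-distribution tests and the cohort summary.
#'
#' @param cohort a `mito_cohort_sim`, or a list with `manifest` (pair_id,
#'   normal_sample, tumour_sample) and `counts` (named list of site-count
#'   data.frames).
#' @param thresholds [calling_thresholds()].
#' @param genome,genes,tree,hotspots reference inputs (packaged defaults).
#' @param haplogroup_overrides optional data.frame (sample, haplogroup)
#'   bypassing the matcher for listed normal samples.
#' @param scores optional pathogenicity score table (pos, ref, alt, score).
#' @param vac_diff somatic count-difference mode, see [call_somatic()].
#' @param out_dir optional directory: writes calls VCF + TSV, heteroplasmy
#'   pairs TSV and a JSON summary.
#' @param verbose emit per-stage messages with filter-attrition counts.
#' @return `mito_pipeline_result` with elements `calls` (all annotated
#'   calls), `het_pairs`, `shift`, `haplogroups`, `summary`,
#'   `spectra`, `region_tests`, `asymmetry`.
#' @export
run_pipeline <- function(cohort, thresholds = calling_thresholds(),
                         genome = NULL, genes = NULL, tree = NULL,
                         hotspots = default_hotspots(),
                         haplogroup_overrides = NULL, scores = NULL,
                         vac_diff = "normalized",
                         out_dir = NULL, verbose = FALSE) {
  if (is.null(genome)) genome <- mito_genome()
  if (is.null(genes)) genes <- mito_genes()
  if (is.null(tree)) tree <- read_phylotree()
  map <- build_region_map(genes, genome$length)
  manifest <- cohort$manifest
  say <- function(...) if (verbose) message(...)

  all_calls <- list()
  het_pairs <- list()
  hap_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$pair_id[i]
    ns <- manifest$normal_sample[i]; ts <- manifest$tumour_sample[i]
    ncounts <- cohort$counts[[ns]]; tcounts <- cohort$counts[[ts]]
    if (is.null(ncounts) || is.null(tcounts)) {
      stop("stage calling, pair ", pid, ": missing counts for ",
           if (is.null(ncounts)) ns else ts)
    }
    const <- call_constitutional(ncounts, thresholds)
    say(pid, ": ", nrow(const), " constitutional calls (attrition: ",
        paste(names(attr(const, "attrition")),
              attr(const, "attrition"), collapse = " ", sep = "="), ")")
    som <- call_somatic(tcounts, ncounts, thresholds, vac_diff = vac_diff)
    say(pid, ": ", nrow(som), " somatic calls")

    override <- if (!is.null(haplogroup_overrides)) {
      haplogroup_overrides$haplogroup[
        match(ns, haplogroup_overrides$sample)]
    } else NA_character_
    if (!is.na(override)) {
      hap <- list(haplogroup = override, score = NA_real_,
                  path_variants = tree$paths[[match(override, tree$nodes)]])
      if (is.null(hap$path_variants)) {
        stop("stage haplogroup, pair ", pid, ": override haplogroup ",
             override, " not in tree")
      }
    } else if (nrow(const)) {
      hap <- assign_haplogroup(const, tree)
    } else {
      hap <- list(haplogroup = NA_character_, score = NA_real_,
                  path_variants = data.frame(pos = integer(0),
                                             ref = character(0),
                                             alt = character(0)))
    }
    hap_rows[[pid]] <- data.frame(pair_id = pid, sample = ns,
                                  haplogroup = hap$haplogroup,
                                  score = hap$score, stringsAsFactors = FALSE)
    const <- derive_private(const, hap, hotspots)
    if (nrow(som)) som$private_class <- NA_character_

    hp <- pair_heteroplasmies(const, tcounts,
                              min_depth = thresholds$min_depth,
                              pair_id = pid)
    het_pairs[[pid]] <- hp
    const$pair_id <- pid
    if (nrow(som)) som$pair_id <- pid
    all_calls[[pid]] <- rbind(const,
                              if (nrow(som)) som[names(const)] else NULL)
  }
  if (nrow(manifest) == 0L) warning("empty manifest: producing empty outputs")
  calls <- do.call(rbind, all_calls)
  if (is.null(calls)) {
    calls <- empty_variant_calls()
    calls$private_class <- character(0)
    calls$pair_id <- character(0)
  }
  rownames(calls) <- NULL
  het_pairs <- do.call(rbind, het_pairs)
  if (is.null(het_pairs)) {
    het_pairs <- pair_heteroplasmies(empty_variant_calls(),
                                     empty_site_counts())
  }
  rownames(het_pairs) <- NULL
  haplogroups <- do.call(rbind, hap_rows)
  if (is.null(haplogroups)) {
    haplogroups <- data.frame(pair_id = character(0), sample = character(0),
                              haplogroup = character(0), score = numeric(0),
                              stringsAsFactors = FALSE)
  }
  rownames(haplogroups) <- NULL

  calls <- annotate_variants(calls, map, genome)
  if (!is.null(scores)) {
    key <- function(d) paste(d$pos, d$ref, d$alt)
    calls$score <- scores$score[match(key(calls), key(scores))]
  }

  som_set <- calls[calls$origin == "somatic", , drop = FALSE]
  priv_set <- calls[calls$origin == "constitutional" &
                      calls$private_class %in% "private", , drop = FALSE]
  spectra <- list(
    somatic_96 = build_96_spectrum(som_set, genome, "somatic"),
    private_96 = build_96_spectrum(priv_set, genome, "private constitutional"),
    somatic_strand = build_strand_spectrum(som_set),
    private_strand = build_strand_spectrum(priv_set))
  region_tests <- list(
    somatic = if (nrow(som_set)) region_distribution_test(som_set, map),
    private = if (nrow(priv_set)) region_distribution_test(priv_set, map))
  asymmetry <- list(
    somatic = if (nrow(som_set)) strand_asymmetry_analysis(som_set),
    private = if (nrow(priv_set)) strand_asymmetry_analysis(priv_set))
  shift <- if (nrow(het_pairs) >= 2L) {
    shift_report(het_pairs, thresholds$het_lower, thresholds$het_upper)
  }
  summary <- summarize_cohort(calls, cohort_size = nrow(manifest))

  res <- structure(list(calls = calls, het_pairs = het_pairs, shift = shift,
                        haplogroups = haplogroups, summary = summary,
                        spectra = spectra, region_tests = region_tests,
                        asymmetry = asymmetry, thresholds = thresholds),
                   class = "mito_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir, genome)
  res
}

#' @export
print.mito_pipeline_result <- function(x, ...) {
  cat("<mito_pipeline_result>\n")
  print(x$summary)
  if (!is.null(x$shift)) print(x$shift)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir, genome) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(res$calls, file.path(out_dir, "calls.vcf"), genome$length)
  utils::write.table(res$calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$het_pairs, file.path(out_dir, "het_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$haplogroups, file.path(out_dir, "haplogroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(
    cohort = as.list(stats::setNames(res$summary$total_variants,
                                     res$summary$class)),
    shift = if (!is.null(res$shift)) {
      list(hf_t = res$shift$hf_test$t, hf_p = res$shift$hf_test$p,
           vaf_t = res$shift$vaf_test$t, vaf_p = res$shift$vaf_test$p,
           n_fixed = res$shift$n_fixed, n_lost = res$shift$n_lost)
    },
    region_tests = lapply(res$region_tests, function(rt) {
      if (is.null(rt)) NULL else list(chisq = rt$chisq, p = rt$p)
    }))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' @param sim `mito_cohort_sim`.
#' @param dir output directory (created).
#' @param format "tsv" count tables or "pileup" text.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(sim, dir, format = c("tsv", "pileup")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in names(sim$counts)) {
    if (format == "tsv") {
      write_site_counts(sim$counts[[s]], file.path(dir, paste0(s, ".counts.tsv")))
    } else {
      writeLines(format_pileup(sim$counts[[s]]),
                 file.path(dir, paste0(s, ".pileup")))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory with manifest.tsv and per-sample count tables or
#'   pileups.
#' @param min_baq base-quality floor applied when reading pileups.
#' @return list with `manifest` and `counts`, usable by [run_pipeline()].
#' @export
read_cohort <- function(dir, min_baq = 20L) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  samples <- c(manifest$normal_sample, manifest$tumour_sample)
  counts <- lapply(stats::setNames(samples, samples), function(s) {
    tsv <- file.path(dir, paste0(s, ".counts.tsv"))
    pu <- file.path(dir, paste0(s, ".pileup"))
    if (file.exists(tsv)) read_site_counts(tsv)
    else if (file.exists(pu)) parse_pileup(readLines(pu), min_baq, sample = s)
    else stop("no counts for sample ", s, " in ", dir)
  })
  list(manifest = manifest, counts = counts)
}
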