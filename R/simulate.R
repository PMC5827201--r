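#' Default strand-labelled somatic substitution weights
#'
#' Twelve strand-labelled substitution classes ("H:C>T" = C>T as read on
#' the heavy strand, realised as a forward G>A substitution, and so on)
#' with the heavy-strand C>T and A>G transitions elevated, emulating the
#' replication-associated deamination asymmetry of mtDNA mutagenesis.
#'
#' @return named numeric 12-vector summing to 1.
#' @export
default_spectrum_weights <- function() {
  w <- c("H:C>T" = 0.35, "H:A>G" = 0.25, "L:C>T" = 0.10, "L:A>G" = 0.08)
  rest <- c("L:C>A", "L:C>G", "L:T>A", "L:T>G",
            "H:C>A", "H:C>G", "H:T>A", "H:T>G")
  c(w, stats::setNames(rep((1 - sum(w)) / length(rest), length(rest)), rest))
}

#' Simulation configuration for tumour-normal mitochondrial cohorts
#'
#' Defaults emulate the observed study conditions: ~2000x depth with
#' overdispersion (negative-binomial, sd about half the mean), per-base
#' error 5e-4, about 3 private constitutional variants, 1 constitutional
#' heteroplasmy and 1.5 somatic mutations per sample, heteroplasmy VAFs
#' mostly below 0.10, private variants enriched in the D-loop, and somatic
#' substitution classes drawn from heavy-strand-elevated weights.
#'
#' @param seed integer master seed; each pair uses a derived substream.
#' @param n_pairs number of tumour-normal pairs.
#' @param mean_depth mean read depth.
#' @param depth_dispersion negative-binomial size parameter (4 gives sd
#'   about half the mean at 2000x).
#' @param error_rate per-base sequencing error fraction.
#' @param n_private_mean,n_het_mean,n_somatic_mean Poisson means of planted
#'   variant counts per sample.
#' @param het_vaf_shape,het_vaf_range Beta shape parameters and truncation
#'   range of constitutional heteroplasmy VAFs.
#' @param somatic_vaf_shape,somatic_vaf_range same for somatic tumour VAFs.
#' @param private_homoplasmy_prob probability a private variant is
#'   homoplasmic (VAF 1) rather than a low-level heteroplasmy.
#' @param somatic_spectrum_weights strand-labelled 12-class weights
#'   ([default_spectrum_weights()]).
#' @param private_dloop_enrichment placement-weight multiplier for D-loop
#'   positions (16024-16569 and 1-576) when planting private variants.
#' @param drift_model `list(model = "neutral_bottleneck", n_seg, generations)`
#'   or `list(model = "directional", shift)`, applied to constitutional
#'   heteroplasmy VAFs between normal and tumour.
#' @param artefact_pair_rate per-pair probability of injecting one
#'   read-linked artefact variant pair.
#' @return `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_pairs = 20L, mean_depth = 2000,
                              depth_dispersion = 4, error_rate = 5e-4,
                              n_private_mean = 3, n_het_mean = 1,
                              n_somatic_mean = 1.5,
                              het_vaf_shape = c(0.7, 6),
                              het_vaf_range = c(0.025, 0.95),
                              somatic_vaf_shape = c(1.2, 3),
                              somatic_vaf_range = c(0.03, 0.95),
                              private_homoplasmy_prob = 0.7,
                              somatic_spectrum_weights =
                                default_spectrum_weights(),
                              private_dloop_enrichment = 5,
                              drift_model = list(model = "neutral_bottleneck",
                                                 n_seg = 50L,
                                                 generations = 20L),
                              artefact_pair_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              error_rate = error_rate, n_private_mean = n_private_mean,
              n_het_mean = n_het_mean, n_somatic_mean = n_somatic_mean,
              het_vaf_shape = het_vaf_shape, het_vaf_range = het_vaf_range,
              somatic_vaf_shape = somatic_vaf_shape,
              somatic_vaf_range = somatic_vaf_range,
              private_homoplasmy_prob = private_homoplasmy_prob,
              somatic_spectrum_weights = somatic_spectrum_weights,
              private_dloop_enrichment = private_dloop_enrichment,
              drift_model = drift_model,
              artefact_pair_rate = artefact_pair_rate)
  stopifnot(cfg$n_pairs >= 0L, cfg$mean_depth > 0, cfg$depth_dispersion > 0,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$artefact_pair_rate >= 0, cfg$artefact_pair_rate <= 1,
            cfg$private_homoplasmy_prob >= 0, cfg$private_homoplasmy_prob <= 1,
            length(cfg$somatic_spectrum_weights) == 12L,
            abs(sum(cfg$somatic_spectrum_weights) - 1) < 1e-8,
            all(cfg$somatic_spectrum_weights >= 0),
            cfg$drift_model$model %in% c("neutral_bottleneck", "directional",
                                         "none"))
  structure(cfg, class = "simulation_config")
}

rbeta_trunc <- function(n, shape, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rbeta(n, shape[1L], shape[2L])
    out <- c(out, x[x >= range[1L] & x <= range[2L]])
  }
  out[seq_len(n)]
}

pair_seed <- function(seed, pair_index) {
  as.integer((as.numeric(seed) + 77003 * pair_index) %% 2147483629)
}

#' Wright-Fisher bottleneck drift of a heteroplasmy fraction
#'
#' Repeated binomial resampling of `n_seg` segregating mtDNA units for
#' `generations` generations. The expectation is preserved (neutral drift);
#' the variance after g generations is `p (1 - p) (1 - (1 - 1/n_seg)^g)`.
#' Fractions 0 and 1 are absorbing.
#'
#' @param vaf numeric vector of starting fractions in \code{[0, 1]}.
#' @param n_seg segregating unit count (bottleneck size), >= 1.
#' @param generations number of resampling generations.
#' @return drifted fractions, same length as `vaf`.
#' @export
neutral_bottleneck_drift <- function(vaf, n_seg = 50L, generations = 20L) {
  stopifnot(n_seg >= 1L, all(vaf >= 0 & vaf <= 1))
  for (g in seq_len(generations)) {
    vaf <- stats::rbinom(length(vaf), n_seg, vaf) / n_seg
  }
  vaf
}

apply_drift <- function(vaf, drift_model) {
  switch(drift_model$model,
    none = vaf,
    neutral_bottleneck = neutral_bottleneck_drift(vaf, drift_model$n_seg,
                                                  drift_model$generations),
    directional = pmin(1, pmax(0, vaf + ifelse(vaf >= 0.5,
                                               drift_model$shift,
                                               -drift_model$shift))),
    stop("unknown drift model: ", drift_model$model))
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

draw_alt <- function(ref, transition_prob = 0.9) {
  vapply(ref, function(b) {
    if (stats::runif(1) < transition_prob) {
      transition_of[[b]]
    } else {
      sample(setdiff(.BASES, c(b, transition_of[[b]])), 1L)
    }
  }, character(1), USE.NAMES = FALSE)
}

# forward-strand (ref, alt) realising a strand-labelled class like "H:C>T"
realize_class <- function(lab) {
  strand <- substr(lab, 1L, 1L)
  sub <- strsplit(substr(lab, 3L, nchar(lab)), ">", fixed = TRUE)[[1L]]
  if (strand == "H") sub <- complement_base(sub)
  sub
}

# strand-split count table for one sample given per-position truth VAFs
emit_counts <- function(genome, vaf, alt, config, sample_id) {
  L <- genome$length
  depth <- stats::rnbinom(L, mu = config$mean_depth,
                          size = config$depth_dispersion)
  vac <- integer(L)
  has <- which(vaf > 0)
  vac[has] <- stats::rbinom(length(has), depth[has], vaf[has])
  nref <- depth - vac
  err <- matrix(0L, nrow = L, ncol = 3L)
  if (config$error_rate > 0) {
    for (k in 1:3) {
      err[, k] <- stats::rbinom(L, nref, config$error_rate / 3)
    }
    over <- rowSums(err) > nref
    err[over, ] <- 0L   # vanishingly rare at realistic error rates
  }
  nref <- nref - rowSums(err)
  M <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, .BASES))
  ref_idx <- match(genome$bases, .BASES)
  M[cbind(seq_len(L), ref_idx)] <- nref
  # errors go to the three non-reference bases in fixed base order
  nonref_table <- t(vapply(1:4, function(r) setdiff(1:4, r), integer(3)))
  nonref <- nonref_table[ref_idx, , drop = FALSE]
  for (k in 1:3) {
    M[cbind(seq_len(L), nonref[, k])] <- M[cbind(seq_len(L), nonref[, k])] +
      err[, k]
  }
  alt_idx <- match(alt, .BASES)
  M[cbind(has, alt_idx[has])] <- M[cbind(has, alt_idx[has])] + vac[has]
  Fw <- matrix(stats::rbinom(length(M), as.vector(M), 0.5), nrow = L)
  Rv <- M - Fw
  out <- data.frame(sample = sample_id, pos = seq_len(L),
                    ref = genome$bases, stringsAsFactors = FALSE)
  for (k in seq_along(.BASES)) {
    out[[paste0(.BASES[k], "_fwd")]] <- as.integer(Fw[, k])
    out[[paste0(.BASES[k], "_rev")]] <- as.integer(Rv[, k])
  }
  out$depth <- as.integer(rowSums(M))
  out
}

#' Inject a read-linked artefact variant pair
#'
#' Adds `n_linked` variant reads carrying both alternative alleles on the
#' same synthetic read identifiers at two positions, plus `n_background`
#' reference reads covering both positions, to a site-count table. Emits
#' the matching read-level observations used by
#' [flag_linked_artefacts()].
#'
#' @param counts site-count data.frame.
#' @param positions integer vector of two distinct positions.
#' @param alts alternative alleles at the two positions.
#' @param n_linked number of linked variant reads.
#' @param n_background number of reference reads covering both positions.
#' @param read_prefix prefix of synthetic read identifiers.
#' @return list with modified `counts` and `observations` (read_id, pos,
#'   allele).
#' @export
inject_artefact_pair <- function(counts, positions, alts, n_linked,
                                 n_background = n_linked,
                                 read_prefix = "artefact") {
  if (length(positions) != 2L || positions[1L] == positions[2L]) {
    stop("positions must be two distinct values")
  }
  counts <- validate_site_counts(counts)
  for (i in 1:2) {
    r <- which(counts$pos == positions[i])
    if (length(r) != 1L) stop("position ", positions[i], " not in counts")
    if (counts$ref[r] == alts[i]) {
      stop("artefact allele equals the reference at position ", positions[i])
    }
    fwd <- stats::rbinom(1L, n_linked, 0.5)
    cf <- paste0(alts[i], "_fwd"); cr <- paste0(alts[i], "_rev")
    counts[[cf]][r] <- counts[[cf]][r] + fwd
    counts[[cr]][r] <- counts[[cr]][r] + n_linked - fwd
    counts$depth[r] <- counts$depth[r] + n_linked
  }
  refs <- counts$ref[match(positions, counts$pos)]
  obs <- rbind(
    data.frame(read_id = rep(sprintf("%s_link_%d", read_prefix,
                                     seq_len(n_linked)), each = 2L),
               pos = rep(positions, n_linked),
               allele = rep(alts, n_linked), stringsAsFactors = FALSE),
    if (n_background > 0L) {
      data.frame(read_id = rep(sprintf("%s_ref_%d", read_prefix,
                                       seq_len(n_background)), each = 2L),
                 pos = rep(positions, n_background),
                 allele = rep(refs, n_background), stringsAsFactors = FALSE)
    })
  list(counts = counts, observations = obs)
}

#' Simulate one tumour-normal pair with known truth
#'
#' Deterministic given `(config$seed, pair_index)`. Plants, in order: the
#' homoplasmic defining variants of a haplogroup drawn from the tree
#' (class "global"); private constitutional variants placed with D-loop
#' enrichment (class "private", mostly homoplasmic); constitutional
#' heteroplasmies with VAFs mostly below 0.10 (class "heteroplasmy");
#' somatic mutations placed uniformly with substitution classes drawn from
#' the strand-labelled spectrum weights (class "somatic", tumour only).
#' Constitutional heteroplasmy VAFs are transformed by the drift model
#' between normal and tumour. Read counts are emitted per position with
#' negative-binomial depth, binomial allele counts, binomial 0.5 strand
#' split and per-base error.
#'
#' @param config [simulation_config()].
#' @param pair_index 1-based pair number.
#' @param genome `mito_genome` (default packaged reference).
#' @param tree `phylotree` (default packaged toy tree).
#' @return list with `normal` and `tumour` site-count data.frames, `truth`
#'   (pair_id, sample, pos, ref, alt, class, vaf_normal, vaf_tumour,
#'   strand_label, haplogroup), and `observations` (read-linked artefact
#'   reads, or NULL).
#' @export
simulate_pair <- function(config, pair_index, genome = NULL, tree = NULL) {
  if (is.null(genome)) genome <- mito_genome()
  if (is.null(tree)) tree <- read_phylotree()
  with_local_seed(pair_seed(config$seed, pair_index), {
    pair_id <- sprintf("P%03d", pair_index)
    used <- integer(0)
    rows <- list()
    add <- function(pos, ref, alt, class, vn, vt, strand_label = NA_character_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        pair_id = pair_id, pos = as.integer(pos), ref = ref, alt = alt,
        class = class, vaf_normal = vn, vaf_tumour = vt,
        strand_label = strand_label, stringsAsFactors = FALSE)
      used <<- c(used, pos)
    }

    nodes <- tree$nodes[tree$depth > 0L]
    hap <- sample(nodes, 1L)
    path <- tree$paths[[match(hap, tree$nodes)]]
    for (i in seq_len(nrow(path))) {
      if (genome_base(genome, path$pos[i]) != path$ref[i]) {
        stop("tree variant reference mismatch at ", path$pos[i])
      }
      add(path$pos[i], path$ref[i], path$alt[i], "global", 1, 1)
    }

    dloop <- c(16024:16569, 1:576)
    w <- rep(1, genome$length)
    w[dloop] <- config$private_dloop_enrichment
    n_p <- stats::rpois(1L, config$n_private_mean)
    while (n_p > 0L) {
      p <- sample.int(genome$length, 1L, prob = w)
      if (p %in% used) next
      ref <- genome_base(genome, p)
      vaf <- if (stats::runif(1) < config$private_homoplasmy_prob) 1 else
        rbeta_trunc(1L, config$het_vaf_shape, config$het_vaf_range)
      add(p, ref, draw_alt(ref), "private", vaf, vaf)
      n_p <- n_p - 1L
    }

    n_h <- stats::rpois(1L, config$n_het_mean)
    while (n_h > 0L) {
      p <- sample.int(genome$length, 1L)
      if (p %in% used) next
      ref <- genome_base(genome, p)
      vaf <- rbeta_trunc(1L, config$het_vaf_shape, config$het_vaf_range)
      add(p, ref, draw_alt(ref), "heteroplasmy", vaf, vaf)
      n_h <- n_h - 1L
    }

    wts <- config$somatic_spectrum_weights
    n_s <- stats::rpois(1L, config$n_somatic_mean)
    while (n_s > 0L) {
      lab <- sample(names(wts), 1L, prob = wts)
      sub <- realize_class(lab)
      cand <- which(genome$bases == sub[1L])
      p <- cand[sample.int(length(cand), 1L)]
      if (p %in% used) next
      add(p, sub[1L], sub[2L], "somatic", 0,
          rbeta_trunc(1L, config$somatic_vaf_shape, config$somatic_vaf_range),
          strand_label = lab)
      n_s <- n_s - 1L
    }

    truth <- do.call(rbind, rows)
    if (is.null(truth)) {
      truth <- data.frame(pair_id = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          class = character(0), vaf_normal = numeric(0),
                          vaf_tumour = numeric(0),
                          strand_label = character(0),
                          stringsAsFactors = FALSE)
    } else {
      drifting <- truth$class %in% c("private", "heteroplasmy") &
        truth$vaf_normal > 0 & truth$vaf_normal < 1
      truth$vaf_tumour[drifting] <- apply_drift(truth$vaf_normal[drifting],
                                                config$drift_model)
    }
    truth$haplogroup <- hap

    vn <- vt <- numeric(genome$length)
    alt <- rep(NA_character_, genome$length)
    vn[truth$pos] <- truth$vaf_normal
    vt[truth$pos] <- truth$vaf_tumour
    alt[truth$pos] <- truth$alt
    normal <- emit_counts(genome, vn, alt, config,
                          paste0(pair_id, "_normal"))
    tumour <- emit_counts(genome, vt, alt, config,
                          paste0(pair_id, "_tumour"))

    observations <- NULL
    if (config$artefact_pair_rate > 0 &&
        stats::runif(1) < config$artefact_pair_rate) {
      repeat {
        p1 <- sample.int(genome$length - 60L, 1L)
        p2 <- p1 + sample(5:60, 1L)
        if (!p1 %in% used && !p2 %in% used) break
      }
      alts <- draw_alt(genome_base(genome, c(p1, p2)))
      n_linked <- max(20L, round(0.05 * config$mean_depth))
      for (tissue in c("normal", "tumour")) {
        cts <- if (tissue == "normal") normal else tumour
        inj <- inject_artefact_pair(cts, c(p1, p2), alts, n_linked,
                                    read_prefix = paste0(pair_id, "_", tissue))
        if (tissue == "normal") normal <- inj$counts else tumour <- inj$counts
        observations <- rbind(observations, inj$observations)
      }
      attr(observations, "pair") <- data.frame(
        pos1 = p1, alt1 = alts[1L], pos2 = p2, alt2 = alts[2L],
        stringsAsFactors = FALSE)
    }
    list(normal = normal, tumour = tumour, truth = truth,
         observations = observations)
  })
}

#' Simulate a tumour-normal cohort
#'
#' @param config [simulation_config()].
#' @param genome,tree as in [simulate_pair()].
#' @return `mito_cohort_sim`: `manifest` (pair_id, normal_sample,
#'   tumour_sample), `counts` (named list of site-count data.frames),
#'   `truth`, `observations`, `config`.
#' @export
simulate_cohort <- function(config, genome = NULL, tree = NULL) {
  if (is.null(genome)) genome <- mito_genome()
  if (is.null(tree)) tree <- read_phylotree()
  counts <- list()
  truth <- list()
  obs <- list()
  manifest <- data.frame(pair_id = character(0),
                         normal_sample = character(0),
                         tumour_sample = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(config$n_pairs)) {
    sp <- simulate_pair(config, i, genome, tree)
    pid <- sprintf("P%03d", i)
    ns <- paste0(pid, "_normal"); ts <- paste0(pid, "_tumour")
    counts[[ns]] <- sp$normal
    counts[[ts]] <- sp$tumour
    truth[[i]] <- sp$truth
    if (!is.null(sp$observations)) obs[[pid]] <- sp$observations
    manifest <- rbind(manifest, data.frame(
      pair_id = pid, normal_sample = ns, tumour_sample = ts,
      stringsAsFactors = FALSE))
  }
  structure(list(manifest = manifest, counts = counts,
                 truth = do.call(rbind, truth), observations = obs,
                 config = config),
            class = "mito_cohort_sim")
}

#' @export
print.mito_cohort_sim <- function(x, ...) {
  cat("<mito_cohort_sim> ", nrow(x$manifest), " pairs, ",
      nrow(x$truth), " planted variants\n", sep = "")
  if (nrow(x$truth)) print(table(x$truth$class))
  invisible(x)
}

#' Simulate observed heteroplasmy pairs without full count emission
#'
#' Reduced generator for the shift statistics: draws constitutional
#' heteroplasmy VAFs, applies the drift model, then emits observed
#' normal/tumour VAFs by binomial sampling at negative-binomial depths.
#' Used to study the behaviour of [shift_report()] over many replicate
#' cohorts at low cost.
#'
#' @param n number of heteroplasmies.
#' @param config [simulation_config()] (drift model, depth and
#'   heteroplasmy-VAF settings are used).
#' @param seed optional seed applied locally.
#' @return data.frame in the [pair_heteroplasmies()] schema.
#' @export
simulate_heteroplasmy_pairs <- function(n, config = simulation_config(),
                                        seed = NULL) {
  run <- function() {
    vaf_n <- rbeta_trunc(n, config$het_vaf_shape, config$het_vaf_range)
    vaf_t <- apply_drift(vaf_n, config$drift_model)
    dn <- pmax(1L, stats::rnbinom(n, mu = config$mean_depth,
                                  size = config$depth_dispersion))
    dt <- pmax(1L, stats::rnbinom(n, mu = config$mean_depth,
                                  size = config$depth_dispersion))
    obs_n <- stats::rbinom(n, dn, vaf_n) / dn
    obs_t <- stats::rbinom(n, dt, vaf_t) / dt
    out <- data.frame(pair_id = "sim", pos = seq_len(n), ref = "C", alt = "T",
                      normal_vaf = obs_n, tumour_vaf = obs_t,
                      normal_hf = pmin(obs_n, 1 - obs_n),
                      tumour_hf = pmin(obs_t, 1 - obs_t),
                      tumour_depth = dt, low_confidence = FALSE,
                      stringsAsFactors = FALSE)
    out$delta_hf <- out$normal_hf - out$tumour_hf
    out$delta_vaf <- out$tumour_vaf - out$normal_vaf
    out
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
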