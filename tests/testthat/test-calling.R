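test_that("Clopper-Pearson interval has exact boundary behaviour", {
  expect_identical(binomial_interval(0, 2000)$lower, 0)
  expect_identical(binomial_interval(2000, 2000)$upper, 1)
  ci <- binomial_interval(10, 100)
  expect_gt(ci$lower, 0)
  expect_lt(ci$upper, 1)
  # defining property: at the lower bound, P(X >= x) = alpha/2
  alpha <- 1 - 0.99999
  expect_equal(1 - pbinom(9, 100, ci$lower), alpha / 2, tolerance = 1e-9)
  expect_equal(pbinom(10, 100, ci$upper), alpha / 2, tolerance = 1e-9)
  expect_error(binomial_interval(1, 0), "depth")
  expect_error(binomial_interval(5, 2), "count")
})

test_that("constitutional cascade accepts and rejects the boundary cases", {
  t <- calling_thresholds()
  called <- call_constitutional(site_row(100, "A", 2000, "G", 25, 25), t)
  expect_identical(nrow(called), 1L)
  expect_equal(called$vaf, 0.025)
  expect_identical(called$zygosity, "heteroplasmy")
  # strand filter: 46/4 split rejected
  expect_identical(
    nrow(call_constitutional(site_row(100, "A", 2000, "G", 46, 4), t)), 0L)
  # depth filter
  expect_identical(
    nrow(call_constitutional(site_row(100, "A", 90, "G", 15, 15), t)), 0L)
  # empty input
  expect_identical(nrow(call_constitutional(site_row(1, "A", 500))), 0L)
})

test_that("multi-allelic sites are filtered independently", {
  s <- site_row(9, "A", 2000, "G", 30, 30)
  s$C_fwd <- 25L; s$C_rev <- 25L
  s$depth <- s$depth + 50L
  calls <- call_constitutional(s)
  expect_setequal(calls$alt, c("C", "G"))
  expect_equal(calls$vaf, calls$vac / 2050, tolerance = 1e-12)
})

test_that("constitutional calls equal the brute-force filter oracle", {
  sites <- random_sites(300L, seed = 17)
  settings <- list(
    calling_thresholds(),
    calling_thresholds(min_depth = 500L, min_vaf = 0.05, min_vac = 25L),
    calling_thresholds(min_per_strand = 1L, ci_confidence = 0.95),
    calling_thresholds(min_vaf = 0.005, min_vac = 3L, min_per_strand = 0L))
  for (t in settings) {
    got <- call_constitutional(sites, t)
    want <- brute_constitutional(sites, t)
    expect_identical(call_key(got), call_key(want))
  }
})

test_that("raising any threshold never adds a constitutional call", {
  sites <- random_sites(200L, seed = 23)
  base <- calling_thresholds()
  n0 <- nrow(call_constitutional(sites, base))
  stricter <- list(
    calling_thresholds(min_depth = 1000L),
    calling_thresholds(min_vaf = 0.10),
    calling_thresholds(min_vac = 50L),
    calling_thresholds(min_per_strand = 20L),
    calling_thresholds(ci_confidence = 0.9999999))
  for (t in stricter) {
    expect_lte(nrow(call_constitutional(sites, t)), n0)
  }
})

test_that("somatic conditions separate true somatic from shared variants", {
  t <- calling_thresholds()
  tum <- site_row(50, "A", 2000, "G", 25, 25)
  nrm <- site_row(50, "A", 2000)
  som <- call_somatic(tum, nrm, t)
  expect_identical(nrow(som), 1L)
  expect_identical(som$origin, "somatic")
  expect_equal(som$normal_vaf, 0)
  # VAF difference 0.01 < 0.02: rejected even though both pass singly
  tum2 <- site_row(51, "A", 2000, "G", 500, 500)
  nrm2 <- site_row(51, "A", 2000, "G", 490, 490)
  expect_identical(nrow(call_somatic(tum2, nrm2, t)), 0L)
  # below min_vac
  tum3 <- site_row(52, "A", 2000, "G", 5, 4)
  expect_identical(nrow(call_somatic(tum3, site_row(52, "A", 2000), t)), 0L)
  # unmatched tumour positions are skipped with a warning
  expect_warning(call_somatic(tum, site_row(99, "A", 2000), t), "unmatched")
})

test_that("somatic calls equal the brute-force oracle in both diff modes", {
  with_seed(31, {
    tum <- random_sites(200L, seed = 41, sample = "t")
    nrm <- random_sites(200L, seed = 42, sample = "n")
  })
  nrm$pos <- tum$pos
  nrm$ref <- tum$ref   # matched loci share the reference allele
  for (t in list(calling_thresholds(),
                 calling_thresholds(somatic_min_vaf_diff = 0.1,
                                    somatic_min_vac_diff = 50))) {
    for (mode in c("normalized", "raw")) {
      got <- suppressWarnings(call_somatic(tum, nrm, t, vac_diff = mode))
      want <- brute_somatic(tum, nrm, t, normalized = mode == "normalized")
      expect_identical(call_key(got), call_key(want))
    }
  }
})

test_that("every somatic call satisfies the somatic conditions a posteriori", {
  sim <- simulate_cohort(simulation_config(seed = 91, n_pairs = 3))
  t <- calling_thresholds()
  for (i in 1:3) {
    pid <- sprintf("P%03d", i)
    som <- call_somatic(sim$counts[[paste0(pid, "_tumour")]],
                        sim$counts[[paste0(pid, "_normal")]], t)
    if (nrow(som) == 0L) next
    expect_true(all(som$vaf - som$normal_vaf >= t$somatic_min_vaf_diff - 1e-9))
    expect_true(all(som$vac >= t$min_vac))
    expect_true(all(som$fwd_vac >= t$min_per_strand &
                      som$rev_vac >= t$min_per_strand))
    expect_true(all(som$depth >= t$min_depth))
  }
})

test_that("zygosity band is inclusive and partitions calls", {
  expect_identical(classify_zygosity(0.05), "heteroplasmy")
  expect_identical(classify_zygosity(0.995), "homoplasmy")
  expect_identical(classify_zygosity(0.98), "heteroplasmy")
  expect_identical(classify_zygosity(0.02), "heteroplasmy")
  expect_identical(classify_zygosity(0.0199), "homoplasmy")
  vafs <- with_seed(7, runif(200))
  z <- classify_zygosity(vafs)
  expect_true(all(z %in% c("heteroplasmy", "homoplasmy")))
})

test_that("linked artefact pairs are flagged by read co-occurrence", {
  mk_obs <- function(n_both, n_first_only, n_second_only, n_ref) {
    ids <- sprintf("r%03d", seq_len(n_both + n_first_only + n_second_only +
                                      n_ref))
    a1 <- c(rep("T", n_both + n_first_only),
            rep("C", n_second_only + n_ref))
    a2 <- c(rep("A", n_both), rep("G", n_first_only),
            rep("A", n_second_only), rep("G", n_ref))
    rbind(data.frame(read_id = ids, pos = 100L, allele = a1),
          data.frame(read_id = ids, pos = 120L, allele = a2))
  }
  pair <- data.frame(pos1 = 100L, alt1 = "T", pos2 = 120L, alt2 = "A")
  # perfect linkage
  res <- flag_linked_artefacts(mk_obs(100, 0, 0, 50), pair)
  expect_true(res$flagged)
  expect_equal(res$fraction, 1)
  # disjoint read sets
  res <- flag_linked_artefacts(mk_obs(0, 50, 50, 0), pair)
  expect_false(res$flagged)
  expect_equal(res$fraction, 0)
  # 95/100 co-carrying, partner absent from reads lacking the first allele
  res <- flag_linked_artefacts(mk_obs(95, 5, 0, 20), pair)
  expect_true(res$flagged)
  expect_equal(res$fraction, 0.95)
  # partner present on reads lacking the first allele defeats the flag
  res <- flag_linked_artefacts(mk_obs(95, 0, 5, 20), pair)
  expect_false(res$flagged)
  # no co-covering reads: untestable
  obs <- data.frame(read_id = c("a", "b"), pos = c(100L, 120L),
                    allele = c("T", "A"))
  res <- flag_linked_artefacts(obs, pair)
  expect_false(res$testable)
  expect_false(res$flagged)
})
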