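# Differentiation statistics: heterozygosity estimators, the G-statistics
# hierarchy, pairwise matrices and iteration aggregation.

two_pop_dataset <- function(calls1, calls2, species = "sp") {
  calls <- rbind(calls1, calls2)
  n1 <- nrow(calls1); n2 <- nrow(calls2)
  genotype_dataset(
    species, calls,
    data.frame(individual_id = paste0("i", seq_len(n1 + n2)),
               site_id = rep(c("P1", "P2"), c(n1, n2))),
    data.frame(locus_id = paste0("L", seq_len(ncol(calls)), "_1"),
               chrom = paste0("L", seq_len(ncol(calls))), pos = 1L))
}

test_that("monomorphic populations have zero gene diversity", {
  ds <- two_pop_dataset(matrix(0L, 4, 3), matrix(0L, 5, 3))
  hs <- het_stats(ds)
  expect_equal(hs$Hs, rep(0, 3))
  expect_equal(hs$Ht, rep(0, 3))
})

test_that("harmonic mean sample size follows the textbook formula", {
  ds <- two_pop_dataset(matrix(rep(c(0L, 1L), length.out = 5), 5, 1),
                        matrix(rep(c(1L, 2L), 5), 10, 1))
  hs <- het_stats(ds)
  expect_equal(hs$n_harm, 2 / (1 / 5 + 1 / 10))  # = 6.666...
  expect_equal(hs$n_harm, 20 / 3)
})

test_that("a worked two-population locus matches hand-computed estimators", {
  # P1: genotypes 0,1,1,2 -> n=4, p_alt = 4/8 = 0.5
  # P2: genotypes 0,0,1   -> n=3, p_alt = 1/6
  ds <- two_pop_dataset(matrix(c(0L, 1L, 1L, 2L), 4, 1),
                        matrix(c(0L, 0L, 1L), 3, 1))
  hs <- het_stats(ds)
  n_tilde <- 2 / (1 / 4 + 1 / 3)
  hs_raw <- mean(c(2 * .5 * .5, 2 * (1 / 6) * (5 / 6)))
  p_bar <- mean(c(.5, 1 / 6))
  ht_raw <- 2 * p_bar * (1 - p_bar)
  expect_equal(hs$n_harm, n_tilde)
  expect_equal(hs$Hs, hs_raw * 2 * n_tilde / (2 * n_tilde - 1))
  expect_equal(hs$Ht, ht_raw + hs$Hs / (2 * n_tilde * 2))
})

test_that("identical allele frequencies give near-zero differentiation", {
  set.seed(1)
  p <- runif(50, .2, .8)
  big <- function() matrix(rbinom(200 * 50, 2, rep(p, each = 200)), 200)
  ds <- two_pop_dataset(big(), big())
  st <- gst_statistics(het_stats(ds))
  expect_lt(abs(st$Gst), 0.01)
  expect_lt(abs(st$Gst_dprime), 0.02)
})

test_that("fixed alternate alleles give complete differentiation", {
  ds <- two_pop_dataset(matrix(0L, 5, 4), matrix(2L, 5, 4))
  st <- gst_statistics(het_stats(ds))
  expect_equal(st$Gst, 1)
  expect_equal(st$Gst_dprime, 1)
})

test_that("all-monomorphic data is flagged undefined, not silently zero", {
  ds <- two_pop_dataset(matrix(0L, 4, 3), matrix(0L, 4, 3))
  st <- gst_statistics(het_stats(ds))
  expect_false(st$defined)
  expect_true(is.na(st$Gst_dprime))
})

test_that("statistics match the independent symbol-by-symbol oracle", {
  set.seed(99)
  for (rep in 1:30) {
    n_pops <- sample(2:4, 1)
    nps <- sample(3:8, n_pops, replace = TRUE)
    n_loci <- sample(5:15, 1)
    pops <- rep(paste0("P", seq_len(n_pops)), nps)
    calls <- matrix(rbinom(sum(nps) * n_loci, 2,
                           rep(runif(n_loci, .1, .9), each = sum(nps))),
                    sum(nps))
    calls[matrix(runif(length(calls)) < 0.05, nrow(calls))] <- NA_integer_
    ds <- genotype_dataset(
      "sp", calls,
      data.frame(individual_id = paste0("i", seq_len(sum(nps))),
                 site_id = pops),
      data.frame(locus_id = paste0("L", seq_len(n_loci), "_1"),
                 chrom = paste0("L", seq_len(n_loci)), pos = 1L))
    st <- gst_statistics(het_stats(ds))
    or <- oracle_gst(calls, pops)
    expect_equal(st$Hs, or$Hs, tolerance = 1e-12)
    expect_equal(st$Ht, or$Ht, tolerance = 1e-12)
    expect_equal(st$Gst, or$Gst, tolerance = 1e-12)
    expect_equal(st$Gst_prime, or$Gst_prime, tolerance = 1e-12)
    expect_equal(st$Gst_dprime, or$Gst_dprime, tolerance = 1e-12)
  }
})

test_that("fewer than two populations is an error", {
  ds <- random_dataset(n_sites = 1, seed = 5)
  expect_error(het_stats(ds), "2 populations")
})

test_that("statistics are invariant to population relabeling and locus order", {
  ds <- random_dataset(n_per_site = 5, n_loci = 12, seed = 13)
  st <- gst_statistics(het_stats(ds))
  # permute loci
  perm <- sample(ncol(ds$calls))
  ds2 <- genotype_dataset(ds$species_id, ds$calls[, perm],
                          ds$individuals, ds$loci[perm, ])
  st2 <- gst_statistics(het_stats(ds2))
  expect_equal(st$Gst_dprime, st2$Gst_dprime)
  # relabel populations
  relab <- c(S1 = "Z9", S2 = "A0", S3 = "M5", S4 = "Q2")
  st3 <- gst_statistics(het_stats(ds, relab[ds$individuals$site_id]))
  expect_equal(st$Gst_dprime, st3$Gst_dprime)
})

test_that("a duplicated site compares to itself at ~zero; k=2 consistency", {
  set.seed(4)
  base <- random_dataset(n_per_site = 40, n_loci = 60, n_sites = 1, seed = 4)
  calls <- rbind(base$calls, base$calls)
  ds <- genotype_dataset(
    "sp", calls,
    data.frame(individual_id = paste0("i", seq_len(nrow(calls))),
               site_id = rep(c("A", "B"), each = nrow(base$calls))),
    base$loci)
  m <- pairwise_gst(ds)
  # identical allele frequencies: only the finite-sample estimator bias
  # (order 1/n) remains, and it shrinks toward zero as n grows
  expect_lt(abs(m["A", "B"]), 0.05)
  base2 <- random_dataset(n_per_site = 200, n_loci = 60, n_sites = 1,
                          seed = 4)
  calls2 <- rbind(base2$calls, base2$calls)
  ds2big <- genotype_dataset(
    "sp", calls2,
    data.frame(individual_id = paste0("i", seq_len(nrow(calls2))),
               site_id = rep(c("A", "B"), each = nrow(base2$calls))),
    base2$loci)
  expect_lt(abs(pairwise_gst(ds2big)["A", "B"]), abs(m["A", "B"]))
  # two-site dataset: pairwise value equals the overall statistic
  ds2 <- random_dataset(n_per_site = 6, n_loci = 30, n_sites = 2, seed = 9)
  m2 <- pairwise_gst(ds2)
  expect_equal(m2["S1", "S2"],
               gst_statistics(het_stats(ds2))$Gst_dprime)
})

test_that("all pairwise entries match the oracle on a 4-site fixture", {
  ds <- random_dataset(n_per_site = 5, n_loci = 25, seed = 17)
  m <- pairwise_gst(ds)
  ids <- rownames(m)
  for (i in 1:3) for (j in (i + 1):4) {
    sel <- ds$individuals$site_id %in% c(ids[i], ids[j])
    or <- oracle_gst(ds$calls[sel, ], ds$individuals$site_id[sel])
    expect_equal(m[i, j], or$Gst_dprime, tolerance = 1e-12)
  }
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
})

test_that("negative estimates from panmictic samples survive unclamped", {
  set.seed(31)
  seen_negative <- FALSE
  for (s in 1:10) {
    p <- runif(40, .2, .8)
    calls <- matrix(rbinom(20 * 40, 2, rep(p, each = 20)), 20)
    ds <- genotype_dataset(
      "sp", calls,
      data.frame(individual_id = paste0("i", 1:20),
                 site_id = rep(c("A", "B"), each = 10)),
      data.frame(locus_id = paste0("L", 1:40, "_1"),
                 chrom = paste0("L", 1:40), pos = 1L))
    st <- gst_statistics(het_stats(ds))
    if (st$Gst_dprime < 0) seen_negative <- TRUE
  }
  expect_true(seen_negative)
})

test_that("expected differentiation falls as exchange between demes rises", {
  # two demes whose allele frequencies are mixtures p_i' = (1-m) p_i + m p_bar:
  # stronger mixing -> lower expected G''ST
  set.seed(77)
  gd_at <- function(m) {
    p1 <- runif(300, .1, .9); p2 <- runif(300, .1, .9)
    pb <- (p1 + p2) / 2
    q1 <- (1 - m) * p1 + m * pb; q2 <- (1 - m) * p2 + m * pb
    calls <- rbind(
      matrix(rbinom(15 * 300, 2, rep(q1, each = 15)), 15),
      matrix(rbinom(15 * 300, 2, rep(q2, each = 15)), 15))
    ds <- genotype_dataset(
      "sp", calls,
      data.frame(individual_id = paste0("i", 1:30),
                 site_id = rep(c("A", "B"), each = 15)),
      data.frame(locus_id = paste0("L", 1:300, "_1"),
                 chrom = paste0("L", 1:300), pos = 1L))
    gst_statistics(het_stats(ds))$Gst_dprime
  }
  expect_gt(gd_at(0.1), gd_at(0.9))
})

test_that("aggregation across iterations is the cellwise mean and sd", {
  m1 <- pairwise_matrix(matrix(c(0, .01, .01, 0), 2), c("A", "B"), "Gst_dprime")
  m3 <- pairwise_matrix(matrix(c(0, .03, .03, 0), 2), c("A", "B"), "Gst_dprime")
  agg <- aggregate_iterations(list(m1, m3))
  expect_equal(agg["A", "B"], 0.02)
  expect_equal(attr(agg, "sd")[1, 2], sd(c(.01, .03)))
  expect_equal(attr(agg, "n_iter"), 2L)
  same <- aggregate_iterations(rep(list(m1), 999))
  expect_equal(unclass(same)[1, 2], 0.01)
  expect_equal(attr(same, "sd")[1, 2], 0)
  m_bad <- pairwise_matrix(matrix(0, 2, 2), c("A", "C"), "Gst_dprime")
  expect_error(aggregate_iterations(list(m1, m_bad)), "mismatched site")
})

test_that("resampling means vary little between iterations", {
  ds <- random_dataset(n_per_site = 12, n_loci = 80, seed = 55)
  cfg <- resample_config(n_iter = 30, target_loci = 60,
                         max_ind_per_site = 10, seed = 2)
  mats <- resample_iterations(ds, cfg, pairwise_gst)
  agg <- aggregate_iterations(mats)
  ut <- upper.tri(agg)
  # iteration noise is small relative to the spread across site pairs
  expect_lt(median(attr(agg, "sd")[ut]), diff(range(unclass(agg)[ut])))
})

test_that("pairwise long-form CSV round-trips values", {
  m <- pairwise_matrix(matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3),
                       c("A", "B", "C"), "beta_jac")
  path <- tempfile(fileext = ".csv")
  write_pairwise_csv(m, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$value[back$site_i == "B" & back$site_j == "C"], 0.3)
})
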