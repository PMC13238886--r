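# Genotype input, filtering and the resampling harness.

write_fixture_vcf <- function(path, samples, records) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
}

test_that("VCF genotypes decode to hand-read dosages", {
  sites <- four_sites()
  vcf <- tempfile(fileext = ".vcf")
  write_fixture_vcf(vcf, c("a1", "a2", "a3"), c(
    "tag1\t12\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t./.",
    "tag1\t48\t.\tC\tT\t.\tPASS\t.\tGT\t1|1\t0/0\t.",
    "tag2\t5\t.\tG\tA,T\t.\tPASS\t.\tGT\t1/2\t0/0\t0/1"))
  map <- data.frame(individual_id = c("a1", "a2", "a3"),
                    site_id = c("S1", "S1", "S2"))
  expect_message(ds <- read_genotypes(vcf, sites, map), "multiallelic")
  # multiallelic tag2 record dropped; GT decoded by hand:
  expect_equal(nrow(ds$loci), 2L)
  expect_identical(unname(ds$calls),
                   matrix(c(0L, 2L, 1L, 0L, NA, NA), nrow = 3, byrow = TRUE))
  expect_equal(ds$individuals$site_id, c("S1", "S1", "S2"))
  expect_equal(ds$loci$pos, c(12L, 48L))
})

test_that("empty VCF body yields a 0-locus dataset with a warning", {
  sites <- four_sites()
  vcf <- tempfile(fileext = ".vcf")
  write_fixture_vcf(vcf, c("a1", "a2", "a3"), character(0))
  map <- data.frame(individual_id = c("a1", "a2", "a3"),
                    site_id = c("S1", "S2", "S3"))
  expect_warning(ds <- read_genotypes(vcf, sites, map), "no variant")
  expect_equal(nrow(ds$individuals), 3L)
  expect_equal(nrow(ds$loci), 0L)
})

test_that("unmapped VCF sample errors with the sample name", {
  sites <- four_sites()
  vcf <- tempfile(fileext = ".vcf")
  write_fixture_vcf(vcf, c("a1", "X9"),
                    "tag1\t12\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1")
  map <- data.frame(individual_id = "a1", site_id = "S1")
  expect_error(read_genotypes(vcf, sites, map), "X9")
})

test_that("individual and SNP missingness filters apply in order", {
  # 4 individuals x 10 loci; i4 has 60% missing -> removed (0.60 > 0.50)
  calls <- matrix(0L, 4, 10)
  calls[4, 1:6] <- NA_integer_
  ds <- genotype_dataset(
    "sp", calls,
    data.frame(individual_id = paste0("i", 1:4),
               site_id = c("S1", "S1", "S2", "S2")),
    data.frame(locus_id = paste0("t", 1:10, "_1"),
               chrom = paste0("t", 1:10), pos = 1L))
  out <- filter_genotypes(ds)
  expect_equal(nrow(out$individuals), 3L)
  expect_false("i4" %in% out$individuals$individual_id)
  rep_ <- attr(out, "filter_report")
  expect_equal(unname(rep_$individuals["removed"] +
                        rep_$individuals["retained"]),
               unname(rep_$individuals["original"]))
})

test_that("only the lowest-position SNP per locus tag survives", {
  calls <- matrix(c(0L, 1L, 2L), 3, 3)
  ds <- genotype_dataset(
    "sp", calls,
    data.frame(individual_id = paste0("i", 1:3), site_id = "S1"),
    data.frame(locus_id = c("t1_48", "t1_12", "t2_5"),
               chrom = c("t1", "t1", "t2"), pos = c(48L, 12L, 5L)))
  out <- filter_genotypes(ds, filter_config(max_snp_missing_per_site = 1,
                                            max_snp_missing_overall = 1))
  expect_setequal(out$loci$locus_id, c("t1_12", "t2_5"))
  expect_equal(out$loci$pos[out$loci$chrom == "t1"], 12L)
})

test_that("surviving counts match a brute-force recount of the three rules", {
  ds <- random_dataset(n_per_site = 6, n_loci = 40, miss = 0.12, seed = 42)
  cfg <- filter_config(max_ind_missing = 0.15,
                       max_snp_missing_per_site = 0.25,
                       max_snp_missing_overall = 0.10,
                       first_snp_per_locus = FALSE)
  out <- filter_genotypes(ds, cfg)

  # brute force, same declared order, denominators recomputed per step
  calls <- ds$calls
  keep_i <- rowMeans(is.na(calls)) <= cfg$max_ind_missing
  calls <- calls[keep_i, , drop = FALSE]
  site <- ds$individuals$site_id[keep_i]
  keep_l <- rep(TRUE, ncol(calls))
  for (l in seq_len(ncol(calls))) {
    for (s in unique(site)) {
      if (mean(is.na(calls[site == s, l])) > cfg$max_snp_missing_per_site)
        keep_l[l] <- FALSE
    }
  }
  calls <- calls[, keep_l, drop = FALSE]
  keep_l2 <- colMeans(is.na(calls)) <= cfg$max_snp_missing_overall

  expect_equal(nrow(out$individuals), sum(keep_i))
  expect_equal(ncol(out$calls), sum(keep_l2))
})

test_that("filtering is idempotent", {
  ds <- random_dataset(n_per_site = 6, n_loci = 40, miss = 0.1, seed = 7)
  f1 <- filter_genotypes(ds)
  f2 <- filter_genotypes(f1)
  expect_identical(f1$calls, f2$calls)
  expect_identical(f1$individuals, f2$individuals)
})

test_that("all-individuals-removed is an explicit error", {
  calls <- matrix(NA_integer_, 2, 4)
  ds <- genotype_dataset(
    "sp", calls,
    data.frame(individual_id = c("i1", "i2"), site_id = "S1"),
    data.frame(locus_id = paste0("t", 1:4), chrom = paste0("t", 1:4),
               pos = 1L))
  expect_error(filter_genotypes(ds), "empty after filtering")
})

test_that("species eligibility requires min individuals at every site", {
  sites <- four_sites()
  mk <- function(counts) {
    n <- sum(counts)
    genotype_dataset(
      "sp", matrix(0L, n, 2),
      data.frame(individual_id = paste0("i", seq_len(n)),
                 site_id = rep(sites$site_id, counts)),
      data.frame(locus_id = c("a_1", "b_1"), chrom = c("a", "b"), pos = 1L))
  }
  expect_true(check_species_eligibility(mk(c(10, 10, 10, 10)), sites))
  bad <- check_species_eligibility(mk(c(10, 10, 2, 10)), sites)
  expect_false(as.logical(bad))
  expect_equal(attr(bad, "report")$failing_sites, "S3")
  # a designed panel of 5 species of which exactly 2 fail
  panel <- list(mk(c(5, 5, 5, 5)), mk(c(3, 3, 3, 3)), mk(c(2, 5, 5, 5)),
                mk(c(4, 4, 4, 4)), mk(c(5, 5, 5, 0)))
  ok <- vapply(panel, function(d)
    isTRUE(check_species_eligibility(d, sites)), logical(1))
  expect_equal(sum(ok), 3L)
})

test_that("resampling caps individuals per site and is seed-deterministic", {
  ds <- random_dataset(n_per_site = 12, n_loci = 30, seed = 3)
  cfg <- resample_config(n_iter = 5, target_loci = 20,
                         max_ind_per_site = 10, seed = 11)
  reps <- resample_iterations(ds, cfg)
  for (r in reps) {
    expect_equal(as.integer(table(r$individuals$site_id)), rep(10L, 4))
    expect_equal(ncol(r$calls), 20L)
    # no fabricated data: every retained call exists in the parent
    expect_true(all(r$individuals$individual_id %in%
                      ds$individuals$individual_id))
    expect_identical(r$calls,
                     ds$calls[r$individuals$individual_id,
                              r$loci$locus_id])
  }
  reps2 <- resample_iterations(ds, cfg)
  expect_identical(lapply(reps, `[[`, "calls"),
                   lapply(reps2, `[[`, "calls"))
  # iteration index recoverable and streams differ across iterations
  expect_equal(attr(resample_once(ds, cfg, 3), "iteration"), 3L)
  expect_false(identical(reps[[1]]$calls, reps[[2]]$calls))
})

test_that("each individual is retained at the uniform-subsampling rate", {
  ds <- random_dataset(n_per_site = 12, n_loci = 5, n_sites = 1, seed = 8)
  cfg <- resample_config(n_iter = 999, target_loci = 5,
                         max_ind_per_site = 10, seed = 21)
  counts <- integer(12); names(counts) <- ds$individuals$individual_id
  for (i in seq_len(cfg$n_iter)) {
    r <- resample_once(ds, cfg, i)
    counts[r$individuals$individual_id] <-
      counts[r$individuals$individual_id] + 1L
  }
  # binomial 99% band around 10/12
  band <- qbinom(c(0.005, 0.995), 999, 10 / 12)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("too few loci for the resampling target is an instructive error", {
  ds <- random_dataset(n_loci = 10, seed = 2)
  cfg <- resample_config(n_iter = 1, target_loci = 50)
  expect_error(resample_once(ds, cfg), "lower target_loci")
})
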