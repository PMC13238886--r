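#' Construct a genotype dataset
#'
#' Container for one species' diploid biallelic SNP genotypes: an
#' individuals x loci matrix of alt-allele dosages (0/1/2, `NA` = missing),
#' individual-to-site assignments, and per-locus metadata (RAD locus tag and
#' SNP position). Phasing is ignored.
#'
#' @param species_id character scalar.
#' @param calls integer matrix, individuals x loci, values in `{0,1,2,NA}`.
#' @param individuals data.frame with columns `individual_id`, `site_id`.
#' @param loci data.frame with columns `locus_id`, `chrom`, `pos`
#'   (`chrom` is the RAD locus tag; `pos` the SNP position within it).
#' @param site_table optional `site_table` to validate site assignments against.
#' @return object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(species_id, calls, individuals, loci,
                             site_table = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(individuals))
    stop("calls has ", nrow(calls), " rows but ", nrow(individuals),
         " individuals")
  if (ncol(calls) != nrow(loci))
    stop("calls has ", ncol(calls), " columns but ", nrow(loci), " loci")
  bad <- calls[!is.na(calls)]
  if (length(bad) && any(bad < 0L | bad > 2L))
    stop("calls must be diploid dosages in {0,1,2,NA}")
  individuals <- as.data.frame(individuals)
  individuals$individual_id <- as.character(individuals$individual_id)
  individuals$site_id <- as.character(individuals$site_id)
  if (!is.null(site_table)) {
    unknown <- setdiff(individuals$site_id, site_table$site_id)
    if (length(unknown))
      stop("individuals assigned to unknown site(s): ",
           paste(unknown, collapse = ", "))
  }
  rownames(calls) <- individuals$individual_id
  loci <- as.data.frame(loci)
  if (nrow(loci)) colnames(calls) <- loci$locus_id
  structure(
    list(species_id = as.character(species_id), calls = calls,
         individuals = individuals, loci = loci),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  miss <- if (length(x$calls)) mean(is.na(x$calls)) else 0
  cat("Genotype dataset '", x$species_id, "': ",
      nrow(x$individuals), " individuals (",
      length(unique(x$individuals$site_id)), " sites) x ",
      nrow(x$loci), " loci; ",
      sprintf("%.1f%%", 100 * miss), " missing\n", sep = "")
  invisible(x)
}

#' Read diploid biallelic genotypes from a VCF file
#'
#' Decodes GT fields to alt-allele dosages 0/1/2 (`./.`, `.` and half-missing
#' calls become `NA`); phasing is ignored. Multiallelic records are dropped
#' with a message reporting the count. Every sample name in the VCF must map
#' to a site in `sites`, either because the sample name *is* a site-annotated
#' individual in `sample_sites`, or via a `sample_sites` lookup.
#'
#' @param vcf_path path to a VCF v4.x file (plain or gzipped).
#' @param sites `site_table`.
#' @param sample_sites data.frame mapping `individual_id` to `site_id`.
#' @param species_id species label stored in the dataset; defaults to the
#'   file name without extension.
#' @return `genotype_dataset`.
#' @export
read_genotypes <- function(vcf_path, sites, sample_sites,
                           species_id = sub("\\.vcf(\\.gz)?$", "",
                                            basename(vcf_path))) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  sample_sites <- as.data.frame(sample_sites)
  sample_sites$individual_id <- as.character(sample_sites$individual_id)
  sample_sites$site_id <- as.character(sample_sites$site_id)
  idx <- match(samples, sample_sites$individual_id)
  if (anyNA(idx))
    stop("VCF sample(s) absent from the site assignment table: ",
         paste(samples[is.na(idx)], collapse = ", "))
  individuals <- data.frame(individual_id = samples,
                            site_id = sample_sites$site_id[idx],
                            stringsAsFactors = FALSE)

  if (nrow(vcf@fix) == 0L) {
    warning("VCF '", basename(vcf_path), "' contains no variant records")
    return(genotype_dataset(
      species_id,
      matrix(integer(0), nrow = length(samples), ncol = 0),
      individuals,
      data.frame(locus_id = character(0), chrom = character(0),
                 pos = integer(0)),
      sites))
  }

  biall <- vcfR::is.biallelic(vcf)
  n_multi <- sum(!biall)
  if (n_multi > 0) {
    message("read_genotypes: dropped ", n_multi, " multiallelic record(s)")
    vcf <- vcf[biall, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count alt alleles; any '.' in the call -> missing
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  half <- nchar(gt) < 3 & !is.na(gt)   # haploid-style or bare '.' entries
  dos <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dos[half] <- NA_integer_
  calls <- t(matrix(dos, nrow = nrow(gt), ncol = ncol(gt),
                    dimnames = dimnames(gt)))
  chrom <- vcf@fix[, "CHROM"]
  pos <- as.integer(vcf@fix[, "POS"])
  loci <- data.frame(locus_id = paste0(chrom, "_", pos),
                     chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  genotype_dataset(species_id, calls, individuals, loci, sites)
}

#' Genotype filtering configuration
#'
#' Defaults mirror a standard ddRAD post-genotyping filter set: individuals
#' with more than 50% missing calls are excluded, then SNPs with more than
#' 20% missing data within any sampling site or more than 5% missing data
#' overall, then a single SNP (the first, i.e. lowest position) is retained
#' per RAD locus. Species eligibility requires at least 3 individuals per
#' site.
#'
#' @param max_ind_missing maximum tolerated missing-call fraction per
#'   individual (default 0.50).
#' @param max_snp_missing_per_site maximum missing fraction per SNP within
#'   each site (default 0.20).
#' @param max_snp_missing_overall maximum missing fraction per SNP across all
#'   individuals (default 0.05).
#' @param first_snp_per_locus keep only the lowest-position SNP of each RAD
#'   locus tag (default TRUE).
#' @param min_ind_per_site minimum individuals per site for a species to be
#'   eligible (default 3).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(max_ind_missing = 0.50,
                          max_snp_missing_per_site = 0.20,
                          max_snp_missing_overall = 0.05,
                          first_snp_per_locus = TRUE,
                          min_ind_per_site = 3L) {
  fr <- c(max_ind_missing, max_snp_missing_per_site, max_snp_missing_overall)
  if (any(fr < 0 | fr > 1)) stop("missingness fractions must lie in [0, 1]")
  structure(list(max_ind_missing = max_ind_missing,
                 max_snp_missing_per_site = max_snp_missing_per_site,
                 max_snp_missing_overall = max_snp_missing_overall,
                 first_snp_per_locus = isTRUE(first_snp_per_locus),
                 min_ind_per_site = as.integer(min_ind_per_site)),
            class = "filter_config")
}

#' Apply genotype quality filters
#'
#' Filter order is fixed and denominators are recomputed after each step:
#' (1) drop individuals whose missing fraction exceeds `max_ind_missing`;
#' (2) drop SNPs whose missing fraction within any site (among remaining
#' individuals) exceeds `max_snp_missing_per_site`; (3) drop SNPs whose
#' overall missing fraction exceeds `max_snp_missing_overall`; (4) keep only
#' the lowest-position SNP per locus tag (ties broken by record order).
#'
#' @param ds `genotype_dataset`.
#' @param cfg `filter_config`.
#' @return filtered `genotype_dataset` with a `filter_report` attribute
#'   listing removed counts per step.
#' @export
filter_genotypes <- function(ds, cfg = filter_config()) {
  stopifnot(inherits(ds, "genotype_dataset"))
  calls <- ds$calls
  n0_ind <- nrow(calls); n0_loc <- ncol(calls)

  # 1. individuals
  ind_miss <- if (n0_loc) rowMeans(is.na(calls)) else rep(0, n0_ind)
  keep_ind <- ind_miss <= cfg$max_ind_missing
  if (!any(keep_ind)) stop("empty after filtering: all individuals removed")
  calls <- calls[keep_ind, , drop = FALSE]
  individuals <- ds$individuals[keep_ind, , drop = FALSE]

  # 2. per-site SNP missingness (denominators after individual removal)
  site_f <- factor(individuals$site_id)
  if (n0_loc) {
    per_site_miss <- vapply(levels(site_f), function(s) {
      sub <- calls[site_f == s, , drop = FALSE]
      colMeans(is.na(sub))
    }, numeric(ncol(calls)))
    per_site_miss <- matrix(per_site_miss, ncol = length(levels(site_f)))
    keep_site <- apply(per_site_miss <= cfg$max_snp_missing_per_site, 1, all)
  } else keep_site <- logical(0)
  n_rm_site <- sum(!keep_site)
  calls <- calls[, keep_site, drop = FALSE]
  loci <- ds$loci[keep_site, , drop = FALSE]

  # 3. overall SNP missingness
  keep_all <- colMeans(is.na(calls)) <= cfg$max_snp_missing_overall
  n_rm_overall <- sum(!keep_all)
  calls <- calls[, keep_all, drop = FALSE]
  loci <- loci[keep_all, , drop = FALSE]

  # 4. first SNP per locus tag (lowest position; ties by record order)
  n_rm_first <- 0L
  if (cfg$first_snp_per_locus && nrow(loci)) {
    ord <- order(factor(loci$chrom, levels = unique(loci$chrom)), loci$pos)
    first_idx <- ord[!duplicated(loci$chrom[ord])]
    first_idx <- sort(first_idx)
    n_rm_first <- nrow(loci) - length(first_idx)
    calls <- calls[, first_idx, drop = FALSE]
    loci <- loci[first_idx, , drop = FALSE]
  }

  out <- genotype_dataset(ds$species_id, calls, individuals, loci)
  attr(out, "filter_report") <- list(
    individuals = c(original = n0_ind, removed = sum(!keep_ind),
                    retained = nrow(individuals)),
    snps = c(original = n0_loc, removed_per_site = n_rm_site,
             removed_overall = n_rm_overall,
             removed_first_snp = n_rm_first, retained = ncol(calls)))
  out
}

#' Check species eligibility for pairwise analyses
#'
#' A species is eligible when every site in `sites` (optionally restricted to
#' one basin) retains at least `min_ind_per_site` genotyped individuals after
#' filtering.
#'
#' @param ds filtered `genotype_dataset`.
#' @param sites `site_table` (already restricted to the basin of interest).
#' @param cfg `filter_config`.
#' @return logical scalar with attribute `report`: per-site counts and the
#'   names of failing sites.
#' @export
check_species_eligibility <- function(ds, sites, cfg = filter_config()) {
  counts <- table(factor(ds$individuals$site_id, levels = sites$site_id))
  failing <- names(counts)[counts < cfg$min_ind_per_site]
  ok <- length(failing) == 0L
  structure(ok, report = list(site_counts = counts, failing_sites = failing,
                              min_ind_per_site = cfg$min_ind_per_site))
}

#' Resampling configuration for loci/individual subsampling
#'
#' @param n_iter number of subsampling iterations (default 999).
#' @param target_loci number of loci drawn (without replacement) each
#'   iteration; set to the minimum locus count across the species compared.
#' @param max_ind_per_site per-site cap on individuals drawn each iteration
#'   (default 10).
#' @param seed master seed; iteration `i` runs on an independently derived
#'   stream seed so any single iteration is reproducible in isolation.
#' @return list of class `resample_config`.
#' @export
resample_config <- function(n_iter = 999L, target_loci, max_ind_per_site = 10L,
                            seed = 1L) {
  n_iter <- as.integer(n_iter)
  target_loci <- as.integer(target_loci)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (target_loci < 1L) stop("target_loci must be >= 1")
  structure(list(n_iter = n_iter, target_loci = target_loci,
                 max_ind_per_site = as.integer(max_ind_per_site),
                 seed = as.integer(seed)),
            class = "resample_config")
}

# Stream seed for iteration i derived from the master seed; kept within
# 32-bit integer range.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 16807) %% 2147483647)
}

#' Draw one subsampled replicate of a genotype dataset
#'
#' Draws `target_loci` loci uniformly without replacement and, within each
#' site, `min(max_ind_per_site, n_site)` individuals without replacement.
#'
#' @param ds `genotype_dataset`.
#' @param cfg `resample_config`.
#' @param iter iteration index (1-based); determines the stream seed.
#' @return subsampled `genotype_dataset` with attribute `iteration`.
#' @export
resample_once <- function(ds, cfg, iter = 1L) {
  if (ncol(ds$calls) < cfg$target_loci)
    stop("dataset has ", ncol(ds$calls), " loci but target_loci = ",
         cfg$target_loci, "; lower target_loci")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, iter))
  loc_idx <- sort(sample.int(ncol(ds$calls), cfg$target_loci))
  site_f <- factor(ds$individuals$site_id)
  ind_idx <- sort(unlist(lapply(split(seq_len(nrow(ds$calls)), site_f),
                                function(ix) {
    if (length(ix) <= cfg$max_ind_per_site) ix
    else sample(ix, cfg$max_ind_per_site)
  }), use.names = FALSE))
  out <- genotype_dataset(ds$species_id,
                          ds$calls[ind_idx, loc_idx, drop = FALSE],
                          ds$individuals[ind_idx, , drop = FALSE],
                          ds$loci[loc_idx, , drop = FALSE])
  attr(out, "iteration") <- as.integer(iter)
  out
}

#' Iterate a metric over subsampled replicates
#'
#' Runs `fun` on each of `cfg$n_iter` subsampled replicates of `ds` and
#' returns the list of results. This is the harness behind
#' "subsampling and all derived metric calculations repeated iteratively".
#'
#' @param ds `genotype_dataset`.
#' @param cfg `resample_config`.
#' @param fun function taking a `genotype_dataset` (one replicate).
#' @return list of length `n_iter` of `fun` results.
#' @export
resample_iterations <- function(ds, cfg, fun = identity) {
  lapply(seq_len(cfg$n_iter), function(i) fun(resample_once(ds, cfg, i)))
}

# Save/restore the global RNG state so seeded internals do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
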