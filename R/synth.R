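#' Configuration for the synthetic two-basin generator
#'
#' Defaults emulate a two-basin comparative design: a compact basin
#' ("compact", Caribbean-like: 4 sites roughly 650 km apart, genetic
#' decay range far beyond the inter-site spacing so gene flow is effectively
#' unconstrained by distance) and a spread basin ("spread", Western Indian
#' Ocean-like: 4 sites roughly 1300 km apart with a genetic decay range
#' comparable to the spacing, producing isolation by distance). Communities
#' in both basins have distance-decaying composition.
#'
#' Genetic model, per locus: ancestral frequency \eqn{p_0 \sim U(0.1,0.9)};
#' site logit-frequencies get a Gaussian field with covariance
#' \eqn{\sigma^2 e^{-d_{ij}/\kappa}} plus independent site noise
#' \eqn{\tau^2} (the baseline differentiation floor); genotypes are
#' \eqn{Binomial(2, p_{site})}; calls go missing independently at rate
#' `miss_call`.
#'
#' Community model, per species: a range centre at one site, occupancy
#' probability \eqn{p_{max} e^{-d(centre, site)/\lambda}} (always present at
#' the centre), independent Bernoulli occupancy; per-site occupancy
#' multipliers create a richness gradient and hence nestedness.
#'
#' @param basins named list of per-basin settings; each needs `n_sites`,
#'   `center` (lon, lat), `spacing_km`, `kappa_km` (genetic decay range),
#'   `lambda_km` (community decay range), `n_species` (genotyped),
#'   `families` (character), `species_per_family` (community richness per
#'   family).
#' @param loci_per_species SNP loci per genotyped species (default 3000).
#' @param ind_per_site genotyped individuals per site (default 12).
#' @param sigma logit-scale field standard deviation (default 0.35).
#' @param tau logit-scale independent site noise sd (default 0.15).
#' @param miss_call per-call missingness rate (default 0.02).
#' @param occupancy_max occupancy probability at the range centre
#'   (default 0.95).
#' @param richness_gradient multiplicative occupancy drop from the first to
#'   the last site within a basin (default 0.35), inducing nestedness.
#' @param grid_res grid resolution in degrees for the synthetic seascape
#'   (default 0.5).
#' @param land_fraction fraction of grid cells turned into island land
#'   (default 0.05).
#' @param seed master seed (default 1).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(
    basins = list(
      compact = list(n_sites = 4, center = c(-70, 14), spacing_km = 650,
                     kappa_km = 1e6, lambda_km = 700, n_species = 7,
                     families = c("FamA", "FamB", "FamC"),
                     species_per_family = 25),
      spread = list(n_sites = 4, center = c(55, -8), spacing_km = 1300,
                    kappa_km = 1500, lambda_km = 1400, n_species = 12,
                    families = c("FamA", "FamB", "FamC"),
                    species_per_family = 25)),
    loci_per_species = 3000, ind_per_site = 12, sigma = 0.35, tau = 0.15,
    miss_call = 0.02, occupancy_max = 0.95, richness_gradient = 0.35,
    grid_res = 0.5, land_fraction = 0.05, seed = 1L) {
  for (b in basins) {
    if (b$n_sites < 2) stop("each basin needs at least 2 sites")
    if (b$kappa_km <= 0 || b$lambda_km <= 0 || b$spacing_km <= 0)
      stop("decay ranges and spacing must be positive")
  }
  if (miss_call < 0 || miss_call >= 1) stop("miss_call must be in [0, 1)")
  structure(list(basins = basins, loci_per_species = loci_per_species,
                 ind_per_site = ind_per_site, sigma = sigma, tau = tau,
                 miss_call = miss_call, occupancy_max = occupancy_max,
                 richness_gradient = richness_gradient, grid_res = grid_res,
                 land_fraction = land_fraction, seed = as.integer(seed)),
            class = "synth_config")
}

# km -> degrees of longitude at a latitude
km_per_deg_lon <- function(lat) haversine_km(0, lat, 1, lat)

#' Simulate a two-basin seascape and site table
#'
#' Builds, per basin, a regular lon/lat grid around the basin centre with
#' procedurally placed island land cells, and places sites on sea cells
#' along an east-west arc at the configured spacing. Sites that would land
#' on a land cell are repositioned to the nearest sea cell (logged).
#'
#' @param cfg `synth_config`.
#' @return list: `sites` (`site_table` over both basins) and `grids`
#'   (named list of `seascape_grid` per basin).
#' @export
simulate_seascape <- function(cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 101L))
  grids <- list(); site_rows <- list()
  for (bn in names(cfg$basins)) {
    b <- cfg$basins[[bn]]
    lat0 <- b$center[2]
    span_km <- b$spacing_km * (b$n_sites - 1)
    span_deg <- span_km / km_per_deg_lon(lat0)
    margin <- max(3, span_deg * 0.15)
    lon <- seq(b$center[1] - span_deg / 2 - margin,
               b$center[1] + span_deg / 2 + margin, by = cfg$grid_res)
    lat <- seq(lat0 - 6, lat0 + 6, by = cfg$grid_res)
    mask <- matrix(TRUE, length(lat), length(lon))
    # sprinkle small square islands away from the site line
    n_land <- round(cfg$land_fraction * length(mask) / 4)
    if (n_land > 0) {
      ri <- sample(seq_along(lat), n_land, replace = TRUE)
      ci <- sample(seq_along(lon), n_land, replace = TRUE)
      for (k in seq_len(n_land)) {
        rs <- pmin(pmax(ri[k] + 0:1, 1), length(lat))
        cs <- pmin(pmax(ci[k] + 0:1, 1), length(lon))
        mask[rs, cs] <- FALSE
      }
    }
    site_lon <- b$center[1] +
      (seq_len(b$n_sites) - (b$n_sites + 1) / 2) * b$spacing_km /
      km_per_deg_lon(lat0)
    site_lat <- rep(lat0, b$n_sites) +
      stats::runif(b$n_sites, -1, 1)   # mild off-axis jitter
    # reposition any site sitting on land to the nearest sea cell
    for (s in seq_len(b$n_sites)) {
      r <- which.min(abs(lat - site_lat[s]))
      c_ <- which.min(abs(lon - site_lon[s]))
      if (!mask[r, c_]) {
        sea <- which(mask, arr.ind = TRUE)
        d <- (lat[sea[, 1]] - site_lat[s])^2 + (lon[sea[, 2]] - site_lon[s])^2
        j <- which.min(d)
        message("simulate_seascape: site ", bn, s, " repositioned off land")
        site_lat[s] <- lat[sea[j, 1]]; site_lon[s] <- lon[sea[j, 2]]
      } else { site_lat[s] <- lat[r]; site_lon[s] <- lon[c_] }
    }
    grids[[bn]] <- seascape_grid(lon, lat, mask)
    site_rows[[bn]] <- data.frame(
      site_id = paste0(toupper(substr(bn, 1, 1)), seq_len(b$n_sites)),
      name = paste0(bn, "_site", seq_len(b$n_sites)),
      lon = site_lon, lat = site_lat, basin = bn,
      stringsAsFactors = FALSE)
  }
  list(sites = site_table(do.call(rbind, site_rows)), grids = grids)
}

# MVN draw via Cholesky with a jitter fallback for near-singular covariances
rmvn <- function(n, Sigma) {
  ch <- tryCatch(chol(Sigma),
                 error = function(e) chol(Sigma + diag(1e-8, nrow(Sigma))))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% ch
}

#' Simulate SNP genotypes for one basin's species
#'
#' Per-locus allele frequencies follow a logit-scale Gaussian field over
#' sites with exponential distance decay (range `kappa_km`) plus independent
#' site noise; diploid genotypes are binomial draws; missingness is injected
#' at the configured per-call rate. Deterministic given the master seed:
#' species `k` of basin `b` uses a derived stream seed.
#'
#' @param cfg `synth_config`.
#' @param distances `pairwise_matrix` (km) over the basin's sites.
#' @param basin basin name in `cfg$basins`.
#' @return named list of `genotype_dataset`, one per genotyped species.
#' @export
simulate_genotypes <- function(cfg, distances, basin) {
  b <- cfg$basins[[basin]]
  if (is.null(b)) stop("unknown basin '", basin, "'")
  ids <- rownames(distances)
  d <- unclass(distances)[ids, ids]
  if (any(!is.finite(d))) stop("distances must be finite")
  k <- length(ids)
  Sigma <- cfg$sigma^2 * exp(-d / b$kappa_km) + diag(cfg$tau^2, k)
  fams <- rep(b$families, length.out = b$n_species)
  out <- list()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (sp in seq_len(b$n_species)) {
    set.seed(derive_seed(cfg$seed,
                         1000L + 100L * match(basin, names(cfg$basins)) + sp))
    L <- cfg$loci_per_species
    p0 <- stats::runif(L, 0.1, 0.9)
    g <- rmvn(L, Sigma)                       # loci x sites
    p_site <- stats::plogis(stats::qlogis(p0) + g)
    n_ind <- cfg$ind_per_site
    calls <- matrix(NA_integer_, k * n_ind, L)
    for (s in seq_len(k)) {
      rows <- (s - 1) * n_ind + seq_len(n_ind)
      calls[rows, ] <- matrix(
        stats::rbinom(n_ind * L, 2, rep(p_site[, s], each = n_ind)),
        n_ind, L)
    }
    if (cfg$miss_call > 0)
      calls[matrix(stats::runif(length(calls)) < cfg$miss_call,
                   nrow(calls))] <- NA_integer_
    sp_id <- sprintf("%s_sp%02d", basin, sp)
    individuals <- data.frame(
      individual_id = sprintf("%s_%s_i%02d", sp_id, rep(ids, each = n_ind),
                              rep(seq_len(n_ind), k)),
      site_id = rep(ids, each = n_ind), stringsAsFactors = FALSE)
    loci <- data.frame(locus_id = sprintf("tag%05d_1", seq_len(L)),
                       chrom = sprintf("tag%05d", seq_len(L)),
                       pos = rep(1L, L), stringsAsFactors = FALSE)
    ds <- genotype_dataset(sp_id, calls, individuals, loci)
    attr(ds, "family") <- fams[sp]
    out[[sp_id]] <- ds
  }
  out
}

#' Simulate a community incidence table for one basin
#'
#' Each species receives a range centre at one of the basin's sites and an
#' occupancy probability decaying with in-water distance from that centre
#' (range `lambda_km`), multiplied by a site richness gradient; occupancy is
#' independent Bernoulli. A family whose species are all absent everywhere
#' is regenerated once, then kept with a warning.
#'
#' @param cfg `synth_config`.
#' @param distances `pairwise_matrix` (km) over the basin's sites.
#' @param basin basin name.
#' @return `community_table` (with a synthetic PLD trait map).
#' @export
simulate_communities <- function(cfg, distances, basin) {
  b <- cfg$basins[[basin]]
  if (is.null(b)) stop("unknown basin '", basin, "'")
  ids <- rownames(distances)
  d <- unclass(distances)[ids, ids]
  if (any(!is.finite(d))) stop("distances must be finite")
  k <- length(ids)
  site_mult <- seq(1, 1 - cfg$richness_gradient, length.out = k)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 5000L + match(basin, names(cfg$basins))))
  gen_family <- function(fam) {
    n_sp <- b$species_per_family
    inc <- matrix(0L, k, n_sp)
    for (s in seq_len(n_sp)) {
      centre <- sample.int(k, 1)
      p <- cfg$occupancy_max * exp(-d[centre, ] / b$lambda_km) * site_mult
      occ <- as.integer(stats::runif(k) < p)
      occ[centre] <- 1L
      inc[, s] <- occ
    }
    inc
  }
  incs <- list()
  for (fam in b$families) {
    inc <- gen_family(fam)
    if (all(inc == 0L)) {
      inc <- gen_family(fam)
      if (all(inc == 0L))
        warning("family ", fam, " has no occurrences after regeneration")
    }
    colnames(inc) <- sprintf("%s_%s_sp%02d", basin, fam,
                             seq_len(ncol(inc)))
    incs[[fam]] <- inc
  }
  incidence <- do.call(cbind, incs)
  rownames(incidence) <- ids
  species <- colnames(incidence)
  fam_map <- data.frame(
    species = species,
    family = rep(b$families, vapply(incs, ncol, 0L)),
    stringsAsFactors = FALSE)
  genus <- sub("_sp[0-9]+$", "", species)
  traits <- data.frame(species = species, genus = genus,
                       pld_days = round(stats::rlnorm(length(species),
                                                      log(30), 0.4), 1),
                       stringsAsFactors = FALSE)
  community_table(incidence, fam_map, traits)
}

#' Write a genotype dataset as a VCF v4.2 file
#'
#' Plain-text VCF with GT-only FORMAT; missing calls are `./.`. Round-trips
#' through [read_genotypes()].
#'
#' @param ds `genotype_dataset`.
#' @param path output `.vcf` path.
#' @export
write_vcf <- function(ds, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=reefscape_synth species=%s", ds$species_id),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$individuals$individual_id), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  n_loci <- nrow(ds$loci)
  if (n_loci) {
    body <- vapply(seq_len(n_loci), function(j) {
      g <- ds$calls[, j]
      gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
      paste(c(ds$loci$chrom[j], ds$loci$pos[j], ds$loci$locus_id[j],
              "A", "G", ".", "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}
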