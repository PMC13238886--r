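# Fixture builders shared across test files.

four_sites <- function(basin = "WIO") {
  site_table(data.frame(
    site_id = c("S1", "S2", "S3", "S4"),
    lon = c(73, 45, 55, 39), lat = c(4, -7, -4, -12), basin = basin,
    stringsAsFactors = FALSE))
}

# random small genotype dataset with optional planted missingness
random_dataset <- function(n_per_site = 5, n_loci = 20, n_sites = 4,
                           miss = 0, seed = 1, species = "spX") {
  set.seed(seed)
  sites <- paste0("S", seq_len(n_sites))
  n_ind <- n_per_site * n_sites
  p <- runif(n_loci, 0.1, 0.9)
  site_shift <- matrix(rnorm(n_sites * n_loci, 0, 0.5), n_sites)
  calls <- matrix(NA_integer_, n_ind, n_loci)
  for (s in seq_len(n_sites)) {
    ps <- plogis(qlogis(p) + site_shift[s, ])
    rows <- (s - 1) * n_per_site + seq_len(n_per_site)
    calls[rows, ] <- matrix(rbinom(n_per_site * n_loci, 2,
                                   rep(ps, each = n_per_site)),
                            n_per_site)
  }
  if (miss > 0)
    calls[matrix(runif(length(calls)) < miss, n_ind)] <- NA_integer_
  genotype_dataset(
    species, calls,
    data.frame(individual_id = sprintf("i%03d", seq_len(n_ind)),
               site_id = rep(sites, each = n_per_site)),
    data.frame(locus_id = sprintf("tag%03d_1", seq_len(n_loci)),
               chrom = sprintf("tag%03d", seq_len(n_loci)),
               pos = rep(1L, n_loci)))
}

# pair data with known MLPE structure for recovery tests
sim_mlpe_pairs <- function(n_sites = 8, n_groups = 6, intercept = 1,
                           slope = 2, rho = 0.3, s2u = 0.5, s2e = 1,
                           seed = 1) {
  set.seed(seed)
  sites <- paste0("P", seq_len(n_sites))
  pr <- t(utils::combn(sites, 2))
  d <- do.call(rbind, lapply(seq_len(n_groups), function(g)
    data.frame(group = paste0("g", g), site_i = pr[, 1], site_j = pr[, 2],
               predictor = runif(nrow(pr)), stringsAsFactors = FALSE)))
  n <- nrow(d)
  S <- matrix(0, n, n); G <- matrix(0, n, n)
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    if (d$group[p] != d$group[q]) next
    G[p, q] <- G[q, p] <- 1
    sh <- length(intersect(c(d$site_i[p], d$site_j[p]),
                           c(d$site_i[q], d$site_j[q])))
    if (sh == 1) S[p, q] <- S[q, p] <- 1
  }
  diag(G) <- 1
  V <- s2e * (diag(n) + rho * S) + s2u * G
  d$response <- intercept + slope * d$predictor + drop(t(chol(V)) %*% rnorm(n))
  d
}

# all-sea grid helper
flat_sea_grid <- function(lon0, lon1, lat0, lat1, res = 0.5) {
  lon <- seq(lon0, lon1, by = res)
  lat <- seq(lat0, lat1, by = res)
  seascape_grid(lon, lat, matrix(TRUE, length(lat), length(lon)))
}

gc_km <- function(lon1, lat1, lon2, lat2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
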