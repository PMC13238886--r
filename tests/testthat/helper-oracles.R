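# Independent brute-force oracles, transcribed symbol-by-symbol from the
# primary formulas with plain scalar loops. These deliberately share no code
# with the package internals.

# --- differentiation -------------------------------------------------------

# calls: individuals x loci dosage matrix; pops: labels per individual.
# Returns multi-locus Hs, Ht, Gst, G'st, G''st via Nei-Chesser unbiased
# estimators and the Hedrick / Meirmans-Hedrick standardizations.
oracle_gst <- function(calls, pops) {
  pops <- as.character(pops)
  pop_levels <- sort(unique(pops))
  k <- length(pop_levels)
  hs_list <- c(); ht_list <- c()
  for (l in seq_len(ncol(calls))) {
    p_vec <- c(); n_vec <- c()
    for (pp in pop_levels) {
      g <- calls[pops == pp, l]
      g <- g[!is.na(g)]
      n_vec <- c(n_vec, length(g))
      p_vec <- c(p_vec, if (length(g)) sum(g) / (2 * length(g)) else NA)
    }
    if (any(n_vec == 0)) next            # locus unusable for this statistic
    n_tilde <- k / sum(1 / n_vec)        # harmonic mean sample size
    hs_raw <- mean(2 * p_vec * (1 - p_vec))
    p_bar <- mean(p_vec)
    ht_raw <- 2 * p_bar * (1 - p_bar)
    hs <- hs_raw * 2 * n_tilde / (2 * n_tilde - 1)
    ht <- ht_raw + hs / (2 * n_tilde * k)
    hs_list <- c(hs_list, hs); ht_list <- c(ht_list, ht)
  }
  Hs <- mean(hs_list); Ht <- mean(ht_list)
  if (!length(ht_list) || Ht <= 0)
    return(list(Hs = Hs, Ht = Ht, Gst = NA, Gst_prime = NA, Gst_dprime = NA))
  Gst <- (Ht - Hs) / Ht
  Gst_prime <- Gst * (k - 1 + Hs) / ((k - 1) * (1 - Hs))
  Gst_dprime <- k * (Ht - Hs) / ((k * Ht - Hs) * (1 - Hs))
  list(Hs = Hs, Ht = Ht, Gst = Gst, Gst_prime = Gst_prime,
       Gst_dprime = Gst_dprime)
}

# --- beta-diversity --------------------------------------------------------

# x, y: character vectors of species present at two sites
oracle_beta_pair <- function(x, y) {
  a <- length(intersect(x, y))
  b <- length(setdiff(x, y))
  c_ <- length(setdiff(y, x))
  if (a + b + c_ == 0) return(c(jac = NA, jtu = NA, jne = NA))
  jac <- (b + c_) / (a + b + c_)
  jtu <- if (a + 2 * min(b, c_) > 0) 2 * min(b, c_) / (a + 2 * min(b, c_)) else 0
  c(jac = jac, jtu = jtu, jne = jac - jtu)
}

# inc: site x species 0/1 matrix
oracle_beta_multi <- function(inc) {
  n <- nrow(inc)
  sets <- lapply(seq_len(n), function(i) colnames(inc)[inc[i, ] == 1])
  smin <- 0; smax <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    bij <- length(setdiff(sets[[i]], sets[[j]]))
    bji <- length(setdiff(sets[[j]], sets[[i]]))
    smin <- smin + min(bij, bji)
    smax <- smax + max(bij, bji)
  }
  Si <- sum(vapply(sets, length, 0L))
  ST <- length(unique(unlist(sets)))
  core <- Si - ST
  jtu <- if (core + 2 * smin > 0) 2 * smin / (core + 2 * smin) else 0
  jac <- if (core + smin + smax > 0) (smin + smax) / (core + smin + smax) else 0
  c(jac = jac, jtu = jtu, jne = jac - jtu)
}

# --- MLPE ------------------------------------------------------------------

# Direct multivariate-normal log density with the covariance assembled
# elementwise from the sharing structure.
oracle_mlpe_loglik <- function(d, beta0, beta1, sigma2_e, sigma2_u, rho) {
  n <- nrow(d)
  V <- matrix(0, n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (p == q) { V[p, q] <- sigma2_e + sigma2_u; next }
    if (d$group[p] != d$group[q]) next
    shared <- length(intersect(c(d$site_i[p], d$site_j[p]),
                               c(d$site_i[q], d$site_j[q])))
    V[p, q] <- sigma2_u + if (shared == 1) rho * sigma2_e else 0
  }
  r <- d$response - beta0 - beta1 * d$predictor
  -0.5 * (n * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            drop(t(r) %*% solve(V, r)))
}
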