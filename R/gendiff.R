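#' Per-locus heterozygosity statistics (Nei & Chesser estimators)
#'
#' Computes, for each biallelic locus, the unbiased within-population gene
#' diversity \eqn{\hat H_S} and total gene diversity \eqn{\hat H_T} with the
#' harmonic-mean sample-size correction:
#' \deqn{\hat H_S = \frac{2\tilde n}{2\tilde n - 1}\, \bar H_S^{raw}, \qquad
#'       \hat H_T = H_T^{raw} + \frac{\hat H_S}{2 \tilde n k},}
#' where \eqn{\bar H_S^{raw}} averages \eqn{2p(1-p)} over the \eqn{k}
#' populations, \eqn{H_T^{raw} = 2\bar p(1-\bar p)} uses the unweighted mean
#' allele frequency, and \eqn{\tilde n} is the harmonic mean of per-population
#' genotyped sample sizes at the locus.
#'
#' Loci at which any population has no genotyped individual are dropped for
#' the statistic (reported via the `n_dropped` field).
#'
#' @param ds `genotype_dataset`.
#' @param populations factor/character of population labels, one per
#'   individual; defaults to the dataset's site assignments.
#' @return list of class `het_stats`: per-locus `Hs`, `Ht`, `n_harm`, number
#'   of populations `k`, locus ids, and `n_dropped`.
#' @export
het_stats <- function(ds, populations = ds$individuals$site_id) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pop <- factor(populations)
  k <- nlevels(pop)
  if (k < 2L) stop("need at least 2 populations, got ", k)
  calls <- ds$calls
  if (ncol(calls) == 0L)
    return(structure(list(Hs = numeric(0), Ht = numeric(0),
                          n_harm = numeric(0), k = k,
                          locus_id = character(0), n_dropped = 0L),
                     class = "het_stats"))
  # per-population allele frequencies and genotyped counts, vectorized
  # across loci: p[pop, locus], n[pop, locus]
  pop_idx <- split(seq_len(nrow(calls)), pop)
  p <- matrix(NA_real_, k, ncol(calls))
  n <- matrix(0, k, ncol(calls))
  for (j in seq_len(k)) {
    sub <- calls[pop_idx[[j]], , drop = FALSE]
    n[j, ] <- colSums(!is.na(sub))
    p[j, ] <- colSums(sub, na.rm = TRUE) / (2 * n[j, ])
  }
  ok <- colSums(n > 0) == k
  n_dropped <- sum(!ok)
  p <- p[, ok, drop = FALSE]; n <- n[, ok, drop = FALSE]
  n_harm <- k / colSums(1 / n)
  hs_raw <- colMeans(2 * p * (1 - p))
  pbar <- colMeans(p)
  ht_raw <- 2 * pbar * (1 - pbar)
  hs <- hs_raw * (2 * n_harm) / (2 * n_harm - 1)
  ht <- ht_raw + hs / (2 * n_harm * k)
  structure(list(Hs = hs, Ht = ht, n_harm = n_harm, k = k,
                 locus_id = ds$loci$locus_id[ok], n_dropped = n_dropped),
            class = "het_stats")
}

#' Differentiation statistics G_ST, G'_ST and G''_ST
#'
#' Multi-locus statistics are ratios of across-locus averaged \eqn{\hat H_S}
#' and \eqn{\hat H_T} (ratio of averages, not average of ratios):
#' \deqn{G_{ST} = \frac{H_T - H_S}{H_T}}
#' \deqn{G'_{ST} = \frac{G_{ST}\,(k - 1 + H_S)}{(k - 1)(1 - H_S)}}
#' \deqn{G''_{ST} = \frac{k (H_T - H_S)}{(k H_T - H_S)(1 - H_S)}}
#' with \eqn{k} populations (Hedrick's standardization and the
#' Meirmans-Hedrick small-k bias correction). Small negative estimates are
#' legitimate sampling outcomes of the unbiased estimators and are never
#' clamped.
#'
#' @param hs `het_stats`.
#' @return list of class `differentiation_stats` with multi-locus `Gst`,
#'   `Gst_prime`, `Gst_dprime`, per-locus vectors, averaged `Hs`/`Ht`,
#'   `n_loci`, and `defined` (FALSE when all loci are monomorphic overall,
#'   in which case the statistics are `NA`, flagged rather than 0).
#' @export
gst_statistics <- function(hs) {
  stopifnot(inherits(hs, "het_stats"))
  k <- hs$k
  Hs <- mean(hs$Hs)
  Ht <- mean(hs$Ht)
  per_locus <- function(hsl, htl) {
    gst <- ifelse(htl > 0, (htl - hsl) / htl, NA_real_)
    gpr <- ifelse(htl > 0, gst * (k - 1 + hsl) / ((k - 1) * (1 - hsl)),
                  NA_real_)
    gdp <- ifelse(htl > 0, k * (htl - hsl) / ((k * htl - hsl) * (1 - hsl)),
                  NA_real_)
    list(gst = gst, gpr = gpr, gdp = gdp)
  }
  pl <- per_locus(hs$Hs, hs$Ht)
  defined <- length(hs$Ht) > 0 && Ht > 0
  if (defined) {
    Gst <- (Ht - Hs) / Ht
    Gp <- Gst * (k - 1 + Hs) / ((k - 1) * (1 - Hs))
    Gpp <- k * (Ht - Hs) / ((k * Ht - Hs) * (1 - Hs))
  } else {
    Gst <- Gp <- Gpp <- NA_real_
  }
  structure(list(Gst = Gst, Gst_prime = Gp, Gst_dprime = Gpp,
                 per_locus = pl, Hs = Hs, Ht = Ht, k = k,
                 n_loci = length(hs$Hs), defined = defined),
            class = "differentiation_stats")
}

#' @export
print.differentiation_stats <- function(x, ...) {
  cat("Differentiation over", x$n_loci, "loci,", x$k, "populations\n")
  cat(sprintf("  Hs = %.4f  Ht = %.4f\n", x$Hs, x$Ht))
  cat(sprintf("  G_ST = %.4f  G'_ST = %.4f  G''_ST = %.4f\n",
              x$Gst, x$Gst_prime, x$Gst_dprime))
  if (!x$defined) cat("  (all loci monomorphic overall: undefined)\n")
  invisible(x)
}

#' Construct a pairwise site-by-site matrix
#'
#' @param values symmetric numeric matrix.
#' @param site_ids ordered site keys (row/col names).
#' @param metric metric label, e.g. `"Gst_dprime"`, `"beta_jac"`,
#'   `"distance_km"`.
#' @param sd optional matrix of cellwise dispersions across iterations.
#' @param n_iter optional iteration count behind the mean.
#' @return matrix of class `pairwise_matrix` with attributes `metric`, `sd`,
#'   `n_iter`.
#' @export
pairwise_matrix <- function(values, site_ids = rownames(values), metric,
                            sd = NULL, n_iter = NULL) {
  values <- as.matrix(values)
  if (is.null(site_ids)) stop("site_ids required")
  dimnames(values) <- list(site_ids, site_ids)
  finite <- is.finite(values)
  if (any(abs(values[finite] - t(values)[finite]) > 1e-10))
    stop("pairwise matrix must be symmetric")
  structure(values, metric = metric, sd = sd, n_iter = n_iter,
            class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("Pairwise", attr(x, "metric"), "matrix over", nrow(x), "sites")
  if (!is.null(attr(x, "n_iter")))
    cat(" (mean of", attr(x, "n_iter"), "iterations)")
  cat("\n")
  print(unclass(structure(x, metric = NULL, sd = NULL, n_iter = NULL)))
  invisible(x)
}

#' Pairwise G''_ST between sampling sites
#'
#' For each unordered pair of sites the two-site subset is extracted
#' (\eqn{k = 2}) and the multi-locus \eqn{G''_{ST}} computed. Loci with all
#' calls missing in either member of a pair are excluded pair-locally, so
#' different pairs may rest on slightly different locus subsets. Sites with
#' zero individuals yield `NA` rows/columns.
#'
#' @param ds `genotype_dataset`.
#' @param sites `site_table` (defines matrix order); defaults to the sites
#'   present in the dataset.
#' @param metric which statistic to tabulate (`"Gst_dprime"` default,
#'   `"Gst"`, or `"Gst_prime"`).
#' @return `pairwise_matrix` with zero diagonal.
#' @export
pairwise_gst <- function(ds, sites = NULL, metric = "Gst_dprime") {
  ids <- if (is.null(sites)) sort(unique(ds$individuals$site_id))
         else sites$site_id
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sel <- ds$individuals$site_id %in% c(ids[i], ids[j])
    if (!any(ds$individuals$site_id == ids[i]) ||
        !any(ds$individuals$site_id == ids[j])) next
    sub <- genotype_dataset(ds$species_id,
                            ds$calls[sel, , drop = FALSE],
                            ds$individuals[sel, , drop = FALSE], ds$loci)
    st <- gst_statistics(het_stats(sub))
    m[i, j] <- m[j, i] <- st[[metric]]
  }
  pairwise_matrix(m, ids, metric)
}

#' Average pairwise matrices across resampling iterations
#'
#' Cellwise mean with cellwise standard deviation stored as the dispersion
#' attribute; the iteration count is recorded.
#'
#' @param matrices list of `pairwise_matrix` objects sharing site ids and
#'   metric.
#' @return `pairwise_matrix` of cellwise means.
#' @export
aggregate_iterations <- function(matrices) {
  if (!length(matrices)) stop("no matrices to aggregate")
  ids <- rownames(matrices[[1]])
  metric <- attr(matrices[[1]], "metric")
  for (m in matrices) {
    if (!identical(rownames(m), ids))
      stop("matrices have mismatched site sets")
    if (!identical(attr(m, "metric"), metric))
      stop("matrices have mismatched metrics")
  }
  arr <- array(unlist(lapply(matrices, unclass)),
               dim = c(length(ids), length(ids), length(matrices)))
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- apply(arr, c(1, 2), stats::sd)
  pairwise_matrix(mean_m, ids, metric, sd = sd_m, n_iter = length(matrices))
}

#' Serialize a pairwise matrix to long-form CSV
#'
#' Columns `site_i,site_j,metric,value,sd,n_iter`, one row per unordered
#' pair.
#'
#' @param x `pairwise_matrix`.
#' @param path output CSV path; when `NULL` the data.frame is returned
#'   without writing.
#' @return invisibly (or visibly when `path` is `NULL`), the long-form
#'   data.frame.
#' @export
write_pairwise_csv <- function(x, path = NULL) {
  ids <- rownames(x)
  pr <- which(upper.tri(x), arr.ind = TRUE)
  sd_m <- attr(x, "sd")
  out <- data.frame(
    site_i = ids[pr[, 1]], site_j = ids[pr[, 2]],
    metric = attr(x, "metric"),
    value = x[pr],
    sd = if (is.null(sd_m)) NA_real_ else sd_m[pr],
    n_iter = if (is.null(attr(x, "n_iter"))) NA_integer_
             else attr(x, "n_iter"),
    stringsAsFactors = FALSE)
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
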