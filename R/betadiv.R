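#' Construct a community incidence table
#'
#' Site x species presence/absence with a species-to-family map and an
#' optional trait map (pelagic larval duration, days). Family-level
#' dissimilarities subset the columns of the incidence table; sites with no
#' member of a family are retained (their presence list is empty), matching
#' presence-list semantics.
#'
#' @param incidence site x species 0/1 matrix with dimnames.
#' @param family_map data.frame `species,family`.
#' @param trait_map optional data.frame `species,genus,pld_days`.
#' @return object of class `community_table`.
#' @export
community_table <- function(incidence, family_map, trait_map = NULL) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence needs site row names and species column names")
  if (!all(incidence %in% c(0, 1)))
    stop("incidence must be strictly binary 0/1")
  storage.mode(incidence) <- "integer"
  family_map <- as.data.frame(family_map)
  family_map$species <- as.character(family_map$species)
  family_map$family <- as.character(family_map$family)
  unmapped <- setdiff(colnames(incidence), family_map$species)
  if (length(unmapped))
    stop("species without a family: ", paste(unmapped, collapse = ", "))
  if (!is.null(trait_map)) {
    trait_map <- as.data.frame(trait_map)
    trait_map$species <- as.character(trait_map$species)
  }
  structure(list(incidence = incidence, family_map = family_map,
                 trait_map = trait_map),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat("Community table:", nrow(x$incidence), "sites x",
      ncol(x$incidence), "species in",
      length(unique(x$family_map$family)), "families\n")
  invisible(x)
}

# Species columns of one family (or all); errors with the available list.
family_columns <- function(community, family) {
  if (is.null(family) || identical(family, "all"))
    return(colnames(community$incidence))
  fams <- unique(community$family_map$family)
  if (!family %in% fams)
    stop("unknown family '", family, "'; available: ",
         paste(sort(fams), collapse = ", "))
  sp <- community$family_map$species[community$family_map$family == family]
  intersect(colnames(community$incidence), sp)
}

# Pairwise Jaccard partition from shared/exclusive counts.
beta_pair_abc <- function(a, b, c) {
  tot <- a + b + c
  bj <- ifelse(tot > 0, (b + c) / tot, NA_real_)
  mn <- pmin(b, c)
  bt <- ifelse(tot > 0, 2 * mn / (a + 2 * mn), NA_real_)
  # a + 2*min == 0 with tot > 0 means complete turnover is impossible
  # (one side empty): 0/0 -> turnover 0
  bt[!is.na(bt) & (a + 2 * mn) == 0] <- 0
  list(jac = bj, jtu = bt, jne = bj - bt)
}

#' Pairwise Jaccard dissimilarity partitioned into turnover and nestedness
#'
#' For each unordered site pair, with `a` shared species and `b`, `c`
#' site-exclusive species of the chosen family:
#' \deqn{\beta_{jac} = \frac{b + c}{a + b + c},\qquad
#'       \beta_{jtu} = \frac{2\min(b,c)}{a + 2\min(b,c)},\qquad
#'       \beta_{jne} = \beta_{jac} - \beta_{jtu}}
#' (Baselga partition of Jaccard dissimilarity). Pairs where both sites lack
#' the family entirely are flagged undefined (`NA`), not zero.
#'
#' @param community `community_table`.
#' @param family family name, or `"all"` for the full table.
#' @return named list of three `pairwise_matrix` objects: `beta_jac`,
#'   `beta_jtu`, `beta_jne`.
#' @export
pairwise_beta <- function(community, family = "all") {
  sp <- family_columns(community, family)
  inc <- community$incidence[, sp, drop = FALSE]
  ids <- rownames(inc)
  shared <- inc %*% t(inc)                      # a
  rich <- rowSums(inc)
  b <- outer(rich, rich, function(x, y) x) - shared   # exclusive to i
  c_ <- outer(rich, rich, function(x, y) y) - shared  # exclusive to j
  comp <- beta_pair_abc(shared, b, c_)
  res <- lapply(comp, function(m) {
    diag(m)[rich > 0] <- 0   # identical-to-self; empty sites stay undefined
    m
  })
  list(beta_jac = pairwise_matrix(res$jac, ids, "beta_jac"),
       beta_jtu = pairwise_matrix(res$jtu, ids, "beta_jtu"),
       beta_jne = pairwise_matrix(res$jne, ids, "beta_jne"))
}

#' Multiple-site Jaccard dissimilarity partition
#'
#' Baselga's multiple-site family of the Jaccard index. With site
#' richnesses \eqn{S_i}, pooled richness \eqn{S_T}, and pairwise exclusive
#' counts \eqn{b_{ij}} (species in site i absent from j):
#' \deqn{\beta_{JTU} = \frac{2\Sigma\min}{\Sigma S_i - S_T + 2\Sigma\min}}
#' \deqn{\beta_{JAC} = \frac{\Sigma\min + \Sigma\max}
#'                          {\Sigma S_i - S_T + \Sigma\min + \Sigma\max}}
#' \deqn{\beta_{JNE} = \beta_{JAC} - \beta_{JTU}}
#' where \eqn{\Sigma\min = \sum_{i<j}\min(b_{ij}, b_{ji})} and
#' \eqn{\Sigma\max} the analogous sum of maxima.
#'
#' @param community `community_table`.
#' @param family family name or `"all"`.
#' @return list of class `beta_triple`: `beta_jac`, `beta_jtu`, `beta_jne`,
#'   `n_sites`, plus `defined` (FALSE and `NA` components when fewer than 2
#'   sites or no species present anywhere).
#' @export
multisite_beta <- function(community, family = "all") {
  sp <- family_columns(community, family)
  inc <- community$incidence[, sp, drop = FALSE]
  n <- nrow(inc)
  if (n < 2L)
    return(structure(list(beta_jac = NA_real_, beta_jtu = NA_real_,
                          beta_jne = NA_real_, n_sites = n, defined = FALSE),
                     class = "beta_triple"))
  shared <- inc %*% t(inc)
  rich <- rowSums(inc)
  bmat <- outer(rich, rich, function(x, y) x) - shared
  ut <- upper.tri(bmat)
  smin <- sum(pmin(bmat[ut], t(bmat)[ut]))
  smax <- sum(pmax(bmat[ut], t(bmat)[ut]))
  S_T <- sum(colSums(inc) > 0)
  core <- sum(rich) - S_T
  if (S_T == 0L)
    return(structure(list(beta_jac = NA_real_, beta_jtu = NA_real_,
                          beta_jne = NA_real_, n_sites = n, defined = FALSE),
                     class = "beta_triple"))
  jtu <- if (core + 2 * smin > 0) 2 * smin / (core + 2 * smin) else 0
  jac <- if (core + smin + smax > 0)
    (smin + smax) / (core + smin + smax) else 0
  structure(list(beta_jac = jac, beta_jtu = jtu, beta_jne = jac - jtu,
                 n_sites = n, defined = TRUE),
            class = "beta_triple")
}

#' @export
print.beta_triple <- function(x, ...) {
  cat(sprintf(
    "Multiple-site Jaccard partition over %d sites:\n  beta_jac = %.4f  beta_jtu = %.4f  beta_jne = %.4f\n",
    x$n_sites, x$beta_jac, x$beta_jtu, x$beta_jne))
  if (!x$defined) cat("  (undefined)\n")
  invisible(x)
}

#' Per-species pelagic larval duration with genus-median fallback
#'
#' Species-level PLD where recorded; otherwise the median PLD of congeners
#' with data; otherwise missing (`NA`), which excludes the species from
#' downstream trait comparisons.
#'
#' @param community `community_table` with a `trait_map`
#'   (`species,genus,pld_days`).
#' @param family family name or `"all"`.
#' @return named numeric vector of PLD (days) for the family's species.
#' @export
trait_summary <- function(community, family = "all") {
  if (is.null(community$trait_map))
    stop("community table has no trait_map")
  sp <- family_columns(community, family)
  tm <- community$trait_map
  idx <- match(sp, tm$species)
  pld <- tm$pld_days[idx]
  genus <- tm$genus[idx]
  # fall back on genus medians computed from species with data
  gmed <- tapply(tm$pld_days, tm$genus, stats::median, na.rm = TRUE)
  need <- is.na(pld) & !is.na(genus)
  pld[need] <- gmed[genus[need]]
  pld[is.nan(pld)] <- NA_real_
  names(pld) <- sp
  pld
}

#' Read a community table from CSV files
#'
#' @param incidence_path CSV, rows = sites (first column site id), columns =
#'   species, cells 0/1.
#' @param family_path CSV `species,family`.
#' @param trait_path optional CSV `species,genus,pld_days`.
#' @return `community_table`.
#' @export
read_community <- function(incidence_path, family_path, trait_path = NULL) {
  inc <- utils::read.csv(incidence_path, row.names = 1, check.names = FALSE)
  fam <- utils::read.csv(family_path, stringsAsFactors = FALSE)
  tr <- if (!is.null(trait_path))
    utils::read.csv(trait_path, stringsAsFactors = FALSE) else NULL
  community_table(as.matrix(inc), fam, tr)
}
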