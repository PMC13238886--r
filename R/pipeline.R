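#' One-way fixed-effects ANOVA for between-basin contrasts
#'
#' Compares a per-unit metric (per-species genetic differentiation,
#' per-family turnover, per-species PLD, ...) between basins with a one-way
#' fixed-effects ANOVA (F = MSB/MSW).
#'
#' @param values numeric metric values, one per unit.
#' @param groups basin labels, same length.
#' @return list: `F`, `p`, `df`, per-group `means` and `sds`, `n`.
#' @export
ocean_anova <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(values) - nlevels(groups) < 1)
    stop("zero within-group degrees of freedom")
  a <- stats::anova(stats::lm(values ~ groups))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       df = c(between = a$Df[1], within = a$Df[2]),
       means = tapply(values, groups, mean),
       sds = tapply(values, groups, stats::sd),
       n = tapply(values, groups, length))
}

#' Pair species-level genetic dissimilarity with family-level species
#' dissimilarity
#'
#' Builds the beta species-genetic diversity correlation (beta-SGDC) pair
#' table: for each genotyped species, the response is the pairwise species
#' dissimilarity of the species' family and the predictor is that species'
#' pairwise genetic dissimilarity; the grouping unit is the species.
#'
#' @param genetic_mats named list (by species) of `pairwise_matrix` of
#'   genetic dissimilarity.
#' @param community_mats named list (by family) of `pairwise_matrix` of one
#'   species-dissimilarity metric.
#' @param family_map data.frame `species,family` covering every genotyped
#'   species.
#' @return `pair_table` with `response` = family beta-SD, `predictor` =
#'   species beta-GD, `group` = species.
#' @export
sgdc_pairing <- function(genetic_mats, community_mats, family_map) {
  fam_of <- stats::setNames(family_map$family, family_map$species)
  unmapped <- setdiff(names(genetic_mats), names(fam_of))
  if (length(unmapped))
    stop("species without a family mapping: ",
         paste(unmapped, collapse = ", "))
  rows <- lapply(names(genetic_mats), function(sp) {
    fam <- fam_of[[sp]]
    if (is.null(community_mats[[fam]]))
      stop("no community matrix for family '", fam, "' (species ", sp, ")")
    gm <- genetic_mats[[sp]]
    cm <- community_mats[[fam]]
    ids <- rownames(gm)
    pr <- which(upper.tri(gm), arr.ind = TRUE)
    data.frame(group = sp, site_i = ids[pr[, 1]], site_j = ids[pr[, 2]],
               response = cm[ids, ids][pr], predictor = gm[pr],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- is.finite(out$response) & is.finite(out$predictor)
  if (any(!keep))
    message("sgdc_pairing: dropped ", sum(!keep),
            " row(s) with undefined cells")
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_table", "data.frame")
  out
}

# One row of the model roster: fit + headline numbers
roster_row <- function(hypothesis, response, predictor, basin, fit) {
  r2 <- r2_nakagawa(fit)
  slope_name <- setdiff(names(coef(fit)), "(Intercept)")[1]
  data.frame(hypothesis = hypothesis, response = response,
             predictor = predictor, basin = basin,
             estimate = unname(coef(fit)[slope_name]),
             p = unname(fit$p_value[slope_name]),
             R2m = unname(r2["R2m"]), R2c = unname(r2["R2c"]),
             rho = fit$rho, stringsAsFactors = FALSE)
}

#' Run the full comparative analysis for one basin
#'
#' Orchestrates the basin-level workflow: genotype filtering and
#' eligibility, (optionally resampled) pairwise genetic differentiation,
#' per-family species dissimilarity partition, and the three MLPE
#' hypotheses — genetic isolation by distance (beta-GD ~ km), species
#' isolation by distance (beta_jtu and beta_jac ~ km, grouped by family),
#' and the beta species-genetic diversity correlation (family beta-SD ~
#' species beta-GD, grouped by species).
#'
#' @param genotypes named list of `genotype_dataset` (one per species);
#'   species whose `family` attribute is unset are matched through
#'   `community$family_map`.
#' @param community `community_table` for the basin's sites.
#' @param sites `site_table` restricted to the basin.
#' @param distances `pairwise_matrix` of in-water distances (km).
#' @param filter_cfg `filter_config` applied to every species.
#' @param resample_cfg optional `resample_config`; when `NULL` the
#'   differentiation is computed once on the filtered data.
#' @param responses which species-dissimilarity responses to fit
#'   (default `c("beta_jtu", "beta_jac")`).
#' @return list of class `basin_summary`: `species` (per-species overall
#'   G''ST), `families` (per-family multi-site partition), `fits` (model
#'   roster data.frame), `fit_objects`, `pair_tables`, `genetic_mats`,
#'   `community_mats`, `excluded_species`.
#' @export
run_basin <- function(genotypes, community, sites, distances,
                      filter_cfg = filter_config(), resample_cfg = NULL,
                      responses = c("beta_jtu", "beta_jac")) {
  # --- genio: filter + eligibility -------------------------------------
  filtered <- lapply(genotypes, filter_genotypes, cfg = filter_cfg)
  eligible <- vapply(filtered, function(ds)
    isTRUE(check_species_eligibility(ds, sites, filter_cfg)), logical(1))
  excluded <- names(filtered)[!eligible]
  if (all(!eligible)) stop("run_basin: no eligible species after filtering")
  filtered <- filtered[eligible]

  # --- gendiff: pairwise + overall G''ST (resampling means) ------------
  gd_of <- function(ds) {
    if (is.null(resample_cfg)) {
      list(mat = pairwise_gst(ds, sites),
           overall = gst_statistics(het_stats(ds))$Gst_dprime)
    } else {
      reps <- resample_iterations(ds, resample_cfg, function(r)
        list(mat = pairwise_gst(r, sites),
             overall = gst_statistics(het_stats(r))$Gst_dprime))
      list(mat = aggregate_iterations(lapply(reps, `[[`, "mat")),
           overall = mean(vapply(reps, `[[`, 0, "overall")))
    }
  }
  gd <- lapply(filtered, gd_of)
  genetic_mats <- lapply(gd, `[[`, "mat")
  species_tbl <- data.frame(
    species = names(gd),
    family = vapply(genotypes[names(gd)], function(ds) {
      f <- attr(ds, "family")
      if (is.null(f)) NA_character_ else f
    }, character(1)),
    beta_gd = vapply(gd, `[[`, 0, "overall"),
    stringsAsFactors = FALSE)
  if (anyNA(species_tbl$family)) {
    fam_of <- stats::setNames(community$family_map$family,
                              community$family_map$species)
    species_tbl$family[is.na(species_tbl$family)] <-
      fam_of[species_tbl$species[is.na(species_tbl$family)]]
  }

  # --- betadiv: per-family pairwise + multi-site -----------------------
  fams <- sort(unique(community$family_map$family))
  beta_pair <- lapply(stats::setNames(fams, fams), pairwise_beta,
                      community = community)
  family_tbl <- do.call(rbind, lapply(fams, function(f) {
    tr <- multisite_beta(community, f)
    data.frame(family = f, beta_jac = tr$beta_jac, beta_jtu = tr$beta_jtu,
               beta_jne = tr$beta_jne, stringsAsFactors = FALSE)
  }))

  # --- mlpe: the three hypotheses --------------------------------------
  fits <- list(); roster <- list(); pair_tables <- list()
  basin_name <- sites$basin[1]

  pt_gibd <- build_pair_table(genetic_mats, distances)
  fits$genetic_ibd <- fit_mlpe(pt_gibd)
  pair_tables$genetic_ibd <- pt_gibd
  roster$genetic_ibd <- roster_row("Genetic IBD", "beta_gd", "distance_km",
                                   basin_name, fits$genetic_ibd)

  for (resp in responses) {
    cm <- lapply(beta_pair, `[[`, resp)
    pt <- build_pair_table(cm, distances)
    key <- paste0("species_ibd_", resp)
    fits[[key]] <- fit_mlpe(pt)
    pair_tables[[key]] <- pt
    roster[[key]] <- roster_row("Species IBD", resp, "distance_km",
                                basin_name, fits[[key]])

    cm_named <- stats::setNames(cm, fams)
    pt_sgdc <- sgdc_pairing(genetic_mats, cm_named,
                            species_tbl[, c("species", "family")])
    key2 <- paste0("sgdc_", resp)
    fits[[key2]] <- fit_mlpe(pt_sgdc)
    pair_tables[[key2]] <- pt_sgdc
    roster[[key2]] <- roster_row("beta-SGDC", resp, "beta_gd",
                                 basin_name, fits[[key2]])
  }

  structure(list(basin = basin_name, species = species_tbl,
                 families = family_tbl,
                 fits = do.call(rbind, roster),
                 fit_objects = fits, pair_tables = pair_tables,
                 genetic_mats = genetic_mats,
                 community_mats = beta_pair,
                 excluded_species = excluded),
            class = "basin_summary")
}

#' @export
print.basin_summary <- function(x, ...) {
  cat("Basin summary '", x$basin, "': ", nrow(x$species),
      " species, ", nrow(x$families), " families\n", sep = "")
  if (length(x$excluded_species))
    cat("  excluded (ineligible):",
        paste(x$excluded_species, collapse = ", "), "\n")
  cat("\nModel roster:\n")
  print(x$fits, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Replicated synthetic two-basin contrast experiment
#'
#' Runs the full pipeline end to end on `n_rep` independent realizations of
#' the synthetic two-basin design (seascape, genotypes, communities,
#' distances, all MLPE hypotheses per basin) and stacks the model rosters.
#' This is the package's own study-scale validation: with default
#' configuration the spread basin should show significant positive genetic
#' isolation by distance, while the compact basin should show species — but
#' not genetic — isolation by distance.
#'
#' @param n_rep number of replicates (default 20).
#' @param seed master seed; replicate `r` derives its own stream seed.
#' @param cfg_fn function taking a `seed` and returning a `synth_config`;
#'   defaults to [synth_config()] with its default (study-like) settings.
#' @return data.frame: one row per replicate x basin x fitted hypothesis,
#'   with `replicate` prepended to the roster columns.
#' @export
run_synth_experiment <- function(n_rep = 20, seed = 1,
                                 cfg_fn = function(s) synth_config(seed = s)) {
  rows <- lapply(seq_len(n_rep), function(r) {
    cfg <- cfg_fn(derive_seed(seed, 7000L + r))
    sc <- simulate_seascape(cfg)
    basin_rows <- lapply(names(cfg$basins), function(bn) {
      st <- site_table(sc$sites[sc$sites$basin == bn, ])
      sg <- build_sea_graph(sc$grids[[bn]])
      d <- least_cost_distance(sg, st)
      gts <- simulate_genotypes(cfg, d, bn)
      com <- simulate_communities(cfg, d, bn)
      bs <- run_basin(gts, com, st, d)
      bs$fits
    })
    cbind(replicate = r, do.call(rbind, basin_rows))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled two-ocean reef fish beta-diversity summary
#'
#' Published per-species genetic beta-diversity (overall G''ST of 19
#' genotyped reef fish species) and per-family Jaccard partition (5 families
#' in each of two ocean basins, Caribbean Sea and Western Indian Ocean),
#' shipped as an example dataset for the summary-stage functions.
#'
#' @return list of two data.frames: `species`
#'   (`species,family,ocean,n_individuals,beta_gd`) and `families`
#'   (`family,ocean,n_species,beta_jac,beta_jtu,beta_jne`).
#' @export
reef_summary <- function() {
  dir <- system.file("extdata", package = "reefscape")
  list(species = utils::read.csv(file.path(dir, "reef_species_beta.csv"),
                                 stringsAsFactors = FALSE),
       families = utils::read.csv(file.path(dir, "reef_family_beta.csv"),
                                  stringsAsFactors = FALSE))
}
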