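#' Stack pairwise matrices into a long-form pair table
#'
#' Combines one response `pairwise_matrix` per group (species or family)
#' with a shared predictor matrix into the long format the MLPE model
#' consumes: one row per group x unordered site pair. Cells that are `NA`
#' or infinite in either matrix are dropped with a message reporting the
#' count.
#'
#' @param response_matrices named list of `pairwise_matrix`, one per group.
#' @param predictor_matrix `pairwise_matrix` on the same site set.
#' @param group_ids group labels; defaults to `names(response_matrices)`.
#' @return data.frame of class `pair_table` with columns
#'   `group`, `site_i`, `site_j`, `response`, `predictor`.
#' @export
build_pair_table <- function(response_matrices, predictor_matrix,
                             group_ids = names(response_matrices)) {
  if (is.null(group_ids) || any(!nzchar(group_ids)))
    stop("response_matrices must be named (or group_ids given)")
  ids <- rownames(response_matrices[[1]])
  miss <- setdiff(ids, rownames(predictor_matrix))
  if (length(miss))
    stop("predictor matrix is missing site(s): ", paste(miss, collapse = ", "))
  pr <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  rows <- lapply(seq_along(response_matrices), function(g) {
    rm_ <- response_matrices[[g]]
    if (!identical(rownames(rm_), ids))
      stop("response matrices have mismatched site sets")
    data.frame(group = group_ids[g],
               site_i = ids[pr[, 1]], site_j = ids[pr[, 2]],
               response = rm_[pr],
               predictor = predictor_matrix[ids, ids][pr],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- is.finite(out$response) & is.finite(out$predictor)
  if (any(!keep))
    message("build_pair_table: dropped ", sum(!keep),
            " row(s) with undefined cells")
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_table", "data.frame")
  out
}

# Sharing-structure matrices for the MLPE covariance:
#   S[p,q] = 1 when rows p,q are distinct pairs of the same group sharing
#            exactly one site;
#   G[p,q] = 1 when rows p,q belong to the same group (random intercept).
mlpe_structure <- function(group, site_i, site_j) {
  n <- length(group)
  S <- matrix(0, n, n)
  G <- matrix(0, n, n)
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    if (group[p] != group[q]) next
    G[p, q] <- G[q, p] <- 1
    shared <- length(intersect(c(site_i[p], site_j[p]),
                               c(site_i[q], site_j[q])))
    if (shared == 1) S[p, q] <- S[q, p] <- 1
  }
  diag(G) <- 1
  list(S = S, G = G)
}

# Profiled (negative) log-likelihood machinery. W = I + rho*S + lambda*G is
# the scaled covariance; sigma^2 and beta are profiled out in closed form.
mlpe_profile <- function(rho, lambda, X, y, S, G, reml = TRUE) {
  n <- length(y); p <- ncol(X)
  W <- diag(n) + rho * S + lambda * G
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE, nll = 1e10))
  logdetW <- 2 * sum(log(diag(ch)))
  Wi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Wi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtWiX <- crossprod(X, Wi_X)
  beta <- solve(XtWiX, crossprod(X, Wi_y))
  r <- y - X %*% beta
  Wi_r <- backsolve(ch, forwardsolve(t(ch), r))
  q <- drop(crossprod(r, Wi_r))
  if (reml) {
    df <- n - p
    sigma2 <- q / df
    ll <- -0.5 * (df * log(2 * pi * sigma2) + logdetW +
                    determinant(XtWiX, logarithm = TRUE)$modulus + df)
  } else {
    sigma2 <- q / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + logdetW + n)
  }
  list(ok = TRUE, nll = -drop(ll), loglik = drop(ll), beta = drop(beta),
       sigma2 = sigma2, XtWiX = XtWiX, chol_W = ch)
}

#' Fit a maximum-likelihood population-effects (MLPE) mixed model
#'
#' Regression for stacked pairwise (distance-matrix) data:
#' \deqn{y_{g,ij} = \alpha + \beta x_{g,ij} + u_g + \varepsilon_{g,ij}}
#' with a random intercept \eqn{u_g \sim N(0, \sigma^2_u)} per group
#' (species or family) and, within a group, correlated residuals
#' \eqn{corr(\varepsilon_{p}, \varepsilon_{q}) = \rho} exactly when the two
#' site pairs share one site (the population-effect structure of Clarke et
#' al. that accounts for the non-independence of pairwise observations).
#' Fitted by restricted maximum likelihood (default) through profile
#' optimization over \eqn{(\rho, \lambda = \sigma^2_u/\sigma^2_\varepsilon)};
#' \eqn{\rho} is constrained to \eqn{[0, 0.5)}, on which the sharing
#' correlation matrix is positive definite for these designs. The covariance
#' is assembled densely; designs here are small.
#'
#' Wald inference on the slope uses
#' \eqn{df = n_{pairs} - n_{groups} - 1} (recorded in the fit).
#'
#' @param formula model formula, e.g. `response ~ predictor`.
#' @param data data.frame (typically a [build_pair_table()] result) with the
#'   model variables plus group and site-pair columns.
#' @param group name of the grouping column (default `"group"`).
#' @param sites names of the two site columns
#'   (default `c("site_i", "site_j")`).
#' @param method `"REML"` (default) or `"ML"`.
#' @param use_random_intercept fit \eqn{\sigma^2_u}? With fewer than 2
#'   groups the model degrades automatically to the no-random-intercept MLPE
#'   with a warning.
#' @param fix_rho optional fixed value for \eqn{\rho} instead of profiling
#'   it; `fix_rho = 0` together with `use_random_intercept = FALSE` reduces
#'   the estimator to ordinary least squares.
#' @return object of class `mlpe`: coefficients, `rho`, variance components
#'   `sigma2_u`/`sigma2_e`, log-likelihood, Wald table, convergence and
#'   boundary flags.
#' @seealso [r2_nakagawa()], [fit_mlpe()]
#' @examples
#' d <- data.frame(group = rep("sp1", 6),
#'                 site_i = c("A","A","A","B","B","C"),
#'                 site_j = c("B","C","D","C","D","D"),
#'                 predictor = c(1, 2, 3, 1.5, 2.5, 1),
#'                 response = c(.1, .2, .32, .15, .27, .12))
#' fit <- mlpe(response ~ predictor, d)
#' summary(fit)
#' @export
mlpe <- function(formula, data, group = "group",
                 sites = c("site_i", "site_j"), method = c("REML", "ML"),
                 use_random_intercept = TRUE, fix_rho = NULL) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (any(!is.finite(y))) stop("non-finite responses")
  X <- stats::model.matrix(formula, mf)
  grp <- as.character(data[[group]])
  si <- as.character(data[[sites[1]]]); sj <- as.character(data[[sites[2]]])
  if (any(si == sj)) stop("self-pairs (site_i == site_j) are not allowed")
  n_groups <- length(unique(grp))
  if (use_random_intercept && n_groups < 2L) {
    warning("fewer than 2 groups: dropping the random intercept")
    use_random_intercept <- FALSE
  }
  str_ <- mlpe_structure(grp, si, sj)

  if (!is.null(fix_rho) && (fix_rho < 0 || fix_rho >= 0.5))
    stop("fix_rho must lie in [0, 0.5)")
  obj <- function(par) {
    rho <- if (is.null(fix_rho)) 0.5 * stats::plogis(par[1]) else fix_rho
    lambda <- if (use_random_intercept) exp(par[length(par)]) else 0
    mlpe_profile(rho, lambda, X, y, str_$S, str_$G, method == "REML")$nll
  }
  if (is.null(fix_rho) && use_random_intercept) {
    starts <- list(c(0, -1), c(-2, 1), c(1, -4))
    fits <- lapply(starts, function(s)
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)))
    best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    rho <- 0.5 * stats::plogis(best$par[1])
    lambda <- exp(best$par[2])
    converged <- best$convergence == 0
  } else if (is.null(fix_rho) || use_random_intercept) {
    # one free parameter: either rho or lambda
    op <- stats::optimize(function(t) obj(t), interval = c(-25, 15),
                          tol = 1e-12)
    if (is.null(fix_rho)) {
      rho <- 0.5 * stats::plogis(op$minimum); lambda <- 0
    } else {
      rho <- fix_rho; lambda <- exp(op$minimum)
    }
    converged <- TRUE
  } else {
    rho <- fix_rho; lambda <- 0; converged <- TRUE
  }
  prof <- mlpe_profile(rho, lambda, X, y, str_$S, str_$G, method == "REML")
  if (!prof$ok) stop("MLPE covariance not positive definite at the optimum")
  sigma2_e <- prof$sigma2
  sigma2_u <- lambda * sigma2_e
  vc <- sigma2_e * solve(prof$XtWiX)
  se <- sqrt(diag(vc))
  df <- length(y) - n_groups - 1
  tval <- stats::setNames(prof$beta / se, colnames(X))
  pval <- 2 * stats::pt(-abs(tval), df)
  boundary <- use_random_intercept && lambda < 1e-6
  fit <- structure(list(
    coefficients = stats::setNames(prof$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)), vcov = vc,
    rho = rho, sigma2_u = sigma2_u, sigma2_e = sigma2_e,
    logLik = prof$loglik, method = method, df_wald = df,
    t_value = tval, p_value = stats::setNames(pval, colnames(X)),
    n = length(y), n_groups = n_groups,
    use_random_intercept = use_random_intercept,
    converged = converged, boundary_sigma2_u = boundary,
    formula = formula, X = X, y = y, group = grp,
    site_i = si, site_j = sj, S = str_$S, G = str_$G,
    call = match.call()),
    class = "mlpe")
  if (!converged)
    warning("MLPE optimizer did not report convergence; ",
            "inspect fit$converged and the profile surface")
  fit
}

#' Spec-style wrapper: fit an MLPE model to a pair table
#'
#' Thin wrapper over [mlpe()] using the standard `pair_table` columns
#' (`response ~ predictor`, grouping column `group`).
#'
#' @param pairs `pair_table` from [build_pair_table()].
#' @param use_random_intercept logical (default TRUE).
#' @param method `"REML"` or `"ML"`.
#' @return `mlpe` fit.
#' @export
fit_mlpe <- function(pairs, use_random_intercept = TRUE, method = "REML") {
  mlpe(response ~ predictor, pairs, method = method,
       use_random_intercept = use_random_intercept)
}

#' Profiled log-likelihood of an MLPE fit at given correlation parameters
#'
#' Re-evaluates the (restricted) log-likelihood of a fitted model at
#' arbitrary \eqn{\rho} and \eqn{\lambda = \sigma^2_u/\sigma^2_\varepsilon},
#' profiling \eqn{\beta} and \eqn{\sigma^2_\varepsilon} out. Useful for
#' verifying that the optimizer reached a no-worse point than any candidate.
#'
#' @param object `mlpe` fit.
#' @param rho residual correlation in `[0, 0.5)`.
#' @param lambda variance ratio `sigma2_u / sigma2_e`.
#' @return log-likelihood value.
#' @export
mlpe_loglik_at <- function(object, rho,
                           lambda = object$sigma2_u / object$sigma2_e) {
  pr <- mlpe_profile(rho, lambda, object$X, object$y, object$S, object$G,
                     object$method == "REML")
  if (!pr$ok) return(-Inf)
  pr$loglik
}

#' Marginal and conditional R-squared (Nakagawa-Schielzeth)
#'
#' \deqn{R^2_m = \frac{\sigma^2_f}{\sigma^2_f + \sigma^2_u +
#'   \sigma^2_\varepsilon}, \qquad
#'   R^2_c = \frac{\sigma^2_f + \sigma^2_u}{\sigma^2_f + \sigma^2_u +
#'   \sigma^2_\varepsilon}}
#' where \eqn{\sigma^2_f} is the variance of the fixed-effect linear
#' predictor over the data.
#'
#' @param fit `mlpe` object.
#' @return named numeric vector `c(R2m, R2c)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "mlpe"))
  eta <- drop(fit$X %*% fit$coefficients)
  s2f <- stats::var(eta) * (length(eta) - 1) / length(eta)
  tot <- s2f + fit$sigma2_u + fit$sigma2_e
  c(R2m = s2f / tot, R2c = (s2f + fit$sigma2_u) / tot)
}

#' @export
print.mlpe <- function(x, ...) {
  cat("MLPE linear mixed model (", x$method, ")\n", sep = "")
  cat("  ", x$n, "pairs,", x$n_groups, "group(s)\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  rho = %.3f  sigma2_u = %.3g  sigma2_e = %.3g\n",
              x$rho, x$sigma2_u, x$sigma2_e))
  invisible(x)
}

#' @export
summary.mlpe <- function(object, ...) {
  coefs <- cbind(Estimate = object$coefficients,
                 `Std. Error` = object$se,
                 `t value` = object$t_value,
                 `Pr(>|t|)` = object$p_value)
  r2 <- r2_nakagawa(object)
  out <- list(coefficients = coefs, rho = object$rho,
              sigma2_u = object$sigma2_u, sigma2_e = object$sigma2_e,
              logLik = object$logLik, method = object$method,
              df_wald = object$df_wald, R2m = r2["R2m"], R2c = r2["R2c"],
              n = object$n, n_groups = object$n_groups,
              boundary = object$boundary_sigma2_u)
  class(out) <- "summary.mlpe"
  out
}

#' @export
print.summary.mlpe <- function(x, ...) {
  cat("MLPE linear mixed model (", x$method, "); ", x$n, " pairs, ",
      x$n_groups, " group(s)\n\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf(
    "\nrho = %.4f   sigma2_u = %.4g   sigma2_e = %.4g   (Wald df = %d)\n",
    x$rho, x$sigma2_u, x$sigma2_e, x$df_wald))
  cat(sprintf("logLik = %.4f   R2m = %.3f   R2c = %.3f\n",
              x$logLik, x$R2m, x$R2c))
  if (x$boundary)
    cat("note: sigma2_u at the zero boundary (weakly identified design)\n")
  invisible(x)
}

#' @export
coef.mlpe <- function(object, ...) object$coefficients

#' @export
vcov.mlpe <- function(object, ...) object$vcov

#' @export
logLik.mlpe <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coefficients) + 2 +
              as.integer(object$use_random_intercept),
            class = "logLik")
}

#' @export
predict.mlpe <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(drop(object$X %*% object$coefficients))
  X <- stats::model.matrix(stats::delete.response(stats::terms(
    object$formula)), newdata)
  drop(X %*% object$coefficients)
}

#' @export
residuals.mlpe <- function(object, ...) {
  drop(object$y - object$X %*% object$coefficients)
}

#' @export
fitted.mlpe <- function(object, ...) predict(object)

#' Simulate responses from a fitted MLPE model
#'
#' Draws from \eqn{N(X\hat\beta,\; \hat\sigma^2_\varepsilon(I + \hat\rho S) +
#' \hat\sigma^2_u G)} with the fitted sharing structure.
#'
#' @param object `mlpe` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.mlpe <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  V <- object$sigma2_e * (diag(n) + object$rho * object$S) +
    object$sigma2_u * object$G
  L <- chol(V)
  mu <- drop(object$X %*% object$coefficients)
  out <- as.data.frame(mu + t(L) %*% matrix(stats::rnorm(n * nsim), n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.mlpe <- function(x, ...) {
  pred_col <- colnames(x$X)[colnames(x$X) != "(Intercept)"][1]
  xv <- x$X[, pred_col]
  graphics::plot(xv, x$y, xlab = pred_col, ylab = "response",
                 col = as.integer(factor(x$group)), pch = 19, ...)
  o <- order(xv)
  graphics::lines(xv[o], predict(x)[o], lwd = 2)
  invisible(x)
}
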