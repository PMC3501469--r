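# Maximum-likelihood fitting of CJS models, delta-method real-scale
# estimates, and the terminal-occasion confounding diagnostic.

#' Fit a CJS model
#'
#' Quasi-Newton (BFGS) maximization from a beta = 0 start (real scale 0.5),
#' with jittered restarts on non-convergence. The variance-covariance
#' matrix is the inverse numerical Hessian at the optimum; real-scale
#' estimates use the inverse-logit link with delta-method standard errors,
#' evaluated at the standardized-covariate mean. When the terminal
#' detection probability is not fixed, the last segment's survival is
#' flagged as confounded (only the product phi_T * p_T is identifiable).
#'
#' @param spec model string or [parse_model_spec()] result
#' @param eh [encounter_histories()]
#' @param c_hat variance inflation factor; real-scale SEs are multiplied by
#'   sqrt(c_hat) when c_hat > 1
#' @param max_restarts jittered restarts allowed on non-convergence
#' @return a `cjs_fit` object
#' @export
cjs_fit <- function(spec, eh, c_hat = 1, max_restarts = 3L) {
  design <- build_design(spec, eh)
  if (sum(eh$history[, -1]) == 0) {
    stop("no detections beyond release; nothing to fit", call. = FALSE)
  }
  nb <- design$n_beta
  coll <- collapse_for_fit(design, eh)
  fn <- function(b) cjs_negloglik(b, coll$design, coll$eh, coll$weights)
  start <- rep(0, nb)
  best <- NULL
  for (try in 0:max_restarts) {
    opt <- stats::optim(start, fn, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0 && is.finite(opt$value)) break
    start <- stats::rnorm(nb, 0, 0.5)
  }
  hess <- tryCatch(stats::optimHess(best$par, fn), error = function(e) NULL)
  vcov <- if (!is.null(hess)) {
    tryCatch(solve(hess), error = function(e) NULL)
  }
  se_ok <- !is.null(vcov) && all(is.finite(diag(vcov))) &&
    all(diag(vcov) > -1e-8)
  terminal_confounded <- is.na(design$fixed_p[1, design$T_occ])
  fit <- structure(list(
    spec = design$spec, design = design, eh = eh,
    beta = best$par, vcov = vcov,
    loglik = -best$value,
    K = design$K, n_beta = design$n_beta,
    n_released = nrow(eh$history),
    c_hat = c_hat,
    converged = best$convergence == 0,
    se_available = se_ok,
    terminal_confounded = terminal_confounded
  ), class = "cjs_fit")
  fit$real_phi <- real_estimates(fit, "phi")
  fit$real_p <- real_estimates(fit, "p")
  fit
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("CJS fit:", x$spec$string, "\n")
  cat(sprintf("  logLik %.3f  K %d  (estimated betas %d)  converged %s\n",
              x$loglik, x$K, x$n_beta, x$converged))
  if (x$terminal_confounded) {
    cat("  note: terminal p not fixed; last-segment phi confounded\n")
  }
  cat("survival (phi):\n"); print(x$real_phi, digits = 3)
  cat("detection (p):\n"); print(x$real_p, digits = 3)
  invisible(x)
}

# newdata grid of distinct factor-cell combinations for a parameter, with
# standardized covariates at 0 (their mean)
cell_grid <- function(design, par = c("phi", "p")) {
  par <- match.arg(par)
  long <- if (par == "phi") design$long_phi else design$long_p
  form <- if (par == "phi") design$spec$phi_formula else design$spec$p_formula
  vars <- intersect(all.vars(form), names(long))
  fvars <- unique(c("segment", vars[vapply(long[vars], is.factor, logical(1))]))
  cvars <- setdiff(vars, fvars)
  grid <- unique(long[, fvars, drop = FALSE])
  grid <- grid[do.call(order, grid), , drop = FALSE]
  for (v in cvars) grid[[v]] <- 0
  rownames(grid) <- NULL
  grid
}

#' Real-scale estimates on a cell grid
#'
#' @param fit a [cjs_fit()]
#' @param par `"phi"` or `"p"`
#' @param newdata optional data.frame of cells; defaults to every distinct
#'   factor combination observed, covariates at their (standardized) mean
#' @return data.frame of cells with `estimate`, `se`, `fixed`
#' @export
real_estimates <- function(fit, par = c("phi", "p"), newdata = NULL) {
  par <- match.arg(par)
  design <- fit$design
  if (is.null(newdata)) newdata <- cell_grid(design, par)
  form <- if (par == "phi") design$spec$phi_formula else design$spec$p_formula
  full <- if (par == "phi") design$X_phi else design$X_p
  est_cols <- if (par == "phi") design$est_phi else design$est_p
  off <- if (par == "phi") 0L else length(design$est_phi)
  # rebuild rows with the same column set as the training design
  long <- if (par == "phi") design$long_phi else design$long_p
  for (v in setdiff(all.vars(form), names(newdata))) newdata[[v]] <- long[[v]][1]
  X <- stats::model.matrix(form, newdata)
  X <- X[, colnames(full), drop = FALSE]
  Xe <- X[, est_cols, drop = FALSE]
  beta <- fit$beta[off + seq_along(est_cols)]
  eta <- as.vector(Xe %*% beta)
  est <- stats::plogis(eta)
  infl <- sqrt(max(fit$c_hat, 1))
  se <- rep(NA_real_, length(eta))
  if (fit$se_available) {
    V <- fit$vcov[off + seq_along(est_cols), off + seq_along(est_cols),
                  drop = FALSE]
    var_eta <- rowSums((Xe %*% V) * Xe)
    se <- stats::dlogis(eta) * sqrt(pmax(var_eta, 0)) * infl
  }
  out <- cbind(newdata, estimate = est, se = se, fixed = FALSE)
  # overwrite cells pinned by fix clauses
  fixed_occ <- if (par == "p") design$fixed_p[1, ] else design$fixed_phi[1, ]
  cells <- if (par == "p") OCCASION_LINES[seq_len(design$T_occ)]
           else SEGMENT_NAMES[seq_len(design$T_occ)]
  for (k in which(!is.na(fixed_occ))) {
    sel <- out$segment == cells[k]
    out$estimate[sel] <- fixed_occ[k]
    out$se[sel] <- NA_real_
    out$fixed[sel] <- TRUE
  }
  if (par == "phi" && fit$terminal_confounded) {
    out$confounded <- out$segment == SEGMENT_NAMES[design$T_occ]
  }
  rownames(out) <- NULL
  out
}

#' Terminal-occasion confounding diagnostic
#'
#' In a CJS model the last segment's survival and the last occasion's
#' detection probability enter the likelihood only through their product,
#' so without a fixed terminal p the likelihood is flat along the
#' compensating ridge. This evaluates the fitted likelihood over
#' compensating (phi_T, p_T) pairs holding the product at its MLE value and
#' reports the likelihood variation along the ridge.
#'
#' @param fit a [cjs_fit()]
#' @param ridge_points interpolation points t in (0, 1); the terminal phi
#'   is placed at product + t (1 - product), which keeps the compensating
#'   p = product / phi inside (0, 1]
#' @return list with `identifiable_product`, `ridge_range` (max - min
#'   negative log-likelihood along the ridge), and `confounded` (TRUE when
#'   the ridge is flat to numerical tolerance)
#' @export
profile_confounding <- function(fit, ridge_points = seq(0.1, 0.9, by = 0.1)) {
  design <- fit$design
  real <- design_to_real(design, fit$beta)
  Tc <- design$T_occ
  hist <- fit$eh$history[, -1, drop = FALSE]
  base <- cjs_negloglik_real(real$phi, real$p, hist)
  prod_T <- real$phi[, Tc] * real$p[, Tc]
  nlls <- vapply(ridge_points, function(t) {
    phi2 <- real$phi; p2 <- real$p
    phi2[, Tc] <- prod_T + t * (1 - prod_T)
    if (!is.na(design$fixed_p[1, Tc])) {
      # terminal p pinned: no compensation possible, likelihood must move
      p2[, Tc] <- design$fixed_p[1, Tc]
    } else {
      p2[, Tc] <- prod_T / phi2[, Tc]
    }
    cjs_negloglik_real(phi2, p2, hist)
  }, numeric(1))
  ridge <- max(nlls) - min(nlls)
  list(identifiable_product = mean(prod_T),
       base_nll = base, ridge_nll = nlls, ridge_points = ridge_points,
       ridge_range = ridge,
       confounded = ridge < 1e-6)
}
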