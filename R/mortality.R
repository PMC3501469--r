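# Cumulative marine survival, distance-scaled instantaneous mortality, and
# the fixed-terminal-p sensitivity range. Mortality is expressed per km of
# corridor rather than per unit time: smolts cover similar distances at
# variable speeds, so M = -ln(phi_ps) / d_s, the exponential-decay rate
# implied by survival phi over a segment of length d.

#' Cumulative survival over segments
#'
#' @param segment_phis vector of per-segment survival probabilities in
#'   (0, 1]; an empty vector returns 1 by convention
#' @return the product of segment survivals
#' @export
cumulative_survival <- function(segment_phis) {
  if (!length(segment_phis)) return(1)
  if (any(segment_phis <= 0) || any(segment_phis > 1)) {
    stop("segment survivals must lie in (0, 1]", call. = FALSE)
  }
  prod(segment_phis)
}

#' Distance-scaled instantaneous mortality rate
#'
#' M = -ln(phi) / d per kilometre. M = 0 iff phi = 1; phi = 0 yields an
#' infinite rate (flagged), and phi > 1 is a domain error.
#'
#' @param phi segment survival probability in \[0, 1\]
#' @param distance_km segment length d_s (> 0)
#' @return data.frame with `phi`, `distance_km`, `M_per_km`, `infinite`
#' @export
instantaneous_mortality <- function(phi, distance_km) {
  if (any(distance_km <= 0)) stop("distance_km must be positive", call. = FALSE)
  if (any(phi > 1) || any(phi < 0)) {
    stop("phi must lie in [0, 1]", call. = FALSE)
  }
  M <- ifelse(phi == 0, Inf, -log(phi) / distance_km)
  data.frame(phi = phi, distance_km = distance_km, M_per_km = M,
             infinite = !is.finite(M))
}

marine_segments <- function(T_occ = 4L) SEGMENT_NAMES[2:T_occ]

#' Per-group cumulative marine survival from a fitted model
#'
#' Multiplies the real-scale marine segment survivals (all segments after
#' the freshwater PR-RM segment) within each group cell of the fitted
#' model, with a delta-method standard error computed on the log scale
#' from the fit's coefficient covariance.
#'
#' @param fit a [cjs_fit()]
#' @return data.frame of group cells with `marine_survival` and `se`
#' @export
marine_survival <- function(fit) {
  design <- fit$design
  grid <- cell_grid(design, "phi")
  groups <- grid[grid$segment == SEGMENT_NAMES[1],
                 setdiff(names(grid), "segment"), drop = FALSE]
  if (!ncol(groups)) groups <- data.frame(row.names = 1)
  segs <- marine_segments(design$T_occ)
  form <- design$spec$phi_formula
  long <- design$long_phi
  est_cols <- design$est_phi
  beta <- fit$beta[seq_along(est_cols)]
  V <- if (fit$se_available) {
    fit$vcov[seq_along(est_cols), seq_along(est_cols), drop = FALSE]
  }
  out <- groups
  out$marine_survival <- NA_real_
  out$se <- NA_real_
  for (g in seq_len(max(nrow(groups), 1L))) {
    nd <- groups[rep(g, length(segs)), , drop = FALSE]
    nd$segment <- factor(segs, levels = levels(long$segment))
    for (v in setdiff(all.vars(form), names(nd))) nd[[v]] <- long[[v]][1]
    X <- stats::model.matrix(form, nd)[, colnames(design$X_phi), drop = FALSE]
    Xe <- X[, est_cols, drop = FALSE]
    phi <- stats::plogis(as.vector(Xe %*% beta))
    P <- prod(phi)
    out$marine_survival[g] <- P
    if (!is.null(V)) {
      grad <- colSums((1 - phi) * Xe)   # d log P / d beta
      se_log <- sqrt(max(0, as.numeric(t(grad) %*% V %*% grad)))
      out$se[g] <- P * se_log * sqrt(max(fit$c_hat, 1))
    }
  }
  rownames(out) <- NULL
  out
}

#' Sensitivity of survival to the fixed terminal detection probability
#'
#' Refits the model with the terminal occasion's detection probability
#' pinned at each supplied value and reports the per-group cumulative
#' marine survival for each, plus the min/max envelope. Survival decreases
#' monotonically as the assumed terminal p increases (a higher assumed
#' detection rate means the missing fish are more likely dead).
#'
#' @param spec model string WITHOUT a terminal fix clause (one is added per
#'   value), or a `model_spec`
#' @param eh [encounter_histories()]
#' @param p_values fixed terminal detection probabilities to sweep
#' @param c_hat variance inflation passed through to the fits
#' @return list with `by_p` (per-value group tables) and `range` (per-group
#'   min/max marine survival)
#' @export
sensitivity_range <- function(spec, eh,
                              p_values = c(0.428, 0.685, 0.863),
                              c_hat = 1) {
  base <- if (inherits(spec, "model_spec")) spec$string else spec
  base <- trimws(sub("fix\\s+p\\s*\\[\\s*JDF\\s*\\][^;]*;?", "", base))
  base <- sub(";\\s*$", "", base)
  term <- OCCASION_LINES[ncol(eh$history) - 1L]
  by_p <- lapply(p_values, function(v) {
    f <- cjs_fit(sprintf("%s; fix p[%s]=%g", base, term, v), eh,
                 c_hat = c_hat)
    cbind(marine_survival(f), fixed_p = v, converged = f$converged)
  })
  names(by_p) <- paste0("p=", p_values)
  surv <- vapply(by_p, function(d) d$marine_survival, by_p[[1]]$marine_survival)
  surv <- matrix(surv, nrow = nrow(by_p[[1]]))
  rng <- by_p[[1]][, setdiff(names(by_p[[1]]),
                             c("marine_survival", "se", "fixed_p",
                               "converged")), drop = FALSE]
  rng$min <- apply(surv, 1, min)
  rng$max <- apply(surv, 1, max)
  list(by_p = by_p, range = rng)
}

#' Distance-scaled mortality table
#'
#' Converts a long table of per-(population, year, segment) survival into
#' instantaneous mortality per km using each population's segment
#' distances.
#'
#' @param phi_table data.frame with columns `population`, `year`,
#'   `segment`, `phi`
#' @param geometries named list of [segment_geometry()] per population;
#'   defaults to [default_geometry()] for each population present
#' @return the input with `distance_km` and `M_per_km` appended
#' @export
mortality_rate_table <- function(phi_table, geometries = NULL) {
  req <- c("population", "year", "segment", "phi")
  stopifnot(all(req %in% names(phi_table)))
  pops <- unique(as.character(phi_table$population))
  if (is.null(geometries)) {
    geometries <- stats::setNames(lapply(pops, default_geometry), pops)
  }
  d <- mapply(function(pop, seg) {
    g <- geometries[[pop]]$segments
    idx <- match(seg, paste(g$from_line, g$to_line, sep = "-"))
    if (is.na(idx)) stop("no distance configured for segment ", seg,
                         " of population ", pop, call. = FALSE)
    g$distance_km[idx]
  }, as.character(phi_table$population), as.character(phi_table$segment))
  out <- phi_table
  out$distance_km <- as.numeric(d)
  out$M_per_km <- ifelse(out$phi == 0, Inf, -log(out$phi) / out$distance_km)
  out
}
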