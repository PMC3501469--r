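# CJS likelihood. The probability of a history factorizes into the
# survival/detection products up to the last detection and the recursive
# never-seen-again tail
#   chi_T = 1,  chi_k = (1 - phi_{k+1}) + phi_{k+1} (1 - p_{k+1}) chi_{k+1}
# so that P(history) = prod_{k<=l} phi_k p_k^{y_k} (1-p_k)^{1-y_k} * chi_l
# where l is the last detection occasion (l = 0 for never-detected fish).

#' CJS negative log-likelihood from real-scale parameter matrices
#'
#' @param phi n x T matrix of per-fish, per-segment survival probabilities
#' @param p n x T matrix of per-fish, per-occasion detection probabilities
#' @param hist n x T 0/1 detection matrix (release column excluded)
#' @param weights optional per-fish multiplicities
#' @return the negative log-likelihood (a single number)
#' @export
cjs_negloglik_real <- function(phi, p, hist, weights = NULL) {
  n <- nrow(hist); T_occ <- ncol(hist)
  stopifnot(all(dim(phi) == c(n, T_occ)), all(dim(p) == c(n, T_occ)))
  if (is.null(weights)) weights <- rep(1, n)
  # chi[, k+1] = P(never seen after occasion k), k = 0..T
  chi <- matrix(1, n, T_occ + 1L)
  for (k in seq(T_occ - 1L, 0L)) {
    chi[, k + 1L] <- (1 - phi[, k + 1L]) +
      phi[, k + 1L] * (1 - p[, k + 1L]) * chi[, k + 2L]
  }
  logterm <- log(phi) + hist * log(p) + (1 - hist) * log1p(-p)
  logterm[hist == 1 & p == 1] <- log(phi)[hist == 1 & p == 1] # 1*log(1) guard
  cum <- logterm
  if (T_occ > 1) for (k in 2:T_occ) cum[, k] <- cum[, k] + cum[, k - 1L]
  # last detection occasion per fish (0 if never detected)
  rev_first <- max.col(hist[, T_occ:1, drop = FALSE], ties.method = "first")
  last <- ifelse(rowSums(hist) > 0, T_occ - rev_first + 1L, 0L)
  ll <- ifelse(last > 0L, cum[cbind(seq_len(n), pmax(last, 1L))], 0) +
    log(chi[cbind(seq_len(n), last + 1L)])
  -sum(weights * ll)
}

#' CJS negative log-likelihood at a coefficient vector
#'
#' Maps the free coefficients through the logit link and the design
#' matrices, applies fixed cells, and evaluates [cjs_negloglik_real()].
#' Non-finite coefficients return a large penalty rather than crashing the
#' optimizer.
#'
#' @param beta free-coefficient vector (phi block then p block)
#' @param design a [build_design()] result
#' @param eh [encounter_histories()] the design was built from
#' @param weights optional per-fish multiplicities
#' @return negative log-likelihood
#' @export
cjs_negloglik <- function(beta, design, eh, weights = NULL) {
  if (any(!is.finite(beta))) return(1e10)
  real <- design_to_real(design, beta)
  hist <- eh$history[, -1, drop = FALSE]
  nll <- cjs_negloglik_real(real$phi, real$p, hist, weights)
  if (!is.finite(nll)) 1e10 else nll
}

# collapse fish with identical design rows and histories to weighted
# representatives; leaves estimates and the likelihood value unchanged
collapse_for_fit <- function(design, eh) {
  n <- design$n_fish; T_occ <- design$T_occ
  block <- function(X) {
    apply(matrix(t(X), nrow = n, byrow = TRUE), 1, paste, collapse = ",")
  }
  key <- paste(block(design$X_phi[, design$est_phi, drop = FALSE]),
               block(design$X_p[, design$est_p, drop = FALSE]),
               apply(eh$history, 1, paste, collapse = ""))
  idx <- which(!duplicated(key))
  if (length(idx) > 0.8 * n) {
    return(list(design = design, eh = eh, weights = NULL))
  }
  w <- as.vector(table(factor(key, levels = key[idx])))
  rows <- as.vector(t(outer(idx - 1L, seq_len(T_occ), function(i, k)
    i * T_occ + k)))
  d2 <- design
  d2$X_phi <- design$X_phi[rows, , drop = FALSE]
  d2$X_p <- design$X_p[rows, , drop = FALSE]
  d2$fixed_phi <- design$fixed_phi[idx, , drop = FALSE]
  d2$fixed_p <- design$fixed_p[idx, , drop = FALSE]
  d2$n_fish <- length(idx)
  eh2 <- eh
  eh2$history <- eh$history[idx, , drop = FALSE]
  list(design = d2, eh = eh2, weights = w)
}
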