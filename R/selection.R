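# Goodness-of-fit and quasi-likelihood model selection: reduced m-array,
# contingency-table GOF components in the style of program RELEASE's TEST2
# and TEST3, variance inflation c-hat, QAICc, and model ranking with
# Akaike weights.

#' Build the reduced m-array
#'
#' Release occasion i (0 = the physical release; detected fish are treated
#' as re-released) contributes R_i animals; m_ij counts those next detected
#' at occasion j > i, and `never` the remainder. Row sums conserve R_i.
#'
#' @param eh [encounter_histories()]
#' @param grouping optional column of `eh$records` to split by
#' @return an `marray` object (or named list of them when grouped); the
#'   histories are retained as an attribute for goodness-of-fit tests
#' @export
build_marray <- function(eh, grouping = NULL) {
  if (!is.null(grouping)) {
    grp <- eh$records[[grouping]]
    out <- lapply(split(seq_len(nrow(eh$history)), grp), function(idx) {
      build_marray(encounter_histories(eh$history[idx, , drop = FALSE],
                                       eh$records[idx, , drop = FALSE],
                                       eh$occasions))
    })
    return(out)
  }
  h <- eh$history
  T1 <- ncol(h) # occasions including release (index 0..T)
  m <- matrix(0L, T1 - 1L, T1 - 1L,
              dimnames = list(release = colnames(h)[-T1],
                              next_detection = colnames(h)[-1]))
  R <- integer(T1 - 1L)
  for (i in seq_len(T1 - 1L)) {       # release occasion index i-1
    released <- which(h[, i] == 1L)
    R[i] <- length(released)
    if (!length(released)) next
    nxt <- apply(h[released, (i + 1L):T1, drop = FALSE], 1, function(y) {
      w <- which(y == 1L); if (length(w)) min(w) else NA_integer_
    })
    tab <- table(factor(nxt + i - 1L, levels = seq_len(T1 - 1L)))
    m[i, ] <- as.integer(tab)
  }
  structure(list(R = R, m = m, never = R - rowSums(m)),
            class = "marray", histories = h)
}

#' @export
print.marray <- function(x, ...) {
  cat("m-array (releases R_i, first-next-detection counts):\n")
  print(cbind(R = x$R, x$m, never = x$never))
  invisible(x)
}

chisq_component <- function(tab, min_expected = 2) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(NULL)
  # pool adjacent columns until all expected counts reach the threshold
  repeat {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(E >= min_expected) || ncol(tab) <= 2) break
    j <- which.min(apply(E, 2, min))
    j2 <- if (j == ncol(tab)) j - 1L else j + 1L
    tab[, min(j, j2)] <- tab[, j] + tab[, j2]
    tab <- tab[, -max(j, j2), drop = FALSE]
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E < min_expected)) return(NULL) # too sparse even after pooling
  list(chi2 = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1L) * (ncol(tab) - 1L))
}

#' RELEASE-style goodness-of-fit and variance inflation
#'
#' Pools contingency-table components testing the two CJS assumptions:
#' equal future-encounter probability for animals detected now versus
#' detected later (TEST2-type tables: among animals seen again after
#' occasion k, does the next-detection occasion depend on whether they were
#' seen at k?) and no effect of past encounter history (TEST3-type tables:
#' among animals seen at k, does being seen again depend on having been
#' seen before k?). Cells are pooled until expected counts reach 2;
#' components still sparser than that are dropped. c-hat is the total
#' chi-square over total df, floored at 1 for downstream use (the unfloored
#' ratio is kept for calibration work).
#'
#' @param x an [build_marray()] result or an [encounter_histories()]
#' @return a `gof_result` list: `chi2_total`, `df_total`, `c_hat`
#'   (floored), `c_hat_raw`, `components`
#' @export
release_gof <- function(x) {
  h <- if (inherits(x, "marray")) attr(x, "histories")
       else if (inherits(x, "encounter_histories")) x$history
       else stop("need an marray or encounter_histories", call. = FALSE)
  T1 <- ncol(h)            # occasions 0..T
  comps <- list()
  next_efter <- function(rows, k) { # first detection occasion after k, NA if none
    apply(h[rows, (k + 2L):T1, drop = FALSE], 1, function(y) {
      w <- which(y == 1L); if (length(w)) min(w) + k else NA_integer_
    })
  }
  # TEST2-type: seen at k vs not, among fish seen again after k
  for (k in seq_len(T1 - 2L)) {      # occasion index k (1..T-1)
    nxt <- next_efter(seq_len(nrow(h)), k)
    seen_again <- !is.na(nxt)
    if (!any(seen_again)) next
    tab <- table(seen_at_k = h[seen_again, k + 1L],
                 next_at = factor(pmin(nxt[seen_again], k + 2L),
                                  levels = c(k + 1L, k + 2L)))
    cc <- chisq_component(tab)
    if (!is.null(cc)) comps[[paste0("TEST2.C", k)]] <- cc
  }
  # TEST3-type: seen before k (beyond release) vs not, among fish seen at k
  if (T1 >= 4L) {
    for (k in 2L:(T1 - 2L)) {
      at_k <- which(h[, k + 1L] == 1L)
      if (!length(at_k)) next
      before <- rowSums(h[at_k, 2L:k, drop = FALSE]) > 0
      nxt <- next_efter(at_k, k)
      tab <- table(seen_before = before, seen_after = !is.na(nxt))
      cc <- chisq_component(tab)
      if (!is.null(cc)) comps[[paste0("TEST3.SR", k)]] <- cc
      # among those seen again: immediately vs later
      again <- !is.na(nxt)
      if (any(again) && k <= T1 - 3L) {
        tab2 <- table(seen_before = before[again],
                      next_at = factor(pmin(nxt[again], k + 2L),
                                       levels = c(k + 1L, k + 2L)))
        cc2 <- chisq_component(tab2)
        if (!is.null(cc2)) comps[[paste0("TEST3.Sm", k)]] <- cc2
      }
    }
  }
  chi2 <- sum(vapply(comps, `[[`, numeric(1), "chi2"))
  df <- sum(vapply(comps, `[[`, numeric(1), "df"))
  raw <- if (df > 0) chi2 / df else NA_real_
  if (df == 0) warning("all GOF tables too sparse; c-hat set to 1")
  structure(list(chi2_total = chi2, df_total = df,
                 c_hat = if (df > 0) max(1, raw) else 1,
                 c_hat_raw = raw, components = comps),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("GOF: chi2 = %.3f on %d df;  c-hat = %.3f (raw %.3f)\n",
              x$chi2_total, x$df_total, x$c_hat,
              if (is.na(x$c_hat_raw)) 1 else x$c_hat_raw))
  invisible(x)
}

#' Quasi-likelihood AICc
#'
#' QAICc = -2 logLik / c-hat + 2K + 2K(K+1) / (n_eff - K - 1).
#'
#' @param loglik maximized log-likelihood
#' @param K parameter count
#' @param n_eff effective sample size (convention here: animals released)
#' @param c_hat variance inflation factor
#' @return QAICc value
#' @export
qaicc <- function(loglik, K, n_eff, c_hat = 1) {
  if (n_eff <= K + 1) {
    stop("QAICc undefined: n_eff must exceed K + 1", call. = FALSE)
  }
  (-2 * loglik) / c_hat + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' QAICc differences and Akaike weights
#'
#' @param qaicc_values numeric vector of QAICc values
#' @return data.frame with `QAICc`, `delta` (difference from the minimum)
#'   and normalized Akaike `weight`, in the input order
#' @export
akaike_weights <- function(qaicc_values) {
  delta <- qaicc_values - min(qaicc_values)
  w <- exp(-delta / 2)
  data.frame(QAICc = qaicc_values, delta = delta, weight = w / sum(w))
}

#' Rank fitted models by QAICc
#'
#' @param fits list of [cjs_fit()] objects (unconverged fits are excluded
#'   with a message)
#' @param c_hat shared variance inflation factor
#' @param n_eff effective sample size; defaults to the number released
#' @return `model_table` data.frame sorted by QAICc with `delta` and
#'   Akaike `weight` columns (weights normalized over the candidate set)
#' @export
rank_models <- function(fits, c_hat = 1, n_eff = NULL) {
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!conv)) {
    message(sum(!conv), " unconverged model(s) excluded from ranking")
    fits <- fits[conv]
  }
  if (!length(fits)) stop("no converged models to rank", call. = FALSE)
  if (is.null(n_eff)) n_eff <- fits[[1]]$n_released
  q <- vapply(fits, function(f) qaicc(f$loglik, f$K, n_eff, c_hat),
              numeric(1))
  out <- data.frame(
    model = vapply(fits, function(f) f$spec$string, character(1)),
    K = vapply(fits, `[[`, integer(1), "K"),
    QAICc = q, stringsAsFactors = FALSE)
  out <- out[order(out$QAICc), ]
  aw <- akaike_weights(out$QAICc)
  out$delta <- aw$delta
  out$weight <- aw$weight
  rownames(out) <- NULL
  class(out) <- c("model_table", "data.frame")
  out
}
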