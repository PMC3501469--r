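# Behavioral hypothesis tests: Williams-corrected G-test of independence
# for smolt-index vs detection contingency tables, two-way fixed-effects
# linear models (Type-III sums of squares) for travel rates and migration
# range, and Tukey-Kramer multiple comparisons gated on a significant
# interaction.

#' Williams-corrected G-test of independence for a 2x2 table
#'
#' G = 2 sum O ln(O/E) with the 0 ln 0 = 0 convention, divided by the
#' Williams correction q = 1 + (n/R1 + n/R2 - 1)(n/C1 + n/C2 - 1)/(6n);
#' q >= 1, so the adjusted statistic never exceeds the raw one. p-value
#' from the chi-square distribution on 1 df.
#'
#' @param table 2x2 matrix of nonnegative counts
#' @return list with `G`, `G_adj`, `q`, `df`, `p`
#' @export
g_test_adj <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  n <- sum(tab)
  R <- rowSums(tab); C <- colSums(tab)
  if (any(R == 0) || any(C == 0)) {
    warning("zero margin: G-test undefined")
    return(list(G = NA_real_, G_adj = NA_real_, q = NA_real_, df = 1L,
                p = NA_real_))
  }
  E <- outer(R, C) / n
  terms <- ifelse(tab == 0, 0, tab * log(tab / E))
  G <- 2 * sum(terms)
  q <- 1 + (n / R[1] + n / R[2] - 1) * (n / C[1] + n / C[2] - 1) / (6 * n)
  G_adj <- G / q
  list(G = G, G_adj = G_adj, q = q, df = 1L,
       p = stats::pchisq(G_adj, 1, lower.tail = FALSE))
}

#' Smolt-index vs river-mouth-detection contingency table
#'
#' Rows: smolt index 1 versus 2-3; columns: detected at or beyond the river
#' mouth versus never.
#'
#' @param fish [fish_records()] subset of interest
#' @param eh [encounter_histories()] covering those fish
#' @return 2x2 integer matrix
#' @export
si_detection_table <- function(fish, eh) {
  idx <- match(fish$fish_id, rownames(eh$history))
  detected <- rowSums(eh$history[idx, -1, drop = FALSE]) > 0
  si1 <- fish$smolt_index == 1
  tab <- matrix(c(sum(si1 & detected), sum(si1 & !detected),
                  sum(!si1 & detected), sum(!si1 & !detected)),
                2, 2, byrow = TRUE,
                dimnames = list(smolt_index = c("SI1", "SI2-3"),
                                detected = c("yes", "no")))
  tab
}

#' Two-way fixed-effects linear model with Type-III tests
#'
#' Least-squares fit of `response ~ A * B` with sum-to-zero contrasts;
#' each term's Type-III (partial) sum of squares is the increase in
#' residual SS when that term's columns are removed from the full model.
#' Unbalanced cells are allowed; an empty cell leaves the interaction
#' inestimable (flagged).
#'
#' @param data data.frame
#' @param response name of the numeric response column; NA responses are
#'   dropped
#' @param factor_a,factor_b names of the two factor columns
#' @return an `anova2` object with the per-term table and fit internals
#' @export
two_way_anova <- function(data, response, factor_a = "origin",
                          factor_b = "year") {
  for (v in c(response, factor_a, factor_b)) {
    if (!v %in% names(data)) stop("column not found: ", v, call. = FALSE)
  }
  df <- data[!is.na(data[[response]]), , drop = FALSE]
  df$.A <- factor(df[[factor_a]])
  df$.B <- factor(df[[factor_b]])
  df$.A <- droplevels(df$.A); df$.B <- droplevels(df$.B)
  if (nlevels(df$.A) < 2 || nlevels(df$.B) < 2) {
    stop("both factors need at least two observed levels", call. = FALSE)
  }
  y <- df[[response]]
  opts <- list(.A = "contr.sum", .B = "contr.sum")
  X <- stats::model.matrix(~ .A * .B, df, contrasts.arg = opts)
  asgn <- attr(X, "assign")
  empty_cell <- any(table(df$.A, df$.B) == 0)
  qrX <- qr(X)
  estimable <- qrX$rank == ncol(X)
  fit <- stats::lm.fit(X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE], y)
  rss_full <- sum(fit$residuals^2)
  df_res <- length(y) - qrX$rank
  terms <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  rows <- lapply(1:3, function(t) {
    keep <- asgn != t
    Xr <- X[, keep, drop = FALSE]
    fr <- stats::lm.fit(Xr[, qr(Xr)$pivot[seq_len(qr(Xr)$rank)],
                           drop = FALSE], y)
    ss <- max(sum(fr$residuals^2) - rss_full, 0)
    dft <- sum(asgn == t)
    Fv <- if (ss <= 1e-12) 0 else (ss / dft) / (rss_full / df_res)
    data.frame(term = terms[t], df1 = dft, df2 = df_res,
               F = max(Fv, 0),
               p = stats::pf(max(Fv, 0), dft, df_res, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  if (empty_cell || !estimable) {
    table$F[3] <- NA_real_; table$p[3] <- NA_real_
  }
  cells <- stats::aggregate(y, list(A = df$.A, B = df$.B),
                            function(v) c(mean = mean(v), n = length(v)))
  structure(list(table = table, mse = rss_full / df_res, df_res = df_res,
                 cell_means = data.frame(A = cells$A, B = cells$B,
                                         mean = cells$x[, "mean"],
                                         n = cells$x[, "n"]),
                 factor_a = factor_a, factor_b = factor_b,
                 response = response,
                 interaction_inestimable = empty_cell || !estimable),
            class = "anova2")
}

#' @export
print.anova2 <- function(x, ...) {
  cat("Two-way fixed-effects model for", x$response, "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Tukey-Kramer comparisons of factor A within each level of factor B
#'
#' Refuses to run unless the interaction term of the supplied fit is
#' significant at the stated gate (the conditional post-hoc procedure).
#' Uses the studentized-range distribution with the harmonic-mean
#' correction for unbalanced cells; the family size is the number of cell
#' means.
#'
#' @param fit an [two_way_anova()] result
#' @param alpha interaction significance gate (default 0.05)
#' @return data.frame of pairwise comparisons with `diff` and adjusted `p`
#' @export
tukey_hsd <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "anova2"))
  p_int <- fit$table$p[3]
  if (is.na(p_int) || p_int > alpha) {
    stop("interaction not significant at the stated gate (p = ",
         format(p_int, digits = 3), "); Tukey comparisons not performed",
         call. = FALSE)
  }
  cm <- fit$cell_means
  nmeans <- nrow(cm)
  out <- list()
  for (b in levels(cm$B)) {
    sub <- cm[cm$B == b, ]
    if (nrow(sub) < 2) next
    pairs <- utils::combn(seq_len(nrow(sub)), 2)
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      d <- sub$mean[i1] - sub$mean[i2]
      se <- sqrt(fit$mse / 2 * (1 / sub$n[i1] + 1 / sub$n[i2]))
      q <- abs(d) / se
      out[[length(out) + 1]] <- data.frame(
        within = b, group1 = as.character(sub$A[i1]),
        group2 = as.character(sub$A[i2]), diff = d,
        p = stats::ptukey(q, nmeans, fit$df_res, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
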