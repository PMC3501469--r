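# Model grammar and design-matrix construction. Model strings follow the
# field's survival/detection shorthand, e.g.
#   "phi ~ segment * SkokH + rd; p ~ segment + RM:line; fix p[JDF]=0.685"
# phi terms: segment, population, reartype, hatchery, SkokH, DuckH, year,
#            rd, L (length), K (condition factor)
# p terms:   segment (occasion line), RM:line (river-mouth-specific
#            detection at the RM occasion only), year, rd
# "fix p[JDF]=v" pins every detection cell of the named occasion at a real
# value; fixed reals are never estimated.

#' Parse a survival/detection model string
#'
#' @param string model string, `"phi ~ <terms>; p ~ <terms>[; fix p[OCC]=v]*"`
#' @return a `model_spec` list with `phi_formula`, `p_formula`, `fixed`
#' @examples
#' parse_model_spec("phi ~ segment * SkokH + rd; p ~ segment + RM:line; fix p[JDF]=0.685")
#' @export
parse_model_spec <- function(string) {
  parts <- trimws(strsplit(string, ";")[[1]])
  parts <- parts[nzchar(parts)]
  phi_part <- grep("^phi\\b", parts, value = TRUE)
  p_part <- grep("^p\\s*~", parts, value = TRUE)
  fixes <- grep("^fix\\b", parts, value = TRUE)
  if (length(phi_part) != 1 || length(p_part) != 1) {
    stop("model string needs exactly one 'phi ~ ...' and one 'p ~ ...' clause",
         call. = FALSE)
  }
  canon <- function(x, p_side = FALSE) {
    x <- sub("^(phi|p)\\s*~", "", x)
    x <- gsub("RM:line", "rm_line", x, fixed = TRUE)
    x <- gsub("\\blength\\b", "L", x)
    x <- gsub("\\bk\\b", "K", x)
    x <- trimws(x)
    if (x == "" || x == "1" || x == ".") x <- "1"
    allowed <- if (p_side) c("segment", "rm_line", "year", "rd", "1")
               else c("segment", "population", "reartype", "hatchery",
                      "SkokH", "DuckH", "year", "rd", "L", "K", "1")
    toks <- unique(trimws(strsplit(x, "[+*:]")[[1]]))
    bad <- setdiff(toks[nzchar(toks)], allowed)
    if (length(bad)) {
      stop("unknown model term(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    stats::as.formula(paste("~", x))
  }
  fixed <- lapply(fixes, function(f) {
    m <- regmatches(f, regexec(
      "^fix\\s+(phi|p)\\s*\\[\\s*([A-Za-z-]+)\\s*\\]\\s*=\\s*([0-9.eE+-]+)$", f))[[1]]
    if (length(m) != 4) stop("cannot parse fix clause: ", f, call. = FALSE)
    list(par = m[2], cell = m[3], value = as.numeric(m[4]))
  })
  structure(list(string = string,
                 phi_formula = canon(phi_part, FALSE),
                 p_formula = canon(p_part, TRUE),
                 fixed = fixed),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("CJS model:", x$string, "\n")
  invisible(x)
}

# long covariate frames: one row per (fish, segment) cell, fish-major order
phi_long_frame <- function(records, T_occ = 4L) {
  n <- nrow(records)
  df <- records[rep(seq_len(n), each = T_occ), , drop = FALSE]
  df$segment <- factor(rep(SEGMENT_NAMES[seq_len(T_occ)], n),
                       levels = SEGMENT_NAMES[seq_len(T_occ)])
  df$population <- factor(df$population, levels = POPULATIONS)
  df$reartype <- factor(population_origin(as.character(df$population)),
                        levels = c("wild", "hatchery"))
  df$hatchery <- factor(ifelse(df$population == "SkokomishH", "McKernan",
                        ifelse(df$population == "DuckabushH", "Lilliwaup",
                               "wild")),
                        levels = c("wild", "McKernan", "Lilliwaup"))
  df$SkokH <- factor(ifelse(df$population == "SkokomishH", "SkokH", "other"),
                     levels = c("other", "SkokH"))
  df$DuckH <- factor(ifelse(df$population == "DuckabushH", "DuckH", "other"),
                     levels = c("other", "DuckH"))
  df$year <- factor(df$year)
  df
}

p_long_frame <- function(records, T_occ = 4L) {
  n <- nrow(records)
  df <- records[rep(seq_len(n), each = T_occ), , drop = FALSE]
  df$segment <- factor(rep(OCCASION_LINES[seq_len(T_occ)], n),
                       levels = OCCASION_LINES[seq_len(T_occ)])
  df$year <- factor(df$year)
  rm_river <- sub("W$|H$", "", as.character(df$population))
  df$rm_line <- factor(ifelse(df$segment == "RM", rm_river, "shared"),
                       levels = c("shared", "BigBeef", "Skokomish",
                                  "Duckabush"))
  df
}

standardize_covariates <- function(df, vars = c("rd", "L", "K")) {
  df$L <- df$fork_length_mm
  df$K <- df$condition_factor
  df$rd <- df$release_date
  transforms <- list()
  for (v in vars) {
    m <- mean(df[[v]]); s <- stats::sd(df[[v]])
    if (!is.finite(s) || s == 0) s <- 1
    transforms[[v]] <- c(mean = m, sd = s)
    df[[v]] <- (df[[v]] - m) / s
  }
  attr(df, "cov_transforms") <- transforms
  df
}

# greedy left-to-right removal of aliased (linearly dependent) columns
drop_aliased <- function(X, tol = 1e-8) {
  keep <- integer(0)
  for (j in seq_len(ncol(X))) {
    cand <- X[, c(keep, j), drop = FALSE]
    if (qr(cand, tol = tol)$rank == length(keep) + 1L) keep <- c(keep, j)
  }
  dropped <- setdiff(seq_len(ncol(X)), keep)
  if (length(dropped)) {
    message("dropping aliased design column(s): ",
            paste(colnames(X)[dropped], collapse = ", "))
  }
  list(X = X[, keep, drop = FALSE], kept = keep,
       dropped = colnames(X)[dropped])
}

#' Build CJS design matrices for a model specification
#'
#' Rows are (fish, segment) cells for survival and (fish, occasion) cells
#' for detection, fish-major. Continuous covariates (rd, L, K) are
#' standardized to mean 0, SD 1 (transform recorded). Aliased columns are
#' dropped deterministically left-to-right. Cells named in `fix` clauses
#' are masked with their fixed real value; design columns that act only on
#' fixed cells are excluded from estimation but still counted in the
#' reported parameter count `K` (the standard convention for this model
#' family, under which the usual top model has K = 15).
#'
#' @param spec a [parse_model_spec()] result (or a model string)
#' @param eh [encounter_histories()]
#' @return a `cjs_design` list
#' @export
build_design <- function(spec, eh) {
  if (is.character(spec)) spec <- parse_model_spec(spec)
  records <- eh$records
  T_occ <- length(eh$occasions)
  lphi <- standardize_covariates(phi_long_frame(records, T_occ))
  lp <- standardize_covariates(p_long_frame(records, T_occ))
  mm <- function(formula, data) {
    suppressMessages(drop_aliased(stats::model.matrix(formula, data)))
  }
  dphi <- mm(spec$phi_formula, lphi)
  dp <- mm(spec$p_formula, lp)

  # fixed-cell mask over (fish, occasion) / (fish, segment) cells
  fixed_phi <- matrix(NA_real_, nrow(records), T_occ)
  fixed_p <- matrix(NA_real_, nrow(records), T_occ)
  for (f in spec$fixed) {
    if (f$par == "p") {
      k <- match(f$cell, OCCASION_LINES)
      if (is.na(k)) stop("unknown occasion in fix clause: ", f$cell,
                         call. = FALSE)
      fixed_p[, k] <- f$value
    } else {
      s <- match(f$cell, SEGMENT_NAMES)
      if (is.na(s)) stop("unknown segment in fix clause: ", f$cell,
                         call. = FALSE)
      fixed_phi[, s] <- f$value
    }
  }
  free_cells_phi <- which(t(is.na(t(fixed_phi))))  # long-frame order
  # long frames are fish-major: row (i-1)*T + k corresponds to cell [i, k]
  free_phi <- as.vector(t(is.na(fixed_phi)))
  free_p <- as.vector(t(is.na(fixed_p)))
  est_cols <- function(X, free) {
    active <- which(colSums(abs(X[free, , drop = FALSE])) > 0)
    sub <- suppressMessages(drop_aliased(X[free, active, drop = FALSE]))
    active[sub$kept]
  }
  est_phi <- est_cols(dphi$X, free_phi)
  est_p <- est_cols(dp$X, free_p)
  structure(list(
    spec = spec,
    X_phi = dphi$X, X_p = dp$X,
    est_phi = est_phi, est_p = est_p,
    free_phi = free_phi, free_p = free_p,
    fixed_phi = fixed_phi, fixed_p = fixed_p,
    n_fish = nrow(records), T_occ = T_occ,
    K = ncol(dphi$X) + ncol(dp$X),
    n_beta = length(est_phi) + length(est_p),
    phi_terms = stats::terms(spec$phi_formula),
    p_terms = stats::terms(spec$p_formula),
    long_phi = lphi, long_p = lp,
    cov_transforms = attr(lphi, "cov_transforms"),
    dropped = c(dphi$dropped, dp$dropped)
  ), class = "cjs_design")
}

# real-scale parameter matrices (n x T) from a free-beta vector
design_to_real <- function(design, beta) {
  bphi <- beta[seq_along(design$est_phi)]
  bp <- beta[length(design$est_phi) + seq_along(design$est_p)]
  eta_phi <- as.vector(design$X_phi[, design$est_phi, drop = FALSE] %*% bphi)
  eta_p <- as.vector(design$X_p[, design$est_p, drop = FALSE] %*% bp)
  phi <- matrix(stats::plogis(eta_phi), design$n_fish, design$T_occ,
                byrow = TRUE)
  p <- matrix(stats::plogis(eta_p), design$n_fish, design$T_occ,
              byrow = TRUE)
  phi[!is.na(design$fixed_phi)] <- design$fixed_phi[!is.na(design$fixed_phi)]
  p[!is.na(design$fixed_p)] <- design$fixed_p[!is.na(design$fixed_p)]
  list(phi = phi, p = p)
}
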