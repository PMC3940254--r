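#' Decompose a parameter into within- and between-line variance
#'
#' Fits the one-way random-intercept model
#' \eqn{y_{ij} = \mu + b_i + e_{ij}}, \eqn{b_i \sim N(0, \sigma^2_b)},
#' \eqn{e_{ij} \sim N(0, \sigma^2_w)} with tumor line as the random effect,
#' and reports the heterogeneity ratio
#' \eqn{\sigma^2_w / (\sigma^2_w + \sigma^2_b)} (within-line variance over
#' total variance): values near 0 mean the parameter is distinctive of the
#' line, values near 1 that tumors vary as much within a line as between
#' lines.
#'
#' REML is computed by 1-D profile optimization over the variance ratio
#' \eqn{\lambda = \sigma^2_b / \sigma^2_w} (closed-form GLS mean and
#' profiled \eqn{\sigma^2_w} given \eqn{\lambda}); negative-variance
#' solutions are truncated at the boundary \eqn{\lambda = 0}. The `"ANOVA"`
#' method is the closed-form method-of-moments estimator
#' (\eqn{\hat\sigma^2_w = MSW}, \eqn{\hat\sigma^2_b = (MSB - MSW)/n_0},
#' truncated at 0); the two agree on balanced designs.
#'
#' @param values numeric vector; missing values are dropped with their
#'   labels.
#' @param line_labels factor (or coercible) of tumor-line labels.
#' @param method `"REML"` (default) or `"ANOVA"`.
#' @return object of class `variance_decomposition`: `sigma2_within`,
#'   `sigma2_between`, `ratio` (within/total), `ratio_intra_inter`
#'   (within/between, `Inf` when between is 0), `method`, `n_groups`,
#'   `n_total`, `undefined` flag.
#' @export
fit_random_intercept <- function(values, line_labels,
                                 method = c("REML", "ANOVA")) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(line_labels)
  y <- as.numeric(values[keep])
  g <- droplevels(factor(line_labels[keep]))
  k <- nlevels(g)
  n <- length(y)
  if (k < 2) stop("need >= 2 groups with data")
  ni <- as.vector(table(g))
  if (max(ni) < 2) stop("need >= 2 observations in at least one group")
  out <- list(sigma2_within = NA_real_, sigma2_between = NA_real_,
              ratio = NA_real_, ratio_intra_inter = NA_real_,
              method = method, n_groups = k, n_total = n, undefined = FALSE)
  class(out) <- "variance_decomposition"
  if (stats::var(y) == 0) {  # zero total variance: ratio undefined
    out$sigma2_within <- 0; out$sigma2_between <- 0
    out$undefined <- TRUE
    return(out)
  }
  ybar <- tapply(y, g, mean)
  ssw <- sum((y - ybar[g])^2)

  if (method == "ANOVA") {
    grand <- mean(y)
    ssb <- sum(ni * (ybar - grand)^2)
    msw <- ssw / (n - k)
    msb <- ssb / (k - 1)
    n0 <- (n - sum(ni^2) / n) / (k - 1)  # = n_per_group when balanced
    s2b <- max((msb - msw) / n0, 0)
    s2w <- msw
  } else {
    # profiled -2 REML log-likelihood in lambda = sigma2_b / sigma2_w
    crit <- function(lambda) {
      w <- ni / (1 + ni * lambda)
      mu <- sum(w * ybar) / sum(w)
      q <- ssw + sum(w * (ybar - mu)^2)
      (n - 1) * log(q / (n - 1)) + sum(log(1 + ni * lambda)) + log(sum(w))
    }
    # optimize over theta = lambda/(1+lambda) in [0, 1) for uniform precision
    f <- function(theta) crit(theta / (1 - theta))
    opt <- stats::optimize(f, c(0, 1 - 1e-10), tol = 1e-12)
    lambda <- opt$minimum / (1 - opt$minimum)
    if (f(0) <= opt$objective) lambda <- 0  # boundary (truncation at 0)
    w <- ni / (1 + ni * lambda)
    mu <- sum(w * ybar) / sum(w)
    s2w <- (ssw + sum(w * (ybar - mu)^2)) / (n - 1)
    s2b <- lambda * s2w
  }
  out$sigma2_within <- s2w
  out$sigma2_between <- s2b
  out$ratio <- s2w / (s2w + s2b)
  out$ratio_intra_inter <- if (s2b > 0) s2w / s2b else Inf
  out
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "Variance decomposition (%s): within %.4g, between %.4g, within/total %.3f (%d groups, n = %d)\n",
    x$method, x$sigma2_within, x$sigma2_between, x$ratio, x$n_groups,
    x$n_total))
  invisible(x)
}

#' Per-column heterogeneity table (within-line variance / total variance)
#'
#' Applies [fit_random_intercept()] to every parameter and feature column of
#' a feature table, preserving column order, and returns the analog of a
#' per-parameter intra-tumor-line heterogeneity table.
#'
#' @param table data.frame with a `line` column and numeric parameter
#'   columns (a `sample_id` column is ignored).
#' @param columns columns to decompose (default: all numeric columns).
#' @param method passed to [fit_random_intercept()].
#' @return data.frame: `column`, `sigma2_within`, `sigma2_between`, `ratio`,
#'   `n_groups`, `n_total`, `undefined`. All-missing columns are skipped
#'   with a warning; constant columns get an undefined-flag row.
#' @export
heterogeneity_table <- function(table, columns = NULL, method = "REML") {
  if (!"line" %in% names(table)) stop("table must have a 'line' column")
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                       c("sample_id"))
  rows <- list()
  for (cl in columns) {
    v <- table[[cl]]
    if (all(is.na(v))) {
      warning("column '", cl, "' is all-missing; skipped")
      next
    }
    vd <- fit_random_intercept(v, table$line, method = method)
    rows[[length(rows) + 1L]] <- data.frame(
      column = cl, sigma2_within = vd$sigma2_within,
      sigma2_between = vd$sigma2_between, ratio = vd$ratio,
      n_groups = vd$n_groups, n_total = vd$n_total,
      undefined = vd$undefined, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pairwise correlation matrix over parameter/feature columns
#'
#' Spearman rank correlation by default (robust to the mixed scales of
#' fractions, SUVs and indices), with pairwise-complete observations; cells
#' with fewer than `min_pairs` complete pairs are flagged missing.
#'
#' @param table data.frame of samples.
#' @param columns columns to correlate (default: all numeric, `sample_id`
#'   excluded).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, columns = NULL,
                               method = c("spearman", "pearson"),
                               min_pairs = 3) {
  method <- match.arg(method)
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                       "sample_id")
  x <- as.matrix(table[columns])
  p <- length(columns)
  out <- matrix(NA_real_, p, p, dimnames = list(columns, columns))
  for (i in seq_len(p)) {
    out[i, i] <- 1
    for (j in seq_len(p)[-seq_len(i)]) {
      ok <- stats::complete.cases(x[, i], x[, j])
      if (sum(ok) >= min_pairs)
        out[i, j] <- out[j, i] <-
          stats::cor(x[ok, i], x[ok, j], method = method)
    }
  }
  out
}
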