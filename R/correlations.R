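#' Spearman rank correlation with optional Bonferroni adjustment
#'
#' Rank correlation between two clinical/physiological variables, with the
#' tie-aware t approximation for the p-value (t = rho * sqrt((n-2)/(1-rho^2)),
#' df = n - 2) and an optional Bonferroni correction for a family of m tests.
#'
#' @param x,y Numeric vectors of equal length (n >= 4). Ties allowed.
#' @param bonferroni_m Size of the test family (default 1 = no adjustment).
#' @return A tibble with `rho`, `n`, `p_raw`, `p_adj`, `m`.
#' @export
spearman_cor <- function(x, y, bonferroni_m = 1) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: Spearman correlation undefined")
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  tibble::tibble(rho = rho, n = n, p_raw = p,
                 p_adj = pmin(1, bonferroni_m * p), m = bonferroni_m)
}

#' Partial Spearman correlation by rank residualization
#'
#' Correlation between x and y with the influence of one or more control
#' variables z removed. Definition used here (one of several conventions,
#' recorded in the output): all variables are rank-transformed, x-ranks and
#' y-ranks are each regressed on the z-ranks by least squares, and the Pearson
#' correlation of the two residual vectors is reported with the usual t
#' approximation on n - q - 2 degrees of freedom (q = number of controls).
#'
#' @param x,y Numeric vectors (n >= 5).
#' @param z Control variable(s): a vector or a data frame / matrix of columns.
#' @return A tibble with `rho_partial`, `n`, `df`, `p`, `method`.
#' @export
partial_spearman <- function(x, y, z) {
  z <- as.matrix(as.data.frame(z))
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x)
  q <- ncol(z)
  if (n < 5) stop("need at least 5 complete cases")
  rx <- rank(x); ry <- rank(y)
  rz <- apply(z, 2, rank)
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
  if (stats::sd(ex) < 1e-10 * stats::sd(rx) ||
      stats::sd(ey) < 1e-10 * stats::sd(ry)) {
    stop("degenerate residuals: a variable is (rank-)collinear with the controls")
  }
  rho <- stats::cor(ex, ey)
  df <- n - q - 2
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  tibble::tibble(rho_partial = rho, n = n, df = df, p = p,
                 method = "rank-residualization")
}

#' Correlate ROI power with a set of clinical variables
#'
#' Convenience wrapper running [spearman_cor()] of one endpoint (typically the
#' per-subject ROI band power) against each listed covariate, Bonferroni
#' adjusted over the family, mirroring the common design of five clinical
#' correlations tested at a family-wise alpha of 0.05 (per-test threshold
#' 0.01).
#'
#' @param data Data frame with one row per subject.
#' @param endpoint Column name of the endpoint.
#' @param covariates Character vector of covariate column names.
#' @param partial_on Optional column name; if given, a partial Spearman
#'   (controlling for this column) is reported alongside each raw correlation.
#' @return A tibble with one row per covariate.
#' @export
correlate_clinical <- function(data, endpoint, covariates, partial_on = NULL) {
  m <- length(covariates)
  rows <- purrr::map(covariates, function(v) {
    s <- spearman_cor(data[[endpoint]], data[[v]], bonferroni_m = m)
    out <- tibble::tibble(variable = v, rho = s$rho, n = s$n,
                          p_raw = s$p_raw, p_adj = s$p_adj)
    if (!is.null(partial_on) && v != partial_on) {
      ps <- partial_spearman(data[[endpoint]], data[[v]], data[[partial_on]])
      out$rho_partial <- ps$rho_partial
      out$p_partial <- ps$p
    }
    out
  })
  dplyr::bind_rows(rows)
}
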