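#' Mixed between-within ANOVA with Huynh-Feldt correction
#'
#' Classical split-plot decomposition for one between-subject factor (group)
#' and one within-subject factor (e.g. sleep stage, or sleep cycle). Reports
#' F, degrees of freedom, Greenhouse-Geisser and Huynh-Feldt epsilon for the
#' within-subject effects, sphericity-corrected p-values, and partial eta
#' squared (SS_effect / (SS_effect + SS_error)). Subjects with a missing
#' within level are removed listwise. Pairwise follow-ups (group contrasts at
#' each within level, and within-level contrasts inside each group) are
#' Bonferroni-adjusted over their family.
#'
#' Hypotheses involving the within-subject marginal means are tested on the
#' unweighted (type III) grand mean, matching the convention of standard
#' statistical software for unbalanced group sizes. Epsilon is computed from
#' the pooled within-group covariance of the orthonormal within-subject
#' contrasts; the Huynh-Feldt value is clipped at 1 when used for p-values
#' (with two within levels it equals 1 analytically).
#'
#' @param data A data frame with one row per subject x within-level.
#' @param value,subject,within,group Column names (strings) of the endpoint,
#'   subject id, within-subject level and group label.
#' @return A `sleep_anova` object; `tidy()` returns the effect table,
#'   `glance()` the design summary, `$pairwise` the follow-up contrasts.
#' @examples
#' d <- expand.grid(subject = 1:10, stage = c("N2", "N3"))
#' d$group <- rep(c("affected", "control"), 5)[d$subject]
#' set.seed(1)
#' d$power <- rnorm(20) + (d$stage == "N3") * 2
#' fit <- mixed_anova(d, "power", "subject", "stage", "group")
#' generics::tidy(fit)
#' @export
mixed_anova <- function(data, value, subject, within, group = NULL) {
  df <- tibble::as_tibble(data)
  for (col in c(value, subject, within, group)) {
    if (!col %in% names(df)) stop("column not found: ", col)
  }
  df <- df[, c(subject, within, value, group)]
  names(df) <- c(".subject", ".within", ".value", if (!is.null(group)) ".group")
  if (is.null(group)) df$.group <- "all"
  if (anyNA(df$.value)) df <- df[!is.na(df$.value), ]

  levels_w <- sort(unique(as.character(df$.within)))
  k <- length(levels_w)
  if (k < 2) stop("need at least two within-subject levels")

  # wide matrix, listwise deletion of subjects missing any level
  wide <- tidyr::pivot_wider(df, id_cols = c(".subject", ".group"),
                             names_from = ".within", values_from = ".value")
  complete <- stats::complete.cases(wide[, levels_w])
  dropped <- wide$.subject[!complete]
  wide <- wide[complete, ]
  Y <- as.matrix(wide[, levels_w])
  grp <- factor(wide$.group)
  a <- nlevels(grp)
  n_g <- as.vector(table(grp))
  N <- nrow(Y)
  if (any(n_g < 2)) stop("every group needs at least 2 complete subjects")

  subj_mean <- rowMeans(Y)
  cell_mean <- rowsum(Y, grp) / n_g              # a x k
  grp_mean <- rowMeans(cell_mean)                # per-group subject-mean

  # ---- between-subject stratum (on subject means, scaled by k) ----
  gm_w <- mean(subj_mean)                        # weighted grand mean
  ss_group <- k * sum(n_g * (grp_mean - gm_w)^2)
  ss_subj_err <- k * sum((subj_mean - grp_mean[grp])^2)
  df_group <- a - 1
  df_subj_err <- N - a

  # ---- within-subject stratum via orthonormal polynomial-free contrasts ----
  C <- qr.Q(qr(stats::contr.helmert(k)))         # k x (k-1), orthonormal
  Ystar <- Y %*% C                               # N x (k-1)
  cell_star <- rowsum(Ystar, grp) / n_g          # a x (k-1)
  # type III within effect: unweighted mean of group cell means
  est <- colMeans(cell_star)
  ss_within <- sum(est^2) / (sum(1 / n_g) / a^2)
  gstar_w <- colSums(Ystar) / N
  ss_inter <- sum(n_g * rowSums(sweep(cell_star, 2, gstar_w)^2))
  resid_star <- Ystar - cell_star[grp, , drop = FALSE]
  ss_within_err <- sum(resid_star^2)
  df_within <- k - 1
  df_inter <- (a - 1) * (k - 1)
  df_within_err <- (N - a) * (k - 1)

  # zero-floor: sums of squares below round-off of the data scale are zero
  tol <- 1e-12 * (sum(Y^2) + 1)
  zero_ss <- function(x) ifelse(x < tol, 0, x)
  ss_group <- zero_ss(ss_group); ss_subj_err <- zero_ss(ss_subj_err)
  ss_within <- zero_ss(ss_within); ss_inter <- zero_ss(ss_inter)
  ss_within_err <- zero_ss(ss_within_err)

  # ---- sphericity: epsilon from the error SSP of the contrast scores ----
  SSPE <- crossprod(resid_star)
  lambda <- eigen(SSPE, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, tol) * 1e-12]
  if (length(lambda) == 0) lambda <- 1
  eps_gg <- (sum(lambda) / (k - 1))^2 / (sum(lambda^2) / (k - 1))
  err_df <- N - a
  eps_hf <- ((err_df + 1) * (k - 1) * eps_gg - 2) /
    ((k - 1) * (err_df - (k - 1) * eps_gg))
  eps_hf_c <- min(1, eps_hf)

  f_row <- function(effect, ss, dfn, ss_err, dfe, eps = NA_real_) {
    f <- if (ss_err == 0) {
      if (ss == 0) 0 else Inf
    } else (ss / dfn) / (ss_err / dfe)
    p <- stats::pf(f, dfn, dfe, lower.tail = FALSE)
    p_hf <- if (is.na(eps)) p else {
      stats::pf(f, eps * dfn, eps * dfe, lower.tail = FALSE)
    }
    tibble::tibble(
      effect = effect, ss = ss, df_num = dfn, df_den = dfe, F = f,
      epsilon_gg = if (is.na(eps)) NA_real_ else eps_gg,
      epsilon_hf = if (is.na(eps)) NA_real_ else eps_hf_c,
      p = p, p_hf = p_hf,
      partial_eta_sq = ss / (ss + ss_err)
    )
  }
  rows <- list(f_row("within", ss_within, df_within, ss_within_err,
                     df_within_err, eps_hf_c))
  if (a > 1) {
    rows <- c(
      list(f_row("group", ss_group, df_group, ss_subj_err, df_subj_err)),
      rows,
      list(f_row("group:within", ss_inter, df_inter, ss_within_err,
                 df_within_err, eps_hf_c))
    )
  }
  table <- dplyr::bind_rows(rows)

  res <- structure(
    list(
      table = table,
      pairwise = anova_pairwise(Y, grp, levels_w),
      epsilon_gg = eps_gg, epsilon_hf = eps_hf_c, epsilon_hf_raw = eps_hf,
      n = N, n_groups = a, k = k, groups = levels(grp),
      within_levels = levels_w, dropped_subjects = dropped
    ),
    class = "sleep_anova"
  )
  res
}

# group contrasts at each within level (unpaired t) and within-level contrasts
# inside each group (paired t), each family Bonferroni-adjusted
anova_pairwise <- function(Y, grp, levels_w) {
  k <- ncol(Y)
  a <- nlevels(grp)
  rows <- list()
  if (a == 2) {
    g1 <- levels(grp)[1]
    g2 <- levels(grp)[2]
    for (j in seq_len(k)) {
      tt <- stats::t.test(Y[grp == g1, j], Y[grp == g2, j], var.equal = TRUE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        family = "group_at_level", contrast = paste(g1, "vs", g2),
        level = levels_w[j], estimate = unname(diff(rev(tt$estimate))),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
      )
    }
  }
  pairs <- utils::combn(k, 2)
  for (g in levels(grp)) {
    Yg <- Y[grp == g, , drop = FALSE]
    for (q in seq_len(ncol(pairs))) {
      j1 <- pairs[1, q]; j2 <- pairs[2, q]
      tt <- stats::t.test(Yg[, j1], Yg[, j2], paired = TRUE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        family = "level_within_group",
        contrast = paste(levels_w[j1], "vs", levels_w[j2]),
        level = g, estimate = unname(tt$estimate),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::ungroup(dplyr::mutate(dplyr::group_by(out, family),
                               p_adj = pmin(1, p * dplyr::n())))
}

#' @export
print.sleep_anova <- function(x, ...) {
  cat("Mixed between-within ANOVA:", x$n, "subjects,",
      x$n_groups, "group(s),", x$k, "within levels\n")
  if (length(x$dropped_subjects)) {
    cat("Dropped (incomplete within levels):",
        paste(x$dropped_subjects, collapse = ", "), "\n")
  }
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy sleep_anova
#' @export
tidy.sleep_anova <- function(x, ...) x$table

#' @method glance sleep_anova
#' @export
glance.sleep_anova <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_groups = x$n_groups, n_within_levels = x$k,
    epsilon_gg = x$epsilon_gg, epsilon_hf = x$epsilon_hf,
    n_dropped = length(x$dropped_subjects)
  )
}
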