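#' Per-channel group statistics for a cohort of power maps
#'
#' Unpaired two-sided t-test at every channel (pooled variance, df =
#' n1 + n2 - 2), or, when a covariate is supplied, the t-statistic of the
#' group term in the per-channel linear model `value ~ group + covariate`
#' (df = n - 3). The sign convention is first group minus second group; if a
#' group is labelled `"affected"` it is taken first.
#'
#' @param maps Tidy power maps: a data frame with columns `subject`,
#'   `channel`, `value` (one row per subject x channel).
#' @param subject_table Data frame with columns `subject`, `group` (exactly
#'   two groups) and any covariate columns.
#' @param covariate Optional name of a covariate column in `subject_table`.
#' @return A tibble with columns `channel`, `t`, `df`, `p`.
#' @export
channel_stat <- function(maps, subject_table, covariate = NULL) {
  d <- assemble_maps(maps, subject_table, covariate)
  t <- unname(perm_t(d$X, matrix(d$g, nrow = 1), d$D)[1, ])
  df <- nrow(d$X) - ncol(d$D) - 1
  tibble::tibble(channel = colnames(d$X), t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df))
}

# shared assembly: subjects x channels matrix, group indicator, nuisance design
assemble_maps <- function(maps, subject_table, covariate = NULL,
                          channel_col = "channel") {
  maps <- tibble::as_tibble(maps)
  stopifnot(all(c("subject", channel_col, "value") %in% names(maps)),
            all(c("subject", "group") %in% names(subject_table)))
  wide <- tidyr::pivot_wider(maps[, c("subject", channel_col, "value")],
                             names_from = dplyr::all_of(channel_col),
                             values_from = "value")
  st <- subject_table[match(wide$subject, subject_table$subject), ]
  if (anyNA(st$group)) stop("subjects in maps missing from subject_table")
  lev <- unique(as.character(st$group))
  if (length(lev) != 2) stop("exactly two groups are required")
  if ("affected" %in% lev) lev <- c("affected", setdiff(lev, "affected"))
  g <- as.numeric(st$group == lev[1])
  if (min(sum(g), sum(1 - g)) < 2) stop("each group needs at least 2 subjects")
  X <- as.matrix(wide[, -1])
  if (anyNA(X)) stop("maps contain missing subject x channel values")
  D <- matrix(1, nrow(X), 1)
  if (!is.null(covariate)) {
    if (!covariate %in% names(st)) stop("covariate column not found: ", covariate)
    D <- cbind(D, as.numeric(st[[covariate]]))
  }
  list(X = X, g = g, D = D, groups = lev, subjects = wide$subject)
}

# t-statistics of the group indicator for every row of the permutation matrix
# G (B x n of 0/1) at every channel, via the partial-regression identity:
# residualize g and the data on the nuisance design D, then
# t = <rg, rx> / (|rg| * sqrt(RSS / df)). With D = intercept this is exactly
# the pooled-variance two-sample t.
perm_t <- function(X, G, D) {
  n <- nrow(X)
  H <- D %*% solve(crossprod(D), t(D))
  RX <- X - H %*% X                       # n x ch
  RG <- G - G %*% t(H)                    # B x n  (H symmetric)
  num <- RG %*% RX                        # B x ch
  rg2 <- rowSums(RG^2)                    # B
  rx2 <- colSums(RX^2)                    # ch
  df <- n - ncol(D) - 1
  b2 <- sweep(num^2, 1, rg2, "/")
  rss <- sweep(-b2, 2, rx2, "+")          # rx2 - b2
  rss[rss < 0] <- 0
  denom <- sqrt(rss / df) * sqrt(rg2)
  t <- num / denom
  t[!is.finite(t)] <- 0
  t
}

#' Connected clusters of significant channels
#'
#' Groups the channels flagged significant at the forming threshold into
#' maximal connected components of the adjacency graph, separately for
#' positive and negative statistics. Components are ordered by size
#' (descending), ties broken by the lexicographically smallest member label.
#'
#' @param stats A tibble from [channel_stat()] (columns `channel`, `t`, `p`).
#' @param graph An `adjacency_graph` over the same channels.
#' @param forming_alpha Uncorrected per-channel threshold defining candidate
#'   cluster members.
#' @return A tibble with columns `cluster`, `sign`, `size`, `mass`
#'   (sum of |t|), and a `channels` list-column.
#' @export
find_clusters <- function(stats, graph, forming_alpha = 0.05) {
  labels <- graph$labels
  stopifnot(all(stats$channel %in% labels))
  t <- stats$t[match(labels, stats$channel)]
  p <- stats$p[match(labels, stats$channel)]
  nbidx <- neighbour_index(graph)
  rows <- list()
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(p) & p < forming_alpha & sign(t) == sgn)
    for (comp in components_of(idx, nbidx)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sign = if (sgn > 0) "positive" else "negative",
        size = length(comp), mass = sum(abs(t[comp])),
        channels = list(sort(labels[comp]))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(cluster = integer(), sign = character(),
                          size = integer(), mass = numeric(),
                          channels = list()))
  }
  first_lab <- vapply(out$channels, function(ch) ch[[1]], character(1))
  out <- out[order(-out$size, first_lab), ]
  out$cluster <- seq_len(nrow(out))
  out[, c("cluster", "sign", "size", "mass", "channels")]
}

neighbour_index <- function(graph) {
  lab2idx <- stats::setNames(seq_along(graph$labels), graph$labels)
  lapply(graph$neighbours, function(nb) unname(lab2idx[nb]))
}

# maximal connected components of the node subset `idx` (integer indices),
# breadth-first search over the restriction of the graph
components_of <- function(idx, nbidx) {
  if (length(idx) == 0) return(list())
  in_set <- logical(length(nbidx))
  in_set[idx] <- TRUE
  seen <- logical(length(nbidx))
  comps <- list()
  for (start in idx) {
    if (seen[start]) next
    comp <- integer()
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      nxt <- nbidx[[v]]
      nxt <- nxt[in_set[nxt] & !seen[nxt]]
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# cluster comparison statistic. "size" orders clusters by electrode count
# with the (continuous) cluster mass as tie-break — size + mass/(1+mass)
# preserves the count ordering exactly but makes the permutation null
# continuous, so the empirical 95th percentile is not distorted by ties on
# small integers. "mass" is the plain sum of |t|.
cluster_stat_value <- function(size, mass, use_mass = FALSE) {
  if (use_mass) mass else size + mass / (1 + mass)
}

# largest component statistic over both signs for one vector of t-values
max_cluster_stat <- function(t, tcrit, nbidx, use_mass = FALSE) {
  best <- 0
  for (sgn in c(1, -1)) {
    idx <- which(sgn * t > tcrit)
    if (length(idx) == 0) next
    if (length(idx) == 1) {
      best <- max(best, cluster_stat_value(1, abs(t[idx]), use_mass))
      next
    }
    for (comp in components_of(idx, nbidx)) {
      best <- max(best, cluster_stat_value(length(comp), sum(abs(t[comp])),
                                           use_mass))
    }
  }
  best
}

#' Cluster-based permutation test over the electrode graph
#'
#' Family-wise-error-controlling comparison of two groups of power maps.
#' Per-channel two-sided t-tests (optionally with a covariate) are
#' thresholded at `forming_alpha`; significant channels are grouped into
#' adjacency-connected clusters separately per sign. The null distribution of
#' the maximum cluster statistic (electrode count by default) is built by
#' randomly shuffling group labels across subjects (covariate values stay
#' attached to their subject), taking at each iteration the largest cluster
#' over both signs. An observed cluster is declared significant when its
#' statistic reaches the critical value: the smallest value whose null
#' exceedance probability is at most `cluster_alpha` (ties resolved
#' conservatively). Permutation p-values use the (1 + exceedances) /
#' (n_permutations + 1) convention and can never fall below
#' 1 / (n_permutations + 1).
#'
#' @inheritParams channel_stat
#' @param graph An `adjacency_graph` over the map channels.
#' @param n_permutations Number of random label shuffles (>= 100).
#' @param forming_alpha Per-channel uncorrected threshold.
#' @param cluster_alpha Family-wise level applied to the null of maximum
#'   cluster statistics.
#' @param statistic `"size"` (electrode count, default) or `"mass"`
#'   (sum of |t| over the cluster).
#' @param seed Integer seed making the shuffle sequence reproducible;
#'   recorded in the result.
#' @param permutations Optional matrix of 0/1 group indicators (one row per
#'   permutation) overriding random shuffling, e.g. for exhaustive
#'   enumeration on small designs.
#' @return A `cluster_result` object. `tidy()` gives per-channel statistics,
#'   `glance()` the test summary; `$clusters` holds the cluster table with
#'   permutation p-values.
#' @export
cluster_permutation_test <- function(maps, subject_table, graph,
                                     n_permutations = 10000,
                                     forming_alpha = 0.05,
                                     cluster_alpha = 0.05,
                                     covariate = NULL,
                                     statistic = c("size", "mass"),
                                     seed = NULL,
                                     permutations = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(permutations) && n_permutations < 100) {
    stop("n_permutations must be at least 100")
  }
  d <- assemble_maps(maps, subject_table, covariate)
  ord <- match(graph$labels, colnames(d$X))
  if (anyNA(ord)) stop("adjacency graph labels do not match map channels")
  X <- d$X[, ord, drop = FALSE]
  n <- nrow(X)
  n1 <- sum(d$g)
  if (choose(n, n1) < 2) stop("too few subjects for any distinct permutation")

  df <- n - ncol(d$D) - 1
  tcrit <- stats::qt(1 - forming_alpha / 2, df)
  nbidx <- neighbour_index(graph)
  use_mass <- statistic == "mass"

  obs_t <- unname(perm_t(X, matrix(d$g, nrow = 1), d$D)[1, ])
  obs_stats <- tibble::tibble(channel = graph$labels, t = obs_t, df = df,
                              p = 2 * stats::pt(-abs(obs_t), df))
  clusters <- find_clusters(obs_stats, graph, forming_alpha)

  if (is.null(permutations)) {
    draw <- function() t(replicate(n_permutations, sample(d$g)))
    G <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  } else {
    G <- permutations
    n_permutations <- nrow(G)
  }
  Tm <- perm_t(X, G, d$D)
  null <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    null[b] <- max_cluster_stat(Tm[b, ], tcrit, nbidx, use_mass)
  }

  critical <- critical_cluster_stat(null, cluster_alpha)
  if (nrow(clusters) > 0) {
    stat_obs <- cluster_stat_value(clusters$size, clusters$mass, use_mass)
    clusters$p_perm <- vapply(
      stat_obs, function(s) (1 + sum(null >= s)) / (n_permutations + 1),
      numeric(1))
    clusters$significant <- stat_obs >= critical
  } else {
    clusters$p_perm <- numeric(0)
    clusters$significant <- logical(0)
  }

  structure(
    list(channel_stats = obs_stats, clusters = clusters, null = null,
         critical = critical, n_permutations = n_permutations,
         forming_alpha = forming_alpha, cluster_alpha = cluster_alpha,
         statistic = statistic, covariate = covariate, seed = seed,
         groups = d$groups, n = n, n1 = n1,
         null_mode = "max over both signs"),
    class = "cluster_result"
  )
}

# smallest statistic value whose null exceedance probability is <= alpha
critical_cluster_stat <- function(null, alpha) {
  cand <- sort(unique(c(null, max(null) + 1)))
  exceed <- vapply(cand, function(c) mean(null >= c), numeric(1))
  cand[which(exceed <= alpha)[1]]
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Cluster-based permutation test (", x$statistic, "; ",
      x$n_permutations, " permutations; forming alpha ", x$forming_alpha,
      ")\n", sep = "")
  cat("Groups:", paste(x$groups, collapse = " vs "), " n =", x$n,
      "\nCritical cluster", x$statistic, ":", x$critical, "\n")
  if (nrow(x$clusters) == 0) {
    cat("No suprathreshold clusters.\n")
  } else {
    print(as.data.frame(x$clusters[, c("cluster", "sign", "size", "mass",
                                       "p_perm", "significant")]),
          digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$channel_stats

#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_permutations = x$n_permutations,
    forming_alpha = x$forming_alpha, cluster_alpha = x$cluster_alpha,
    statistic = x$statistic, critical = x$critical,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    largest_cluster = if (nrow(x$clusters)) max(x$clusters$size) else 0L,
    null_mode = x$null_mode,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' Channels of the significant clusters
#'
#' Harvests the union of channels belonging to significant clusters of a
#' [cluster_permutation_test()] result, e.g. to define a region of interest
#' from a band comparison.
#'
#' @param result A `cluster_result`.
#' @param sign Restrict to `"positive"` or `"negative"` clusters (default both).
#' @return Character vector of channel labels (possibly empty).
#' @export
significant_channels <- function(result, sign = c("positive", "negative")) {
  cl <- result$clusters
  cl <- cl[cl$significant & cl$sign %in% sign, ]
  sort(unique(unlist(cl$channels)))
}

#' Cluster-based permutation test over frequency bins
#'
#' One-dimensional analogue of [cluster_permutation_test()] applied to
#' per-subject spectra (typically the PSD averaged across all scalp
#' channels): neighbouring frequency bins form the adjacency chain, and
#' significant contiguous bin ranges are returned.
#'
#' @param spectra Tidy spectra: data frame with columns `subject`, `freq`
#'   (bin centre, Hz), `value`.
#' @inheritParams cluster_permutation_test
#' @return A `cluster_result` with an extra `$ranges` tibble giving the
#'   significant frequency intervals (`lo`, `hi`, `n_bins`, `p_perm`).
#' @export
spectrum_cluster_test <- function(spectra, subject_table,
                                  n_permutations = 10000,
                                  forming_alpha = 0.05, cluster_alpha = 0.05,
                                  covariate = NULL, seed = NULL) {
  spectra <- tibble::as_tibble(spectra)
  stopifnot(all(c("subject", "freq", "value") %in% names(spectra)))
  bins <- sort(unique(spectra$freq))
  labels <- format(bins, trim = TRUE)
  maps <- tibble::tibble(subject = spectra$subject,
                         channel = format(spectra$freq, trim = TRUE),
                         value = spectra$value)
  graph <- chain_adjacency(labels)
  res <- cluster_permutation_test(maps, subject_table, graph,
                                  n_permutations = n_permutations,
                                  forming_alpha = forming_alpha,
                                  cluster_alpha = cluster_alpha,
                                  covariate = covariate, seed = seed)
  freq_of <- stats::setNames(bins, labels)
  cl <- res$clusters
  if (nrow(cl)) {
    res$ranges <- tibble::tibble(
      lo = vapply(cl$channels, function(ch) min(freq_of[ch]), numeric(1)),
      hi = vapply(cl$channels, function(ch) max(freq_of[ch]), numeric(1)),
      n_bins = cl$size, sign = cl$sign, p_perm = cl$p_perm,
      significant = cl$significant
    )
  } else {
    res$ranges <- tibble::tibble(lo = numeric(), hi = numeric(),
                                 n_bins = integer(), sign = character(),
                                 p_perm = numeric(), significant = logical())
  }
  res
}
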