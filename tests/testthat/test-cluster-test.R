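# Per-channel statistics, cluster finding against a union-find oracle, and
# the permutation test against exhaustive enumeration.

test_that("channel_stat reduces to the pooled t-test and honors sign convention", {
  set.seed(10)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(NULL, sprintf("E%03d", 1:6)))
  X[1:10, 1] <- X[1:10, 1] + 2
  st <- two_group_table(10, 10)
  cs <- channel_stat(maps_from_matrix(X), st)
  for (ch in 1:6) {
    ref <- t.test(X[1:10, ch], X[11:20, ch], var.equal = TRUE)
    expect_equal(cs$t[ch], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(cs$p[ch], ref$p.value, tolerance = 1e-10)
  }
  expect_gt(cs$t[1], 0)                       # affected-minus-control
  expect_equal(cs$df[1], 18)

  # identical groups: t = 0, p = 1 everywhere
  X2 <- rbind(X[1:10, ], X[1:10, ])
  cs2 <- channel_stat(maps_from_matrix(X2), st)
  expect_true(all(abs(cs2$t) < 1e-10))
  expect_true(all(cs2$p > 1 - 1e-10))
})

test_that("covariate-adjusted channel_stat matches the least-squares oracle", {
  set.seed(11)
  n <- 24
  st <- two_group_table(12, 12, age = rnorm(n, 10, 2))
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, sprintf("E%03d", 1:5)))
  X <- X + outer(st$age, rep(0.3, 5))
  cs <- channel_stat(maps_from_matrix(X), st, covariate = "age")
  g <- as.numeric(st$group == "affected")
  for (ch in 1:5) {
    fit <- summary(lm(X[, ch] ~ g + st$age))
    expect_equal(cs$t[ch], fit$coefficients["g", "t value"],
                 tolerance = 1e-10)
    expect_equal(cs$df[ch], n - 3)
  }
})

test_that("find_clusters matches a brute-force union-find oracle on random graphs", {
  set.seed(12)
  for (case in 1:100) {
    nn <- sample(4:12, 1)
    labels <- sprintf("N%02d", seq_len(nn))
    A <- matrix(FALSE, nn, nn, dimnames = list(labels, labels))
    for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
      A[i, j] <- A[j, i] <- runif(1) < 0.25
    }
    edges <- which(A & upper.tri(A), arr.ind = TRUE)
    g <- tiny_graph(labels, lapply(seq_len(nrow(edges)), function(r) {
      c(labels[edges[r, 1]], labels[edges[r, 2]])
    }))
    t_vals <- rnorm(nn) * 3
    p_vals <- 2 * pt(-abs(t_vals), df = 20)
    stats <- tibble::tibble(channel = labels, t = t_vals, p = p_vals)
    cl <- find_clusters(stats, g, forming_alpha = 0.3)

    for (sgn in c(1, -1)) {
      sig <- labels[p_vals < 0.3 & sign(t_vals) == sgn]
      want <- if (length(sig)) {
        unname(lapply(uf_components(sig, A), function(x) sort(unname(x))))
      } else list()
      got <- cl$channels[cl$sign == if (sgn > 0) "positive" else "negative"]
      expect_setequal(vapply(got, paste, "", collapse = ","),
                      vapply(want, paste, "", collapse = ","))
    }
  }
})

test_that("cluster ordering is deterministic: by size then first label", {
  labels <- c("A", "B", "C", "D", "E")
  g <- tiny_graph(labels, list(c("A", "B"), c("D", "E")))
  stats <- tibble::tibble(channel = labels,
                          t = c(3, 3, 3, 3, 3), p = rep(0.01, 5))
  cl <- find_clusters(stats, g)
  expect_equal(cl$size, c(2, 2, 1))
  expect_equal(vapply(cl$channels, `[`, "", 1), c("A", "D", "C"))
})

test_that("permutation critical value matches exhaustive enumeration (n1=n2=4, 6 channels)", {
  set.seed(13)
  labels <- sprintf("E%03d", 1:6)
  g <- tiny_graph(labels, list(c("E001", "E002"), c("E002", "E003"),
                               c("E003", "E004"), c("E004", "E005"),
                               c("E005", "E006")))
  X <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(NULL, labels))
  A <- adjacency_matrix(g)

  null_exact <- exhaustive_null(X, 4, A)
  crit_exact <- sleeptopo:::critical_cluster_stat(null_exact, 0.05)

  st <- two_group_table(4, 4)
  res <- cluster_permutation_test(maps_from_matrix(X), st, g,
                                  n_permutations = 10000, seed = 99)
  crit_mc <- res$critical
  expect_equal(crit_mc, crit_exact, tolerance = 1e-9)

  # sanity: the exact tail is not knife-edge at the 5% level for this fixture
  tail_at_crit <- mean(null_exact >= crit_exact)
  expect_lt(tail_at_crit, 0.05 + 1e-9)
})

test_that("permutation p-values respect the 1/(B+1) floor and seeds reproduce", {
  set.seed(14)
  labels <- sprintf("E%03d", 1:8)
  g <- tiny_graph(labels, lapply(1:7, function(i) c(labels[i], labels[i + 1])))
  X <- matrix(rnorm(16 * 8), 16, 8, dimnames = list(NULL, labels))
  X[1:8, 3:6] <- X[1:8, 3:6] + 3
  st <- two_group_table(8, 8)
  r1 <- cluster_permutation_test(maps_from_matrix(X), st, g,
                                 n_permutations = 200, seed = 5)
  r2 <- cluster_permutation_test(maps_from_matrix(X), st, g,
                                 n_permutations = 200, seed = 5)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$clusters$p_perm, r2$clusters$p_perm)
  expect_true(all(r1$clusters$p_perm >= 1 / 201))
  expect_true(any(r1$clusters$significant))
  # the injected contiguous block is recovered as the top cluster
  expect_true(all(c("E003", "E004", "E005", "E006") %in%
                    r1$clusters$channels[[1]]))
})

test_that("too few subjects for distinct permutations is an error", {
  labels <- sprintf("E%03d", 1:4)
  g <- tiny_graph(labels, list(c("E001", "E002"), c("E003", "E004")))
  X <- matrix(rnorm(4 * 4), 4, 4, dimnames = list(NULL, labels))
  st <- two_group_table(2, 2)
  expect_error(channel_stat(maps_from_matrix(X[1:3, ]), st), "2 subjects")
})

test_that("monotonicity: larger injected effects never shrink the detected cluster", {
  set.seed(15)
  m <- make_montage(32)
  g <- electrode_adjacency(m)
  roi <- select_roi_channels(m, 8)
  sizes <- sapply(c(0.3, 0.8, 1.6), function(eff) {
    median(sapply(1:8, function(s) {
      set.seed(100 + s)
      X <- matrix(rnorm(20 * 32), 20, 32, dimnames = list(NULL, m$channel))
      X[1:10, roi] <- X[1:10, roi] + eff
      st <- two_group_table(10, 10)
      res <- cluster_permutation_test(maps_from_matrix(X), st, g,
                                      n_permutations = 300, seed = s)
      if (nrow(res$clusters)) max(res$clusters$size) else 0
    }))
  })
  expect_true(!is.unsorted(sizes))
})

test_that("spectrum cluster test recovers a contiguous injected range", {
  set.seed(16)
  bins <- 1:20
  n <- 24
  V <- matrix(rnorm(n * 20, sd = 1), n, 20)
  V[1:12, 6:10] <- V[1:12, 6:10] + 2        # effect at 6-10 Hz
  spectra <- tibble::tibble(
    subject = rep(sprintf("S%02d", 1:n), 20),
    freq = rep(bins, each = n),
    value = as.vector(V)
  )
  st <- two_group_table(12, 12)
  res <- spectrum_cluster_test(spectra, st, n_permutations = 500, seed = 3)
  sig <- res$ranges[res$ranges$significant & res$ranges$sign == "positive", ]
  expect_gte(nrow(sig), 1)
  expect_gte(sig$lo[1], 5)
  expect_lte(sig$hi[1], 11)
})
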