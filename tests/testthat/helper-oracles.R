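# Independent oracles and small data builders shared across tests.

# connected components by plain union-find, independent of the package's BFS
uf_components <- function(nodes, adj_matrix) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (a in nodes) for (b in nodes) {
    if (a < b && adj_matrix[a, b]) parent[[find(a)]] <- find(b)
  }
  split(nodes, vapply(nodes, find, character(1)))
}

# exhaustive permutation null of the max cluster statistic for small designs,
# coded from first principles (plain t-tests + components on a matrix)
exhaustive_null <- function(X, n1, adj, forming_alpha = 0.05,
                            tie_break = TRUE) {
  n <- nrow(X)
  labels <- colnames(adj)
  combos <- utils::combn(n, n1)
  tcrit <- stats::qt(1 - forming_alpha / 2, n - 2)
  apply(combos, 2, function(idx) {
    t <- vapply(seq_len(ncol(X)), function(ch) {
      a <- X[idx, ch]; b <- X[-idx, ch]
      sp <- sqrt(((length(a) - 1) * stats::var(a) +
                    (length(b) - 1) * stats::var(b)) / (n - 2))
      (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    }, numeric(1))
    best <- 0
    for (sgn in c(1, -1)) {
      sig <- labels[sgn * t > tcrit]
      if (!length(sig)) next
      for (comp in uf_components(sig, adj)) {
        mass <- sum(abs(t[match(comp, labels)]))
        val <- if (tie_break) length(comp) + mass / (1 + mass)
               else length(comp)
        best <- max(best, val)
      }
    }
    best
  })
}

# deterministic small montage + graph for cluster tests
tiny_graph <- function(labels, edges) {
  nb <- stats::setNames(rep(list(character()), length(labels)), labels)
  for (e in edges) {
    nb[[e[1]]] <- sort(union(nb[[e[1]]], e[2]))
    nb[[e[2]]] <- sort(union(nb[[e[2]]], e[1]))
  }
  structure(list(neighbours = nb, labels = labels, method = "manual",
                 params = list()), class = "adjacency_graph")
}

# tidy maps from a subjects x channels matrix
maps_from_matrix <- function(X, subjects = sprintf("S%02d", seq_len(nrow(X)))) {
  tibble::tibble(
    subject = rep(subjects, ncol(X)),
    channel = rep(colnames(X), each = nrow(X)),
    value = as.vector(X)
  )
}

two_group_table <- function(n1, n2, age = NULL) {
  n <- n1 + n2
  tibble::tibble(
    subject = sprintf("S%02d", seq_len(n)),
    group = c(rep("affected", n1), rep("control", n2)),
    age = age %||% seq(8, 14, length.out = n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# constant-stage recording with one sine channel, for spectral checks
sine_recording <- function(freq, amp, fs = 120, minutes = 6, n_channels = 8) {
  m <- make_montage(n_channels)
  tt <- seq(0, minutes * 60 - 1 / fs, by = 1 / fs)
  x <- matrix(stats::rnorm(n_channels * length(tt), sd = 5), n_channels)
  x[1, ] <- amp * sin(2 * pi * freq * tt)
  eeg_recording(x, fs, m)
}
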