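# Fixture builders and independent naive oracles used across the suite.
# Oracles use explicit per-sample loops and base arithmetic only, never the
# package's log-domain implementations.

# cube from a list of learner matrices (samples x classes)
cube_from_matrices <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) && !is.matrix(mats[[1]])) {
    mats <- mats[[1]]
  }
  arr <- array(NA_real_, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  confidence_cube(arr)
}

# cube whose single sample has the given per-learner confidence rows
cube_from_rows <- function(...) {
  rows <- list(...)
  cube_from_matrices(lapply(rows, function(r) matrix(r, nrow = 1)))
}

# random simplex-row cube via normalized uniforms
random_cube <- function(n, N, K, min_conf = 0) {
  arr <- array(runif(n * N * K, min = min_conf), dim = c(n, N, K))
  for (i in seq_len(n)) {
    for (s in seq_len(N)) arr[i, s, ] <- arr[i, s, ] / sum(arr[i, s, ])
  }
  confidence_cube(arr)
}

oracle_arithmetic <- function(cube) {
  n <- dim(cube)[1]; N <- dim(cube)[2]; K <- dim(cube)[3]
  out <- matrix(0, N, K)
  for (s in seq_len(N)) {
    for (a in seq_len(K)) {
      acc <- 0
      for (i in seq_len(n)) acc <- acc + cube[i, s, a]
      out[s, a] <- acc / n
    }
  }
  out
}

oracle_geometric <- function(cube) {
  n <- dim(cube)[1]; N <- dim(cube)[2]; K <- dim(cube)[3]
  out <- matrix(0, N, K)
  for (s in seq_len(N)) {
    for (a in seq_len(K)) {
      p <- 1
      for (i in seq_len(n)) p <- p * cube[i, s, a]
      out[s, a] <- p^(1 / n)
    }
  }
  out
}

oracle_product <- function(cube) {
  n <- dim(cube)[1]; N <- dim(cube)[2]; K <- dim(cube)[3]
  out <- matrix(0, N, K)
  for (s in seq_len(N)) {
    for (a in seq_len(K)) {
      p <- 1
      for (i in seq_len(n)) p <- p * cube[i, s, a]
      out[s, a] <- p
    }
  }
  out
}

oracle_similarity <- function(cube) {
  n <- dim(cube)[1]; N <- dim(cube)[2]
  s_per <- numeric(N)
  for (s in seq_len(N)) {
    acc <- 0; npairs <- 0
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        acc <- acc + sum(cube[i, s, ] * cube[j, s, ])
        npairs <- npairs + 1
      }
    }
    s_per[s] <- acc / npairs
  }
  s_per
}

oracle_wrong_counts <- function(cube, truth) {
  n <- dim(cube)[1]; N <- dim(cube)[2]
  m <- integer(N)
  for (s in seq_len(N)) {
    for (i in seq_len(n)) {
      if (which.max(cube[i, s, ]) != truth[s]) m[s] <- m[s] + 1L
    }
  }
  m
}
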