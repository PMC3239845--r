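# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Upper-tail hypergeometric probability by direct summation of the mass
# function k -> C(m, k) C(N - m, n - k) / C(N, n).
brute_hyper_tail <- function(N, n, m, k) {
  ks <- k:min(n, m)
  sum(choose(m, ks) * choose(N - m, n - ks)) / choose(N, n)
}

# Edge density of a node subset by exhaustive pair enumeration.
brute_density <- function(W, nodes) {
  tot <- 0
  cnt <- 0
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i < j) {
        tot <- tot + W[nodes[i], nodes[j]]
        cnt <- cnt + 1
      }
    }
  }
  tot / cnt
}

# Random symmetric positive-definite-ish weight matrix with bounded condition
# number (used for reconstruction and eigen-route cross-checks).
random_spd <- function(N, cond_max = 100) {
  Q <- qr.Q(qr(matrix(rnorm(N * N), N)))
  d <- seq(1, cond_max, length.out = N)
  Q %*% diag(d) %*% t(Q)
}

# Angle (radians) between the spans of two vectors.
vector_angle <- function(u, v) {
  cosang <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, cosang))
}

# Smallest fixture reused by several files.
make_binary_fixture <- function(seed = 1) {
  generate_binary_pair(seed = seed)
}
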