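# Independent oracles used across the suite. These deliberately avoid the
# package's analysis path: dense eigendecompositions, direct polynomial
# evaluation, and raw per-layer update loops.

oracle_rho <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

# characteristic polynomial coefficients (ascending, monic) from the
# eigenvalue product prod(lambda_i - lambda) — independent of char_poly()
oracle_charpoly <- function(M) {
  ev <- eigen(M, only.values = TRUE)$values
  co <- 1 + 0i
  for (l in ev) co <- c(0, co) - c(l * co, 0)  # multiply by (lambda - l)
  Re(co)  # ascending: constant term first, like char_poly()
}

# raw per-layer update loop written directly from the scalar equations,
# bypassing effective_matrix / iterate_dynamics
oracle_simulate <- function(m_ff, m_fb, x, scheme, steps = 2000, h0 = NULL) {
  N <- nrow(m_ff)
  h <- if (is.null(h0)) rep(0, N) else h0
  for (t in seq_len(steps)) {
    h_new <- numeric(N)
    for (l in seq_len(N)) {
      ff_src <- if (l > 1) (if (scheme == "biological") h[l - 1] else h_new[l - 1]) else 0
      h_new[l] <- (if (l == 1) x else 0) +
        m_ff[l, max(l - 1, 1)] * ff_src +
        sum(m_fb[l, ] * h)
    }
    h <- h_new
    if (max(abs(h)) > 1e8) return(list(h = h, diverged = TRUE))
  }
  list(h = h, diverged = FALSE)
}

# uniform-chain + single-distance-q matrices built directly, not via from_family
oracle_single_q_mats <- function(N, q, w_ff, w_fb) {
  m_ff <- matrix(0, N, N)
  if (N > 1) m_ff[cbind(2:N, 1:(N - 1))] <- w_ff
  m_fb <- matrix(0, N, N)
  if (N - q >= 1) m_fb[cbind(1:(N - q), (1:(N - q)) + q)] <- w_fb
  list(m_ff = m_ff, m_fb = m_fb)
}

random_spec_pool <- function(n, seed, n_layers = 3:8, distances_max = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    N <- sample(n_layers, 1)
    nd <- sample.int(distances_max, 1)
    dists <- sample(0:(N - 1), min(nd, N))
    random_network(N, dists, seed = sample.int(1e6, 1))
  })
}

# cortically signed random network: excitatory feedforward chain (weights in
# [0, 1]), inhibitory feedback (weights in [-1, 0]) at random distances
random_cortical_spec <- function(N, dists) {
  w <- data.frame(from = if (N > 1) 1:(N - 1) else integer(0),
                  to = if (N > 1) 2:N else integer(0),
                  value = if (N > 1) stats::runif(N - 1, 0, 1) else numeric(0))
  for (q in dists) {
    k <- N - q
    w <- rbind(w, data.frame(from = (1:k) + q, to = 1:k,
                             value = stats::runif(k, -1, 0)))
  }
  layered_network_spec(N, w)
}
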