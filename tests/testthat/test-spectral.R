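as_poly <- function(co) structure(list(coefficients = co,
                                       degree = length(co) - 1L),
                                  class = "char_poly")

test_that("effective matrices implement both delay schemes", {
  # no feedback: artificial effective matrix is zero (always stable)
  chain <- build_matrices(layered_network_spec(
    4, data.frame(from = 1:3, to = 2:4, value = 0.9)))
  expect_equal(effective_matrix(chain, "artificial"), matrix(0, 4, 4))

  # nilpotent feedforward: inverse equals the finite Neumann series
  set.seed(31)
  sp <- random_network(6, c(1, 4), seed = 8)
  mats <- build_matrices(sp)
  S <- diag(6)
  P <- diag(6)
  for (k in 1:5) { P <- P %*% mats$m_ff; S <- S + P }
  expect_equal(effective_matrix(mats, "artificial"), S %*% mats$m_fb,
               tolerance = 1e-12)

  # 2-layer hand computation: feedforward beta, feedback f
  beta <- 0.7; f <- -0.4
  sp2 <- layered_network_spec(2, data.frame(from = c(1, 2), to = c(2, 1),
                                            value = c(beta, f)))
  MA <- effective_matrix(build_matrices(sp2), "artificial")
  expect_equal(MA[1, 2], f)
  expect_equal(MA[2, 2], beta * f)
  expect_equal(MA[1, 1], 0)
})

test_that("characteristic polynomials reproduce the N=2 and N=3 closed forms", {
  set.seed(7)
  for (rep in 1:10) {
    a <- matrix(runif(9, -1, 1), 3, 3)  # a[j, i] = alpha_{j -> i}
    # N = 2 network with self-loops and a reciprocal pair
    sp2 <- layered_network_spec(2, data.frame(
      from = c(1, 2, 1, 2), to = c(1, 2, 2, 1),
      value = c(a[1, 1], a[2, 2], a[1, 2], a[2, 1])))
    m2 <- build_matrices(sp2)
    cb <- char_poly(effective_matrix(m2, "biological"))$coefficients
    ca <- char_poly(effective_matrix(m2, "artificial"))$coefficients
    expect_equal(cb[1], a[1, 1] * a[2, 2] - a[1, 2] * a[2, 1], tolerance = 1e-12)
    expect_equal(cb[2], -(a[1, 1] + a[2, 2]), tolerance = 1e-12)
    expect_equal(ca[1], a[1, 1] * a[2, 2], tolerance = 1e-12)
    expect_equal(ca[2], -(a[1, 1] + a[2, 2] + a[1, 2] * a[2, 1]), tolerance = 1e-12)

    # N = 3 with all allowed connections
    sp3 <- layered_network_spec(3, data.frame(
      from = c(1, 2, 1, 2, 3, 2, 3, 3),
      to   = c(2, 3, 1, 2, 3, 1, 2, 1),
      value = c(a[1, 2], a[2, 3], a[1, 1], a[2, 2], a[3, 3],
                a[2, 1], a[3, 2], a[3, 1])))
    m3 <- build_matrices(sp3)
    k1 <- a[1, 1] + a[2, 2] + a[3, 3]
    k2 <- a[1, 2] * a[2, 1] + a[2, 3] * a[3, 2]
    k3 <- a[1, 2] * a[2, 3] * a[3, 1]
    k4 <- a[1, 1] * a[2, 2] + a[1, 1] * a[3, 3] + a[2, 2] * a[3, 3]
    k5 <- a[1, 1] * a[2, 3] * a[3, 2] + a[3, 3] * a[1, 2] * a[2, 1]
    k6 <- a[1, 1] * a[2, 2] * a[3, 3]
    cb3 <- char_poly(effective_matrix(m3, "biological"))$coefficients
    ca3 <- char_poly(effective_matrix(m3, "artificial"))$coefficients
    expect_equal(cb3[1:3], c(-(k6 + k3 - k5), k4 - k2, -k1), tolerance = 1e-10)
    expect_equal(ca3[1:3], c(-k6, k4 + k5, -(k1 + k2 + k3)), tolerance = 1e-10)
  }

  expect_equal(char_poly(matrix(0, 4, 4))$coefficients, c(0, 0, 0, 0, 1))
})

test_that("char_poly roots equal the eigenvalue multiset up to N = 12", {
  set.seed(12)
  for (N in c(3, 6, 9, 12)) {
    sp <- random_network(N, sample(0:(N - 1), 2), seed = N)
    for (scheme in c("biological", "artificial")) {
      M <- effective_matrix(build_matrices(sp), scheme)
      co <- char_poly(M)$coefficients
      # oracle: coefficients from the eigenvalue product
      expect_equal(co, oracle_charpoly(M), tolerance = 1e-8)
      # nonzero roots (zero root deflated first — polyroot scatters
      # multiple zero roots by eps^(1/multiplicity) otherwise)
      keep <- which(abs(co) > 1e-9 * max(abs(co)))
      mult0 <- keep[1] - 1  # zero-root multiplicity from deflation
      rts <- if (mult0 >= length(co) - 1) complex(0)
             else polyroot(co[(mult0 + 1):length(co)])
      # eigen() scatters defective zeros by eps^(1/mult), so select the
      # N - mult0 largest eigenvalues as the genuine nonzero ones
      ev <- sort(Mod(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
      ev_nz <- ev[seq_len(N - mult0)]
      expect_equal(sort(Mod(rts), decreasing = TRUE), ev_nz,
                   tolerance = 1e-6)
    }
  }
})

test_that("unit-circle conditions detect roots on the circle", {
  # lambda^2 - lambda + 1 has roots e^{+/- i pi/3}
  p <- as_poly(c(1, -1, 1))
  res <- unit_circle_condition(p, pi / 3)
  expect_lt(max(abs(res)), 1e-12)
  expect_lt(Mod(eval_poly(p, exp(1i * pi / 3))), 1e-12)

  # theta = 0 reduces to p(1)
  p0 <- as_poly(c(-0.5, -0.5, 1))
  expect_equal(as.numeric(unit_circle_condition(p0, 0)), 0)

  # N = 2 reduction: residuals are c0 - 1 and c1 + 2 cos(theta)
  set.seed(3)
  for (i in 1:10) {
    co <- c(runif(2, -2, 2), 1)
    th <- runif(1, 0.1, pi - 0.1)
    r <- unit_circle_condition(as_poly(co), th)
    expect_equal(as.numeric(r), c(co[1] - 1, co[2] + 2 * cos(th)),
                 tolerance = 1e-12)
  }

  # residuals vanish iff e^{i theta} is a root (both directions)
  set.seed(19)
  for (i in 1:200) {
    N <- sample(2:6, 1)
    th <- runif(1, 0.05, pi - 0.05)
    if (i %% 2 == 0) {
      # plant the conjugate root pair e^{+/- i theta}
      rest <- c(runif(N - 2, -1, 1), 1)
      quad <- c(1, -2 * cos(th), 1)
      co <- numeric(N + 1)
      for (k in seq_along(rest)) co[k:(k + 2)] <- co[k:(k + 2)] + rest[k] * quad
      r <- unit_circle_condition(as_poly(co), th)
      expect_lt(max(abs(r)), 1e-10)
      expect_lt(Mod(eval_poly(as_poly(co), exp(1i * th))), 1e-10)
    } else {
      co <- c(runif(N, -1, 1), 1)
      pv <- Mod(eval_poly(as_poly(co), exp(1i * th)))
      r <- unit_circle_condition(as_poly(co), th)
      if (pv > 1e-6) expect_gt(max(abs(r)), 1e-10)
    }
  }
})

test_that("stability classification follows the spectral radius", {
  z <- classify_stability(matrix(0, 3, 3))
  expect_equal(z$classification, "stable")
  expect_equal(z$spectral_radius, 0)

  spf <- from_family(canonical_family("fully_connected",
                                      list(w_i = 0, w_e = 0.4)), 3)
  rf <- classify_stability(build_matrices(spf), scheme = "biological")
  expect_equal(rf$classification, "stable")
  expect_equal(sort(Re(rf$eigenvalues)), c(-0.4, -0.4, 0.8), tolerance = 1e-12)

  spq <- from_family(canonical_family("single_q",
                                      list(q = 3, w_ff = 1, w_fb = 0.5)), 5)
  rq <- classify_stability(build_matrices(spq), scheme = "artificial")
  expect_equal(rq$classification, "marginal")
  expect_equal(rq$spectral_radius, 1, tolerance = 1e-12)
})

test_that("single-distance closed forms match dense eigensolver output", {
  # exact regime N/2 - 1 < q: dominant eigenvalue is g_q (N - q)
  cases <- list(c(5, 3, 0.8, 0.5), c(5, 4, 1.1, -0.3), c(7, 4, 0.9, 0.6),
                c(4, 3, 1.0, 0.7), c(9, 5, 0.95, 0.2))
  for (cs in cases) {
    N <- cs[1]; q <- cs[2]; wf <- cs[3]; wb <- cs[4]
    pred <- single_q_dominant_eigenvalue(N, q, wf, wb)
    m <- oracle_single_q_mats(N, q, wf, wb)
    MA <- solve(diag(N) - m$m_ff, m$m_fb)
    ev <- eigen(MA, only.values = TRUE)$values
    dom <- ev[which.max(Mod(ev))]
    expect_lt(Mod(dom - as.numeric(pred)), 1e-10)
    expect_true(attr(pred, "exact_regime"))
  }
  expect_equal(as.numeric(single_q_dominant_eigenvalue(6, 5, 0.9, 0.4)),
               0.4 * 0.9^5)   # single loop: N - q = 1
  expect_equal(as.numeric(single_q_dominant_eigenvalue(5, 3, 0.8, 0)), 0)

  # trace identity for q <= N/2 - 1, and zero-root multiplicity >= 2q
  expect_warning(single_q_dominant_eigenvalue(6, 1, 1, 0.2), "trace")
  set.seed(4)
  for (cs in list(c(6, 1), c(8, 2), c(10, 3), c(9, 2))) {
    N <- cs[1]; q <- cs[2]
    wf <- runif(1, 0.5, 1.2); wb <- runif(1, -0.8, 0.8)
    m <- oracle_single_q_mats(N, q, wf, wb)
    MA <- solve(diag(N) - m$m_ff, m$m_fb)
    ev <- eigen(MA, only.values = TRUE)$values
    expect_lt(abs(Re(sum(ev)) - single_q_trace_identity(N, q, wf, wb)), 1e-10)
    expect_lt(abs(Im(sum(ev))), 1e-10)
    expect_gte(sum(Mod(ev) < 1e-8), 2 * q)
  }
  expect_equal(single_q_trace_identity(6, 1, 1, 0), 0)
})

test_that("fully connected closed form and stability interval are exact", {
  expect_equal(fully_connected_eigenvalues(4, 0.3, 0),
               as.complex(rep(0.3, 4)))
  expect_equal(sort(Re(fully_connected_eigenvalues(3, 0, 0.4))),
               c(-0.4, -0.4, 0.8))

  # closed form vs dense solver on random parameters
  set.seed(6)
  for (i in 1:10) {
    N <- sample(2:9, 1); wi <- runif(1, -1, 1); we <- runif(1, -1, 1)
    M <- matrix(we, N, N); diag(M) <- wi
    expect_equal(sort(Re(fully_connected_eigenvalues(N, wi, we))),
                 sort(Re(eigen(M, only.values = TRUE)$values)),
                 tolerance = 1e-10)
  }

  # N = 11, w_i = 0: stable iff |w_e| < 0.1 (numeric sweep oracle)
  iv <- fully_connected_stable_interval(11, 0)
  expect_equal(iv, c(-0.1, 0.1))
  for (we in c(-0.11, -0.09, 0.09, 0.11)) {
    M <- matrix(we, 11, 11); diag(M) <- 0
    expect_equal(oracle_rho(M) < 1, we > iv[1] && we < iv[2])
  }
})

test_that("mixed-feedback prediction matches the dense spectrum", {
  # g2 = 0 reduces to the single-q interval
  r0 <- mixed_feedback_prediction(8, 4, 6, 0.1, 0)
  expect_equal(r0$stable_interval_g1, c(-0.25, 0.25))

  two_dist <- function(N, q1, q2, g1, g2) {
    w <- data.frame(from = 1:(N - 1), to = 2:N, value = 1)
    w <- rbind(w, data.frame(from = (1:(N - q1)) + q1, to = 1:(N - q1), value = g1),
               data.frame(from = (1:(N - q2)) + q2, to = 1:(N - q2), value = g2))
    build_matrices(layered_network_spec(N, w))
  }
  r <- mixed_feedback_prediction(8, 4, 6, 0.1, 0.1)
  expect_equal(r$predicted_eigenvalue, 0.6)
  rho <- oracle_rho(effective_matrix(two_dist(8, 4, 6, 0.1, 0.1), "artificial"))
  expect_lt(abs(rho - 0.6), 0.05)

  # upper interval edge sits on the bifurcation boundary (approximately)
  g2 <- 0.1
  edge <- mixed_feedback_prediction(8, 4, 6, 0, g2)$stable_interval_g1[2]
  rho_edge <- oracle_rho(effective_matrix(two_dist(8, 4, 6, edge, g2), "artificial"))
  expect_lt(abs(rho_edge - 1), 0.05)
})

test_that("scheme equivalence holds exactly for single-distance feedback", {
  # no feedback: trivially equivalent
  er0 <- verify_equivalence(layered_network_spec(
    3, data.frame(from = 1:2, to = 2:3, value = 0.5)))
  expect_true(er0$nonzero_root_match)
  expect_equal(er0$max_root_mismatch, 0)

  set.seed(21)
  for (i in 1:30) {
    N <- sample(3:8, 1)
    q <- sample(1:(N - 1), 1)
    sp <- random_network(N, q, seed = 500 + i)
    er <- verify_equivalence(sp)
    expect_true(er$is_single_distance)
    expect_true(er$nonzero_root_match)
    expect_lt(er$max_root_mismatch, 1e-8)
    expect_equal(er$k3, q + 1L)
  }

  # mixed distances 0 and 2 in N = 3: boundaries differ for some weights
  found <- FALSE
  for (w0 in c(-0.9, -0.5, 0.5, 0.9)) for (w2 in c(-0.9, 0.9)) {
    sp <- layered_network_spec(3, data.frame(
      from = c(1, 2, 1, 2, 3, 3), to = c(2, 3, 1, 2, 3, 1),
      value = c(1, 1, w0, w0, w0, w2)))
    er <- verify_equivalence(sp)
    expect_false(er$is_single_distance)
    if (er$max_root_mismatch > 1e-6) found <- TRUE
  }
  expect_true(found)
})

test_that("boundary tracing locates the fig5a bifurcation curve", {
  # on the w_p axis (w_i = 0) the biological boundary is at w_p = 1:
  # eigenvalues are w_i +/- sqrt(w_p)
  rho_bio <- function(wp) {
    m <- build_matrices(slice_spec("fig5a", 0, wp))
    max(Mod(eigen(effective_matrix(m, "biological"), only.values = TRUE)$values))
  }
  expect_equal(bisect_radius(rho_bio, 0.5, 1.5), 1, tolerance = 1e-8)

  bs <- trace_boundary(canonical_family("fig5a"), grid = 41,
                       ranges = list(c(-2, 0), c(-2, 0)))
  expect_s3_class(bs, "boundary_slice")
  # boundary points sit on |rho - 1| < 1e-6
  for (k in seq_len(min(nrow(bs$boundary), 20))) {
    p <- bs$boundary[k, ]
    m <- build_matrices(slice_spec("fig5a", p$param1, p$param2))
    rho <- max(Mod(eigen(effective_matrix(m, as.character(p$scheme)),
                         only.values = TRUE)$values))
    expect_lt(abs(rho - 1), 1e-5)
  }
  # inhibitory quadrant: artificial stable region inside the biological one
  viol <- bs$classification$artificial == "stable" &
          bs$classification$biological == "unstable"
  expect_equal(sum(viol), 0L)

  expect_error(trace_boundary(canonical_family("fig5a"), grid = 11,
                              ranges = list(c(0, 0), c(-1, 1))),
               "degenerate")
})

test_that("stability thresholds rise with feedback distance", {
  # monotonicity holds in the per-link parameterization (a distance-q loop
  # traverses q + 1 links); raw feedback-weight thresholds with the chain
  # pinned at 1 are non-monotone at small q
  th_link <- vapply(1:5, function(q) feedback_threshold(6, q, per_link = TRUE), 0)
  expect_true(all(diff(th_link) >= -1e-9))
  th <- vapply(1:5, function(q) feedback_threshold(6, q), 0)
  # exact regime check: threshold equals 1/(N - q) for w_ff = 1
  expect_equal(th[4], 1 / 2, tolerance = 1e-8)
  expect_equal(th[5], 1, tolerance = 1e-8)

  # per-link threshold formula beats the fully connected 1/(N - 1)
  for (N in 3:10) for (q in 1:(N - 1))
    expect_gt((1 / (N - q))^(1 / (q + 1)), 1 / (N - 1))

  # per-link bisection agrees with the closed form in the exact regime
  expect_equal(feedback_threshold(6, 4, per_link = TRUE),
               (1 / 2)^(1 / 5), tolerance = 1e-8)
})
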