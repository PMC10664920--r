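#' Effective one-step update matrix of the linear dynamics
#'
#' Biological scheme (feedforward delayed): `M_B = M_FF + M_FB`.
#' Artificial scheme (feedforward instantaneous):
#' `M_A = (Id - M_FF)^{-1} M_FB`. Because `M_FF` is strictly subdiagonal the
#' inverse is the finite Neumann series `Id + M_FF + ... + M_FF^{N-1}`.
#'
#' @param mats A [build_matrices()] result.
#' @param scheme `"biological"` or `"artificial"`.
#' @return N x N real matrix.
#' @export
effective_matrix <- function(mats, scheme = c("biological", "artificial")) {
  scheme <- match.arg(scheme)
  if (scheme == "biological") mats$m_ff + mats$m_fb
  else solve(diag(nrow(mats$m_ff)) - mats$m_ff, mats$m_fb)
}

#' Monic characteristic polynomial of a square matrix
#'
#' @param m Square real matrix.
#' @return Object of class `char_poly` holding ascending coefficients
#'   `c_0, ..., c_N` with `c_N = 1` (monic).
#' @export
#' @examples
#' char_poly(matrix(c(0, 1, 2, 0), 2, 2))  # lambda^2 - 2
char_poly <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  co <- pracma::charpoly(m)       # descending, monic
  structure(list(coefficients = rev(co), degree = nrow(m)),
            class = "char_poly")
}

#' @export
print.char_poly <- function(x, ...) {
  cat("Monic characteristic polynomial, degree", x$degree, "\n")
  cat("  c_0..c_N:", paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a char_poly at (complex) points
#' @param poly A `char_poly`.
#' @param z Complex or numeric vector of evaluation points.
#' @return Complex vector of values.
#' @export
eval_poly <- function(poly, z) {
  co <- poly$coefficients
  out <- rep(0 + 0i, length(z))
  for (k in rev(seq_along(co))) out <- out * z + co[k]
  out
}

# Chebyshev polynomials of the second kind U_0..U_n at z, via the
# three-term recurrence U_0 = 1, U_1 = 2z, U_n = 2z U_{n-1} - U_{n-2}.
cheb_u <- function(n_max, z) {
  u <- numeric(n_max + 1L)
  u[1L] <- 1
  if (n_max >= 1L) u[2L] <- 2 * z
  if (n_max >= 2L) for (n in 2:n_max) u[n + 1L] <- 2 * z * u[n] - u[n - 1L]
  u
}

#' Unit-circle root conditions for a real polynomial
#'
#' `e^{i theta}` is a root of the monic real polynomial `p` iff the returned
#' residuals all vanish. For `theta` away from 0 and pi the pair
#' `(c_0 - sum_{n=0}^{N-2} c_{n+2} U_n(z), sum_{n=0}^{N-1} c_{n+1} U_n(z))`
#' with `z = cos(theta)` and `U_n` the Chebyshev polynomials of the second
#' kind; at `theta = 0` or `pi` the single alternating sum
#' `sum_n c_n (-1)^{m n}` (i.e. `p(1)` or `p(-1)`).
#'
#' @param poly A [char_poly()].
#' @param theta Angle in `[0, 2 pi)`.
#' @param endpoint_tol Angular tolerance for treating theta as 0 or pi.
#' @return Numeric residual vector (length 2 away from the endpoints,
#'   length 1 at them), with attribute `"theta_case"`.
#' @export
unit_circle_condition <- function(poly, theta, endpoint_tol = 1e-12) {
  co <- poly$coefficients            # c_0 .. c_N, ascending
  N <- poly$degree
  cc <- function(n) co[n + 1L]       # c_n by subscript
  m <- theta / pi
  if (min(abs(theta), abs(theta - pi), abs(theta - 2 * pi)) < endpoint_tol) {
    mm <- round(m) %% 2
    res <- sum(co * (-1)^(mm * (0:N)))
    return(structure(res, theta_case = if (mm == 0) "theta=0" else "theta=pi"))
  }
  z <- cos(theta)
  u <- cheb_u(max(N - 1L, 0L), z)     # U_0 .. U_{N-1}
  r1 <- cc(0) - if (N >= 2L) sum(vapply(0:(N - 2L), function(n) cc(n + 2L) * u[n + 1L], 0)) else 0
  r2 <- sum(vapply(0:(N - 1L), function(n) cc(n + 1L) * u[n + 1L], 0))
  structure(c(r1, r2), theta_case = "interior")
}

#' Spectral stability classification
#'
#' Computes the eigenvalues of the effective matrix and classifies the fixed
#' point: stable when the spectral radius is `< 1 - marginal_tol`, unstable
#' when `> 1 + marginal_tol`, marginal within the band. The band separates
#' genuine bifurcation-boundary points from floating-point noise.
#'
#' @param m Square real matrix (an effective matrix), or a
#'   `connectivity_matrices` object together with `scheme`.
#' @param marginal_tol Half-width of the marginal band (default 1e-8).
#' @param scheme Recorded in the report (and used to form the effective
#'   matrix when `m` is a `connectivity_matrices`).
#' @return A `stability_report`: `eigenvalues`, `spectral_radius`,
#'   `classification`, `dominant_eigenvalue`, `scheme`.
#' @export
#' @examples
#' classify_stability(matrix(c(0, 1, 2, 0), 2, 2))  # rho = sqrt(2): unstable
classify_stability <- function(m, marginal_tol = 1e-8, scheme = NULL) {
  stopifnot(marginal_tol > 0)
  if (inherits(m, "connectivity_matrices")) {
    scheme <- match.arg(scheme, c("biological", "artificial"))
    m <- effective_matrix(m, scheme)
  }
  ev <- eigen(m, only.values = FALSE)$values
  mags <- Mod(ev)
  rho <- max(mags)
  cls <- if (rho < 1 - marginal_tol) "stable"
         else if (rho > 1 + marginal_tol) "unstable"
         else "marginal"
  structure(list(eigenvalues = ev,
                 spectral_radius = rho,
                 classification = cls,
                 dominant_eigenvalue = ev[which.max(mags)],
                 scheme = scheme,
                 marginal_tol = marginal_tol),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability: %s (spectral radius %.6g)%s\n", x$classification,
              x$spectral_radius,
              if (!is.null(x$scheme)) paste0(", ", x$scheme, " scheme") else ""))
  cat("  dominant eigenvalue:", format(x$dominant_eigenvalue, digits = 6), "\n")
  invisible(x)
}

# spectral radius of a spec under a scheme (internal fast path)
spectral_radius <- function(mats, scheme) {
  max(Mod(eigen(effective_matrix(mats, scheme), only.values = TRUE)$values))
}

#' Closed-form dominant eigenvalue for single-distance feedback
#'
#' For a uniform feedforward chain (weight `w_ff`) with feedback of a single
#' distance `q` (weight `w_fb`), the loop gain is `g_q = w_fb * w_ff^q` (one
#' feedback link plus q feedforward hops) and the network holds `N - q` such
#' loops. When `N/2 - 1 < q <= N - 1` the dominant eigenvalue of the
#' effective matrix is exactly `g_q * (N - q)`; outside that regime the same
#' quantity is only the trace (eigenvalue-sum) prediction and the result is
#' flagged approximate.
#'
#' @param n_layers N.
#' @param q Feedback distance, `1 <= q <= N - 1`.
#' @param w_ff,w_fb Uniform feedforward / feedback weights.
#' @return The predicted dominant eigenvalue, with attribute
#'   `"exact_regime"` (TRUE/FALSE).
#' @export
#' @examples
#' single_q_dominant_eigenvalue(5, 3, 0.8, 0.5)  # 0.5 * 0.8^3 * 2 = 0.512
single_q_dominant_eigenvalue <- function(n_layers, q, w_ff, w_fb) {
  N <- as.integer(n_layers); q <- as.integer(q)
  stopifnot(q >= 0L, q <= N - 1L)
  exact <- (N / 2 - 1) < q
  if (!exact)
    warning("q <= N/2 - 1: returning the trace prediction, not an exact eigenvalue")
  g <- w_fb * w_ff^q
  structure(g * (N - q), exact_regime = exact)
}

#' Trace identity for single-distance feedback
#'
#' For `q <= N/2 - 1` the characteristic polynomial of the artificial
#' effective matrix factors as `lambda^{2q} g(lambda)`, and the sum of the
#' nonzero eigenvalues equals `g_q * (N - q)` with loop gain
#' `g_q = w_fb * w_ff^q`.
#'
#' @inheritParams single_q_dominant_eigenvalue
#' @return The predicted eigenvalue sum `g_q * (N - q)`.
#' @export
single_q_trace_identity <- function(n_layers, q, w_ff, w_fb) {
  N <- as.integer(n_layers); q <- as.integer(q)
  stopifnot(q >= 0L, q <= N - 1L)
  w_fb * w_ff^q * (N - q)
}

#' Eigenvalues and stability interval of a fully connected network
#'
#' For the all-to-all matrix with self-weight `w_i` and coupling `w_e` the
#' eigenvalues are `w_i - w_e` (multiplicity N - 1) and
#' `w_i + (N - 1) w_e` (multiplicity 1). The fixed point is stable iff
#' `-(1 + w_i)/(N - 1) < w_e < min(w_i + 1, (1 - w_i)/(N - 1))`.
#'
#' @param n_layers N (>= 2); here the number of units.
#' @param w_i Self-interaction weight.
#' @param w_e Between-unit coupling weight.
#' @return `fully_connected_eigenvalues`: complex vector of length N.
#'   `fully_connected_stable_interval`: the `(lo, hi)` interval on `w_e`.
#' @export
fully_connected_eigenvalues <- function(n_layers, w_i, w_e) {
  N <- as.integer(n_layers)
  stopifnot(N >= 2L)
  as.complex(c(rep(w_i - w_e, N - 1L), w_i + (N - 1L) * w_e))
}

#' @rdname fully_connected_eigenvalues
#' @export
fully_connected_stable_interval <- function(n_layers, w_i) {
  N <- as.integer(n_layers)
  c(-(1 + w_i) / (N - 1L), min(w_i + 1, (1 - w_i) / (N - 1L)))
}

#' Dominant-eigenvalue prediction for feedback at two distances
#'
#' For feedback at distances `q1 < q2` with loop gains `g1`, `g2` (each
#' `g = w_fb * w_ff^q`), in the regime `N/2 - 1 < q1` the relevant
#' eigenvalue is approximately `g1 (N - q1) + g2 (N - q2)`, giving the
#' stability interval on `g1`
#' `[-1/(N - q1) - g2 (N - q2)/(N - q1), 1/(N - q1) - g2 (N - q2)/(N - q1)]`:
#' a longer second loop with negative contribution enlarges the admissible
#' range of the shorter one.
#'
#' @param n_layers N.
#' @param q1,q2 Feedback distances with `q1 < q2 <= N - 1`.
#' @param g1,g2 Loop gains of the two distances.
#' @return List with `predicted_eigenvalue`, `stable_interval_g1`, and
#'   `exact_regime` flag (FALSE marks the approximate regime).
#' @export
mixed_feedback_prediction <- function(n_layers, q1, q2, g1, g2) {
  N <- as.integer(n_layers)
  stopifnot(q1 < q2, q2 <= N - 1L)
  exact <- (N / 2 - 1) < q1
  shift <- g2 * (N - q2) / (N - q1)
  list(predicted_eigenvalue = g1 * (N - q1) + g2 * (N - q2),
       stable_interval_g1 = c(-1 / (N - q1) - shift, 1 / (N - q1) - shift),
       exact_regime = exact)
}

#' Bisection estimate of the feedback-weight stability threshold
#'
#' For a uniform chain with single-distance-q feedback, finds the feedback
#' weight at which the spectral radius of the effective matrix crosses 1.
#' With `per_link = TRUE` the same weight `w` is placed on every link
#' (feedforward and feedback) and the per-link threshold is returned
#' (closed form `(1/(N - q))^{1/(q + 1)}` in the exact regime).
#'
#' @param n_layers N.
#' @param q Feedback distance.
#' @param w_ff Feedforward weight when `per_link = FALSE`.
#' @param scheme Delay scheme used for the effective matrix.
#' @param per_link Sweep a common per-link weight instead of the feedback
#'   weight alone.
#' @param upper Upper end of the bisection bracket.
#' @param tol Bisection tolerance on the weight.
#' @return The threshold weight (spectral radius 1 within `tol`).
#' @export
feedback_threshold <- function(n_layers, q, w_ff = 1,
                               scheme = "artificial", per_link = FALSE,
                               upper = 10, tol = 1e-10) {
  rho_at <- function(w) {
    p <- if (per_link) list(q = q, w_ff = w, w_fb = w)
         else list(q = q, w_ff = w_ff, w_fb = w)
    sp <- from_family(canonical_family("single_q", p), n_layers)
    spectral_radius(build_matrices(sp), scheme)
  }
  lo <- 0; hi <- upper
  if (rho_at(hi) < 1) return(structure(Inf, note = "stable throughout bracket"))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (rho_at(mid) < 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Check the spectral equivalence of the two delay schemes
#'
#' For a network whose feedback sits at a single distance q, the
#' characteristic polynomials of the two effective matrices are related by
#' `p_A(lambda) = lambda^{k1} g(lambda)`,
#' `p_B(lambda) = lambda^{k2} g(lambda^{k3})`: every nonzero root `z` of
#' `p_B` satisfies `z^{k3}` is a root of `p_A`, so the bifurcation
#' boundaries of the two schemes coincide. The exponent `k3` is discovered
#' by search over `1..N` (expected `q + 1`). For mixed feedback distances
#' the best-matching `k3` and the residual mismatch are reported; a strictly
#' positive mismatch signals that the two schemes' boundaries differ.
#'
#' Nonzero roots are extracted by deflating the zero root first: the
#' trailing (low-order) characteristic coefficients below
#' `zero_tol * max|c|` are dropped and `polyroot` is applied to the deflated
#' polynomial. Deflation is the numerically safe route here — both effective
#' matrices are typically defective at zero (nilpotent Jordan blocks), so
#' dense eigensolvers scatter the zero eigenvalue by as much as
#' `eps^(1/multiplicity)`, which magnitude thresholds cannot separate from
#' genuine small roots. The two polynomials share their nonzero coefficient
#' values (both equal the coefficients of `g`), so the deflation cutoff acts
#' consistently on both schemes.
#'
#' @param spec A `layered_network_spec`.
#' @param tol Root-matching tolerance (default 1e-8).
#' @param zero_tol Relative characteristic-coefficient cutoff used to
#'   deflate the zero root (default 1e-9).
#' @return An `equivalence_report`: `is_single_distance`, `q` (or NA), `k3`,
#'   `nonzero_root_match`, `max_root_mismatch`.
#' @export
verify_equivalence <- function(spec, tol = 1e-8, zero_tol = 1e-9) {
  mats <- build_matrices(spec)
  N <- nrow(mats$m_ff)
  qs <- feedback_distances(spec)
  single <- length(qs) <= 1L

  if (all(mats$m_fb == 0)) {
    return(structure(list(is_single_distance = TRUE, q = NA_integer_,
                          k3 = 1L, nonzero_root_match = TRUE,
                          max_root_mismatch = 0),
                     class = "equivalence_report"))
  }
  roots_nz <- function(scheme) {
    co <- char_poly(effective_matrix(mats, scheme))$coefficients
    keep <- which(abs(co) > zero_tol * max(abs(co)))
    mult0 <- keep[1L] - 1L  # algebraic multiplicity of the zero root
    if (mult0 >= length(co) - 1L) return(complex(0))
    polyroot(co[(mult0 + 1L):length(co)])
  }
  zb <- roots_nz("biological")
  za <- roots_nz("artificial")

  mismatch_for <- function(k3) {
    if (!length(zb)) return(0)
    if (!length(za)) return(Inf)
    max(vapply(zb, function(z) min(Mod(z^k3 - za)), 0))
  }
  mis <- vapply(seq_len(N), mismatch_for, 0)
  k3 <- which.min(mis)
  # prefer the smallest k3 achieving a within-tolerance match
  ok <- which(mis <= tol)
  if (length(ok)) k3 <- min(ok)
  structure(list(is_single_distance = single,
                 q = if (single) qs[1L] else NA_integer_,
                 k3 = as.integer(k3),
                 nonzero_root_match = mis[k3] <= tol,
                 max_root_mismatch = mis[k3]),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat("Scheme-equivalence report\n")
  cat("  single feedback distance:", x$is_single_distance,
      if (!is.na(x$q)) sprintf("(q = %d)", x$q) else "", "\n")
  cat(sprintf("  k3 = %d, roots match: %s (max mismatch %.3g)\n",
              x$k3, x$nonzero_root_match, x$max_root_mismatch))
  invisible(x)
}
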