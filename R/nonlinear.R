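#' Activation-function library
#'
#' Builds an activation object with value and derivative callables plus the
#' conventional stated ranges of the function and its derivative. Available
#' names: `sigmoid`, `tanh` (alias `hyperbolic tangent`), `gaussian`,
#' `relu`, `prelu`, `silu` (alias `sigmoid-linear`), `gelu`, `elu`,
#' `softplus`, `identity`. `prelu` and `elu` take a slope parameter `alpha`
#' (default 0.01 and 1).
#'
#' Conventions: the ReLU/PReLU derivative at exactly 0 is the right limit
#' (step function with `theta(0) = 1`); GELU uses the exact Gaussian-CDF
#' form `x * pnorm(x)`, not the tanh approximation. The stated ranges follow
#' the conventional tabulations and are loose for some entries (e.g. the
#' sigmoid derivative's tight range is (0, 0.25]); use [derivative_range()]
#' for numerically tight bounds.
#'
#' @param name Activation name (see above).
#' @param parameters Named list, e.g. `list(alpha = 1)` for ELU/PReLU.
#' @return An `activation_function` with elements `name`, `fn`, `grad`,
#'   `stated_range`, `stated_derivative_range`, `parameters`.
#' @export
#' @examples
#' act <- make_activation("relu")
#' act$fn(c(-1, 2)); act$grad(c(-1, 2))
make_activation <- function(name, parameters = list()) {
  key <- tolower(gsub("[ _]", "-", name))
  key <- switch(key,
                "hyperbolic-tangent" = "tanh", "h-tangent" = "tanh",
                "sigmoid-linear" = "silu", "swish" = "silu",
                key)
  sig <- function(x) 1 / (1 + exp(-x))
  a <- parameters$alpha
  def <- switch(key,
    sigmoid = list(fn = sig,
                   grad = function(x) sig(x) * (1 - sig(x)),
                   r = c(0, 1), dr = c(0, 1)),
    tanh = list(fn = function(x) tanh(x),
                grad = function(x) 1 - tanh(x)^2,
                r = c(0, 1), dr = c(0, 1)),
    gaussian = list(fn = function(x) exp(-x^2),
                    grad = function(x) -2 * x * exp(-x^2),
                    r = c(0, 1), dr = c(-0.86, 0.86)),
    relu = list(fn = function(x) pmax(x, 0),
                grad = function(x) as.numeric(x >= 0),
                r = c(0, Inf), dr = c(0, 1)),
    prelu = {
      if (is.null(a)) a <- 0.01
      list(fn = function(x) ifelse(x >= 0, x, a * x),
           grad = function(x) ifelse(x >= 0, 1, a),
           r = c(-Inf, Inf), dr = range(c(a, 1)))
    },
    silu = list(fn = function(x) x * sig(x),
                grad = function(x) sig(x) + x * sig(x) * (1 - sig(x)),
                r = c(0, Inf), dr = c(-0.1, 1.1)),
    gelu = list(fn = function(x) x * stats::pnorm(x),
                grad = function(x) stats::pnorm(x) + x * stats::dnorm(x),
                r = c(-0.17, Inf), dr = c(-0.12, 1.12)),
    elu = {
      if (is.null(a)) a <- 1
      list(fn = function(x) ifelse(x > 0, x, a * (exp(x) - 1)),
           grad = function(x) ifelse(x > 0, 1, a * exp(x)),
           r = c(-a, Inf), dr = c(0, max(a, 1)))
    },
    softplus = list(fn = function(x) pmax(x, 0) + log1p(exp(-abs(x))),
                    grad = sig,
                    r = c(0, Inf), dr = c(0, 1)),
    identity = list(fn = function(x) x, grad = function(x) rep(1, length(x)),
                    r = c(-Inf, Inf), dr = c(1, 1)),
    stop("unknown activation: ", name)
  )
  structure(list(name = key, fn = def$fn, grad = def$grad,
                 stated_range = def$r, stated_derivative_range = def$dr,
                 parameters = if (key %in% c("prelu", "elu")) list(alpha = a)
                              else parameters),
            class = "activation_function")
}

#' @export
print.activation_function <- function(x, ...) {
  cat(sprintf("Activation '%s': stated range [%g, %g], derivative range [%g, %g]\n",
              x$name, x$stated_range[1], x$stated_range[2],
              x$stated_derivative_range[1], x$stated_derivative_range[2]))
  invisible(x)
}

#' Numerically tight range of an activation derivative
#'
#' Scans the derivative on a dense grid over `search_interval`, then refines
#' the extremes with local continuous optimization around the best grid
#' points.
#'
#' @param act An [make_activation()] object.
#' @param search_interval Interval `c(lo, hi)` to search (default
#'   `c(-10, 10)`).
#' @param grid Number of scan points, >= 1000.
#' @return Numeric `c(min, max)` of the derivative over the interval.
#' @export
#' @examples
#' round(derivative_range(make_activation("gaussian")), 2)  # c(-0.86, 0.86)
derivative_range <- function(act, search_interval = c(-10, 10), grid = 10000L) {
  stopifnot(grid >= 1000L)
  xs <- seq(search_interval[1L], search_interval[2L], length.out = grid)
  g <- act$grad(xs)
  refine <- function(idx, maximize) {
    lo <- xs[max(1L, idx - 1L)]; hi <- xs[min(grid, idx + 1L)]
    if (lo == hi) return(g[idx])
    stats::optimize(act$grad, c(lo, hi), maximum = maximize,
                    tol = 1e-12)[[2L]]
  }
  c(min(g[which.min(g)], refine(which.min(g), FALSE)),
    max(g[which.max(g)], refine(which.max(g), TRUE)))
}

#' Fixed point of the nonlinear delayed dynamics
#'
#' Solves `h* = F(x e_1 + (M_FF + M_FB) h*)` by damped fixed-point
#' iteration from `h = 0` (mirroring the dynamics' initialization):
#' `h <- (1 - eta) h + eta F(x e_1 + M h)`, with the damping factor started
#' at 0.5, doubled (up to 1) when the residual shrinks and halved when it
#' grows — plain iteration can cycle for steep sigmoids. Only the fixed
#' point in the basin reachable from 0 is reported.
#'
#' @param mats A [build_matrices()] result.
#' @param act An [make_activation()] object.
#' @param x Input amplitude (defaults to the spec's).
#' @param tol Residual tolerance in sup-norm (default 1e-10).
#' @param max_iter Iteration cap; non-convergence is reported, not an error.
#' @return A `nonlinear_fixed_point`: `h_star`, `i_star`, `residual`,
#'   `converged`, `iterations`.
#' @export
solve_nonlinear_fixed_point <- function(mats, act, x = NULL,
                                        tol = 1e-10, max_iter = 10000L) {
  stopifnot(tol > 0)
  if (is.null(x)) x <- mats$spec$input_amplitude
  N <- nrow(mats$m_ff)
  M <- mats$m_ff + mats$m_fb
  drive <- c(x, rep(0, N - 1L))
  h <- rep(0, N)
  eta <- 0.5
  res_prev <- Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    i_cur <- drive + as.numeric(M %*% h)
    target <- act$fn(i_cur)
    res <- max(abs(h - target))
    if (res < tol) { converged <- TRUE; break }
    if (it >= max_iter || !is.finite(res)) break
    eta <- if (res < res_prev) min(1, eta * 2) else max(1e-4, eta / 2)
    res_prev <- res
    h <- (1 - eta) * h + eta * target
  }
  structure(list(h_star = h, i_star = drive + as.numeric(M %*% h),
                 residual = res, converged = converged, iterations = it),
            class = "nonlinear_fixed_point")
}

#' @export
print.nonlinear_fixed_point <- function(x, ...) {
  cat(sprintf("Nonlinear fixed point: %s after %d iterations (residual %.3g)\n",
              if (x$converged) "converged" else "not converged",
              x$iterations, x$residual))
  cat("  h* = (", paste(signif(x$h_star, 6), collapse = ", "), ")\n")
  invisible(x)
}

#' Linearized stability around a nonlinear fixed point
#'
#' Classifies stability from the Jacobian of the dynamics at the fixed
#' point: with `D = Diag[F'(I*)]`, the biological-scheme Jacobian is
#' `D %*% M_B` and the artificial one
#' `(Id - D M_FF)^{-1} D M_FB`. Since `D M_FF` is strictly subdiagonal the
#' inverse always exists.
#'
#' @param fp A converged [solve_nonlinear_fixed_point()] result.
#' @param mats The `connectivity_matrices` the fixed point was computed on.
#' @param act The activation used.
#' @param scheme Delay scheme for the Jacobian.
#' @param marginal_tol Passed to [classify_stability()].
#' @return A `stability_report` for the scheme-appropriate Jacobian.
#' @export
nonlinear_jacobian_stability <- function(fp, mats, act,
                                         scheme = c("biological", "artificial"),
                                         marginal_tol = 1e-8) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(fp, "nonlinear_fixed_point"))
  if (!fp$converged)
    stop("fixed point did not converge; Jacobian analysis requires a fixed point")
  D <- diag(act$grad(fp$i_star), nrow = length(fp$i_star))
  J <- if (scheme == "biological") D %*% (mats$m_ff + mats$m_fb)
       else solve(diag(nrow(D)) - D %*% mats$m_ff, D %*% mats$m_fb)
  classify_stability(J, marginal_tol = marginal_tol, scheme = scheme)
}
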