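#' Trace a bifurcation boundary over a two-parameter slice
#'
#' Classifies the fixed point's stability at every node of a rectangular
#' grid in a two-parameter slice of weight space, for both delay schemes,
#' and extracts the bifurcation boundary: wherever the classification flips
#' between stable and unstable along a grid edge, the crossing is refined by
#' scalar bisection on the spectral radius along that edge until
#' `|rho - 1| < radius_tol` (the spectral radius is continuous in the
#' parameters along these slices).
#'
#' @param slice A [canonical_family()] whose family is one of `fig5a`,
#'   `fig5b`, `fig5c`, or a function `(p1, p2) -> layered_network_spec` for
#'   a custom slice (then supply `axis_names`).
#' @param grid Integer grid size per axis (length 1 or 2).
#' @param ranges List of two numeric ranges `c(lo, hi)`, one per axis.
#' @param schemes Character vector of delay schemes to classify.
#' @param marginal_tol Marginal band for classification.
#' @param radius_tol Bisection stop on `|rho - 1|` (default 1e-6).
#' @param axis_names Axis labels for a custom slice function.
#' @return A `boundary_slice`: axis definitions, per-scheme classification
#'   and spectral-radius grids, and a data frame of refined boundary points.
#' @export
#' @examples
#' bs <- trace_boundary(canonical_family("fig5a"), grid = 21,
#'                      ranges = list(c(-1.5, 1.5), c(-1.5, 1.5)))
#' head(bs$boundary)
trace_boundary <- function(slice, grid = 101L,
                           ranges = list(c(-2, 2), c(-2, 2)),
                           schemes = c("biological", "artificial"),
                           marginal_tol = 1e-8, radius_tol = 1e-6,
                           axis_names = c("param1", "param2")) {
  grid <- rep_len(as.integer(grid), 2L)
  stopifnot(length(ranges) == 2L, all(grid >= 2L))
  if (any(vapply(ranges, function(r) diff(range(r)) == 0, TRUE)))
    stop("degenerate axis range: zero width")
  if (inherits(slice, "canonical_family")) {
    fam <- slice$family
    if (!fam %in% c("fig5a", "fig5b", "fig5c"))
      stop("trace_boundary supports fig5a/fig5b/fig5c or a custom slice function")
    axis_names <- slice_axis_names(fam)
    rho_fn <- function(p1, p2, scheme) slice_radius(fam, p1, p2, scheme)
  } else if (is.function(slice)) {
    rho_fn <- function(p1, p2, scheme)
      spectral_radius(build_matrices(slice(p1, p2)), scheme)
  } else stop("slice must be a canonical_family or a function")

  p1 <- seq(ranges[[1L]][1L], ranges[[1L]][2L], length.out = grid[1L])
  p2 <- seq(ranges[[2L]][1L], ranges[[2L]][2L], length.out = grid[2L])

  radius <- list(); classification <- list(); boundary <- NULL
  for (scheme in schemes) {
    R <- matrix(NA_real_, grid[1L], grid[2L])
    for (i in seq_along(p1)) for (j in seq_along(p2))
      R[i, j] <- rho_fn(p1[i], p2[j], scheme)
    cls <- matrix("marginal", grid[1L], grid[2L])
    cls[R < 1 - marginal_tol] <- "stable"
    cls[R > 1 + marginal_tol] <- "unstable"
    radius[[scheme]] <- R
    classification[[scheme]] <- cls

    pts <- list()
    add_crossing <- function(a, b) {      # a, b = c(p1, p2) endpoints
      f <- function(t) {
        p <- a + t * (b - a)
        rho_fn(p[1L], p[2L], scheme) - 1
      }
      lo <- 0; hi <- 1
      flo <- f(lo)
      for (it in seq_len(30L)) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (abs(fm) < radius_tol) { lo <- hi <- mid; break }
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      p <- a + ((lo + hi) / 2) * (b - a)
      pts[[length(pts) + 1L]] <<- p
    }
    flips <- function(c1, c2) (c1 == "stable" & c2 == "unstable") |
                              (c1 == "unstable" & c2 == "stable")
    for (i in seq_len(grid[1L] - 1L)) for (j in seq_len(grid[2L]))
      if (flips(cls[i, j], cls[i + 1L, j]))
        add_crossing(c(p1[i], p2[j]), c(p1[i + 1L], p2[j]))
    for (i in seq_len(grid[1L])) for (j in seq_len(grid[2L] - 1L))
      if (flips(cls[i, j], cls[i, j + 1L]))
        add_crossing(c(p1[i], p2[j]), c(p1[i], p2[j + 1L]))
    if (length(pts)) {
      m <- do.call(rbind, pts)
      boundary <- rbind(boundary,
                        data.frame(param1 = m[, 1L], param2 = m[, 2L],
                                   scheme = scheme))
    }
  }
  if (is.null(boundary))
    boundary <- data.frame(param1 = numeric(0), param2 = numeric(0),
                           scheme = character(0))
  structure(list(axis_names = axis_names,
                 param1 = p1, param2 = p2, ranges = ranges,
                 schemes = schemes,
                 classification = classification,
                 spectral_radius = radius,
                 boundary = boundary),
            class = "boundary_slice")
}

#' @export
print.boundary_slice <- function(x, ...) {
  cat(sprintf("Boundary slice over (%s, %s): %d x %d grid\n",
              x$axis_names[1L], x$axis_names[2L],
              length(x$param1), length(x$param2)))
  for (s in x$schemes)
    cat(sprintf("  %s: %d stable, %d unstable, %d marginal; %d boundary points\n",
                s, sum(x$classification[[s]] == "stable"),
                sum(x$classification[[s]] == "unstable"),
                sum(x$classification[[s]] == "marginal"),
                sum(x$boundary$scheme == s)))
  invisible(x)
}

slice_axis_names <- function(fam) {
  switch(fam,
         fig5a = c("w_i", "w_p"),
         fig5b = c("w_i", "w_p"),
         fig5c = c("w_short", "w_long"))
}

# fast direct matrix construction for the canonical slices (avoids spec
# object overhead inside dense grid sweeps)
slice_mats <- function(fam, p1, p2) {
  if (fam == "fig5a") {
    m_ff <- matrix(0, 2, 2); m_ff[2, 1] <- 1
    m_fb <- matrix(c(p1, 0, p2, p1), 2, 2)
  } else if (fam == "fig5b") {
    m_ff <- matrix(0, 3, 3); m_ff[cbind(2:3, 1:2)] <- 1
    m_fb <- diag(p1, 3); m_fb[cbind(1:2, 2:3)] <- p2
  } else if (fam == "fig5c") {
    m_ff <- matrix(0, 5, 5); m_ff[cbind(2:5, 1:4)] <- 1
    m_fb <- matrix(0, 5, 5)
    m_fb[cbind(2:4, 3:5)] <- p1   # short reciprocal loops
    m_fb[2, 5] <- p2              # long loop 2 -> 3 -> 4 -> 5 -> 2
  } else stop("unknown slice family: ", fam)
  list(m_ff = m_ff, m_fb = m_fb)
}

slice_radius <- function(fam, p1, p2, scheme) {
  m <- slice_mats(fam, p1, p2)
  M <- if (scheme == "biological") m$m_ff + m$m_fb
       else solve(diag(nrow(m$m_ff)) - m$m_ff, m$m_fb)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Spec at a point of a canonical Fig-5 slice
#'
#' @param family Slice family name: `fig5a`, `fig5b` or `fig5c`.
#' @param p1,p2 Coordinates on the slice's two axes (in the order given by
#'   the axis names of the slice).
#' @param ... Passed to [from_family()].
#' @return A `layered_network_spec`.
#' @export
slice_spec <- function(family, p1, p2, ...) {
  nm <- slice_axis_names(family)
  p <- stats::setNames(list(p1, p2), nm)
  n <- switch(family, fig5a = 2L, fig5b = 3L, fig5c = 5L)
  from_family(canonical_family(family, p), n_layers = n, ...)
}

#' Bisect a one-parameter spectral-radius crossing
#'
#' Generic scalar bisection for the parameter value at which the spectral
#' radius of a parameterized matrix crosses 1. Used to locate boundary
#' crossings on slice axes and stability thresholds.
#'
#' @param rho_fn Function `p -> spectral radius`.
#' @param lower,upper Bracket with `rho(lower) < 1 < rho(upper)` (or the
#'   reverse).
#' @param tol Stop when the bracket is narrower than `tol`.
#' @return The crossing parameter value.
#' @export
bisect_radius <- function(rho_fn, lower, upper, tol = 1e-10) {
  flo <- rho_fn(lower) - 1
  fhi <- rho_fn(upper) - 1
  if (sign(flo) == sign(fhi)) stop("bracket does not straddle the boundary")
  while (abs(upper - lower) > tol) {
    mid <- (lower + upper) / 2
    fm <- rho_fn(mid) - 1
    if (sign(fm) == sign(flo)) { lower <- mid; flo <- fm } else upper <- mid
  }
  (lower + upper) / 2
}
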