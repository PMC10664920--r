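#' Build feedforward and feedback connectivity matrices
#'
#' Populates the N x N matrices `m_ff` and `m_fb` from a network
#' specification: `(m_ff)[i, j] = alpha_{j -> i}` only for `j = i - 1`
#' (strict subdiagonal), and `(m_fb)[i, j] = alpha_{j -> i}` only for
#' `i <= j` (upper triangle including the diagonal, i.e. self-loops).
#' All unspecified entries are zero.
#'
#' For a non-layered (fully connected) spec the dense matrix is carried
#' entirely in `m_fb` with `m_ff = 0`, so both delay schemes share the same
#' effective matrix; the result keeps the `non_layered` flag.
#'
#' @param spec A [layered_network_spec()].
#' @return An object of class `connectivity_matrices` with elements `m_ff`,
#'   `m_fb` and the originating spec.
#' @export
#' @examples
#' sp <- layered_network_spec(2, data.frame(from = c(1, 2, 1),
#'                                          to = c(2, 1, 1),
#'                                          value = c(0.5, 0.3, 0.2)))
#' build_matrices(sp)
build_matrices <- function(spec) {
  stopifnot(inherits(spec, "layered_network_spec"))
  validate_spec(spec)
  N <- spec$n_layers
  m_ff <- matrix(0, N, N)
  m_fb <- matrix(0, N, N)
  w <- spec$weights
  if (nrow(w)) {
    for (k in seq_len(nrow(w))) {
      j <- as.integer(w[k, "from"]); i <- as.integer(w[k, "to"])
      if (!isTRUE(spec$non_layered) && j == i - 1L) {
        m_ff[i, j] <- w[k, "value"]
      } else {
        m_fb[i, j] <- w[k, "value"]
      }
    }
  }
  mats <- structure(list(m_ff = m_ff, m_fb = m_fb, spec = spec,
                         non_layered = isTRUE(spec$non_layered)),
                    class = "connectivity_matrices")
  if (spec$units_per_layer > 1L)
    mats <- expand_units(spec, spec$units_per_layer)
  mats
}

#' @export
print.connectivity_matrices <- function(x, ...) {
  cat(sprintf("Connectivity matrices (%d x %d)%s\n", nrow(x$m_ff), ncol(x$m_ff),
              if (x$non_layered) ", non-layered" else ""))
  cat("m_ff (feedforward):\n"); print(x$m_ff)
  cat("m_fb (feedback):\n"); print(x$m_fb)
  invisible(x)
}

#' Expand scalar layers into uniform multi-unit blocks
#'
#' Each scalar weight `alpha` becomes the uniform block `(alpha/units) * J`
#' (J the all-ones units x units matrix), so block-row sums preserve the
#' scalar gain and the nonzero spectrum of the scalar system is recovered
#' exactly (each block is rank 1).
#'
#' @param spec A `layered_network_spec`.
#' @param units Units per layer, >= 1. `units = 1` reproduces
#'   [build_matrices()] exactly.
#' @return A `connectivity_matrices` object of dimension
#'   `(n_layers * units) x (n_layers * units)`.
#' @export
expand_units <- function(spec, units) {
  units <- as.integer(units)
  stopifnot(units >= 1L)
  base <- build_matrices(strip_units(spec))
  if (units == 1L) return(base)
  J <- matrix(1 / units, units, units)
  structure(list(m_ff = kronecker(base$m_ff, J),
                 m_fb = kronecker(base$m_fb, J),
                 spec = spec,
                 non_layered = base$non_layered),
            class = "connectivity_matrices")
}

strip_units <- function(spec) { spec$units_per_layer <- 1L; spec }
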