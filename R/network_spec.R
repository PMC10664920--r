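#' Declarative specification of a layered recurrent network
#'
#' A layered network has `n_layers` layers (one unit each unless
#' `units_per_layer > 1`). Connections are either feedforward (from layer
#' `l` to layer `l + 1`) or feedback (from layer `l` to any layer `<= l`;
#' a self-loop is feedback of distance 0). A constant input of amplitude
#' `x` drives the first layer. The `delay_scheme` fixes how feedforward
#' transmission is timed: `"biological"` delays it by one time step (as
#' axonal conduction does), `"artificial"` makes it instantaneous within a
#' time step (as in conventional deep networks). Feedback is always delayed
#' by one step under both schemes.
#'
#' @param n_layers Positive integer, number of layers N.
#' @param weights Weight table: a data frame or matrix with columns
#'   `from`, `to`, `value`, one row per connection `from -> to`. An entry
#'   with `to == from + 1` is feedforward; `to <= from` is feedback;
#'   anything else is a structural error.
#' @param delay_scheme `"biological"` or `"artificial"`.
#' @param input_amplitude Real input x applied to layer 1 at every step.
#' @param units_per_layer Positive integer; scalar weights expand to
#'   uniform blocks when > 1 (see [expand_units()]).
#'
#' @return An object of class `layered_network_spec`.
#' @seealso [build_matrices()], [from_family()], [random_network()]
#' @export
#' @examples
#' sp <- layered_network_spec(2, data.frame(from = c(1, 2), to = c(2, 1),
#'                                          value = c(0.5, 0.3)))
#' build_matrices(sp)
layered_network_spec <- function(n_layers, weights = NULL,
                                 delay_scheme = c("biological", "artificial"),
                                 input_amplitude = 1,
                                 units_per_layer = 1L) {
  delay_scheme <- match.arg(delay_scheme)
  n_layers <- as.integer(n_layers)
  stopifnot(length(n_layers) == 1L, n_layers >= 1L,
            is.numeric(input_amplitude), length(input_amplitude) == 1L,
            units_per_layer >= 1L)
  w <- normalize_weights(weights)
  spec <- structure(list(
    n_layers = n_layers,
    weights = w,
    delay_scheme = delay_scheme,
    input_amplitude = as.numeric(input_amplitude),
    units_per_layer = as.integer(units_per_layer),
    non_layered = FALSE
  ), class = "layered_network_spec")
  validate_spec(spec)
  spec
}

# weights stored internally as a numeric matrix with columns from, to, value
normalize_weights <- function(weights) {
  if (is.null(weights) || (is.data.frame(weights) && nrow(weights) == 0L)) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("from", "to", "value"))))
  }
  w <- as.matrix(as.data.frame(weights)[, c("from", "to", "value")])
  storage.mode(w) <- "double"
  dimnames(w) <- list(NULL, c("from", "to", "value"))
  w
}

validate_spec <- function(spec) {
  w <- spec$weights
  n <- spec$n_layers
  if (nrow(w) == 0L) return(invisible(spec))
  if (any(w[, "from"] < 1 | w[, "from"] > n | w[, "to"] < 1 | w[, "to"] > n))
    stop("layer indices must lie in 1..", n)
  if (any(w[, "from"] != round(w[, "from"]) | w[, "to"] != round(w[, "to"])))
    stop("layer indices must be integers")
  if (anyDuplicated(w[, c("from", "to"), drop = FALSE]))
    stop("duplicate connection entries")
  if (!isTRUE(spec$non_layered)) {
    bad <- w[, "to"] > w[, "from"] + 1
    if (any(bad)) {
      j <- which(bad)[1L]
      stop(sprintf(
        "forbidden connection %d -> %d: feedforward must target the next layer, feedback an earlier or equal one",
        as.integer(w[j, "from"]), as.integer(w[j, "to"])))
    }
  }
  invisible(spec)
}

#' @export
print.layered_network_spec <- function(x, ...) {
  cat(sprintf("Layered network: N = %d, %s scheme, input x = %g\n",
              x$n_layers, x$delay_scheme, x$input_amplitude))
  if (x$units_per_layer > 1L)
    cat(sprintf("  units per layer: %d\n", x$units_per_layer))
  if (isTRUE(x$non_layered))
    cat("  (non-layered: dense connectivity, carried as feedback)\n")
  nff <- sum(x$weights[, "to"] == x$weights[, "from"] + 1)
  cat(sprintf("  connections: %d feedforward, %d feedback\n",
              nff, nrow(x$weights) - nff))
  invisible(x)
}

#' Canonical network families
#'
#' Named parametric families of network structures used throughout the
#' stability analysis:
#' \describe{
#'   \item{`single_q`}{Uniform feedforward chain of weight `w_ff` with
#'     feedback of a single distance `q` and uniform weight `w_fb`
#'     (`q = 0` means self-loops).}
#'   \item{`fully_connected`}{All-to-all coupling: self-weight `w_i` on the
#'     diagonal, `w_e` everywhere else. Flagged non-layered.}
#'   \item{`fig5a`}{N = 2 slice: self-loops `w_i` on both layers and a
#'     reciprocal pair with product `w_p`.}
#'   \item{`fig5b`}{N = 3 slice: self-loops `w_i`, both adjacent reciprocal
#'     pairs with product `w_p`, no distance-2 feedback.}
#'   \item{`fig5c`}{N = 5 slice: adjacent reciprocal pairs among layers
#'     2..5 with product `w_short`, plus one long loop 2 -> 3 -> 4 -> 5 -> 2
#'     with product `w_long`.}
#'   \item{`chain_time_decay`}{Feedforward chain with per-layer leak
#'     self-feedback `tau` (the scalar reduction of a time-decay recurrence
#'     h_t = tau * h_{t-1} + input).}
#' }
#'
#' Slices specify only loop-gain *products*; all feedforward weights are set
#' to 1 and the full product is placed on the feedback weight, which leaves
#' the spectrum unchanged (diagonal similarity).
#'
#' @param family Family name, see Details.
#' @param parameters Named list of family parameters.
#' @return An object of class `canonical_family`.
#' @export
canonical_family <- function(family = c("single_q", "fully_connected",
                                        "fig5a", "fig5b", "fig5c",
                                        "chain_time_decay"),
                             parameters = list()) {
  family <- match.arg(family)
  structure(list(family = family, parameters = parameters),
            class = "canonical_family")
}

need_params <- function(p, nm, family) {
  miss <- setdiff(nm, names(p))
  if (length(miss))
    stop(sprintf("family '%s' requires parameter(s): %s",
                 family, paste(miss, collapse = ", ")))
}

#' Instantiate a network specification from a canonical family
#'
#' @param family A [canonical_family()] object (or family name with
#'   `parameters` supplied).
#' @param n_layers Number of layers N; fixed for the Fig-5 slices
#'   (`fig5a` needs N = 2, `fig5b` N = 3, `fig5c` N = 5).
#' @param parameters Parameter list when `family` is given as a name.
#' @param delay_scheme Delay scheme of the resulting spec.
#' @param input_amplitude Input amplitude of the resulting spec.
#' @return A `layered_network_spec`.
#' @export
#' @examples
#' sp <- from_family(canonical_family("single_q",
#'         list(q = 3, w_ff = 1, w_fb = 0.5)), n_layers = 5)
#' classify_stability(effective_matrix(build_matrices(sp), "artificial"))
from_family <- function(family, n_layers, parameters = list(),
                        delay_scheme = "biological", input_amplitude = 1) {
  if (is.character(family))
    family <- canonical_family(family, parameters)
  stopifnot(inherits(family, "canonical_family"))
  p <- family$parameters
  fam <- family$family
  N <- as.integer(n_layers)

  chain <- function(N, w = 1) {
    if (N < 2L) return(NULL)
    data.frame(from = 1:(N - 1L), to = 2:N, value = w)
  }
  fb <- function(from, to, value) data.frame(from = from, to = to, value = value)

  w <- switch(fam,
    single_q = {
      need_params(p, c("q", "w_ff", "w_fb"), fam)
      q <- as.integer(p$q)
      if (q < 0L || q > N - 1L) stop("single_q requires 0 <= q <= N-1")
      rows <- chain(N, p$w_ff)
      if (N - q >= 1L)
        rows <- rbind(rows, fb((1:(N - q)) + q, 1:(N - q), p$w_fb))
      rows
    },
    fig5a = {
      need_params(p, c("w_i", "w_p"), fam)
      if (N != 2L) stop("fig5a requires N = 2")
      rbind(chain(2L, 1), fb(c(1, 2, 2), c(1, 2, 1), c(p$w_i, p$w_i, p$w_p)))
    },
    fig5b = {
      need_params(p, c("w_i", "w_p"), fam)
      if (N != 3L) stop("fig5b requires N = 3")
      rbind(chain(3L, 1),
            fb(1:3, 1:3, p$w_i),          # self-loops
            fb(c(2, 3), c(1, 2), p$w_p))  # adjacent reciprocal pairs, no 3->1
    },
    fig5c = {
      need_params(p, c("w_short", "w_long"), fam)
      if (N != 5L) stop("fig5c requires N = 5")
      rbind(chain(5L, 1),
            fb(c(3, 4, 5), c(2, 3, 4), p$w_short),
            fb(5, 2, p$w_long))
    },
    chain_time_decay = {
      need_params(p, "tau", fam)
      tau <- rep_len(as.numeric(p$tau), N)
      w_ff <- if (is.null(p$w_ff)) 1 else p$w_ff
      rbind(chain(N, w_ff), fb(1:N, 1:N, tau))
    },
    fully_connected = {
      need_params(p, c("w_i", "w_e"), fam)
      g <- expand.grid(from = 1:N, to = 1:N)
      data.frame(from = g$from, to = g$to,
                 value = ifelse(g$from == g$to, p$w_i, p$w_e))
    }
  )

  spec <- structure(list(
    n_layers = N,
    weights = normalize_weights(w),
    delay_scheme = match.arg(delay_scheme, c("biological", "artificial")),
    input_amplitude = as.numeric(input_amplitude),
    units_per_layer = 1L,
    non_layered = fam == "fully_connected",
    family = fam,
    parameters = p
  ), class = "layered_network_spec")
  validate_spec(spec)
  spec
}

#' Randomly generated layered network specifications
#'
#' Draws a feedforward chain and feedback connections at the requested
#' distances, with weights from a bounded distribution. Generation is
#' bit-reproducible for a fixed seed.
#'
#' @param n_layers Number of layers N.
#' @param feedback_distances Integer vector of feedback distances, each in
#'   `0..N-1` (0 = self-loops). May be empty.
#' @param weight_distribution Either a function `n -> numeric(n)` or a list
#'   `list(min =, max =)` for a uniform draw. Default uniform(-1, 1).
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @param include_feedforward Draw feedforward chain weights (default TRUE).
#' @param delay_scheme,input_amplitude Passed to the resulting spec.
#' @return A `layered_network_spec`.
#' @export
random_network <- function(n_layers, feedback_distances,
                           weight_distribution = list(min = -1, max = 1),
                           seed,
                           include_feedforward = TRUE,
                           delay_scheme = "biological",
                           input_amplitude = 1) {
  N <- as.integer(n_layers)
  q <- unique(as.integer(feedback_distances))
  if (length(q) && (any(q < 0L) || any(q > N - 1L)))
    stop("feedback distances must lie in 0..N-1")
  if (!length(q) && !include_feedforward)
    warning("degenerate network: no feedforward and no feedback connections")
  rdist <- if (is.function(weight_distribution)) weight_distribution else
    function(n) stats::runif(n, weight_distribution$min, weight_distribution$max)

  rows <- NULL
  # seed scoped locally so callers' RNG state is untouched
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (include_feedforward && N >= 2L)
    rows <- data.frame(from = 1:(N - 1L), to = 2:N, value = rdist(N - 1L))
  for (qq in sort(q)) {
    k <- N - qq
    rows <- rbind(rows, data.frame(from = (1:k) + qq, to = 1:k, value = rdist(k)))
  }
  layered_network_spec(N, rows, delay_scheme = delay_scheme,
                       input_amplitude = input_amplitude)
}

#' Feedback distances present in a specification
#'
#' @param spec A `layered_network_spec`.
#' @return Sorted integer vector of distances `q = from - to` over feedback
#'   entries (self-loops count as distance 0).
#' @export
feedback_distances <- function(spec) {
  w <- spec$weights
  fbk <- w[, "to"] <= w[, "from"] & w[, "value"] != 0
  sort(unique(as.integer(w[fbk, "from"] - w[fbk, "to"])))
}

#' Read / write network specifications as JSON
#'
#' The JSON layout is `{"n_layers":, "delay_scheme":, "input":,
#' "units_per_layer":, "weights": [{"from":, "to":, "value":}, ...]}`.
#' A family shorthand `{"family":, "parameters":, "n_layers": ...}` is
#' accepted on read.
#'
#' @param spec A `layered_network_spec`.
#' @param path File path.
#' @return `read_network_spec` returns a `layered_network_spec`;
#'   `write_network_spec` returns `path` invisibly.
#' @export
write_network_spec <- function(spec, path) {
  w <- spec$weights
  obj <- list(
    n_layers = spec$n_layers,
    delay_scheme = spec$delay_scheme,
    input = spec$input_amplitude,
    units_per_layer = spec$units_per_layer,
    weights = data.frame(from = as.integer(w[, "from"]),
                         to = as.integer(w[, "to"]),
                         value = w[, "value"])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$family)) {
    return(from_family(canonical_family(obj$family, as.list(obj$parameters)),
                       n_layers = obj$n_layers,
                       delay_scheme = obj$delay_scheme %||% "biological",
                       input_amplitude = obj$input %||% 1))
  }
  layered_network_spec(
    n_layers = obj$n_layers,
    weights = obj$weights,
    delay_scheme = obj$delay_scheme %||% "biological",
    input_amplitude = obj$input %||% 1,
    units_per_layer = obj$units_per_layer %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
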