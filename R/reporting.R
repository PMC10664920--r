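#' Write an analysis report to disk
#'
#' Serializes the package's report objects deterministically: stability,
#' equivalence and trajectory metadata as JSON (complex eigenvalues as
#' `[re, im]` pairs, floats at 17 significant digits so round-trips are
#' lossless), trajectories and boundary slices as CSV. For a
#' `boundary_slice`, `path` is used as a base name and two CSVs are written:
#' `<base>_grid.csv` (param1, param2, scheme, classification,
#' spectral_radius) and `<base>_boundary.csv`.
#'
#' @param report A `stability_report`, `equivalence_report`,
#'   `trajectory_result` or `boundary_slice`.
#' @param path Output path (base name for `boundary_slice`).
#' @param ... Unused.
#' @return Invisibly, the path(s) written.
#' @export
write_report <- function(report, path, ...) UseMethod("write_report")

write_json_det <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

cplx_pairs <- function(z) lapply(z, function(v) c(Re(v), Im(v)))

#' @export
write_report.stability_report <- function(report, path, ...) {
  write_json_det(list(
    type = "stability_report",
    scheme = report$scheme,
    classification = report$classification,
    spectral_radius = report$spectral_radius,
    dominant_eigenvalue = c(Re(report$dominant_eigenvalue),
                            Im(report$dominant_eigenvalue)),
    marginal_tol = report$marginal_tol,
    eigenvalues = cplx_pairs(report$eigenvalues)
  ), path)
}

#' @export
write_report.equivalence_report <- function(report, path, ...) {
  write_json_det(list(
    type = "equivalence_report",
    is_single_distance = report$is_single_distance,
    q = if (is.na(report$q)) NULL else report$q,
    k3 = report$k3,
    nonzero_root_match = report$nonzero_root_match,
    max_root_mismatch = report$max_root_mismatch
  ), path)
}

#' @export
write_report.trajectory_result <- function(report, path, ...) {
  df <- as.data.frame(report$states)
  names(df) <- paste0("h_", seq_len(ncol(df)))
  df <- cbind(t = seq_len(nrow(df)) - 1L, df)
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  side <- paste0(side, "_meta.json")
  write_json_det(list(
    type = "trajectory_result",
    scheme = report$scheme,
    verdict = report$verdict,
    steps_to_converge = report$steps_to_converge,
    fixed_point_estimate = report$fixed_point_estimate,
    tol = report$tol
  ), side)
  invisible(c(path, side))
}

#' @export
write_report.boundary_slice <- function(report, path, ...) {
  base <- sub("\\.csv$", "", path)
  rows <- list()
  for (s in report$schemes) {
    g <- expand.grid(i = seq_along(report$param1), j = seq_along(report$param2))
    rows[[s]] <- data.frame(
      param1 = report$param1[g$i],
      param2 = report$param2[g$j],
      scheme = s,
      classification = report$classification[[s]][cbind(g$i, g$j)],
      spectral_radius = report$spectral_radius[[s]][cbind(g$i, g$j)]
    )
  }
  grid_df <- do.call(rbind, rows)
  names(grid_df)[1:2] <- report$axis_names
  bd <- report$boundary
  if (nrow(bd)) names(bd)[1:2] <- report$axis_names
  p1 <- paste0(base, "_grid.csv")
  p2 <- paste0(base, "_boundary.csv")
  utils::write.csv(format(grid_df, digits = 17, trim = TRUE), p1, row.names = FALSE)
  utils::write.csv(format(bd, digits = 17, trim = TRUE), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a run configuration (JSON, or YAML when available)
#'
#' @param path Config file; `.yaml`/`.yml` requires the yaml package.
#' @return A named list as passed to [run_command()].
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

config_spec <- function(config) {
  net <- config$network
  if (is.null(net)) stop("config field 'network' is missing")
  if (!is.null(net$family)) {
    from_family(canonical_family(net$family, as.list(net$parameters)),
                n_layers = net$n_layers,
                delay_scheme = net$delay_scheme %||% "biological",
                input_amplitude = net$input %||% 1)
  } else {
    layered_network_spec(net$n_layers, net$weights,
                         delay_scheme = net$delay_scheme %||% "biological",
                         input_amplitude = net$input %||% 1,
                         units_per_layer = net$units_per_layer %||% 1L)
  }
}

#' Run a pipeline command from a configuration
#'
#' Dispatches one of the analysis commands and writes its artifacts to
#' `config$out`. Supported commands:
#' \describe{
#'   \item{classify}{Stability reports for both schemes (JSON).}
#'   \item{simulate}{Trajectory under `config$scheme` (CSV + JSON sidecar).}
#'   \item{boundary}{Boundary slice for `config$slice` (two CSVs).}
#'   \item{equivalence}{Scheme-equivalence report (JSON).}
#'   \item{sweep-q}{Feedback-weight stability thresholds over q (CSV).}
#'   \item{nonlinear}{Nonlinear fixed point and Jacobian reports (JSON).}
#'   \item{activations}{Numerically tight derivative ranges (CSV).}
#' }
#' All numeric options default to the analysis modules' values; the seed,
#' when supplied, is recorded in the run metadata written next to the
#' artifacts. Validation failures raise errors naming the offending field.
#'
#' @param config Named list (see [read_run_config()]): `command`, `network`
#'   and/or `slice`, `out`, and per-command numeric options.
#' @return Invisibly, a list with `status` (0 on success) and `artifacts`
#'   (paths written).
#' @export
run_command <- function(config) {
  cmd <- config$command
  if (is.null(cmd)) stop("config field 'command' is missing")
  out <- config$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  artifacts <- character(0)
  logmsg <- function(...) message(sprintf("[netstab] %s", sprintf(...)))

  if (cmd == "classify") {
    mats <- build_matrices(config_spec(config))
    for (s in c("biological", "artificial")) {
      rep_s <- classify_stability(effective_matrix(mats, s),
                                  marginal_tol = config$marginal_tol %||% 1e-8,
                                  scheme = s)
      p <- file.path(out, paste0("stability_", s, ".json"))
      write_report(rep_s, p)
      artifacts <- c(artifacts, p)
    }
  } else if (cmd == "simulate") {
    mats <- build_matrices(config_spec(config))
    traj <- iterate_dynamics(mats,
                             scheme = config$scheme %||% "biological",
                             max_steps = config$max_steps %||% 10000L,
                             tol = config$tol %||% 1e-10)
    p <- file.path(out, "trajectory.csv")
    artifacts <- c(artifacts, write_report(traj, p))
  } else if (cmd == "boundary") {
    slice <- config$slice
    if (is.null(slice)) stop("config field 'slice' is missing")
    bs <- trace_boundary(canonical_family(slice),
                         grid = config$grid %||% 101L,
                         ranges = config$ranges %||% list(c(-2, 2), c(-2, 2)))
    artifacts <- c(artifacts, write_report(bs, file.path(out, paste0(slice, ".csv"))))
  } else if (cmd == "equivalence") {
    er <- verify_equivalence(config_spec(config))
    p <- file.path(out, "equivalence.json")
    artifacts <- c(artifacts, write_report(er, p))
  } else if (cmd == "sweep-q") {
    N <- config$n_layers %||% stop("config field 'n_layers' is missing")
    qs <- config$q %||% seq_len(N - 1L)
    th <- vapply(qs, function(q)
      feedback_threshold(N, q, w_ff = config$w_ff %||% 1,
                         scheme = config$scheme %||% "artificial"), 0)
    th_link <- vapply(qs, function(q)
      feedback_threshold(N, q, per_link = TRUE,
                         scheme = config$scheme %||% "artificial"), 0)
    p <- file.path(out, "sweep_q.csv")
    utils::write.csv(data.frame(q = qs, threshold = th,
                                threshold_per_link = th_link),
                     p, row.names = FALSE)
    artifacts <- c(artifacts, p)
  } else if (cmd == "nonlinear") {
    mats <- build_matrices(config_spec(config))
    act <- make_activation(config$activation$name %||% "relu",
                           as.list(config$activation$parameters))
    fp <- solve_nonlinear_fixed_point(mats, act,
                                      tol = config$tol %||% 1e-10)
    p <- file.path(out, "nonlinear_fixed_point.json")
    write_json_det(list(type = "nonlinear_fixed_point",
                        activation = act$name,
                        h_star = fp$h_star, i_star = fp$i_star,
                        residual = fp$residual, converged = fp$converged), p)
    artifacts <- c(artifacts, p)
    if (fp$converged) {
      for (s in c("biological", "artificial")) {
        rp <- nonlinear_jacobian_stability(fp, mats, act, s)
        ps <- file.path(out, paste0("nonlinear_stability_", s, ".json"))
        write_report(rp, ps)
        artifacts <- c(artifacts, ps)
      }
    }
  } else if (cmd == "activations") {
    nms <- c("sigmoid", "tanh", "gaussian", "relu", "prelu", "silu",
             "gelu", "elu", "softplus")
    rng <- t(vapply(nms, function(nm) derivative_range(make_activation(nm)),
                    numeric(2)))
    p <- file.path(out, "activation_derivative_ranges.csv")
    utils::write.csv(data.frame(name = nms, deriv_min = rng[, 1],
                                deriv_max = rng[, 2]), p, row.names = FALSE)
    artifacts <- c(artifacts, p)
  } else {
    stop("unknown command: ", cmd)
  }

  meta <- file.path(out, "run_metadata.json")
  write_json_det(list(command = cmd, seed = seed,
                      tool = "netstab",
                      version = as.character(utils::packageVersion("netstab")),
                      artifacts = basename(artifacts)), meta)
  logmsg("command '%s' wrote %d artifact(s) to %s", cmd, length(artifacts), out)
  invisible(list(status = 0L, artifacts = c(artifacts, meta)))
}
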