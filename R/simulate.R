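#' Simulate the Langevin dynamics of the circuit
#'
#' Euler-Maruyama integration of
#' \deqn{dx_i = F_i(x) dt + \xi_i(t) dt} with independent Gaussian white
#' noises of equal intensity, \eqn{\langle\xi_i(t)\xi_i(s)\rangle =
#' 2 D \delta(t-s)}: each step adds \eqn{F(x) dt + \sqrt{2 D dt}\,\eta}
#' with standard-normal \eqn{\eta}.  With `D = 0` the scheme reduces to a
#' fixed-step deterministic Euler integration.  Concentrations are kept
#' non-negative by reflection at the origin (`x <- |x|`) unless
#' `boundary = "none"`.
#'
#' @param params a [model_params] object.
#' @param D noise intensity (>= 0).
#' @param x_init numeric `c(x1, x2)` initial state.
#' @param dt time step (default 1e-3, dimensionless time).
#' @param t_end final time.
#' @param seed optional RNG seed (`set.seed`); identical seeds give
#'   bit-identical trajectories.
#' @param thin keep every `thin`-th step (default 1).
#' @param boundary `"reflect"` (default) or `"none"`.
#' @return a data frame of class `trajectory` with columns `t`, `x1`, `x2`
#'   and the run settings as attributes.
#' @examples
#' p <- model_params(a1 = 0.8, a2 = 0.85)
#' tr <- simulate_sde(p, D = 0.02, x_init = c(0.9, 0.1), t_end = 10,
#'                    seed = 1)
#' @export
simulate_sde <- function(params, D, x_init, dt = 1e-3, t_end, seed = NULL,
                         thin = 1L, boundary = c("reflect", "none")) {
  validate_params(params)
  validate_state(x_init)
  boundary <- match.arg(boundary)
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (dt <= 0 || t_end < dt) stop("need dt > 0 and t_end >= dt",
                                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- floor(t_end / dt)
  m <- .sim_em_cpp(params, D, x_init, dt, as.integer(n_steps),
                   as.integer(thin), boundary == "reflect")
  out <- data.frame(t = seq(0, by = dt * thin, length.out = nrow(m)),
                    x1 = m[, 1], x2 = m[, 2])
  attr(out, "params") <- params
  attr(out, "noise") <- list(D = D, seed = seed)
  attr(out, "dt") <- dt
  attr(out, "boundary") <- boundary
  class(out) <- c("trajectory", "data.frame")
  out
}

# deterministic-relaxation basin labels for a matrix of states (rows);
# returns integer indices into the attractor table (0 = unresolved)
relax_to_basin <- function(params, states, attractors, dt = 0.05,
                           t_max = 400, radius = 0.02) {
  .relax_cpp(params, as.matrix(states),
             as.matrix(attractors[, c("x1", "x2")]), dt, t_max, radius)
}

# basin lookup map over a rectangular grid of cell centres, by deterministic
# relaxation; used for watershed-correct occupancy assignment
basin_map <- function(params, attractors, domain, nx = 160, ny = 200) {
  cx <- domain$x1[1] + (seq_len(nx) - 0.5) * diff(domain$x1) / nx
  cy <- domain$x2[1] + (seq_len(ny) - 0.5) * diff(domain$x2) / ny
  starts <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  matrix(relax_to_basin(params, starts, attractors), nx, ny)
}

#' Long-run basin occupancies under noise
#'
#' Simulates `n_replicates` independent trajectories, discards the burn-in,
#' and assigns every post-burn-in sample to the basin of one of the supplied
#' stable attractors by deterministic relaxation (each sample is relaxed
#' under the noise-free flow and labelled by the attractor it approaches;
#' implemented as a precomputed relaxation lookup grid, so the assignment is
#' watershed-correct without computing separatrices).  `method = "nearest"`
#' falls back to Euclidean nearest-attractor assignment.
#'
#' @param params a [model_params] object.
#' @param D noise intensity (> 0).
#' @param attractors a `fixed_points` frame (only its stable rows are used).
#' @param dt time step (default 1e-3).
#' @param t_end simulated time per replicate (default 2000).
#' @param burn_in discarded initial time per replicate (default 200).
#' @param n_replicates independent replicates (default 8); each starts at a
#'   different attractor (cycled) so the estimate does not condition on one
#'   initial phenotype.
#' @param seed optional RNG seed.
#' @param method `"relax"` (default) or `"nearest"`.
#' @return an object of class `occupancy`: list with `probability` and
#'   `se` (named per phenotype, plus `"other"`), `t_total`, `burn_in`, and
#'   the per-replicate fractions in `replicates`.
#' @export
estimate_occupancy <- function(params, D, attractors, dt = 1e-3,
                               t_end = 2000, burn_in = 200,
                               n_replicates = 8, seed = NULL,
                               method = c("relax", "nearest")) {
  validate_params(params)
  method <- match.arg(method)
  st <- attractors[attractors$stability == "stable", , drop = FALSE]
  if (nrow(st) == 0) stop("no stable attractors supplied", call. = FALSE)
  if (t_end <= burn_in) stop("t_end must exceed burn_in", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  box <- invariant_box(params)
  domain <- list(x1 = c(0, 1.4 * box[["x1"]]), x2 = c(0, 1.4 * box[["x2"]]))
  bmap <- if (method == "relax") {
    basin_map(params, st, domain)
  } else {
    nx <- 160; ny <- 200
    cx <- domain$x1[1] + (seq_len(nx) - 0.5) * diff(domain$x1) / nx
    cy <- domain$x2[1] + (seq_len(ny) - 0.5) * diff(domain$x2) / ny
    d2 <- function(x, y) outer(seq_len(nx), seq_len(ny), function(i, j)
      (cx[i] - x)^2 + (cy[j] - y)^2)
    dist <- lapply(seq_len(nrow(st)), function(k) d2(st$x1[k], st$x2[k]))
    matrix(apply(do.call(cbind, lapply(dist, as.vector)), 1, which.min),
           nx, ny)
  }
  n_steps <- floor(t_end / dt)
  burn_steps <- floor(burn_in / dt)
  frac <- matrix(NA_real_, n_replicates, nrow(st) + 1)
  for (r in seq_len(n_replicates)) {
    k <- (r - 1) %% nrow(st) + 1
    tall <- .sim_occupancy_cpp(params, D, c(st$x1[k], st$x2[k]), dt,
                               n_steps, burn_steps, bmap, domain$x1[1],
                               domain$x1[2], domain$x2[1], domain$x2[2],
                               nrow(st), TRUE)
    frac[r, ] <- c(tall[-1], tall[1]) / sum(tall)  # basins..., unassigned
  }
  labels <- c(st$phenotype, "other")
  prob <- colMeans(frac)
  se <- apply(frac, 2, stats::sd) / sqrt(n_replicates)
  names(prob) <- names(se) <- labels
  structure(list(probability = prob, se = se,
                 t_total = n_replicates * (t_end - burn_in),
                 burn_in = burn_in, replicates = frac, D = D,
                 params = params, method = method),
            class = "occupancy")
}

#' @export
print.occupancy <- function(x, ...) {
  cat(sprintf("Basin occupancies at D = %g (total time %g)\n", x$D,
              x$t_total))
  print(round(rbind(probability = x$probability, se = x$se), 4))
  invisible(x)
}

#' Monte-Carlo first-passage times between attractors
#'
#' Each sample starts at the source attractor and is integrated until the
#' state first enters the max-norm capture disk of radius `radius` around
#' the target attractor (crossing the saddle alone does not count).
#' `dynamics = "reduced"` instead clamps `x1` at the source's `x1` value and
#' runs the one-dimensional `x2` dynamics with reflection at the origin,
#' stopping at the first crossing of the target's `x2`; this matches the
#' exact double-integral mean first-passage time of the reduced system (see
#' [mfpt_integral()]).
#'
#' @param params a [model_params] object.
#' @param D noise intensity (> 0).
#' @param source,target stable fixed points: single-row data frames or
#'   numeric `c(x1, x2)`.
#' @param n_samples number of independent passages (default 400).
#' @param dt time step (default 1e-3).
#' @param t_max censoring time per sample (default 1e4).
#' @param radius capture-disk radius in max-norm (default 0.05).
#' @param seed optional RNG seed.
#' @param dynamics `"full"` (2-D) or `"reduced"` (1-D at clamped x1).
#' @return an object of class `mfpt_result` with `value` (mean over
#'   uncensored samples), `se`, `n_censored`, `method = "monte-carlo"`,
#'   and the raw `times` (censored samples are `NA`).  A warning is embedded
#'   in the result (field `warning`) when more than half the samples are
#'   censored.
#' @export
first_passage_times <- function(params, D, source, target, n_samples = 400,
                                dt = 1e-3, t_max = 1e4, radius = 0.05,
                                seed = NULL,
                                dynamics = c("full", "reduced")) {
  validate_params(params)
  dynamics <- match.arg(dynamics)
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  src <- as_point(source); tgt <- as_point(target)
  if (max(abs(src - tgt)) < radius)
    stop("source and target must be distinct attractors", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  times <- if (dynamics == "full") {
    .fpt2d_cpp(params, D, src, tgt, radius, dt, t_max,
               as.integer(n_samples), TRUE)
  } else {
    .fpt1d_cpp(params, src[1], D, src[2], tgt[2], dt, t_max,
               as.integer(n_samples))
  }
  ok <- !is.na(times)
  warn <- if (mean(!ok) > 0.5)
    sprintf("%.0f%% of samples censored at t_max = %g", 100 * mean(!ok),
            t_max) else NULL
  if (!is.null(warn)) warning(warn, call. = FALSE)
  new_mfpt(value = mean(times[ok]),
           method = "monte-carlo",
           direction = c(source = paste(signif(src, 4), collapse = ","),
                         target = paste(signif(tgt, 4), collapse = ",")),
           D = D,
           uncertainty = stats::sd(times[ok]) / sqrt(sum(ok)),
           extra = list(n_censored = sum(!ok), times = times,
                        warning = warn, dynamics = dynamics, dt = dt))
}

as_point <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    c(x$x1, x$x2)
  } else {
    validate_state(x)
    as.numeric(x)
  }
}

new_mfpt <- function(value, method, direction, D, uncertainty,
                     extra = list()) {
  structure(c(list(value = value, method = method, direction = direction,
                   D = D, uncertainty = uncertainty), extra),
            class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  cat(sprintf("MFPT (%s): %.6g", x$method, x$value))
  if (is.finite(x$uncertainty) && x$uncertainty > 0)
    cat(sprintf(" +/- %.3g", x$uncertainty))
  cat(sprintf("  [D = %g]\n", x$D))
  invisible(x)
}
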