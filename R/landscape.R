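#' Stationary probability landscape from the Fokker-Planck equation
#'
#' Solves the stationary two-dimensional Fokker-Planck equation
#' \deqn{0 = -\nabla\cdot(F P) + D \nabla^2 P}
#' by a conservative finite-volume discretization with Scharfetter-Gummel
#' (exponentially fitted) face fluxes and no-flux (reflecting) boundaries,
#' then the effective potential \eqn{U = -\ln P}.  The discrete operator is
#' an irreducible generator (every column sums to zero), so the stationary
#' density is its one-dimensional null space; it is obtained by a direct
#' sparse solve with one row replaced by the normalization constraint.
#'
#' @param params a [model_params] object.
#' @param D noise intensity (> 0).
#' @param domain list with `x1`, `x2` ranges; default `[0,2] x [0,2.5]`,
#'   which exceeds the invariant box of the default parameters with margin
#'   for noise excursions.
#' @param resolution cells per axis, `c(nx, ny)` or a single number (min 64
#'   per axis; default 128 x 160).
#' @param p_floor cells with `P < p_floor * max(P)` are masked (`NA`) in `U`
#'   to avoid log-of-zero (default 1e-12).
#' @return an object of class `landscape`: list with cell-centre axes `x1`,
#'   `x2`, density matrix `P` (rows = x1), potential `U = -log(P)`, cell
#'   sizes, `method = "fpe"`, and metadata.
#' @examples
#' \donttest{
#' land <- solve_stationary_fpe(model_params(a1 = 0.8, a2 = 0.85), D = 0.02)
#' landscape_modes(land)
#' }
#' @export
solve_stationary_fpe <- function(params, D,
                                 domain = list(x1 = c(0, 2),
                                               x2 = c(0, 2.5)),
                                 resolution = c(128, 160),
                                 p_floor = 1e-12) {
  validate_params(params)
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  if (length(resolution) == 1) resolution <- rep(resolution, 2)
  if (any(resolution < 64))
    stop("resolution must be at least 64 cells per axis", call. = FALSE)
  box <- invariant_box(params)
  if (domain$x1[2] < box[["x1"]] || domain$x2[2] < box[["x2"]])
    stop("domain must contain the invariant box with margin", call. = FALSE)
  nx <- resolution[1]; ny <- resolution[2]
  hx <- diff(domain$x1) / nx; hy <- diff(domain$x2) / ny
  cx <- domain$x1[1] + (seq_len(nx) - 0.5) * hx
  cy <- domain$x2[1] + (seq_len(ny) - 0.5) * hy

  A <- fpe_operator(params, D, cx, cy, hx, hy)
  N <- nx * ny
  # replace the equation of the cell nearest the domain centre by sum(P)=1
  r <- (ny %/% 2) * nx + nx %/% 2
  M <- A
  M[r, ] <- 1
  b <- numeric(N); b[r] <- 1
  P <- as.numeric(Matrix::solve(M, b))
  P[P < 0] <- 0
  P <- matrix(P, nx, ny)
  P <- P / (sum(P) * hx * hy)
  new_landscape(cx, cy, P, hx, hy, method = "fpe", params = params, D = D,
                p_floor = p_floor,
                residual = max(abs(A %*% as.numeric(P))))
}

# sparse Scharfetter-Gummel finite-volume generator for
# dP/dt = -d/dx(F1 P) - d/dy(F2 P) + D (Pxx + Pyy), no-flux boundaries.
# Face flux J = (D/h) [B(-w) P_left - B(w) P_right], w = v h / D,
# B the Bernoulli function w/(e^w - 1); columns sum to zero by construction.
fpe_operator <- function(params, D, cx, cy, hx, hy) {
  nx <- length(cx); ny <- length(cy)
  N <- nx * ny
  bern <- function(w) ifelse(abs(w) < 1e-10, 1 - w / 2, w / expm1(w))
  ii <- jj <- vv <- list(); k <- 0
  add <- function(i, j, v) {
    k <<- k + 1; ii[[k]] <<- i; jj[[k]] <<- j; vv[[k]] <<- v
  }
  idx <- function(i, j) i + (j - 1L) * nx

  # vertical faces (between i and i+1 in x): velocity F1 at the face
  if (nx > 1) {
    xi <- cx[-nx] + hx / 2
    for (j in seq_len(ny)) {
      v <- drift_x1(xi, params)
      w <- v * hx / D
      cl <- D / hx * bern(-w)   # coefficient of left cell in flux
      cr <- -D / hx * bern(w)   # coefficient of right cell
      l <- idx(seq_len(nx - 1), j); r <- l + 1L
      # dP_l/dt -= J/hx ; dP_r/dt += J/hx
      add(l, l, -cl / hx); add(l, r, -cr / hx)
      add(r, l, cl / hx); add(r, r, cr / hx)
    }
  }
  # horizontal faces (between j and j+1 in y): velocity F2 at the face
  if (ny > 1) {
    yj <- cy[-ny] + hy / 2
    for (j in seq_len(ny - 1)) {
      v <- drift_x2(cx, yj[j], params)
      w <- v * hy / D
      cl <- D / hy * bern(-w)
      cr <- -D / hy * bern(w)
      l <- idx(seq_len(nx), j); r <- idx(seq_len(nx), j + 1L)
      add(l, l, -cl / hy); add(l, r, -cr / hy)
      add(r, l, cl / hy); add(r, r, cr / hy)
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(N, N))
}

new_landscape <- function(cx, cy, P, hx, hy, method, params, D, p_floor,
                          residual = NA_real_, n_samples = NA_real_) {
  U <- -log(P)
  U[P < p_floor * max(P)] <- NA_real_
  structure(list(x1 = cx, x2 = cy, P = P, U = U, dx1 = hx, dx2 = hy,
                 method = method, params = params, D = D,
                 p_floor = p_floor, residual = residual,
                 n_samples = n_samples),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("Stationary landscape (%s): %d x %d cells, D = %g\n",
              x$method, length(x$x1), length(x$x2), x$D))
  m <- landscape_modes(x)
  cat(sprintf("  %d local maxima of P; mass normalized to %.6f\n",
              nrow(m), sum(x$P) * x$dx1 * x$dx2))
  invisible(x)
}

#' Empirical landscape from simulated trajectories
#'
#' Normalized 2-D histogram of one or more post-burn-in trajectories,
#' with `U = -ln P` masked below the probability floor.  This is the
#' histogram estimator of the same stationary density that
#' [solve_stationary_fpe()] computes from the Fokker-Planck equation.
#'
#' @param trajectories a `trajectory` data frame or a list of them (see
#'   [simulate_sde()]); samples are pooled.
#' @param domain,resolution,p_floor as in [solve_stationary_fpe()].
#' @return a `landscape` object with `method = "histogram"`.
#' @export
histogram_landscape <- function(trajectories,
                                domain = list(x1 = c(0, 2),
                                              x2 = c(0, 2.5)),
                                resolution = c(128, 160),
                                p_floor = 1e-12) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  if (length(trajectories) == 0 ||
      sum(vapply(trajectories, nrow, integer(1))) == 0)
    stop("empty trajectory ensemble", call. = FALSE)
  if (length(resolution) == 1) resolution <- rep(resolution, 2)
  nx <- resolution[1]; ny <- resolution[2]
  hx <- diff(domain$x1) / nx; hy <- diff(domain$x2) / ny
  counts <- matrix(0, nx, ny)
  for (tr in trajectories) {
    ix <- floor((tr$x1 - domain$x1[1]) / hx) + 1L
    iy <- floor((tr$x2 - domain$x2[1]) / hy) + 1L
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    tab <- table(factor(ix[ok], levels = seq_len(nx)),
                 factor(iy[ok], levels = seq_len(ny)))
    counts <- counts + unclass(tab)
  }
  pars <- attr(trajectories[[1]], "params")
  D <- attr(trajectories[[1]], "noise")$D
  P <- counts / (sum(counts) * hx * hy)
  cx <- domain$x1[1] + (seq_len(nx) - 0.5) * hx
  cy <- domain$x2[1] + (seq_len(ny) - 0.5) * hy
  new_landscape(cx, cy, P, hx, hy, method = "histogram", params = pars,
                D = D, p_floor = p_floor, n_samples = sum(counts))
}

#' Streaming empirical landscape from a long simulation
#'
#' Convenience wrapper that integrates the Langevin dynamics in compiled
#' code and accumulates the histogram on the fly, so arbitrarily long runs
#' never materialize a trajectory.  One replicate is started at each
#' attractor in turn when `attractors` is given, otherwise at `x_init`.
#'
#' @param params a [model_params] object.
#' @param D noise intensity (> 0).
#' @param n_steps steps per replicate (default 1e7).
#' @param dt time step (default 1e-3).
#' @param burn_in discarded initial time per replicate (default 100).
#' @param n_replicates number of replicates (default 1).
#' @param attractors optional `fixed_points` frame of starting points.
#' @param x_init starting state when `attractors` is missing.
#' @param seed optional RNG seed.
#' @param domain,resolution,p_floor as in [solve_stationary_fpe()].
#' @return a `landscape` object with `method = "histogram"`.
#' @export
sample_landscape <- function(params, D, n_steps = 1e7, dt = 1e-3,
                             burn_in = 100, n_replicates = 1,
                             attractors = NULL, x_init = NULL, seed = NULL,
                             domain = list(x1 = c(0, 2), x2 = c(0, 2.5)),
                             resolution = c(128, 160), p_floor = 1e-12) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (length(resolution) == 1) resolution <- rep(resolution, 2)
  nx <- resolution[1]; ny <- resolution[2]
  starts <- if (!is.null(attractors)) {
    st <- attractors[attractors$stability == "stable", , drop = FALSE]
    cbind(st$x1, st$x2)
  } else {
    matrix(if (is.null(x_init)) invariant_box(params) / 2 else x_init,
           nrow = 1)
  }
  counts <- matrix(0, nx, ny)
  for (r in seq_len(n_replicates)) {
    s <- starts[(r - 1) %% nrow(starts) + 1, ]
    counts <- counts + .sim_hist_cpp(params, D, s, dt, n_steps,
                                     floor(burn_in / dt), domain$x1[1],
                                     domain$x1[2], nx, domain$x2[1],
                                     domain$x2[2], ny, TRUE)
  }
  hx <- diff(domain$x1) / nx; hy <- diff(domain$x2) / ny
  cx <- domain$x1[1] + (seq_len(nx) - 0.5) * hx
  cy <- domain$x2[1] + (seq_len(ny) - 0.5) * hy
  P <- counts / (sum(counts) * hx * hy)
  new_landscape(cx, cy, P, hx, hy, method = "histogram", params = params,
                D = D, p_floor = p_floor, n_samples = sum(counts))
}

#' Local maxima of a landscape
#'
#' Grid cells whose density exceeds all eight neighbours and a relative
#' threshold; with the Fokker-Planck solution these co-locate (to one grid
#' cell) with the stable fixed points.
#'
#' @param land a `landscape` object.
#' @param min_rel minimum density relative to the global maximum
#'   (default 1e-6).
#' @return data frame with columns `x1`, `x2`, `P`, `U`.
#' @export
landscape_modes <- function(land, min_rel = 1e-6) {
  P <- land$P
  nx <- nrow(P); ny <- ncol(P)
  out <- NULL
  thr <- min_rel * max(P)
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    v <- P[i, j]
    if (v < thr) next
    nb <- P[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v > max(nb[-5])) out <- rbind(out, c(land$x1[i], land$x2[j], v))
  }
  if (is.null(out)) return(data.frame(x1 = numeric(0), x2 = numeric(0),
                                      P = numeric(0), U = numeric(0)))
  data.frame(x1 = out[, 1], x2 = out[, 2], P = out[, 3], U = -log(out[, 3]))
}

#' Basin-resolved probabilities from a landscape
#'
#' Partitions the grid cells between the supplied stable attractors by
#' deterministic-relaxation basin assignment and sums the probability mass
#' per basin.
#'
#' @param land a `landscape` object.
#' @param attractors a `fixed_points` frame (stable rows used).
#' @return named numeric vector of probabilities (per phenotype, plus
#'   `"other"` for unresolved cells), summing to 1.
#' @export
basin_probabilities <- function(land, attractors) {
  st <- attractors[attractors$stability == "stable", , drop = FALSE]
  if (nrow(st) == 0) stop("no stable attractors supplied", call. = FALSE)
  rx <- range(land$x1); ry <- range(land$x2)
  if (any(st$x1 < rx[1] | st$x1 > rx[2] | st$x2 < ry[1] | st$x2 > ry[2]))
    stop("attractor outside the landscape domain", call. = FALSE)
  starts <- cbind(rep(land$x1, times = length(land$x2)),
                  rep(land$x2, each = length(land$x1)))
  lab <- relax_to_basin(land$params, starts, st)
  mass <- land$P * land$dx1 * land$dx2
  tot <- vapply(seq_len(nrow(st)), function(k) sum(mass[lab == k]),
                numeric(1))
  out <- c(tot, sum(mass[lab == 0]))
  names(out) <- c(st$phenotype, "other")
  out / sum(out)
}

#' Total-variation distance between two landscapes
#'
#' One half the absolute difference of the cell probability masses; the two
#' landscapes must share the same grid.
#'
#' @param a,b `landscape` objects on identical grids.
#' @return a number in `[0, 1]`.
#' @export
landscape_tv <- function(a, b) {
  stopifnot(length(a$x1) == length(b$x1), length(a$x2) == length(b$x2))
  0.5 * sum(abs(a$P - b$P)) * a$dx1 * a$dx2
}
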