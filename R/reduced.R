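#' Stationary expression levels of the first gene
#'
#' Stable roots of `F1(x1) = a1 hill(x1) + b1 - k1 x1`.  When the x1
#' subsystem is bistable, the basal (B) and stem-like (S) attractors share
#' the high root and the luminal (L) attractor sits on the low root, so the
#' one-dimensional reduction of the switching problem between B and S clamps
#' `x1` at the high branch.
#'
#' @param params a [model_params] object.
#' @param branch `"high"`, `"low"`, or `"all"`.
#' @return the requested stable root(s) of `F1`.
#' @export
stationary_x1 <- function(params, branch = c("high", "low", "all")) {
  validate_params(params)
  branch <- match.arg(branch)
  hi <- 1.05 * (params$a1 + params$b1) / params$k1
  roots <- bracket_roots(function(x) drift_x1(x, params), 0, hi, 400, 1e-12)
  stable <- roots[params$a1 * hill_prime(roots, params$theta, params$n) -
                    params$k1 < 0]
  if (length(stable) == 0)
    stop("internal error: F1 has no stable root", call. = FALSE)
  switch(branch,
         all = stable,
         low = {
           if (length(stable) < 2)
             stop("x1 subsystem is monostable: only the '",
                  if (stable[1] > params$theta) "high" else "low",
                  "' branch exists", call. = FALSE)
           min(stable)
         },
         high = {
           if (length(stable) < 2 && stable[1] < params$theta)
             stop("x1 subsystem is monostable: only the 'low' branch exists",
                  call. = FALSE)
           max(stable)
         })
}

#' One-dimensional potential of the reduced dynamics
#'
#' With `x1` clamped at a stationary level `x0`, the `x2` dynamics is a
#' gradient flow `dx2/dt = -U'(x2)` in the potential
#' \deqn{U(x_0, x_2) = \frac{a_2\theta}{2\sqrt2}\left[\mathrm{arctg}
#'  \frac{x_2^2-\theta^2}{\sqrt2\,\theta x_2} - \frac12 \ln
#'  \frac{x_2^2-\sqrt2\,\theta x_2+\theta^2}
#'       {x_2^2+\sqrt2\,\theta x_2+\theta^2}\right]
#'  + \frac{k_2}{2} x_2^2
#'  - \left(\frac{b_2\theta^4}{\theta^4+x_0^4}+a_2\right) x_2,}
#' the closed-form antiderivative of \eqn{-F_2(x_0, \cdot)} for Hill
#' coefficient `n = 4` (for other `n` the antiderivative is computed by
#' adaptive quadrature of \eqn{-F_2}).  The two minima (the B and S states)
#' and the interior maximum (the saddle `u1`) are located by bracketed root
#' finding on `U' = -F2`, with analytic curvatures.
#'
#' @param params a [model_params] object.
#' @param x0 clamped x1 level (>= 0), e.g. from [stationary_x1()].
#' @return an object of class `reduced_potential`: list with the potential
#'   function `U` (vectorised over x2), `x0`, stationary points `x_min`
#'   (length 2, increasing), `x_saddle`, curvatures `curv_min`,
#'   `curv_saddle`, and `params`.  Errors if the reduced system is not
#'   bistable.
#' @export
reduced_potential <- function(params, x0) {
  validate_params(params)
  if (x0 < 0) stop("x0 must be >= 0", call. = FALSE)
  p <- params
  c0 <- p$b2 * (1 - hill_activation(x0, p$theta, p$n))
  U <- if (p$n == 4) {
    th <- p$theta
    function(y) {
      p$a2 * th / (2 * sqrt(2)) *
        (atan((y^2 - th^2) / (sqrt(2) * th * y)) -
           0.5 * log((y^2 - sqrt(2) * th * y + th^2) /
                       (y^2 + sqrt(2) * th * y + th^2))) +
        0.5 * p$k2 * y^2 - (c0 + p$a2) * y
    }
  } else {
    # numeric antiderivative of -F2(x0, .) from the origin
    function(y) vapply(y, function(yy)
      -stats::integrate(function(k) drift_x2(x0, k, p), 0, yy,
                        rel.tol = 1e-10)$value, numeric(1))
  }
  hi <- 1.05 * (p$a2 + p$b2) / p$k2
  crit <- bracket_roots(function(y) drift_x2(x0, y, p), 0, hi, 800, 1e-12)
  curv <- p$k2 - p$a2 * hill_prime(crit, p$theta, p$n)  # U'' = -dF2/dx2
  mins <- crit[curv > 0]
  sads <- crit[curv < 0]
  if (length(mins) < 2 || length(sads) < 1)
    stop("reduced system is not bistable at x0 = ", signif(x0, 6),
         ": found ", length(mins), " minima", call. = FALSE)
  structure(list(U = U, x0 = x0, x_min = sort(mins),
                 x_saddle = sads[1],
                 curv_min = curv[match(sort(mins), crit)],
                 curv_saddle = curv[match(sads[1], crit)],
                 c0 = c0, params = p),
            class = "reduced_potential")
}

#' @export
print.reduced_potential <- function(x, ...) {
  cat(sprintf("Reduced 1-D potential at x0 = %.6g\n", x$x0))
  cat(sprintf("  minima at x2 = %.6g, %.6g; saddle at %.6g\n",
              x$x_min[1], x$x_min[2], x$x_saddle))
  cat(sprintf("  curvatures %.6g, %.6g (minima), %.6g (saddle)\n",
              x$curv_min[1], x$curv_min[2], x$curv_saddle))
  invisible(x)
}

# map "B"/"S" direction labels to (start, end) x2 values of a reduced
# potential: B is the low-x2 minimum, S the high-x2 one
direction_points <- function(pot, direction) {
  direction <- match.arg(direction, c("BS", "SB"))
  if (direction == "BS") c(pot$x_min[1], pot$x_min[2])
  else c(pot$x_min[2], pot$x_min[1])
}

#' Exact mean first-passage time of the reduced dynamics
#'
#' Evaluates the double-integral mean first-passage time
#' \deqn{\tau = \int_{y_1}^{y_2} \frac{dy}{D\,P_{st}(y)}
#'   \int_{0}^{y} P_{st}(k)\,dk, \qquad P_{st}(y) \propto e^{-U(y)/D},}
#' by nested adaptive quadrature, with the integrand rescaled by
#' \eqn{e^{(U(k)-U(y))/D}} inside the inner integral so no large
#' exponentials are formed.  The textbook lower limit \eqn{-\infty} is
#' replaced by the reflecting origin (concentrations are non-negative and
#' the density is negligible below 0); for a passage downhill in `y`
#' (`y1 > y2`) the mirrored form with the reflecting boundary above is
#' used.
#'
#' @param pot a [reduced_potential()] object.
#' @param D noise intensity (> 0).
#' @param y1,y2 start and end x2 levels; alternatively give `direction =
#'   "BS"` or `"SB"` to use the potential's two minima.
#' @param direction optional direction label overriding `y1`, `y2`.
#' @param rel.tol quadrature tolerance.
#' @return an `mfpt_result` with `method = "integral"` and zero
#'   uncertainty.
#' @export
mfpt_integral <- function(pot, D, y1 = NULL, y2 = NULL, direction = NULL,
                          rel.tol = 1e-8) {
  if (!inherits(pot, "reduced_potential"))
    stop("pot must be a reduced_potential", call. = FALSE)
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  if (!is.null(direction)) {
    ys <- direction_points(pot, direction)
    y1 <- ys[1]; y2 <- ys[2]
  }
  if (is.null(y1) || is.null(y2) || y1 == y2)
    stop("need distinct y1 and y2 (or a direction label)", call. = FALSE)
  U <- pot$U
  up <- y2 > y1
  ymax <- 1.6 * (pot$params$a2 + pot$params$b2) / pot$params$k2
  inner <- function(yy) {
    g <- function(k) exp(-(U(k) - U(yy)) / D)
    if (up) stats::integrate(g, 0, yy, rel.tol = rel.tol)$value
    else stats::integrate(g, yy, ymax, rel.tol = rel.tol)$value
  }
  outer_f <- function(y) vapply(y, inner, numeric(1)) / D
  val <- tryCatch(
    if (up) stats::integrate(outer_f, y1, y2, rel.tol = rel.tol)$value
    else stats::integrate(outer_f, y2, y1, rel.tol = rel.tol)$value,
    error = function(e) stop("quadrature failed (", conditionMessage(e),
                             "); at very small D use mfpt_kramers()",
                             call. = FALSE))
  if (!is.finite(val))
    stop("quadrature overflowed; at very small D use mfpt_kramers()",
         call. = FALSE)
  new_mfpt(val, "integral",
           c(from = signif(y1, 6), to = signif(y2, 6)), D, 0)
}

#' Steepest-descent (Kramers) mean first-passage time
#'
#' The saddle-point evaluation of the exact double integral,
#' \deqn{\tau = \frac{2\pi}{|U''(x_2^{st})\,U''(x_2^{u})|^{1/2}}
#'  \exp\!\left[\frac{U(x_2^{u}) - U(x_2^{st})}{D}\right],}
#' with `U` the deterministic reduced potential, its minimum \eqn{x_2^{st}}
#' the starting state and \eqn{x_2^{u}} the interior saddle.
#'
#' @param pot a [reduced_potential()] object (must be bistable).
#' @param D noise intensity (> 0).
#' @param direction `"BS"` (escape from the low-x2 basal well) or `"SB"`.
#' @return an `mfpt_result` with `method = "kramers"`.
#' @export
mfpt_kramers <- function(pot, D, direction = c("BS", "SB")) {
  if (!inherits(pot, "reduced_potential"))
    stop("pot must be a reduced_potential", call. = FALSE)
  direction <- match.arg(direction)
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  i <- if (direction == "BS") 1 else 2
  dU <- pot$U(pot$x_saddle) - pot$U(pot$x_min[i])
  pref <- 2 * pi / sqrt(pot$curv_min[i] * abs(pot$curv_saddle))
  new_mfpt(pref * exp(dU / D), "kramers",
           c(from = if (i == 1) "B" else "S",
             to = if (i == 1) "S" else "B"), D, 0,
           extra = list(barrier = dU, prefactor = pref))
}

#' Barrier heights of the reduced potential
#'
#' Potential differences between the interior saddle `u1` and each minimum:
#' \eqn{\Delta U_{u_1 B} = U(u_1) - U(B)} and
#' \eqn{\Delta U_{u_1 S} = U(u_1) - U(S)}.  Works on the deterministic
#' reduced potential or, via the default method, on any sampled potential
#' section (`x`, `U` vectors) such as a slice of `-ln P_st`, whose interior
#' maximum and flanking minima are located numerically.
#'
#' @param x a `reduced_potential` object, or a numeric vector of positions.
#' @param ... for the numeric method, `U`: potential values at `x`.
#' @return named vector `c(dU_u1B, dU_u1S)`, both `>= 0` when the
#'   stationary points are correctly ordered.
#' @export
barrier_heights <- function(x, ...) UseMethod("barrier_heights")

#' @rdname barrier_heights
#' @export
barrier_heights.reduced_potential <- function(x, ...) {
  c(dU_u1B = x$U(x$x_saddle) - x$U(x$x_min[1]),
    dU_u1S = x$U(x$x_saddle) - x$U(x$x_min[2]))
}

#' @rdname barrier_heights
#' @export
barrier_heights.numeric <- function(x, U, ...) {
  stopifnot(length(x) == length(U), length(x) > 4)
  ok <- is.finite(U)
  x <- x[ok]; U <- U[ok]
  n <- length(U)
  loc_min <- which(diff(sign(diff(U))) > 0) + 1L
  loc_max <- which(diff(sign(diff(U))) < 0) + 1L
  if (length(loc_min) < 2 || length(loc_max) < 1)
    stop("section is not a double well", call. = FALSE)
  # interior maximum between the two deepest minima
  m <- loc_min[order(U[loc_min])][1:2]
  m <- sort(m)
  sad <- loc_max[loc_max > m[1] & loc_max < m[2]]
  if (length(sad) == 0) stop("no saddle between the minima", call. = FALSE)
  sad <- sad[which.max(U[sad])]
  lo <- if (x[m[1]] < x[m[2]]) m[1] else m[2]
  hi <- if (x[m[1]] < x[m[2]]) m[2] else m[1]
  c(dU_u1B = U[sad] - U[lo], dU_u1S = U[sad] - U[hi])
}

#' Noise threshold of the switching direction
#'
#' The noise intensity `D_c` at which the mean first-passage times of the
#' two directions are equal, \eqn{\tau_{BS}(D_c) = \tau_{SB}(D_c)}; below it
#' the stem-like-to-basal passage is the faster one, above it the reverse.
#' Found by bisection of \eqn{\tau_{BS}(D) - \tau_{SB}(D)} with the chosen
#' MFPT method.  For the steepest-descent method the threshold also has the
#' closed form
#' \deqn{D_c = \frac{\Delta U_{u_1 B} - \Delta U_{u_1 S}}
#'       {\tfrac12 \ln(U''_B / U''_S)},}
#' which is checked against the bisection answer to 1e-6.
#'
#' @param pot a [reduced_potential()] object.
#' @param bracket `c(D_lo, D_hi)` straddling the crossing
#'   (default `c(0.05, 0.12)`).
#' @param method `"kramers"` (default) or `"integral"`.
#' @param tol bisection tolerance on D (default 1e-8).
#' @return the threshold `D_c`; for the Kramers method the closed-form value
#'   is attached as attribute `"closed_form"`.
#' @export
find_noise_threshold <- function(pot, bracket = c(0.05, 0.12),
                                 method = c("kramers", "integral"),
                                 tol = 1e-8) {
  method <- match.arg(method)
  tau <- function(D, dir) switch(method,
    kramers = mfpt_kramers(pot, D, dir)$value,
    integral = mfpt_integral(pot, D, direction = dir)$value)
  g <- function(D) log(tau(D, "BS")) - log(tau(D, "SB"))
  glo <- g(bracket[1]); ghi <- g(bracket[2])
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
    tab <- vapply(seq(bracket[1], bracket[2], length.out = 5),
                  function(D) c(D = D, tau_BS = tau(D, "BS"),
                                tau_SB = tau(D, "SB")), numeric(3))
    stop("tau_BS - tau_SB does not change sign on the bracket; diagnostic ",
         "table:\n", paste(utils::capture.output(print(t(tab))),
                           collapse = "\n"), call. = FALSE)
  }
  Dc <- stats::uniroot(g, bracket, tol = tol)$root
  if (method == "kramers") {
    dU <- barrier_heights(pot)
    cf <- (dU[["dU_u1B"]] - dU[["dU_u1S"]]) /
      (0.5 * log(pot$curv_min[1] / pot$curv_min[2]))
    if (abs(cf - Dc) > 1e-6)
      warning("closed-form and bisection thresholds disagree: ", cf,
              " vs ", Dc, call. = FALSE)
    attr(Dc, "closed_form") <- cf
  }
  Dc
}
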