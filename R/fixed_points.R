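#' Enumerate and classify the fixed points of the circuit
#'
#' Exploits the skew-product structure of the kinetics: `F1` depends on `x1`
#' only, so its roots are found first by dense sign-change bracketing plus
#' bisection on `x1`; for each root `x0`, `F2(x0, x2) = 0` is solved on `x2`
#' the same way.  Each fixed point is classified from the (triangular)
#' Jacobian eigenvalues, stable points are given a phenotype label, and the
#' result is sorted by `(x1, x2)`.
#'
#' @param params a [model_params] object.
#' @param domain list with `x1` and `x2` ranges (each `c(lo, hi)`); defaults
#'   to the invariant box `[0,(a1+b1)/k1] x [0,(a2+b2)/k2]` with a 5% margin.
#' @param seeds_per_axis number of bracketing seeds per axis (default 400).
#' @param tol root tolerance passed to the bisection (default 1e-9).
#' @return a data frame of class `fixed_points` with columns `x1`, `x2`,
#'   `stability` ("stable", "saddle" or "unstable"), `phenotype` ("S", "B",
#'   "L", "other", or "none" for non-stable points), and the two real
#'   eigenvalues `lambda1`, `lambda2`.
#' @examples
#' fps <- find_fixed_points(model_params(a1 = 0.8, a2 = 0.85))
#' subset(fps, stability == "stable")
#' @export
find_fixed_points <- function(params, domain = NULL, seeds_per_axis = 400,
                              tol = 1e-9) {
  validate_params(params)
  if (is.null(domain)) {
    box <- invariant_box(params)
    domain <- list(x1 = c(0, 1.05 * box[["x1"]]),
                   x2 = c(0, 1.05 * box[["x2"]]))
  }
  box <- invariant_box(params)
  if (domain$x1[2] < box[["x1"]] || domain$x2[2] < box[["x2"]])
    stop("domain must contain the invariant box [0,(a1+b1)/k1] x ",
         "[0,(a2+b2)/k2]", call. = FALSE)

  x1_roots <- bracket_roots(function(x) drift_x1(x, params),
                            domain$x1[1], domain$x1[2], seeds_per_axis, tol)
  pts <- NULL
  for (x0 in x1_roots) {
    x2_roots <- bracket_roots(function(y) drift_x2(x0, y, params),
                              domain$x2[1], domain$x2[2], seeds_per_axis, tol)
    for (y in x2_roots) pts <- rbind(pts, c(x0, y))
  }
  if (is.null(pts))
    stop("internal error: no fixed point found although the drift is ",
         "bounded and continuous", call. = FALSE)
  # deduplicate in max-norm and order deterministically
  pts <- pts[!duplicated(round(pts, 7)), , drop = FALSE]
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]

  out <- data.frame(x1 = pts[, 1], x2 = pts[, 2],
                    stability = NA_character_, phenotype = NA_character_,
                    lambda1 = NA_real_, lambda2 = NA_real_)
  for (i in seq_len(nrow(out))) {
    J <- drift_jacobian(c(out$x1[i], out$x2[i]), params)
    ev <- sort(c(J[1, 1], J[2, 2]))  # triangular Jacobian: real eigenvalues
    out$lambda1[i] <- ev[1]
    out$lambda2[i] <- ev[2]
    if (any(abs(ev) < 1e-9))
      warning("eigenvalue within 1e-9 of zero: parameters sit on a ",
              "bifurcation point", call. = FALSE)
    out$stability[i] <-
      if (all(ev < 0)) "stable" else if (prod(ev) < 0) "saddle" else "unstable"
    out$phenotype[i] <- if (out$stability[i] == "stable")
      classify_phenotype(out$x1[i], out$x2[i], params) else "none"
  }
  class(out) <- c("fixed_points", "data.frame")
  attr(out, "params") <- params
  out
}

# all sign-change roots of f on [lo, hi] via seeded bracketing + uniroot
bracket_roots <- function(f, lo, hi, n_seed, tol) {
  xs <- seq(lo, hi, length.out = n_seed)
  fs <- vapply(xs, f, numeric(1))
  roots <- numeric(0)
  if (fs[1] == 0) roots <- xs[1]
  idx <- which(fs[-n_seed] * fs[-1] <= 0 & fs[-n_seed] != 0)
  for (i in idx)
    roots <- c(roots,
               stats::uniroot(f, c(xs[i], xs[i + 1]), tol = tol)$root)
  sort(roots[!duplicated(round(roots, 7))])
}

#' Phenotype label of a stable fixed point
#'
#' High zeb1 / low cdh1 is the basal state (B), high/high the stem-like
#' state (S), low/high the luminal state (L); anything else is "other".
#' "High" and "low" are relative to the Hill threshold `theta`, the model's
#' only intrinsic concentration scale.
#'
#' @param x1,x2 coordinates of the fixed point.
#' @param params a [model_params] object.
#' @return one of `"S"`, `"B"`, `"L"`, `"other"`.
#' @export
classify_phenotype <- function(x1, x2, params) {
  th <- params$theta
  if (x1 > th && x2 < th) "B"
  else if (x1 > th && x2 > th) "S"
  else if (x1 < th && x2 > th) "L"
  else "other"
}

#' @export
print.fixed_points <- function(x, ...) {
  cat(sprintf("Fixed points (%d stable, %d saddle, %d unstable)\n",
              sum(x$stability == "stable"), sum(x$stability == "saddle"),
              sum(x$stability == "unstable")))
  print.data.frame(x, digits = 6, row.names = FALSE)
  invisible(x)
}

# region code: phenotype letters of the stable points in fixed L < B < S
# order, e.g. "LBS" for tristability
region_code <- function(fps) {
  ph <- unique(fps$phenotype[fps$stability == "stable"])
  ph <- ph[ph != "none"]
  lev <- c("L", "B", "S")
  code <- paste(lev[lev %in% ph], collapse = "")
  if (any(ph == "other")) code <- paste0(code, "+")
  if (code == "") "other" else code
}

#' Two-parameter phase diagram of stability regions
#'
#' Re-solves the fixed points on every cell of a rectangular grid over any
#' pair of kinetic parameters (typically `a1`, `a2`) and records the region
#' code: the phenotype letters of the coexisting stable states in fixed
#' L, B, S order (`"L"`, `"B"`, `"LB"`, `"LS"`, `"BS"`, `"LBS"`, ...).
#'
#' @param params a [model_params] object giving the base parameter set.
#' @param axis1,axis2 lists `list(name = <parameter>, values = <grid>)` with
#'   strictly increasing grids.
#' @param seeds_per_axis passed to [find_fixed_points()].
#' @return an object of class `phase_map`: list with the two grids, a label
#'   matrix `cell_label` (axis1 on rows), and matrices `n_stable`,
#'   `n_unstable`.
#' @export
phase_diagram <- function(params, axis1, axis2, seeds_per_axis = 400) {
  for (ax in list(axis1, axis2)) {
    if (!ax$name %in% names(params))
      stop("unknown parameter name '", ax$name, "'", call. = FALSE)
    if (any(diff(ax$values) <= 0))
      stop("grid for '", ax$name, "' must be strictly increasing",
           call. = FALSE)
  }
  n1 <- length(axis1$values); n2 <- length(axis2$values)
  lab <- matrix(NA_character_, n1, n2)
  nst <- matrix(NA_integer_, n1, n2)
  nun <- matrix(NA_integer_, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    p <- params
    p[[axis1$name]] <- axis1$values[i]
    p[[axis2$name]] <- axis2$values[j]
    fps <- find_fixed_points(p, seeds_per_axis = seeds_per_axis)
    lab[i, j] <- region_code(fps)
    nst[i, j] <- sum(fps$stability == "stable")
    nun[i, j] <- sum(fps$stability != "stable")
  }
  structure(list(axis1 = axis1, axis2 = axis2, cell_label = lab,
                 n_stable = nst, n_unstable = nun, params = params),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("Phase map over (%s, %s): %d x %d cells\n", x$axis1$name,
              x$axis2$name, length(x$axis1$values), length(x$axis2$values)))
  print(table(x$cell_label))
  invisible(x)
}

#' One-parameter bifurcation scan
#'
#' Records every fixed point (its `x2` coordinate in particular, the
#' E-cadherin readout) and its stability along a grid of one parameter,
#' together with the region code per grid value.
#'
#' @param params base [model_params].
#' @param parameter name of the swept parameter (e.g. `"a1"`).
#' @param values strictly increasing numeric grid.
#' @param seeds_per_axis passed to [find_fixed_points()].
#' @return a data frame of class `bifurcation_branch` with columns `value`
#'   (the parameter), `x1`, `x2`, `stability`, `phenotype`, `region` (the
#'   code of the whole grid value).
#' @export
bifurcation_scan <- function(params, parameter, values,
                             seeds_per_axis = 400) {
  if (!parameter %in% names(params))
    stop("unknown parameter name '", parameter, "'", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("grid must be strictly increasing", call. = FALSE)
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    p <- params
    p[[parameter]] <- values[i]
    fps <- find_fixed_points(p, seeds_per_axis = seeds_per_axis)
    n_st <- sum(fps$stability == "stable")
    if (!n_st %in% 1:3)
      warning("grid value ", values[i], ": ", n_st, " stable points",
              call. = FALSE)
    rows[[i]] <- data.frame(value = values[i], x1 = fps$x1, x2 = fps$x2,
                            stability = fps$stability,
                            phenotype = fps$phenotype,
                            region = region_code(fps))
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- "value"
  attr(out, "parameter") <- parameter
  class(out) <- c("bifurcation_branch", "data.frame")
  out
}

# fast tristability scan used by critical_hill(): same skew-product root
# finding as find_fixed_points(), restricted to stable points and their
# labels, with early exit on the first L+B+S cell.
has_tristability <- function(params, a1_values, a2_values,
                             seeds_per_axis = 400) {
  th <- params$theta; n <- params$n
  for (a1 in a1_values) {
    p1 <- params; p1$a1 <- a1
    r1 <- bracket_roots(function(x) drift_x1(x, p1), 0,
                        1.05 * (a1 + params$b1) / params$k1,
                        seeds_per_axis, 1e-10)
    st1 <- r1[p1$a1 * hill_prime(r1, th, n) - p1$k1 < 0]
    if (length(st1) < 2) next  # need both a low and a high x1 branch
    inhib <- params$b2 * (1 - hill_activation(st1, th, n))
    for (a2 in a2_values) {
      labels <- character(0)
      for (j in seq_along(st1)) {
        f <- function(y) a2 * hill_activation(y, th, n) + inhib[j] -
          params$k2 * y
        r2 <- bracket_roots(f, 0, 1.05 * (a2 + params$b2) / params$k2,
                            seeds_per_axis, 1e-10)
        r2 <- r2[a2 * hill_prime(r2, th, n) - params$k2 < 0]
        for (y in r2) {
          pp <- params; pp$a2 <- a2
          labels <- c(labels, classify_phenotype(st1[j], y, pp))
        }
      }
      if (all(c("S", "B", "L") %in% labels)) return(TRUE)
    }
  }
  FALSE
}

#' Critical Hill coefficient for tristability
#'
#' Bisects on the Hill coefficient `n`: for each candidate, the `(a1, a2)`
#' plane is scanned on a rectangular grid and tristability is declared
#' present if any cell has three coexisting stable states labelled S, B and
#' L.  Returns the infimum `n` with tristability, to the requested width.
#'
#' Note that S/B/L coexistence needs two stable roots of
#' `F1 = a1 hill(x1) + b1 - k1 x1`; the fold of that subsystem disappears at
#' the cusp \eqn{b_1 = \theta ((n-1)/(n+1))^{(n+1)/n}}, so for the default
#' `b1 = 0.2`, `theta = 0.5` no tristability exists below `n = 3.0194`
#' regardless of `a1`, `a2`.  [critical_hill_cusp()] evaluates that closed
#' form.
#'
#' @param params base [model_params] (its `a1`, `a2`, `n` are overridden by
#'   the scan).
#' @param a1_range,a2_range scan ranges (defaults `[0.05, 2]`).
#' @param grid_n grid resolution per axis (default 80).
#' @param n_bracket bisection bracket on `n` (default `c(2, 3)`); must
#'   straddle the transition.
#' @param tol bracket width at which bisection stops (default 0.02).
#' @param seeds_per_axis root-bracketing seeds (default 400).
#' @return the critical Hill coefficient (upper end of the final bracket,
#'   i.e. the smallest tested `n` with tristability), with the final bracket
#'   as attribute `"bracket"`.
#' @export
critical_hill <- function(params, a1_range = c(0.05, 2),
                          a2_range = c(0.05, 2), grid_n = 80,
                          n_bracket = c(2, 3), tol = 0.02,
                          seeds_per_axis = 400) {
  a1s <- seq(a1_range[1], a1_range[2], length.out = grid_n)
  a2s <- seq(a2_range[1], a2_range[2], length.out = grid_n)
  tri <- function(n) {
    p <- params; p$n <- n
    has_tristability(p, a1s, a2s, seeds_per_axis)
  }
  lo <- n_bracket[1]; hi <- n_bracket[2]
  if (tri(lo) || !tri(hi))
    stop("bracket [", lo, ", ", hi, "] does not straddle the tristability ",
         "transition; widen it (tristability at lo: ", tri(lo),
         ", at hi: ", tri(hi), ")", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (tri(mid)) hi <- mid else lo <- mid
  }
  structure(hi, bracket = c(lo, hi))
}

#' Closed-form cusp bound for the critical Hill coefficient
#'
#' The x1 subsystem `a1 hill(x1) + b1 - k1 x1` admits two stable roots for
#' some `a1` if and only if `b1/k1 < theta ((n-1)/(n+1))^((n+1)/n)`.
#' Solving the equality for `n` gives the exact infimum Hill coefficient
#' below which L cannot coexist with B or S for any `(a1, a2)`.
#'
#' @param b1 basal rate (on the scale of `k1 = 1`).
#' @param theta Hill threshold.
#' @return the critical Hill coefficient.
#' @export
critical_hill_cusp <- function(b1 = 0.2, theta = 0.5) {
  f <- function(n) theta * ((n - 1) / (n + 1))^((n + 1) / n) - b1
  stats::uniroot(f, c(1 + 1e-6, 50), tol = 1e-10)$root
}
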