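#' Kinetic parameters of the two-gene circuit
#'
#' Bundles the eight dimensionless constants of the deterministic kinetics
#' \deqn{dx_1/dt = a_1 x_1^n/(\theta^n + x_1^n) + b_1 - k_1 x_1 = F_1(x_1)}
#' \deqn{dx_2/dt = a_2 x_2^n/(\theta^n + x_2^n) +
#'       b_2 \theta^n/(\theta^n + x_1^n) - k_2 x_2 = F_2(x_1, x_2)}
#' where `x1` is the expression level of the EMT driver (zeb1-like) gene and
#' `x2` that of the E-cadherin (cdh1-like) gene.  `a1`, `a2` are
#' self-activation rates, `b1` the basal production of gene 1, `b2` the
#' strength with which gene 1 represses gene 2, `k1`, `k2` linear degradation
#' rates, `theta` the Hill threshold and `n` the Hill coefficient (any real
#' > 0; the circuit is studied down to n close to 2).
#'
#' The defaults fix `k1 = k2 = 1`, `theta = 0.5`, `n = 4`, `b1 = 0.2`,
#' `b2 = 1`; the self-activation rates `a1` and `a2` have no privileged
#' value (they are the axes of the phase diagram) and must be supplied.
#'
#' @param a1,a2 self-activation rates (> 0).
#' @param b1 basal expression rate of gene 1 (>= 0).
#' @param b2 repression strength of gene 2 by gene 1 (>= 0).
#' @param k1,k2 degradation rates (> 0).
#' @param theta Hill threshold (> 0).
#' @param n Hill coefficient (> 0, real).
#' @return an object of class `model_params` (named list of the eight rates).
#' @examples
#' p <- model_params(a1 = 0.8, a2 = 0.85)
#' drift(c(0.5, 0.5), p)
#' @export
model_params <- function(a1, a2, b1 = 0.2, b2 = 1.0, k1 = 1.0, k2 = 1.0,
                         theta = 0.5, n = 4) {
  p <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, k1 = k1, k2 = k2,
            theta = theta, n = n)
  validate_params(p)
  structure(p, class = "model_params")
}

validate_params <- function(p) {
  need <- c("a1", "a2", "b1", "b2", "k1", "k2", "theta", "n")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing model parameters: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in need) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number",
           call. = FALSE)
  }
  strict <- c("a1", "a2", "k1", "k2", "theta", "n")
  bad <- strict[vapply(strict, function(f) p[[f]] <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be > 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (p$b1 < 0 || p$b2 < 0)
    stop("b1 and b2 must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-gene circuit parameters\n")
  cat(sprintf("  a1 = %g, a2 = %g, b1 = %g, b2 = %g\n",
              x$a1, x$a2, x$b1, x$b2))
  cat(sprintf("  k1 = %g, k2 = %g, theta = %g, n = %g\n",
              x$k1, x$k2, x$theta, x$n))
  invisible(x)
}

#' Hill activation function
#'
#' The sigmoidal regulation term \eqn{x^n/(\theta^n + x^n)}.  Powers are
#' evaluated as `exp(n * log(x))` so that non-integer Hill coefficients are
#' exact, with `x = 0` handled as its limit 0.
#'
#' @param x concentration (>= 0), vectorised.
#' @param theta threshold (> 0).
#' @param n Hill coefficient (> 0).
#' @return activation fraction in `[0, 1]`.
#' @export
hill_activation <- function(x, theta, n) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("x must be finite and >= 0", call. = FALSE)
  if (theta <= 0 || n <= 0)
    stop("theta and n must be > 0", call. = FALSE)
  out <- numeric(length(x))
  pos <- x > 0
  # 1/(1 + (theta/x)^n) avoids overflow of x^n for large x and any real n
  out[pos] <- 1 / (1 + exp(n * (log(theta) - log(x[pos]))))
  out
}

# derivative of the Hill function, the limit at 0 being 0 for n > 1
hill_prime <- function(x, theta, n) {
  out <- numeric(length(x))
  pos <- x > 0
  h <- hill_activation(x[pos], theta, n)
  out[pos] <- n * h * (1 - h) / x[pos]
  out
}

#' Deterministic drift of the circuit
#'
#' @param state numeric vector `c(x1, x2)` of non-negative expression levels.
#' @param params a [model_params] object.
#' @return numeric vector `c(F1, F2)`.  `F1` does not depend on `x2`.
#' @export
drift <- function(state, params) {
  validate_state(state)
  c(drift_x1(state[1], params), drift_x2(state[1], state[2], params))
}

drift_x1 <- function(x1, p) {
  p$a1 * hill_activation(x1, p$theta, p$n) + p$b1 - p$k1 * x1
}

drift_x2 <- function(x1, x2, p) {
  p$a2 * hill_activation(x2, p$theta, p$n) +
    p$b2 * (1 - hill_activation(x1, p$theta, p$n)) - p$k2 * x2
}

validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)) ||
      any(state < 0))
    stop("state must be two finite non-negative numbers c(x1, x2)",
         call. = FALSE)
  invisible(state)
}

#' Jacobian of the drift
#'
#' Closed-form partial derivatives of `(F1, F2)`.  Because `F1` is
#' independent of `x2` the matrix is lower triangular and both eigenvalues
#' are real (the diagonal entries).
#'
#' @inheritParams drift
#' @return a 2 x 2 numeric matrix, rows = equations, columns = variables.
#' @export
drift_jacobian <- function(state, params) {
  validate_state(state)
  p <- params
  hp1 <- hill_prime(state[1], p$theta, p$n)
  hp2 <- hill_prime(state[2], p$theta, p$n)
  matrix(c(p$a1 * hp1 - p$k1, 0,
           -p$b2 * hp1,       p$a2 * hp2 - p$k2),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("F1", "F2"), c("x1", "x2")))
}

# the box [0, (a1+b1)/k1] x [0, (a2+b2)/k2] that all trajectories enter
invariant_box <- function(p) {
  c(x1 = (p$a1 + p$b1) / p$k1, x2 = (p$a2 + p$b2) / p$k2)
}
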