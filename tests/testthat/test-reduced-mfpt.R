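test_that("stationary x1 branches are stable roots of F1", {
  p <- ref_params()
  hi <- stationary_x1(p, "high")
  lo <- stationary_x1(p, "low")
  expect_equal(hi, ref$x1_high, tolerance = 1e-6)
  expect_equal(lo, ref$x1_low, tolerance = 1e-6)
  expect_lt(abs(drift(c(hi, 0), p)[1]), 1e-10)
  expect_lt(abs(drift(c(lo, 0), p)[1]), 1e-10)
  expect_length(stationary_x1(p, "all"), 2)
  # monostable regime: the missing branch is reported by name
  expect_error(stationary_x1(model_params(a1 = 0.3, a2 = 0.8), "high"),
               "only the 'low' branch")
})

test_that("the closed-form potential differentiates back to -F2 and has the
           expected stationary points", {
  p <- ref_params()
  pot <- reduced_potential(p, stationary_x1(p, "high"))
  xs <- seq(0.01, 2, length.out = 1000)
  h <- 1e-6
  dU <- (pot$U(xs + h) - pot$U(xs - h)) / (2 * h)
  F2 <- vapply(xs, function(y) drift(c(pot$x0, y), p)[2], numeric(1))
  expect_lt(max(abs(dU + F2)), 1e-8)
  expect_equal(pot$x_min, c(ref$B[2], ref$S[2]), tolerance = 1e-6)
  expect_equal(pot$x_saddle, ref$u1[2], tolerance = 1e-6)
  expect_true(all(pot$curv_min > 0))
  expect_lt(pot$curv_saddle, 0)
  expect_equal(c(pot$curv_min, pot$curv_saddle),
               c(ref$curv_B, ref$curv_S, ref$curv_u1), tolerance = 1e-6)
  # minima and the interior maximum interleave
  expect_true(pot$x_min[1] < pot$x_saddle && pot$x_saddle < pot$x_min[2])
  # clamping at the low branch gives a monostable well: explicit error
  expect_error(reduced_potential(p, stationary_x1(p, "low")),
               "not bistable")
})

test_that("the numeric-antiderivative fallback agrees with the closed form", {
  p <- ref_params()
  x0 <- stationary_x1(p, "high")
  pot4 <- reduced_potential(p, x0)
  pn <- p; pn$n <- 4 + 1e-12  # force the generic quadrature path
  potn <- reduced_potential(pn, x0)
  xs <- seq(0.05, 1.5, length.out = 20)
  d <- (pot4$U(xs) - pot4$U(0.05)) - (potn$U(xs) - potn$U(0.05))
  expect_lt(max(abs(d)), 1e-7)
})

test_that("barrier heights match the frozen quadrature values and drive the
           Kramers ordering", {
  pot <- reduced_potential(ref_params(), stationary_x1(ref_params(), "high"))
  dU <- barrier_heights(pot)
  expect_true(all(dU >= 0))
  expect_equal(unname(dU), c(ref$dU_u1B, ref$dU_u1S), tolerance = 1e-5)
  # the better-protected well (larger barrier) is slower to leave
  expect_gt(mfpt_kramers(pot, 0.02, "BS")$value,
            mfpt_kramers(pot, 0.02, "SB")$value)
  # sampled-section method recovers the same barriers
  xs <- seq(0.01, 1.4, length.out = 2000)
  dU2 <- barrier_heights(xs, U = pot$U(xs))
  expect_equal(unname(dU2), unname(dU), tolerance = 1e-4)
})

test_that("Kramers MFPT has the steepest-descent structure", {
  pot <- reduced_potential(ref_params(), stationary_x1(ref_params(), "high"))
  r <- mfpt_kramers(pot, 1e6, "BS")  # exponent ~ 0: bare prefactor
  expect_equal(r$value,
               2 * pi / sqrt(pot$curv_min[1] * abs(pot$curv_saddle)),
               tolerance = 1e-6)
  # log tau is affine in 1/D with slope equal to the barrier height
  Ds <- c(0.02, 0.05, 0.1)
  lt <- vapply(Ds, function(D) log(mfpt_kramers(pot, D, "SB")$value),
               numeric(1))
  fit <- lm(lt ~ I(1 / Ds))
  expect_equal(unname(coef(fit)[2]), unname(barrier_heights(pot)[2]),
               tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("the exact MFPT integral grows as noise vanishes and stays close
           to steepest descent at weak noise", {
  pot <- reduced_potential(ref_params(), stationary_x1(ref_params(), "high"))
  taus <- vapply(c(0.2, 0.1, 0.05), function(D)
    mfpt_integral(pot, D, direction = "BS")$value, numeric(1))
  expect_true(all(diff(taus) > 0))  # increasing as D decreases
  for (dir in c("BS", "SB")) {
    ratio <- mfpt_integral(pot, 0.02, direction = dir)$value /
      mfpt_kramers(pot, 0.02, dir)$value
    expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
  }
  expect_error(mfpt_integral(pot, 0.05, y1 = 0.3, y2 = 0.3), "distinct")
})

test_that("the noise threshold is found by bisection, matches its closed
           form, and demands a straddling bracket", {
  pot <- reduced_potential(ref_params(), stationary_x1(ref_params(), "high"))
  Dc <- find_noise_threshold(pot)
  expect_equal(as.numeric(Dc), ref$Dc_kramers, tolerance = 1e-6)
  expect_lt(abs(as.numeric(Dc) - attr(Dc, "closed_form")), 1e-6)
  # below the threshold S -> B is the fast direction, above it B -> S
  expect_lt(mfpt_kramers(pot, 0.9 * Dc, "SB")$value,
            mfpt_kramers(pot, 0.9 * Dc, "BS")$value)
  expect_gt(mfpt_kramers(pot, 1.1 * Dc, "SB")$value,
            mfpt_kramers(pot, 1.1 * Dc, "BS")$value)
  expect_error(find_noise_threshold(pot, bracket = c(0.05, 0.06)),
               "does not change sign")
})
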