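test_that("noise-free integration is stationary at fixed points and matches
           an independent ODE solve elsewhere", {
  skip_if_not_installed("deSolve")
  p <- ref_params()
  fps <- find_fixed_points(p, tol = 1e-12)
  B <- as.numeric(stable_points(fps)[2, c("x1", "x2")])
  tr <- simulate_sde(p, D = 0, x_init = B, t_end = 1)
  expect_lt(max(abs(diff(tr$x1))), 1e-12)
  expect_lt(max(abs(diff(tr$x2))), 1e-12)
  # from a generic start the D = 0 path lands on the attractor that an
  # independent adaptive ODE integration reaches
  rhs <- function(t, y, parms) list(drift(pmax(y, 0), p))
  ode_end <- deSolve::ode(c(0.5, 0.5), times = c(0, 60), func = rhs,
                          parms = NULL)[2, 2:3]
  tr <- simulate_sde(p, D = 0, x_init = c(0.5, 0.5), t_end = 60, thin = 100)
  expect_lt(max(abs(as.numeric(ode_end) -
                      as.numeric(tr[nrow(tr), c("x1", "x2")]))), 1e-3)
})

test_that("identical seeds reproduce trajectories bit for bit", {
  p <- ref_params()
  a <- simulate_sde(p, D = 0.05, x_init = c(0.5, 0.5), t_end = 5, seed = 99)
  b <- simulate_sde(p, D = 0.05, x_init = c(0.5, 0.5), t_end = 5, seed = 99)
  expect_identical(a, b)
  c <- simulate_sde(p, D = 0.05, x_init = c(0.5, 0.5), t_end = 5, seed = 100)
  expect_false(identical(a$x2, c$x2))
  expect_true(all(a$x1 >= 0 & a$x2 >= 0))  # reflecting boundary
})

test_that("occupancies are a probability vector and the luminal basin is
           rare at weak noise", {
  p <- ref_params()
  fps <- find_fixed_points(p)
  occ <- estimate_occupancy(p, D = 0.01, fps, t_end = 500, burn_in = 50,
                            n_replicates = 4, seed = 21)
  expect_equal(sum(occ$probability), 1, tolerance = 1e-12)
  expect_true(all(occ$probability >= 0))
  expect_lt(occ$probability["L"], occ$probability["B"])
  expect_lt(occ$probability["L"], occ$probability["S"])
  expect_error(estimate_occupancy(p, 0.01, fps[fps$stability == "saddle", ]),
               "no stable attractors")
})

test_that("halving dt shifts occupancies by less than two combined SEs", {
  p <- ref_params()
  fps <- find_fixed_points(p)
  a <- estimate_occupancy(p, D = 0.05, fps, dt = 1e-3, t_end = 400,
                          burn_in = 40, n_replicates = 6, seed = 5)
  b <- estimate_occupancy(p, D = 0.05, fps, dt = 5e-4, t_end = 400,
                          burn_in = 40, n_replicates = 6, seed = 6)
  for (ph in c("L", "B", "S"))
    expect_lt(abs(a$probability[ph] - b$probability[ph]),
              2 * sqrt(a$se[ph]^2 + b$se[ph]^2) + 1e-8)
})

test_that("first-passage sampling censors, warns, and respects direction
           asymmetry of the reduced dynamics", {
  p <- ref_params()
  fps <- find_fixed_points(p)
  B <- stable_points(fps)[2, ]; S <- stable_points(fps)[3, ]
  expect_error(first_passage_times(p, 0.05, B, B), "distinct")
  expect_warning(
    r <- first_passage_times(p, 0.01, B, S, n_samples = 10, t_max = 1,
                             seed = 3),
    "censored")
  expect_gt(r$n_censored, 5)
  # at weak noise the stem-to-basal passage of the reduced system is the
  # faster direction; at strong noise the order reverses
  t_bs <- first_passage_times(p, 0.02, B, S, n_samples = 150, seed = 11,
                              dynamics = "reduced")
  t_sb <- first_passage_times(p, 0.02, S, B, n_samples = 150, seed = 12,
                              dynamics = "reduced")
  expect_gt(t_bs$value, t_sb$value)
  h_bs <- first_passage_times(p, 0.12, B, S, n_samples = 150, seed = 13,
                              dynamics = "reduced")
  h_sb <- first_passage_times(p, 0.12, S, B, n_samples = 150, seed = 14,
                              dynamics = "reduced")
  expect_lt(h_bs$value, h_sb$value)
  # passage times shrink with noise (full 2-D dynamics)
  f1 <- first_passage_times(p, 0.03, B, S, n_samples = 80, seed = 15)
  f2 <- first_passage_times(p, 0.10, B, S, n_samples = 80, seed = 16)
  expect_lt(f2$value, f1$value)
})
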