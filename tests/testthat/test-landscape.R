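test_that("the discrete Fokker-Planck operator conserves probability and its
           stationary solution is normalized", {
  p <- ref_params()
  cx <- (seq_len(64) - 0.5) * 2 / 64
  cy <- (seq_len(80) - 0.5) * 2.5 / 80
  A <- phenoswitch:::fpe_operator(p, 0.05, cx, cy, 2 / 64, 2.5 / 80)
  expect_lt(max(abs(Matrix::colSums(A))), 1e-10)
  land <- solve_stationary_fpe(p, D = 0.05, resolution = c(64, 80))
  expect_equal(sum(land$P) * land$dx1 * land$dx2, 1, tolerance = 1e-8)
  expect_true(all(land$P >= 0))
  expect_lt(land$residual, 1e-8)
  expect_error(solve_stationary_fpe(p, D = 0.05, resolution = 32),
               "at least 64")
  expect_error(solve_stationary_fpe(p, D = 0), "> 0")
})

test_that("doubling the grid moves each mode by less than one coarse cell
           and mass concentrates as noise falls", {
  p <- ref_params()
  co <- solve_stationary_fpe(p, D = 0.05, resolution = c(64, 80))
  fi <- solve_stationary_fpe(p, D = 0.05, resolution = c(128, 160))
  mc <- landscape_modes(co, min_rel = 1e-4)
  mf <- landscape_modes(fi, min_rel = 1e-4)
  expect_equal(nrow(mc), nrow(mf))
  mc <- mc[order(mc$x1, mc$x2), ]; mf <- mf[order(mf$x1, mf$x2), ]
  expect_lt(max(abs(mc$x1 - mf$x1)), co$dx1 + 1e-12)
  expect_lt(max(abs(mc$x2 - mf$x2)), co$dx2 + 1e-12)
  peaks <- vapply(c(0.1, 0.05, 0.02), function(D)
    max(solve_stationary_fpe(p, D, resolution = c(64, 80))$P *
          (2 / 64) * (2.5 / 80)), numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("histogram landscape is a normalized density whose potential is a
           monotone transform of P", {
  p <- ref_params()
  tr <- simulate_sde(p, D = 0.05, x_init = c(0.9, 0.1), t_end = 200,
                     seed = 8)
  land <- histogram_landscape(tr, resolution = c(64, 80))
  expect_equal(sum(land$P) * land$dx1 * land$dx2, 1, tolerance = 1e-12)
  expect_equal(which.max(land$P), which.min(replace(land$U, is.na(land$U),
                                                    Inf)))
  # pooling the same trajectory twice doubles all counts: U shifts by at
  # most an additive constant (here zero, since P is renormalized)
  land2 <- histogram_landscape(list(tr, tr), resolution = c(64, 80))
  d <- land2$U - land$U
  expect_lt(diff(range(d[is.finite(d)])), 1e-12)
  expect_error(histogram_landscape(list()), "empty")
})

test_that("basin probabilities sum to one, favour B and S, and agree with
           direct occupancy estimates", {
  p <- ref_params()
  fps <- find_fixed_points(p)
  land <- solve_stationary_fpe(p, D = 0.02, resolution = c(64, 80))
  bp <- basin_probabilities(land, fps)
  expect_equal(sum(bp), 1, tolerance = 1e-12)
  expect_lt(bp["L"], min(bp["B"], bp["S"]))  # rare luminal basin
  occ <- estimate_occupancy(p, D = 0.02, fps, t_end = 1500, burn_in = 150,
                            n_replicates = 6, seed = 31)
  for (ph in c("L", "B", "S"))
    expect_lt(abs(bp[ph] - occ$probability[ph]),
              2 * occ$se[ph] + 0.02)  # 2 SE plus FPE discretization slack
  expect_error(
    basin_probabilities(land, transform(fps, x1 = x1 + 10)),
    "outside")
})
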