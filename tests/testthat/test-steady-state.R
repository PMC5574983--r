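test_that("the reference regime has three stable states and two saddles", {
  fps <- find_fixed_points(ref_params())
  expect_equal(sum(fps$stability == "stable"), 3)
  expect_equal(sum(fps$stability == "saddle"), 2)
  st <- stable_points(fps)
  expect_equal(st$phenotype, c("L", "B", "S"))  # sorted by (x1, x2)
  got <- as.matrix(st[, c("x1", "x2")])
  want <- rbind(ref$L, ref$B, ref$S)
  expect_lt(max(abs(got - want)), 1e-6)
  sad <- fps[fps$stability == "saddle", c("x1", "x2")]
  expect_lt(max(abs(as.matrix(sad) - rbind(ref$U2, ref$u1))), 1e-6)
  # B and S share the same x1 coordinate exactly (skew-product structure)
  expect_lt(abs(st$x1[2] - st$x1[3]), 1e-9)
})

test_that("fixed points are invariant under seed doubling and confirmed by
           forward integration", {
  skip_if_not_installed("deSolve")
  p <- ref_params()
  a <- find_fixed_points(p, seeds_per_axis = 400)
  b <- find_fixed_points(p, seeds_per_axis = 800)
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a$x1 - b$x1)), 1e-7)
  expect_lt(max(abs(a$x2 - b$x2)), 1e-7)
  # perturbed trajectories relax back onto each stable point
  rhs <- function(t, y, parms) list(drift(pmax(y, 0), p))
  for (i in which(a$stability == "stable")) {
    y0 <- c(a$x1[i], a$x2[i]) + 1e-3
    out <- deSolve::ode(y0, times = c(0, 50), func = rhs, parms = NULL)
    expect_lt(max(abs(out[2, 2:3] - c(a$x1[i], a$x2[i]))), 1e-4)
  }
})

test_that("stable and saddle points alternate along x2 at fixed x1", {
  fps <- find_fixed_points(ref_params())
  hi <- fps[abs(fps$x1 - ref$x1_high) < 1e-6, ]
  hi <- hi[order(hi$x2), ]
  expect_equal(hi$stability, c("stable", "saddle", "stable"))
})

test_that("phenotype labels follow the theta-threshold rule", {
  p <- ref_params()
  expect_equal(classify_phenotype(0.94, 0.07, p), "B")
  expect_equal(classify_phenotype(0.94, 0.82, p), "S")
  expect_equal(classify_phenotype(0.24, 1.79, p), "L")
  expect_equal(classify_phenotype(0.3, 0.2, p), "other")
})

test_that("phase diagram recovers the mono-, bi- and tri-stable regions", {
  p <- ref_params()
  pm <- phase_diagram(p,
                      list(name = "a1", values = c(0.3, 0.8, 0.95)),
                      list(name = "a2", values = c(0.8, 0.85)))
  expect_equal(pm$cell_label[2, 2], "LBS")  # a1 = 0.8, a2 = 0.85
  expect_equal(pm$cell_label[1, 1], "L")    # a1 = 0.3, a2 = 0.8
  expect_equal(pm$cell_label[3, 1], "B")    # a1 = 0.95, a2 = 0.8
  expect_equal(pm$n_stable[2, 2], 3L)
  expect_error(phase_diagram(p, list(name = "zz", values = 1:2),
                             list(name = "a2", values = 1:2)),
               "unknown parameter")
  expect_error(phase_diagram(p, list(name = "a1", values = c(1, 1)),
                             list(name = "a2", values = 1:2)),
               "strictly increasing")
})

test_that("bifurcation scan in a1 walks B -> LB -> LBS -> LS -> L", {
  p <- model_params(a1 = 0.8, a2 = 0.8)
  bif <- bifurcation_scan(p, "a1", seq(0.3, 0.95, length.out = 33))
  per_value <- unique(bif[, c("value", "region")])
  runs <- rle(per_value$region)
  expect_equal(runs$values, c("L", "LS", "LBS", "LB", "B"))
  counts <- tapply(bif$stability == "stable", bif$value, sum)
  expect_equal(rle(as.vector(counts))$values, c(1, 2, 3, 2, 1))
})

test_that("tristability exists at n = 4 but not at n = 2 and the bisection
           demands a straddling bracket", {
  p <- ref_params()
  grid <- seq(0.05, 2, length.out = 40)
  expect_true(phenoswitch:::has_tristability(p, grid, grid))
  p2 <- p; p2$n <- 2
  expect_false(phenoswitch:::has_tristability(p2, grid, grid))
  expect_error(critical_hill(p, grid_n = 40), "does not straddle")
})

test_that("the closed-form cusp matches a direct scan of the x1 subsystem", {
  nc <- critical_hill_cusp(b1 = 0.2, theta = 0.5)
  expect_equal(nc, 3.0194, tolerance = 1e-4)
  # just below the cusp the x1 equation is monostable for every a1 ...
  two_stable <- function(n) {
    p <- model_params(a1 = 1, a2 = 1, n = n)
    any(vapply(seq(0.3, 1.5, by = 0.002), function(a1) {
      p$a1 <- a1
      r <- phenoswitch:::bracket_roots(function(x)
        phenoswitch:::drift_x1(x, p), 0, 1.05 * (a1 + 0.2), 800, 1e-10)
      sum(p$a1 * phenoswitch:::hill_prime(r, 0.5, n) - 1 < 0) >= 2
    }, logical(1)))
  }
  expect_false(two_stable(nc - 0.05))
  # ... and just above it a bistable a1 window exists
  expect_true(two_stable(nc + 0.05))
})
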