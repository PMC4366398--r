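test_that("two-lesion concentrations follow the fixed-mean
           parameterisation", {
  expect_equal(build_two_lesion(0, v = 1e-3)$concentrations, c(50, 50))
  expect_equal(build_two_lesion(100, v = 1e-3)$concentrations, c(0, 100))
  expect_equal(build_two_lesion(50, v = 1e-3)$concentrations, c(25, 75))
  expect_error(build_two_lesion(150, v = 1e-3), "delta_d")
  sc <- build_two_lesion(100, v = 1e-4)
  expect_equal(sum(sc$census$count), 1e3 + 1e8)
  expect_true(all(sc$census$genotype == 0))
})

test_that("onion shells conserve cells and decay outward", {
  on <- build_onion(inv_tau_d = 1, M = 30)
  expect_equal(sum(on$census$count), 1e11)
  expect_true(all(diff(on$shells$drug) < 0))
  expect_true(all(diff(on$shells$beta) < 0))
  expect_equal(on$model$n_genotypes, 3L)
  # line topology: edge shells lose v/2, interior shells v
  out <- on$model$mig_out[on$model$classes$genotype == 0]
  expect_equal(out[1], 2e-4 / 2)
  expect_equal(out[15], 2e-4)

  # uniform-density limit: weights approach shell volumes
  w <- spatialresist:::shell_weights(5, 1, tau_c = 1e9, pow = 2)
  vol <- diff((0:5 / 5)^3)
  expect_equal(w, vol / sum(vol), tolerance = 1e-6)
})

test_that("onion escape goes from certain eradication to certain failure
           with drug heterogeneity", {
  e_lo <- escape_probability(build_onion(0.01)$model,
                             build_onion(0.01)$census)
  on_hi <- build_onion(2)
  e_hi <- escape_probability(on_hi$model, on_hi$census)
  expect_lt(e_lo, 0.05)
  expect_gt(e_hi, 0.95)
})

test_that("ring concentrations hit the requested heterogeneity and the
           degenerate cases coincide", {
  rg <- build_ring(sigma = 24.7, v = 0.01)
  D <- rg$concentrations
  expect_equal(mean(D), 50, tolerance = 1e-9)
  expect_equal(sqrt(mean((D - 50)^2)), 24.7, tolerance = 1e-6)
  expect_equal(rg$census$compartment, which.min(D) - 1L)

  flat <- build_ring(sigma = 0, v = 0.01)
  expect_equal(flat$concentrations, rep(50, 20))
  expect_error(build_ring(sigma = 500, v = 0.01), "maximum")

  # ring and global migration coincide for two compartments
  r2 <- build_ring(sigma = 10, v = 0.01, topology = "ring", M = 2,
                   n_genotypes = 2)
  g2 <- build_ring(sigma = 10, v = 0.01, topology = "global", M = 2,
                   n_genotypes = 2)
  expect_equal(r2$model$mig, g2$model$mig)
  expect_equal(r2$model$birth, g2$model$birth)
})

test_that("escape probability shows the sharp eradication-to-failure
           transition in drug heterogeneity", {
  tab <- scenario_sweep(seq(0, 100, by = 20),
                        function(dd) build_two_lesion(dd, v = 1e-3),
                        quantity = "escape")
  # eradication side: escape stays small (it even decreases slightly as
  # the big lesion receives more drug); failure side: near-certain escape
  expect_true(all(tab$value[tab$parameter <= 40] < 0.05))
  expect_true(all(tab$value[tab$parameter >= 60] > 0.95))
})

test_that("per-lesion relapse ordering follows lesion size", {
  sc <- build_two_lesion(delta_d = 100, v = 1e-4)
  t_l0 <- mean_time_to_resistance(sc$model, cell_census(0, 0, 1e3))
  t_l1 <- mean_time_to_resistance(sc$model, cell_census(0, 1, 1e8))
  expect_lt(t_l1, t_l0)  # the much bigger lesion seeds resistance sooner
  t_l1_small <- mean_time_to_resistance(sc$model, cell_census(0, 1, 100))
  expect_gt(t_l1_small, t_l0)  # shrinking it reverses the order
})

test_that("with a shallower resistance benefit the time to sufficient
           resistance jumps where two mutations become necessary", {
  # rho = 3.5: genotype 1 is supercritical in compartment 1 only while
  # D1 < 175 * sqrt(beta1/alpha1 - 1), i.e. delta_d below ~70.6
  p35 <- drug_response(50, 2, 3.5, 0.01)
  suff_time <- function(dd) {
    sc <- build_two_lesion(delta_d = dd, v = 1e-4, params = p35,
                           n_genotypes = 3)
    gr <- sc$model$birth - sc$model$death
    msk <- sc$model$classes$compartment == 1 & gr > 0 &
      sc$model$classes$genotype > 0
    mean_time_to_resistance(sc$model, sc$census, msk)
  }
  below <- suff_time(70)   # one mutation still sufficient
  above <- suff_time(75)   # two mutations required
  expect_gt(above, 1.5 * below)
})

test_that("sweeps reduce to direct calls on a single-point grid", {
  tab <- scenario_sweep(100, function(dd) build_two_lesion(dd, v = 1e-3),
                        quantity = "escape")
  sc <- build_two_lesion(100, v = 1e-3)
  expect_equal(tab$value, escape_probability(sc$model, sc$census))
  expect_named(tab, c("parameter", "value"))
})
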