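test_that("pure-death process: certain extinction, mean lifetime 1/d", {
  mod <- multitype_model(birth = 0, death = 0.5)
  sim <- simulate_branching(mod, census = 1, horizon = 100,
                            checkpoints = c(50, 100), n_reps = 4000,
                            seed = 2, mask = c(TRUE))
  expect_true(all(sim$final_counts == 0))
  # time of the single death event: exponential with mean 1/d = 2
  # (mask marks the initial cell, so first_resistance is 0; use counts)
  cm <- sim_counts(sim, 50)
  expect_equal(unname(colSums(cm)), 0)
})

test_that("single-cell extinction fraction matches q = d/b", {
  mod <- multitype_model(birth = 0.5, death = 0.4)
  sim <- simulate_branching(mod, census = 1, horizon = 150, n_reps = 1e4,
                            seed = 4, mask = c(TRUE), count_cap = 1e5)
  extinct <- mean(sim$final_counts[, 1] == 0 & !sim$truncated)
  se <- sqrt(0.8 * 0.2 / 1e4)
  expect_lt(abs(extinct - 0.8), 3 * se + 0.01)  # 0.01 covers t < Inf bias
})

test_that("ensembles are reproducible and order-independent by seed", {
  mod <- fig3_model()
  cen <- cell_census(0, 1, 1)
  s1 <- simulate_branching(mod, cen, horizon = 30, n_reps = 200, seed = 9)
  s2 <- simulate_branching(mod, cen, horizon = 30, n_reps = 200, seed = 9)
  expect_identical(s1$presence, s2$presence)
  expect_identical(s1$final_counts, s2$final_counts)
  # replicate streams are counter-derived: a larger ensemble reproduces
  # the smaller one as its prefix
  s3 <- simulate_branching(mod, cen, horizon = 30, n_reps = 300, seed = 9)
  expect_identical(s3$final_counts[1:200, ], s1$final_counts)
  # single replicate: aggregate equals the replicate
  s4 <- simulate_branching(mod, cen, horizon = 30, n_reps = 1, seed = 9)
  expect_equal(glance(s4)$p_no_resistance,
               1 - as.numeric(s4$presence[1, 1]))
})

test_that("short-horizon event probabilities match first-order rates", {
  mod <- multitype_model(birth = 0.3, death = 0.2)
  dt <- 0.05
  sim <- simulate_branching(mod, census = 1, horizon = dt, n_reps = 2e4,
                            seed = 6, mask = c(TRUE))
  frac_div <- mean(sim$final_counts[, 1] == 2)
  frac_death <- mean(sim$final_counts[, 1] == 0)
  expect_lt(abs(frac_div - 0.3 * dt), 3 * sqrt(0.3 * dt / 2e4) + 1e-3)
  expect_lt(abs(frac_death - 0.2 * dt), 3 * sqrt(0.2 * dt / 2e4) + 1e-3)
})

test_that("PGF no-resistance probabilities agree with the simulator across
           random small models", {
  set.seed(99)
  for (i in 1:10) {
    mod <- random_small_model()
    cen <- numeric(mod$n_classes); cen[1] <- 1
    pgf <- solve_pgf(mod, masked_point(mod), times = c(0, 25))$F[2, 1]
    sim <- simulate_branching(mod, cen, horizon = 25, n_reps = 1e4,
                              seed = i, count_cap = 1e5)
    gl <- glance(sim)
    expect_lt(abs(gl$p_no_resistance - pgf), 3 * gl$se + 3 / gl$n_reps)
  }
})

test_that("ensemble confidence intervals cover the PGF value", {
  land <- fig2a_landscape()
  mod <- build_pathway(land, "mutation_migration", u = 1e-4, v = 1e-3)
  mask <- resistant_mask(mod, classes = 3)
  pgf <- solve_pgf(mod, ifelse(mask, 0, 1), times = c(0, 50))$F[2, 1]
  cover <- 0
  for (e in 1:100) {
    sim <- simulate_branching(mod, c(1, 0, 0), horizon = 50, n_reps = 400,
                              seed = 1000 + e, mask = mask,
                              count_cap = 1e5)
    ci <- stats::binom.test(sum(sim$presence[, 1]), 400)$conf.int
    cover <- cover + (1 - pgf >= ci[1] && 1 - pgf <= ci[2])
  }
  expect_gte(cover, 93)
})

test_that("the simulated conditional no-resistance integral reproduces the
           analytic one on a scaled two-lesion scenario", {
  sc <- build_two_lesion(delta_d = 100, v = 1e-3, n0 = 20, n1 = 1e3,
                         u = 1e-2)
  cps <- seq(5, 400, by = 5)
  tt <- c(0, cps)
  trapz <- function(ps) sum(diff(tt) * (utils::head(ps, -1) +
                                          utils::tail(ps, -1)) / 2)
  tr <- solve_pgf(sc$model, masked_point(sc$model), times = tt)
  N <- c(20, 1e3, 0, 0)
  Fp <- apply(tr$F, 1, function(f) prod(f^N))
  ps_pgf <- (Fp - Fp[length(Fp)]) / (1 - Fp[length(Fp)])
  T_pgf <- trapz(ps_pgf)

  sim <- simulate_branching(sc$model, sc$census, horizon = 400,
                            checkpoints = cps, n_reps = 1500, seed = 5,
                            count_cap = 1e5)
  P <- 1 - sim$presence
  emp_T <- function(idx) {
    Fh <- colMeans(P[idx, , drop = FALSE])
    trapz(c(1, (Fh - Fh[length(Fh)]) / (1 - Fh[length(Fh)])))
  }
  That <- emp_T(seq_len(nrow(P)))
  set.seed(17)
  boot <- replicate(100, emp_T(sample.int(nrow(P), replace = TRUE)))
  expect_lt(abs(That - T_pgf), 3 * stats::sd(boot))
})

test_that("below the sanctuary transition the no-resistance probability is
           non-monotone in time (transient resistant clones), and the
           simulator reproduces it", {
  # scaled DeltaD = 0 lesions: resistant clones arise early from the large
  # decaying lesion, mostly die out, so P(no resistance at t) dips below
  # its limit before recovering
  sc <- build_two_lesion(delta_d = 0, v = 1e-3, n0 = 10, n1 = 2e3,
                         u = 5e-5)
  mask <- resistant_mask(sc$model)
  N <- spatialresist:::census_vector(sc$model, sc$census)
  tr <- solve_pgf(sc$model, masked_point(sc$model), times = c(0, 10, 80))
  Fp <- apply(tr$F, 1, function(f) prod(f^N))
  Ginf <- spatialresist:::limiting_deficit(sc$model, as.numeric(mask))
  F_inf <- exp(sum(N * log1p(-Ginf)))
  expect_lt(Fp[2], F_inf - 0.002)   # the dip
  expect_gt(Fp[3], Fp[2])           # and the recovery

  sim <- simulate_branching(sc$model, sc$census, horizon = 80,
                            checkpoints = c(10, 80), n_reps = 3000,
                            seed = 3, count_cap = 2e4)
  gl <- glance(sim)
  expect_lt(abs(gl$p_no_resistance[1] - Fp[2]), 3 * gl$se[1] + 1e-3)
  expect_gt(gl$p_no_resistance[2], gl$p_no_resistance[1])
})
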