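test_that("single-type extinction trajectory matches the closed form
           uniformly", {
  mod <- multitype_model(birth = 0.5, death = 0.4)
  tg <- seq(0, 100, by = 0.5)
  tr <- solve_pgf(mod, eval_point = 0, times = tg)
  expect_lt(max(abs(tr$F[, 1] - bd_extinction_cdf(tg, 0.5, 0.4))), 1e-6)
  expect_equal(unname(limiting_pgf(mod, 0))[1], 0.8, tolerance = 1e-10)
})

test_that("the PGF stays in [0,1] at real points and F(1;t) = 1", {
  set.seed(11)
  for (i in 1:5) {
    mod <- random_small_model()
    x <- round(runif(mod$n_classes), 2)
    tr <- solve_pgf(mod, x, times = seq(0, 60, by = 2))
    expect_true(all(tr$F >= -1e-10 & tr$F <= 1 + 1e-10))
    one <- solve_pgf(mod, rep(1, mod$n_classes), times = c(0, 10, 40))
    expect_equal(max(abs(one$F - 1)), 0, tolerance = 1e-9)
  }
})

test_that("limiting PGF: flow limit equals the polished fixed point and
           the all-zeros point matches the resistant-masked point", {
  mod <- fig3_model()
  lim0 <- limiting_pgf(mod, rep(0, 4))
  limm <- limiting_pgf(mod, masked_point(mod))
  # surviving lineages almost surely generate resistance when u > 0
  expect_lt(max(abs(lim0 - limm)), 1e-8)
  # it is a genuine fixed point of the backward equations
  expect_lt(max(abs(pgf_rhs(mod, as.numeric(limm)))), 1e-12)
})

test_that("escape probability: trivial zero, lineage independence,
           log-domain composition at 1e11 cells", {
  # u = 0: resistance can never arise from a sensitive cell
  b <- c("00" = 0.5, "01" = 0.39, "10" = 0.48, "11" = 0.45)
  d <- c("00" = 0.4, "01" = 0.4, "10" = 0.4, "11" = 0.4)
  mod0 <- minimal_model(b, d, u = 0, v = 1e-3)
  expect_equal(escape_probability(mod0, cell_census(0, 0, 1)), 0)

  # census composition: A union B composes multiplicatively
  mod <- fig3_model()
  cenA <- cell_census(0, 0, 7)
  cenB <- cell_census(0, 1, 12)
  cenAB <- cell_census(c(0, 0), c(0, 1), c(7, 12))
  pA <- escape_probability(mod, cenA)
  pB <- escape_probability(mod, cenB)
  expect_equal(escape_probability(mod, cenAB), 1 - (1 - pA) * (1 - pB),
               tolerance = 1e-12)

  # by-compartment decomposition is the per-origin restriction
  tab <- escape_probability(mod, cenAB, by_compartment = TRUE)
  expect_equal(tab$escape[tab$compartment == 0][1], pA)
  expect_equal(tab$escape[is.na(tab$compartment)],
               escape_probability(mod, cenAB))

  # 1e11 cells with per-cell escape of order u: no underflow, sane value
  huge <- escape_probability(mod, cell_census(0, 0, 1e11))
  expect_true(huge > 0 && huge <= 1)
})

test_that("relapse curve starts at 1, ends at 0, and is a probability in
           the supercritical regime", {
  sc <- build_two_lesion(delta_d = 100, v = 1e-3)
  rc <- relapse_curve(sc$model, sc$census)
  expect_equal(rc$curve$ps[1], 1)
  expect_lt(abs(utils::tail(rc$curve$ps, 1)), 1e-4)
  expect_true(all(rc$curve$ps >= -1e-10 & rc$curve$ps <= 1 + 1e-10))
  # non-increasing up to the small transient-clone ripple (resistant cells
  # from the decaying large lesion that die out again)
  expect_true(all(diff(rc$curve$ps) <= 1e-4))
  expect_gt(rc$mean_time, 0)
  # single-cell census with no escape route errors, not NaN
  b <- c("00" = 0.5, "01" = 0.39, "10" = 0.48, "11" = 0.45)
  d <- c("00" = 0.4, "01" = 0.4, "10" = 0.4, "11" = 0.4)
  mod0 <- minimal_model(b, d, u = 0, v = 0)
  expect_error(relapse_curve(mod0, cell_census(0, 0, 1)), "null")
})

test_that("mean time to resistance responds to mutation supply and census
           size", {
  land_b <- c("00" = 0.5, "01" = 0.1, "10" = 0.48, "11" = 0.427)
  land_d <- c("00" = 0.04, "01" = 0.4, "10" = 0.04, "11" = 0.4)
  mk <- function(u) minimal_model(land_b, land_d, u = u, v = 1e-3)
  cen <- cell_census(0, 0, 1)
  t_small_u <- mean_time_to_resistance(mk(1e-4), cen)
  t_large_u <- mean_time_to_resistance(mk(0.1), cen)
  expect_lt(t_large_u, t_small_u)

  mod <- mk(1e-4)
  t1 <- mean_time_to_resistance(mod, cell_census(0, 0, 10))
  t2 <- mean_time_to_resistance(mod, cell_census(0, 0, 20))
  expect_lt(t2, t1)

  # refining the reporting grid does not change the integral
  rc <- relapse_curve(mod, cen)
  expect_equal(mean_time_to_resistance(mod, cen), rc$mean_time,
               tolerance = 1e-6)
})

test_that("masks and censuses validate", {
  mod <- fig3_model()
  expect_equal(which(resistant_mask(mod)), 3:4)
  expect_equal(which(resistant_mask(mod, compartments = 1)), 4L)
  expect_error(resistant_mask(mod, min_genotype = 5), "empty")
  expect_error(census_vec <- spatialresist:::census_vector(
    mod, cell_census(3, 0, 1)), "absent")
  expect_error(escape_probability(mod, cell_census(0, 0, 0)),
               "at least one cell")
})

test_that("tidiers return well-formed tibbles", {
  mod <- fig3_model()
  tr <- solve_pgf(mod, masked_point(mod), times = c(0, 10, 20))
  td <- tidy(tr)
  expect_named(td, c("time", "class", "genotype", "compartment", "F"))
  expect_equal(nrow(td), 3 * 4)
  sc <- build_two_lesion(delta_d = 100, v = 1e-3)
  rc <- relapse_curve(sc$model, sc$census)
  expect_named(glance(rc), c("escape_prob", "mean_time_days", "ps_infinity"))
  expect_s3_class(autoplot(rc), "ggplot")
})
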