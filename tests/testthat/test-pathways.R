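test_that("landscape constructor derives costs and rejects broken
           landscapes", {
  land <- fig2a_landscape()
  expect_equal(land$s, 1 - 0.48 / 0.5)
  expect_equal(land$delta, 1 - 0.39 / 0.5)
  expect_error(pathway_landscape(0.3, 0.4, 0.48, 0.4, 0.39, 0.4, 0.45, 0.4),
               "supercritical")
  expect_error(pathway_landscape(0.5, 0.4, 0.48, 0.4, 0.39, 0.4, 0.35, 0.4),
               "supercritical")
  expect_warning(pathway_landscape(0.5, 0.4, 0.55, 0.4, 0.39, 0.4, 0.45,
                                   0.4, warn = TRUE), "canonical")
})

test_that("pathway chains have exactly the stated one-directional flows", {
  land <- fig2a_landscape()
  mm <- build_pathway(land, "mutation_migration", u = 1e-4, v = 1e-3)
  expect_equal(mm$birth, c(0.5, 0.48, 0.45))
  expect_equal(mm$mut_rate, c(0.5 * 1e-4, 0, 0))
  expect_equal(mm$mut_target[1], 2L)
  expect_equal(mm$mig[2, 3], 1e-3)
  expect_equal(sum(mm$mig), 1e-3)

  gm <- build_pathway(land, "migration_mutation", u = 1e-4, v = 1e-3)
  expect_equal(gm$birth, c(0.5, 0.39, 0.45))
  expect_equal(gm$mut_rate, c(0, 0.39 * 1e-4, 0))
  expect_equal(gm$mig[1, 2], 1e-3)

  # broken chains: v = 0 blocks migration-mutation, u = 0 blocks both
  gm0 <- build_pathway(land, "migration_mutation", u = 1e-4, v = 0)
  lim <- limiting_pgf(gm0, c(1, 1, 0))
  expect_equal(unname(lim[1]), 1, tolerance = 1e-12)
  for (which in c("mutation_migration", "migration_mutation")) {
    m0 <- build_pathway(land, which, u = 0, v = 1e-3)
    expect_equal(escape_probability(m0, c(1, 0, 0),
                                    resistant_mask(m0, classes = 3)), 0)
  }
})

test_that("dominance conditions: arithmetic, neutral limit, and
           equivalence under equal death rates", {
  # Fig 2 parameterisation: s = 0.04, delta = 0.1 -> mutation-migration
  land <- pathway_landscape(0.5, 0.4, 0.96 * 0.5, 0.4, 0.9 * 0.5, 0.4,
                            0.45, 0.4)
  expect_true(pathway_dominance_general(land))
  expect_true(pathway_dominance_simplified(0.04, 0.1))
  expect_equal(0.04 / 1.04, 0.0384615384615, tolerance = 1e-10)
  expect_false(pathway_dominance_simplified(0.04, 0.03))

  # neutral or advantageous resistance: always mutation-migration
  expect_true(pathway_dominance_simplified(0, 1e-6))
  land_neutral <- pathway_landscape(0.5, 0.4, 0.5, 0.4, 0.45, 0.4,
                                    0.45, 0.4)
  expect_true(pathway_dominance_general(land_neutral))

  # outside the validity domain: drug compartment as fit as the sanctuary
  land_bad <- pathway_landscape(0.5, 0.4, 0.48, 0.4, 0.5, 0.4, 0.55, 0.4)
  expect_error(pathway_dominance_general(land_bad), "validity")

  # property: general == simplified on a random grid under equal deaths
  set.seed(21)
  for (i in 1:2000) {
    s <- runif(1, 0.001, 0.5)
    delta <- runif(1, 0.001, 0.5)
    land_i <- pathway_landscape(b00 = 0.5, d00 = 0.1,
                                b10 = (1 - s) * 0.5, d10 = 0.1,
                                b01 = (1 - delta) * 0.5, d01 = 0.1,
                                b11 = 0.45, d11 = 0.1)
    expect_identical(pathway_dominance_general(land_i),
                     pathway_dominance_simplified(s, delta))
  }
})

test_that("conditional mean times order as the landscape dictates", {
  land <- fig2a_landscape()  # s = 0.04, delta = 0.22 > s/(1+s)
  tt <- compare_pathway_times(land, u = 1e-4, v = 1e-3)
  t_mm <- tt$mean_time_days[tt$pathway == "mutation_migration"]
  t_gm <- tt$mean_time_days[tt$pathway == "migration_mutation"]
  expect_lt(t_mm, t_gm)

  # delta below the threshold: ordering reverses
  land_lo <- pathway_landscape(b00 = 0.5, d00 = 0.4, b10 = 0.48, d10 = 0.4,
                               b01 = (1 - 0.01) * 0.5, d01 = 0.4,
                               b11 = 0.45, d11 = 0.4)
  tt_lo <- compare_pathway_times(land_lo, u = 1e-4, v = 1e-4)
  expect_gt(tt_lo$mean_time_days[tt_lo$pathway == "mutation_migration"],
            tt_lo$mean_time_days[tt_lo$pathway == "migration_mutation"])
})

test_that("slowing the sanctuary delays both pathways without reordering", {
  land <- pathway_landscape(b00 = 0.5, d00 = 0.4, b10 = 0.99 * 0.5,
                            d10 = 0.4, b01 = 0.35, d01 = 0.4,
                            b11 = 0.45, d11 = 0.4)  # s = 0.01, b01 = 0.35
  tt1 <- compare_pathway_times(land, u = 1e-4, v = 1e-3)
  for (phi in c(0.8, 0.5)) {
    ttp <- compare_pathway_times(scale_sanctuary(land, phi),
                                 u = 1e-4, v = 1e-3)
    expect_true(all(ttp$mean_time_days > tt1$mean_time_days))
    expect_equal(order(ttp$mean_time_days), order(tt1$mean_time_days))
  }
})
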