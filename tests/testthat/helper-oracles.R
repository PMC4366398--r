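# Independent oracles and shared fixtures, built in code.

# Literal transcription of the four backward equations of the minimal
# two-genotype, two-compartment model, kept deliberately separate from the
# package's generic assembly.  F and the return value are in the order
# (F00, F01, F10, F11).
minimal_backward_rhs <- function(F, b, d, u, v) {
  F00 <- F[1]; F01 <- F[2]; F10 <- F[3]; F11 <- F[4]
  unname(c(
    d["00"] + b["00"] * (1 - u) * F00^2 + b["00"] * u * F00 * F10 +
      v * F01 - (d["00"] + b["00"] + v) * F00,
    d["01"] + b["01"] * (1 - u) * F01^2 + b["01"] * u * F01 * F11 +
      v * F00 - (d["01"] + b["01"] + v) * F01,
    d["10"] + b["10"] * F10^2 + v * F11 - (d["10"] + b["10"] + v) * F10,
    d["11"] + b["11"] * F11^2 + v * F10 - (d["11"] + b["11"] + v) * F11
  ))
}

# Closed-form extinction CDF of a single-type linear birth-death process
# started from one cell: P(extinct by t).
bd_extinction_cdf <- function(t, b, d) {
  r <- b - d
  d * (exp(r * t) - 1) / (b * exp(r * t) - d)
}

# Minimal model with explicit rates (no Hill function), e.g. the
# two-compartment model used for the joint-distribution panels.
minimal_model <- function(b, d, u, v) {
  rt <- tibble::tibble(
    genotype = c(0L, 0L, 1L, 1L),
    compartment = c(0L, 1L, 0L, 1L),
    birth = c(b["00"], b["01"], b["10"], b["11"]),
    death = c(d["00"], d["01"], d["10"], d["11"]),
    growth = 0
  )
  rt$growth <- rt$birth - rt$death
  branching_model(rt, u = u, v = v, topology = "pairwise")
}

fig3_rates_b <- c("00" = 0.1, "01" = 0.38, "10" = 0.099, "11" = 0.5)
fig3_rates_d <- c("00" = 0.05, "01" = 0.4, "10" = 0.05, "11" = 0.4)
fig3_model <- function() minimal_model(fig3_rates_b, fig3_rates_d,
                                       u = 1e-4, v = 1e-2)

fig2a_landscape <- function() {
  pathway_landscape(b00 = 0.5, d00 = 0.4, b10 = 0.48, d10 = 0.4,
                    b01 = 0.39, d01 = 0.4, b11 = 0.45, d11 = 0.4)
}

# Random small genotype-by-compartment model for property tests.
random_small_model <- function() {
  n <- sample(2:3, 1)
  M <- sample(2:3, 1)
  grid <- expand.grid(genotype = 0:(n - 1), compartment = 0:(M - 1))
  birth <- runif(n * M, 0.05, 0.5)
  death <- runif(n * M, 0.05, 0.5)
  rt <- tibble::tibble(genotype = grid$genotype,
                       compartment = grid$compartment,
                       birth = birth, death = death,
                       growth = birth - death)
  u <- 10^runif(1, -3, -1)
  v <- 10^runif(1, -3, -1)
  topo <- if (M == 2) "pairwise" else sample(c("ring", "global"), 1)
  branching_model(rt, u = u, v = v, topology = topo)
}

masked_point <- function(model, mask = resistant_mask(model)) {
  ifelse(mask, 0, 1)
}
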