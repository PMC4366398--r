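#' Two-lesion metastasis treatment scenario
#'
#' Two metastatic lesions of different sizes and growth rates under a
#' total drug budget: concentrations are parameterised by their fixed mean
#' `d_bar` and difference `delta_d`, so `D0 = d_bar - delta_d / 2` (the
#' poorly penetrated lesion) and `D1 = d_bar + delta_d / 2`.  One point
#' mutation confers strong resistance by default.
#'
#' @param delta_d Concentration difference `D1 - D0`, in `[0, 2 * d_bar]`.
#' @param v Migration rate between the lesions (per cell per day).
#' @param d_bar Mean drug concentration (held fixed as `delta_d` varies).
#' @param n0,n1 Initial sensitive cell counts in lesions 0 and 1.
#' @param beta,alpha Length-2 vectors of drug-free division and death rates
#'   of the two lesions.
#' @param params A [drug_response()] object.
#' @param u Mutation probability per division.
#' @param n_genotypes Number of genotypes (2 = sensitive/resistant).
#' @return A list with elements `model` (a [branching_model()]), `census`
#'   (all-sensitive [cell_census()]) and `concentrations`.
#' @examples
#' sc <- build_two_lesion(delta_d = 100, v = 1e-4)
#' sc$concentrations
#' @export
build_two_lesion <- function(delta_d, v, d_bar = 50,
                             n0 = 1e3, n1 = 1e8,
                             beta = c(0.05, 0.5), alpha = c(0.04, 0.4),
                             params = drug_response(ic50 = 50, m = 2,
                                                    rho = 5, s = 0.01),
                             u = 1e-9, n_genotypes = 2) {
  if (delta_d < 0 || delta_d > 2 * d_bar)
    stop("`delta_d` must lie in [0, 2 * d_bar] so both concentrations ",
         "are non-negative", call. = FALSE)
  D <- c(d_bar - delta_d / 2, d_bar + delta_d / 2)
  comps <- tibble::tibble(beta = beta, alpha = alpha, drug = D)
  rt <- build_rate_table(comps, n_genotypes = n_genotypes, params = params)
  model <- branching_model(rt, u = u, v = v, topology = "pairwise")
  census <- cell_census(genotype = c(0, 0), compartment = c(0, 1),
                        count = c(n0, n1))
  list(model = model, census = census, concentrations = D)
}

# shell weights ~ integral of x^pow * exp(-x / tau_c) over each shell
shell_weights <- function(M, R, tau_c, pow) {
  edges <- seq(0, R, length.out = M + 1)
  f <- function(x) x^pow * exp(-x / tau_c)
  w <- vapply(seq_len(M), function(k) {
    stats::integrate(f, edges[k], edges[k + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  w / sum(w)
}

# round fractional counts to integers preserving the exact total
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  fl
}

#' Onion solid-tumor scenario
#'
#' A solid tumor discretised into `M` concentric shells of equal radial
#' width around a central blood vessel.  Proliferation and turnover decay
#' with distance `x` from the vessel, `beta(x) = b0 exp(-x / tau_g)` and
#' `alpha(x) = d0 exp(-x / tau_g)`; the drug decays as
#' `D(x) = D0 exp(-x / tau_D)`, so `1 / tau_D` measures the spatial drug
#' heterogeneity (0 = perfect penetration).  Cell density decays as
#' `exp(-x / tau_c)`; shell populations are the density integrated over the
#' shell volume (spherical `x^2` Jacobian by default, cylindrical `x`
#' optionally), rounded by largest remainder so they sum exactly to `N`.
#' Rates and drug are evaluated at shell midpoints.  Cells migrate to the
#' two adjacent shells at rate `v/2` each (the innermost and outermost
#' shell have a single neighbour; see `edge_rule` of [branching_model()]).
#'
#' @param inv_tau_d Spatial drug heterogeneity `1 / tau_D` (per cm).
#' @param v Migration rate (per cell per day).
#' @param M Number of shells.
#' @param n_genotypes Number of genotypes (3 = two point mutations needed
#'   for full resistance).
#' @param N Total tumor cell count.
#' @param diameter Tumor diameter in cm.
#' @param tau_g,tau_c Decay lengths (cm) of proliferation and cell density.
#' @param D0 Drug concentration at the vessel.
#' @param b0,d0 Birth and death rates at the vessel (per cell per day).
#' @param params A [drug_response()] object.
#' @param u Mutation probability per division.
#' @param weighting `"spherical"` (default) or `"cylindrical"` shell
#'   volume element.
#' @param edge_rule Edge-shell migration rule, see [branching_model()].
#' @return A list with `model`, `census` (all-sensitive, one row per
#'   shell) and a `shells` tibble (midpoints, rates, drug, populations).
#' @export
build_onion <- function(inv_tau_d, v = 2e-4, M = 30, n_genotypes = 3,
                        N = 1e11, diameter = 4.6, tau_g = 1, tau_c = 1,
                        D0 = 500, b0 = 0.5, d0 = 0.4,
                        params = drug_response(ic50 = 50, m = 2, rho = 5,
                                               s = 0.01),
                        u = 1e-9,
                        weighting = c("spherical", "cylindrical"),
                        edge_rule = c("half", "full")) {
  weighting <- match.arg(weighting)
  edge_rule <- match.arg(edge_rule)
  stopifnot(M >= 2, n_genotypes >= 2, inv_tau_d >= 0, N >= 1)
  R <- diameter / 2
  x <- (seq_len(M) - 0.5) * R / M
  comps <- tibble::tibble(beta = b0 * exp(-x / tau_g),
                          alpha = d0 * exp(-x / tau_g),
                          drug = D0 * exp(-x * inv_tau_d))
  rt <- build_rate_table(comps, n_genotypes = n_genotypes, params = params)
  model <- branching_model(rt, u = u, v = v, topology = "line",
                           edge_rule = edge_rule)
  w <- shell_weights(M, R, tau_c,
                     pow = if (weighting == "spherical") 2 else 1)
  pop <- largest_remainder(N * w, N)
  if (any(pop < 0)) stop("negative shell population after rounding",
                         call. = FALSE)
  shells <- dplyr::mutate(comps, midpoint = x, weight = w, cells = pop,
                          .before = 1)
  census <- cell_census(genotype = 0, compartment = seq_len(M) - 1,
                        count = pop)
  list(model = model, census = census, shells = shells)
}

#' Multi-compartment ring / fully connected scenario
#'
#' `M` compartments with identical drug-free rates and a spatially
#' heterogeneous drug profile: a Gaussian bump centred on the middle
#' compartment (in ring distance), rescaled so the across-compartment mean
#' concentration is `d_bar` and the population standard deviation of the
#' concentration values equals `sigma` — the measure of spatial
#' heterogeneity, with `sigma = 0` the homogeneous limit (all compartments
#' at `d_bar`) and the upper bound `d_bar * sqrt(M - 1)` the
#' single-compartment spike.  The bump width that realises the requested
#' `sigma` is found by root solving.  Migration is either `"ring"`
#' (nearest neighbours, `v/2` each) or `"global"` (any other compartment,
#' `v/(M-1)` each).
#'
#' @param sigma Standard deviation of the concentrations over compartments
#'   (same units as `d_bar`).
#' @param v Migration rate.
#' @param topology `"ring"` or `"global"`.
#' @param M Number of compartments.
#' @param n_genotypes Number of genotypes.
#' @param d_bar Mean drug concentration over compartments.
#' @param b0,d0 Drug-free division and death rates (all compartments).
#' @param params A [drug_response()] object.
#' @param u Mutation probability per division.
#' @param start_compartment 0-based compartment of the single founding
#'   sensitive cell; defaults to the lowest-concentration compartment.
#' @return A list with `model`, `census` (one sensitive cell) and
#'   `concentrations`.
#' @export
build_ring <- function(sigma, v, topology = c("ring", "global"), M = 20,
                       n_genotypes = 5, d_bar = 50, b0 = 0.2, d0 = 0.1,
                       params = drug_response(ic50 = 100, m = 2, rho = 1.1,
                                              s = 0.01),
                       u = 1e-4, start_compartment = NULL) {
  topology <- match.arg(topology)
  stopifnot(sigma >= 0, M >= 2)
  j <- seq_len(M) - 1
  centre <- (M - 1) / 2
  dist <- pmin(abs(j - centre), M - abs(j - centre))
  dist <- dist - min(dist)  # peak exactly on the central compartment(s)
  profile <- function(w) {
    g <- exp(-dist^2 / (2 * w^2))
    d_bar * g / mean(g)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  if (sigma == 0) {
    D <- rep(d_bar, M)
  } else if (M == 2) {
    # both compartments are equidistant from the centre; the two-point
    # profile with the requested spread is d_bar +/- sigma
    if (sigma > d_bar)
      stop("`sigma` exceeds the maximum concentration spread d_bar ",
           "attainable with two non-negative concentrations", call. = FALSE)
    D <- c(d_bar + sigma, d_bar - sigma)
  } else {
    if (sigma >= d_bar * sqrt(M - 1))
      stop("`sigma` exceeds the maximum concentration spread ",
           "d_bar * sqrt(M - 1) attainable with non-negative ",
           "concentrations", call. = FALSE)
    w <- stats::uniroot(function(lw) pop_sd(profile(exp(lw))) - sigma,
                        lower = log(1e-3), upper = log(1e3),
                        tol = 1e-12)$root
    D <- profile(exp(w))
  }
  if (any(D < 0)) {
    warning("negative rescaled concentrations clipped at zero",
            call. = FALSE)
    D <- pmax(D, 0)
  }
  comps <- tibble::tibble(beta = b0, alpha = d0, drug = D)
  rt <- build_rate_table(comps, n_genotypes = n_genotypes, params = params)
  top <- if (M == 2 && topology == "ring") "pairwise" else topology
  model <- branching_model(rt, u = u, v = v, topology = top)
  if (is.null(start_compartment)) start_compartment <- j[which.min(D)]
  census <- cell_census(genotype = 0, compartment = start_compartment,
                        count = 1)
  list(model = model, census = census, concentrations = D)
}

#' Sweep a scenario parameter and collect escape or mean time
#'
#' Maps a builder function over a parameter grid, computing the requested
#' quantity for each resulting `(model, census)` pair.  Deterministic given
#' the configuration (no randomness is involved).
#'
#' @param grid Numeric vector of parameter values.
#' @param builder A function of one numeric argument returning a list with
#'   elements `model` and `census`, e.g.
#'   `function(dd) build_two_lesion(delta_d = dd, v = 1e-3)`.
#' @param quantity `"escape"` (escape probability) or `"mean_time"`
#'   (conditional mean time to resistance, days).
#' @param mask Optional resistant mask (defaults to each model's top
#'   genotype).
#' @param ... Passed to [escape_probability()] / [mean_time_to_resistance()].
#' @return A tibble with columns `parameter` and `value`.
#' @examples
#' \donttest{
#' scenario_sweep(c(0, 50, 100),
#'                function(dd) build_two_lesion(delta_d = dd, v = 1e-3),
#'                quantity = "escape")
#' }
#' @export
scenario_sweep <- function(grid, builder,
                           quantity = c("escape", "mean_time"),
                           mask = NULL, ...) {
  quantity <- match.arg(quantity)
  stopifnot(length(grid) >= 1)
  vals <- purrr::map_dbl(grid, function(p) {
    sc <- builder(p)
    msk <- if (is.null(mask)) resistant_mask(sc$model) else mask
    if (quantity == "escape") {
      escape_probability(sc$model, sc$census, msk, ...)
    } else {
      mean_time_to_resistance(sc$model, sc$census, msk, ...)
    }
  })
  tibble::tibble(parameter = grid, value = vals)
}
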