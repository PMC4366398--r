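#' Two-compartment fitness landscape for the pathway analysis
#'
#' Rates of the four cell classes of the minimal sanctuary model: sensitive
#' (`s`) and resistant (`r`) cells in the sanctuary compartment 0 and the
#' drug-containing compartment 1.  The canonical rugged landscape has
#' supercritical sensitive and resistant cells in the sanctuary
#' (`b00 > d00`, `b10 > d10`, with a cost of resistance `b10 < b00`) and a
#' subcritical sensitive / supercritical resistant pattern under drug
#' (`b01 < d01`, `b11 > d11`, `b11 > b01`).
#'
#' Only the conditions the pathway machinery genuinely needs are enforced
#' as errors (`b00 > d00`: the sanctuary must sustain growth; `b11 > d11`:
#' established resistance in the drug compartment must be possible).
#' Deviations from the remaining canonical pattern are allowed — parameter
#' sweeps such as the drug-efficacy scan cross them — and flagged with a
#' warning only when `warn = TRUE`.
#'
#' @param b00,d00 Sensitive birth/death rates in the sanctuary.
#' @param b10,d10 Resistant rates in the sanctuary.
#' @param b01,d01 Sensitive rates in the drug compartment.
#' @param b11,d11 Resistant rates in the drug compartment.
#' @param warn Warn when the canonical rugged pattern is violated.
#' @return A `pathway_landscape` object with derived fields
#'   `s = 1 - b10/b00` (cost of resistance) and `delta = 1 - b01/b00`
#'   (drug efficacy of growth inhibition of sensitive cells).
#' @examples
#' pathway_landscape(b00 = 0.5, d00 = 0.4, b10 = 0.48, d10 = 0.4,
#'                   b01 = 0.39, d01 = 0.4, b11 = 0.45, d11 = 0.4)
#' @export
pathway_landscape <- function(b00, d00, b10, d10, b01, d01, b11, d11,
                              warn = FALSE) {
  rates <- c(b00, d00, b10, d10, b01, d01, b11, d11)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all landscape rates must be finite and non-negative", call. = FALSE)
  if (b00 <= d00)
    stop("sanctuary sensitive cells must be supercritical (b00 > d00)",
         call. = FALSE)
  if (b11 <= d11)
    stop("resistant cells in the drug compartment must be supercritical ",
         "(b11 > d11)", call. = FALSE)
  if (warn && (b10 >= b00 || b01 >= d01 || b11 <= b01 || b10 <= d10))
    warning("landscape deviates from the canonical rugged pattern ",
            "(b10 < b00, b10 > d10, b01 < d01, b11 > b01)", call. = FALSE)
  structure(list(b00 = b00, d00 = d00, b10 = b10, d10 = d10,
                 b01 = b01, d01 = d01, b11 = b11, d11 = d11,
                 s = 1 - b10 / b00, delta = 1 - b01 / b00),
            class = "pathway_landscape")
}

#' @export
print.pathway_landscape <- function(x, ...) {
  cat("<pathway_landscape>\n",
      " sanctuary:  sensitive", x$b00, "/", x$d00,
      "  resistant", x$b10, "/", x$d10, "\n",
      " drug comp:  sensitive", x$b01, "/", x$d01,
      "  resistant", x$b11, "/", x$d11, "\n",
      " s =", signif(x$s, 4), "  delta =", signif(x$delta, 4), "\n")
  invisible(x)
}

#' Rescale sanctuary growth relative to the drug compartment
#'
#' Multiplies all sanctuary rates (`b00`, `d00`, `b10`, `d10`) by
#' `phi` in `(0, 1]`, so that in the absence of treatment cells grow
#' `1/phi` times as fast in the drug compartment as in the sanctuary.
#'
#' @param landscape A [pathway_landscape()].
#' @param phi Scaling factor in `(0, 1]`.
#' @return A rescaled `pathway_landscape`.
#' @export
scale_sanctuary <- function(landscape, phi) {
  stopifnot(inherits(landscape, "pathway_landscape"), phi > 0, phi <= 1)
  pathway_landscape(b00 = landscape$b00 * phi, d00 = landscape$d00 * phi,
                    b10 = landscape$b10 * phi, d10 = landscape$d10 * phi,
                    b01 = landscape$b01, d01 = landscape$d01,
                    b11 = landscape$b11, d11 = landscape$d11)
}

#' Build a constrained three-class pathway process
#'
#' Realises each competing route to resistance in the drug compartment as
#' its own three-class branching process with strictly one-directional
#' inter-class flows:
#'
#' * `"migration_mutation"`: sensitive in the sanctuary --(migration `v`)-->
#'   sensitive in the drug compartment --(mutation at division,
#'   `b01 * u`)--> resistant in the drug compartment;
#' * `"mutation_migration"`: sensitive in the sanctuary --(mutation at
#'   division, `b00 * u`)--> resistant in the sanctuary --(migration
#'   `v`)--> resistant in the drug compartment.
#'
#' The destination class (index 3) is the resistant class in the drug
#' compartment in both cases.  The chains are bespoke models rather than
#' the full bidirectional model with rates zeroed, so each is exactly one
#' pathway.
#'
#' @param landscape A [pathway_landscape()].
#' @param which `"mutation_migration"` or `"migration_mutation"`.
#' @param u Mutation probability per division.
#' @param v Migration rate (per cell per day).
#' @return A [multitype_model()] with three classes.
#' @export
build_pathway <- function(landscape,
                          which = c("mutation_migration",
                                    "migration_mutation"),
                          u, v) {
  which <- match.arg(which)
  stopifnot(inherits(landscape, "pathway_landscape"),
            u >= 0, u <= 1, v >= 0)
  L <- landscape
  if (which == "migration_mutation") {
    birth <- c(L$b00, L$b01, L$b11)
    death <- c(L$d00, L$d01, L$d11)
    mut_rate <- c(0, L$b01 * u, 0)
    mut_target <- c(NA, 3L, NA)
    mig <- matrix(0, 3, 3)
    mig[1, 2] <- v
    classes <- tibble::tibble(class = 1:3, genotype = c(0L, 0L, 1L),
                              compartment = c(0L, 1L, 1L))
  } else {
    birth <- c(L$b00, L$b10, L$b11)
    death <- c(L$d00, L$d10, L$d11)
    mut_rate <- c(L$b00 * u, 0, 0)
    mut_target <- c(2L, NA, NA)
    mig <- matrix(0, 3, 3)
    mig[2, 3] <- v
    classes <- tibble::tibble(class = 1:3, genotype = c(0L, 1L, 1L),
                              compartment = c(0L, 0L, 1L))
  }
  mod <- multitype_model(birth, death, mut_rate, mut_target, mig, classes)
  mod$pathway <- which
  mod
}

#' Low-rate dominance condition for the mutation-migration pathway
#'
#' In the limit of low mutation and migration rates the mutation-migration
#' pathway reaches resistance in the drug compartment faster than the
#' migration-mutation pathway iff
#'
#' \deqn{\frac{b_{00}}{(b_{00}-d_{00}) - (b_{10}-d_{10})} >
#'       \frac{b_{01}}{(b_{00}-d_{00}) - (b_{01}-d_{01})}.}
#'
#' When the resistant mutation is neutral or advantageous in the sanctuary
#' (left denominator `<= 0`) the left side diverges and the
#' mutation-migration pathway always dominates.  A non-positive right
#' denominator (sensitive cells growing at least as fast under drug as in
#' the sanctuary) is outside the condition's validity domain and raises an
#' error.
#'
#' @param landscape A [pathway_landscape()].
#' @return `TRUE` if the mutation-migration pathway is predicted faster.
#' @export
pathway_dominance_general <- function(landscape) {
  L <- landscape
  r00 <- L$b00 - L$d00
  den_mm <- r00 - (L$b10 - L$d10)
  den_gm <- r00 - (L$b01 - L$d01)
  if (den_gm <= 0)
    stop("outside the validity domain of the dominance condition: ",
         "sensitive cells under drug grow at least as fast as in the ",
         "sanctuary ((b00 - d00) - (b01 - d01) <= 0)", call. = FALSE)
  if (den_mm <= 0) return(TRUE)
  L$b00 / den_mm > L$b01 / den_gm
}

#' Simplified dominance condition under equal death rates
#'
#' With all death rates equal and the parameterisation
#' `b10 = (1 - s) b00`, `b01 = (1 - delta) b00`, the general condition
#' reduces to `delta > s / (1 + s)`.
#'
#' @param s Cost of resistance in the absence of drug (`s < 1`).
#' @param delta Drug efficacy of growth inhibition of sensitive cells
#'   (`0 <= delta < 1`).
#' @return Logical; vectorised over `s` and `delta`.
#' @examples
#' pathway_dominance_simplified(s = 0.04, delta = 0.1)   # TRUE
#' s <- 0.04; s / (1 + s)                                # threshold delta*
#' @export
pathway_dominance_simplified <- function(s, delta) {
  stopifnot(all(s < 1), all(delta >= 0), all(delta < 1))
  delta > s / (1 + s)
}

#' Conditional mean times to resistance along the two pathways
#'
#' Builds both constrained pathway processes and computes, for each, the
#' conditional mean time until resistant cells are present in the drug
#' compartment (destination class), starting from a single sensitive cell
#' in the sanctuary.
#'
#' @inheritParams build_pathway
#' @param rtol,atol Integrator tolerances passed to the PGF engine.
#' @param p_cut,max_horizon See [relapse_curve()].
#' @return A tibble with one row per pathway: `pathway`, `escape_prob`,
#'   `mean_time_days`.
#' @export
compare_pathway_times <- function(landscape, u, v, rtol = 1e-10,
                                  atol = 1e-20, p_cut = 1e-5,
                                  max_horizon = 5e6) {
  stopifnot(u > 0, v > 0)
  census <- c(1, 0, 0)
  one <- function(which) {
    mod <- build_pathway(landscape, which, u = u, v = v)
    mask <- resistant_mask(mod, classes = 3)
    rc <- relapse_curve(mod, census, mask, rtol = rtol, atol = atol,
                        p_cut = p_cut, max_horizon = max_horizon)
    tibble::tibble(pathway = which, escape_prob = rc$escape_prob,
                   mean_time_days = rc$mean_time)
  }
  dplyr::bind_rows(one("mutation_migration"), one("migration_mutation"))
}

#' Numerically locate the pathway crossing in drug efficacy
#'
#' Under the equal-death parameterisation (`b10 = (1 - s) b00`,
#' `b01 = (1 - delta) b00`, common death rate `d`), finds by bisection the
#' drug efficacy `delta*` at which the two pathways' conditional mean times
#' to resistance are equal.  In the low-rate limit the crossing equals the
#' analytic threshold `s / (1 + s)`.
#'
#' @param s Cost of resistance.
#' @param u Mutation probability per division.
#' @param v Migration rate.
#' @param b00,d Sanctuary sensitive birth rate and the common death rate.
#' @param b11 Resistant birth rate in the drug compartment.
#' @param interval Search interval for `delta`.
#' @param tol Absolute bisection tolerance on `delta`.
#' @param ... Passed to [compare_pathway_times()].
#' @return The crossing `delta*`.
#' @export
pathway_crossing_delta <- function(s, u, v, b00 = 0.5, d = 0.4, b11 = 0.45,
                                   interval = c(0.005, 0.2), tol = 1e-4,
                                   ...) {
  land <- function(delta) {
    pathway_landscape(b00 = b00, d00 = d, b10 = (1 - s) * b00, d10 = d,
                      b01 = (1 - delta) * b00, d01 = d, b11 = b11, d11 = d)
  }
  # positive when migration-mutation is still the slower pathway
  gap <- function(delta) {
    tt <- compare_pathway_times(land(delta), u = u, v = v, ...)
    tt$mean_time_days[tt$pathway == "migration_mutation"] -
      tt$mean_time_days[tt$pathway == "mutation_migration"]
  }
  lo <- interval[1]; hi <- interval[2]
  g_lo <- gap(lo); g_hi <- gap(hi)
  if (sign(g_lo) == sign(g_hi))
    stop("no crossing inside the search interval (", lo, ", ", hi, ")",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    g_mid <- gap(mid)
    if (sign(g_mid) == sign(g_lo)) {
      lo <- mid; g_lo <- g_mid
    } else {
      hi <- mid; g_hi <- g_mid
    }
  }
  (lo + hi) / 2
}
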