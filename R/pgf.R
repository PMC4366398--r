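#' Resistant-class mask
#'
#' Selects the set of cell classes whose presence counts as "resistance".
#' The PGF evaluated at the masked dummy point (masked coordinates 0, all
#' others 1) is the probability that no cell of a masked class is alive.
#'
#' @param model A [branching_model()] or [multitype_model()] object.
#' @param min_genotype Genotypes `>= min_genotype` are resistant; defaults
#'   to the top genotype (full resistance).  Ignored when `classes` is
#'   given.
#' @param compartments Optional compartment indices (0-based) to restrict
#'   the mask to; default: any compartment.
#' @param classes Optional explicit 1-based class indices (required for
#'   models without genotype labels, e.g. pathway chains).
#'
#' @return A logical vector with one entry per class.
#' @export
resistant_mask <- function(model, min_genotype = NULL, compartments = NULL,
                           classes = NULL) {
  K <- model$n_classes
  if (!is.null(classes)) {
    stopifnot(all(classes >= 1), all(classes <= K))
    m <- rep(FALSE, K)
    m[classes] <- TRUE
    return(m)
  }
  gt <- model$classes$genotype
  if (anyNA(gt))
    stop("model classes carry no genotype labels; supply `classes`",
         call. = FALSE)
  if (is.null(min_genotype)) min_genotype <- max(gt)
  m <- gt >= min_genotype
  if (!is.null(compartments)) m <- m & model$classes$compartment %in% compartments
  if (!any(m)) stop("resistant mask is empty", call. = FALSE)
  m
}

#' Initial cell census
#'
#' @param genotype,compartment 0-based indices (vectorised).
#' @param count Initial number of cells of each class.
#' @return A tibble with columns `genotype`, `compartment`, `count`.
#' @export
cell_census <- function(genotype, compartment, count) {
  tibble::tibble(genotype = as.integer(genotype),
                 compartment = as.integer(compartment),
                 count = as.numeric(count))
}

# census -> per-class count vector, matching model class labels
census_vector <- function(model, census) {
  K <- model$n_classes
  if (is.numeric(census) && is.null(dim(census))) {
    if (length(census) != K)
      stop("numeric census must have one entry per class", call. = FALSE)
    return(as.numeric(census))
  }
  census <- tibble::as_tibble(census)
  if (any(census$count < 0))
    stop("census counts must be >= 0", call. = FALSE)
  N <- numeric(K)
  if (all(c("genotype", "compartment") %in% names(census)) &&
      !anyNA(model$classes$genotype)) {
    key_model <- paste(model$classes$genotype, model$classes$compartment)
    key <- paste(census$genotype, census$compartment)
    pos <- match(key, key_model)
    if (anyNA(pos))
      stop("census refers to classes absent from the model", call. = FALSE)
    N[pos] <- N[pos] + census$count
  } else if ("class" %in% names(census)) {
    N[census$class] <- N[census$class] + census$count
  } else {
    stop("census needs either genotype/compartment or class columns",
         call. = FALSE)
  }
  N
}

masked_eval_point <- function(mask) ifelse(mask, 0, 1)

# ---------------------------------------------------------------------------
# ODE drivers

ode_deficit <- function(model, G0, times, rtol = 1e-10, atol = 1e-20) {
  f <- function(t, y, p) list(deficit_rhs(model, y))
  sol <- deSolve::ode(y = G0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e5)
  if (attr(sol, "istate")[1] < 0)
    stop("PGF integration failed near t = ", max(sol[, 1]), call. = FALSE)
  sol
}

#' Integrate the backward PGF equations
#'
#' Solves the backward Kolmogorov equations for the per-lineage generating
#' functions `F_k(X; t)` with initial condition `F_k(X; 0) = x_k`, at a
#' fixed dummy-variable evaluation point `X`.
#'
#' Real evaluation points in `[0, 1]` are integrated in deficit coordinates
#' `G = 1 - F`, which preserves relative accuracy when `1 - F` is of the
#' order of the mutation rate; points on the complex unit disc (used by the
#' torus inversion) are integrated directly with a complex-capable solver.
#'
#' @param model A branching model.
#' @param eval_point Numeric or complex vector of dummy variables, one per
#'   class, with modulus at most 1.
#' @param times Increasing time grid in days, starting at 0.
#' @param rtol,atol Integrator tolerances.
#' @return A `pgf_trajectory` object; `tidy()` gives a long tibble with
#'   columns `time`, `class`, `genotype`, `compartment`, `F`.
#' @examples
#' mod <- multitype_model(birth = 0.5, death = 0.4)
#' tr <- solve_pgf(mod, eval_point = 0, times = seq(0, 50, 1))
#' @export
solve_pgf <- function(model, eval_point, times, rtol = 1e-9, atol = 1e-12) {
  K <- model$n_classes
  stopifnot(length(eval_point) == K)
  if (any(Mod(eval_point) > 1 + 1e-12))
    stop("`eval_point` entries must have modulus <= 1", call. = FALSE)
  if (times[1] != 0) times <- c(0, times)
  if (is.numeric(eval_point) && all(eval_point >= 0)) {
    sol <- ode_deficit(model, 1 - eval_point, times,
                       rtol = min(rtol, 1e-10), atol = min(atol, 1e-20))
    Fmat <- 1 - sol[, -1, drop = FALSE]
  } else {
    f <- function(t, y, p) list(pgf_rhs(model, y))
    sol <- deSolve::zvode(y = as.complex(eval_point), times = times,
                          func = f, parms = NULL, mf = 10,
                          rtol = rtol, atol = atol, maxsteps = 1e5)
    if (attr(sol, "istate")[1] < 0)
      stop("PGF integration failed near t = ", max(Re(sol[, 1])),
           call. = FALSE)
    Fmat <- sol[, -1, drop = FALSE]
  }
  colnames(Fmat) <- paste0("F", seq_len(K))
  structure(list(times = times, F = Fmat, eval_point = eval_point,
                 classes = model$classes),
            class = "pgf_trajectory")
}

#' @export
print.pgf_trajectory <- function(x, ...) {
  cat("<pgf_trajectory> ", length(x$times), " time points, ",
      ncol(x$F), " classes\n", sep = "")
  invisible(x)
}

#' @rdname solve_pgf
#' @param x A `pgf_trajectory`.
#' @param ... Unused.
#' @export
tidy.pgf_trajectory <- function(x, ...) {
  K <- ncol(x$F)
  tibble::tibble(
    time = rep(x$times, each = K),
    class = rep(seq_len(K), times = length(x$times)),
    genotype = rep(x$classes$genotype, times = length(x$times)),
    compartment = rep(x$classes$compartment, times = length(x$times)),
    F = as.vector(t(x$F))
  )
}

# ---------------------------------------------------------------------------
# Limiting PGF (t -> infinity)

# Newton iteration on the algebraic fixed-point system; NULL unless it
# genuinely converges (bounded, local steps), so a caller can fall back to
# more integration.  Clamping keeps iterates in [0, 1]; a slow mode that is
# still growing leaves Newton stuck at a pseudo-root, which is reported as
# failure rather than silently accepted.
newton_polish <- function(model, G, max_iter = 100) {
  for (i in seq_len(max_iter)) {
    r <- deficit_rhs(model, G)
    J <- deficit_jacobian(model, G)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    if (max(abs(step)) > 0.1 * max(G, 1e-12) + 1e-9) return(NULL)
    G <- pmin(pmax(G - step, 0), 1)
    if (max(abs(step)) <= 1e-14 * max(G, 1e-300)) return(G)
  }
  NULL
}

# Backward flow of the deficit system from G0 until its fixed point is
# reached, in doubling time chunks, accepting the limit only once the
# Newton polish converges (or, as a degenerate fallback, the residual is
# at rounding level).  Near-critical classes seeded by a mutation term of
# order u can grow for thousands of days before saturating; the Newton
# failure path keeps the integration going through that regime.
limiting_deficit <- function(model, G0, rtol = 1e-10, atol = 1e-20,
                             max_horizon = 1e8) {
  G <- pmin(pmax(G0, 0), 1)
  t_total <- 0
  chunk <- 25 / max(model$birth + model$death + model$mig_out, 0.01)
  repeat {
    res <- max(abs(deficit_rhs(model, G)))
    if (res < 1e-9 * max(G, 1e-6)) {
      polished <- newton_polish(model, G)
      if (!is.null(polished)) return(polished)
      if (res < 1e-16) return(G)
    }
    if (t_total >= max_horizon)
      stop("limiting PGF did not converge by t = ", max_horizon,
           "; last residual ", signif(res, 3), call. = FALSE)
    sol <- ode_deficit(model, G, c(0, chunk), rtol = rtol, atol = atol)
    G <- pmin(pmax(sol[nrow(sol), -1], 0), 1)
    t_total <- t_total + chunk
    chunk <- chunk * 2
  }
}

#' Limiting value of the backward PGF
#'
#' The `t -> Inf` limit of the backward flow started at `eval_point`,
#' obtained by integrating the deficit equations until the residual is
#' negligible and then Newton-polishing the algebraic fixed-point system.
#' At the masked point of a [resistant_mask()], `1 -` the limit for class
#' `k` is the probability that a lineage founded by one class-`k` cell ever
#' establishes a surviving resistant population.
#'
#' @inheritParams solve_pgf
#' @return Numeric vector of per-class limits in `[0, 1]`, with the deficit
#'   `1 - F` attached as attribute `"deficit"` (computed without
#'   cancellation; use it when the limit is close to 1).
#' @export
limiting_pgf <- function(model, eval_point, rtol = 1e-10, atol = 1e-20) {
  stopifnot(length(eval_point) == model$n_classes,
            is.numeric(eval_point), all(eval_point >= 0), all(eval_point <= 1))
  G <- limiting_deficit(model, 1 - eval_point, rtol = rtol, atol = atol)
  structure(1 - G, deficit = G)
}

# ---------------------------------------------------------------------------
# Escape probability and relapse curves

# stable p_s from log-products A(t), A_inf (both <= 0):
# p_s = (exp(A) - exp(Ainf)) / (1 - exp(Ainf))
ps_from_logprod <- function(A, A_inf) {
  # = exp(A) * (1 - exp(A_inf - A)) / (1 - exp(A_inf)), stable for
  # A_inf anywhere in [-Inf, 0) and A >= A_inf
  if (A_inf == -Inf) return(exp(A))
  exp(A) * (-expm1(A_inf - A)) / (-expm1(A_inf))
}

log_no_resistance <- function(N, G) {
  # sum_k N_k log(1 - G_k), -Inf when a populated class escapes surely
  active <- N > 0
  if (!any(active)) return(0)
  if (any(G[active] >= 1)) return(-Inf)
  sum(N[active] * log1p(-G[active]))
}

#' Probability that treatment fails (escape probability)
#'
#' Probability that at least one lineage from the initial census ever
#' establishes a surviving resistant population, composed multiplicatively
#' over the independent lineages of the census:
#' `1 - prod_k F_k(masked; Inf)^{N_k}`.  Products are evaluated in the log
#' domain, so censuses up to `1e11` cells and per-cell escape probabilities
#' of order the mutation rate are handled without underflow.
#'
#' @param model A branching model.
#' @param census Initial cell counts: a [cell_census()] tibble or a
#'   per-class numeric vector.
#' @param mask Logical resistant-class mask; default [resistant_mask()]
#'   (top genotype in any compartment).
#' @param by_compartment If `TRUE`, also return the per-origin
#'   decomposition (escape probability of the sub-census of each
#'   compartment alone).
#' @param rtol,atol Integrator tolerances.
#' @return A single probability, or (with `by_compartment = TRUE`) a tibble
#'   with columns `compartment` and `escape` plus the overall value in the
#'   last row (`compartment = NA`).
#' @export
escape_probability <- function(model, census, mask = resistant_mask(model),
                               by_compartment = FALSE,
                               rtol = 1e-10, atol = 1e-20) {
  N <- census_vector(model, census)
  if (sum(N) < 1) stop("census must contain at least one cell", call. = FALSE)
  G_inf <- limiting_deficit(model, as.numeric(mask), rtol = rtol, atol = atol)
  total <- -expm1(log_no_resistance(N, G_inf))
  if (!by_compartment) return(total)
  comp <- model$classes$compartment
  per <- purrr::map_dbl(sort(unique(comp[N > 0])), function(j) {
    Nj <- ifelse(comp == j, N, 0)
    -expm1(log_no_resistance(Nj, G_inf))
  })
  tibble::tibble(compartment = c(sort(unique(comp[N > 0])), NA),
                 escape = c(per, total))
}

# Adaptive integration of the masked deficit system, collecting (t, A(t)).
# Stops once p_s has fallen below p_cut (with tail extrapolation data) or
# errors if the tail does not decay by max_horizon.
relapse_solve <- function(model, N, mask, rtol = 1e-10, atol = 1e-20,
                          p_cut = 1e-5, max_horizon = 5e6,
                          points_per_chunk = 200) {
  G_inf <- limiting_deficit(model, as.numeric(mask), rtol = rtol, atol = atol)
  A_inf <- log_no_resistance(N, G_inf)
  if (A_inf == 0)
    stop("conditioning event is null: escape probability is zero",
         call. = FALSE)
  G <- as.numeric(mask)
  t0 <- 0
  chunk <- 2 / max(model$birth + model$death + model$mig_out, 0.01)
  times <- 0
  A <- log_no_resistance(N, G)  # 0 for an all-sensitive census
  ps <- ps_from_logprod(A, A_inf)
  repeat {
    grid <- seq(0, chunk, length.out = points_per_chunk + 1)
    sol <- ode_deficit(model, G, grid, rtol = rtol, atol = atol)
    Gmat <- pmin(pmax(sol[-1, -1, drop = FALSE], 0), 1)
    A_new <- apply(Gmat, 1, function(g) log_no_resistance(N, g))
    times <- c(times, t0 + grid[-1])
    ps <- c(ps, vapply(A_new, ps_from_logprod, numeric(1), A_inf = A_inf))
    G <- Gmat[nrow(Gmat), ]
    t0 <- t0 + chunk
    chunk <- chunk * 2
    ps_end <- ps[length(ps)]
    # stop only when p_s is small now AND provably stays small: the gap
    # between the trajectory and its limit bounds all future |p_s|
    gapA <- sum(N * abs(G - G_inf))
    tail_bound <- if (!is.finite(A_inf)) {
      A_end <- log_no_resistance(N, G)
      exp(min(A_end + gapA, 0))
    } else {
      ps_from_logprod(min(A_inf + gapA, 0), A_inf)
    }
    if (abs(ps_end) < p_cut && tail_bound < p_cut) break
    if (t0 >= max_horizon)
      stop("conditional no-resistance probability is not decaying: p_s(",
           t0, ") = ", signif(ps_end, 3),
           " (is a resistant class misconfigured subcritical?)",
           call. = FALSE)
  }
  list(times = times, ps = ps, G_inf = G_inf, A_inf = A_inf,
       escape = -expm1(A_inf))
}

# trapezoid + exponential tail extrapolated from the final decade of decay
integrate_ps <- function(times, ps) {
  main <- sum(diff(times) * (utils::head(ps, -1) + utils::tail(ps, -1)) / 2)
  ps_end <- ps[length(ps)]
  tail_int <- 0
  if (ps_end > 0) {
    sel <- which(ps > 0 & ps <= 10 * ps_end)
    sel <- sel[sel > which.max(ps)]  # decaying flank only
    if (length(sel) >= 3) {
      fit <- stats::lm.fit(cbind(1, times[sel]), log(ps[sel]))
      lambda <- -fit$coefficients[2]
      if (is.finite(lambda) && lambda > 0) tail_int <- ps_end / lambda
    }
  }
  main + tail_int
}

#' Conditional relapse curve and mean time to resistance
#'
#' Computes `p_s(t)`, the probability that no resistant cells are present
#' at time `t` conditional on eventual establishment of resistance:
#'
#' \deqn{p_s(t) = \frac{\prod_k F_k(X_m; t)^{N_k} -
#'   \prod_k F_k(X_m; \infty)^{N_k}}{1 - \prod_k F_k(X_m; \infty)^{N_k}}}
#'
#' where `X_m` is the masked evaluation point, together with the
#' conditional mean time to resistance `T = integral of p_s(t) dt`
#' (trapezoid quadrature on an adaptive grid plus an exponential-tail
#' correction fitted to the final decade of decay).
#'
#' @inheritParams escape_probability
#' @param t_grid Optional time grid (days) at which to report `p_s`; by
#'   default the adaptive integration grid is returned.
#' @param p_cut Integration continues until `p_s` falls below this value.
#' @param max_horizon Error out if `p_s` has not decayed by this time.
#' @return A `relapse_curve` object: use `tidy()` for the `(time, ps)`
#'   tibble, `glance()` for the one-row summary (`escape_prob`,
#'   `mean_time_days`, `ps_infinity`), `autoplot()` to plot.
#' @export
relapse_curve <- function(model, census, mask = resistant_mask(model),
                          t_grid = NULL, rtol = 1e-10, atol = 1e-20,
                          p_cut = 1e-5, max_horizon = 5e6) {
  N <- census_vector(model, census)
  if (sum(N) < 1) stop("census must contain at least one cell", call. = FALSE)
  rs <- relapse_solve(model, N, mask, rtol = rtol, atol = atol,
                      p_cut = p_cut, max_horizon = max_horizon)
  mean_time <- integrate_ps(rs$times, rs$ps)
  if (!is.null(t_grid)) {
    ps <- stats::approx(rs$times, rs$ps, xout = t_grid, yleft = 1,
                        yright = 0, rule = 2)$y
    curve <- tibble::tibble(time = t_grid, ps = ps)
  } else {
    curve <- tibble::tibble(time = rs$times, ps = rs$ps)
  }
  structure(list(curve = curve, escape_prob = rs$escape,
                 ps_infinity = exp(rs$A_inf), mean_time = mean_time),
            class = "relapse_curve")
}

#' @export
print.relapse_curve <- function(x, ...) {
  cat("<relapse_curve>\n  escape probability:", signif(x$escape_prob, 6),
      "\n  conditional mean time to resistance:",
      signif(x$mean_time, 6), "days\n")
  invisible(x)
}

#' @rdname relapse_curve
#' @param x A `relapse_curve`.
#' @param ... Unused.
#' @export
tidy.relapse_curve <- function(x, ...) x$curve

#' @rdname relapse_curve
#' @export
glance.relapse_curve <- function(x, ...) {
  tibble::tibble(escape_prob = x$escape_prob,
                 mean_time_days = x$mean_time,
                 ps_infinity = x$ps_infinity)
}

#' @rdname relapse_curve
#' @param object A `relapse_curve`.
#' @export
autoplot.relapse_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$time, y = .data$ps)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)",
                  y = "P(no resistant cells | eventual resistance)")
}

#' Conditional mean time to resistance
#'
#' The integral of the conditional no-resistance curve `p_s(t)` over
#' `[0, Inf)`; see [relapse_curve()].
#'
#' @inheritParams relapse_curve
#' @return Mean time in days.
#' @export
mean_time_to_resistance <- function(model, census,
                                    mask = resistant_mask(model),
                                    rtol = 1e-10, atol = 1e-20,
                                    p_cut = 1e-5, max_horizon = 5e6) {
  N <- census_vector(model, census)
  rs <- relapse_solve(model, N, mask, rtol = rtol, atol = atol,
                      p_cut = p_cut, max_horizon = max_horizon)
  integrate_ps(rs$times, rs$ps)
}
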