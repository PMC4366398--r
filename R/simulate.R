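#' Exact Gillespie simulation of the branching process
#'
#' Direct-method stochastic simulation algorithm for the same process the
#' PGF engine analyses: exponential waiting times at the total event rate;
#' divisions spawn two cells, one daughter mutating with the per-class
#' mutation probability (never for the top genotype); deaths remove one
#' cell; migration moves one cell along the topology's per-target rates.
#' This is the independent oracle used to validate escape probabilities,
#' no-resistance curves and joint count distributions.
#'
#' Replicates draw from counter-derived random streams (one per replicate,
#' derived from `seed` and the replicate index), so ensembles are
#' reproducible and order-independent.  Supercritical escapees grow without
#' bound; replicates whose total population exceeds `count_cap` are stopped
#' and flagged `truncated`, carrying their state forward to the remaining
#' checkpoints.
#'
#' @param model A branching model.
#' @param census Initial cell counts ([cell_census()] tibble or per-class
#'   vector).
#' @param horizon Simulation end time (days).
#' @param checkpoints Times at which per-replicate state is recorded;
#'   defaults to `horizon`.
#' @param n_reps Number of replicates.
#' @param seed Integer seed of the ensemble.
#' @param mask Resistant-class mask used for the resistance-presence
#'   indicator and first-resistance times.
#' @param count_cap Population cap (see Details).
#' @param stop_at_resistance Stop a replicate at its first resistant cell
#'   (first-passage studies); its state is carried to later checkpoints.
#' @return A `sim_summary` object: `tidy()` gives the per-replicate tibble
#'   (`rep`, `first_resistance`, `truncated`), `glance()` the aggregate
#'   no-resistance fractions per checkpoint with Monte-Carlo standard
#'   errors.  `sim_counts()` extracts per-replicate class counts at a
#'   checkpoint.
#' @examples
#' mod <- multitype_model(birth = 0.5, death = 0.4)
#' sim <- simulate_branching(mod, census = 1, horizon = 100, n_reps = 200,
#'                           seed = 1, mask = c(TRUE))
#' @export
simulate_branching <- function(model, census, horizon,
                               checkpoints = horizon, n_reps = 1, seed = 1,
                               mask = resistant_mask(model),
                               count_cap = 1e6, stop_at_resistance = FALSE) {
  stopifnot(horizon > 0, n_reps >= 1, all(checkpoints <= horizon),
            all(checkpoints >= 0))
  N <- census_vector(model, census)
  checkpoints <- sort(checkpoints)
  mt <- ifelse(is.na(model$mut_target), 0L, model$mut_target)
  raw <- .ssa_ensemble(model$birth, model$death, model$mut_rate, mt,
                       model$mig, N, horizon, checkpoints,
                       as.logical(mask), as.integer(n_reps),
                       as.double(seed), count_cap,
                       isTRUE(stop_at_resistance))
  structure(list(presence = raw$presence, counts = raw$counts,
                 first_resistance = raw$first_resistance,
                 final_counts = raw$final_counts,
                 truncated = raw$truncated,
                 checkpoints = checkpoints, n_reps = n_reps, seed = seed,
                 horizon = horizon, classes = model$classes),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat("<sim_summary> ", x$n_reps, " replicates to t = ", x$horizon,
      " (seed ", x$seed, ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname simulate_branching
#' @param x,object A `sim_summary`.
#' @param ... Unused.
#' @export
tidy.sim_summary <- function(x, ...) {
  tibble::tibble(rep = seq_len(x$n_reps),
                 first_resistance = x$first_resistance,
                 truncated = as.logical(x$truncated))
}

#' @rdname simulate_branching
#' @export
glance.sim_summary <- function(x, ...) {
  frac <- 1 - colMeans(x$presence)
  tibble::tibble(
    time = x$checkpoints,
    p_no_resistance = frac,
    se = sqrt(frac * (1 - frac) / x$n_reps),
    n_reps = x$n_reps
  )
}

#' @rdname simulate_branching
#' @param sim A `sim_summary`.
#' @param time One of the recorded checkpoints.
#' @export
sim_counts <- function(sim, time = NULL) {
  if (is.null(time)) time <- utils::tail(sim$checkpoints, 1)
  cp <- match(time, sim$checkpoints)
  if (is.na(cp)) stop("`time` is not a recorded checkpoint", call. = FALSE)
  m <- sim$counts[, , cp]
  dim(m) <- c(sim$n_reps, nrow(sim$classes))
  colnames(m) <- paste0("class", seq_len(ncol(m)))
  m
}
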