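#' Low-level multi-type branching model constructor
#'
#' A continuous-time multi-type branching process over `K` cell classes.
#' Each class `k` divides at rate `birth[k]`; at a division event one
#' daughter mutates into class `mut_target[k]` at rate `mut_rate[k]`
#' (so divisions without mutation occur at rate `birth[k] - mut_rate[k]`),
#' dies at rate `death[k]`, and migrates (changes class, e.g. moves to a
#' neighbouring compartment) to class `l` at rate `mig[k, l]`.
#'
#' Most users build models with [branching_model()] (genotype-by-compartment
#' lattice) or [build_pathway()] (constrained three-class chains); this
#' constructor is the common representation they share and the one the PGF
#' engine and the stochastic simulator consume.
#'
#' @param birth,death Numeric vectors of per-class division and death rates
#'   (per cell per day).
#' @param mut_rate Numeric vector of per-class division-with-mutation rates
#'   (`birth * u` for classes that can mutate, 0 otherwise).
#' @param mut_target Integer vector of 1-based class indices receiving the
#'   mutant daughter; `NA` for classes that do not mutate.
#' @param mig A `K x K` matrix of class-change rates (zero diagonal).
#' @param classes Optional tibble labelling the classes (columns `class`,
#'   `genotype`, `compartment`).
#'
#' @return An object of class `branching_model`.
#' @export
multitype_model <- function(birth, death, mut_rate = NULL, mut_target = NULL,
                            mig = NULL, classes = NULL) {
  K <- length(birth)
  stopifnot(K >= 1, length(death) == K)
  if (is.null(mut_rate)) mut_rate <- numeric(K)
  if (is.null(mut_target)) mut_target <- rep(NA_integer_, K)
  if (is.null(mig)) mig <- matrix(0, K, K)
  mut_target <- as.integer(mut_target)
  stopifnot(length(mut_rate) == K, length(mut_target) == K,
            is.matrix(mig), nrow(mig) == K, ncol(mig) == K)
  if (any(birth < 0) || any(death < 0) || any(mut_rate < 0) || any(mig < 0))
    stop("all rates must be non-negative", call. = FALSE)
  if (any(mut_rate > birth + 1e-12))
    stop("mutation rate cannot exceed the division rate", call. = FALSE)
  if (any(diag(mig) != 0))
    stop("`mig` must have a zero diagonal", call. = FALSE)
  has_mut <- mut_rate > 0
  if (any(has_mut & (is.na(mut_target) | mut_target < 1 | mut_target > K)))
    stop("every class with a positive mutation rate needs a valid target",
         call. = FALSE)
  if (any(!is.na(mut_target) & mut_target == seq_len(K)))
    stop("a class cannot mutate into itself", call. = FALSE)
  if (is.null(classes)) {
    classes <- tibble::tibble(class = seq_len(K),
                              genotype = NA_integer_,
                              compartment = NA_integer_)
  }
  structure(
    list(birth = as.numeric(birth), death = as.numeric(death),
         mut_rate = as.numeric(mut_rate), mut_target = mut_target,
         mig = mig, mig_out = rowSums(mig), n_classes = K,
         classes = tibble::as_tibble(classes)),
    class = "branching_model"
  )
}

#' @export
print.branching_model <- function(x, ...) {
  cat("<branching_model> ", x$n_classes, " classes\n", sep = "")
  df <- x$classes
  df$birth <- x$birth
  df$death <- x$death
  df$mut_rate <- x$mut_rate
  df$mig_out <- x$mig_out
  print(df, n = min(nrow(df), 12))
  invisible(x)
}

# genotype-major flat index (genotype i, compartment j, both 0-based)
class_index <- function(genotype, compartment, n_compartments) {
  as.integer(genotype * n_compartments + compartment + 1L)
}

migration_matrix <- function(M, v, topology, edge_rule = c("half", "full")) {
  edge_rule <- match.arg(edge_rule)
  W <- matrix(0, M, M)
  if (v < 0) stop("migration rate must be >= 0", call. = FALSE)
  if (v == 0) return(W)
  if (M == 1) {
    if (topology == "none") return(W)
    stop("migration with a single compartment: no neighbour exists",
         call. = FALSE)
  }
  switch(topology,
    none = stop("positive migration rate with topology \"none\"",
                call. = FALSE),
    pairwise = {
      if (M != 2) stop("pairwise topology requires exactly 2 compartments",
                       call. = FALSE)
      W[1, 2] <- W[2, 1] <- v
    },
    ring = {
      for (j in seq_len(M)) {
        left <- if (j == 1) M else j - 1
        right <- if (j == M) 1 else j + 1
        W[j, left] <- W[j, left] + v / 2
        W[j, right] <- W[j, right] + v / 2
      }
    },
    global = {
      W[] <- v / (M - 1)
      diag(W) <- 0
    },
    line = {
      for (j in seq_len(M)) {
        if (j > 1) W[j, j - 1] <- v / 2
        if (j < M) W[j, j + 1] <- v / 2
      }
      if (edge_rule == "full") {
        W[1, 2] <- v
        W[M, M - 1] <- v
      }
    },
    stop("unknown topology: ", topology, call. = FALSE)
  )
  W
}

#' Assemble a genotype-by-compartment branching model
#'
#' Builds the full multi-type branching process from a rate table: genotype
#' `i` in compartment `j` divides at rate `b_ij` (one daughter mutating to
#' genotype `i + 1` with probability `u`; the top genotype produces no
#' further mutants), dies at rate `d_ij`, and migrates to neighbouring
#' compartments (same genotype) according to the chosen topology.
#'
#' Classes are flattened genotype-major: for the two-genotype,
#' two-compartment minimal model the class order is
#' `(0,0), (0,1), (1,0), (1,1)`, matching the conventional dummy-variable
#' ordering `x00, x01, x10, x11`.
#'
#' @param rates A rate table from [build_rate_table()] (columns `genotype`,
#'   `compartment`, `birth`, `death`).
#' @param u Probability that one daughter cell mutates at a division event.
#' @param v Total per-cell migration rate (per cell per day); split across
#'   target compartments by the topology.
#' @param topology One of `"pairwise"` (two compartments), `"ring"`
#'   (nearest neighbours on a ring, `v/2` each), `"global"` (any other
#'   compartment, `v/(M-1)` each), `"line"` (radial line of shells, `v/2`
#'   per neighbour) or `"none"`.
#' @param edge_rule For `"line"` only: `"half"` sends `v/2` to the single
#'   neighbour of an edge shell (total outflow `v/2` at the edges);
#'   `"full"` sends `v`.
#'
#' @return A [multitype_model()] object with labelled classes.
#' @examples
#' pars <- drug_response(ic50 = 50, m = 2, rho = 5, s = 0.01)
#' comps <- tibble::tibble(beta = c(0.05, 0.5), alpha = c(0.04, 0.4),
#'                         drug = c(0, 100))
#' rt <- build_rate_table(comps, n_genotypes = 2, params = pars)
#' branching_model(rt, u = 1e-9, v = 1e-4, topology = "pairwise")
#' @export
branching_model <- function(rates, u, v,
                            topology = c("pairwise", "ring", "global",
                                         "line", "none"),
                            edge_rule = c("half", "full")) {
  topology <- match.arg(topology)
  edge_rule <- match.arg(edge_rule)
  stopifnot(is.numeric(u), length(u) == 1, u >= 0, u <= 1,
            is.numeric(v), length(v) == 1, v >= 0)
  rates <- dplyr::arrange(tibble::as_tibble(rates),
                          .data$genotype, .data$compartment)
  n <- max(rates$genotype) + 1L
  M <- max(rates$compartment) + 1L
  if (nrow(rates) != n * M)
    stop("rate table must cover the full genotype x compartment grid",
         call. = FALSE)

  K <- n * M
  idx <- class_index(rates$genotype, rates$compartment, M)
  birth <- death <- numeric(K)
  birth[idx] <- rates$birth
  death[idx] <- rates$death

  gt <- integer(K); cp <- integer(K)
  gt[idx] <- rates$genotype
  cp[idx] <- rates$compartment

  mut_rate <- ifelse(gt < n - 1L, birth * u, 0)
  mut_target <- ifelse(gt < n - 1L, class_index(gt + 1L, cp, M), NA_integer_)

  Wc <- migration_matrix(M, v, topology, edge_rule)
  mig <- matrix(0, K, K)
  for (i in 0:(n - 1L)) {
    rows <- class_index(i, 0:(M - 1L), M)
    mig[rows, rows] <- Wc
  }

  mod <- multitype_model(
    birth, death, mut_rate, mut_target, mig,
    classes = tibble::tibble(class = seq_len(K), genotype = gt,
                             compartment = cp)
  )
  mod$n_genotypes <- n
  mod$n_compartments <- M
  mod$u <- u
  mod$v <- v
  mod$topology <- topology
  mod
}

#' Right-hand side of the backward PGF equations
#'
#' For class `k` with division rate `b`, death rate `d`, mutation rate
#' `b u`, mutant target `k+`, and migration rates `w_{k -> l}`, the backward
#' equation for the generating function `F_k(X; t)` of the lineage started
#' by one class-`k` cell reads
#'
#' \deqn{\partial_t F_k = d + b(1-u)F_k^2 + b u F_k F_{k^+}
#'       + \sum_l w_{kl} F_l - (d + b + w_k) F_k}
#'
#' with `w_k` the total migration outflow.  `F = 1` is always a fixed point
#' (normalisation).
#'
#' @param model A [multitype_model()] / [branching_model()] object.
#' @param F Numeric or complex vector with one entry per class, or a matrix
#'   with one column per independent evaluation point.
#' @return The time derivative, same shape as `F`.
#' @export
pgf_rhs <- function(model, F) {
  K <- model$n_classes
  vec <- is.null(dim(F))
  Fm <- if (vec) matrix(F, nrow = K) else F
  if (nrow(Fm) != K) stop("`F` must have one entry per class", call. = FALSE)
  mt <- ifelse(is.na(model$mut_target), 1L, model$mut_target)
  bu <- model$mut_rate
  bnu <- model$birth - bu
  Fmut <- Fm[mt, , drop = FALSE]
  out <- model$death + bnu * Fm^2 + bu * Fm * Fmut +
    model$mig %*% Fm - (model$death + model$birth + model$mig_out) * Fm
  if (vec) drop(out) else out
}

# RHS in deficit coordinates G = 1 - F; algebraically identical to
# pgf_rhs but free of the catastrophic cancellation 1 - F when the
# per-cell escape probabilities are of order u or u*v.
#   dG/dt = (b - d - bu - w) G - (b - bu) G^2 + bu G+ - bu G G+ + W G
deficit_rhs <- function(model, G) {
  K <- model$n_classes
  vec <- is.null(dim(G))
  Gm <- if (vec) matrix(G, nrow = K) else G
  mt <- ifelse(is.na(model$mut_target), 1L, model$mut_target)
  bu <- model$mut_rate
  bnu <- model$birth - bu
  Gmut <- Gm[mt, , drop = FALSE]
  out <- (model$birth - model$death - bu - model$mig_out) * Gm -
    bnu * Gm^2 + bu * Gmut - bu * Gm * Gmut + model$mig %*% Gm
  if (vec) drop(out) else out
}

# Jacobian of deficit_rhs at G (K x K), used by the Newton polish of the
# limiting PGF.
deficit_jacobian <- function(model, G) {
  K <- model$n_classes
  mt <- ifelse(is.na(model$mut_target), 1L, model$mut_target)
  bu <- model$mut_rate
  bnu <- model$birth - bu
  Gmut <- G[mt]
  J <- model$mig
  diag(J) <- diag(J) +
    (model$birth - model$death - bu - model$mig_out) -
    2 * bnu * G - bu * Gmut
  add <- bu * (1 - G)
  for (k in seq_len(K)) {
    if (!is.na(model$mut_target[k]) && bu[k] > 0) {
      J[k, model$mut_target[k]] <- J[k, model$mut_target[k]] + add[k]
    }
  }
  J
}
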