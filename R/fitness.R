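#' Hill dose-response parameters
#'
#' Bundle of the four parameters of the Hill-function fitness landscape that
#' maps a genotype (number of acquired point mutations) and a local drug
#' concentration to a cell division rate.  The division rate of a cell with
#' `i` mutations in a compartment with drug concentration `D` and drug-free
#' sensitive division rate `beta` is
#'
#' \deqn{b = \beta (1 - i s) / (1 + (D / (\rho^i \cdot IC_{50}))^m)}
#'
#' Death rates are unaffected by the drug (cytostatic, not cytotoxic, drug
#' action).
#'
#' @param ic50 Drug concentration at which the division rate of a sensitive
#'   cell is halved (concentration units, > 0).
#' @param m Hill steepness exponent (dimensionless, > 0).
#' @param rho Fold-increase in IC50 per acquired point mutation
#'   (dimensionless, >= 1).
#' @param s Fitness cost per point mutation in the absence of drug
#'   (dimensionless, < 1; zero or negative values model neutral or
#'   advantageous mutations).
#'
#' @return An object of class `drug_response` (a named list).
#' @examples
#' drug_response(ic50 = 50, m = 2, rho = 5, s = 0.01)
#' @export
drug_response <- function(ic50, m, rho, s = 0) {
  stopifnot(is.numeric(ic50), length(ic50) == 1, is.finite(ic50),
            is.numeric(m), length(m) == 1, is.finite(m),
            is.numeric(rho), length(rho) == 1, is.finite(rho),
            is.numeric(s), length(s) == 1, is.finite(s))
  if (ic50 <= 0) stop("`ic50` must be > 0", call. = FALSE)
  if (m <= 0) stop("`m` must be > 0", call. = FALSE)
  if (rho < 1) stop("`rho` must be >= 1 (no loss of resistance per mutation)",
                    call. = FALSE)
  if (s >= 1) stop("`s` must be < 1 so that birth rates stay positive",
                   call. = FALSE)
  structure(list(ic50 = ic50, m = m, rho = rho, s = s),
            class = "drug_response")
}

#' @export
print.drug_response <- function(x, ...) {
  cat("<drug_response> IC50 =", x$ic50, " m =", x$m,
      " rho =", x$rho, " s =", x$s, "\n")
  invisible(x)
}

#' Hill-function division rate for one genotype in one compartment
#'
#' @param genotype Number of acquired point mutations (integer >= 0).
#' @param beta Drug-free division rate of a sensitive cell in the
#'   compartment (per cell per day).
#' @param drug Drug concentration in the compartment (>= 0).
#' @param params A [drug_response()] object.
#'
#' @return Division rate in per cell per day.  Vectorised over `genotype`,
#'   `beta` and `drug`.
#' @examples
#' pars <- drug_response(ic50 = 50, m = 2, rho = 5, s = 0.01)
#' hill_birth_rate(0, beta = 0.5, drug = 0, params = pars)    # 0.5
#' hill_birth_rate(0, beta = 0.5, drug = 50, params = pars)   # 0.25
#' @export
hill_birth_rate <- function(genotype, beta, drug, params) {
  stopifnot(inherits(params, "drug_response"))
  if (any(genotype < 0) || any(genotype != round(genotype)))
    stop("`genotype` must be a non-negative mutation count", call. = FALSE)
  if (any(beta <= 0)) stop("`beta` must be > 0", call. = FALSE)
  if (any(drug < 0)) stop("`drug` must be >= 0", call. = FALSE)
  cost <- 1 - genotype * params$s
  if (any(cost <= 0))
    stop("invalid genotype: mutation cost i*s >= 1 gives a non-positive ",
         "birth rate (genotype ", max(genotype), ", s = ", params$s, ")",
         call. = FALSE)
  beta * cost / (1 + (drug / (params$rho^genotype * params$ic50))^params$m)
}

#' Build the genotype-by-compartment rate table
#'
#' Evaluates the Hill fitness landscape for every genotype in every
#' compartment.  Death rates equal the compartment's drug-free death rate
#' for every genotype (drug action is cytostatic).
#'
#' @param compartments A data frame with one row per compartment and columns
#'   `beta` (drug-free sensitive division rate, per cell per day), `alpha`
#'   (death rate, per cell per day) and `drug` (concentration, >= 0).
#' @param n_genotypes Number of genotypes; genotype `i` carries `i` point
#'   mutations, `i = 0 .. n_genotypes - 1`.
#' @param params A [drug_response()] object.
#'
#' @return A tibble with columns `genotype`, `compartment` (0-based
#'   indices), `birth`, `death` and `growth = birth - death`, ordered
#'   genotype-major.
#' @examples
#' pars <- drug_response(ic50 = 50, m = 2, rho = 5, s = 0.01)
#' lesions <- tibble::tibble(beta = c(0.05, 0.5), alpha = c(0.04, 0.4),
#'                           drug = c(0, 100))
#' build_rate_table(lesions, n_genotypes = 2, params = pars)
#' @export
build_rate_table <- function(compartments, n_genotypes, params) {
  compartments <- tibble::as_tibble(compartments)
  req <- c("beta", "alpha", "drug")
  if (!all(req %in% names(compartments)))
    stop("`compartments` needs columns beta, alpha, drug", call. = FALSE)
  if (nrow(compartments) < 1) stop("need at least one compartment",
                                   call. = FALSE)
  if (n_genotypes < 1 || n_genotypes != round(n_genotypes))
    stop("`n_genotypes` must be a positive integer", call. = FALSE)
  if (any(compartments$beta <= 0) || any(compartments$alpha < 0) ||
      any(compartments$drug < 0))
    stop("compartments must have beta > 0, alpha >= 0, drug >= 0",
         call. = FALSE)

  grid <- tidyr::expand_grid(genotype = seq_len(n_genotypes) - 1L,
                             compartment = seq_len(nrow(compartments)) - 1L)
  tab <- dplyr::mutate(
    grid,
    birth = hill_birth_rate(.data$genotype,
                            compartments$beta[.data$compartment + 1L],
                            compartments$drug[.data$compartment + 1L],
                            params),
    death = compartments$alpha[.data$compartment + 1L],
    growth = .data$birth - .data$death
  )
  bad <- which(tab$birth <= 0)
  if (length(bad))
    stop("non-positive birth rate for genotype ", tab$genotype[bad[1]],
         ", compartment ", tab$compartment[bad[1]], call. = FALSE)
  tab
}
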