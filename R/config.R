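#' Load and validate a scenario configuration file
#'
#' Scenario files are YAML with a `scenario` kind (`two_lesion`, `onion`,
#' `ring`, `pathway` or `custom`) and one section of parameters per kind;
#' `custom` models are specified either by an explicit `rates` table
#' (`genotype`, `compartment`, `birth`, `death`) or by `compartments`
#' (`beta`, `alpha`, `drug`) plus `drug_response` and `n_genotypes`,
#' together with `mutation: {u}`, `migration: {v, topology}` and a
#' `census` list.  Unknown keys are rejected; missing required fields
#' raise an error naming the field; defaulted fields are reported so a
#' run's resolved configuration is fully documented.
#'
#' @param path Path to a YAML scenario file.
#' @param quiet Suppress the message listing defaulted fields.
#' @return A validated `scenario_config` list with defaults filled in.
#' @export
load_scenario_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_scenario_config(cfg, quiet = quiet)
}

kind_defaults <- list(
  two_lesion = list(delta_d = NULL, v = NULL, d_bar = 50, n0 = 1e3,
                    n1 = 1e8, beta = c(0.05, 0.5), alpha = c(0.04, 0.4),
                    u = 1e-9, n_genotypes = 2),
  onion = list(inv_tau_d = NULL, v = 2e-4, M = 30, n_genotypes = 3,
               n_cells = 1e11, diameter = 4.6, tau_g = 1, tau_c = 1, D0 = 500,
               b0 = 0.5, d0 = 0.4, u = 1e-9, weighting = "spherical",
               edge_rule = "half"),
  ring = list(sigma = NULL, v = NULL, topology = "ring", M = 20,
              n_genotypes = 5, d_bar = 50, b0 = 0.2, d0 = 0.1, u = 1e-4,
              start_compartment = NULL)
)

#' @rdname load_scenario_config
#' @param cfg A raw configuration list (as parsed from YAML).
#' @export
validate_scenario_config <- function(cfg, quiet = FALSE) {
  kinds <- c("two_lesion", "onion", "ring", "pathway", "custom")
  if (is.null(cfg$scenario))
    stop("missing required field: scenario", call. = FALSE)
  if (!cfg$scenario %in% kinds)
    stop("unknown scenario kind: ", cfg$scenario, call. = FALSE)
  kind <- cfg$scenario
  allowed <- c("scenario", "seed", "drug_response",
               switch(kind,
                      custom = c("rates", "compartments", "n_genotypes",
                                 "mutation", "migration", "census"),
                      pathway = "pathway",
                      kind))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  # YAML without a sign after "e" (1.0e8) parses as a string; recover it
  coerce_num <- function(x) {
    if (is.character(x) && length(x) == 1 &&
        grepl("^[-+]?[0-9.]+([eE][-+]?[0-9]+)?$", x)) as.numeric(x) else x
  }

  defaulted <- character()
  if (kind %in% names(kind_defaults)) {
    sec <- lapply(cfg[[kind]], coerce_num)
    defs <- kind_defaults[[kind]]
    unknown <- setdiff(names(sec), names(defs))
    if (length(unknown))
      stop("unknown key(s) in section ", kind, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (f in names(defs)) {
      if (is.null(sec[[f]])) {
        if (is.null(defs[[f]]) && !(kind == "ring" &&
                                    f == "start_compartment"))
          stop("missing required field: ", kind, ".", f, call. = FALSE)
        sec[f] <- defs[f]
        defaulted <- c(defaulted, paste0(kind, ".", f))
      }
    }
    cfg[[kind]] <- sec
  } else if (kind == "pathway") {
    sec <- cfg$pathway
    for (f in c("landscape", "which", "u", "v"))
      if (is.null(sec[[f]]))
        stop("missing required field: pathway.", f, call. = FALSE)
    need <- c("b00", "d00", "b10", "d10", "b01", "d01", "b11", "d11")
    miss <- setdiff(need, names(sec$landscape))
    if (length(miss))
      stop("missing required field: pathway.landscape.", miss[1],
           call. = FALSE)
  } else {  # custom
    if (is.null(cfg$mutation) || is.null(cfg$mutation$u))
      stop("missing required field: mutation.u", call. = FALSE)
    if (is.null(cfg$migration) || is.null(cfg$migration$v))
      stop("missing required field: migration.v", call. = FALSE)
    if (is.null(cfg$migration$topology)) {
      cfg$migration$topology <- "pairwise"
      defaulted <- c(defaulted, "migration.topology")
    }
    if (is.null(cfg$rates)) {
      for (f in c("compartments", "drug_response", "n_genotypes"))
        if (is.null(cfg[[f]]))
          stop("missing required field: ", f,
               " (custom scenarios need `rates` or compartments + ",
               "drug_response + n_genotypes)", call. = FALSE)
    }
    if (is.null(cfg$census))
      stop("missing required field: census", call. = FALSE)
  }
  if (!is.null(cfg$drug_response)) {
    miss <- setdiff(c("ic50", "m", "rho", "s"), names(cfg$drug_response))
    if (length(miss))
      stop("missing required field: drug_response.", miss[1], call. = FALSE)
  }
  if (is.null(cfg$seed)) {
    cfg$seed <- 1L
    defaulted <- c(defaulted, "seed")
  }
  if (!quiet && length(defaulted))
    message("defaults filled for: ", paste(defaulted, collapse = ", "))
  structure(cfg, class = c("scenario_config", "list"))
}

#' Build the model and census described by a scenario configuration
#'
#' @param cfg A validated `scenario_config` (see [load_scenario_config()]).
#' @return A list with elements `model` and `census` (plus any extras the
#'   scenario builder returns).
#' @export
build_scenario <- function(cfg) {
  if (!inherits(cfg, "scenario_config")) cfg <- validate_scenario_config(cfg,
                                                                  quiet = TRUE)
  dr <- function(default) {
    if (is.null(cfg$drug_response)) default else
      do.call(drug_response, cfg$drug_response)
  }
  switch(cfg$scenario,
    two_lesion = {
      a <- cfg$two_lesion
      build_two_lesion(delta_d = a$delta_d, v = a$v, d_bar = a$d_bar,
                       n0 = a$n0, n1 = a$n1, beta = unlist(a$beta),
                       alpha = unlist(a$alpha),
                       params = dr(drug_response(50, 2, 5, 0.01)),
                       u = a$u, n_genotypes = a$n_genotypes)
    },
    onion = {
      a <- cfg$onion
      build_onion(inv_tau_d = a$inv_tau_d, v = a$v, M = a$M,
                  n_genotypes = a$n_genotypes, N = a$n_cells,
                  diameter = a$diameter, tau_g = a$tau_g, tau_c = a$tau_c,
                  D0 = a$D0, b0 = a$b0, d0 = a$d0,
                  params = dr(drug_response(50, 2, 5, 0.01)), u = a$u,
                  weighting = a$weighting, edge_rule = a$edge_rule)
    },
    ring = {
      a <- cfg$ring
      build_ring(sigma = a$sigma, v = a$v, topology = a$topology, M = a$M,
                 n_genotypes = a$n_genotypes, d_bar = a$d_bar, b0 = a$b0,
                 d0 = a$d0, params = dr(drug_response(100, 2, 1.1, 0.01)),
                 u = a$u, start_compartment = a$start_compartment)
    },
    pathway = {
      a <- cfg$pathway
      land <- do.call(pathway_landscape, a$landscape)
      model <- build_pathway(land, which = a$which, u = a$u, v = a$v)
      list(model = model, census = c(1, 0, 0), landscape = land)
    },
    custom = {
      if (!is.null(cfg$rates)) {
        rt <- dplyr::bind_rows(lapply(cfg$rates, tibble::as_tibble))
        rt$growth <- rt$birth - rt$death
      } else {
        comps <- dplyr::bind_rows(lapply(cfg$compartments,
                                         tibble::as_tibble))
        rt <- build_rate_table(comps, cfg$n_genotypes,
                               do.call(drug_response, cfg$drug_response))
      }
      model <- branching_model(rt, u = cfg$mutation$u, v = cfg$migration$v,
                               topology = cfg$migration$topology)
      cen <- dplyr::bind_rows(lapply(cfg$census, tibble::as_tibble))
      list(model = model, census = cen)
    }
  )
}

#' Write a table as TSV with full-precision numerics
#'
#' Numeric columns are written in scientific notation with 17 significant
#' digits, so values round-trip bit-identically through the file.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.16e", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

parse_mask_spec <- function(model, spec) {
  if (is.null(spec)) return(resistant_mask(model))
  m <- regmatches(spec, regexec(
    "^genotype>=([0-9]+)(,compartment=([0-9]+))?$", spec))[[1]]
  if (!length(m)) stop("cannot parse mask spec: ", spec, call. = FALSE)
  comp <- if (m[4] != "") as.integer(m[4]) else NULL
  resistant_mask(model, min_genotype = as.integer(m[2]),
                 compartments = comp)
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i], call. = FALSE)
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("flag --", key, " needs a value", call. = FALSE)
    flags[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line interface
#'
#' Dispatches the subcommands `escape`, `relapse-time`, `pathway-compare`,
#' `joint-distribution`, `simulate` and `sweep`.  A thin executable wrapper
#' is installed at `system.file("cli", "spatialresist.R", package =
#' "spatialresist")`.  Every run echoes its resolved configuration to the
#' output directory for provenance.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return The path(s) of the file(s) written, invisibly.
#' @export
resist_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: spatialresist <escape|relapse-time|pathway-compare|",
         "joint-distribution|simulate|sweep> --config FILE ",
         "[--out-dir DIR] ...", call. = FALSE)
  cmd <- args[1]
  flags <- parse_cli_flags(args[-1])
  if (is.null(flags$config)) stop("--config is required", call. = FALSE)
  out_dir <- if (is.null(flags$out_dir)) "." else flags$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- load_scenario_config(flags$config, quiet = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_echo.yaml"))
  sc <- build_scenario(cfg)
  num <- function(x, default = NULL) if (is.null(x)) default else
    as.numeric(x)

  written <- switch(cmd,
    escape = {
      mask <- parse_mask_spec(sc$model, flags$mask)
      ep <- escape_probability(sc$model, sc$census, mask,
                               by_compartment = TRUE)
      write_table(ep, file.path(out_dir, "escape.tsv"))
    },
    `relapse-time` = {
      mask <- parse_mask_spec(sc$model, flags$mask)
      rc <- relapse_curve(sc$model, sc$census, mask)
      write_table(tidy(rc), file.path(out_dir, "relapse_curve.tsv"))
      write_table(glance(rc), file.path(out_dir, "relapse_summary.tsv"))
    },
    `pathway-compare` = {
      if (cfg$scenario != "pathway")
        stop("pathway-compare needs a pathway scenario", call. = FALSE)
      scan <- flags$scan
      if (is.null(scan)) {
        tt <- compare_pathway_times(sc$landscape, u = cfg$pathway$u,
                                    v = cfg$pathway$v)
        write_table(tt, file.path(out_dir, "pathway_times.tsv"))
      } else {
        p <- strsplit(scan, ":")[[1]]  # delta:lo:hi:n
        grid <- seq(as.numeric(p[2]), as.numeric(p[3]),
                    length.out = as.integer(p[4]))
        L <- sc$landscape
        rows <- purrr::map_dfr(grid, function(delta) {
          land <- pathway_landscape(b00 = L$b00, d00 = L$d00, b10 = L$b10,
                                    d10 = L$d10,
                                    b01 = (1 - delta) * L$b00, d01 = L$d01,
                                    b11 = L$b11, d11 = L$d11)
          tt <- compare_pathway_times(land, u = cfg$pathway$u,
                                      v = cfg$pathway$v)
          tibble::tibble(
            delta = delta,
            T_mutation_migration =
              tt$mean_time_days[tt$pathway == "mutation_migration"],
            T_migration_mutation =
              tt$mean_time_days[tt$pathway == "migration_mutation"],
            predicted_dominant = if (pathway_dominance_general(land))
              "mutation_migration" else "migration_mutation")
        })
        write_table(rows, file.path(out_dir, "pathway_scan.tsv"))
      }
    },
    `joint-distribution` = {
      start <- as.integer(num(flags$start, 1))
      jd <- joint_count_distribution(
        sc$model, start_class = start, time = num(flags$time, 50),
        grid_size = as.integer(num(flags$grid_size, 128)),
        max_count = as.integer(num(flags$max_count, 20)))
      write_table(tidy(jd), file.path(out_dir, "joint_distribution.tsv"))
    },
    simulate = {
      cps <- if (is.null(flags$checkpoints)) NULL else
        as.numeric(strsplit(flags$checkpoints, ",")[[1]])
      horizon <- num(flags$horizon, 50)
      sim <- simulate_branching(sc$model, sc$census, horizon = horizon,
                                checkpoints = if (is.null(cps)) horizon
                                              else cps,
                                n_reps = as.integer(num(flags$reps, 100)),
                                seed = as.integer(num(flags$seed,
                                                      cfg$seed)))
      write_table(tidy(sim), file.path(out_dir, "sim_replicates.tsv"))
      write_table(glance(sim), file.path(out_dir, "sim_aggregate.tsv"))
    },
    sweep = {
      p <- strsplit(flags$grid, ":")[[1]]  # lo:hi:n
      grid <- seq(as.numeric(p[1]), as.numeric(p[2]),
                  length.out = as.integer(p[3]))
      param <- flags$param
      quantity <- if (is.null(flags$quantity)) "mean_time" else
        flags$quantity
      builder <- function(val) {
        cfg2 <- cfg
        cfg2[[cfg$scenario]][[param]] <- val
        build_scenario(cfg2)
      }
      tab <- scenario_sweep(grid, builder, quantity = quantity)
      names(tab) <- c(param, quantity)
      write_table(tab, file.path(out_dir, "sweep.tsv"))
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(written)
}
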