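# Pipeline stages tying the modules into the full workflow, driven by a
# single YAML/JSON configuration. A thin command-line wrapper over
# run_stage() is shipped in inst/cli/equiloc.

#' Write a solution to JSON (open sites, capacities, objectives)
#'
#' @param solution a [solution_allocation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(solution, path) {
  payload <- list(
    status = solution$status, gap = solution$gap,
    of1 = solution$of1, of2 = solution$of2,
    open_sites = as.list(names(solution$X)[solution$X > 0.5]),
    X = as.list(solution$X),
    C = apply(solution$C, 1, as.list)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the nonzero flows of a solution to long-format CSV
#'
#' @param solution a [solution_allocation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flows_csv <- function(solution, path) {
  dn <- dimnames(solution$Y)
  idx <- which(solution$Y > 0, arr.ind = TRUE)
  df <- data.frame(
    node = dn[[1]][idx[, 1]],
    site = dn[[2]][idx[, 2]],
    intervention = dn[[3]][idx[, 3]],
    patients = solution$Y[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$intervention, df$node, df$site), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.read_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config)) stop("config file not found: ", config,
                                 call. = FALSE)
  if (grepl("\\.json$", config, ignore.case = TRUE)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config)
  }
}

.cfg_get <- function(cfg, name, default) {
  if (!is.null(cfg[[name]])) cfg[[name]] else default
}

.pipeline_instance <- function(cfg, output_dir) {
  pfile <- .cfg_get(cfg$inputs, "profiles",
                    file.path(output_dir, "profiles.csv"))
  dfile <- .cfg_get(cfg$inputs, "distances",
                    file.path(output_dir, "distances.csv"))
  profiles <- read_profiles_csv(pfile)
  dm <- if (file.exists(dfile)) {
    load_distance_csv(dfile, node_ids = profiles$node_id)
  } else NULL
  budget <- unlist(.cfg_get(cfg, "budget",
                            stop("config must provide 'budget'",
                                 call. = FALSE)))
  instance_from_profiles(
    profiles, dm = dm, budget = budget,
    hourly_cost = unlist(.cfg_get(cfg, "hourly_cost", c(11250, 38125))),
    hours_per_patient = unlist(.cfg_get(cfg, "hours_per_patient", c(0.05, 1))),
    r_min = .cfg_get(cfg, "r_min", 2080),
    phi = .cfg_get(cfg, "phi", 0),
    delta = .cfg_get(cfg, "delta", 0.7),
    pi_weight = .cfg_get(cfg, "pi_weight", 0.7)
  ) -> inst
  list(instance = inst, profiles = profiles)
}

#' Run one pipeline stage
#'
#' Stages: `synth` (generate and write a synthetic network), `indices`
#' (index table from profiles), `solve` (both single-objective optima),
#' `pareto` (epsilon sweep, frontier CSV, ideal/knee summary), `baseline`
#' (population-ranked heuristic), `report` (coverage/capacity/allocation
#' tables for the knee solution), `sensitivity` (weight sweep and epsilon
#' grid variation). Artifacts are CSV/JSON files in `output_dir`; a
#' `run_log.json` records the stage, seed, solver gap, and wall-clock time.
#'
#' @param stage one of the stage names above.
#' @param config a list or path to a YAML/JSON configuration.
#' @param output_dir artifact directory (created if absent).
#' @return named character vector of written artifact paths, invisibly.
#' @export
run_stage <- function(stage = c("synth", "indices", "solve", "pareto",
                                "baseline", "report", "sensitivity"),
                      config, output_dir) {
  stage <- match.arg(stage)
  cfg <- .read_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  gap <- .cfg_get(cfg$solver, "gap", 1e-4)
  artifacts <- character(0)
  art <- function(name, path) artifacts[[name]] <<- path

  if (stage == "synth") {
    gen_args <- as.list(.cfg_get(cfg, "generator", list()))
    gen_args$seed <- .cfg_get(gen_args, "seed", .cfg_get(cfg, "seed", 1L))
    gen <- generate_instance(do.call(generator_config, gen_args))
    art("profiles", write_profiles_csv(gen$profiles,
                                       file.path(output_dir, "profiles.csv")))
    art("distances", write_distance_csv(gen$instance$dm,
                                        file.path(output_dir, "distances.csv")))
    scalars <- list(
      budget = as.list(gen$instance$budget),
      hourly_cost = as.list(gen$instance$hourly_cost),
      hours_per_patient = as.list(gen$instance$hours_per_patient),
      r_min = gen$instance$r_min, phi = gen$instance$phi,
      delta = gen$instance$delta, pi_weight = gen$instance$pi_weight
    )
    p <- file.path(output_dir, "scalars.json")
    jsonlite::write_json(scalars, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    art("scalars", p)
  } else if (stage == "indices") {
    pfile <- .cfg_get(cfg$inputs, "profiles",
                      file.path(output_dir, "profiles.csv"))
    idx <- compute_indices(read_profiles_csv(pfile))
    art("indices", write_indices_csv(idx,
                                     file.path(output_dir, "indices.csv")))
  } else {
    ip <- .pipeline_instance(.merge_scalars(cfg, output_dir), output_dir)
    inst <- ip$instance

    if (stage == "solve") {
      for (obj in c("of1", "of2")) {
        sol <- build_and_solve(inst, objective = obj, gap = gap)
        if (is_infeasible(sol)) stop("solve stage: ", sol$message,
                                     call. = FALSE)
        art(paste0("solution_", obj),
            write_solution_json(sol, file.path(output_dir,
                                               paste0("solution_", obj, ".json"))))
        art(paste0("flows_", obj),
            write_flows_csv(sol, file.path(output_dir,
                                           paste0("flows_", obj, ".csv"))))
      }
    } else if (stage == "pareto") {
      fr <- epsilon_sweep(inst,
                          n_points = .cfg_get(cfg$pareto, "n_points", 20),
                          gap = gap)
      art("frontier", write_frontier_csv(fr,
                                         file.path(output_dir, "frontier.csv")))
      summ <- list(ideal = as.list(fr$ideal), knee = fr$points[fr$knee, ],
                   skipped = fr$skipped)
      p <- file.path(output_dir, "pareto_summary.json")
      jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      art("summary", p)
    } else if (stage == "baseline") {
      sol <- population_heuristic(inst, ip$profiles)
      if (is_infeasible(sol)) stop("baseline stage: ", sol$message,
                                   call. = FALSE)
      art("solution", write_solution_json(sol,
                                          file.path(output_dir, "solution_baseline.json")))
      art("flows", write_flows_csv(sol,
                                   file.path(output_dir, "flows_baseline.csv")))
    } else if (stage == "report") {
      fr <- epsilon_sweep(inst,
                          n_points = .cfg_get(cfg$pareto, "n_points", 20),
                          gap = gap)
      sol <- fr$solutions[[fr$knee]]
      radius <- .cfg_get(cfg, "radius_km", 40)
      cov <- coverage_report(inst, sol, radius_km = radius)
      covdf <- cov$per_node
      p <- file.path(output_dir, "coverage.csv")
      write.csv(rbind(covdf[, 1:3],
                      data.frame(node_id = "Avg",
                                 prevention = cov$averages[[1]],
                                 mitigation = cov$averages[[2]])),
                p, row.names = FALSE)
      art("coverage", p)
      p <- file.path(output_dir, "capacity.csv")
      write.csv(capacity_report(inst, sol), p, row.names = FALSE)
      art("capacity", p)
      art("allocation", write_flows_csv(sol,
                                        file.path(output_dir, "allocation.csv")))
    } else if (stage == "sensitivity") {
      sw <- weight_sweep(inst,
                         values = unlist(.cfg_get(cfg$sensitivity, "values",
                                                  seq(0.1, 0.9, by = 0.1))),
                         which = .cfg_get(cfg$sensitivity, "which", "both"),
                         variants = unlist(.cfg_get(cfg$sensitivity, "variants",
                                                    c("of1", "of2"))),
                         n_points = .cfg_get(cfg$pareto, "n_points", 10),
                         radius_km = .cfg_get(cfg, "radius_km", 40),
                         gap = gap)
      p <- file.path(output_dir, "weight_sweep.csv")
      write.csv(sw, p, row.names = FALSE)
      art("weight_sweep", p)
      fr <- epsilon_sweep(inst,
                          n_points = .cfg_get(cfg$pareto, "n_points", 10),
                          gap = gap)
      p <- file.path(output_dir, "epsilon_variation.json")
      jsonlite::write_json(list(max_relative_variation_pct =
                                  epsilon_variation(fr)),
                           p, auto_unbox = TRUE, digits = NA)
      art("epsilon_variation", p)
    }
  }

  log <- list(stage = stage, seed = .cfg_get(cfg, "seed", NA),
              gap = gap, elapsed_s = as.numeric(Sys.time() - t0, units = "secs"),
              artifacts = as.list(artifacts))
  logfile <- file.path(output_dir, "run_log.json")
  prev <- if (file.exists(logfile)) {
    jsonlite::read_json(logfile, simplifyVector = FALSE)
  } else list()
  jsonlite::write_json(c(prev, list(log)), logfile, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(unlist(artifacts))
}

# synth writes its scalar parameters next to the CSVs; later stages pick
# them up unless the config overrides them explicitly.
.merge_scalars <- function(cfg, output_dir) {
  sfile <- file.path(output_dir, "scalars.json")
  if (!file.exists(sfile)) return(cfg)
  sc <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  for (nm in names(sc)) if (is.null(cfg[[nm]])) cfg[[nm]] <- sc[[nm]]
  cfg
}
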