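## End-to-end orchestration: one configuration drives field statistics,
## WHAM profiles with barriers and Eyring rates, the Stark decomposition,
## committor validation, and a stitched multi-stage profile, collected in a
## single reproducible report.

parse_atom_ref <- function(s) {
  parts <- strsplit(trimws(s), ":")[[1]]
  if (length(parts) != 2)
    stop("atom reference must be 'RESID:ATOM', got: ", s)
  c(as.integer(parts[1]), parts[2])
}

#' Validate a pipeline run configuration
#'
#' Schema violations are collected and reported all at once rather than
#' failing on the first. Checks referenced paths, per-stage required keys
#' and that each stage with a temperature sets it explicitly.
#'
#' @param config named list (parsed YAML or built in code).
#' @return `config`, invisibly, on success; otherwise an error listing
#'   every violation.
#' @export
validate_run_config <- function(config) {
  errs <- character()
  need_path <- function(p, what) {
    if (!is.null(p) && !file.exists(p))
      errs <<- c(errs, sprintf("%s path does not exist: %s", what, p))
  }
  if (is.null(config$seed)) errs <- c(errs, "config$seed is required")
  if (!is.null(config$wham)) {
    for (nm in names(config$wham)) {
      st <- config$wham[[nm]]
      if (is.null(st$manifest))
        errs <- c(errs, sprintf("wham stage '%s' needs a manifest", nm))
      else need_path(st$manifest, sprintf("wham stage '%s' manifest", nm))
      if (is.null(st$temperature))
        errs <- c(errs, sprintf("wham stage '%s' needs an explicit temperature", nm))
    }
  }
  if (!is.null(config$fields)) {
    if (is.null(config$fields$axes) || length(config$fields$axes) == 0)
      errs <- c(errs, "fields stage needs at least one axis")
    for (stn in names(config$fields$states))
      for (p in config$fields$states[[stn]])
        need_path(p, sprintf("fields state '%s' frame", stn))
  }
  if (!is.null(config$stark)) {
    need_path(config$stark$rc_table, "stark rc_table")
    need_path(config$stark$ts_table, "stark ts_table")
    for (k in c("f_reactant", "f_ts"))
      if (is.null(config$stark[[k]]))
        errs <- c(errs, paste0("stark stage needs ", k))
  }
  if (!is.null(config$kinetics)) {
    for (i in seq_along(config$kinetics)) {
      k <- config$kinetics[[i]]
      if (is.null(k$temperature))
        errs <- c(errs, sprintf("kinetics entry %d needs an explicit temperature", i))
      if (is.null(k$dg) && is.null(k$rate))
        errs <- c(errs, sprintf("kinetics entry %d needs dg or rate", i))
    }
  }
  if (length(errs) > 0)
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(config)
}

read_window_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("window_id", "center", "force_constant", "series_path") %in%
                  names(man)))
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    sp <- man$series_path[i]
    if (!file.exists(sp)) sp <- file.path(base, sp)
    umbrella_window(bias_spec(man$center[i], man$force_constant[i]),
                    read_window_series(sp))
  })
}

stage_fields <- function(cfg, seed) {
  axes <- lapply(cfg$axes, function(a)
    reaction_axis(parse_atom_ref(a$tail), parse_atom_ref(a$head),
                  label = a$label))
  env <- selection(residues = as.integer(cfg$exclude_residues %||% integer()),
                   mode = "exclude")
  discard <- cfg$discard_fraction %||% 0.5
  states <- lapply(cfg$states, function(paths) {
    frames <- lapply(paths, read_structure)
    per_axis <- lapply(axes, function(ax)
      trajectory_axial_field(frames, ax, env))
    names(per_axis) <- vapply(axes, function(a) a$label, character(1))
    stats_tab <- do.call(rbind, lapply(names(per_axis), function(lb) {
      s <- window_field_statistics(per_axis[[lb]], discard)
      data.frame(axis = lb, mean_MV_per_cm = s$mean, std_MV_per_cm = s$std,
                 n = s$n_samples, stringsAsFactors = FALSE)
    }))
    corr <- if (length(per_axis) >= 2 &&
                all(vapply(per_axis, stats::sd, numeric(1)) > 0))
      field_correlation(per_axis) else NULL
    list(statistics = stats_tab, correlation = corr)
  })
  list(states = states)
}

stage_wham_one <- function(st, seed) {
  windows <- read_window_manifest(st$manifest)
  cfg <- wham_config(
    temperature = st$temperature,
    bin_width = st$bin_width %||% 0.02,
    tolerance = st$tolerance %||% 1e-5,
    n_bootstrap = st$n_bootstrap %||% 100,
    discard_fraction = st$discard_fraction %||% 0.5,
    seed = st$seed %||% seed)
  side <- st$reactant_side %||% "left"
  prof <- bootstrap_pmf(windows, cfg, reactant_side = side)
  bar <- barrier_from_profile(prof, side)
  list(profile = data.frame(bin_center = prof$bin_centers, pmf = prof$pmf,
                            pmf_std = prof$pmf_std,
                            occupied = prof$occupied),
       dg_barrier = bar$dg_barrier, dg_reaction = bar$dg_reaction,
       barrier_std = prof$barrier_std,
       rate_per_s = eyring_rate(bar$dg_barrier, st$temperature),
       overlap_min_adjacent = overlap_diagnostic(windows, cfg)$min_adjacent,
       n_iterations = prof$n_iterations)
}

stage_kinetics <- function(entries) {
  lapply(entries, function(k) {
    rb <- rate_barrier(dg = k$dg, rate = k$rate,
                       temperature = k$temperature,
                       transmission_coefficient = k$kappa %||% 1)
    unclass(rb)
  })
}

stage_stark <- function(cfg) {
  rc <- fit_stark_model(utils::read.csv(cfg$rc_table), cfg$order %||% 1, "RC")
  ts <- fit_stark_model(utils::read.csv(cfg$ts_table), cfg$order %||% 1, "TS")
  dec <- decompose_dynamic_shift(rc, ts, cfg$f_reactant, cfg$f_ts)
  curve <- if (!is.null(cfg$field_grid))
    barrier_vs_field_curve(rc, ts, as.numeric(cfg$field_grid)) else NULL
  list(rc = rc[c("label", "e0", "mu", "alpha", "residual_rms")],
       ts = ts[c("label", "e0", "mu", "alpha", "residual_rms")],
       decomposition = unclass(dec), curve = curve)
}

stage_committor <- function(cfg, seed) {
  pot <- model_potential("double_well",
                         barrier_height = cfg$barrier_height %||% 5,
                         half_separation = cfg$half_separation %||% 1)
  dyn <- langevin_dynamics(temperature = cfg$temperature %||% 343.15,
                           friction = cfg$friction %||% 10,
                           timestep = cfg$timestep %||% 1e-3,
                           max_steps = cfg$max_steps %||% 1e5)
  if (!is.null(cfg$candidates)) {
    v <- validate_ts_ensemble(pot, as.numeric(cfg$candidates),
                              n_shots = cfg$n_shots %||% 100,
                              dynamics = dyn, seed = cfg$seed %||% seed)
    list(p_values = v$p_values, histogram = v$histogram,
         median_p = v$median_p, pass = v$pass)
  } else {
    r <- committor_probability(pot, cfg$start %||% 0,
                               n_shots = cfg$n_shots %||% 100,
                               dynamics = dyn, seed = cfg$seed %||% seed)
    unclass(r)
  }
}

stage_assembly <- function(segments, wham_out) {
  pieces <- lapply(segments, function(sg) {
    st <- wham_out[[sg$stage]]
    if (is.null(st) || !is.null(st$error))
      stop("assembly references missing or failed wham stage: ", sg$stage)
    p <- st$profile[st$profile$occupied, c("bin_center", "pmf")]
    p$pmf <- p$pmf + (sg$offset %||% 0)   # offsets only, never rescaling
    p$stage <- sg$stage
    p
  })
  do.call(rbind, pieces)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages run in dependency order: field statistics over trajectory frames,
#' WHAM profiles with barriers and Eyring rates per window manifest, barrier
#' and rate conversions, the Stark static/dynamic decomposition, committor
#' validation, and an optional stitched multi-stage profile whose segment
#' offsets are explicit configuration numbers (assembly offsets, never
#' rescales). Stages named in `config$optional_stages` (default:
#' `"committor"`) report their error and let the run continue; any other
#' stage failure aborts.
#'
#' @param config named list or path to a YAML file; see
#'   [validate_run_config()].
#' @return List of class `run_report`: `provenance` (config digest, seed,
#'   constants, package version) and one entry per enabled stage. The
#'   report is a pure function of the configuration and inputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  seed <- as.integer(config$seed)
  optional <- config$optional_stages %||% "committor"
  report <- list(provenance = list(
    config_digest = config_digest(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("fieldcat")),
    constants = list(R_kcal = fc_constants$R_kcal,
                     coulomb_MV_cm = fc_constants$coulomb_MV_cm,
                     debye_MV_cm_kcal = fc_constants$debye_MV_cm_kcal)))
  run_stage <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e) {
      if (name %in% optional) list(failed = TRUE, error = conditionMessage(e))
      else stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
                call. = FALSE)
    })
    out
  }
  if (!is.null(config$fields))
    report$fields <- run_stage("fields",
                               function() stage_fields(config$fields, seed))
  if (!is.null(config$wham)) {
    report$wham <- list()
    for (nm in names(config$wham))
      report$wham[[nm]] <- run_stage(
        paste0("wham:", nm),
        function() stage_wham_one(config$wham[[nm]], seed))
  }
  if (!is.null(config$kinetics))
    report$kinetics <- run_stage("kinetics",
                                 function() stage_kinetics(config$kinetics))
  if (!is.null(config$stark))
    report$stark <- run_stage("stark", function() stage_stark(config$stark))
  if (!is.null(config$committor))
    report$committor <- run_stage(
      "committor", function() stage_committor(config$committor, seed))
  if (!is.null(config$assembly))
    report$global_profile <- run_stage(
      "assembly", function() stage_assembly(config$assembly, report$wham))
  class(report) <- "run_report"
  report
}

#' Generate a complete synthetic demo input set plus run configuration
#'
#' Writes everything [run_pipeline()] consumes into `dir`: umbrella-window
#' series files with a manifest CSV sampled exactly from a 5 kcal/mol
#' double well under 21 harmonic windows, XYZQ trajectory frames for a
#' reactant-like state (mean axial field -37.1 MV/cm, s.d. 11.1) and a
#' transition-state-like state (-52.5, s.d. 10.2), Stark scan tables from
#' planted linear+quadratic state models with 0.05 kcal/mol Gaussian noise,
#' kinetics and committor settings, and `config.yaml` tying them together.
#' A manifest JSON records the generator spec and seed.
#'
#' @param dir output directory (created).
#' @param seed integer seed controlling every random draw.
#' @param n_window_samples samples per umbrella window.
#' @param n_state_frames trajectory frames per field state.
#' @param n_bootstrap bootstrap replicates the config requests.
#' @return The configuration list (also written as `config.yaml`),
#'   invisibly.
#' @export
write_demo_inputs <- function(dir, seed = 1L, n_window_samples = 3000,
                              n_state_frames = 200, n_bootstrap = 20) {
  dir.create(file.path(dir, "windows"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  seed <- as.integer(seed)

  pot <- model_potential("double_well", barrier_height = 5,
                         half_separation = 1)
  centers <- seq(-1.25, 1.25, length.out = 21)
  biases <- lapply(centers, function(c0) bias_spec(c0, 50))
  wins <- sample_umbrella_windows(pot, biases, temperature = 343.15,
                                  n_samples = n_window_samples,
                                  seed = seed)
  man <- data.frame(window_id = seq_along(wins), center = centers,
                    force_constant = 50,
                    series_path = sprintf("windows/win_%02d.dat",
                                          seq_along(wins)))
  for (i in seq_along(wins)) {
    s <- wins[[i]]$series
    writeLines(c("# time_ps coordinate_A",
                 sprintf("%.6f %.9f", s$time, s$value)),
               file.path(dir, man$series_path[i]))
  }
  utils::write.csv(man, file.path(dir, "windows.csv"), row.names = FALSE)

  set.seed(seed + 1L)
  schedules <- list(RC = stats::rnorm(n_state_frames, -37.1, 11.1),
                    TS1 = stats::rnorm(n_state_frames, -52.5, 10.2))
  state_paths <- lapply(names(schedules), function(st) {
    frames <- gen_prescribed_field_traj(schedules[[st]], seed = seed + 2L)
    paths <- file.path(dir, sprintf("frames/%s_%04d.xyzq", st,
                                    seq_along(frames)))
    for (i in seq_along(frames)) write_xyzq(frames[[i]], paths[i])
    paths
  })
  names(state_paths) <- names(schedules)

  set.seed(seed + 3L)
  fields <- seq(-75, 75, length.out = 7)
  rc_true <- stark_model("RC", 0, 2.0, 0.4)
  ts_true <- stark_model("TS1", 15, 6.0, 1.0)
  utils::write.csv(
    data.frame(field_MV_per_cm = fields,
               energy_kcal_per_mol = rc_true$energy(fields) +
                 stats::rnorm(7, 0, 0.05)),
    file.path(dir, "stark_rc.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(field_MV_per_cm = fields,
               energy_kcal_per_mol = ts_true$energy(fields) +
                 stats::rnorm(7, 0, 0.05)),
    file.path(dir, "stark_ts.csv"), row.names = FALSE)

  config <- list(
    seed = seed,
    fields = list(
      discard_fraction = 0.5,
      exclude_residues = list(),
      axes = list(list(label = "O1-C1", tail = "1:O1", head = "1:C1")),
      states = state_paths),
    wham = list(step = list(
      manifest = file.path(dir, "windows.csv"),
      temperature = 343.15, bin_width = 0.02, n_bootstrap = n_bootstrap,
      discard_fraction = 0, reactant_side = "left", seed = seed)),
    kinetics = list(list(dg = 10.7, temperature = 298.15),
                    list(rate = 1.6, temperature = 298.15),
                    list(rate = 0.3, temperature = 298.15)),
    stark = list(rc_table = file.path(dir, "stark_rc.csv"),
                 ts_table = file.path(dir, "stark_ts.csv"),
                 order = 2, f_reactant = -37.1, f_ts = -52.5,
                 field_grid = seq(-60, 60, by = 20)),
    committor = list(barrier_height = 5, half_separation = 1, start = 0,
                     n_shots = 150, max_steps = 2e4,
                     temperature = 343.15, seed = seed),
    assembly = list(list(stage = "step", offset = 0)))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  write_manifest(dir, list(generator = "write_demo_inputs", seed = seed,
                           n_window_samples = n_window_samples,
                           n_state_frames = n_state_frames))
  invisible(config)
}

#' Write a run report as JSON
#'
#' The body contains no timestamps, so regenerating the report from the
#' same configuration and inputs yields a byte-identical file.
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(path)
}
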