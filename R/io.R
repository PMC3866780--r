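#' Read compound definitions from a config file
#'
#' YAML (default) or JSON, dispatched on the file extension. Each entry needs
#' a name, half-lives and dissolution time in minutes; experimental peak
#' statistics, display digits, hydrophobic flags and published reference
#' values are optional.
#'
#' @param path Config file path.
#' @return Named list of [pk_compound] objects.
#' @export
read_compounds_config <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$compounds)) stop("config has no 'compounds' list", call. = FALSE)
  cl <- lapply(cfg$compounds, function(x) {
    dd <- x$display_digits %||% list(gi = 2, plasma = 2)
    pk_compound(
      name = x$name,
      t_half_gi = x$t_half_gi_min,
      t_half_plasma = x$t_half_plasma_min,
      dissolution_time = x$dissolution_time_min,
      cmax_exp = x$cmax_exp_ng_ml %||% NA_real_,
      cmax_exp_sd = x$cmax_exp_sd_ng_ml %||% NA_real_,
      tmax_exp = x$tmax_exp_min %||% NA_real_,
      display_digits = c(gi = dd$gi, plasma = dd$plasma),
      hydrophobic = x$hydrophobic %||% FALSE,
      hydrophobic_ref = x$hydrophobic_ref %||% NA_character_,
      reported = x$reported
    )
  })
  stats::setNames(cl, vapply(cl, `[[`, character(1), "name"))
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

run_config_keys <- c("compounds_file", "strategy", "seed", "shortrange",
                     "longrange", "synth", "outdir")

#' Read and validate a run configuration
#'
#' The run config drives [run_pipeline()]: compound file, hydrophobic
#' strategy, seed, short- and long-range grids and the synthetic-study
#' settings. Unknown top-level keys are rejected so typos fail loudly before
#' any computation.
#'
#' @param path Run-config file (YAML or JSON); default: bundled config.
#' @return Validated config list of class `pk_config`, with compounds loaded.
#' @export
read_run_config <- function(path = system.file("extdata",
                                               "default_config.yaml",
                                               package = "ncpk")) {
  cfg <- read_config_file(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cf <- cfg$compounds_file %||% "compounds.yaml"
  if (!file.exists(cf)) cf <- file.path(dirname(path), cf)
  cfg$compounds <- read_compounds_config(cf)
  cfg$strategy <- cfg$strategy %||% "output_scale"
  if (!cfg$strategy %in% c("output_scale", "slow_elimination")) {
    stop("unknown hydrophobic-adjustment strategy: ", cfg$strategy,
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$shortrange <- utils::modifyList(list(t_end_min = 30, dt_min = 0.01),
                                      cfg$shortrange %||% list())
  cfg$longrange <- utils::modifyList(
    list(dt_h = 0.01, horizon_periods = 15, burn_in_cycles = 10,
         base_dose_ug_ml = 0.49, pulse_shape = "rectangular",
         pulse_width_h = 0.5, periods_h = list()),
    cfg$longrange %||% list())
  cfg$synth <- utils::modifyList(
    list(cv = 0.05, n_times = 25, n_replicates = 20),
    cfg$synth %||% list())
  structure(cfg, class = "pk_config")
}

# Content hash of a config for output provenance: canonical JSON -> md5.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

csv_header <- function(meta) {
  c(sprintf("# ncpk %s", as.character(utils::packageVersion("ncpk"))),
    vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]),
           character(1)))
}

#' Write a table as CSV with a commented metadata header
#'
#' Deterministic dialect: period decimal separator, UTF-8, `#`-prefixed
#' header comments, units embedded in column names by the callers.
#'
#' @param df data.frame to write.
#' @param path Output file.
#' @param meta Named list of metadata recorded as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_csv_commented <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(csv_header(meta), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_commented()]
#'
#' @param path File path.
#' @return data.frame (header comments skipped).
#' @export
read_csv_commented <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a short-range trajectory as CSV
#'
#' Columns `time_min`, `gi_ng_per_ml`, `plasma_ng_per_ml`,
#' `metabolite_ng_per_ml`; parameters and adjustment strategy go into the
#' commented header.
#'
#' @param traj A `pk_trajectory`.
#' @param path Output file.
#' @param meta Extra metadata for the header.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, meta = list()) {
  stopifnot(inherits(traj, "pk_trajectory"))
  out <- data.frame(
    time_min = traj$time,
    gi_ng_per_ml = traj$gi,
    plasma_ng_per_ml = traj$plasma,
    metabolite_ng_per_ml = traj$metabolite
  )
  meta <- c(meta, list(strategy = attr(traj, "strategy"),
                       plasma_output_factor = attr(traj, "plasma_output_factor")))
  write_csv_commented(out, path, meta)
}

#' Write synthetic observations as CSV plus a JSON truth sidecar
#'
#' The CSV uses the trajectory dialect (`time_min`, `observed_ng_per_ml`);
#' the sidecar (`<path>.json`) carries the true parameters, the noise model
#' and the clipping rate.
#'
#' @param obs A `pk_observations`.
#' @param path CSV output file.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(obs, path) {
  stopifnot(inherits(obs, "pk_observations"))
  df <- data.frame(time_min = obs$times, observed_ng_per_ml = obs$observed)
  write_csv_commented(df, path,
                      meta = list(seed = obs$noise$seed,
                                  noise = obs$noise$type,
                                  cv_or_sd = obs$noise$cv_or_sd))
  sidecar <- list(truth = obs$truth,
                  noise = unclass(obs$noise),
                  clip_rate = obs$clip_rate)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read observations written by [write_observations_csv()]
#'
#' @param path CSV path (sidecar is `<path>.json`).
#' @return A `pk_observations` object.
#' @export
read_observations_csv <- function(path) {
  df <- read_csv_commented(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(times = df$time_min, observed = df$observed_ng_per_ml,
         truth = as.list(side$truth),
         noise = structure(as.list(side$noise), class = "pk_noise"),
         clip_rate = side$clip_rate),
    class = "pk_observations"
  )
}

#' Run the analysis pipeline
#'
#' Executes the selected stages over the configured compounds and writes
#' their artifacts (CSV/JSON) under the output directory. Stages:
#' `"rates"` (rate-table and fold reproduction), `"shortrange"`
#' (GI/plasma/metabolite trajectories), `"longrange"` (periodic-dosing
#' simulations and limit-cycle metrics), `"validate"` (predicted-versus-
#' experimental table), `"synth"` (seeded recovery study). Every output file
#' records the config hash; rerunning with the same config and seed is
#' byte-identical.
#'
#' @param config A `pk_config` from [read_run_config()].
#' @param stages Subset of the stage names, in any order; executed in
#'   pipeline order.
#' @param outdir Output directory (overrides the config's).
#' @return List with `status` (`"ok"` or `"nothing to do"`) and `files`
#'   (paths written), invisibly.
#' @export
run_pipeline <- function(config = read_run_config(),
                         stages = c("rates", "shortrange", "longrange",
                                    "validate", "synth"),
                         outdir = NULL) {
  stopifnot(inherits(config, "pk_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  compounds <- config$compounds
  if (length(compounds) == 0) {
    message("nothing to do: empty compound list")
    return(invisible(list(status = "nothing to do", files = character(0))))
  }
  outdir <- outdir %||% config$outdir %||% "results"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta0 <- list(config_md5 = hash, seed = config$seed,
                strategy = config$strategy)
  files <- character(0)
  emit <- function(p) files <<- c(files, p)
  safe <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

  order <- c("rates", "shortrange", "longrange", "validate", "synth")
  for (stage in intersect(order, stages)) {
    if (stage == "rates") {
      p <- file.path(outdir, "rates.csv")
      write_csv_commented(rate_table(compounds), p, meta0)
      emit(p)
      folds <- fold_table(compounds)
      p <- file.path(outdir, "folds.csv")
      write_csv_commented(folds, p, meta0)
      emit(p)
    } else if (stage == "shortrange") {
      for (cmp in compounds) {
        traj <- shortrange_trajectory(
          cmp, compounds, t_end = config$shortrange$t_end_min,
          dt = config$shortrange$dt_min, strategy = config$strategy)
        p <- file.path(outdir, sprintf("shortrange_%s.csv", safe(cmp$name)))
        write_trajectory_csv(traj, p, c(meta0, list(compound = cmp$name)))
        emit(p)
      }
    } else if (stage == "longrange") {
      lr <- config$longrange
      t_ref <- min(vapply(compounds, `[[`, numeric(1), "dissolution_time"))
      cycles <- list()
      for (cmp in compounds) {
        period <- lr$periods_h[[cmp$name]] %||% 24
        scale <- 1 / dissolution_fold(cmp$dissolution_time, t_ref)
        reg <- dose_regimen(lr$base_dose_ug_ml, period,
                            pulse_shape = lr$pulse_shape,
                            pulse_width = lr$pulse_width_h,
                            dissolution_scale = scale)
        st <- simulate_longrange(cmp, reg,
                                 horizon = lr$horizon_periods * period,
                                 dt = lr$dt_h)
        p <- file.path(outdir, sprintf("longrange_%s.csv", safe(cmp$name)))
        write_csv_commented(
          data.frame(time_h = st$times, gi_ug_per_ml = st$gi,
                     plasma_ug_per_ml = st$plasma),
          p, c(meta0, list(compound = cmp$name, period_h = period,
                           dose_scale = scale)))
        emit(p)
        mt <- limit_cycle_metrics(st, reg, burn_in_cycles = lr$burn_in_cycles)
        cycles[[cmp$name]] <- data.frame(
          compound = cmp$name, period_h = period,
          detected_period_h = mt$detected_period,
          peak_gi = mt$peak_gi, peak_plasma = mt$peak_plasma,
          convergence_ratio = mt$convergence_ratio)
      }
      p <- file.path(outdir, "limit_cycles.csv")
      write_csv_commented(do.call(rbind, cycles), p, meta0)
      emit(p)
    } else if (stage == "validate") {
      vt <- build_validation_table(compounds, strategy = config$strategy)
      p <- file.path(outdir, "validation.csv")
      write_csv_commented(as.data.frame(vt), p, meta0)
      emit(p)
      p <- file.path(outdir, "validation.json")
      jsonlite::write_json(as.data.frame(vt), p, auto_unbox = TRUE,
                           digits = NA, dataframe = "rows")
      emit(p)
    } else if (stage == "synth") {
      sy <- config$synth
      rs <- recovery_study(
        k_gi = 2.88, k_plasma = 2.1, c0 = 1.0,
        times = default_schedule(n = sy$n_times),
        cv = sy$cv, n_replicates = sy$n_replicates, seed = config$seed)
      p <- file.path(outdir, "recovery.csv")
      write_csv_commented(rs, p, meta0)
      emit(p)
    }
  }
  invisible(list(status = "ok", files = files))
}

# Fold factors and refined rates for all compounds with complete
# experimental data, from printed rounded inputs.
fold_table <- function(compounds) {
  rows <- lapply(compounds, function(cmp) {
    rep <- cmp$reported
    if (is.na(cmp$cmax_exp) || is.na(cmp$tmax_exp) || is.null(rep$cmax_pre)) {
      return(NULL)
    }
    fold <- fold_factor(cmp$tmax_exp, rep$cmax_pre, rep$tmax_pre,
                        cmp$cmax_exp)
    mag <- shortrange_rate_magnitudes(cmp)
    data.frame(compound = cmp$name, fold = fold,
               k_gi_refined = mag$k_gi / fold,
               k_plasma_refined = mag$k_plasma / fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}
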