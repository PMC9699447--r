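#' Define a temperature-sweep experiment
#'
#' One config describes a full factorial experiment: every combination of
#' repeat unit, chain length, target temperature and seed becomes one
#' independent quench run (fresh high-temperature coil, quenched to the
#' target; a continuous cooling ramp is available via `ramp = TRUE`).
#'
#' @param units character vector of repeat-unit specs (e.g. `"H3N1P1"`).
#' @param lengths integer vector of chain lengths.
#' @param Tstar_grid reduced target temperatures, each in (0, 10).
#' @param seeds integer vector of distinct seeds (one independent run each).
#' @param steps_per_leg production-leg step count.
#' @param equilibration_steps steps of the initial high-temperature leg
#'   (default `steps_per_leg %/% 4`).
#' @param Tstar_high temperature of the initial coil leg (default 1.5, or
#'   `max(Tstar_grid)` if larger).
#' @param equilibration_fraction fraction of the production leg discarded
#'   from averages.
#' @param snapshot_stride,sample_stride,dt,tau passed to [run_protocol()].
#' @param ramp if `TRUE`, one run per (unit, length, seed) visits all of
#'   `Tstar_grid` in decreasing order as successive legs of a single
#'   trajectory instead of independent quenches.
#' @param output_dir where [run_experiment()] writes artifacts.
#' @param ff force field (overrides applied here affect every run).
#' @return object of class `hnp_experiment_config`.
#' @export
experiment_config <- function(units, lengths, Tstar_grid, seeds = 1L,
                              steps_per_leg = 1e5,
                              equilibration_steps = max(1L, steps_per_leg %/% 4L),
                              Tstar_high = max(1.5, Tstar_grid),
                              equilibration_fraction = 0.5,
                              snapshot_stride = 500L, sample_stride = 50L,
                              dt = 2.5, tau = 25,
                              ramp = FALSE, output_dir = tempfile("hnpmd_"),
                              ff = forcefield()) {
  stopifnot(length(units) >= 1, length(lengths) >= 1,
            length(Tstar_grid) >= 1, all(Tstar_grid > 0), all(Tstar_grid < 10),
            length(seeds) >= 1, !anyDuplicated(seeds))
  structure(list(
    units = units, lengths = as.integer(lengths), Tstar_grid = Tstar_grid,
    seeds = as.integer(seeds), steps_per_leg = as.integer(steps_per_leg),
    equilibration_steps = as.integer(equilibration_steps),
    Tstar_high = Tstar_high,
    equilibration_fraction = equilibration_fraction,
    snapshot_stride = as.integer(snapshot_stride),
    sample_stride = as.integer(sample_stride), dt = dt, tau = tau,
    ramp = isTRUE(ramp), output_dir = output_dir, ff = ff),
    class = "hnp_experiment_config")
}

#' Read an experiment config from JSON
#'
#' @param path JSON file whose keys mirror [experiment_config()] arguments.
#' @return an `hnp_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- x[intersect(names(x), names(formals(experiment_config)))]
  do.call(experiment_config, args)
}

#' The run matrix of an experiment
#'
#' @param config an `hnp_experiment_config`.
#' @return data.frame with one row per planned run: `run_id`, `unit`,
#'   `length`, `Tstar` (NA when ramping), `seed`.
#' @export
experiment_plan <- function(config) {
  stopifnot(inherits(config, "hnp_experiment_config"))
  if (config$ramp) {
    g <- expand.grid(unit = config$units, length = config$lengths,
                     seed = config$seeds, stringsAsFactors = FALSE)
    g$Tstar <- NA_real_
  } else {
    g <- expand.grid(unit = config$units, length = config$lengths,
                     Tstar = config$Tstar_grid, seed = config$seeds,
                     stringsAsFactors = FALSE)
  }
  g$run_id <- sprintf("%s_N%d_T%s_s%d", g$unit, g$length,
                      ifelse(is.na(g$Tstar), "ramp", format(g$Tstar)), g$seed)
  g[, c("run_id", "unit", "length", "Tstar", "seed")]
}

.run_seed <- function(base_seed, unit, length, Tstar) {
  # distinct, reproducible, < 2^31 sub-seed per factor combination
  key <- paste(unit, length, format(Tstar))
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 31 + 1))
  (as.integer(base_seed) * 7919L + as.integer(h %% 100000)) %% 2147483647L
}

#' Run a temperature-sweep experiment
#'
#' Executes every run of [experiment_plan()], writes one XYZ trajectory and
#' JSON sidecar per run plus a long-format `summary.csv` (one row per run
#' and temperature), per-run stem histograms in `stems.csv`, and a
#' `manifest.json` keyed by a hash of the config.  Already-completed runs
#' (present in the manifest with matching config hash) are skipped, making
#' interrupted experiments resumable.
#'
#' @param config an `hnp_experiment_config`.
#' @param dry_run print the run matrix and return it without executing.
#' @param keep_trajectories write XYZ/sidecar files (default `TRUE`; the
#'   summaries are always written).
#' @param verbose log each run to stderr.
#' @return invisibly, a list with `summary` (data.frame), `stems`
#'   (data.frame), `manifest` (list), `failed` (character vector of run
#'   ids).  Errors in single runs are recorded and do not abort the rest.
#' @export
run_experiment <- function(config, dry_run = FALSE, keep_trajectories = TRUE,
                           verbose = TRUE) {
  plan <- experiment_plan(config)
  if (dry_run) {
    print(plan)
    return(invisible(plan))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_for_hash <- unclass(config)
  cfg_for_hash$output_dir <- NULL
  cfg_for_hash$ff <- unclass(cfg_for_hash$ff)
  cfg_for_hash$ff$epsilon_matrix <- as.numeric(cfg_for_hash$ff$epsilon_matrix)
  cfg_for_hash$ff$lambda_matrix <- as.numeric(cfg_for_hash$ff$lambda_matrix)
  cfg_hash <- .config_hash(cfg_for_hash)
  manifest_path <- file.path(config$output_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(m$config_hash, cfg_hash)) m
    else list(config_hash = cfg_hash, runs = list())
  } else list(config_hash = cfg_hash, runs = list())
  done <- names(manifest$runs)

  summaries <- list(); stem_rows <- list(); failed <- character(0)
  for (k in seq_len(nrow(plan))) {
    row <- plan[k, ]
    sum_path <- file.path(config$output_dir, paste0(row$run_id, "_summary.csv"))
    stem_path <- file.path(config$output_dir, paste0(row$run_id, "_stems.csv"))
    if (row$run_id %in% done && file.exists(sum_path)) {
      summaries[[k]] <- read.csv(sum_path)
      if (file.exists(stem_path)) stem_rows[[k]] <- read.csv(stem_path)
      if (verbose) message("[skip] ", row$run_id, " (manifest)")
      next
    }
    seed_k <- .run_seed(row$seed, row$unit, row$length, row$Tstar)
    sched <- if (config$ramp) {
      rbind(data.frame(Tstar = config$Tstar_high,
                       steps = config$equilibration_steps),
            data.frame(Tstar = sort(config$Tstar_grid, decreasing = TRUE),
                       steps = config$steps_per_leg))
    } else {
      data.frame(Tstar = c(config$Tstar_high, row$Tstar),
                 steps = c(config$equilibration_steps, config$steps_per_leg))
    }
    if (verbose)
      message(sprintf("[run ] %s (seed %d -> %d)", row$run_id, row$seed, seed_k))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      proto <- run_protocol(sched, dt = config$dt, tau = config$tau,
                            seed = seed_k,
                            snapshot_stride = config$snapshot_stride,
                            sample_stride = config$sample_stride)
      traj <- run_quench(row$unit, proto, ff = config$ff, n = row$length)
      legs <- seq(2, nrow(sched))   # leg 1 is the high-T coil equilibration
      s <- sweep_summary(traj, leg = legs,
                         equilibration_fraction = config$equilibration_fraction,
                         boot_seed = seed_k)
      s <- cbind(run_id = row$run_id, unit = row$unit, length = row$length,
                 seed = row$seed, s)
      sd <- do.call(rbind, lapply(legs, function(l) {
        h <- stem_distribution(traj, leg = l,
               equilibration_fraction = config$equilibration_fraction)
        if (nrow(h) == 0) return(NULL)
        cbind(run_id = row$run_id, unit = row$unit, length = row$length,
              seed = row$seed, Tstar = sched$Tstar[l], h)
      }))
      if (keep_trajectories) {
        write_xyz(traj, file.path(config$output_dir, paste0(row$run_id, ".xyz")))
        write_run_metadata(traj, file.path(config$output_dir,
                                           paste0(row$run_id, ".json")))
      }
      list(summary = s, stems = sd)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, row$run_id)
      warning("run ", row$run_id, " failed: ", conditionMessage(res))
      next
    }
    write.csv(res$summary, sum_path, row.names = FALSE)
    if (!is.null(res$stems)) write.csv(res$stems, stem_path, row.names = FALSE)
    summaries[[k]] <- res$summary
    stem_rows[[k]] <- res$stems
    manifest$runs[[row$run_id]] <- list(
      seed = row$seed, derived_seed = seed_k,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  summary <- do.call(rbind, summaries)
  stems <- do.call(rbind, stem_rows)
  write.csv(summary, file.path(config$output_dir, "summary.csv"),
            row.names = FALSE)
  if (!is.null(stems))
    write.csv(stems, file.path(config$output_dir, "stems.csv"),
              row.names = FALSE)
  if (length(failed))
    warning(length(failed), " run(s) failed: ", paste(failed, collapse = ", "))
  invisible(list(summary = summary, stems = stems, manifest = manifest,
                 failed = failed))
}

.config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  # stable content hash without extra dependencies
  tf <- tempfile()
  writeLines(json, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Rank chain compositions by an observable
#'
#' Compares repeat units at one temperature: per-unit means over runs
#' (seeds) with percentile bootstrap confidence intervals.  Ties in the
#' mean are broken by unit name.
#'
#' @param results long-format summary data.frame from [run_experiment()]
#'   (or any data.frame with columns `unit`, `Tstar` and the observable).
#' @param observable column name, e.g. `"P"`, `"Rg"`,
#'   `"per_bond_nonbonded"`, `"contacts"`.
#' @param Tstar temperature to compare at (matched within 1e-9).
#' @param decreasing rank direction (default `TRUE`: largest first).
#' @param n_boot,boot_seed bootstrap resamples over runs and seed.
#' @return data.frame ranked by mean: `unit`, `mean`, `lo`, `hi`
#'   (95% bootstrap CI), `n_runs`.
#' @export
compare_compositions <- function(results, observable, Tstar,
                                 decreasing = TRUE, n_boot = 200L,
                                 boot_seed = 1L) {
  stopifnot(is.data.frame(results))
  if (!observable %in% names(results))
    stop("observable ", sQuote(observable), " not in results; available: ",
         paste(setdiff(names(results),
                       c("run_id", "unit", "length", "seed", "Tstar", "leg")),
               collapse = ", "))
  sub <- results[abs(results$Tstar - Tstar) < 1e-9, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no rows at Tstar = ", Tstar, "; available: ",
         paste(sort(unique(results$Tstar)), collapse = ", "))
  set.seed(as.integer(boot_seed))
  rows <- lapply(split(sub, sub$unit), function(d) {
    x <- d[[observable]]
    boots <- replicate(n_boot, mean(sample(x, replace = TRUE)))
    data.frame(unit = d$unit[1], mean = mean(x),
               lo = unname(quantile(boots, 0.025)),
               hi = unname(quantile(boots, 0.975)), n_runs = length(x))
  })
  out <- do.call(rbind, rows)
  out <- out[order(if (decreasing) -out$mean else out$mean, out$unit), ]
  rownames(out) <- NULL
  out
}
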