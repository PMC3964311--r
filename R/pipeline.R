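# Pipeline layer: simulate -> preprocess -> decompose -> report, driven by a
# plain-text YAML configuration and a master seed. Child seeds for each
# (well, replicate) stream come from split_seed().

#' Default pipeline configuration
#'
#' The configuration mirrors the study design: an IPTG titration
#' (7 log-spaced points over 0.0625--25 uM) at one Dox level with
#' triplicates, plus one uninduced (Dox 0) control per replicate for the
#' positive gate. Any [circuit_params()] field can be overridden under
#' `$simulator`.
#'
#' @param architecture circuit architecture.
#' @param seed master seed.
#' @param dox Dox concentration (ng/ml); 5000 is the saturating ("high")
#'   condition, 625 the "low" one.
#' @param n_cells events per well.
#' @param replicates number of replicates.
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(architecture = "negative_feedback",
                                    seed = 1L, dox = 5000,
                                    n_cells = 20000L, replicates = 3L) {
  structure(list(
    seed = as.integer(seed),
    simulator = list(
      architecture = architecture,
      n_cells = as.integer(n_cells),
      replicates = as.integer(replicates),
      dox = dox,
      iptg_grid = signif(exp(seq(log(0.0625), log(25), length.out = 7)), 4)),
    preprocess = list(
      positive_quantile = 0.995,
      trim_k = 2.5,
      scatter_keep = 0.95,
      background_floor = NA),
    decompose = list(mode = "log")),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' Configurations are plain YAML; values absent from the file fall back to
#' [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`; for
#'   `write_pipeline_config`, `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config(
    architecture = user$simulator$architecture %||% "negative_feedback")
  cfg <- utils::modifyList(base, user)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# circuit_params from the simulator section (unknown keys are ignored).
config_circuit_params <- function(config) {
  sim <- config$simulator
  keep <- intersect(names(sim), names(formals(circuit_params)))
  do.call(circuit_params, sim[keep])
}

#' Simulate the full titration layout to disk
#'
#' Writes one event CSV per well and replicate over the configured IPTG grid
#' plus one uninduced (Dox 0) control per replicate, a `manifest.csv`
#' describing them (with the `fully_induced` flag on the highest-IPTG well
#' of each replicate), the resolved configuration (`config.yaml`) and a
#' `provenance.txt` (config MD5, master seed, package version). Rerunning
#' with the same configuration and seed reproduces the files byte for byte.
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory (created if needed).
#' @return The manifest data frame, invisibly; its rows carry the file
#'   paths.
#' @export
run_simulate <- function(config = default_pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("run_simulate: cannot create output directory ", outdir,
         call. = FALSE)
  params <- config_circuit_params(config)
  sim <- config$simulator
  arch_tag <- if (params$architecture == "negative_feedback") "nf" else "sr"

  manifest <- list()
  stream <- 0L
  for (r in seq_len(sim$replicates)) {
    rep_id <- paste0("r", r)
    # uninduced control for the positive gate
    stream <- stream + 1L
    ctrl_id <- sprintf("%s_d%g_%s_ctrl", arch_tag, sim$dox, rep_id)
    ctrl <- simulate_population(params,
                                well_condition(iptg = 0, dox = 0,
                                               replicate = rep_id),
                                sim$n_cells, split_seed(config$seed, stream),
                                well_id = ctrl_id)
    ctrl_file <- file.path(outdir, paste0(ctrl_id, ".csv"))
    write_events(ctrl, ctrl_file)
    manifest[[length(manifest) + 1L]] <-
      data.frame(well_id = ctrl_id, file = basename(ctrl_file),
                 iptg_uM = 0, dox_ng_ml = 0, replicate = rep_id,
                 role = "control", fully_induced = FALSE,
                 stringsAsFactors = FALSE)
    for (k in seq_along(sim$iptg_grid)) {
      stream <- stream + 1L
      iptg <- sim$iptg_grid[k]
      well_id <- sprintf("%s_d%g_%s_w%02d", arch_tag, sim$dox, r, k)
      ev <- simulate_population(params,
                                well_condition(iptg = iptg, dox = sim$dox,
                                               replicate = rep_id),
                                sim$n_cells, split_seed(config$seed, stream),
                                well_id = well_id)
      f <- file.path(outdir, paste0(well_id, ".csv"))
      write_events(ev, f)
      manifest[[length(manifest) + 1L]] <-
        data.frame(well_id = well_id, file = basename(f),
                   iptg_uM = iptg, dox_ng_ml = sim$dox, replicate = rep_id,
                   role = "sample",
                   fully_induced = k == length(sim$iptg_grid),
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  data.table::fwrite(manifest, file.path(outdir, "manifest.csv"))

  cfg_path <- file.path(outdir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  writeLines(c(sprintf("package_version: %s",
                       as.character(utils::packageVersion("reporternoise"))),
               sprintf("master_seed: %d", config$seed),
               sprintf("config_md5: %s",
                       unname(tools::md5sum(cfg_path)))),
             file.path(outdir, "provenance.txt"))
  attr(manifest, "outdir") <- outdir
  invisible(manifest)
}

#' Preprocess and decompose a simulated or measured run
#'
#' Reads the wells named in a run's manifest, applies the fixed
#' preprocessing chain (scatter gate, positive gate against the replicate's
#' uninduced control on the constitutive channel, optional background floor,
#' s.d. trim), decomposes every replicate's titration, and writes a tidy
#' `results.csv` plus the two standard plot views (PDF). A replicate whose
#' calibration is undefined is reported with a warning and skipped; the
#' other replicates are still processed.
#'
#' @param config a `pipeline_config`.
#' @param rundir directory produced by [run_simulate()] (or laid out the
#'   same way: event CSVs plus `manifest.csv`).
#' @param make_plots write `noise_vs_iptg.pdf` and `noise_vs_mean.pdf`.
#' @return The `noise_breakdown`, invisibly.
#' @export
run_decompose <- function(config, rundir, make_plots = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- as.data.frame(data.table::fread(file.path(rundir,
                                                        "manifest.csv"),
                                              showProgress = FALSE))
  params_arch <- config$simulator$architecture
  x_ch <- regulated_channel(params_arch)
  y_ch <- constitutive_channel(params_arch)
  pp <- config$preprocess

  wells <- list()
  for (rep_id in unique(manifest$replicate)) {
    sub <- manifest[manifest$replicate == rep_id, ]
    ctrl_row <- sub[sub$role == "control", ]
    ctrl <- if (nrow(ctrl_row))
      read_events(file.path(rundir, ctrl_row$file[1])) else NULL
    for (i in which(sub$role == "sample")) {
      ev <- read_events(file.path(rundir, sub$file[i]))
      ev <- preprocess_events(
        ev, control = ctrl, constitutive = y_ch,
        positive_quantile = pp$positive_quantile,
        trim_k = pp$trim_k, scatter_keep = pp$scatter_keep,
        background_floor = if (is.na(pp$background_floor %||% NA)) NULL
                           else pp$background_floor,
        floor_channel = x_ch)
      wells[[length(wells) + 1L]] <- ev
    }
  }

  # decompose replicate by replicate so one undefined calibration does not
  # take down the others
  reps <- unique(vapply(wells, function(w) w$replicate[1], character(1)))
  parts <- list()
  for (rep_id in reps) {
    rep_wells <- Filter(function(w) w$replicate[1] == rep_id, wells)
    bd <- tryCatch(
      decompose_series(rep_wells, x_channel = x_ch, y_channel = y_ch,
                       mode = config$decompose$mode),
      error = function(e) {
        warning("run_decompose: replicate '", rep_id, "' skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(bd)) parts[[length(parts) + 1L]] <- bd
  }
  if (!length(parts))
    stop("run_decompose: no replicate could be decomposed", call. = FALSE)
  stats_all <- do.call(c, lapply(parts, attr, "log_stats"))
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  out <- structure(out, class = c("noise_breakdown", "data.frame"),
                   mode = config$decompose$mode,
                   x_channel = x_ch, y_channel = y_ch,
                   log_stats = stats_all)

  data.table::fwrite(as.data.frame(out), file.path(rundir, "results.csv"))
  if (make_plots) {
    for (view in c("iptg", "mean")) {
      grDevices::pdf(file.path(rundir, sprintf("noise_vs_%s.pdf", view)),
                     width = 9, height = 4.5)
      graphics::par(mfrow = c(1, 2))
      for (rp in c("X", "Y"))
        plot(out, reporter = rp, against = view)
      grDevices::dev.off()
    }
  }
  invisible(out)
}

#' Built-in validation battery
#'
#' Recomputes the checks that certify the decomposition on known ground
#' truth: the pure-extrinsic scenario must come out almost entirely
#' extrinsic, the pure-intrinsic scenario almost entirely intrinsic, the
#' mixture scenario's log-covariance must match its analytic value, a
#' shrunken scatter gate must lower the extrinsic (not the intrinsic)
#' component on circuit simulations, and the log-scale decomposition must
#' agree with the classical raw-moment estimators for identical constitutive
#' reporters. With `sigma_ext = 0` in the configuration the small-gate check
#' instead verifies that there is no extrinsic noise to remove.
#'
#' @param config a `pipeline_config` (its simulator noise parameters feed
#'   the small-gate check).
#' @param n_cells events per scenario.
#' @param seed integer seed (defaults to the config's).
#' @return Data frame with one row per check: `name`, `value`, `bound`,
#'   `pass`, `note`.
#' @export
run_validate <- function(config = default_pipeline_config(),
                         n_cells = 100000L, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(seed)) seed <- config$seed
  rows <- list()
  push <- function(name, value, bound, pass, note = "")
    rows[[length(rows) + 1L]] <<- data.frame(name = name, value = value,
                                             bound = bound, pass = pass,
                                             note = note,
                                             stringsAsFactors = FALSE)

  # 1: perfectly correlated reporters -> only extrinsic noise
  ev <- make_validation_scenario("pure_extrinsic",
                                 generative_params(sigma_int_x = 0,
                                                   sigma_int_y = 0,
                                                   alpha_true = 1),
                                 n_cells, split_seed(seed, 1))
  st <- log_stats(drop_nonpositive(ev))
  bd <- decompose_well(st, alpha = 1)
  push("pure_extrinsic_int_share",
       max(bd$cv2_int / bd$cv2_total), 0.05,
       max(bd$cv2_int / bd$cv2_total) <= 0.05)

  # 2: independent reporters -> only intrinsic noise
  ev <- make_validation_scenario("pure_intrinsic",
                                 generative_params(sigma_ext = 0),
                                 n_cells, split_seed(seed, 2))
  bd <- suppressWarnings(decompose_well(log_stats(drop_nonpositive(ev)),
                                        alpha = 1))
  push("pure_intrinsic_ext_share",
       max(bd$cv2_ext / bd$cv2_total), 0.05,
       max(bd$cv2_ext / bd$cv2_total) <= 0.05)

  # 3: mixture covariance against the analytic value
  gen <- generative_params()
  ev <- make_validation_scenario("mixture", gen, n_cells, split_seed(seed, 3))
  st <- log_stats(drop_nonpositive(ev))
  truth <- expected_noise_components(gen)$cov_log
  se <- sqrt((st$var_log_x * st$var_log_y + st$cov_log^2) / st$n_events)
  push("mixture_cov_z", abs(st$cov_log - truth) / se, 3,
       abs(st$cov_log - truth) / se <= 3)

  # 4: shrinking the scatter gate removes extrinsic, not intrinsic, noise
  params <- config_circuit_params(config)
  cond <- well_condition(iptg = max(config$simulator$iptg_grid),
                         dox = config$simulator$dox)
  ev <- simulate_population(params, cond, n_cells, split_seed(seed, 4))
  ev <- drop_nonpositive(ev)
  full <- decompose_well(log_stats(ev), alpha = 1)
  gated <- decompose_well(log_stats(gate_scatter(ev, 0.5)), alpha = 1)
  int_chg <- abs(gated$cv2_int[1] / full$cv2_int[1] - 1)
  if (params$sigma_ext == 0) {
    # both extrinsic estimates are sampling noise around zero; measure the
    # change relative to the total so the ratio cannot blow up
    ext_red <- (full$cv2_ext[1] - gated$cv2_ext[1]) / full$cv2_total[1]
    push("small_gate_ext_reduction", ext_red, 0.02, abs(ext_red) <= 0.02,
         "no extrinsic noise present; nothing to filter")
  } else {
    ext_red <- 1 - gated$cv2_ext[1] / full$cv2_ext[1]
    push("small_gate_ext_reduction", ext_red, 0, ext_red > 0)
    push("small_gate_int_change", int_chg, 0.10, int_chg < 0.10)
  }

  # 5: log-mode vs classical raw-moment estimators, identical reporters
  gen <- generative_params(sigma_ext = 0.1, sigma_int_x = 0.1,
                           sigma_int_y = 0.1, alpha_true = 1)
  ev <- make_validation_scenario("mixture", gen, n_cells, split_seed(seed, 5))
  ev <- drop_nonpositive(ev)
  lg <- decompose_well(log_stats(ev), alpha = 1)
  cl <- elowitz_decompose(ev)
  rel_ext <- abs(lg$cv2_ext[1] - cl$ext) / cl$ext
  rel_int <- abs(lg$cv2_int[1] - cl$int) / cl$int
  push("oracle_equiv_ext_rel", rel_ext, 0.10, rel_ext < 0.10)
  push("oracle_equiv_int_rel", rel_int, 0.10, rel_int < 0.10)

  do.call(rbind, rows)
}
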