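#' Analysis options for the ECIS pipeline
#'
#' @param cellfree_R cell-free 4 kHz resistance, Ohm.
#' @param wound_tol fractional tolerance for wound detection.
#' @param fit_window_h sigmoid fit window, h.
#' @param threshold healing-completion threshold for [healing_time()].
#' @param wound_radius_um wound radius, um.
#' @param rate_convention `"radius"` or `"diameter"`.
#' @param electrode `gk_electrode` used as the cell-free reference for
#'   alpha fitting (default: calibrated to `cellfree_R`).
#' @param mm_window,mm_step,mm_segment moving-variance parameters.
#' @return list of options.
#' @export
pipeline_options <- function(cellfree_R = 2600, wound_tol = 0.1,
                             fit_window_h = 24, threshold = 0.95,
                             wound_radius_um = 125,
                             rate_convention = "radius",
                             electrode = NULL,
                             mm_window = 150L, mm_step = 1L,
                             mm_segment = 512L) {
  if (is.null(electrode)) electrode <- calibrate_naked_electrode(cellfree_R)
  list(cellfree_R = cellfree_R, wound_tol = wound_tol,
       fit_window_h = fit_window_h, threshold = threshold,
       wound_radius_um = wound_radius_um,
       rate_convention = rate_convention, electrode = electrode,
       mm_window = mm_window, mm_step = mm_step, mm_segment = mm_segment)
}

#' Analyse one well end to end
#'
#' Runs the complete single-well analysis chain: channel extraction,
#' attachment slope, wound detection, healing sigmoid, migration rate via
#' the coverage-front estimator, adhesion-parameter fit on the averaged
#' pre-wound spectrum, and the post-wound micromotion transition. Any
#' stage that fails leaves its endpoint NA rather than aborting the well.
#'
#' @param ts an `ecis_its`.
#' @param well well identifier.
#' @param opts a [pipeline_options()] list.
#' @return list of per-stage results plus an `endpoints` named vector.
#' @export
analyze_well <- function(ts, well, opts = pipeline_options()) {
  r4k <- extract_channel(ts, well, 4000, "R")
  has_c64 <- any(abs(ts$frequencies - 64000) < 1e-9)
  c64 <- if (has_c64) extract_channel(ts, well, 64000, "C") else NULL

  att <- tryCatch(attachment_slope(window_channel(r4k, -Inf, min(r4k$time_h) + 24)),
                  error = function(e) NULL)
  wound <- tryCatch(detect_wound(r4k, opts$cellfree_R, opts$wound_tol),
                    error = function(e) NULL)
  sig <- NULL; ht <- NA_real_; mig <- NULL; trans <- NULL; cov <- NULL
  if (!is.null(wound)) {
    sig <- tryCatch(fit_healing_sigmoid(r4k, wound, opts$fit_window_h),
                    error = function(e) NULL)
    if (!is.null(sig) && isTRUE(sig$converged)) {
      ht <- healing_time(sig, opts$threshold)
    }
    if (!is.null(c64)) {
      # self-calibrate the coverage channel: cell-free capacitance from the
      # wound sample (coverage 0); confluent capacitance from the healed
      # migration plateau at the end of the fit window (coverage 1 in the
      # migration state, whose barrier resistance differs from the mature
      # pre-wound layer)
      cal <- tryCatch({
        post0 <- window_channel(c64, wound$t_wound - 1e-6, wound$t_wound + 0.5)
        healed <- window_channel(c64, wound$t_wound + opts$fit_window_h - 2,
                                 wound$t_wound + opts$fit_window_h)
        list(C_free = max(post0$value, na.rm = TRUE),
             C_conf = median(healed$value, na.rm = TRUE))
      }, error = function(e) NULL)
      if (!is.null(cal) && cal$C_free > cal$C_conf) {
        cov <- coverage_from_capacitance(c64, cal$C_free, cal$C_conf)
        mig <- tryCatch(
          front_speed_from_coverage(cov, wound, opts$wound_radius_um),
          error = function(e) NULL)
      }
    }
    trans <- tryCatch({
      post <- window_channel(r4k, wound$t_wound, Inf)
      vt <- micromotion_analysis(post, opts$mm_window, opts$mm_step,
                                 opts$mm_segment)[[1]]
      est <- transition_half_time(vt)
      est$half_time_from_wound <- est$half_time - wound$t_wound
      est
    }, error = function(e) NULL)
  }

  afit <- NULL
  if (!is.null(wound)) {
    afit <- tryCatch({
      pre_t <- ts$times / 3600
      sel <- pre_t >= wound$t_wound - 5 & pre_t < wound$t_wound - 1e-9
      iw <- match(well, ts$wells)
      zbar <- vapply(seq_along(ts$frequencies), function(jf) {
        v <- ts$z[sel, iw, jf]
        mean(v[!is.na(v)])
      }, complex(1))
      fit_alpha(data.frame(frequency_hz = ts$frequencies, z_ohm = zbar),
                opts$electrode)
    }, error = function(e) NULL)
  }

  list(
    well = well,
    attachment = att,
    wound = wound,
    sigmoid = sig,
    healing_time_sigmoid = ht,
    migration = mig,
    alpha_fit = afit,
    transition = trans,
    endpoints = c(
      migration_rate = if (!is.null(mig)) mig$rate else NA_real_,
      alpha = if (!is.null(afit) && afit$converged) afit$params$alpha else NA_real_,
      attachment_slope = if (!is.null(att)) att$slope else NA_real_,
      hill_slope = if (!is.null(sig) && isTRUE(sig$converged)) sig$hill_slope else NA_real_,
      t50 = if (!is.null(sig) && isTRUE(sig$converged)) sig$t50 else NA_real_,
      transition_half_time =
        if (!is.null(trans) && isTRUE(trans$converged)) trans$half_time_from_wound else NA_real_)
  )
}

#' Run the full ECIS analysis pipeline
#'
#' Executes the complete analysis on a simulated or loaded experiment:
#' maturation QC channels, wound detection, healing sigmoid kinetics,
#' migration rate via the coverage-front estimator, adhesion parameter
#' fitting, post-wound micromotion transition, and group statistics over
#' the endpoint set (migration rate, alpha, attachment slope, hill slope,
#' inflection point). Returns the per-well results, group comparisons and
#' a run manifest; optionally writes a JSON report, endpoint CSV and
#' manifest to `out_dir`.
#'
#' @param config either a [sim_config()] (the experiment is simulated), a
#'   list with `$simulation` (arguments to [sim_config()]) and optional
#'   `$analysis` (arguments to [pipeline_options()]), a list with
#'   `$input = list(path, dialect)` naming a timecourse CSV, or a path to
#'   a JSON file with that structure.
#' @param out_dir optional output directory.
#' @param quiet suppress stage logging.
#' @return a `pipeline_result`: `wells` (per-well results), `endpoints`
#'   (data.frame well x endpoint), `comparisons` (per endpoint
#'   [tukey_kramer()] reports), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  raw_cfg <- config
  if (is.character(config) && length(config) == 1) {
    raw_cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  log_msg <- function(...) if (!quiet) message("[ecisr] ", ...)

  opts_args <- list()
  if (inherits(raw_cfg, "sim_config")) {
    simcfg <- raw_cfg
    input <- NULL
  } else {
    stopifnot(is.list(raw_cfg))
    input <- raw_cfg$input
    simcfg <- if (!is.null(raw_cfg$simulation)) {
      if (inherits(raw_cfg$simulation, "sim_config")) raw_cfg$simulation
      else sim_config_from_list(raw_cfg$simulation)
    } else NULL
    opts_args <- raw_cfg$analysis %||% list()
  }
  if (is.null(simcfg) && is.null(input)) {
    stop_domain("config must provide a simulation block or an input file")
  }

  if (!is.null(simcfg)) {
    log_msg("simulating experiment (seed ", simcfg$seed, ")")
    ts <- simulate_timecourse(simcfg)
    if (is.null(opts_args$electrode)) opts_args$electrode <- simcfg$electrode
    if (is.null(opts_args$cellfree_R)) {
      opts_args$cellfree_R <- simcfg$schedule$cellfree_R4k
    }
    if (is.null(opts_args$wound_radius_um)) {
      opts_args$wound_radius_um <- simcfg$wound_radius_um
    }
  } else {
    log_msg("reading timecourse from ", input$path)
    ts <- tryCatch(
      read_timecourse(input$path, input$dialect %||% "long"),
      error = function(e) {
        stop_domain("stage read_timecourse failed for ", input$path, ": ",
                    conditionMessage(e))
      })
  }
  opts <- do.call(pipeline_options, opts_args)
  log_msg(length(ts$wells), " wells, ", length(ts$times), " sweeps, ",
          sum(ts$missing), " missing cells")

  wells <- lapply(ts$wells, function(w) {
    log_msg("analyzing well ", w)
    analyze_well(ts, w, opts)
  })
  names(wells) <- ts$wells

  endpoints <- do.call(rbind, lapply(wells, function(x) {
    data.frame(well = x$well, t(x$endpoints))
  }))
  rownames(endpoints) <- NULL
  endpoints$group <- sub("_w[0-9]+$", "", endpoints$well)

  comparisons <- list()
  if (length(unique(endpoints$group)) >= 2) {
    for (ep in c("migration_rate", "alpha", "attachment_slope",
                 "hill_slope", "t50")) {
      vals <- split(endpoints[[ep]], endpoints$group)
      vals <- lapply(vals, function(v) v[!is.na(v)])
      vals <- vals[vapply(vals, length, 0L) >= 2]
      if (length(vals) >= 2) {
        comparisons[[ep]] <- tryCatch(tukey_kramer(group_samples(vals)),
                                      error = function(e) NULL)
      }
    }
  }

  cfg_for_hash <- if (inherits(raw_cfg, "sim_config")) unclass_rec(raw_cfg)
                  else unclass_rec(raw_cfg)
  manifest <- list(
    config_hash = fnv1a32(canonical_json(cfg_for_hash)),
    seed = if (!is.null(simcfg)) simcfg$seed else NA,
    package_version = as.character(utils::packageVersion("ecisr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = character(0))

  result <- structure(list(wells = wells, endpoints = endpoints,
                           comparisons = comparisons, manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(report = file.path(out_dir, "report.json"),
               endpoints = file.path(out_dir, "endpoints.csv"),
               manifest = file.path(out_dir, "manifest.json"))
    jsonlite::write_json(pipeline_report(result), paths["report"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    data.table::fwrite(endpoints, paths["endpoints"])
    result$manifest$outputs <- unname(paths)
    jsonlite::write_json(result$manifest, paths["manifest"],
                         auto_unbox = TRUE, pretty = TRUE)
    log_msg("wrote ", paste(basename(paths), collapse = ", "), " to ", out_dir)
  }
  result
}

# strip S3 classes recursively so jsonlite can serialise configs
unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}

# rebuild a sim_config from a plain (e.g. JSON-decoded) list
sim_config_from_list <- function(lst) {
  args <- lst
  if (!is.null(args$schedule)) args$schedule <- do.call(phase_schedule, as.list(args$schedule))
  if (!is.null(args$groups)) {
    args$groups <- lapply(args$groups, function(g) do.call(sim_group, as.list(g)))
  }
  if (!is.null(args$electrode)) {
    args$electrode <- do.call(naked_electrode_model, as.list(args$electrode))
  }
  do.call(sim_config, args)
}

# JSON-friendly summary of a pipeline result
pipeline_report <- function(result) {
  list(
    wells = lapply(result$wells, function(x) list(
      well = x$well,
      endpoints = as.list(x$endpoints),
      wound = if (!is.null(x$wound)) list(t_wound = x$wound$t_wound,
                                          baseline = x$wound$baseline),
      sigmoid = if (!is.null(x$sigmoid)) unclass(x$sigmoid),
      migration = if (!is.null(x$migration)) unclass(x$migration),
      alpha = if (!is.null(x$alpha_fit) && x$alpha_fit$converged)
        list(alpha = x$alpha_fit$params$alpha,
             Rb = x$alpha_fit$params$Rb, Cm = x$alpha_fit$params$Cm,
             se = as.list(x$alpha_fit$se)),
      transition = if (!is.null(x$transition)) unclass(x$transition))),
    comparisons = lapply(result$comparisons, function(cr) list(
      F = cr$F, p = round(cr$p, 4),
      pairwise = transform(cr$pairwise, p_adj = round(p_adj, 4)))),
    manifest = result$manifest)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$endpoints), " wells; endpoints:\n", sep = "")
  print(x$endpoints, digits = 4)
  for (ep in names(x$comparisons)) {
    cat("\n== ", ep, " ==\n", sep = "")
    print(x$comparisons[[ep]])
  }
  invisible(x)
}
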