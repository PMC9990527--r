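# End-to-end orchestration: configuration, seeded runs
# (simulate -> fit -> analyze -> decode -> tuning -> report) and the
# regime-comparison report.

#' Default run configuration
#'
#' Plain nested list fully determining a pipeline run.  Every value is
#' echoed into the output manifest so a report is self-describing.
#'
#' @param regime scenario regime.
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_run_config <- function(regime = "line_attractor", seed = 1L) {
  list(
    scenario = list(regime = regime, seed = seed),
    fit = list(K = NULL, D = NULL, max_iter = 40L, tol = 1e-4,
               cross_validate = FALSE, K_grid = NULL, D_grid = NULL,
               n_folds = 5L),
    analysis = list(n_grid = 50L, margin = 0.1, slow_point_percentile = 5,
                    velocity_mode = "literal"),
    decoding = list(gap_seconds = 5, n_shuffles = 1000, glm_folds = 5),
    seed = seed)
}

# INI-style plain-text config: "[section]" headers and "key: value" lines
#' Read / write a pipeline configuration
#'
#' Plain-text key-value format with \code{[section]} headers; values are
#' parsed as numbers, logicals, or comma-separated vectors where
#' possible.  Unset keys fall back to \code{\link{default_run_config}}.
#'
#' @param path file path.
#' @return \code{read_run_config}: a configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list(); section <- NULL
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    conv <- suppressWarnings(as.numeric(parts))
    out <- if (!anyNA(conv)) conv
           else if (all(tolower(parts) %in% c("true", "false"))) as.logical(toupper(parts))
           else parts
    if (length(out) == 1) out else out
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl(":", ln, fixed = TRUE)) {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- parse_val(paste(kv[-1], collapse = ":"))
      if (is.null(section)) cfg[[key]] <- val else cfg[[section]][[key]] <- val
    }
  }
  base <- default_run_config(
    regime = cfg$scenario$regime %||% "line_attractor",
    seed = as.integer(cfg$seed %||% cfg$scenario$seed %||% 1L))
  modifyList(base, cfg)
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) paste(v, collapse = ", ")
  lines <- character(0)
  for (nm in names(config)) {
    v <- config[[nm]]
    if (is.list(v)) {
      lines <- c(lines, sprintf("[%s]", nm))
      for (k in names(v)) if (!is.null(v[[k]]))
        lines <- c(lines, sprintf("%s: %s", k, fmt(v[[k]])))
    } else if (!is.null(v)) {
      lines <- c(lines, sprintf("%s: %s", nm, fmt(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_report_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Simulates a session from the configured scenario, fits the rSLDS
#' (optionally with cross-validated (K, D) selection), characterizes the
#' dynamics (time constants, line-attractor score, integration
#' dimension, PCA flow field, slow points, dynamic velocity), decodes
#' behavior from the integration dimension with a shuffle null, runs the
#' tuning and pose analyses, and writes all tables plus a manifest to
#' \code{out_dir}.  Deterministic given the configuration.
#'
#' @param config configuration list (see \code{\link{default_run_config}})
#'   or path to a plain-text config file.
#' @param out_dir output directory (created); NULL skips file artifacts.
#' @return An object of class \code{run_report}.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stage <- "configure"
  on_fail <- function(e) stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  tryCatch({
    stage <- "simulate"
    sc_args <- config$scenario
    scenario <- do.call(ground_truth_scenario, sc_args)
    session <- synthetic_session(scenario)
    rotational <- scenario$regime == "rotational"
    target <- if (rotational) "mount_usv" else "attack"
    pair <- if (rotational) c("sniff", "intromission") else c("sniff", "attack")

    stage <- "fit"
    fit_cfg <- list(max_iter = config$fit$max_iter, tol = config$fit$tol,
                    seed = config$seed)
    chosen <- c(K = config$fit$K %||% scenario$K, D = config$fit$D %||% scenario$D)
    cv <- NULL
    if (isTRUE(config$fit$cross_validate)) {
      cv <- cross_validate_rslds(session$recording, session$inputs,
                                 K_grid = config$fit$K_grid %||% scenario$K,
                                 D_grid = config$fit$D_grid %||% scenario$D,
                                 n_folds = config$fit$n_folds,
                                 seed = config$seed, config = fit_cfg)
      chosen <- cv$chosen
    }
    fit <- fit_rslds(session$recording, session$inputs,
                     K = chosen["K"], D = chosen["D"], config = fit_cfg)

    stage <- "analyze"
    enriched <- select_analysis_state(fit$most_likely_states, session$annotations,
                                      target)
    spectrum <- time_constants(fit$params$A[[enriched$state]],
                               fit$sampling_rate, state = enriched$state)
    score <- line_attractor_score(spectrum)
    integ <- identify_integration_dimension(
      fit, enriched$state,
      reference_frames = which(session$annotations$behavior == target))
    pca <- pca_transform_latents(fit)
    field <- flow_field(fit, pca, n_grid = config$analysis$n_grid,
                        margin = config$analysis$margin)
    sp <- slow_points(field, config$analysis$slow_point_percentile)
    vel <- dynamic_velocity(fit, session$annotations,
                            mode = config$analysis$velocity_mode)
    fse <- forward_simulation_error(fit)
    ev <- explained_variance_by_dimension(fit, Y = session$recording$activity)

    stage <- "decode"
    signal <- integration_signal(fit, integ$direction)
    bouts <- merge_bouts(session$annotations, config$decoding$gap_seconds)
    decoder <- tryCatch(fit_threshold_decoder(signal, bouts, pair),
                        error = function(e) { warnf("decoder skipped: %s", conditionMessage(e)); NULL })
    null <- if (!is.null(decoder))
      shuffle_null(signal, bouts, pair, n_shuffles = config$decoding$n_shuffles,
                   seed = config$seed) else NULL
    cdf <- behavior_cdf(signal, session$annotations)
    glm_rep <- pose_glm(signal, session$pose, cv_folds = config$decoding$glm_folds)

    stage <- "tuning"
    tuning <- behavior_mean_activity(session$recording, session$annotations)
    bank <- build_regressor_bank()
    assign <- assign_neurons(tuning, bank)
    seq_res <- NULL; rot <- NULL
    eps <- episodes_from_annotations(session$annotations)
    if (rotational && nrow(eps) >= 2) {
      rot <- rotation_angle(pca, session$annotations, eps)
      seq_res <- sequentiality_index(session$recording, eps, seed = config$seed)
    }

    stage <- "report"
    report <- structure(list(
      config = config, scenario = scenario,
      chosen = chosen, cv = cv,
      fse_performance = fse$performance,
      enriched_state = enriched$state,
      spectrum = spectrum,
      line_attractor_score = score,
      stability = spectrum$tau_seconds[1],
      integration = integ,
      explained_variance = ev,
      pca_explained_12 = sum(pca$explained[1:2]),
      slow_points = sp,
      dynamic_velocity = vel,
      decoder = decoder, shuffle = null,
      cdf_means = cdf$means,
      pose_glm_r2 = glm_rep$r_squared,
      rotation = rot, sequentiality = seq_res,
      manifest = list()), class = "run_report")

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_session(session, file.path(out_dir, "session"))
      write_report_csv(as.data.frame(spectrum)[, c("modulus", "tau_frames", "tau_seconds")],
                       file.path(out_dir, "spectrum.csv"))
      write_report_csv(vel, file.path(out_dir, "dynamic_velocity.csv"))
      write_report_csv(cdf$means, file.path(out_dir, "cdf_means.csv"))
      write_report_csv(assign, file.path(out_dir, "neuron_assignments.csv"))
      if (!is.null(sp$points) && nrow(sp$points) > 0)
        write_report_csv(sp$points, file.path(out_dir, "slow_points.csv"))
      summary_df <- data.frame(
        metric = c("K", "D", "fse_performance", "line_attractor_score",
                   "stability_s", "enriched_state", "integration_tau_s",
                   "decoder_f1", "null_97_5", "pose_glm_r2",
                   "sequentiality", "sequentiality_null"),
        value = c(chosen["K"], chosen["D"], fse$performance, score,
                  spectrum$tau_seconds[1], enriched$state, integ$tau_seconds,
                  decoder$f1 %||% NA, null$percentile_97_5 %||% NA,
                  glm_rep$r_squared,
                  seq_res$index %||% NA, seq_res$shuffle_mean %||% NA))
      write_report_csv(summary_df, file.path(out_dir, "summary.csv"))
      write_run_config(config, file.path(out_dir, "manifest.ini"))
      report$manifest <- list(dir = out_dir,
                              files = list.files(out_dir, recursive = TRUE))
    }
    report
  }, error = on_fail)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run [%s], K=%d D=%d\n", x$scenario$regime,
              x$chosen["K"], x$chosen["D"]))
  cat(sprintf("  model performance (1-FSE): %.3f\n", x$fse_performance))
  cat(sprintf("  line attractor score: %.2f bits (stability %.1f s)\n",
              x$line_attractor_score, x$stability))
  if (!is.null(x$decoder))
    cat(sprintf("  decoder %s vs %s F1: %.3f (null 97.5%%: %.3f)\n",
                x$decoder$pair[1], x$decoder$pair[2], x$decoder$f1,
                x$shuffle$percentile_97_5))
  if (!is.null(x$sequentiality))
    cat(sprintf("  sequentiality index: %.3f (null mean %.3f)\n",
                x$sequentiality$index, x$sequentiality$shuffle_mean))
  invisible(x)
}

#' Compare two pipeline reports
#'
#' Side-by-side table of the headline dynamics metrics of two runs
#' (e.g. a line-attractor and a rotational regime), including the
#' line-attractor-score versus attractor-stability coordinates that
#' separate integrator-like from rotation-like sessions.  Metrics absent
#' from a report are marked NA.
#'
#' @param report_a,report_b \code{run_report} objects.
#' @return data.frame of class \code{regime_comparison}.
#' @export
compare_regimes <- function(report_a, report_b) {
  grab <- function(r) c(
    line_attractor_score = r$line_attractor_score %||% NA_real_,
    stability_s = r$stability %||% NA_real_,
    fse_performance = r$fse_performance %||% NA_real_,
    decoder_f1 = r$decoder$f1 %||% NA_real_,
    sequentiality = r$sequentiality$index %||% NA_real_,
    pose_glm_r2 = r$pose_glm_r2 %||% NA_real_)
  a <- grab(report_a); b <- grab(report_b)
  out <- data.frame(metric = names(a),
                    a = unname(a), b = unname(b), difference = unname(a - b))
  attr(out, "labels") <- c(report_a$scenario$regime, report_b$scenario$regime)
  class(out) <- c("regime_comparison", "data.frame")
  out
}
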