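# Session container I/O.
#
# A session is stored as a directory of plain-text files: CSV for the
# numeric arrays (frames as rows), a bout-event CSV for annotations
# (columns frame,start_flag,behavior,intruder_sex; 0-based frames,
# half-open bouts), and JSON for parameters and metadata.  Plain text keeps
# the container portable and diffable; numeric arrays round-trip to at
# least 1e-8 and labels/shapes bit-exactly.

write_matrix_csv <- function(M, path, col_prefix = "c") {
  M <- as.matrix(M)
  df <- as.data.frame(t(M))
  names(df) <- paste0(col_prefix, seq_len(ncol(df)))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
            path, row.names = FALSE, quote = FALSE)
}

read_matrix_csv <- function(path, expected_cols = NULL, what = "dataset") {
  if (!file.exists(path)) stopf("session container is missing %s (%s)", what, path)
  df <- read.csv(path, check.names = FALSE)
  M <- t(as.matrix(df))
  if (!is.null(expected_cols) && nrow(M) != expected_cols)
    stopf("%s has %d series but %d expected", what, nrow(M), expected_cols)
  dimnames(M) <- NULL
  M
}

annotations_to_bouts <- function(ann) {
  runs <- label_runs(ann$behavior)
  sex <- ann$intruder_sex[runs$start_frame + 1L]
  ev <- rbind(
    data.frame(frame = runs$start_frame, start_flag = 1L,
               behavior = runs$behavior, intruder_sex = sex),
    data.frame(frame = runs$end_frame, start_flag = 0L,
               behavior = runs$behavior, intruder_sex = sex))
  ev[order(ev$frame, -ev$start_flag), ]
}

bouts_to_annotations <- function(ev, n_frames, sampling_rate) {
  lab <- rep("background", n_frames)
  sex <- rep(NA_character_, n_frames)
  st <- ev[ev$start_flag == 1L, , drop = FALSE]
  en <- ev[ev$start_flag == 0L, , drop = FALSE]
  for (i in seq_len(nrow(st))) {
    e <- en$frame[en$behavior == st$behavior[i] & en$frame > st$frame[i]]
    if (length(e) == 0) stopf("annotation bout starting at frame %d has no end event", st$frame[i])
    idx <- (st$frame[i] + 1L):min(e)
    lab[idx] <- st$behavior[i]
    sex[idx] <- st$intruder_sex[i]
  }
  sex[is.na(sex)] <- if (all(is.na(sex))) "male" else unique(sex[!is.na(sex)])[1]
  ann <- data.frame(frame = 0:(n_frames - 1), behavior = lab,
                    intruder_sex = sex, stringsAsFactors = FALSE)
  attr(ann, "sampling_rate") <- sampling_rate
  class(ann) <- c("behavior_annotation", "data.frame")
  ann
}

params_to_list <- function(p) {
  list(K = p$K, D = p$D, m = p$m, N = p$N,
       A = lapply(p$A, unclass), V = lapply(p$V, unclass), b = p$b,
       C = unclass(p$C), d_bias = p$d_bias,
       obs_noise = unclass(p$obs_noise), process_noise = unclass(p$process_noise),
       R_tr = unclass(p$R_tr), W_tr = unclass(p$W_tr), r_tr = p$r_tr,
       markov_bias = if (is.null(p$markov_bias)) NULL else unclass(p$markov_bias))
}

params_from_list <- function(l) {
  D <- l$D; m <- l$m; K <- l$K
  # jsonlite may simplify a list of K equal-shaped matrices into a
  # K x r x c array, a list of matrices, or (for K = 1 / m = 0) collapse
  # dimensions; normalize all of these back to a list of r x c matrices
  as_mat <- function(x, nr, nc) {
    if (nr * nc == 0) return(matrix(0, nr, nc))
    if (is.list(x)) x <- do.call(rbind, lapply(x, unlist))
    matrix(as.numeric(as.matrix(x)), nr, nc)
  }
  stack_to_list <- function(x, nr, nc) {
    if (is.array(x) && length(dim(x)) == 3) {
      lapply(seq_len(dim(x)[1]), function(k) as_mat(x[k, , ], nr, nc))
    } else if (is.list(x)) {
      lapply(x, as_mat, nr, nc)
    } else {
      list(as_mat(x, nr, nc))
    }
  }
  rows_to_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(k) as.numeric(x[k, ]))
    else if (is.list(x)) lapply(x, as.numeric)
    else list(as.numeric(x))
  }
  fix <- function(M, nr, nc) as_mat(M, nr, nc)
  rslds_params(A = stack_to_list(l$A, D, D),
               V = stack_to_list(l$V, D, m),
               b = rows_to_list(l$b),
               C = fix(l$C, l$N, D), d_bias = as.numeric(l$d_bias),
               obs_noise = fix(l$obs_noise, l$N, l$N),
               process_noise = fix(l$process_noise, D, D),
               R_tr = fix(l$R_tr, l$K, D), W_tr = fix(l$W_tr, l$K, m),
               r_tr = as.numeric(l$r_tr),
               markov_bias = if (is.null(l$markov_bias) || length(l$markov_bias) == 0)
                 NULL else fix(l$markov_bias, l$K, l$K))
}

#' Write a synthetic session to a plain-text container
#'
#' @param session a \code{\link{synthetic_session}}.
#' @param path directory to create (overwritten if present).
#' @return \code{path}, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(session$recording$activity, file.path(path, "neural.csv"), "n")
  write_matrix_csv(session$latents, file.path(path, "latents.csv"), "x")
  write_matrix_csv(matrix(session$states, nrow = 1), file.path(path, "states.csv"), "z")
  write_matrix_csv(session$inputs$values, file.path(path, "inputs.csv"), "u")
  write.csv(annotations_to_bouts(session$annotations),
            file.path(path, "annotations.csv"), row.names = FALSE, quote = FALSE)
  pose <- as.data.frame(session$pose)
  write.csv(format(pose, digits = 17, trim = TRUE), file.path(path, "pose.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(params_to_list(session$params), file.path(path, "params.json"),
                       digits = NA, auto_unbox = TRUE)
  meta <- list(sampling_rate = session$recording$sampling_rate,
               animal_id = session$recording$animal_id,
               n_frames = ncol(session$recording$activity),
               input_names = session$inputs$names,
               scenario = unclass(session$scenario),
               ground_truth = {
                 gt <- attr(session$params, "ground_truth")
                 if (is.null(gt)) NULL else
                   lapply(gt, function(x) if (is.matrix(x)) unclass(x) else x)
               })
  jsonlite::write_json(meta, file.path(path, "meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a session container written by \code{\link{write_session}}
#'
#' @param path directory containing the session files.
#' @return A \code{\link{synthetic_session}}.
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stopf("no session metadata found at %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  T_ <- meta$n_frames
  Y <- read_matrix_csv(file.path(path, "neural.csv"), what = "neural activity")
  if (ncol(Y) != T_) stopf("neural activity has %d frames but metadata says %d", ncol(Y), T_)
  X <- read_matrix_csv(file.path(path, "latents.csv"), what = "latents")
  z <- as.integer(read_matrix_csv(file.path(path, "states.csv"), what = "states"))
  U <- read_matrix_csv(file.path(path, "inputs.csv"), what = "inputs")
  ann_path <- file.path(path, "annotations.csv")
  if (!file.exists(ann_path))
    stopf("session container is missing the annotation file (%s)", ann_path)
  ev <- read.csv(ann_path, stringsAsFactors = FALSE)
  need <- c("frame", "start_flag", "behavior", "intruder_sex")
  if (!all(need %in% names(ev)))
    stopf("annotation file must have columns %s", paste(need, collapse = ", "))
  ann <- bouts_to_annotations(ev, T_, meta$sampling_rate)
  pose <- read.csv(file.path(path, "pose.csv"))
  attr(pose, "sampling_rate") <- meta$sampling_rate
  class(pose) <- c("pose_features", "data.frame")
  params <- params_from_list(jsonlite::read_json(file.path(path, "params.json"),
                                                 simplifyVector = TRUE))
  sc <- meta$scenario
  scenario <- ground_truth_scenario(regime = sc$regime, K = sc$K, D = sc$D, N = sc$N,
                                    m = sc$m, sampling_rate = sc$sampling_rate,
                                    duration = sc$duration,
                                    target_slow_tau = sc$target_slow_tau %||% 150,
                                    rotation_period = sc$rotation_period,
                                    rotation_modulus = sc$rotation_modulus,
                                    emission_noise_sd = sc$emission_noise_sd,
                                    process_noise_sd = sc$process_noise_sd,
                                    behavior_thresholds = sc$behavior_thresholds,
                                    bout_mean_s = sc$bout_mean_s,
                                    ibi_mean_s = sc$ibi_mean_s,
                                    intro_delay_s = sc$intro_delay_s,
                                    pose_noise_sd = sc$pose_noise_sd,
                                    seed = sc$seed)
  if (!is.null(meta$ground_truth)) {
    gt <- meta$ground_truth
    for (nm in c("basis", "rotation_plane")) {
      if (!is.null(gt[[nm]])) gt[[nm]] <- as.matrix(gt[[nm]])
    }
    if (!is.null(gt$slow_axis)) gt$slow_axis <- as.numeric(gt$slow_axis)
    attr(params, "ground_truth") <- gt
  }
  structure(list(params = params, states = z, latents = X,
                 recording = recording(Y, meta$sampling_rate, meta$animal_id),
                 inputs = input_series(U, if (nrow(U) > 0) meta$input_names else character(0)),
                 annotations = ann, pose = pose, scenario = scenario),
            class = "synthetic_session")
}
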