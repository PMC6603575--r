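# End-to-end orchestration: change detection -> superframe scheduling ->
# feature extraction and classification at the data sink -> transition
# alerting, with a full delay decomposition; plus the published-table
# verification utilities.

#' Published confusion matrices
#'
#' Loads the published 5-fold cross-validation confusion matrices (three
#' classifiers per modality) and their published per-class / overall
#' F-scores from the bundled fixture.
#'
#' @param path Fixture path; defaults to the copy shipped with the package.
#' @return A nested list: `$classes`, then `$<modality>$<algorithm>` with
#'   `matrix` (3x3 `confusion_matrix`) and `printed_f` (named numeric).
#' @export
printed_tables <- function(path = system.file("extdata",
                                              "confusion_tables.json",
                                              package = "bedegress")) {
  if (!nzchar(path) || !file.exists(path)) {
    abort_bad_input("confusion-table fixture not found")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- raw$classes
  out <- list(classes = classes)
  for (mod in c("smartphone", "rfid")) {
    if (is.null(raw[[mod]])) abort_bad_input("malformed fixture: missing modality")
    out[[mod]] <- lapply(raw[[mod]], function(entry) {
      list(matrix = as_confusion_matrix(entry$matrix, classes),
           printed_f = unlist(entry$printed_f))
    })
  }
  out
}

#' Verify the published performance tables
#'
#' Recomputes per-class and overall F-scores from each published confusion
#' matrix via [f_scores()] and compares them, after rounding to one
#' decimal, with the published values. Six matrices and four cells each
#' give a 24-cell pass/fail grid.
#'
#' @param fixtures Output of [printed_tables()] (loaded from the default
#'   fixture when omitted).
#' @return A tibble with columns `modality`, `algorithm`, `cell`
#'   (class or `overall`), `printed`, `recomputed`, `pass`.
#' @examples
#' grid <- verify_printed_tables()
#' all(grid$pass)
#' @export
verify_printed_tables <- function(fixtures = printed_tables()) {
  if (is.null(fixtures$classes)) abort_bad_input("malformed fixture")
  rows <- list()
  for (mod in c("smartphone", "rfid")) {
    for (alg in names(fixtures[[mod]])) {
      entry <- fixtures[[mod]][[alg]]
      rep <- f_scores(entry$matrix)
      rec <- c(rep$per_class_f, overall = rep$overall_f)
      for (cell in names(entry$printed_f)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          modality = mod, algorithm = alg, cell = cell,
          printed = unname(entry$printed_f[[cell]]),
          recomputed = unname(rec[[cell]]),
          pass = round(rec[[cell]], 1) == round(entry$printed_f[[cell]], 1)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Sensor-change request detector
#'
#' Emits a channel request whenever the signal magnitude vector changes by
#' more than `delta_th` between consecutive (received) samples. A device
#' holds at most one pending request until it is served at the next
#' superframe boundary, so request times are thinned to one per superframe.
#'
#' @param stream A stream tibble (`t`, `ax`, `ay`, `az`, ...).
#' @param delta_th Request threshold on the SMV difference (same units as
#'   the accelerations; > 0).
#' @param T_frame Superframe duration used for the one-pending-request
#'   thinning (default 5 ms).
#' @return A tibble with columns `time` (request instants, seconds) and
#'   `magnitude` (the triggering SMV change).
#' @export
change_detector <- function(stream, delta_th, T_frame = 5e-3) {
  check_number(delta_th, "delta_th", min = 0, strict_min = TRUE)
  v <- smv(stream$ax, stream$ay, stream$az)
  if (length(v) < 2L) {
    return(tibble::tibble(time = numeric(), magnitude = numeric()))
  }
  dv <- abs(diff(v))
  hit <- which(dv > delta_th)
  if (length(hit) == 0L) {
    return(tibble::tibble(time = numeric(), magnitude = numeric()))
  }
  tt <- stream$t[hit + 1L]
  # one pending request per device until served: keep the first trigger in
  # each superframe interval
  keep <- !duplicated(floor(tt / T_frame))
  tibble::tibble(time = tt[keep], magnitude = dv[hit][keep])
}

#' Pipeline configuration
#'
#' Bundles the protocol, generator and model settings of an end-to-end run.
#' `sigma_budget` is the processing-delay allowance entered into the delay
#' report (the actual feature-extraction plus prediction wall time is also
#' measured and reported separately, being machine-specific);
#' `debounce_windows` is the number of consecutive windows a predicted
#' class must persist before an alert fires.
#'
#' @param superframe A [superframe_config()].
#' @param generator A [generator_params()].
#' @param model A [model_spec()].
#' @param debounce_windows Integer >= 1 (default 1).
#' @param sigma_budget Processing-delay allowance in seconds (default 76 ms,
#'   a conservative upper budget for feature extraction plus class
#'   identification).
#' @param alpha Average channel requests per frame assumed for the
#'   scheduling simulation (default 5).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(superframe = superframe_config(),
                            generator = generator_params(),
                            model = model_spec("rf"),
                            debounce_windows = 1L,
                            sigma_budget = 76e-3,
                            alpha = 5) {
  stopifnot(inherits(superframe, "superframe_config"),
            inherits(generator, "generator_params"),
            inherits(model, "model_spec"))
  check_number(debounce_windows, "debounce_windows", min = 1)
  check_number(sigma_budget, "sigma_budget", min = 0)
  check_number(alpha, "alpha", min = 0)
  structure(list(superframe = superframe, generator = generator,
                 model = model, debounce_windows = as.integer(debounce_windows),
                 sigma_budget = sigma_budget, alpha = alpha),
            class = "pipeline_config")
}

# alert extraction from a window-level prediction sequence: fire once when
# the predicted class enters on_bed / off_bed and persists for
# debounce_windows consecutive windows; re-arm when the class changes.
detect_alerts <- function(windows, predicted, debounce, latency) {
  alerts <- list()
  run_label <- NA_character_
  run_len <- 0L
  alerted <- FALSE
  for (i in seq_along(predicted)) {
    lab <- as.character(predicted[i])
    if (identical(lab, run_label)) {
      run_len <- run_len + 1L
    } else {
      run_label <- lab
      run_len <- 1L
      alerted <- FALSE
    }
    if (!alerted && run_len >= debounce && lab %in% c("on_bed", "off_bed")) {
      alerts[[length(alerts) + 1L]] <- tibble::tibble(
        time = windows$t_end[i], device_id = 1L,
        from_label = if (i - run_len >= 1L) {
          as.character(predicted[i - run_len])
        } else NA_character_,
        to_label = lab, latency = latency)
      alerted <- TRUE
    }
  }
  if (length(alerts) == 0L) {
    return(tibble::tibble(time = numeric(), device_id = integer(),
                          from_label = character(), to_label = character(),
                          latency = numeric()))
  }
  dplyr::bind_rows(alerts)
}

#' Run the end-to-end bed-exit pipeline
#'
#' Generates a synthetic stream for the given protocol, runs sensor-change
#' detection, simulates the superframe communications schedule, extracts
#' features per window at the data sink, classifies them with a model
#' trained on a disjoint synthetic training set (or a supplied model), and
#' emits an alert whenever the predicted class enters `on_bed` or `off_bed`
#' sustained for `debounce_windows` consecutive windows. The per-alert
#' latency is `ds + sigma_budget + dc`; the measured processing wall time is
#' reported alongside for information.
#'
#' @param config A [pipeline_config()].
#' @param protocol An [activity_protocol()] for the monitored stream.
#' @param seed Integer seed driving stream generation, scheduling and model
#'   training.
#' @param model Optional pre-trained `bedegress_model`; when omitted one is
#'   trained on [default_protocol()] data generated with a seed disjoint
#'   from the evaluation stream's.
#' @param n_frames Frames for the scheduling simulation (default 20000).
#' @return A list of class `pipeline_run`: `alerts` (tibble of alert
#'   events), `delay` (a `delay_report` whose `total = ds + sigma + dc`),
#'   `performance` (a `performance_report` of window predictions against
#'   ground truth), `requests` (change-detector output), and
#'   `sigma_measured` (seconds).
#' @export
run_pipeline <- function(config, protocol, seed = 1L, model = NULL,
                         n_frames = 2e4) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(protocol, "activity_protocol"))
  modality <- attr(protocol, "modality")
  gen <- config$generator
  gen$seed <- as.integer(seed)
  stream <- generate_stream(protocol, gen)

  requests <- change_detector(stream, config$superframe$delta_th,
                              config$superframe$T_frame)

  if (is.null(model)) {
    train_gen <- config$generator
    train_gen$seed <- as.integer(seed) + 104729L # disjoint training stream
    train_stream <- generate_stream(default_protocol(modality), train_gen)
    train_feats <- extract_features(train_stream, modality)
    model <- train_classifier(train_feats, config$model)
  }
  if (!inherits(model, "bedegress_model")) {
    abort_bad_input("`model` must be a trained bedegress_model")
  }

  windows <- segment_windows(stream, modality)
  if (nrow(windows) == 0L) abort_bad_input("protocol too short for one window")
  t_proc <- system.time({
    feats <- extract_features(stream, modality)
    predicted <- predict(model, feats)
  })["elapsed"]
  sigma_measured <- unname(t_proc) / nrow(windows)

  sched <- simulate_superframes(config$superframe, config$alpha, n_frames,
                                seed = as.integer(seed) + 7L,
                                sigma = config$sigma_budget)
  delay <- sched # total = ds + sigma_budget + dc

  alerts <- detect_alerts(windows, predicted, config$debounce_windows,
                          latency = delay$total)
  performance <- f_scores(confusion_matrix(windows$label, predicted))

  structure(list(alerts = alerts, delay = delay, performance = performance,
                 requests = requests, sigma_measured = sigma_measured,
                 windows = windows, predicted = predicted, seed = seed),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d windows, %d alerts, %d channel requests\n",
              nrow(x$windows), nrow(x$alerts), nrow(x$requests)))
  print(x$delay)
  cat(sprintf("  measured sigma = %.3g ms per window (informational)\n",
              x$sigma_measured * 1e3))
  print(x$performance)
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML or JSON configuration with blocks
#' `superframe.{T,n,m,p,t,delta,omega,delta_th}`,
#' `delay.{alpha,sigma,dc}` and `simulation.{n_frames,seed}` and returns the
#' corresponding package objects. Missing keys fall back to the package
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with `superframe` ([superframe_config()]), `delay`
#'   ([delay_params()]), and `simulation` (list with `n_frames`, `seed`).
#' @export
read_bedegress_config <- function(path) {
  if (!file.exists(path)) abort_bad_input("config file not found")
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_bad_input("yaml package required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sf <- raw$superframe %||% list()
  cfg <- superframe_config(
    T_frame = sf$T %||% 5e-3, n_devices = sf$n %||% 50,
    m_slots = sf$m %||% 10, p_slots = sf$p %||% ((sf$m %||% 10) / 2),
    t_slot = sf$t %||% 300e-6, delta = sf$delta %||% (1 / 6),
    omega = sf$omega %||% 4, delta_th = sf$delta_th %||% 0.05)
  dl <- raw$delay %||% list()
  params <- delay_params(alpha = dl$alpha %||% 5, sigma = dl$sigma %||% 0,
                         dc = dl$dc, config = cfg)
  sim <- raw$simulation %||% list()
  list(superframe = cfg, delay = params,
       simulation = list(n_frames = sim$n_frames %||% 1e5,
                         seed = sim$seed %||% 1L))
}
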