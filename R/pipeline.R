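#' Ground-truth per-sample labels from annotations
#'
#' @param signal a `breathing_signal` tibble.
#' @param annotations annotation tibble (`start_s`, `end_s`, `type`).
#' @return Character vector, one `"apnea"`/`"normal"` label per sample.
#' @export
truth_labels <- function(signal, annotations) {
  signal <- as_signal_df(signal)
  ann <- as_annotations(annotations)
  lab <- rep("normal", nrow(signal))
  for (i in seq_len(nrow(ann))) {
    lab[signal$t >= ann$start_s[i] & signal$t <= ann$end_s[i]] <- "apnea"
  }
  lab
}

#' Train-and-score workflow on one recording
#'
#' Reproduces the full unsupervised analysis of a single record: build
#' training segments around the annotated events, extract window features,
#' train the competitive network on them, map clusters to classes, then
#' (a) score the segments per sample against the annotation truth and
#' (b) classify the whole signal and run event-level detection.
#'
#' @param signal a `breathing_signal` tibble (10 Hz canonical).
#' @param annotations annotation tibble (`start_s`, `end_s`, `type`).
#' @param window_s,step_s analysis window length and step (s).
#' @param band dominant-frequency search band (Hz).
#' @param epochs competitive-net training epochs.
#' @param seed integer seed.
#' @param mapping `"heuristic"` or `"supervised"` cluster-to-class
#'   mapping.
#' @param margin,min_gap segment construction parameters (s).
#' @return A list of class `apnea_analysis`: `net`, `segments`, `labeled`
#'   (signal + `label` column), `confusion`, `metrics` (per-sample, over
#'   segments), `events` ([detect_events()] report on the whole record).
#' @export
#' @examples
#' \donttest{
#' ev <- sample_apnea_schedule(600, n_events = 3, seed = 2)
#' rec <- simulate_recording(600, events = ev, seed = 2)
#' sig <- extract_breathing_signal(rec$sequence)
#' fit <- apnea_workflow(sig, rec$annotations, epochs = 200, seed = 2)
#' fit$metrics
#' }
apnea_workflow <- function(signal, annotations, window_s = 10, step_s = 0.1,
                           band = c(0.05, 1), epochs = 1000, seed = 1L,
                           mapping = c("heuristic", "supervised"),
                           margin = 25, min_gap = 25) {
  mapping <- match.arg(mapping)
  segments <- build_training_segments(signal, annotations,
                                      margin = margin, min_gap = min_gap)
  abort_if(length(segments$segments) == 0,
           "no usable training segments (all events excluded?)")
  tr <- segment_features(segments$segments, window_s, step_s, band)
  net <- train_competitive(tr$features, epochs = epochs, seed = seed)
  net <- if (mapping == "heuristic") {
    map_clusters_to_classes(net)
  } else {
    map_clusters_to_classes(net, tr$features, tr$truth)
  }
  seg_pred <- unlist(lapply(segments$segments, function(seg)
    classify_segment(net, seg, window_s, step_s, band)))
  seg_truth <- unlist(lapply(segments$segments, `[[`, "truth"))
  cm <- confusion_matrix(seg_pred, seg_truth)
  labeled <- classify_signal(net, signal, window_s = window_s,
                             step_s = step_s, band = band)
  structure(
    list(net = net, segments = segments, labeled = labeled,
         confusion = cm, metrics = compute_metrics(cm),
         events = detect_events(labeled, annotations)),
    class = "apnea_analysis"
  )
}

#' @export
print.apnea_analysis <- function(x, ...) {
  cat("<apnea_analysis>\n")
  print(x$events)
  print(x$metrics)
  invisible(x)
}

# Model file ------------------------------------------------------------

#' Write and read a trained classifier as JSON
#'
#' @param model a mapped [train_competitive()] model.
#' @param path JSON file path.
#' @return `read_model()` returns the `competitive_net`.
#' @export
write_model <- function(model, path) {
  abort_if(!inherits(model, "competitive_net"),
           "only competitive_net models are serialized")
  obj <- list(weights = model$weights, L = model$L,
              scaling = model$scaling,
              class_of_cluster = as.list(model$class_of_cluster %||% list()),
              config = model$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- matrix(as.numeric(obj$weights), nrow = obj$L)
  colnames(w) <- feature_cols
  mapping <- if (length(obj$class_of_cluster) > 0) {
    setNames(unlist(obj$class_of_cluster), names(obj$class_of_cluster))
  } else NULL
  structure(
    list(weights = w, L = obj$L,
         scaling = tibble::as_tibble(obj$scaling),
         class_of_cluster = mapping,
         config = obj$config),
    class = "competitive_net"
  )
}

# Run configuration ------------------------------------------------------

#' Default end-to-end run configuration
#'
#' A nested list mirroring each stage's defaults. `run_pipeline()` rejects
#' keys not present here.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "run",
    simulate = list(duration = 600, rate = 0.27, amplitude = 6,
                    baseline_depth = 1000, noise_sd = 1, drift_sd = 0,
                    sensor = "r200", n_events = 3,
                    event_types = c("central", "obstructive"),
                    event_duration_range = c(12, 37),
                    attenuation = NA_real_, events_csv = NULL),
    extract = list(fs = 10, f1 = 0.01, f2 = 1, taps = 1001,
                   smooth = TRUE, sg_window = 11, filter_first = TRUE),
    features = list(window_s = 10, step_s = 0.1, band = c(0.05, 1)),
    train = list(epochs = 1000, lr_start = 0.1, lr_end = 0.01,
                 mapping = "heuristic"),
    evaluate = list(margin = 25, min_gap = 25, min_event_s = 5,
                    merge_gap_s = 2)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  abort_if(length(unknown) > 0,
           sprintf("unknown config key(s): %s",
                   paste0(path, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the full simulate-to-report pipeline
#'
#' Wires every stage end to end: simulate a depth recording (unless an
#' existing frame stack is analysed through the lower-level functions),
#' extract the breathing signal, compute features, train and map the
#' competitive network, classify, and evaluate. All artifacts (signal,
#' features, model, labels, report, effective config) are written into the
#' run directory; the run is bit-reproducible given the same config, with
#' per-stage seeds derived from the global seed by fixed offsets.
#'
#' @param config a nested list (see [default_config()]) or the path of a
#'   YAML file with the same structure; unknown keys are rejected.
#' @return Invisibly, a list with the run directory path, the
#'   [apnea_workflow()] analysis and the report list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    s <- cfg$simulate
    events <- if (!is.null(s$events_csv)) {
      ann <- read_annotations(s$events_csv)
      apnea_events(ann$start_s, ann$end_s - ann$start_s, ann$type,
                   attenuation = s$attenuation, check_duration = FALSE)
    } else if (s$n_events > 0) {
      sample_apnea_schedule(s$duration, n_events = s$n_events,
                            types = s$event_types,
                            duration_range = s$event_duration_range,
                            attenuation = s$attenuation,
                            seed = cfg$seed + 11L)
    } else {
      apnea_events()
    }
    profile <- breathing_profile(rate = s$rate, amplitude = s$amplitude,
                                 baseline_depth = s$baseline_depth,
                                 noise_sd = s$noise_sd, drift_sd = s$drift_sd)
    simulate_recording(s$duration, profile, events,
                       sensor = sensor_profile(s$sensor), seed = cfg$seed)
  })
  write_annotations(sim$annotations, file.path(cfg$out_dir, "annotations.csv"))
  write_signal_csv(
    tibble::tibble(t = sim$waveform$t, value = sim$waveform$displacement),
    file.path(cfg$out_dir, "waveform_truth.csv"))

  sig <- stage("extract", {
    e <- cfg$extract
    extract_breathing_signal(sim$sequence, fs = e$fs, f1 = e$f1, f2 = e$f2,
                             taps = e$taps, smooth = e$smooth,
                             sg_window = e$sg_window,
                             filter_first = e$filter_first)
  })
  write_signal_csv(sig, file.path(cfg$out_dir, "signal.csv"))

  analysis <- stage("classify", {
    apnea_workflow(sig, sim$annotations,
                   window_s = cfg$features$window_s,
                   step_s = cfg$features$step_s,
                   band = cfg$features$band,
                   epochs = cfg$train$epochs, seed = cfg$seed + 23L,
                   mapping = cfg$train$mapping,
                   margin = cfg$evaluate$margin,
                   min_gap = cfg$evaluate$min_gap)
  })
  feats <- stage("features", {
    extract_features(sliding_windows(sig, cfg$features$window_s,
                                     cfg$features$step_s),
                     band = cfg$features$band)
  })
  readr::write_csv(
    tibble::tibble(t_center_s = feats$t_center, domfreq_hz = feats$domfreq,
                   std = feats$std),
    file.path(cfg$out_dir, "features.csv"))
  write_model(analysis$net, file.path(cfg$out_dir, "model.json"))
  readr::write_csv(
    tibble::tibble(t_s = analysis$labeled$t, label = analysis$labeled$label),
    file.path(cfg$out_dir, "labels.csv"))

  report <- stage("evaluate", {
    ev <- detect_events(analysis$labeled, sim$annotations,
                        min_event_s = cfg$evaluate$min_event_s,
                        merge_gap_s = cfg$evaluate$merge_gap_s)
    list(
      confusion = analysis$confusion[c("tp", "fp", "fn", "tn")],
      metrics_percent = lapply(as.list(analysis$metrics)[
        c("tpr", "tnr", "ppv", "acc", "f1")], function(v) round(v, 1)),
      events = list(detected = ev$detected_count, total = ev$total_count,
                    events_per_hour = ev$events_per_hour)
    )
  })
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))
  invisible(list(out_dir = cfg$out_dir, analysis = analysis, report = report))
}
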