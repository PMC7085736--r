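#' Training segments around annotated apnea events
#'
#' Each retained annotated event yields one segment: the signal slice
#' spanning the event plus `margin` seconds before and after (clipped to
#' the signal bounds), with per-sample truth labels `"apnea"` inside the
#' annotated span and `"normal"` in the margins. An event is excluded when
#' another event starts or ends within `min_gap` seconds of its span --
#' its margins would then contain breathing that is not normal, poisoning
#' the training truth.
#'
#' @param signal a `breathing_signal` tibble (`t`, `value`).
#' @param annotations annotation tibble (`start_s`, `end_s`, `type`), see
#'   [read_annotations()].
#' @param margin seconds of context on each side of the event (default
#'   25).
#' @param min_gap exclusion distance between events in seconds (default
#'   25).
#' @return An object of class `segment_set`: a list with `segments` (each
#'   a list with `signal`, `truth`, `event`), and `excluded` (tibble of
#'   dropped events with reasons).
#' @export
build_training_segments <- function(signal, annotations, margin = 25,
                                    min_gap = 25) {
  signal <- as_signal_df(signal)
  ann <- as_annotations(annotations)
  t0 <- signal$t[1]; t1 <- signal$t[nrow(signal)]
  abort_if(nrow(ann) > 0 && any(ann$start_s < t0 | ann$end_s > t1),
           "annotated event outside the signal span")
  n <- nrow(ann)
  keep <- rep(TRUE, n)
  if (n > 1) {
    for (i in seq_len(n)) {
      others <- ann[-i, ]
      too_close <- others$end_s > ann$start_s[i] - min_gap &
        others$start_s < ann$end_s[i] + min_gap
      if (any(too_close)) keep[i] <- FALSE
    }
  }
  segments <- lapply(which(keep), function(i) {
    lo <- max(t0, ann$start_s[i] - margin)
    hi <- min(t1, ann$end_s[i] + margin)
    idx <- which(signal$t >= lo - 1e-9 & signal$t <= hi + 1e-9)
    slice <- signal[idx, ]
    attr(slice, "fs") <- attr(signal, "fs", exact = TRUE)
    truth <- ifelse(slice$t >= ann$start_s[i] & slice$t <= ann$end_s[i],
                    "apnea", "normal")
    list(signal = slice, truth = truth, event = ann[i, ])
  })
  excluded <- ann[!keep, ]
  excluded$reason <- if (nrow(excluded) > 0) {
    sprintf("another event within %g s", min_gap)
  } else character(0)
  structure(list(segments = segments, excluded = excluded,
                 margin = margin, min_gap = min_gap),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments (%d events excluded, margin %g s)\n",
              length(x$segments), nrow(x$excluded), x$margin))
  invisible(x)
}

#' @export
length.segment_set <- function(x) length(x$segments)

#' Confusion matrix for apnea classification
#'
#' Tallies predictions against truth with `"apnea"` as the positive
#' class: TP (hit), FP (type I error), FN (type II error / miss), TN
#' (correct rejection).
#'
#' @param pred,truth equal-length character vectors of
#'   `"apnea"`/`"normal"` labels.
#' @return An object of class `confusion_matrix` (named list `tp`, `fp`,
#'   `fn`, `tn`).
#' @export
confusion_matrix <- function(pred, truth) {
  pred <- check_labels(pred, "pred")
  truth <- check_labels(truth, "truth")
  abort_if(length(pred) != length(truth),
           sprintf("length mismatch: %d predictions vs %d truth labels",
                   length(pred), length(truth)))
  new_confusion(
    tp = sum(pred == "apnea" & truth == "apnea"),
    fp = sum(pred == "apnea" & truth == "normal"),
    fn = sum(pred == "normal" & truth == "apnea"),
    tn = sum(pred == "normal" & truth == "normal")
  )
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn cell counts (non-negative).
#' @export
new_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  abort_if(any(counts < 0) || anyNA(counts), "confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("apnea", "normal"),
                              pred = c("apnea", "normal")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes sensitivity `TPR = TP/(TP+FN)`, specificity
#' `TNR = TN/(TN+FP)`, precision `PPV = TP/(TP+FP)`, accuracy
#' `ACC = (TP+TN)/(TP+TN+FP+FN)` and
#' `F1 = 2*PPV*TPR/(PPV+TPR) = 2TP/(2TP+FP+FN)`, all reported as percent.
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' coerced to 0.
#'
#' @param cm a [confusion_matrix()] (or list with `tp`, `fp`, `fn`, `tn`).
#' @return A one-row tibble of class `metrics_report` with columns `tpr`,
#'   `tnr`, `ppv`, `acc`, `f1` (percent, full precision; the print method
#'   shows one decimal).
#' @export
#' @examples
#' compute_metrics(new_confusion(tp = 2855, fp = 139, fn = 347, tn = 11802))
compute_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  abort_if(total == 0, "confusion matrix is all zeros")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tpr <- safe_div(tp, tp + fn)
  tnr <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  acc <- (tp + tn) / total
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  out <- tibble::tibble(tpr = 100 * tpr, tnr = 100 * tnr, ppv = 100 * ppv,
                        acc = 100 * acc, f1 = 100 * f1)
  class(out) <- c("metrics_report", class(out))
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Sensitivity (TPR):", fmt_pct(x$tpr),
      "\nSpecificity (TNR):", fmt_pct(x$tnr),
      "\nPrecision   (PPV):", fmt_pct(x$ppv),
      "\nAccuracy    (ACC):", fmt_pct(x$acc),
      "\nF1 score        :", fmt_pct(x$f1), "\n")
  invisible(x)
}

fmt_pct <- function(v) ifelse(is.na(v), "undefined", sprintf("%.1f%%", v))

#' Event-level detection report
#'
#' Turns per-sample labels into predicted apnea events: maximal
#' apnea-labelled runs, after merging gaps of at most `merge_gap_s`
#' seconds, that last at least `min_event_s` seconds (the shortest
#' clinically plausible event). An annotated event counts as detected if
#' any predicted event overlaps it. `events_per_hour` is the predicted
#' event count divided by the record length in hours -- the clinical
#' severity index.
#'
#' @param labeled a tibble with columns `t` and `label`
#'   (output of [classify_signal()]), aligned to the signal grid.
#' @param annotations annotation tibble (`start_s`, `end_s`, `type`); may
#'   be empty.
#' @param min_event_s minimum predicted event duration (s), default 5.
#' @param merge_gap_s gaps between apnea runs up to this length are
#'   bridged (s), default 2.
#' @return An object of class `event_report`: `events` (annotations plus a
#'   `detected` flag), `predicted` (tibble `start_s`, `end_s`),
#'   `detected_count`, `total_count`, `events_per_hour`.
#' @export
detect_events <- function(labeled, annotations = NULL, min_event_s = 5,
                          merge_gap_s = 2) {
  abort_if(!is.data.frame(labeled) || !all(c("t", "label") %in% names(labeled)),
           "labeled must have columns t and label")
  check_labels(labeled$label)
  ann <- if (is.null(annotations)) {
    tibble::tibble(start_s = numeric(), end_s = numeric(), type = character())
  } else as_annotations(annotations)

  runs <- rle(labeled$label == "apnea")
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- ends_idx - runs$lengths + 1L
  pred <- tibble::tibble(
    start_s = labeled$t[starts_idx[runs$values]],
    end_s = labeled$t[ends_idx[runs$values]]
  )
  # merge across short gaps
  if (nrow(pred) > 1) {
    merged <- pred[1, ]
    for (i in 2:nrow(pred)) {
      if (pred$start_s[i] - merged$end_s[nrow(merged)] <= merge_gap_s) {
        merged$end_s[nrow(merged)] <- pred$end_s[i]
      } else {
        merged <- dplyr::bind_rows(merged, pred[i, ])
      }
    }
    pred <- merged
  }
  pred <- pred[pred$end_s - pred$start_s >= min_event_s, ]

  detected <- vapply(seq_len(nrow(ann)), function(i) {
    any(pred$start_s <= ann$end_s[i] & pred$end_s >= ann$start_s[i])
  }, logical(1))
  hours <- diff(range(labeled$t)) / 3600
  structure(
    list(events = dplyr::mutate(ann, detected = detected),
         predicted = pred,
         detected_count = sum(detected),
         total_count = nrow(ann),
         events_per_hour = nrow(pred) / hours),
    class = "event_report"
  )
}

#' @export
print.event_report <- function(x, ...) {
  cat(sprintf("<event_report> %d/%d annotated events detected; %.1f predicted events/hour\n",
              x$detected_count, x$total_count, x$events_per_hour))
  invisible(x)
}

# features + per-window truth for a list of segments (windows never cross
# segment boundaries)
segment_features <- function(segments, window_s, step_s, band) {
  per_seg <- lapply(segments, function(seg) {
    wins <- sliding_windows(seg$signal, window_s = window_s, step_s = step_s)
    feats <- extract_features(wins, band = band)
    truth <- seg$truth[attr(feats, "center_idx", exact = TRUE)]
    list(feats = feats, truth = truth)
  })
  feats <- dplyr::bind_rows(lapply(per_seg, `[[`, "feats"))
  f1 <- per_seg[[1]]$feats
  attr(feats, "scaling") <- feature_scaling(
    as.matrix(feats[feature_cols]),
    fs = attr(f1, "fs", exact = TRUE),
    wlen = attr(f1, "wlen", exact = TRUE))
  class(feats) <- c("resp_features", class(feats))
  list(features = feats,
       truth = unlist(lapply(per_seg, `[[`, "truth")),
       per_segment = per_seg)
}

# per-sample labels for one segment given a mapped model
classify_segment <- function(model, seg, window_s, step_s, band) {
  classify_signal(model, seg$signal, window_s = window_s, step_s = step_s,
                  band = band)$label
}

#' Repeated random-split cross-validation over training segments
#'
#' Performs `n_repeats` seeded random splits at segment granularity
#' (`train_fraction` of segments for training, the rest held out). Each
#' repeat trains a competitive network on the training segments' window
#' features, maps clusters to classes, scores the held-out segments per
#' sample, and computes the confusion-matrix metrics.
#'
#' @param segments a [build_training_segments()] segment set (>= 4
#'   segments).
#' @param n_repeats number of random splits (default 5).
#' @param train_fraction fraction of segments used for training (default
#'   0.70).
#' @param seed integer seed; repeat r uses `seed + r`.
#' @param window_s,step_s window parameters for feature extraction.
#' @param band dominant-frequency band (Hz).
#' @param epochs competitive-net training epochs.
#' @param mapping `"heuristic"` (smaller-std cluster is apnea) or
#'   `"supervised"` (majority vote against training truth).
#' @return An object of class `crossval_result`: `per_repeat` (tibble of
#'   metrics per repeat), `summary` (mean and sd per metric).
#' @export
cross_validate <- function(segments, n_repeats = 5, train_fraction = 0.70,
                           seed = 1L, window_s = 10, step_s = 0.1,
                           band = c(0.05, 1), epochs = 1000,
                           mapping = c("heuristic", "supervised")) {
  mapping <- match.arg(mapping)
  abort_if(!inherits(segments, "segment_set"), "segments must be a segment_set")
  n_seg <- length(segments$segments)
  abort_if(n_seg < 4, "need at least 4 segments for cross-validation")
  n_train <- max(1L, round(train_fraction * n_seg))
  abort_if(n_train >= n_seg, "train_fraction leaves no held-out segments")

  reports <- purrr::map(seq_len(n_repeats), function(r) {
    idx_train <- withr::with_seed(seed + r, sample.int(n_seg, n_train))
    train <- segments$segments[idx_train]
    test <- segments$segments[-idx_train]
    tr <- segment_features(train, window_s, step_s, band)
    net <- train_competitive(tr$features, epochs = epochs, seed = seed + r)
    net <- if (mapping == "heuristic") {
      map_clusters_to_classes(net)
    } else {
      map_clusters_to_classes(net, tr$features, tr$truth)
    }
    pred <- unlist(lapply(test, function(seg)
      classify_segment(net, seg, window_s, step_s, band)))
    truth <- unlist(lapply(test, `[[`, "truth"))
    dplyr::mutate(compute_metrics(confusion_matrix(pred, truth)),
                  repeat_id = r, .before = 1)
  })
  per_repeat <- dplyr::bind_rows(reports)
  summary <- per_repeat |>
    tidyr::pivot_longer(-"repeat_id", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
  structure(list(per_repeat = per_repeat, summary = summary,
                 n_repeats = n_repeats, train_fraction = train_fraction),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d repeats, %.0f%% of segments for training\n",
              x$n_repeats, 100 * x$train_fraction))
  print(x$summary)
  invisible(x)
}
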