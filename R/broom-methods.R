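#' Tidy a trained competitive network
#'
#' One row per neuron with its weight vector in both z-scored and original
#' feature units, and the mapped class if clusters have been mapped.
#'
#' @param x a [train_competitive()] model.
#' @param ... unused.
#' @return A tibble with columns `cluster`, `domfreq_z`, `std_z`,
#'   `domfreq`, `std`, `class`.
#' @method tidy competitive_net
#' @export
tidy.competitive_net <- function(x, ...) {
  orig <- model_centroids(x)
  tibble::tibble(
    cluster = seq_len(x$L),
    domfreq_z = x$weights[, "domfreq"],
    std_z = x$weights[, "std"],
    domfreq = orig[, "domfreq"],
    std = orig[, "std"],
    class = if (is.null(x$class_of_cluster)) NA_character_
            else unname(x$class_of_cluster[as.character(seq_len(x$L))])
  )
}

#' @rdname tidy.competitive_net
#' @method glance competitive_net
#' @export
glance.competitive_net <- function(x, ...) {
  tibble::tibble(L = x$L, epochs = x$config$epochs,
                 lr_start = x$config$lr_start, lr_end = x$config$lr_end,
                 seed = x$config$seed, mapped = !is.null(x$class_of_cluster))
}

#' Tidy a k-means baseline fit
#' @param x a [train_kmeans()] object.
#' @param ... unused.
#' @return A tibble with one row per cluster.
#' @method tidy resp_kmeans
#' @export
tidy.resp_kmeans <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    domfreq = x$centroids[, "domfreq"],
    std = x$centroids[, "std"],
    size = as.integer(table(factor(x$cluster, levels = seq_len(x$k)))),
    class = if (is.null(x$class_of_cluster)) NA_character_
            else unname(x$class_of_cluster[as.character(seq_len(x$k))])
  )
}

#' @rdname tidy.resp_kmeans
#' @method glance resp_kmeans
#' @export
glance.resp_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, tot_withinss = x$tot_withinss, scaled = x$scaled)
}

#' Tidy a confusion matrix
#' @param x a [confusion_matrix()].
#' @param ... unused.
#' @return A long tibble with columns `cell`, `count`.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "fn", "tn"),
                 count = c(x$tp, x$fp, x$fn, x$tn))
}

#' @rdname tidy.confusion_matrix
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  compute_metrics(x) |> tibble::as_tibble()
}

#' Tidy an event-detection report
#' @param x a [detect_events()] report.
#' @param ... unused.
#' @return The per-event tibble with the `detected` flag.
#' @method tidy event_report
#' @export
tidy.event_report <- function(x, ...) x$events

#' @rdname tidy.event_report
#' @method glance event_report
#' @export
glance.event_report <- function(x, ...) {
  tibble::tibble(detected_count = x$detected_count,
                 total_count = x$total_count,
                 events_per_hour = x$events_per_hour)
}

#' Tidy cross-validation results
#' @param x a [cross_validate()] result.
#' @param ... unused.
#' @return The per-repeat metrics tibble.
#' @method tidy crossval_result
#' @export
tidy.crossval_result <- function(x, ...) x$per_repeat

#' @rdname tidy.crossval_result
#' @method glance crossval_result
#' @export
glance.crossval_result <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"))
}
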