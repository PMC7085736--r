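feature_cols <- c("domfreq", "std")

# standardize a feature tibble with the given (or its own) scaling table
feature_matrix <- function(features, scaling = NULL) {
  abort_if(!is.data.frame(features) || !all(feature_cols %in% names(features)),
           "features need columns domfreq and std")
  X <- as.matrix(features[feature_cols])
  abort_if(anyNA(X) || any(!is.finite(X)), "features must be finite")
  X
}

zscore_features <- function(X, scaling) {
  sds <- pmax(scaling$sd, .Machine$double.eps)
  sweep(sweep(X, 2, scaling$mean), 2, sds, "/")
}

# z-scoring parameters for a feature matrix. The dominant-frequency sd is
# floored at half a native spectral bin (0.5 * fs / wlen): a window's peak
# position is only meaningful to that resolution (zero-padding merely
# interpolates), so when the observed spread is smaller the feature is
# effectively constant and dividing by its raw sd would amplify
# quantization noise into spurious outliers.
feature_scaling <- function(X, fs = NULL, wlen = NULL) {
  sds <- apply(X, 2, sd)
  if (!is.null(fs) && !is.null(wlen)) {
    sds[1] <- max(sds[1], 0.5 * fs / wlen)
  }
  tibble::tibble(feature = feature_cols, mean = unname(colMeans(X)),
                 sd = unname(sds))
}

scaling_of <- function(features) {
  sc <- attr(features, "scaling", exact = TRUE)
  if (is.null(sc)) {
    sc <- feature_scaling(feature_matrix(features),
                          fs = attr(features, "fs", exact = TRUE),
                          wlen = attr(features, "wlen", exact = TRUE))
  }
  sc
}

# canonical row order so training is invariant to input row permutation
canonical_order <- function(X) order(X[, 1], X[, 2])

#' Train a two-neuron competitive network on window features
#'
#' Unsupervised winner-take-all (Kohonen) learning on z-scored features:
#' each presented vector moves only its nearest weight vector,
#' `w <- w + eta * (x - w)`, with the learning rate decaying linearly from
#' `lr_start` to `lr_end` over the epochs. Weight vectors act as cluster
#' centroids (learning vector quantization without a teacher). Rows are
#' put in a canonical order before the seeded per-epoch shuffles, so the
#' result depends only on the data values and the seed, not on row order.
#'
#' @param features a [extract_features()] tibble (columns `domfreq`,
#'   `std`).
#' @param epochs training epochs (default 1000).
#' @param lr_start,lr_end linear learning-rate schedule, `0 < lr_end <=
#'   lr_start < 1`.
#' @param seed integer seed for initialization and per-epoch shuffling.
#' @param L number of neurons (default 2: apnea vs normal).
#' @param init `"sample"` (distinct seeded data points, default) or
#'   `"random"` (seeded Gaussian jitter around the feature mean).
#' @param restarts number of independently seeded training runs; the run
#'   with the smallest quantization error (summed squared distance of each
#'   vector to its winning weight) is kept, like the multi-start
#'   convention of k-means. Online winner-take-all learning can settle in
#'   a poor local partition from an unlucky start; restarts make the
#'   selection an explicit objective.
#' @return An object of class `competitive_net`: weights (L x 2, z-scored
#'   space), the feature `scaling`, an initially empty `class_of_cluster`
#'   mapping (see [map_clusters_to_classes()]) and the training config.
#' @export
#' @examples
#' feats <- tibble::tibble(domfreq = c(rnorm(50, .25, .01), rnorm(50, .5, .1)),
#'                         std = c(rnorm(50, 2, .1), rnorm(50, .1, .02)))
#' net <- train_competitive(feats, epochs = 100, seed = 1)
#' tidy(net)
train_competitive <- function(features, epochs = 1000, lr_start = 0.1,
                              lr_end = 0.01, seed = 1L, L = 2,
                              init = c("sample", "random"), restarts = 5) {
  init <- match.arg(init)
  abort_if(epochs < 1, "epochs must be at least 1")
  abort_if(restarts < 1, "restarts must be at least 1")
  abort_if(!(lr_end > 0 && lr_end <= lr_start && lr_start < 1),
           "need 0 < lr_end <= lr_start < 1")
  scaling <- scaling_of(features)
  X <- zscore_features(feature_matrix(features), scaling)
  X <- X[canonical_order(X), , drop = FALSE]
  Xu <- unique(X)
  abort_if(nrow(Xu) < L,
           sprintf("need at least %d distinct feature vectors, found %d",
                   L, nrow(Xu)))
  quant_err <- function(W) {
    D <- vapply(seq_len(L), function(l) rowSums(sweep(X, 2, W[l, ])^2),
                numeric(nrow(X)))
    sum(do.call(pmin, as.data.frame(D)))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    seed_r <- seed + 101L * (r - 1L)
    w0 <- if (init == "sample") {
      idx <- withr::with_seed(seed_r, sample.int(nrow(Xu), L))
      Xu[idx, , drop = FALSE]
    } else {
      ctr <- colMeans(X)
      jit <- withr::with_seed(seed_r, matrix(rnorm(L * ncol(X), 0, 0.1), L))
      sweep(jit, 2, ctr, "+")
    }
    W <- competitive_train_cpp(X, w0, as.integer(epochs), lr_start, lr_end,
                               as.double(seed_r))
    err <- quant_err(W)
    if (is.null(best) || err < best$err) best <- list(W = W, err = err)
  }
  W <- best$W
  dimnames(W) <- list(NULL, feature_cols)
  structure(
    list(weights = W, L = L, scaling = scaling,
         class_of_cluster = NULL, quant_error = best$err,
         config = list(epochs = epochs, lr_start = lr_start,
                       lr_end = lr_end, seed = seed, init = init,
                       restarts = restarts)),
    class = "competitive_net"
  )
}

#' @export
print.competitive_net <- function(x, ...) {
  cat(sprintf("<competitive_net> %d neurons, %d epochs (lr %.3g -> %.3g)\n",
              x$L, x$config$epochs, x$config$lr_start, x$config$lr_end))
  print(tidy(x))
  invisible(x)
}

#' Assign feature vectors to competitive clusters
#'
#' Winner-take-all readout: each feature vector is assigned to the neuron
#' with minimum Euclidean distance in the net's z-scored feature space;
#' ties go to the lower neuron index.
#'
#' @param net a [train_competitive()] model.
#' @param features feature tibble or numeric matrix with columns matching
#'   the net's feature space.
#' @return Integer vector of cluster indices (1..L).
#' @export
predict_cluster <- function(net, features) {
  abort_if(!inherits(net, "competitive_net"), "net must be a competitive_net")
  X <- if (is.matrix(features)) features else feature_matrix(features)
  abort_if(ncol(X) != ncol(net$weights),
           sprintf("feature dimension %d does not match the net's %d",
                   ncol(X), ncol(net$weights)))
  Z <- zscore_features(X, net$scaling)
  D <- vapply(seq_len(net$L), function(l) {
    rowSums(sweep(Z, 2, net$weights[l, ])^2)
  }, numeric(nrow(Z)))
  max.col(-matrix(D, nrow = nrow(Z)), ties.method = "first")
}

#' K-means baseline clustering of window features
#'
#' Lloyd's algorithm (at most 300 iterations) from a seeded sample of k
#' distinct feature rows. By default the features are used unscaled
#' (original units), so whichever feature has the larger numeric spread
#' dominates the distances -- the natural pitfall this baseline
#' illustrates; set `scale = TRUE` to cluster in z-scored space.
#'
#' @param features feature tibble (columns `domfreq`, `std`).
#' @param k number of clusters (default 2).
#' @param seed integer seed for the initialization draw.
#' @param scale z-score features before clustering (default FALSE).
#' @return An object of class `resp_kmeans`: `centroids` (k x 2, original
#'   units), `cluster` assignments, `tot_withinss`, `scaling`/`scaled`
#'   bookkeeping and a NULL `class_of_cluster`.
#' @export
train_kmeans <- function(features, k = 2, seed = 1L, scale = FALSE) {
  X <- feature_matrix(features)
  scaling <- scaling_of(features)
  Z <- if (scale) zscore_features(X, scaling) else X
  Zu <- unique(Z)
  abort_if(nrow(Zu) < k,
           sprintf("need at least %d distinct feature vectors, found %d",
                   k, nrow(Zu)))
  centers <- Zu[withr::with_seed(seed, sample.int(nrow(Zu), k)), , drop = FALSE]
  km <- stats::kmeans(Z, centers = centers, iter.max = 300,
                      algorithm = "Lloyd")
  cent <- km$centers
  if (scale) {
    cent <- sweep(sweep(cent, 2, pmax(scaling$sd, .Machine$double.eps), "*"),
                  2, scaling$mean, "+")
  }
  dimnames(cent) <- list(NULL, feature_cols)
  structure(
    list(centroids = cent, cluster = km$cluster,
         tot_withinss = km$tot.withinss, k = k,
         scaled = scale, scaling = scaling,
         class_of_cluster = NULL, seed = seed),
    class = "resp_kmeans"
  )
}

#' @export
print.resp_kmeans <- function(x, ...) {
  cat(sprintf("<resp_kmeans> k = %d (%s features), within-SS %.4g\n",
              x$k, if (x$scaled) "z-scored" else "unscaled", x$tot_withinss))
  print(tibble::as_tibble(x$centroids))
  invisible(x)
}

#' Cluster assignments from a fitted k-means baseline
#' @param fit a [train_kmeans()] object.
#' @param features feature tibble.
#' @return Integer cluster indices (1..k).
#' @export
predict_kmeans <- function(fit, features) {
  abort_if(!inherits(fit, "resp_kmeans"), "fit must come from train_kmeans()")
  X <- feature_matrix(features)
  Z <- if (fit$scaled) zscore_features(X, fit$scaling) else X
  cent <- fit$centroids
  if (fit$scaled) cent <- zscore_features(cent, fit$scaling)
  D <- vapply(seq_len(fit$k), function(l) {
    rowSums(sweep(Z, 2, cent[l, ])^2)
  }, numeric(nrow(Z)))
  max.col(-matrix(D, nrow = nrow(Z)), ties.method = "first")
}

# centroids of a model in original feature units
model_centroids <- function(model) {
  if (inherits(model, "competitive_net")) {
    sweep(sweep(model$weights, 2, pmax(model$scaling$sd, .Machine$double.eps), "*"),
          2, model$scaling$mean, "+")
  } else if (inherits(model, "resp_kmeans")) {
    model$centroids
  } else {
    stop("model must be a competitive_net or resp_kmeans", call. = FALSE)
  }
}

#' Map unsupervised clusters to apnea / normal classes
#'
#' The default heuristic exploits what apnea does to the signal: breathing
#' cessation collapses the window standard deviation, so the cluster whose
#' centroid has the smaller `std` (in original units) is labelled
#' `"apnea"` and the other `"normal"`. With `labels` supplied the mapping
#' is instead a per-cluster majority vote against those labels.
#'
#' @param model a [train_competitive()] or [train_kmeans()] fit with 2
#'   clusters.
#' @param features feature tibble (needed for the supervised vote).
#' @param labels optional per-row truth labels (`"apnea"`/`"normal"`)
#'   enabling supervised mapping.
#' @return The model with its `class_of_cluster` field set (named
#'   character vector, cluster index -> class).
#' @export
map_clusters_to_classes <- function(model, features = NULL, labels = NULL) {
  cent <- model_centroids(model)
  abort_if(nrow(cent) != 2, "class mapping requires exactly 2 clusters")
  if (is.null(labels)) {
    abort_if(isTRUE(all.equal(cent[1, ], cent[2, ], tolerance = 1e-12)),
             "identical centroids: heuristic mapping degenerate, supply labels for supervised mapping")
    apnea_cluster <- which.min(cent[, "std"])
  } else {
    abort_if(is.null(features), "supervised mapping needs the features")
    labels <- check_labels(labels)
    cl <- if (inherits(model, "competitive_net")) {
      predict_cluster(model, features)
    } else {
      predict_kmeans(model, features)
    }
    frac_apnea <- vapply(1:2, function(l) mean(labels[cl == l] == "apnea"),
                         numeric(1))
    frac_apnea[is.nan(frac_apnea)] <- 0
    apnea_cluster <- which.max(frac_apnea)
  }
  mapping <- rep("normal", 2)
  mapping[apnea_cluster] <- "apnea"
  model$class_of_cluster <- setNames(mapping, as.character(1:2))
  model
}

#' Classify feature vectors into apnea / normal
#'
#' @param model a mapped model (see [map_clusters_to_classes()]).
#' @param features feature tibble.
#' @return Character vector of `"apnea"`/`"normal"`, one per feature row.
#' @export
predict_class <- function(model, features) {
  abort_if(is.null(model$class_of_cluster),
           "model has no cluster->class mapping; run map_clusters_to_classes() first")
  cl <- if (inherits(model, "competitive_net")) {
    predict_cluster(model, features)
  } else {
    predict_kmeans(model, features)
  }
  unname(model$class_of_cluster[as.character(cl)])
}

#' Per-sample apnea labels for a breathing signal
#'
#' Slides windows over the signal, computes features, classifies each
#' window with the trained model, and assigns every signal sample the
#' label of the window whose centre is nearest (the leading and trailing
#' half-windows inherit the nearest centre's label). With the default
#' 0.1 s step on a 10 Hz signal this is a 10 Hz label grid.
#'
#' @param model a mapped [train_competitive()] or [train_kmeans()] model.
#' @param signal a `breathing_signal` tibble.
#' @param window_s,step_s window length and step in seconds (defaults 10
#'   and 0.1); must match what the model was trained on.
#' @param band dominant-frequency search band (Hz).
#' @return The signal tibble with an added `label` column (length equals
#'   the signal length).
#' @export
classify_signal <- function(model, signal, window_s = 10, step_s = 0.1,
                            band = c(0.05, 1)) {
  abort_if(is.null(model$class_of_cluster),
           "model has no cluster->class mapping; run map_clusters_to_classes() first")
  signal <- as_signal_df(signal)
  wins <- sliding_windows(signal, window_s = window_s, step_s = step_s)
  feats <- extract_features(wins, band = band)
  win_label <- predict_class(model, feats)
  centers <- attr(feats, "center_idx", exact = TRUE)
  # nearest window centre for every sample index
  nearest <- findInterval(seq_len(nrow(signal)) - 0.5, centers) + 1L
  nearest <- pmin(pmax(nearest, 1L), length(centers))
  lower <- pmax(nearest - 1L, 1L)
  pick_lower <- abs(seq_len(nrow(signal)) - centers[lower]) <=
    abs(seq_len(nrow(signal)) - centers[nearest])
  nearest[pick_lower] <- lower[pick_lower]
  out <- signal
  out$label <- win_label[nearest]
  out
}
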