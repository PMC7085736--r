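test_that("near-identical inputs collapse both weights onto the common point", {
  feats <- tibble::tibble(domfreq = c(rep(0.25, 199), 0.25 + 1e-9),
                          std = c(rep(1.5, 199), 1.5 + 1e-9))
  net <- train_competitive(feats, epochs = 200, seed = 2)
  cent <- tidy(net)
  expect_lt(max(abs(cent$domfreq - 0.25)), 1e-6)
  expect_lt(max(abs(cent$std - 1.5)), 1e-6)
})

test_that("training errors when there are fewer distinct points than neurons", {
  feats <- tibble::tibble(domfreq = rep(0.25, 50), std = rep(1, 50))
  expect_error(train_competitive(feats, epochs = 10, seed = 1), "distinct")
  expect_error(train_kmeans(feats, k = 2, seed = 1), "distinct")
})

test_that("competitive weights land on the blob means and are seed-deterministic", {
  blobs <- blob_features(n_per = 100, seed = 6)
  net1 <- train_competitive(blobs, epochs = 300, seed = 5)
  net2 <- train_competitive(blobs, epochs = 300, seed = 5)
  expect_identical(net1$weights, net2$weights)

  cent <- tidy(net1)[, c("domfreq", "std")]
  means <- blobs |>
    dplyr::group_by(blob) |>
    dplyr::summarise(domfreq = mean(domfreq), std = mean(std))
  # each weight within 0.2 of a distinct blob mean
  d <- as.matrix(dist(rbind(as.matrix(cent), as.matrix(means[, -1]))))[1:2, 3:4]
  best <- apply(d, 1, which.min)
  expect_setequal(best, c(1, 2))
  expect_true(all(apply(d, 1, min) < 0.2))
})

test_that("training is invariant to feature row permutation", {
  blobs <- blob_features(n_per = 50, seed = 9)
  shuffled <- blobs[withr::with_seed(99, sample.int(nrow(blobs))), ]
  n1 <- train_competitive(blobs, epochs = 100, seed = 3)
  n2 <- train_competitive(shuffled, epochs = 100, seed = 3)
  expect_identical(n1$weights, n2$weights)
})

test_that("a single neuron converges to the standardized data mean", {
  blobs <- blob_features(n_per = 150, seed = 12)
  net <- train_competitive(blobs, epochs = 500, seed = 4, L = 1,
                           lr_end = 0.001)
  expect_lt(max(abs(net$weights)), 0.05)  # z-scored space: mean is the origin
})

test_that("cluster prediction is the brute-force nearest weight with low-index ties", {
  blobs <- blob_features(n_per = 100, seed = 14)
  net <- train_competitive(blobs, epochs = 100, seed = 1)
  pts <- withr::with_seed(15,
    tibble::tibble(domfreq = runif(1000, -3, 3), std = runif(1000, -3, 3)))
  pred <- predict_cluster(net, pts)
  Z <- sweep(sweep(as.matrix(pts), 2, net$scaling$mean), 2, net$scaling$sd, "/")
  oracle <- apply(Z, 1, function(z) {
    d <- colSums((t(net$weights) - z)^2)
    which(d == min(d))[1]
  })
  expect_equal(pred, unname(oracle))

  # exact weight recovers its own cluster; equidistant point -> lower index
  w_orig <- tidy(net)
  expect_equal(predict_cluster(net, w_orig[1, c("domfreq", "std")]), 1L)
  net2 <- net
  net2$weights <- matrix(c(1, -1, 0, 0), 2, 2,
                         dimnames = list(NULL, c("domfreq", "std")))
  net2$scaling$mean <- c(0, 0); net2$scaling$sd <- c(1, 1)
  expect_equal(predict_cluster(net2, matrix(c(0, 5), 1)), 1L)
  expect_error(predict_cluster(net, matrix(1, 1, 3)), "dimension")
})

test_that("k-means baseline recovers blob centroids and reduces within-SS", {
  blobs <- blob_features(n_per = 100, seed = 16)
  km <- train_kmeans(blobs, k = 2, seed = 2)
  cent <- km$centroids
  means <- as.matrix(
    dplyr::summarise(dplyr::group_by(blobs, blob),
                     domfreq = mean(domfreq), std = mean(std))[, -1])
  d <- as.matrix(dist(rbind(cent, means)))[1:2, 3:4]
  expect_true(all(apply(d, 1, min) < 0.2))
  expect_setequal(apply(d, 1, which.min), c(1, 2))

  # Lloyd never increases the objective relative to its seeded start
  X <- as.matrix(blobs[, c("domfreq", "std")])
  init <- unique(X)[withr::with_seed(2, sample.int(nrow(unique(X)), 2)), ]
  wss0 <- sum(vapply(seq_len(nrow(X)), function(i) {
    min(colSums((t(init) - X[i, ])^2))
  }, numeric(1)))
  expect_lte(km$tot_withinss, wss0)

  km1 <- train_kmeans(blobs, k = 1, seed = 3)
  expect_equal(as.numeric(km1$centroids), unname(colMeans(X)))
})

test_that("cluster-to-class mapping uses the std heuristic and supervised votes", {
  feats <- tibble::tibble(domfreq = c(rnorm(50, 0.25, 0.01), rnorm(50, 0.5, 0.1)),
                          std = c(rnorm(50, 2, 0.05), rnorm(50, 0.1, 0.02)))
  km <- train_kmeans(feats, seed = 1)
  km <- map_clusters_to_classes(km)
  mapped <- tidy(km)
  expect_equal(mapped$class[which.min(mapped$std)], "apnea")
  expect_equal(mapped$class[which.max(mapped$std)], "normal")

  truth <- ifelse(seq_len(100) <= 50, "normal", "apnea")
  km_sup <- map_clusters_to_classes(km, feats, truth)
  expect_equal(km_sup$class_of_cluster, km$class_of_cluster)
  km_flip <- map_clusters_to_classes(km, feats, rev(truth))
  expect_equal(unname(sort(km_flip$class_of_cluster)),
               unname(sort(km$class_of_cluster)))
  expect_false(identical(km_flip$class_of_cluster, km$class_of_cluster))

  degenerate <- km
  degenerate$centroids[2, ] <- degenerate$centroids[1, ]
  expect_error(map_clusters_to_classes(degenerate), "supervised")
})

test_that("heuristic and supervised mappings agree on strong central apnea", {
  agree <- vapply(1:20, function(s) {
    rec <- waveform_record(duration = 200, amplitude = 1, noise_sd = 0.02,
                           events = apnea_events(c(60, 140), c(20, 20),
                                                 rep("central", 2),
                                                 attenuation = 0.2),
                           seed = s)
    feats <- extract_features(sliding_windows(rec$signal, 10, 0.5))
    truth <- truth_labels(tibble::tibble(t = feats$t_center, value = 0),
                          rec$annotations)
    net <- train_competitive(feats, epochs = 150, seed = s)
    identical(map_clusters_to_classes(net)$class_of_cluster,
              map_clusters_to_classes(net, feats, truth)$class_of_cluster)
  }, logical(1))
  expect_true(all(agree))
})

test_that("per-sample classification labels the whole grid sensibly", {
  # attenuated (not fully silenced) events keep the apnea windows'
  # dominant frequency anchored at the breathing rate, which is what makes
  # the two-cluster structure clean; see the methods vignette
  rec <- waveform_record(duration = 300, amplitude = 1, noise_sd = 0.02,
                         events = apnea_events(c(80, 200), c(20, 20),
                                               rep("central", 2),
                                               attenuation = 0.15),
                         seed = 33)
  feats <- extract_features(sliding_windows(rec$signal, 10, 0.1))
  net <- map_clusters_to_classes(train_competitive(feats, epochs = 300, seed = 1))

  labeled <- classify_signal(net, rec$signal)
  expect_equal(nrow(labeled), nrow(rec$signal))

  # a pure breathing signal is almost entirely 'normal'
  t <- (0:1499) / 10
  pure <- make_signal(sin(2 * pi * 0.25 * t) +
                        0.02 * withr::with_seed(8, rnorm(1500)))
  expect_gt(mean(classify_signal(net, pure)$label == "normal"), 0.95)

  # a flatlined signal is almost entirely 'apnea'
  flat <- make_signal(0.02 * withr::with_seed(9, rnorm(1500)))
  expect_gt(mean(classify_signal(net, flat)$label == "apnea"), 0.95)

  unmapped <- train_competitive(feats, epochs = 10, seed = 1)
  expect_error(classify_signal(unmapped, pure), "mapping")
})

test_that("models survive a JSON round trip", {
  blobs <- blob_features(seed = 40)
  net <- map_clusters_to_classes(train_competitive(blobs, epochs = 50, seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(net, path)
  back <- read_model(path)
  expect_equal(back$weights, net$weights)
  expect_equal(back$scaling$mean, net$scaling$mean)
  expect_equal(back$class_of_cluster, net$class_of_cluster)
  pts <- blobs[1:10, ]
  expect_equal(predict_class(back, pts), predict_class(net, pts))
})
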