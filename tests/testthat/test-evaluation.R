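test_that("segment construction adds margins and excludes crowded events", {
  sig <- make_signal(rep(0, 6001))  # 600 s at 10 Hz
  one <- tibble::tibble(start_s = 100, end_s = 120, type = "central")
  segs <- build_training_segments(sig, one)
  expect_length(segs$segments, 1)
  seg <- segs$segments[[1]]
  expect_equal(diff(range(seg$signal$t)), 70)  # 25 + 20 + 25
  expect_equal(sum(seg$truth == "apnea"), 201)  # 20 s inclusive at 10 Hz
  expect_true(all(seg$truth[seg$signal$t < 100] == "normal"))

  close2 <- tibble::tibble(start_s = c(100, 140), end_s = c(110, 150),
                           type = c("central", "central"))
  segs2 <- build_training_segments(sig, close2)  # 30 s gap < 25? no: 30 > 25
  expect_length(segs2$segments, 2)
  close3 <- tibble::tibble(start_s = c(100, 130), end_s = c(110, 140),
                           type = c("central", "central"))
  segs3 <- build_training_segments(sig, close3)  # 20 s gap -> both excluded
  expect_length(segs3$segments, 0)
  expect_equal(nrow(segs3$excluded), 2)

  # 5 events, the 2nd and 3rd closer than 25 s -> 3 segments (hand enumeration)
  five <- tibble::tibble(start_s = c(50, 150, 185, 300, 450),
                         end_s = c(70, 170, 200, 320, 470),
                         type = rep("obstructive", 5))
  segs5 <- build_training_segments(sig, five)
  expect_length(segs5$segments, 3)
  expect_equal(vapply(segs5$segments, function(s) s$event$start_s, numeric(1)),
               c(50, 300, 450))

  outside <- tibble::tibble(start_s = 590, end_s = 620, type = "central")
  expect_error(build_training_segments(sig, outside), "outside")
})

test_that("confusion matrices tally the four cells", {
  expect_equal(confusion_matrix(rep("apnea", 4), rep("apnea", 4))$fp, 0)
  cm <- confusion_matrix(rep("normal", 10),
                         rep(c("apnea", "normal"), each = 5))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 5, tn = 5))

  withr::with_seed(44, {
    pred <- sample(c("apnea", "normal"), 1000, replace = TRUE)
    truth <- sample(c("apnea", "normal"), 1000, replace = TRUE)
  })
  cm2 <- confusion_matrix(pred, truth)
  expect_equal(cm2$tp, sum(pred == "apnea" & truth == "apnea"))
  expect_equal(cm2$tn, sum(pred == "normal" & truth == "normal"))
  expect_equal(cm2$tp + cm2$fp + cm2$fn + cm2$tn, 1000)
  expect_error(confusion_matrix("apnea", c("apnea", "normal")), "mismatch")
  expect_error(confusion_matrix("hypopnea", "apnea"), "apnea")
})

test_that("metrics follow the defining equations and flag undefined cells", {
  m <- compute_metrics(new_confusion(tp = 50, fp = 10, fn = 25, tn = 100))
  expect_equal(m$tpr, 100 * 50 / 75)
  expect_equal(m$tnr, 100 * 100 / 110)
  expect_equal(m$ppv, 100 * 50 / 60)
  expect_equal(m$acc, 100 * 150 / 185)
  expect_equal(m$f1, 100 * 2 * 50 / (2 * 50 + 10 + 25))

  perfect <- compute_metrics(new_confusion(10, 0, 0, 20))
  expect_true(all(unlist(perfect[c("tpr", "tnr", "ppv", "acc", "f1")]) == 100))

  no_pos <- compute_metrics(new_confusion(0, 0, 0, 5))
  expect_true(is.na(no_pos$tpr) && is.na(no_pos$ppv) && is.na(no_pos$f1))
  expect_equal(no_pos$acc, 100)
  expect_error(compute_metrics(new_confusion(0, 0, 0, 0)), "zeros")
})

test_that("both algebraic forms of F1 agree on random confusion matrices", {
  withr::with_seed(45, {
    for (i in 1:1000) {
      cm <- new_confusion(sample(0:500, 1) + 1, sample(0:500, 1),
                          sample(0:500, 1), sample(0:500, 1))
      m <- compute_metrics(cm)
      f1_from_parts <- 2 * m$ppv * m$tpr / (m$ppv + m$tpr)
      f1_from_counts <- 100 * 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn)
      expect_equal(m$f1, f1_from_counts, tolerance = 1e-12)
      if (!is.na(f1_from_parts)) {
        expect_equal(m$f1, f1_from_parts, tolerance = 1e-12)
      }
    }
  })
})

test_that("event detection merges gaps, drops short runs and counts overlaps", {
  t <- (0:5999) / 10
  lab <- rep("normal", 6000)
  truth_events <- tibble::tibble(start_s = c(100, 300), end_s = c(120, 330),
                                 type = c("central", "obstructive"))
  lab[t >= 100 & t <= 120] <- "apnea"
  lab[t >= 300 & t <= 330] <- "apnea"
  labeled <- tibble::tibble(t = t, label = lab)
  rep1 <- detect_events(labeled, truth_events)
  expect_equal(rep1$detected_count, 2)
  expect_equal(rep1$total_count, 2)
  expect_equal(rep1$events_per_hour, 2 / (599.9 / 3600))

  # a 3 s apnea run is suppressed by the 5 s minimum (hand-worked trace)
  lab2 <- rep("normal", 6000)
  lab2[t >= 50 & t <= 53] <- "apnea"
  rep2 <- detect_events(tibble::tibble(t = t, label = lab2), truth_events)
  expect_equal(nrow(rep2$predicted), 0)
  expect_equal(rep2$detected_count, 0)

  # two runs separated by a 1.5 s gap merge into one event
  lab3 <- rep("normal", 6000)
  lab3[t >= 100 & t <= 103] <- "apnea"
  lab3[t >= 104.5 & t <= 108] <- "apnea"
  rep3 <- detect_events(tibble::tibble(t = t, label = lab3), truth_events)
  expect_equal(nrow(rep3$predicted), 1)
  expect_equal(rep3$predicted$end_s - rep3$predicted$start_s, 8)

  # empty annotations: zero totals, predictions still reported
  rep4 <- detect_events(labeled, NULL)
  expect_equal(rep4$total_count, 0)
  expect_equal(nrow(rep4$predicted), 2)
})

test_that("adding correct apnea labels never un-detects an event", {
  t <- (0:2999) / 10
  truth_events <- tibble::tibble(start_s = 100, end_s = 130, type = "central")
  lab <- rep("normal", 3000)
  lab[t >= 105 & t <= 112] <- "apnea"
  base <- detect_events(tibble::tibble(t = t, label = lab), truth_events)
  expect_equal(base$detected_count, 1)
  lab2 <- lab
  lab2[t >= 100 & t <= 130] <- "apnea"
  more <- detect_events(tibble::tibble(t = t, label = lab2), truth_events)
  expect_gte(more$detected_count, base$detected_count)
})

test_that("cross-validation splits are disjoint, exhaustive and reproducible", {
  rec <- waveform_record(
    duration = 700, amplitude = 1, noise_sd = 0.02,
    events = apnea_events(c(100, 250, 400, 550), rep(20, 4),
                          rep("central", 4), attenuation = 0.1),
    seed = 50)
  segs <- build_training_segments(rec$signal, rec$annotations)
  expect_length(segs$segments, 4)
  cv <- cross_validate(segs, n_repeats = 3, seed = 2, epochs = 100)
  expect_equal(nrow(cv$per_repeat), 3)
  expect_true(all(c("tpr", "tnr", "ppv", "acc", "f1") %in%
                    names(cv$per_repeat)))
  expect_equal(nrow(cv$summary), 5)
  cv2 <- cross_validate(segs, n_repeats = 3, seed = 2, epochs = 100)
  expect_identical(cv$per_repeat, cv2$per_repeat)

  # split arithmetic: 70% of 4 segments -> 3 train, 1 held out
  idx <- withr::with_seed(3, sample.int(4, 3))
  expect_length(setdiff(seq_len(4), idx), 1)
  expect_error(cross_validate(build_training_segments(
    rec$signal, rec$annotations[1:2, ])), "at least 4")
})

test_that("duplicated identical segments give identical metrics across repeats", {
  rec <- waveform_record(duration = 200, amplitude = 1, noise_sd = 0,
                         events = apnea_events(90, 20, "central",
                                               attenuation = 0),
                         seed = 60)
  segs <- build_training_segments(rec$signal, rec$annotations)
  seg <- segs$segments[[1]]
  segs$segments <- list(seg, seg, seg, seg, seg)
  cv <- cross_validate(segs, n_repeats = 3, seed = 4, epochs = 100)
  for (col in c("tpr", "tnr", "ppv", "acc", "f1")) {
    expect_equal(length(unique(cv$per_repeat[[col]])), 1)
  }
})
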