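# Spike detection, grouping and per-channel local maxima.

test_that("planted criterion-passing events are detected with high sensitivity and timing accuracy", {
  gen <- planted_recording(n_events = 20, seed = 7, duration_s = 30)
  ev <- detect_spikes(preprocess(gen$recording))
  hits <- 0
  for (i in seq_len(nrow(gen$events))) {
    ok <- any(ev$channel == gen$events$channel[i] &
              abs(ev$peak_time_ms - gen$events$planted_peak_ms[i]) <= 5)
    hits <- hits + ok
  }
  expect_gte(hits / nrow(gen$events), 0.95)
  expect_true(all(diff(ev$peak_time_ms) >= 0))   # sorted by time
  # every returned event satisfies all three criteria
  expect_true(all(ev$peak_amplitude_sd > 4))
  expect_true(all(abs(ev$ascending_slope) > 7 & abs(ev$descending_slope) > 7))
  expect_true(all(ev$width_ms < 20))
})

test_that("single-criterion distractor recordings yield zero detections", {
  lay <- tiny_layout()
  for (w in c("amplitude", "slope", "width")) {
    for (s in 1:3) {
      d <- make_distractor_events(lay, w, seed = s)
      ev <- detect_spikes(preprocess(d$recording))
      expect_equal(nrow(ev), 0L, info = sprintf("%s seed %d", w, s))
    }
  }
})

test_that("false positives on pure noise stay below one per channel-minute", {
  fp <- 0
  n_min <- 0
  for (s in 1:100) {
    set.seed(s)
    rec <- new_recording(matrix(stats::rnorm(60000, 0, 10), 1), 1000)
    fp <- fp + nrow(detect_spikes(preprocess(rec)))
    n_min <- n_min + 1
  }
  expect_lt(fp / n_min, 1)
})

test_that("detection is invariant to a global sign flip", {
  gen <- planted_recording(n_events = 8, seed = 3, duration_s = 15)
  rec <- preprocess(gen$recording)
  flipped <- rec
  flipped$samples <- -flipped$samples
  a <- detect_spikes(rec); b <- detect_spikes(flipped)
  expect_equal(a$peak_time_ms, b$peak_time_ms)
  expect_equal(a$peak_amplitude_sd, b$peak_amplitude_sd)
  expect_equal(a$peak_amplitude_uv, -b$peak_amplitude_uv)
})

test_that("segments shorter than 1 s are rejected", {
  expect_error(detect_spikes(new_recording(matrix(rnorm(500), 1), 1000)),
               "shorter than 1 s")
})

test_that("grouping chains events within the window and needs two distinct channels", {
  ev <- function(ch, t) data.frame(channel = ch, label = sprintf("B%02d", ch),
                                   position = ch, peak_time_ms = t,
                                   peak_amplitude_uv = 100,
                                   peak_amplitude_sd = 6,
                                   ascending_slope = 10, descending_slope = 10,
                                   width_ms = 10)
  # pairwise gaps <= 200 ms chain into one group of three
  g <- group_spikes(rbind(ev(1, 0), ev(2, 50), ev(3, 180)))
  expect_length(g, 1L)
  expect_equal(nrow(g[[1]]$members), 3L)
  expect_equal(g[[1]]$reference_time_ms, 0)
  # 0 and 300 ms exceed the window: two singletons, no group
  expect_length(group_spikes(rbind(ev(1, 0), ev(2, 300))), 0L)
  # many spikes on one channel only never form a group
  expect_length(group_spikes(rbind(ev(1, 0), ev(1, 50), ev(1, 120))), 0L)
  # chaining: consecutive gaps of 150 ms extend a single-linkage group
  g <- group_spikes(rbind(ev(1, 0), ev(2, 150), ev(3, 300)))
  expect_length(g, 1L)
  # clique mode trims the chain to the densest 200 ms window
  g <- group_spikes(rbind(ev(1, 0), ev(2, 150), ev(3, 300)),
                    linkage = "clique")
  expect_length(g, 1L)
  expect_lte(diff(range(g[[1]]$members$peak_time_ms)), 200)
})

test_that("grouping is invariant to event input order", {
  set.seed(1)
  ev <- data.frame(channel = rep(1:4, 5), label = "x",
                   position = rep(1:4, 5),
                   peak_time_ms = as.vector(outer(1:4 * 10, (0:4) * 1000, `+`)),
                   peak_amplitude_uv = rnorm(20, 100, 5),
                   peak_amplitude_sd = 6, ascending_slope = 10,
                   descending_slope = 10, width_ms = 10)
  g1 <- group_spikes(ev)
  g2 <- group_spikes(ev[sample(nrow(ev)), ])
  expect_equal(length(g1), length(g2))
  for (i in seq_along(g1))
    expect_equal(g1[[i]]$members$peak_time_ms, g2[[i]]$members$peak_time_ms)
})

test_that("local maxima around a group recover planted peaks and respect the inclusion floor", {
  gen <- planted_recording(n_events = 3, seed = 2, jitter_sd = 0,
                           noise_sd = 0, duration_s = 8)
  rec <- gen$recording
  ev <- detect_spikes(preprocess(rec))
  g <- group_spikes(ev)[[1]]
  lm1 <- local_maxima_around_group(rec, g)
  planted <- gen$events[gen$events$event == 1, ]
  expect_equal(lm1$peak_time_ms, planted$planted_peak_ms, tolerance = 1)
  # an inverted-polarity spike is still found (absolute deflection)
  rec2 <- rec; rec2$samples <- -rec2$samples
  lm2 <- local_maxima_around_group(rec2, g)
  expect_equal(lm2$peak_time_ms, lm1$peak_time_ms)
  # a pure-noise channel below 2 SD within the window is excluded
  set.seed(4)
  noisy <- rbind(rec$samples, rnorm(ncol(rec$samples), 0, 10))
  rec3 <- new_recording(noisy, 1000, positions = c(-2:2, 3))
  lm3 <- local_maxima_around_group(rec3, g)
  expect_true(is.na(lm3$peak_time_ms[6]) || lm3$peak_sd[6] >= 2)
})
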