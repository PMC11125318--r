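# Synthetic recordings, cohorts and training sets.

test_that("zero rates give pure background and an empty label track", {
  sr <- synth_recording(burst_params(0), burst_params(0),
                        durations_min = c(0.5, 0.5), seed = 1)
  expect_equal(nrow(sr$labels), 0)
  expect_true(all(sr$frame_labels == 0))
  expect_lt(max(abs(sr$recording$samples)), 0.01 * 6) # Gaussian background
  expect_equal(sr$recording$ingestion_time, 30)
})

test_that("event counts concentrate around the Poisson mean", {
  sr <- synth_recording(burst_params(30), burst_params(30),
                        durations_min = c(5, 5), seed = 2)
  n_ev <- nrow(sr$labels)
  expect_lt(abs(n_ev - 300), 3 * sqrt(300))
})

test_that("rendering is bit-identical for identical seeds", {
  a <- synth_recording(burst_params(40), burst_params(80),
                       durations_min = c(0.25, 0.25), seed = 7)
  b <- synth_recording(burst_params(40), burst_params(80),
                       durations_min = c(0.25, 0.25), seed = 7)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$labels, b$labels)
  c <- synth_recording(burst_params(40), burst_params(80),
                       durations_min = c(0.25, 0.25), seed = 8)
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("burst spectral mass stays inside the configured band", {
  # near-noiseless rendering isolates the bursts
  sr <- synth_recording(burst_params(20, snr_db = 60),
                        burst_params(0),
                        durations_min = c(1, 0.05), seed = 3,
                        noise_floor = 1e-4)
  fs <- 4000
  for (i in seq_len(min(5, nrow(sr$labels)))) {
    i0 <- floor(sr$labels$start_s[i] * fs) + 1
    i1 <- ceiling(sr$labels$end_s[i] * fs)
    x <- sr$recording$samples[i0:i1]
    spec <- Mod(stats::fft(x))^2
    freqs <- (seq_along(spec) - 1) * fs / length(spec)
    half <- freqs <= fs / 2
    in_band <- half & freqs >= 100 & freqs <= 1500
    expect_gt(sum(spec[in_band]) / sum(spec[half]), 0.9)
  }
})

test_that("frame truth marks exactly the frames with audible burst energy", {
  sr <- synth_recording(burst_params(30), burst_params(30),
                        durations_min = c(0.5, 0.5), seed = 10)
  fr <- segment_frames(sr$recording)
  expect_length(sr$frame_labels, fr$n)
  # positive frames overlap an annotated event; allow the rare merged tail
  pos <- which(sr$frame_labels == 1)
  starts <- (pos - 1) * 0.016
  on_event <- vapply(starts, function(s) {
    any(sr$labels$start_s < s + 0.064 & sr$labels$end_s > s)
  }, logical(1))
  expect_true(all(on_event))
  # every event contributes at least one positive frame at 20 dB SNR
  covered <- vapply(seq_len(nrow(sr$labels)), function(i) {
    any(starts + 0.064 > sr$labels$start_s[i] &
        starts < sr$labels$end_s[i])
  }, logical(1))
  expect_true(all(covered))
})

test_that("empirical event rates track the requested rates across seeds", {
  rates <- numeric(6)
  for (s in 1:6) {
    sr <- synth_recording(burst_params(45), burst_params(45),
                          durations_min = c(1, 1), seed = 100 + s)
    rates[s] <- nrow(sr$labels) / 2
  }
  expect_lt(abs(mean(rates) - 45), 3 * sqrt(45 * 12) / 12 / sqrt(6) * 6)
  expect_lt(abs(mean(rates) - 45), 10)
})

test_that("noiseless cohorts sit exactly on the preset line", {
  preset <- cohort_preset("carbonated")
  co <- synth_cohort(preset, seed = 42, log_noise_sd = 0)
  expect_equal(log(co$ratio), -0.706 * log(co$xb_bar) + 3.85,
               tolerance = 1e-12)
  expect_true(all(co$xb_bar >= 5 & co$xb_bar <= 150))

  co2 <- synth_cohort(preset, seed = 43, log_noise_sd = 0)
  f <- fit_loglog_linear(build_bssrp(co2))
  expect_equal(unname(coef(f)), c(-0.706, 3.85), tolerance = 1e-12)
})

test_that("cohort preconditions are enforced", {
  expect_error(synth_cohort(cohort_preset("water"), n = 2), "at least 3")
  expect_error(cohort_preset("water", log_noise_sd = -0.1), "non-negative")
  expect_error(preset_exponential(cohort_preset("water"), 1:3),
               "no exponential")
  co <- synth_cohort(cohort_preset("water"), seed = 3)
  co2 <- synth_cohort(cohort_preset("water"), seed = 3)
  expect_identical(co, co2)
})

test_that("the carbonated exponential preset evaluates the response curve", {
  preset <- cohort_preset("carbonated")
  expect_equal(preset_exponential(preset, 0), 16.4 + 1.20)
  x <- c(5, 50, 150)
  expect_equal(preset_exponential(preset, x),
               16.4 * exp(-0.0412 * x) + 1.20)
})

test_that("high-SNR training features separate classes for a linear probe", {
  tr <- synth_feature_training_set(400, 400, snr_db = 30, seed = 21)
  expect_equal(dim(tr$features), c(800, 40))
  expect_equal(sum(tr$labels), 400)
  dat <- data.frame(y = tr$labels, tr$features)
  probe <- suppressWarnings(stats::glm(y ~ ., data = dat, family = "binomial"))
  acc <- mean((stats::predict(probe, type = "response") >= 0.5) == tr$labels)
  expect_gte(acc, 0.95)

  tr2 <- synth_feature_training_set(400, 400, snr_db = 30, seed = 21)
  expect_identical(tr, tr2)
})

test_that("without rendered bursts the classes are indistinguishable", {
  tr <- synth_feature_training_set(300, 300, snr_db = -400, seed = 22)
  te <- synth_feature_training_set(300, 300, snr_db = -400, seed = 23)
  dat <- data.frame(y = tr$labels, tr$features)
  probe <- suppressWarnings(stats::glm(y ~ ., data = dat, family = "binomial"))
  pred <- stats::predict(probe, newdata = data.frame(te$features),
                         type = "response")
  acc <- mean((pred >= 0.5) == te$labels)
  expect_gt(acc, 0.40)
  expect_lt(acc, 0.62)
})
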