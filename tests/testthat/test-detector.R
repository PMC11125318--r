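# Segment classifier, episode formation, detection scoring.

test_that("the network separates two linearly separable clusters", {
  set.seed(10)
  n <- 200
  X <- rbind(matrix(stats::rnorm(n * 40, mean = 0), n, 40),
             matrix(stats::rnorm(n * 40, mean = 1.5), n, 40))
  y <- rep(c(0, 1), each = n)
  m <- train_ann(X, y, epochs = 200, seed = 7)
  expect_equal(mean(classify_segments(m, X) == y), 1)
  expect_lt(m$final_loss, m$loss_curve[1])
})

test_that("training is deterministic and the loss decreases", {
  set.seed(20)
  X <- matrix(stats::rnorm(100 * 40), 100, 40)
  y <- rep(c(0, 1), 50)
  m1 <- train_ann(X, y, epochs = 50, seed = 3)
  m2 <- train_ann(X, y, epochs = 50, seed = 3)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$biases, m2$biases)
  m3 <- train_ann(X, y, epochs = 50, seed = 4)
  expect_false(identical(m1$weights, m3$weights))
  # full-batch descent: no epoch may increase the loss appreciably
  expect_lt(max(diff(m1$loss_curve)), 0.05 * m1$loss_curve[1])
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(stats::rnorm(40 * 40), 40, 40)
  expect_error(train_ann(X, rep(1, 40)), "both classes")
  expect_error(train_ann(X, rep(0, 40)), "both classes")
  Xn <- X
  Xn[1, 1] <- NaN
  expect_error(train_ann(Xn, rep(c(0, 1), 20)), "non-finite")
})

test_that("classification threshold is a >= rule with valid range", {
  # hand-built single-layer model with zero weights: output exactly 0.5
  m <- structure(
    list(sizes = c(2L, 1L), weights = list(matrix(0, 2, 1)),
         biases = list(0), activation = "logistic", standardize = FALSE,
         center = c(0, 0), scale = c(1, 1)),
    class = "bs_ann")
  X <- matrix(c(1, 2), 1, 2)
  expect_equal(predict(m, X), 0.5)
  expect_equal(classify_segments(m, X, threshold = 0.5), 1L) # tie -> positive
  expect_equal(classify_segments(m, X, threshold = 0.51), 0L)
  expect_error(classify_segments(m, X, threshold = 1.1), "threshold")
  expect_error(classify_segments(m, X, threshold = -0.1), "threshold")
})

test_that("episode formation follows the run-length and duration rules", {
  ep <- form_episodes(c(0, 1, 1, 0, 1, 0))
  expect_equal(nrow(ep), 2)
  expect_equal(ep$onset_s, c(1, 4) * 0.016)
  expect_equal(ep$offset_s[1] - ep$onset_s[1], 0.016 + 0.064)
  expect_equal(ep$n_segments, c(2L, 1L))

  expect_equal(nrow(form_episodes(rep(0, 10))), 0)

  all1 <- form_episodes(rep(1, 10))
  expect_equal(nrow(all1), 1)
  expect_equal(all1$offset_s - all1$onset_s, 9 * 0.016 + 0.064)
})

test_that("episode formation is consistent with label structure", {
  set.seed(31)
  for (i in 1:20) {
    labels <- stats::rbinom(200, 1, 0.3)
    ep <- form_episodes(labels)
    # episode count equals the number of 0 -> 1 transitions
    expect_equal(nrow(ep), sum(diff(c(0L, labels)) == 1L))
    # total positive segments preserved
    expect_equal(sum(ep$n_segments), sum(labels))
    # re-expanding episodes to labels and re-forming is idempotent
    back <- integer(200)
    for (j in seq_len(nrow(ep))) {
      i0 <- round(ep$onset_s[j] / 0.016) + 1
      back[i0:(i0 + ep$n_segments[j] - 1)] <- 1L
    }
    expect_equal(back, labels)
    ep2 <- form_episodes(back)
    expect_equal(as.data.frame(ep2), as.data.frame(ep))
  }
})

test_that("detection metrics match hand arithmetic and brute force", {
  # TP=3, FP=1, FN=1, TN=5
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  tru <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- evaluate_detection(pred, tru)$per_recording
  expect_equal(m$sensitivity, 75)
  expect_equal(m$ppv, 75)
  expect_equal(m$f1, 75)
  expect_equal(m$accuracy, 80)

  perfect <- evaluate_detection(tru, tru)$per_recording
  expect_equal(unlist(perfect[, 6:11]), rep(100, 6), ignore_attr = TRUE)

  set.seed(17)
  for (i in 1:10) {
    p <- stats::rbinom(50, 1, 0.4)
    y <- stats::rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2 || length(unique(p)) < 2) next
    got <- evaluate_detection(p, y)$per_recording
    tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y); tn <- sum(!p & !y)
    expect_equal(got$sensitivity, 100 * tp / (tp + fn))
    expect_equal(got$specificity, 100 * tn / (tn + fp))
    expect_equal(got$ppv, 100 * tp / (tp + fp))
    expect_equal(got$npv, 100 * tn / (tn + fn))
  }
})

test_that("F1 is the harmonic mean of sensitivity and PPV", {
  # at the reported sensitivity/PPV operating point the harmonic mean is
  # 76.98%, consistent with a per-recording-averaged F1 near 76.6%
  sens <- 90.58
  ppv <- 66.92
  f1 <- 2 * sens * ppv / (sens + ppv)
  expect_equal(f1, 76.98, tolerance = 1e-4)
})

test_that("recordings without positives are excluded from that metric", {
  pred <- list(c(1, 0, 1), c(0, 0, 1))
  tru <- list(c(1, 0, 1), c(0, 0, 0)) # second recording has no positives
  msgs <- capture_messages(m <- evaluate_detection(pred, tru))
  expect_true(any(grepl("sensitivity", msgs)))
  expect_true(is.na(m$per_recording$sensitivity[2]))
  expect_equal(m$summary["sensitivity", "mean"], 100)
})

test_that("model JSON round-trips through save/load", {
  set.seed(50)
  X <- matrix(stats::rnorm(60 * 40), 60, 40)
  y <- rep(c(0, 1), 30)
  m <- train_ann(X, y, epochs = 30, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  save_ann(m, path)
  m2 <- load_ann(path)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
})
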