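# Stimulus-response plots, fits, correlation statistics and the log-log
# distance metric.

test_that("stimulus-response points are ratios with exclusion semantics", {
  p <- sr_point(10, 20)
  expect_equal(p$ratio, 2)
  expect_equal(sr_point(7, 7)$ratio, 1)
  expect_error(sr_point(0, 5), "positive")
})

test_that("cohort plots exclude unusable participants with a warning", {
  co <- data.frame(participant_id = sprintf("P%02d", 1:20),
                   xb_bar = seq(5, 100, length.out = 20),
                   xa_bar = seq(10, 120, length.out = 20))
  b <- build_bssrp(co)
  expect_equal(nrow(b$points), 20)

  co$xb_bar[7] <- 0
  expect_warning(b2 <- build_bssrp(co), "P07")
  expect_equal(nrow(b2$points), 19)
  expect_equal(b2$excluded_ids, "P07")

  co3 <- co[1:3, ]
  co3$xb_bar[1] <- 0
  expect_warning(expect_error(build_bssrp(co3), "fewer than 3"))
})

test_that("log points use the natural logarithm", {
  co <- data.frame(participant_id = c("a", "b", "c"),
                   xb_bar = c(exp(1), exp(2), exp(3)),
                   xa_bar = c(exp(1) * exp(2), exp(2), exp(3) * exp(1)))
  b <- build_bssrp(co)
  expect_equal(b$points$ln_xb_bar, c(1, 2, 3))
  expect_equal(b$points$ln_ratio, c(2, 0, 1))
})

test_that("log-log OLS reproduces exact lines and flat data", {
  # collinear points on y = 2x - 1
  f <- fit_loglog_linear(c(0, 1, 2), c(-1, 1, 3))
  expect_equal(unname(coef(f)), c(2, -1), tolerance = 1e-12)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-12)

  set.seed(2)
  x <- stats::rnorm(10)
  f0 <- fit_loglog_linear(x, rep(3.5, 10) + 0 * x)
  expect_lt(abs(coef(f0)["slope"]), 1e-12)

  expect_error(fit_loglog_linear(rep(1, 5), stats::rnorm(5)), "degenerate")
})

test_that("the noiseless carbonated preset is recovered exactly", {
  co <- synth_cohort(cohort_preset("carbonated"), seed = 123,
                     log_noise_sd = 0)
  b <- build_bssrp(co)
  f <- fit_loglog_linear(b)
  expect_equal(unname(coef(f)["slope"]), -0.706, tolerance = 1e-12)
  expect_equal(unname(coef(f)["intercept"]), 3.85, tolerance = 1e-12)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-9)
})

test_that("exponential fits recover noiseless parameters and are idempotent", {
  x <- seq(5, 150, by = 5)
  y <- 16.4 * exp(-0.0412 * x) + 1.20
  f <- fit_exponential(x, y)
  expect_equal(unname(coef(f)),
               c(16.4, -0.0412, 1.20), tolerance = 1e-6)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-9)

  # refit on its own residual-free predictions
  f2 <- fit_exponential(x, predict(f))
  expect_equal(coef(f2), coef(f), tolerance = 1e-6)

  expect_warning(fc <- fit_exponential(x, rep(2, length(x))),
                 "unidentifiable")
  expect_false(fc$identifiable)
  expect_equal(unname(coef(fc)["b"]), 0)
  expect_error(fit_exponential(1:3, c(1, 2, 3)), "at least 4")
})

test_that("pearson_cor matches cor.test and the published threshold", {
  x <- 1:5
  pc <- pearson_cor(x, 2 * x + 1)
  expect_equal(pc$r, 1)
  expect_equal(pc$p_value, 0)

  # cross-check against the reference implementation
  set.seed(33)
  for (i in 1:10) {
    a <- stats::rnorm(15)
    b <- stats::rnorm(15)
    got <- pearson_cor(a, b)
    ref <- stats::cor.test(a, b)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }

  # at n = 20 the two-sided 5% threshold on |r| is 0.4438
  mk_r <- function(target_r, n = 20) {
    x <- scale(seq_len(n))[, 1]
    set.seed(77)
    z <- stats::rnorm(n)
    z <- scale(stats::resid(stats::lm(z ~ x)))[, 1]
    target_r * x + sqrt(1 - target_r^2) * z
  }
  x20 <- scale(seq_len(20))[, 1]
  expect_true(pearson_cor(x20, mk_r(0.4439))$p_value < 0.05)
  expect_false(pearson_cor(x20, mk_r(0.4437))$p_value < 0.05)

  expect_error(pearson_cor(rep(1, 5), 1:5), "variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("t-based p-values agree with a permutation test", {
  set.seed(44)
  n <- 15
  x <- stats::rnorm(n)
  y <- 0.5 * x + stats::rnorm(n)
  got <- pearson_cor(x, y)

  B <- 1e5
  perms <- replicate(B, sample.int(n))
  Y <- matrix(y[perms], n, B)
  r_null <- as.numeric(stats::cor(x, Y))
  p_perm <- (1 + sum(abs(r_null) >= abs(got$r))) / (B + 1)
  expect_lt(abs(p_perm - got$p_value), 0.01)
})

test_that("adjusted R-squared follows the textbook formula", {
  expect_equal(adjusted_r2(numeric(10), stats::rnorm(10) + 5, k = 1), 1)

  # null-model residuals: R^2 = 0, so adjusted = 1 - (n-1)/(n-k-1) = -1/8
  set.seed(55)
  y <- stats::rnorm(10)
  expect_equal(adjusted_r2(y - mean(y), y, k = 1), -1 / 8, tolerance = 1e-12)

  for (i in 1:5) {
    x <- stats::rnorm(30)
    y <- 1 + 2 * x + stats::rnorm(30)
    fit <- stats::lm(y ~ x)
    expect_equal(adjusted_r2(stats::resid(fit), y, k = 1),
                 summary(fit)$adj.r.squared, tolerance = 1e-12)
    # penalty: adjusted never exceeds plain R^2
    r2 <- summary(fit)$r.squared
    expect_lte(adjusted_r2(stats::resid(fit), y, k = 1), r2)
  }
  expect_error(adjusted_r2(numeric(3), 1:3, k = 2), "undefined")
})

test_that("the log-log distance is a metric on valid points", {
  A <- list(xb_bar = exp(1), ratio = exp(1))
  B <- list(xb_bar = exp(2), ratio = exp(1))
  expect_equal(plot_distance(A, A), 0)
  expect_equal(plot_distance(A, B), 1)

  set.seed(66)
  for (i in 1:25) {
    pts <- lapply(1:3, function(j) {
      list(xb_bar = exp(stats::rnorm(1)), ratio = exp(stats::rnorm(1)))
    })
    d12 <- plot_distance(pts[[1]], pts[[2]])
    d21 <- plot_distance(pts[[2]], pts[[1]])
    d13 <- plot_distance(pts[[1]], pts[[3]])
    d23 <- plot_distance(pts[[2]], pts[[3]])
    expect_gte(d12, 0)
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
  expect_error(plot_distance(list(xb_bar = -1, ratio = 2), A), "invalid")
})

test_that("interval dispersion shrinks with longer analysis intervals", {
  # participants with time-constant rates: all dispersion is Poisson noise
  set.seed(88)
  cohort <- lapply(1:30, function(i) {
    lam <- stats::runif(1, 20, 60) # events/min
    n_ev <- stats::rpois(1, lam * 15)
    list(onsets = sort(stats::runif(n_ev, 0, 900)), ingestion_time = 300,
         participant_id = sprintf("P%02d", i))
  })
  d <- interval_dispersion(cohort)
  s <- d$summary
  expect_equal(s$median[1], 0)          # reference vs itself
  expect_gte(s$median[3], s$median[2])  # 10-1 disperses more than 10-5
  expect_equal(nrow(d$distances), 90)
})

test_that("participants without episodes are dropped per comparison only", {
  cohort <- list(
    list(onsets = c(100, 250, 310, 400, 500), ingestion_time = 300,
         participant_id = "ok"),
    # no events within 1 min of ingestion on the before side
    list(onsets = c(100, 150, 310, 400), ingestion_time = 300,
         participant_id = "sparse")
  )
  d <- interval_dispersion(cohort)
  dropped <- d$dropped[["1-1"]]
  expect_true("sparse" %in% dropped)
  expect_false("ok" %in% dropped)
  kept_5_5 <- d$distances$participant_id[d$distances$comparison == "5-5"]
  expect_true("sparse" %in% kept_5_5)
})

test_that("the detection limit follows the framing geometry", {
  expect_equal(detection_limit(), 3747L)
  expect_equal(detection_limit(shift = 0.064), 937L)
  expect_equal(detection_limit(duration = 0.064), 1L)
  expect_equal(detection_limit(duration = 0.05), 0L)
})

test_that("sub-interval scans separate segments from episodes", {
  # identity regime: every episode is a single segment
  set.seed(91)
  labels <- integer(3747 * 5)
  ones <- sort(sample(seq(5, length(labels) - 5, by = 7), 400))
  labels[ones] <- 1L
  ep <- form_episodes(labels)
  expect_true(all(ep$n_segments == 1))
  sc <- subinterval_scan(labels, ep)
  expect_equal(sc$table$segments, sc$table$episodes)
  expect_equal(sc$cor_raw$r, 1)

  # long-burst regime: few long episodes, many segments
  labels2 <- integer(3747 * 5)
  for (s in seq(1, length(labels2) - 400, by = 3000)) {
    labels2[s:(s + 200)] <- 1L
  }
  ep2 <- form_episodes(labels2)
  sc2 <- subinterval_scan(labels2, ep2)
  expect_true(all(sc2$table$episodes * 50 < sc2$table$segments))

  # exceedance fraction is a plain proportion
  sc3 <- subinterval_scan(labels, ep, threshold = 80)
  expect_equal(sc3$exceedance, mean(sc$table$segments >= 80))
})

test_that("segment-based plots equal episode-based plots in the identity regime", {
  co <- data.frame(participant_id = rep(sprintf("P%d", 1:6), each = 2),
                   side = rep(c("before", "after"), 6),
                   width_min = rep(c(5, 10), 6),
                   episodes_per_min = c(10, 20, 30, 25, 50, 40,
                                        8, 12, 60, 30, 15, 20),
                   segments_per_min = c(10, 20, 30, 25, 50, 40,
                                        8, 12, 60, 30, 15, 20))
  b1 <- build_bssrp(co, "episodes_per_min")
  b2 <- bssrp_from_segments(co)
  expect_equal(b1$points[, -1], b2$points[, -1])
  expect_equal(log(b2$points$xb_bar), b2$points$ln_xb_bar)
})

test_that("log-log slope estimates are unbiased over Monte-Carlo replicates", {
  m_true <- -0.7
  q_true <- 3.8
  sigma <- 0.3
  n <- 20
  slopes <- numeric(200)
  ses <- numeric(200)
  set.seed(1234)
  for (r in 1:200) {
    lnxb <- log(stats::runif(n, 5, 150))
    lnratio <- m_true * lnxb + q_true + stats::rnorm(n, 0, sigma)
    f <- fit_loglog_linear(lnxb, lnratio)
    slopes[r] <- coef(f)["slope"]
    ses[r] <- summary(f)$slope_se
  }
  # mean estimate within 3 standard errors of the Monte-Carlo mean
  expect_lt(abs(mean(slopes) - m_true), 3 * stats::sd(slopes) / sqrt(200))
  expect_lt(abs(mean(ses) - stats::sd(slopes)) / stats::sd(slopes), 0.15)
})

test_that("water-preset cohorts show no systematic correlation", {
  rs <- numeric(200)
  for (i in 1:200) {
    co <- synth_cohort(cohort_preset("water"), seed = 5000 + i)
    b <- build_bssrp(co)
    rs[i] <- pearson_cor(b$points$ln_xb_bar, b$points$ln_ratio)$r
  }
  qs <- stats::quantile(rs, c(0.025, 0.975))
  expect_lt(qs[1], 0)
  expect_gt(qs[2], 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("simulated responses reproduce the fitted law's noise level", {
  set.seed(3)
  x <- log(stats::runif(50, 5, 150))
  y <- -0.7 * x + 3.8 + stats::rnorm(50, 0, 0.2)
  f <- fit_loglog_linear(x, y)
  sims <- simulate(f, nsim = 200, seed = 1)
  expect_equal(dim(sims), c(50, 200))
  # refitting a simulated response recovers the slope on average
  slopes <- vapply(sims, function(ys) {
    unname(coef(fit_loglog_linear(x, ys))["slope"])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - coef(f)["slope"]),
            3 * stats::sd(slopes) / sqrt(200))
})

test_that("bssrp reports serialize the fits and the correlation", {
  co <- synth_cohort(cohort_preset("carbonated"), seed = 9,
                     log_noise_sd = 0.1)
  b <- build_bssrp(co)
  rep <- bssrp_report(b)
  expect_equal(rep$n, 20)
  expect_lt(rep$loglog$slope, 0)
  expect_true(rep$correlation$significant)
  expect_true(all(c("a", "b", "c") %in% names(rep$exponential)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_bssrp(b, path)
  back <- utils::read.csv(path)
  expect_equal(names(back),
               c("participant_id", "xb_bar", "xa_bar", "ratio",
                 "ln_xb_bar", "ln_ratio"))
})
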