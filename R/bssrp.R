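# Stimulus-response plots (BSSRPs), their fits, correlation statistics,
# the log-log distance metric and detection-limit diagnostics.

#' Stimulus-response point of one participant
#'
#' The response is measured as the ratio of the post-ingestion to the
#' pre-ingestion mean feature value, `ratio = xa_bar / xb_bar`.
#'
#' @param xb_bar Pre-ingestion mean feature value (must be > 0; a
#'   participant with no detected bowel sounds before ingestion is
#'   excluded at the cohort level rather than producing NaN here).
#' @param xa_bar Post-ingestion mean feature value.
#' @param participant_id Identifier.
#' @return A list of class `sr_point` with `xb_bar`, `xa_bar`, `ratio`.
#' @export
sr_point <- function(xb_bar, xa_bar, participant_id = NA_character_) {
  if (!is.finite(xb_bar) || xb_bar <= 0) {
    stop("xb_bar must be positive; exclude this participant upstream")
  }
  structure(list(participant_id = participant_id, xb_bar = xb_bar,
                 xa_bar = xa_bar, ratio = xa_bar / xb_bar),
            class = "sr_point")
}

#' Build a cohort stimulus-response plot
#'
#' One point per retained participant: `x = xb_bar` (pre-ingestion mean
#' of the chosen feature), `y = ratio = xa_bar / xb_bar`.  Participants
#' with `xb_bar` zero/undefined or non-positive ratio (no bowel sounds
#' detected in one of the intervals) are excluded with a warning, which
#' mirrors how cohort members without detected sounds are dropped from
#' the correlation analyses.  Natural logarithms of both axes give the
#' log-log BSSRP.
#'
#' @param cohort BSTDAF table for the cohort: data frame in the layout
#'   of [bstdaf_table()] rows (long format, one row per participant and
#'   side), or a data frame with columns `participant_id`, `xb_bar`,
#'   `xa_bar` already paired.
#' @param feature Which feature to plot (column name in the BSTDAF
#'   table, e.g. `"episodes_per_min"`, `"ssi_s"`, `"power"`,
#'   `"length_s"`, `"segments_per_min"`).
#' @param before_width,after_width Interval widths (minutes) selecting
#'   the table rows.
#' @return An object of class `bssrp`: list with `points` (data frame
#'   `participant_id, xb_bar, xa_bar, ratio, ln_xb_bar, ln_ratio`),
#'   `feature`, `before_width`, `after_width`, `excluded_ids`.
#' @export
build_bssrp <- function(cohort, feature = "episodes_per_min",
                        before_width = 5, after_width = 10) {
  if (all(c("xb_bar", "xa_bar") %in% names(cohort))) {
    pts <- data.frame(participant_id = as.character(cohort$participant_id),
                      xb_bar = cohort$xb_bar, xa_bar = cohort$xa_bar)
  } else if (all(c("xb_bar", "ratio") %in% names(cohort))) {
    pts <- data.frame(participant_id = as.character(cohort$participant_id),
                      xb_bar = cohort$xb_bar,
                      xa_bar = cohort$ratio * cohort$xb_bar)
  } else {
    if (!feature %in% names(cohort)) {
      stop("feature column not found in BSTDAF table: ", feature)
    }
    bef <- cohort[cohort$side == "before" & cohort$width_min == before_width, ]
    aft <- cohort[cohort$side == "after" & cohort$width_min == after_width, ]
    ids <- union(bef$participant_id, aft$participant_id)
    pts <- data.frame(
      participant_id = as.character(ids),
      xb_bar = bef[[feature]][match(ids, bef$participant_id)],
      xa_bar = aft[[feature]][match(ids, aft$participant_id)]
    )
  }
  bad <- !is.finite(pts$xb_bar) | pts$xb_bar <= 0 |
         !is.finite(pts$xa_bar) | pts$xa_bar <= 0
  excluded <- pts$participant_id[bad]
  if (length(excluded) > 0) {
    warning("excluding participant(s) without usable feature values: ",
            paste(excluded, collapse = ", "))
  }
  pts <- pts[!bad, , drop = FALSE]
  if (nrow(pts) < 3) {
    stop("fewer than 3 retained participants; BSSRP not built")
  }
  pts$ratio <- pts$xa_bar / pts$xb_bar
  pts$ln_xb_bar <- log(pts$xb_bar)
  pts$ln_ratio <- log(pts$ratio)
  rownames(pts) <- NULL
  structure(list(points = pts, feature = feature,
                 before_width = before_width, after_width = after_width,
                 excluded_ids = as.character(excluded)),
            class = "bssrp")
}

#' @export
print.bssrp <- function(x, ...) {
  cat("BSSRP of", x$feature, ":", nrow(x$points), "participants",
      sprintf("(before %g min, after %g min)\n", x$before_width, x$after_width))
  if (length(x$excluded_ids)) {
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.bssrp <- function(x, log_log = FALSE, ...) {
  p <- x$points
  if (log_log) {
    graphics::plot(p$ln_xb_bar, p$ln_ratio,
                   xlab = expression(ln(bar(x)[b])),
                   ylab = "ln(ratio)", main = paste("log-log BSSRP:", x$feature),
                   ...)
  } else {
    graphics::plot(p$xb_bar, p$ratio, xlab = expression(bar(x)[b]),
                   ylab = "ratio", main = paste("BSSRP:", x$feature), ...)
  }
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (n - 1) / (n - k - 1)` with
#' `R^2 = 1 - SSR / SST`; `k` is the number of predictors-equivalent
#' (1 for the log-log line, 2 for the three-parameter exponential).
#'
#' @param residuals Fit residuals.
#' @param y Observed responses.
#' @param n Number of observations (default `length(y)`).
#' @param k Predictor count of the model.
#' @return Adjusted R-squared (a number `<= 1`, possibly negative).
#' @export
adjusted_r2 <- function(residuals, y, n = length(y), k) {
  if (n <= k + 1) stop("adjusted R-squared undefined for n <= k + 1")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero total variance in y")
  r2 <- 1 - sum(residuals^2) / sst
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

new_bssrp_fit <- function(model, parameters, x, y, fitted, k,
                          extra = list()) {
  res <- y - fitted
  adj <- tryCatch(adjusted_r2(res, y, k = k), error = function(e) NA_real_)
  structure(c(list(model = model, parameters = parameters,
                   x = x, y = y, fitted = fitted, residuals = res,
                   n = length(y), k = k, adjusted_r2 = adj),
              extra),
            class = "bssrp_fit")
}

#' Exponential fit of a stimulus-response plot
#'
#' Least-squares fit of `ratio = a * exp(b * xb_bar) + c` by
#' Levenberg-Marquardt with multi-start initialization: `c0 = min(y)`
#' (shrunk slightly toward zero), `a0 = max(y) - min(y)`, and `b0` from
#' a log-linear pre-fit of `log(y - c0)` on `x`, plus sign-flipped and
#' rescaled variants of `b0`.  The best converged start (lowest residual
#' sum of squares) is returned.  Adjusted R-squared uses `k = 2`
#' predictors-equivalent for the 3-parameter model.  Data with
#' essentially constant response are flagged unidentifiable (`a` and
#' `c` are then only jointly determined) and returned with `b = 0`.
#'
#' @param object A `bssrp`, or a numeric vector `x` when `y` is given.
#' @param y Optional response vector when `object` is the predictor
#'   vector.
#' @return A `bssrp_fit` with `model = "exponential"` and parameters
#'   `a`, `b`, `c`.
#' @export
fit_exponential <- function(object, y = NULL) {
  if (inherits(object, "bssrp")) {
    x <- object$points$xb_bar
    y <- object$points$ratio
  } else {
    x <- as.numeric(object)
  }
  if (length(x) < 4) stop("exponential fit needs at least 4 points")

  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    fitted <- rep(mean(y), length(y))
    out <- new_bssrp_fit("exponential",
                         c(a = 0, b = 0, c = mean(y)),
                         x, y, fitted, k = 2,
                         extra = list(identifiable = FALSE))
    warning("constant response: exponential parameters unidentifiable ",
            "(returning a + c decomposition with b = 0)")
    return(out)
  }

  c0 <- min(y) - 0.05 * diff(range(y))
  a0 <- max(y) - min(y)
  pos <- y - c0 > 0
  b0 <- tryCatch(
    unname(stats::coef(stats::lm(log(y[pos] - c0) ~ x[pos]))[2]),
    error = function(e) -1 / max(abs(x)))
  if (!is.finite(b0) || b0 == 0) b0 <- -1 / max(abs(x))
  starts <- list(
    c(a = a0, b = b0, c = c0),
    c(a = a0, b = -b0, c = c0),
    c(a = a0, b = b0 / 4, c = c0),
    c(a = a0, b = 4 * b0, c = c0),
    c(a = -a0, b = -b0, c = max(y))
  )

  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x) + c,
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  if (is.null(best)) stop("exponential fit failed to converge from any start")
  pars <- stats::coef(best)
  fitted <- pars["a"] * exp(pars["b"] * x) + pars["c"]
  new_bssrp_fit("exponential", pars, x, y, fitted, k = 2,
                extra = list(identifiable = TRUE))
}

#' Ordinary least-squares fit of the log-log stimulus-response plot
#'
#' Fits `ln(ratio) = m * ln(xb_bar) + q` by OLS (natural logarithms).
#' Adjusted R-squared uses `k = 1`.
#'
#' @param object A `bssrp`, or the `ln(xb_bar)` vector when `y` is
#'   given.
#' @param y Optional `ln(ratio)` vector when `object` is a plain
#'   vector.
#' @return A `bssrp_fit` with `model = "loglog_linear"` and parameters
#'   `slope`, `intercept`.
#' @export
fit_loglog_linear <- function(object, y = NULL) {
  if (inherits(object, "bssrp")) {
    x <- object$points$ln_xb_bar
    y <- object$points$ln_ratio
  } else {
    x <- as.numeric(object)
  }
  if (length(x) < 3) stop("log-log fit needs at least 3 points")
  if (stats::var(x) == 0) stop("degenerate predictor: zero variance in ln(xb_bar)")
  fit <- stats::lm(y ~ x)
  pars <- c(slope = unname(stats::coef(fit)[2]),
            intercept = unname(stats::coef(fit)[1]))
  fitted <- pars["intercept"] + pars["slope"] * x
  new_bssrp_fit("loglog_linear", pars, x, y, fitted, k = 1,
                extra = list(lm = fit))
}

#' @export
print.bssrp_fit <- function(x, ...) {
  if (x$model == "exponential") {
    cat(sprintf("Exponential fit: ratio = %.4g * exp(%.4g x) + %.4g\n",
                x$parameters["a"], x$parameters["b"], x$parameters["c"]))
  } else {
    cat(sprintf("Log-log linear fit: ln(ratio) = %.4g * ln(xb) + %.4g\n",
                x$parameters["slope"], x$parameters["intercept"]))
  }
  cat(sprintf("  n = %d, adjusted R-squared = %.4f\n", x$n, x$adjusted_r2))
  invisible(x)
}

#' @export
coef.bssrp_fit <- function(object, ...) object$parameters

#' @export
residuals.bssrp_fit <- function(object, ...) object$residuals

#' @export
predict.bssrp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  p <- object$parameters
  if (object$model == "exponential") {
    p["a"] * exp(p["b"] * x) + p["c"]
  } else {
    p["intercept"] + p["slope"] * x
  }
}

#' Simulate responses from a fitted stimulus-response model
#'
#' Draws new response vectors at the fitted values plus Gaussian noise
#' with the residual standard deviation, in the convention of
#' [stats::simulate()].
#'
#' @param object A `bssrp_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns (`sim_1`, ...), one row per
#'   original observation.
#' @export
simulate.bssrp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(sum(object$residuals^2) /
                max(1, object$n - object$k - 1))
  out <- replicate(nsim,
                   object$fitted + stats::rnorm(object$n, 0, sigma),
                   simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' @export
summary.bssrp_fit <- function(object, ...) {
  out <- list(model = object$model, parameters = object$parameters,
              n = object$n, adjusted_r2 = object$adjusted_r2,
              rss = sum(object$residuals^2),
              sigma = sqrt(sum(object$residuals^2) /
                           max(1, object$n - object$k - 1)))
  if (!is.null(object$lm)) {
    sm <- summary(object$lm)
    out$slope_se <- sm$coefficients[2, 2]
    out$intercept_se <- sm$coefficients[1, 2]
  }
  class(out) <- "summary.bssrp_fit"
  out
}

#' @export
print.summary.bssrp_fit <- function(x, ...) {
  cat("Model:", x$model, "\n")
  print(x$parameters)
  cat(sprintf("n = %d, adj. R^2 = %.4f, residual sigma = %.4g\n",
              x$n, x$adjusted_r2, x$sigma))
  if (!is.null(x$slope_se)) {
    cat(sprintf("slope SE = %.4g, intercept SE = %.4g\n",
                x$slope_se, x$intercept_se))
  }
  invisible(x)
}

#' @export
plot.bssrp_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "x", ylab = "y",
                 main = paste("BSSRP fit:", x$model), ...)
  ord <- order(x$x)
  graphics::lines(x$x[ord], x$fitted[ord], col = "red")
  invisible(x)
}

#' Pearson correlation with Student-t significance test
#'
#' Sample Pearson coefficient `r`, test statistic
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` and two-sided p-value from the
#' Student-t distribution with `n - 2` degrees of freedom, under the
#' null hypothesis of no correlation.  Significance is declared at
#' `p < 0.05`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both with
#'   non-zero variance.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `cor_result`: `r`, `n`, `t_stat`, `p_value`,
#'   `significant`.
#' @export
pearson_cor <- function(x, y, alpha = 0.05) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3) stop("need at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    t_stat <- Inf * sign(r)
    p <- 0
  } else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(r = r, n = n, t_stat = t_stat, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d), t = %.3f, p = %.4g%s\n",
              x$r, x$n, x$t_stat, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Distance between two points of a log-log stimulus-response plot
#'
#' Euclidean distance in the (natural) log-log plane:
#' `r_AB = sqrt((ln xb_A - ln xb_B)^2 + (ln ratio_A - ln ratio_B)^2)`.
#'
#' @param a,b Points: `sr_point` objects, or lists/one-row data frames
#'   with `xb_bar` and `ratio` entries.
#' @return Non-negative distance.
#' @export
plot_distance <- function(a, b) {
  get_pt <- function(p) {
    xb <- p$xb_bar
    rt <- p$ratio
    if (is.null(xb) || is.null(rt) || !is.finite(xb) || !is.finite(rt) ||
        xb <= 0 || rt <= 0) {
      stop("invalid stimulus-response point (need positive xb_bar and ratio)")
    }
    c(xb, rt)
  }
  pa <- get_pt(a)
  pb <- get_pt(b)
  sqrt((log(pa[1]) - log(pb[1]))^2 + (log(pa[2]) - log(pb[2]))^2)
}

#' Dispersion of a participant's plot point across interval lengths
#'
#' For each participant the stimulus-response point is computed at a
#' reference interval pair (default 5 min before / 10 min after) and at
#' each comparison pair (default 5/5 and 1/1), and the log-log plane
#' distance from the reference point is reported.  The reference
#' compared with itself is the zero baseline.  Participants without
#' bowel sounds on either side of a given pair are dropped from that
#' comparison only (they still contribute to the longer intervals).
#'
#' @param cohort A list, one element per participant:
#'   `list(onsets = <episode onset times in s>, ingestion_time = <s>,
#'   participant_id = <chr>)`.
#' @param reference `c(before, after)` interval widths in minutes.
#' @param comparisons List of `c(before, after)` pairs.
#' @return A list of class `interval_dispersion`: `distances` (long
#'   data frame `participant_id, comparison, distance`), `summary`
#'   (median/quartiles/whiskers per comparison), `dropped` (ids per
#'   comparison).
#' @export
interval_dispersion <- function(cohort, reference = c(5, 10),
                                comparisons = list(c(5, 5), c(1, 1))) {
  pair_label <- function(p) paste0(p[2], "-", p[1]) # after-before, as plotted
  point_at <- function(part, widths) {
    t0 <- part$ingestion_time
    nb <- sum(part$onsets >= t0 - widths[1] * 60 & part$onsets < t0)
    na_ <- sum(part$onsets >= t0 & part$onsets < t0 + widths[2] * 60)
    if (nb == 0 || na_ == 0) return(NULL)
    xb <- nb / widths[1]
    xa <- na_ / widths[2]
    list(xb_bar = xb, ratio = xa / xb)
  }
  all_pairs <- c(list(reference), comparisons)
  labels <- c(paste0(pair_label(reference), " (ref)"),
              vapply(comparisons, pair_label, character(1)))
  rows <- list()
  dropped <- stats::setNames(vector("list", length(all_pairs)), labels)
  for (j in seq_along(all_pairs)) {
    for (part in cohort) {
      ref_pt <- point_at(part, reference)
      cmp_pt <- point_at(part, all_pairs[[j]])
      if (is.null(ref_pt) || is.null(cmp_pt)) {
        dropped[[j]] <- c(dropped[[j]], part$participant_id)
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = part$participant_id,
        comparison = labels[j],
        distance = plot_distance(ref_pt, cmp_pt))
    }
  }
  distances <- do.call(rbind, rows)
  distances$comparison <- factor(distances$comparison, levels = labels)
  summ <- do.call(rbind, lapply(labels, function(lb) {
    d <- distances$distance[distances$comparison == lb]
    if (length(d) == 0) {
      return(data.frame(comparison = lb, n = 0L, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_,
                        whisker_lo = NA_real_, whisker_hi = NA_real_))
    }
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(comparison = lb, n = length(d), q1 = q[1], median = q[2],
               q3 = q[3],
               whisker_lo = min(d[d >= q[1] - 1.5 * iqr]),
               whisker_hi = max(d[d <= q[3] + 1.5 * iqr]))
  }))
  structure(list(distances = distances, summary = summ, dropped = dropped,
                 reference = reference),
            class = "interval_dispersion")
}

#' @export
print.interval_dispersion <- function(x, ...) {
  cat("Log-log plot-point dispersion vs reference interval pair\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Maximum number of detectable segments in a given duration
#'
#' With 64 ms windows every 16 ms, one minute admits at most
#' `floor((60 - 0.064) / 0.016) + 1 = 3747` segments; this is the
#' detection limit of the segment classifier.
#'
#' @param segment_length Window length in seconds (default 0.064).
#' @param shift Hop in seconds (default 0.016).
#' @param duration Interval length in seconds (default 60).
#' @return Integer segment count (0 when `duration < segment_length`).
#' @export
detection_limit <- function(segment_length = 0.064, shift = 0.016,
                            duration = 60) {
  if (duration < segment_length) return(0L)
  as.integer(floor((duration - segment_length) / shift + 1e-9) + 1)
}

#' Segments-vs-episodes sub-interval scan
#'
#' Divides a recording into equal sub-intervals (default 1 min), counts
#' detected segments and episodes per sub-interval, and reports their
#' Pearson correlation on the raw counts and on the natural logs
#' (sub-intervals with a zero count are dropped from the log
#' correlation and noted).  Also returns an occurrence histogram of
#' `ln(segments/min)` and, when `threshold` is given, the fraction of
#' sub-intervals whose segment count reaches it.
#'
#' @param labels Binary segment labels of the recording.
#' @param episodes `episode_set` of the recording (recording time).
#' @param shift,segment_length Framing parameters in seconds.
#' @param width_min Sub-interval width in minutes (default 1).
#' @param threshold Optional segment-count threshold for the exceedance
#'   fraction (e.g. `exp(7.8)`).
#' @param breaks Histogram breaks passed to [hist()] (default
#'   `"Sturges"`).
#' @return A list of class `subinterval_scan` with `table`
#'   (`sub_interval, segments, episodes`), `cor_raw`, `cor_log`
#'   (`cor_result`s), `n_zero_dropped`, `histogram`, `exceedance`.
#' @export
subinterval_scan <- function(labels, episodes, shift = 0.016,
                             segment_length = 0.064, width_min = 1,
                             threshold = NULL, breaks = "Sturges") {
  labels <- as.integer(labels)
  n_seg <- length(labels)
  duration <- (n_seg - 1) * shift + segment_length
  w <- width_min * 60
  n_bins <- floor(duration / w)
  if (n_bins < 1) stop("recording shorter than one sub-interval")
  starts <- (seq_len(n_seg) - 1) * shift
  seg_bin <- floor(starts / w) + 1
  ep_bin <- floor(episodes$onset_s / w) + 1
  segments <- vapply(seq_len(n_bins),
                     function(b) sum(labels[seg_bin == b]), numeric(1))
  eps <- vapply(seq_len(n_bins), function(b) sum(ep_bin == b), numeric(1))
  tab <- data.frame(sub_interval = seq_len(n_bins),
                    segments = segments, episodes = eps)
  cor_raw <- pearson_cor(segments, eps)
  nz <- segments > 0 & eps > 0
  n_zero <- sum(!nz)
  cor_log <- if (sum(nz) >= 3 && stats::var(log(segments[nz])) > 0 &&
                 stats::var(log(eps[nz])) > 0) {
    pearson_cor(log(segments[nz]), log(eps[nz]))
  } else NULL
  h <- graphics::hist(log(segments[segments > 0] / width_min),
                      breaks = breaks, plot = FALSE)
  exceed <- if (!is.null(threshold)) {
    mean(segments >= threshold)
  } else NA_real_
  structure(list(table = tab, cor_raw = cor_raw, cor_log = cor_log,
                 n_zero_dropped = n_zero, histogram = h,
                 exceedance = exceed, threshold = threshold,
                 width_min = width_min),
            class = "subinterval_scan")
}

#' @export
print.subinterval_scan <- function(x, ...) {
  cat("Sub-interval scan:", nrow(x$table), "intervals of", x$width_min,
      "min\n")
  cat(sprintf("  raw r = %.3f; log-log r = %s (%d zero bins dropped)\n",
              x$cor_raw$r,
              if (is.null(x$cor_log)) "NA" else sprintf("%.3f", x$cor_log$r),
              x$n_zero_dropped))
  if (!is.na(x$exceedance)) {
    cat(sprintf("  fraction of sub-intervals with >= %.0f segments: %.4f\n",
                x$threshold, x$exceedance))
  }
  invisible(x)
}

#' Stimulus-response plot built from segment counts
#'
#' Identical pipeline to [build_bssrp()] with segments/min in place of
#' episodes/min: `x = xsb_bar`, `ratio_s = xsa_bar / xsb_bar`.
#'
#' @inheritParams build_bssrp
#' @return A `bssrp` with `feature = "segments_per_min"`.
#' @export
bssrp_from_segments <- function(cohort, before_width = 5, after_width = 10) {
  build_bssrp(cohort, feature = "segments_per_min",
              before_width = before_width, after_width = after_width)
}

#' Write the points of a stimulus-response plot to CSV
#'
#' Layout: `participant_id,xb_bar,xa_bar,ratio,ln_xb_bar,ln_ratio`.
#'
#' @param bssrp A `bssrp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bssrp <- function(bssrp, path) {
  utils::write.csv(bssrp$points, path, row.names = FALSE)
  invisible(path)
}

#' Fit / correlation report of a stimulus-response plot
#'
#' Bundles the log-log OLS fit, the exponential fit (optional) and the
#' Pearson test of the log-log points into one list, suitable for JSON
#' serialization.
#'
#' @param bssrp A `bssrp`.
#' @param exponential Also fit the exponential model (default TRUE;
#'   needs >= 4 points).
#' @return List with `feature`, `n`, `excluded_ids`, `loglog`
#'   (slope/intercept/adjusted_r2), `correlation` (r/t/p/significant)
#'   and optionally `exponential` (a/b/c/adjusted_r2).
#' @export
bssrp_report <- function(bssrp, exponential = TRUE) {
  ll <- fit_loglog_linear(bssrp)
  ct <- pearson_cor(bssrp$points$ln_xb_bar, bssrp$points$ln_ratio)
  out <- list(
    feature = bssrp$feature,
    before_width = bssrp$before_width,
    after_width = bssrp$after_width,
    n = nrow(bssrp$points),
    excluded_ids = bssrp$excluded_ids,
    loglog = list(slope = unname(ll$parameters["slope"]),
                  intercept = unname(ll$parameters["intercept"]),
                  adjusted_r2 = ll$adjusted_r2),
    correlation = list(r = ct$r, t = ct$t_stat, p = ct$p_value,
                       significant = ct$significant)
  )
  if (exponential && nrow(bssrp$points) >= 4) {
    ex <- tryCatch(fit_exponential(bssrp), error = function(e) NULL)
    if (!is.null(ex)) {
      out$exponential <- list(a = unname(ex$parameters["a"]),
                              b = unname(ex$parameters["b"]),
                              c = unname(ex$parameters["c"]),
                              adjusted_r2 = ex$adjusted_r2)
    }
  }
  out
}
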