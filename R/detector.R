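# Segment classifier (small feed-forward network), episode formation and
# detection scoring.

logistic <- function(z) 1 / (1 + exp(-z))

#' Train the bowel-sound segment classifier
#'
#' A fully connected feed-forward network with logistic-sigmoid hidden
#' and output units, trained by full-batch gradient descent (with
#' momentum) on the cross-entropy loss.  Training is deterministic for a
#' given seed: the same call twice returns bit-identical weights.
#' Features are z-scored internally by default (statistics stored in the
#' model and re-applied at prediction time).
#'
#' @param features n x d numeric matrix (d = 40 for the PNCC+LPCC
#'   front-end).
#' @param labels Binary vector of length n; both classes must be
#'   present.
#' @param hidden_sizes Integer vector of hidden-layer widths (default
#'   32, a single hidden layer).
#' @param epochs Number of full-batch epochs (default 500).
#' @param learning_rate Gradient-descent step size (default 0.5).
#' @param momentum Classical momentum coefficient (default 0.9).
#' @param seed RNG seed for the weight initialization.
#' @param standardize Z-score the features with training-set statistics
#'   (default `TRUE`).
#' @param pos_weight Weight applied to positive-class terms of the loss
#'   (default 1; > 1 counteracts class imbalance).
#' @return An object of class `bs_ann`: layer weights, activation name,
#'   training metadata (`seed`, `epochs`, `loss_curve`, `final_loss`),
#'   and the standardization statistics.
#' @export
train_ann <- function(features, labels, hidden_sizes = 32, epochs = 500,
                      learning_rate = 0.5, momentum = 0.9, seed = 1,
                      standardize = TRUE, pos_weight = 1) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  if (any(!is.finite(features))) stop("non-finite feature values")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2) {
    stop("both classes must be present in the training labels")
  }

  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  X <- if (standardize) sweep(sweep(features, 2, mu), 2, sdv, "/") else features

  sizes <- c(ncol(X), hidden_sizes, 1L)
  n_layers <- length(sizes) - 1L
  set.seed(as.integer(seed))
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  vW <- vector("list", n_layers)
  vb <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
    vW[[l]] <- W[[l]] * 0
    vb[[l]] <- b[[l]] * 0
  }

  n <- nrow(X)
  w_obs <- ifelse(labels == 1, pos_weight, 1)
  w_sum <- sum(w_obs)
  loss_curve <- numeric(epochs)
  eps <- 1e-12

  for (ep in seq_len(epochs)) {
    # forward
    act <- vector("list", n_layers + 1L)
    act[[1]] <- X
    for (l in seq_len(n_layers)) {
      act[[l + 1]] <- logistic(sweep(act[[l]] %*% W[[l]], 2, b[[l]], "+"))
    }
    p <- act[[n_layers + 1L]][, 1]
    loss_curve[ep] <- -sum(w_obs * (labels * log(p + eps) +
                                    (1 - labels) * log(1 - p + eps))) / w_sum
    # backward (logistic output + cross-entropy gives delta = p - y)
    delta <- matrix(w_obs * (p - labels) / w_sum, ncol = 1)
    for (l in rev(seq_len(n_layers))) {
      gW <- crossprod(act[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(W[[l]])) * act[[l]] * (1 - act[[l]])
      }
      vW[[l]] <- momentum * vW[[l]] - learning_rate * gW
      vb[[l]] <- momentum * vb[[l]] - learning_rate * gb
      W[[l]] <- W[[l]] + vW[[l]]
      b[[l]] <- b[[l]] + vb[[l]]
    }
  }

  structure(
    list(sizes = sizes, weights = W, biases = b, activation = "logistic",
         standardize = standardize, center = mu, scale = sdv,
         seed = as.integer(seed), epochs = epochs,
         learning_rate = learning_rate, momentum = momentum,
         pos_weight = pos_weight,
         loss_curve = loss_curve, final_loss = loss_curve[epochs]),
    class = "bs_ann"
  )
}

#' @export
print.bs_ann <- function(x, ...) {
  cat("bs_ann: layers", paste(x$sizes, collapse = " -> "),
      "| logistic units\n")
  cat("  trained", x$epochs, "epochs (seed", x$seed,
      "), final loss", signif(x$final_loss, 4), "\n")
  invisible(x)
}

#' Network output probabilities
#'
#' @param object A `bs_ann` model.
#' @param features n x d feature matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.bs_ann <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != object$sizes[1]) {
    stop("feature width ", ncol(X), " does not match model input width ",
         object$sizes[1])
  }
  if (object$standardize) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  }
  for (l in seq_along(object$weights)) {
    X <- logistic(sweep(X %*% object$weights[[l]], 2, object$biases[[l]], "+"))
  }
  X[, 1]
}

#' Threshold network outputs into segment labels
#'
#' A segment is labelled positive when the network output is greater
#' than or equal to `threshold` (ties go to the positive class).
#'
#' @param model A `bs_ann` model.
#' @param features n x d feature matrix.
#' @param threshold Decision threshold in `[0, 1]` (default 0.5).
#' @return Integer vector of 0/1 labels.
#' @export
classify_segments <- function(model, features, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  as.integer(predict(model, features) >= threshold)
}

#' Merge consecutive positive segments into bowel-sound episodes
#'
#' Single positive segments and maximal runs of consecutive positive
#' segments each form one episode.  With 0-based first/last segment
#' indices `i`/`j`, the episode spans `onset = i * shift` to
#' `offset = j * shift + segment_length`, i.e. a run of `k` segments
#' lasts `(k - 1) * shift + segment_length` seconds.
#'
#' @param labels Binary segment labels.
#' @param shift Hop size in seconds (default 0.016).
#' @param segment_length Segment length in seconds (default 0.064).
#' @param recording_id Optional source-recording identifier.
#' @return A data frame of class `episode_set` with columns `onset_s`,
#'   `offset_s`, `n_segments`; attributes carry the framing parameters.
#' @export
form_episodes <- function(labels, shift = 0.016, segment_length = 0.064,
                          recording_id = NULL) {
  labels <- as.integer(labels)
  if (length(labels) == 0 || !any(labels == 1L)) {
    out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      n_segments = integer(0))
  } else {
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values == 1L
    first <- starts[keep] - 1L # 0-based
    last <- ends[keep] - 1L
    out <- data.frame(onset_s = first * shift,
                      offset_s = last * shift + segment_length,
                      n_segments = as.integer(last - first + 1L))
  }
  structure(out, class = c("episode_set", "data.frame"),
            shift = shift, segment_length = segment_length,
            recording_id = recording_id)
}

#' Detection performance per recording and cohort summary
#'
#' Confusion counts are accumulated per recording and converted to
#' sensitivity, specificity, PPV, NPV, accuracy and F1 (all percent);
#' F1 is the harmonic mean of sensitivity and PPV.  The cohort summary
#' is mean and SD across recordings; a recording for which a metric is
#' undefined (e.g. no positive segments) is excluded from that metric's
#' mean with a message.
#'
#' @param predicted Binary labels: a vector, or a list with one vector
#'   per recording.
#' @param truth Ground-truth labels, same shape as `predicted`.
#' @param recording_ids Optional recording names.
#' @return An object of class `detection_metrics`: list with
#'   `per_recording` (data frame) and `summary` (mean/sd per metric).
#' @export
evaluate_detection <- function(predicted, truth, recording_ids = NULL) {
  if (!is.list(predicted)) predicted <- list(predicted)
  if (!is.list(truth)) truth <- list(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted/truth recording counts differ")
  }
  if (is.null(recording_ids)) {
    recording_ids <- paste0("rec", seq_along(predicted))
  }
  rows <- lapply(seq_along(predicted), function(i) {
    p <- as.integer(predicted[[i]])
    y <- as.integer(truth[[i]])
    if (length(p) != length(y)) {
      stop("label length mismatch in recording ", recording_ids[i])
    }
    tp <- sum(p == 1 & y == 1)
    fp <- sum(p == 1 & y == 0)
    fn <- sum(p == 0 & y == 1)
    tn <- sum(p == 0 & y == 0)
    sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_
    acc <- 100 * (tp + tn) / length(p)
    f1 <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0) {
      2 * sens * ppv / (sens + ppv)
    } else NA_real_
    data.frame(recording = recording_ids[i], tp = tp, fp = fp, fn = fn,
               tn = tn, sensitivity = sens, specificity = spec, ppv = ppv,
               npv = npv, accuracy = acc, f1 = f1)
  })
  per_rec <- do.call(rbind, rows)
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "accuracy", "f1")
  summ <- lapply(metrics, function(m) {
    v <- per_rec[[m]]
    if (anyNA(v)) {
      message("metric ", m, " undefined for ",
              paste(per_rec$recording[is.na(v)], collapse = ", "),
              "; excluded from its mean")
      v <- v[!is.na(v)]
    }
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  names(summ) <- metrics
  structure(list(per_recording = per_rec,
                 summary = do.call(rbind, summ)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat("Detection performance over", nrow(x$per_recording), "recording(s)\n")
  s <- x$summary
  for (m in rownames(s)) {
    cat(sprintf("  %-12s %6.2f +/- %.2f %%\n", m, s[m, "mean"], s[m, "sd"]))
  }
  invisible(x)
}

#' Persist a trained classifier as JSON
#'
#' @param model A `bs_ann`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_ann <- function(model, path) {
  obj <- list(sizes = model$sizes,
              weights = lapply(model$weights, function(w) unclass(w)),
              biases = model$biases, activation = model$activation,
              standardize = model$standardize,
              center = model$center, scale = model$scale,
              seed = model$seed, epochs = model$epochs,
              learning_rate = model$learning_rate,
              momentum = model$momentum, pos_weight = model$pos_weight,
              final_loss = model$final_loss)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a classifier saved by [save_ann()]
#'
#' @param path JSON path.
#' @return A `bs_ann` model (without the loss curve).
#' @export
load_ann <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$sizes)
  W <- lapply(seq_along(obj$weights), function(l) {
    matrix(unlist(obj$weights[[l]]), sizes[l], sizes[l + 1])
  })
  structure(
    list(sizes = sizes, weights = W,
         biases = lapply(obj$biases, as.numeric),
         activation = obj$activation, standardize = obj$standardize,
         center = as.numeric(obj$center), scale = as.numeric(obj$scale),
         seed = obj$seed, epochs = obj$epochs,
         learning_rate = obj$learning_rate, momentum = obj$momentum,
         pos_weight = obj$pos_weight,
         loss_curve = NULL, final_loss = obj$final_loss),
    class = "bs_ann"
  )
}
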