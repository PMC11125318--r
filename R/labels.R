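# Ground-truth label handling: event intervals and per-segment labels.

#' Read a label file
#'
#' Two CSV layouts are accepted: event intervals with header
#' `start_s,end_s`, or per-segment labels with header
#' `segment_index,label` (0-based segment indices, label 1 = bowel
#' sound).  The layout is inferred from the header.
#'
#' @param path CSV path.
#' @return A data frame, either of intervals (`start_s`, `end_s`, sorted
#'   and checked non-overlapping) or of per-segment labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("start_s", "end_s") %in% names(df))) {
    df <- df[order(df$start_s), c("start_s", "end_s"), drop = FALSE]
    if (any(df$end_s < df$start_s)) stop("label intervals with end < start")
    if (nrow(df) > 1 && any(df$start_s[-1] < df$end_s[-nrow(df)])) {
      stop("label intervals overlap after sorting")
    }
    rownames(df) <- NULL
    df
  } else if (all(c("segment_index", "label") %in% names(df))) {
    df[, c("segment_index", "label"), drop = FALSE]
  } else {
    stop("unrecognized label file header (expect start_s,end_s or ",
         "segment_index,label)")
  }
}

#' Write event intervals or per-segment labels to CSV
#'
#' @param labels A data frame with columns `start_s,end_s` or
#'   `segment_index,label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' Convert event intervals to per-segment binary labels
#'
#' A segment is labelled positive when its overlap with some annotated
#' event reaches `min_overlap` seconds (default half the hop, 8 ms at
#' the standard 16 ms shift).  This is the rule applied to external
#' (human-annotated) interval files; synthetic recordings carry an
#' exact energy-based frame truth instead (see [synth_recording()]).
#'
#' @param intervals Data frame with `start_s`, `end_s` columns.
#' @param n_segments Number of segments in the recording.
#' @param segment_length,shift Framing parameters in seconds.
#' @param min_overlap Minimum event overlap (seconds) for a positive
#'   label.
#' @return Integer vector of 0/1 labels, one per segment.
#' @export
intervals_to_labels <- function(intervals, n_segments,
                                segment_length = 0.064, shift = 0.016,
                                min_overlap = shift / 2) {
  labels <- integer(n_segments)
  if (is.null(intervals) || nrow(intervals) == 0 || n_segments == 0) {
    return(labels)
  }
  starts <- (seq_len(n_segments) - 1) * shift
  ends <- starts + segment_length
  for (i in seq_len(nrow(intervals))) {
    ev_s <- intervals$start_s[i]
    ev_e <- intervals$end_s[i]
    lo <- max(1L, floor((ev_s - segment_length) / shift) + 1L)
    hi <- min(n_segments, floor(ev_e / shift) + 1L)
    if (lo > hi) next
    j <- lo:hi
    ov <- pmin(ends[j], ev_e) - pmax(starts[j], ev_s)
    labels[j[ov >= min_overlap - 1e-12]] <- 1L
  }
  labels
}

#' Merge possibly overlapping event intervals
#'
#' @param intervals Data frame with `start_s`, `end_s`.
#' @return Sorted, non-overlapping intervals (touching intervals are
#'   fused).
#' @export
merge_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  o <- order(intervals$start_s)
  s <- intervals$start_s[o]
  e <- intervals$end_s[o]
  out_s <- s[1]
  out_e <- e[1]
  k <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1L
      out_s[k] <- s[i]
      out_e[k] <- e[i]
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}
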