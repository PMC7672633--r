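# Event-based scoring of detections against reference annotations: a
# detection is a true positive if its onset falls within a time collar of
# an unmatched annotation onset (one-to-one matching, 6 s collar by
# default, as in onset-only sound-event-detection scoring).

#' Match detected onsets to annotated onsets under a time collar
#'
#' Greedy one-to-one matching in time order: each detection (ascending
#' onset) is matched to the nearest still-unmatched annotation within
#' `collar_s` (two-sided by default; `collar_before_s` / `collar_after_s`
#' allow asymmetric bounds, i.e. the detection may lie up to
#' `collar_before_s` before and `collar_after_s` after the annotation).
#' `method = "optimal"` instead computes a maximum-cardinality bipartite
#' matching.
#'
#' @param detections Numeric vector of detected onsets (seconds).
#' @param annotations Numeric vector of reference onsets (seconds).
#' @param collar_s Two-sided collar half-width in seconds (default 6).
#' @param collar_before_s,collar_after_s Optional asymmetric bounds;
#'   default to `collar_s`.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A list of class `match_result`: `tp`, `fp`, `fn`, `precision`,
#'   `recall` (precision is 1 with no detections, recall 1 with no
#'   annotations), and `pairs` (matrix of matched index pairs).
#' @examples
#' match_events(c(10, 40), c(13, 80), collar_s = 6)  # TP 1, FP 1, FN 1
#' @export
match_events <- function(detections, annotations, collar_s = 6,
                         collar_before_s = collar_s,
                         collar_after_s = collar_s,
                         method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (collar_before_s < 0 || collar_after_s < 0 ||
      collar_before_s + collar_after_s <= 0) {
    stop("collar must be positive")
  }
  d <- sort(as.numeric(detections))
  a <- sort(as.numeric(annotations))
  ok <- function(di, ai) {
    delta <- d[di] - a[ai]          # >0: detection after annotation
    delta >= -collar_before_s && delta <= collar_after_s
  }
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("detection", "annotation")))
  if (length(d) > 0 && length(a) > 0) {
    if (method == "greedy") {
      used <- logical(length(a))
      for (i in seq_along(d)) {
        cand <- which(!used)
        cand <- cand[vapply(cand, function(j) ok(i, j), logical(1))]
        if (length(cand) == 0) next
        j <- cand[which.min(abs(d[i] - a[cand]))]
        used[j] <- TRUE
        pairs <- rbind(pairs, c(i, j))
      }
    } else {
      # maximum-cardinality bipartite matching by augmenting paths
      adj <- lapply(seq_along(d), function(i) {
        which(vapply(seq_along(a), function(j) ok(i, j), logical(1)))
      })
      match_a <- rep(0L, length(a))
      augment <- function(i, seen) {
        for (j in adj[[i]]) {
          if (seen[j]) next
          seen[j] <- TRUE
          if (match_a[j] == 0L || Recall(match_a[j], seen)) {
            match_a[j] <<- i
            return(TRUE)
          }
        }
        FALSE
      }
      for (i in seq_along(d)) augment(i, logical(length(a)))
      for (j in which(match_a > 0L)) pairs <- rbind(pairs, c(match_a[j], j))
    }
  }
  tp <- nrow(pairs)
  fp <- length(d) - tp
  fn <- length(a) - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (length(d) == 0) 1 else tp / length(d),
    recall = if (length(a) == 0) 1 else tp / length(a),
    pairs = pairs
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d  FP %d  FN %d  precision %.3f  recall %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}
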