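#' Confusion-matrix metrics
#'
#' Standard 2x2 metrics with the lethal class positive. The weighted F1 is
#' the class-support-weighted mean of the two per-class F1 scores. Ratios
#' with a zero denominator are reported as 0 and named in `flags` (e.g. PPV
#' of an all-negative predictor).
#'
#' @param truth,pred Equal-length logical (or 0/1) vectors.
#' @return List: `ppv`, `npv`, `sensitivity`, `specificity`, `accuracy`,
#'   `f1_weighted`, `counts` (tp/fp/fn/tn), `flags`.
#' @export
confusion_metrics <- function(truth, pred) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  if (length(truth) != length(pred))
    stop("validation error: length mismatch", call. = FALSE)
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  fn <- sum(truth & !pred); tn <- sum(!truth & !pred)
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); 0 } else num / den
  }
  ppv <- safe(tp, tp + fp, "ppv")
  npv <- safe(tn, tn + fn, "npv")
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  acc <- (tp + tn) / length(truth)
  f1_pos <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  f1_neg <- if (npv + spec > 0) 2 * npv * spec / (npv + spec) else 0
  P <- tp + fn; N <- tn + fp
  f1_w <- (P * f1_pos + N * f1_neg) / (P + N)
  list(ppv = ppv, npv = npv, sensitivity = sens, specificity = spec,
       accuracy = acc, f1_weighted = f1_w,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn), flags = flags)
}

#' Precision-recall-gain curve
#'
#' Rescales precision and recall against the prevalence baseline pi:
#' `gain = (value - pi) / ((1 - pi) * value)`, so a no-skill classifier
#' scores zero gain. Operating points are the distinct score thresholds
#' (ties collapsed). Points with negative recall gain are dropped after
#' being used to interpolate the curve's crossing of `recall_gain = 0`;
#' the always-positive point closes the curve at `(1, 0)` or above.
#'
#' @param truth Logical (or 0/1) outcomes; both classes must be present.
#' @param scores Numeric classifier scores (higher = more lethal).
#' @return A `prg_curve`: `points` (recall_gain, precision_gain, in sweep
#'   order), `prevalence`, and the raw operating points.
#' @export
prg_curve <- function(truth, scores) {
  truth <- as.logical(truth)
  stopifnot(length(truth) == length(scores), all(is.finite(scores)))
  P <- sum(truth); n <- length(truth)
  pi_ <- P / n
  if (P == 0 || P == n)
    stop("degenerate prevalence: both classes required", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- rg <- pg <- numeric(length(thr))
  for (t in seq_along(thr)) {
    predpos <- scores >= thr[t]
    tp <- sum(truth & predpos)
    rec[t] <- tp / P
    prec[t] <- tp / sum(predpos)
    rg[t] <- if (rec[t] == 0) -Inf else (rec[t] - pi_) / ((1 - pi_) * rec[t])
    pg[t] <- if (prec[t] == 0) -Inf else
      (prec[t] - pi_) / ((1 - pi_) * prec[t])
  }
  i0 <- which(rg >= 0)[1]
  if (is.na(i0))
    stop("no operating point reaches recall >= prevalence", call. = FALSE)
  if (rg[i0] > 0) {
    if (i0 > 1 && is.finite(rg[i0 - 1]) && is.finite(pg[i0 - 1])) {
      w <- (0 - rg[i0 - 1]) / (rg[i0] - rg[i0 - 1])
      pg0 <- pg[i0 - 1] + w * (pg[i0] - pg[i0 - 1])
    } else {
      pg0 <- pg[i0]
    }
    pts <- data.frame(recall_gain = c(0, rg[i0:length(rg)]),
                      precision_gain = c(pg0, pg[i0:length(pg)]))
  } else {
    pts <- data.frame(recall_gain = rg[i0:length(rg)],
                      precision_gain = pg[i0:length(pg)])
  }
  structure(list(points = pts, prevalence = pi_,
                 operating = data.frame(threshold = thr, recall = rec,
                                        precision = prec,
                                        recall_gain = rg,
                                        precision_gain = pg)),
            class = "prg_curve")
}

#' Area under the precision-recall-gain curve
#'
#' Trapezoidal integration of the PRG curve over `recall_gain` in
#' `[0, 1]`. 1 for a perfect ranking, 0 gain for a no-skill classifier.
#'
#' @param curve A [prg_curve()], or `truth` when `scores` is supplied.
#' @param scores Optional: compute the curve first.
#' @return Scalar AUPRG (at most 1; can be negative for a worse-than-
#'   baseline ranker).
#' @export
auprg <- function(curve, scores = NULL) {
  if (!inherits(curve, "prg_curve")) curve <- prg_curve(curve, scores)
  p <- curve$points
  rg <- p$recall_gain; pg <- p$precision_gain
  keep <- rg >= 0 & rg <= 1
  rg <- rg[keep]; pg <- pg[keep]
  if (length(rg) < 2) return(0)
  sum(diff(rg) * (utils::head(pg, -1) + utils::tail(pg, -1)) / 2)
}
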