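# Independent oracles, coded separately from the package implementations.

# Brute-force AUPRG: explicit confusion counts at every threshold, gains by
# direct substitution, trapezoid with the same boundary convention as the
# package (interpolated crossing at recall_gain = 0, constant extension
# when the first usable point already has positive recall gain).
oracle_auprg <- function(truth, scores) {
  truth <- as.logical(truth)
  n <- length(truth)
  P <- 0
  for (i in seq_len(n)) if (truth[i]) P <- P + 1
  pi_ <- P / n
  thr <- sort(unique(scores), decreasing = TRUE)
  rg <- pg <- numeric(0)
  for (t in thr) {
    tp <- 0; fp <- 0
    for (i in seq_len(n)) {
      if (scores[i] >= t) {
        if (truth[i]) tp <- tp + 1 else fp <- fp + 1
      }
    }
    rec <- tp / P
    prec <- tp / (tp + fp)
    rg <- c(rg, if (rec == 0) -Inf else (rec - pi_) / ((1 - pi_) * rec))
    pg <- c(pg, if (prec == 0) -Inf else
      (prec - pi_) / ((1 - pi_) * prec))
  }
  i0 <- which(rg >= 0)[1]
  if (rg[i0] > 0) {
    pg0 <- if (i0 > 1 && is.finite(rg[i0 - 1]) && is.finite(pg[i0 - 1])) {
      w <- (0 - rg[i0 - 1]) / (rg[i0] - rg[i0 - 1])
      pg[i0 - 1] + w * (pg[i0] - pg[i0 - 1])
    } else pg[i0]
    rg <- c(0, rg[i0:length(rg)])
    pg <- c(pg0, pg[i0:length(pg)])
  } else {
    rg <- rg[i0:length(rg)]
    pg <- pg[i0:length(pg)]
  }
  area <- 0
  for (s in seq_len(length(rg) - 1))
    area <- area + (rg[s + 1] - rg[s]) * (pg[s] + pg[s + 1]) / 2
  area
}

# Partial correlations by direct inversion of the sample correlation
# matrix (the penalty-0 oracle for the graphical lasso).
oracle_partial_cor <- function(data) {
  theta <- solve(cor(data))
  pc <- -theta / sqrt(diag(theta) %o% diag(theta))
  diag(pc) <- 0
  pc
}

# Weighted F1 from an explicit 2x2 table.
oracle_weighted_f1 <- function(tp, fp, fn, tn) {
  prec_p <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec_p <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1p <- if (prec_p + rec_p > 0) 2 * prec_p * rec_p / (prec_p + rec_p) else 0
  prec_n <- if (tn + fn > 0) tn / (tn + fn) else 0
  rec_n <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1n <- if (prec_n + rec_n > 0) 2 * prec_n * rec_n / (prec_n + rec_n) else 0
  ((tp + fn) * f1p + (tn + fp) * f1n) / (tp + fp + fn + tn)
}
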