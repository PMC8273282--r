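# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: residuals and reconstructions by explicit loops,
# weights by a scalar root-finder on the KKT condition, AUC by all-pairs
# comparison, confusion metrics by direct formula evaluation.

oracle_residual <- function(R, Gi, S, Gj) {
  total <- 0
  for (a in seq_len(nrow(R))) {
    for (b in seq_len(ncol(R))) {
      pred <- 0
      for (p in seq_len(ncol(Gi))) {
        for (q in seq_len(ncol(Gj))) {
          pred <- pred + Gi[a, p] * S[p, q] * Gj[b, q]
        }
      }
      total <- total + (R[a, b] - pred)^2
    }
  }
  total
}

oracle_reconstruct <- function(Gi, S, Gj) {
  out <- matrix(0, nrow(Gi), nrow(Gj))
  for (a in seq_len(nrow(Gi))) {
    for (b in seq_len(nrow(Gj))) {
      for (p in seq_len(ncol(Gi))) {
        for (q in seq_len(ncol(Gj))) {
          out[a, b] <- out[a, b] + Gi[a, p] * S[p, q] * Gj[b, q]
        }
      }
    }
  }
  out
}

# Solve min_w sum(w*H) + alpha*sum(w^2) over the simplex by finding the
# Lagrange multiplier with a scalar root-finder.
oracle_weights <- function(H, alpha) {
  f <- function(g) sum(pmax(g - H, 0)) / (2 * alpha) - 1
  g <- stats::uniroot(f, lower = min(H), upper = max(H) + 2 * alpha + 1,
                      tol = .Machine$double.eps^0.75)$root
  pmax(g - H, 0) / (2 * alpha)
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

oracle_confusion <- function(scores, labels, threshold) {
  tp <- sum(scores > threshold & labels == 1)
  fp <- sum(scores > threshold & labels == 0)
  fn <- sum(scores <= threshold & labels == 1)
  tn <- sum(scores <= threshold & labels == 0)
  den <- sqrt(as.numeric(tp + fp)) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
    acc = (tp + tn) / (tp + tn + fp + fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
    specificity = if (fp + tn == 0) 0 else tn / (fp + tn)
  )
}
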