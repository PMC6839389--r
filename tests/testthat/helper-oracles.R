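# Independent reference implementations ("oracles") used to validate the
# package's fast routines. These deliberately take the slow, literal route:
# quadruple sums, exhaustive searches, all-pairs statistics.

# Direct quadruple-sum orthonormal type-II 2-D DCT:
#   B[p,q] = a_p a_q sum_m sum_n A[m,n] cos(pi(2m+1)p / 2M) cos(pi(2n+1)q / 2N)
dct2_direct <- function(A) {
  M <- nrow(A)
  N <- ncol(A)
  B <- matrix(0, M, N)
  for (p in 0:(M - 1)) {
    for (q in 0:(N - 1)) {
      s <- 0
      for (m in 0:(M - 1)) {
        for (n in 0:(N - 1)) {
          s <- s + A[m + 1, n + 1] *
            cos(pi * (2 * m + 1) * p / (2 * M)) *
            cos(pi * (2 * n + 1) * q / (2 * N))
        }
      }
      ap <- if (p == 0) sqrt(1 / M) else sqrt(2 / M)
      aq <- if (q == 0) sqrt(1 / N) else sqrt(2 / N)
      B[p + 1, q + 1] <- ap * aq * s
    }
  }
  B
}

# Exhaustive Otsu search over the same candidate cuts as otsu_threshold():
# quantize values to equal-width bin centers, then evaluate the between-class
# variance w0 * w1 * (mu0 - mu1)^2 directly from the two groups at every
# interior bin edge, keeping the first (lowest) maximum.
otsu_exhaustive <- function(values, n_bins = 256L) {
  lo <- min(values)
  hi <- max(values)
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((values - lo) / width) + 1L, n_bins)
  q <- lo + (bin - 0.5) * width
  best <- -Inf
  best_k <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {
    low <- q[bin <= k]
    high <- q[bin > k]
    if (length(low) == 0L || length(high) == 0L) next
    w0 <- length(low) / length(q)
    b <- w0 * (1 - w0) * (mean(low) - mean(high))^2
    if (b > best * (1 + 1e-12)) {
      best <- b
      best_k <- k
    }
  }
  list(threshold = lo + best_k * width, between_var = best)
}

# All-pairs Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(equal).
auc_mann_whitney <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Singular values via the eigen-decomposition of the Gram matrix.
singular_values_eigen <- function(G) {
  n <- min(dim(G))
  gram <- if (ncol(G) <= nrow(G)) crossprod(G) else tcrossprod(G)
  sqrt(pmax(eigen(gram, symmetric = TRUE, only.values = TRUE)$values[seq_len(n)], 0))
}

# Block-level intersection-over-union of two logical matrices.
block_iou <- function(pred, truth) {
  u <- sum(pred | truth)
  if (u == 0L) return(1)
  sum(pred & truth) / u
}

# Small lesion templates so full dataset machinery runs fast on small images.
small_templates <- function() {
  list(
    benign = list(shape = "ellipse", size_range = c(10, 18),
                  drop_range = c(0.65, 0.80), het_range = c(0.01, 0.05),
                  smooth_sigma = 4),
    malignant = list(shape = "rect", size_range = c(24, 40),
                     drop_range = c(0.15, 0.25), het_range = c(0.30, 0.40),
                     smooth_sigma = 4)
  )
}
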