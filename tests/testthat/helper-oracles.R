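# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# O(n^2) pairwise Harrell C: enumerate every ordered pair.
bf_concordance <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[i] < time[j]) {
        den <- den + 1
        if (scores[i] > scores[j]) num <- num + 1
        else if (scores[i] == scores[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# Brute-force anisotropic distance-to-background for every mask voxel.
bf_edt <- function(mask, spacing) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  bgp <- sweep(bg - 1, 2, spacing, "*")
  out <- array(0, d)
  for (k in seq_len(nrow(fg))) {
    p <- (fg[k, ] - 1) * spacing
    out[fg[k, 1], fg[k, 2], fg[k, 3]] <-
      sqrt(min(rowSums(sweep(bgp, 2, p)^2)))
  }
  out
}

# Naive per-slice 3x3 median with clamped borders.
bf_median3x3 <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    ys <- pmin(pmax(y + (-1:1), 1), d[2])
    xs <- pmin(pmax(x + (-1:1), 1), d[3])
    out[z, y, x] <- median(arr[z, ys, xs][c(1:3, 4:6, 7:9)])
  }
  out
}

# Empirical survival function (no censoring): S(t) = mean(T > t).
bf_empirical_surv <- function(times, t) vapply(t, function(u) mean(times > u), numeric(1))

# Plain binary AUC by pairwise comparison.
bf_binary_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  num <- 0
  for (p in pos) num <- num + sum(p > neg) + 0.5 * sum(p == neg)
  num / (length(pos) * length(neg))
}
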