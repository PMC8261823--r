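# Independent brute-force oracles, deliberately implemented with different
# mechanisms than the package (explicit index scans, no rle; explicit vote
# counting loops).

# run-length open/close by explicit scanning
bruteSieve <- function(b, openLen, closeLen) {
  n <- length(b)
  out <- as.integer(b)
  i <- 1L
  while (i <= n) {
    if (out[i] == 1L) {
      j <- i
      while (j < n && out[j + 1L] == 1L) j <- j + 1L
      if (j - i + 1L < openLen) out[i:j] <- 0L
      i <- j + 1L
    } else i <- i + 1L
  }
  i <- 1L
  while (i <= n) {
    if (out[i] == 0L) {
      j <- i
      while (j < n && out[j + 1L] == 0L) j <- j + 1L
      if (i > 1L && j < n && j - i + 1L < closeLen) out[i:j] <- 1L
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# plurality vote with explicit counting; ties to class 0
bruteVote <- function(votes) {
  n0 <- sum(votes == 0L)
  n1 <- sum(votes == 1L)
  n2 <- sum(votes == 2L)
  mx <- max(n0, n1, n2)
  tied <- c(0L, 1L, 2L)[c(n0, n1, n2) == mx]
  if (length(tied) == 1L) tied else 0L
}

bruteConfusion <- function(pred, truth) {
  tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (truth[i] == 1L) {
      if (pred[i] == 1L) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pred[i] == 1L) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# all binary sequences of length len as rows
allBinarySequences <- function(len) {
  as.matrix(expand.grid(rep(list(0:1), len)))
}
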