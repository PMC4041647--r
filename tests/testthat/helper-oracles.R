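# brute-force oracles kept deliberately naive and independent of the
# package's vectorised implementations

# O(N * R) double-loop nearest-river distance
bruteDistance <- function(mask, cellSize) {
  riv <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      best <- Inf
      for (k in seq_len(nrow(riv))) {
        d <- sqrt((i - riv[k, 1])^2 + (j - riv[k, 2])^2)
        if (d < best) best <- d
      }
      out[i, j] <- best * cellSize
    }
  }
  out
}

# exhaustive best split by looping over every variable and midpoint
bruteBestSplit <- function(x, y) {
  giniOf <- function(lab) {
    p <- table(lab) / length(lab)
    1 - sum(p^2)
  }
  n <- length(y)
  best <- list(decrease = -Inf)
  for (v in names(x)) {
    vals <- sort(unique(x[[v]]))
    if (length(vals) < 2) next
    for (k in seq_len(length(vals) - 1)) {
      thr <- (vals[k] + vals[k + 1]) / 2
      left <- x[[v]] <= thr
      dec <- giniOf(y) -
        (sum(left) * giniOf(y[left]) + sum(!left) * giniOf(y[!left])) / n
      if (dec > best$decrease + 1e-12)
        best <- list(var = v, threshold = thr, decrease = dec)
    }
  }
  if (best$decrease <= 1e-12) NULL else best
}

md5OfDir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  structure(unname(tools::md5sum(files)),
            names = basename(files))
}
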