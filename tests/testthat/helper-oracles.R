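# Independent brute-force oracles. These re-derive expected results from
# first principles and stay independent of the implementation paths they
# check.

# greedy maximin selection, re-evaluating every candidate distance from
# scratch at every step
ks_oracle <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(-1, 0, 0)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (d(i, j) > best[1] + 1e-12) best <- c(d(i, j), i, j)
  sel <- best[2:3]
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    dmin <- vapply(cand, function(i) min(vapply(sel, d, numeric(1), i = i)),
                   numeric(1))
    sel <- c(sel, cand[which.max(dmin)])
  }
  as.integer(sel)
}

# naive agglomerative clustering on a distance matrix; returns the sequence
# of merge heights. method: "average" or "ward" (Ward.D2 via Lance-Williams)
agglom_oracle_heights <- function(D, method) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, 0, 0)
    for (a in seq_along(active)) for (b in seq_along(active)) if (a < b) {
      i <- active[a]; j <- active[b]
      if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    for (k in setdiff(active, c(i, j))) {
      if (method == "average") {
        new_d <- (sizes[i] * D[i, k] + sizes[j] * D[j, k]) /
          (sizes[i] + sizes[j])
      } else {  # ward.D2 Lance-Williams on euclidean distances
        s <- sizes[i] + sizes[j] + sizes[k]
        new_d <- sqrt(((sizes[i] + sizes[k]) * D[i, k]^2 +
                         (sizes[j] + sizes[k]) * D[j, k]^2 -
                         sizes[k] * D[i, j]^2) / s)
      }
      D[i, k] <- D[k, i] <- new_d
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}
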