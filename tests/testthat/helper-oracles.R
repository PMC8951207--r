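# Independent brute-force oracles, deliberately written with different
# algorithms than the package (Floyd-Warshall instead of BFS, explicit
# triple loops instead of matrix algebra).

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

oracle_metrics <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  lp <- mean(off[is.finite(off)])
  eg <- mean(ifelse(is.finite(off), 1 / off, 0))
  deg <- rowSums(A != 0)
  cc_i <- numeric(n)
  el_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    sub <- A[nb, nb, drop = FALSE]
    tri <- sum(sub[upper.tri(sub)] != 0)
    cc_i[i] <- 2 * tri / (k * (k - 1))
    Ds <- oracle_distances(sub)
    offs <- Ds[row(Ds) != col(Ds)]
    el_i[i] <- mean(ifelse(is.finite(offs), 1 / offs, 0))
  }
  c(L_p = lp, C_c = mean(cc_i), E_global = eg, E_local = mean(el_i))
}

random_graph <- function(n, p) {
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- stats::rbinom(length(ut), 1, p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# symmetric uniform weight matrix standing in for a null PLI matrix
random_weight_matrix <- function(n = 20) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  w[ut] <- stats::runif(length(ut))
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}

two_channel_montage <- function() montage(c("A", "B"), list(A = "B", B = "A"))

chain_montage <- function() {
  montage(c("A", "B", "C"), list(A = "B", B = c("A", "C"), C = "B"))
}

# small broadband test recording with sinusoid + noise content
sine_recording <- function(freq, fs = 512, dur = 10, amp = 10,
                           montage = two_channel_montage()) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- rbind(amp * cos(2 * pi * freq * t), amp * sin(2 * pi * freq * t))
  rownames(x) <- montage$labels
  recording(x, fs, montage)
}
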