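# Shared builders for small synthetic fixtures. Everything is generated in
# code under fixed seeds; no data files.

tiny_kernel <- function(rate = 100) make_triphasic_kernel(rate)

# A short onset-driven recording with known ground truth.
quick_sim <- function(duration_s = 60, n_events = 40, snr_db = 10,
                      n_channels = 2, seed = 1, eeg_rate = 100,
                      kernel = tiny_kernel(eeg_rate)) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 2))
  events <- generate_event_train(duration_s, n_events, min_gap_s = 0.6,
                                 categories = "tone", seed = seeds[1])
  eeg <- synthesize_eeg(events, kernel, snr_db, n_channels, eeg_rate,
                        seed = seeds[2], duration_s = duration_s)
  onsets <- events_to_markers(events, nrow(eeg$data), eeg_rate)
  list(events = events, eeg = eeg, onsets = onsets, kernel = kernel,
       rate = eeg_rate)
}

# Independent oracle: clean EEG as an explicit convolution of the event
# impulse train with the kernel (naive O(n * k) loop, no shared code path).
oracle_event_convolution <- function(events, kernel, n, rate) {
  out <- rep(0, n)
  for (o in events$onset_s) {
    i0 <- round(o * rate) + 1
    for (j in seq_along(kernel$amplitude)) {
      idx <- i0 + j - 1
      if (idx <= n) out[idx] <- out[idx] + kernel$amplitude[j]
    }
  }
  out
}

# Independent oracle: ridge solution via the augmented least-squares system
# [S; sqrt(lambda) I] solved by QR -- a different route than the normal
# equations used by the package.
oracle_ridge_qr <- function(s, y, lambda) {
  p <- ncol(s)
  aug_x <- rbind(s, diag(sqrt(lambda), p))
  aug_y <- rbind(as.matrix(y), matrix(0, p, ncol(as.matrix(y))))
  qr.coef(qr(aug_x), aug_y)
}

# Independent oracle: explainable proportion by explicit interval union.
oracle_union_proportion <- function(onset_idx, n, lag_lo, lag_hi) {
  covered <- rep(FALSE, n)
  for (e in onset_idx) {
    lo <- max(1, e + lag_lo)
    hi <- min(n, e + lag_hi)
    if (hi >= lo) covered[lo:hi] <- TRUE
  }
  mean(covered)
}

# Independent oracle: BH step-up rejection set and adjusted p-values.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * q)
  rejected <- rep(FALSE, m)
  if (length(k) > 0) rejected[o[seq_len(max(k))]] <- TRUE
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(1, adj_sorted)
  list(rejected = rejected, adjusted = adj)
}
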