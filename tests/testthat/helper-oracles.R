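# Independent straight-loop oracles used to cross-check the vectorized
# implementations, plus small shared fixtures. Everything here is
# deliberately naive: plain loops, no shared code with the package.

options(capseeg.verbose = FALSE)

# Routing-by-agreement, one sample, written directly from the update rules.
oracle_routing <- function(u_hat, r) {
  I <- dim(u_hat)[1]; K <- dim(u_hat)[2]; D <- dim(u_hat)[3]
  b <- matrix(0, I, K)
  v <- matrix(0, K, D)
  cpl <- NULL
  for (t in seq_len(r)) {
    cpl <- matrix(0, I, K)
    for (i in seq_len(I)) {
      e <- exp(b[i, ] - max(b[i, ]))
      cpl[i, ] <- e / sum(e)
    }
    for (j in seq_len(K)) {
      s <- numeric(D)
      for (i in seq_len(I)) s <- s + cpl[i, j] * u_hat[i, j, ]
      n2 <- sum(s^2)
      v[j, ] <- if (n2 > 0) s * sqrt(n2) / (1 + n2) else s
    }
    if (t < r)
      for (i in seq_len(I)) for (j in seq_len(K))
        b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
  }
  list(v = v, c = cpl, b = b)
}

# Sliding-window start positions by explicit enumeration.
oracle_segment_count <- function(len, window, stride) {
  count <- 0L
  s <- 0L
  while (s + window <= len) {
    count <- count + 1L
    s <- s + stride
  }
  count
}

# Near-square factor pair: enumerate every admissible (h, w) over candidate
# lengths and take the first length with any pair obeying h/w <= 2, then the
# most square such pair.
oracle_factorize <- function(L) {
  for (Lp in L:(2L * L)) {
    pairs <- NULL
    for (w in seq_len(floor(sqrt(Lp))))
      if (Lp %% w == 0L) {
        h <- Lp %/% w
        if (h <= 2L * w) pairs <- rbind(pairs, c(h, w))
      }
    if (!is.null(pairs)) {
      best <- pairs[which.min(pairs[, 1] - pairs[, 2]), ]
      return(c(best, Lp))
    }
  }
}

# Per-sample recount of accuracy / sensitivity / specificity (binary:
# class 1 positive; multiclass: macro one-vs-rest), in percent.
oracle_metrics <- function(actual, predicted, K) {
  acc <- mean(actual == predicted)
  if (K == 2) {
    sens <- mean(predicted[actual == 1] == 1)
    spec <- mean(predicted[actual == 0] == 0)
  } else {
    sens_k <- spec_k <- numeric(0)
    for (k in 0:(K - 1)) {
      if (!any(actual == k)) next
      sens_k <- c(sens_k, mean(predicted[actual == k] == k))
      spec_k <- c(spec_k, mean(predicted[actual != k] != k))
    }
    sens <- mean(sens_k); spec <- mean(spec_k)
  }
  c(accuracy = 100 * acc, sensitivity = 100 * sens, specificity = 100 * spec)
}

# Small in-memory synthetic surrogate corpora (shared fixture).
tiny_surrogate <- function(n_files, seed = 11, sets = c("A", "B", "C", "D", "E")) {
  gen_bonn_surrogate(synth_config(seed = seed), n_files_per_set = n_files,
                     seed = seed, sets = sets)
}

# A hand-built constant-free recording for I/O tests.
toy_recording <- function(n = 64, seed = 1, set_label = "A", id = "toy") {
  set.seed(seed)
  eeg_recording(round(rnorm(n, sd = 40)), set_label = set_label, source_id = id)
}
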