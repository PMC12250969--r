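# Independent brute-force oracles, written directly from the defining
# formulas with explicit loops. They share no code with the package
# implementations they are used to check.

oracle_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (t in seq_len(n)) {
    sxy <- sxy + (x[t] - mx) * (y[t] - my)
    sxx <- sxx + (x[t] - mx)^2
    syy <- syy + (y[t] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# joint histogram by an explicit loop over samples, then a double loop over
# cells for the MI sum (log base 2)
oracle_mi <- function(x, y, bins = 16) {
  n <- length(x)
  lox <- min(x); hix <- max(x); loy <- min(y); hiy <- max(y)
  bin_of <- function(v, lo, hi) {
    if (hi == lo) return(1L)
    b <- floor((v - lo) / (hi - lo) * bins) + 1L
    if (b > bins) bins else b
  }
  counts <- matrix(0, bins, bins)
  for (t in seq_len(n)) {
    i <- bin_of(x[t], lox, hix)
    j <- bin_of(y[t], loy, hiy)
    counts[i, j] <- counts[i, j] + 1
  }
  mi <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    pij <- counts[i, j] / n
    if (pij > 0) {
      pi_ <- sum(counts[i, ]) / n
      pj_ <- sum(counts[, j]) / n
      mi <- mi + pij * log2(pij / (pi_ * pj_))
    }
  }
  mi
}

oracle_plv <- function(dphi) {
  re <- 0; im <- 0
  for (t in seq_along(dphi)) {
    re <- re + cos(dphi[t])
    im <- im + sin(dphi[t])
  }
  sqrt(re^2 + im^2) / length(dphi)
}

oracle_pli <- function(dphi) {
  s <- 0
  for (t in seq_along(dphi)) s <- s + sign(dphi[t])
  abs(s / length(dphi))
}

oracle_psi <- function(dphi) {
  n <- length(dphi)
  acc <- 0
  for (t in seq_len(n - 1)) {
    d <- dphi[t + 1] - dphi[t]
    while (d > pi) d <- d - 2 * pi
    while (d <= -pi) d <- d + 2 * pi
    acc <- acc + abs(d)
  }
  acc / (n - 1)
}

# full connectivity matrix by a double loop over channel pairs; phase-based
# measures take a precomputed phase matrix
oracle_conn_matrix <- function(x, measure, phases = NULL, bins = 16) {
  C <- nrow(x)
  A <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    if (i == j) {
      A[i, j] <- if (measure %in% c("pcc", "plv")) 1 else 0
    } else if (measure == "pcc") {
      A[i, j] <- oracle_pcc(x[i, ], x[j, ])
    } else if (measure == "mi") {
      A[i, j] <- oracle_mi(x[i, ], x[j, ], bins)
    } else {
      d <- phases[i, ] - phases[j, ]
      d <- d - 2 * pi * ceiling((d - pi) / (2 * pi))   # wrap to (-pi, pi]
      A[i, j] <- switch(measure, plv = oracle_plv(d), pli = oracle_pli(d),
                        psi = oracle_psi(d))
    }
  }
  A
}

# every metric recomputed from scratch starting from raw label vectors
oracle_metrics <- function(y_true, y_pred, classes) {
  K <- length(classes)
  n <- length(y_true)
  cm <- matrix(0, K, K)
  for (t in seq_len(n)) {
    i <- which(classes == y_true[t])
    j <- which(classes == y_pred[t])
    cm[i, j] <- cm[i, j] + 1
  }
  acc <- sum(diag(cm)) / n
  prec <- numeric(K); rec <- numeric(K); spec <- numeric(K); f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    tn <- n - tp - fp - fn
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[k] <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  p_o <- acc
  p_e <- 0
  for (k in seq_len(K)) p_e <- p_e + sum(cm[k, ]) * sum(cm[, k]) / n^2
  list(accuracy = acc, macro_f1 = mean(f1),
       kappa = (p_o - p_e) / (1 - p_e),
       specificity = mean(spec), sensitivity = mean(rec),
       per_class_precision = prec, confusion = cm)
}

# FFT amplitude of one channel at frequency f (Hz)
fft_amplitude <- function(ch, f, fs) {
  n <- length(ch)
  k <- round(f * n / fs)
  2 * Mod(stats::fft(ch)[k + 1]) / n
}

rms <- function(x) sqrt(mean(x^2))
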