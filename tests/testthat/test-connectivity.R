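# Pairwise estimators against closed forms and brute-force oracles.

test_that("Pearson correlation matches its defining formula", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  expect_equal(pearson_cc(x, y), oracle_pcc(x, y), tolerance = 1e-12)

  set.seed(7)
  z <- rnorm(100)
  expect_equal(pearson_cc(z, z), 1)
  expect_equal(pearson_cc(z, -z), -1)
  expect_warning(v <- pearson_cc(rep(1, 10), z[1:10]), "constant")
  expect_equal(v, 0)
})

test_that("histogram MI: identity, independence and oracle equivalence", {
  # 16 equally frequent values, x == y: joint histogram is diagonal,
  # MI = H(x) = log2(16) = 4 bits
  x <- rep(1:16, each = 8)
  expect_equal(mutual_information(x, x), 4.0, tolerance = 1e-12)
  expect_equal(oracle_mi(x, x), 4.0, tolerance = 1e-12)

  # joint histogram an exact product of marginals -> MI = 0
  g <- expand.grid(a = 1:16, b = 1:16)
  expect_equal(mutual_information(g$a, g$b), 0, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(500)
    b <- 0.5 * a + rnorm(500)
    expect_equal(mutual_information(a, b), oracle_mi(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mutual_information(1, 1), "length")
})

test_that("instantaneous phase follows the analytic-signal closed form", {
  fs <- 100
  n <- 3000
  t <- seq_len(n) / fs
  f <- 7
  ph <- instantaneous_phase(matrix(cos(2 * pi * f * t), 1))
  expect_true(all(ph > -pi & ph <= pi))
  # unwrapped slope on the interior ~ 2*pi*f/fs per sample
  interior <- 500:2500
  d <- diff(ph[1, interior])
  d <- d - 2 * pi * ceiling((d - pi) / (2 * pi))
  expect_lt(abs(mean(d) - 2 * pi * f / fs) / (2 * pi * f / fs), 0.01)

  two <- matrix(rep(cos(2 * pi * 3 * t), 2), 2, byrow = TRUE)
  p2 <- instantaneous_phase(two)
  expect_equal(p2[1, interior], p2[2, interior], tolerance = 1e-10)
})

test_that("phase-difference statistics match closed forms and oracles", {
  # constant lag: perfectly locked, zero instability
  const <- rep(1.3, 100)
  expect_equal(plv(const), 1, tolerance = 1e-12)
  expect_equal(psi(const), 0, tolerance = 1e-12)
  expect_equal(pli(rep(pi / 2, 50)), 1)
  expect_equal(pli(rep(0, 50)), 0)
  expect_equal(pli(rep(c(pi / 3, -pi / 3), 25)), 0)
  expect_equal(plv(rep(c(0, pi), 50)), 0, tolerance = 1e-12)

  # linear drift with wrapped step d: mean |first difference| = |d|
  d <- 0.37
  expect_equal(psi(wrap_phase((1:200) * d)), d, tolerance = 1e-12)

  set.seed(13)
  dphi <- runif(3000, -pi, pi)
  expect_equal(plv(dphi), oracle_plv(dphi), tolerance = 1e-12)
  expect_equal(pli(dphi), oracle_pli(dphi), tolerance = 1e-12)
  expect_equal(psi(dphi), oracle_psi(dphi), tolerance = 1e-12)
  expect_error(plv(numeric(0)), "empty")
  expect_error(psi(1.0), "at least 2")
})

test_that("connectivity matrices match brute-force pairwise evaluation", {
  set.seed(17)
  x <- matrix(rnorm(8 * 500), 8)
  ph <- instantaneous_phase(x)
  for (m in MVBN_MEASURES) {
    A <- connectivity_matrix(x, m)
    expect_equal(unclass(A), oracle_conn_matrix(x, m, phases = ph),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(A, t(A), ignore_attr = TRUE)
  }
  two <- matrix(rep(sin(2 * pi * 5 * (1:300) / 100), 2), 2, byrow = TRUE)
  expect_equal(connectivity_matrix(two, "plv")[1, 2], 1, tolerance = 1e-9)
})

test_that("estimator bounds and symmetry hold across 1000 random epochs", {
  set.seed(19)
  asym <- 0L; oob <- 0L
  for (i in 1:1000) {
    x <- matrix(rnorm(8 * 256), 8)
    for (m in MVBN_MEASURES) {
      A <- connectivity_matrix(x, m)
      if (max(abs(A - t(A))) > 1e-9) asym <- asym + 1L
      bad <- switch(m,
        pcc = any(A < -1 | A > 1),
        plv = , pli = any(A < 0 | A > 1),
        mi = , psi = any(A < -1e-12))
      if (bad) oob <- oob + 1L
    }
  }
  expect_identical(asym, 0L)
  expect_identical(oob, 0L)
})

test_that("PLV of independent uniform phases concentrates at sqrt(pi/(4N))", {
  set.seed(23)
  n_t <- 3000
  trials <- 200
  vals <- replicate(trials, plv(runif(n_t, -pi, pi)))
  expected <- sqrt(pi / (4 * n_t))
  se <- sd(vals) / sqrt(trials)
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("delta-band PLV and PCC rise with shared-oscillator coupling", {
  set.seed(29)
  fs <- 100
  t <- seq_len(30 * fs) / fs
  mean_conn <- function(a) {
    plvs <- numeric(20); pccs <- numeric(20)
    for (i in 1:20) {
      osc <- sin(2 * pi * 2 * t + runif(1, 0, 2 * pi))
      x <- rbind(a * osc + rnorm(length(t), sd = 0.5),
                 a * osc + rnorm(length(t), sd = 0.5))
      xd <- bandpass_filter(x, 1, 4, fs)
      plvs[i] <- connectivity_matrix(xd, "plv")[1, 2]
      pccs[i] <- abs(connectivity_matrix(xd, "pcc")[1, 2])
    }
    c(plv = mean(plvs), pcc = mean(pccs))
  }
  m0 <- mean_conn(0); m5 <- mean_conn(0.5); m1 <- mean_conn(1)
  expect_lt(m0["plv"], m5["plv"]); expect_lt(m5["plv"], m1["plv"])
  expect_lt(m0["pcc"], m5["pcc"]); expect_lt(m5["pcc"], m1["pcc"])
})

test_that("view specs validate and the multi-view tensor stacks in order", {
  vs <- view_spec()
  expect_equal(nrow(vs), 10)
  expect_equal(vs$measure, rep(MVBN_MEASURES, 2))
  expect_equal(unique(vs$band), c("broadband", "delta"))
  expect_error(view_spec("pcc", "gamma"), "unknown band")
  expect_error(view_spec(c("pcc", "pcc"), c("delta", "delta")), "duplicate")

  set.seed(31)
  x <- matrix(rnorm(8 * 1000), 8)
  bs <- extract_rhythms(x, 100)
  G <- build_multiview(bs, vs)
  expect_equal(dim(G), c(10, 8, 8))
  G3 <- build_multiview(bs, view_spec(c("pcc", "plv", "mi"),
                                      c("delta", "delta", "theta")))
  expect_equal(dim(G3), c(3, 8, 8))

  # normalized mi/psi views span [0, 1]; stacking order follows the spec
  for (k in which(vs$measure %in% c("mi", "psi"))) {
    expect_equal(min(G[k, , ]), 0)
    expect_equal(max(G[k, , ]), 1)
  }
  expect_equal(G[1, , ], unclass(connectivity_matrix(bs$broadband, "pcc")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(G3[1, , ], unclass(connectivity_matrix(bs$delta, "pcc")),
               tolerance = 1e-12, ignore_attr = TRUE)
})
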