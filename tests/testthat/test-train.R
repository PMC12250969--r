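# Training behaviour, cross-validation folds and the metric suite.

# two well-separated classes built directly in connectivity space
separable_tensors <- function(n_per_class = 100, seed = 1) {
  set.seed(seed)
  L <- 2 * n_per_class
  x <- array(runif(L * 10 * 64, 0, 0.2), dim = c(L, 10, 8, 8))
  y <- rep(c("W", "QS"), each = n_per_class)
  for (l in which(y == "QS")) x[l, , 1:2, 1:2] <- x[l, , 1:2, 1:2] + 0.8
  for (l in which(y == "W")) x[l, , 7:8, 7:8] <- x[l, , 7:8, 7:8] + 0.8
  list(x = x, y = factor(y, levels = c("W", "QS")))
}

test_that("training reduces the loss on separable data", {
  d <- separable_tensors(100, seed = 1)
  fit <- mvbn_fit(d$x, d$y, iterations = 30, seed = 1)
  expect_length(fit$loss_trace, 30)
  expect_lt(tail(fit$loss_trace, 1), fit$loss_trace[1])
  # past the early plateau the classes separate completely
  fit60 <- mvbn_fit(d$x, d$y, iterations = 60, seed = 1)
  expect_gt(mean(predict(fit60, d$x) == d$y), 0.95)
})

test_that("training is deterministic given the seed", {
  d <- separable_tensors(30, seed = 2)
  f1 <- mvbn_fit(d$x, d$y, iterations = 5, seed = 7)
  f2 <- mvbn_fit(d$x, d$y, iterations = 5, seed = 7)
  expect_identical(f1$net$params, f2$net$params)
  expect_identical(f1$loss_trace, f2$loss_trace)
})

test_that("frozen view weights stay at their initial value", {
  d <- separable_tensors(30, seed = 3)
  fit <- mvbn_fit(d$x, d$y, iterations = 5, seed = 1,
                  freeze_view_weights = TRUE)
  expect_equal(coef(fit), matrix(1, 10, 64))
  fit2 <- mvbn_fit(d$x, d$y, iterations = 5, seed = 1)
  expect_false(all(coef(fit2) == 1))
})

test_that("single-class training data is rejected", {
  d <- separable_tensors(10, seed = 4)
  keep <- d$y == "W"
  expect_error(mvbn_fit(d$x[keep, , , , drop = FALSE], d$y[keep]),
               "2 classes")
})

test_that("fit methods expose coefficients, predictions and the trace", {
  d <- separable_tensors(30, seed = 5)
  fit <- mvbn_fit(d$x, d$y, iterations = 5, seed = 1)
  expect_s3_class(fit, "mvbn_fit")
  expect_equal(dim(coef(fit)), c(10, 64))
  pr <- predict(fit, d$x, type = "prob")
  expect_equal(dim(pr), c(60, 2))
  expect_equal(rowSums(pr), rep(1, 60), tolerance = 1e-9)
  lg <- predict(fit, d$x, type = "logits")
  expect_equal(dim(lg), c(60, 2))
  expect_output(print(fit), "classifier")
  expect_output(print(summary(fit)), "loss")
})

test_that("LOSO folds cover every subject exactly once", {
  subj <- rep(paste0("s", 1:5), each = 4)
  folds <- loso_folds(subj)
  expect_length(folds, 5)
  tests <- vapply(folds, function(f) f$test, "")
  expect_setequal(tests, paste0("s", 1:5))
  for (f in folds) expect_false(f$test %in% f$train)
  expect_error(loso_folds("s1"), "2 subjects")
  expect_length(loso_folds(paste0("n", 1:64)), 64)
})

test_that("subject-wise k-fold partitions subjects, not epochs", {
  subj <- paste0("s", 1:20)
  folds <- subjectwise_kfold(subj, k = 10, seed = 3)
  expect_length(folds, 10)
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 2))
  expect_setequal(unlist(lapply(folds, function(f) f$test)), subj)
  folds2 <- subjectwise_kfold(subj, k = 10, seed = 3)
  expect_identical(folds, folds2)
  expect_error(subjectwise_kfold(paste0("s", 1:5), k = 10), "at least k")
})

test_that("metric suite matches brute-force formulas", {
  # perfect prediction
  y <- factor(rep(c("W", "AS", "QS"), 10), levels = MVBN_STAGES)
  m <- compute_metrics(y, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$kappa, 1)
  expect_equal(m$specificity, 1)
  expect_equal(unname(m$per_class_precision), rep(1, 3))

  # balanced truth, constant predictor: accuracy 1/3, kappa 0
  yt <- factor(rep(c("W", "AS", "QS"), each = 10), levels = MVBN_STAGES)
  yp <- factor(rep("W", 30), levels = MVBN_STAGES)
  m2 <- compute_metrics(yt, yp)
  expect_equal(m2$accuracy, 1 / 3, tolerance = 1e-12)
  expect_equal(m2$kappa, 0, tolerance = 1e-12)

  # random confusion cases against the oracle
  set.seed(37)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    classes <- paste0("c", seq_len(k))
    n <- 200
    a <- sample(classes, n, replace = TRUE)
    b <- sample(classes, n, replace = TRUE)
    m <- compute_metrics(a, b, classes = classes)
    o <- oracle_metrics(a, b, classes)
    expect_equal(m$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(m$macro_f1, o$macro_f1, tolerance = 1e-12)
    expect_equal(m$kappa, o$kappa, tolerance = 1e-12)
    expect_equal(m$specificity, o$specificity, tolerance = 1e-12)
    expect_equal(m$sensitivity, o$sensitivity, tolerance = 1e-12)
    expect_equal(unname(m$per_class_precision), o$per_class_precision,
                 tolerance = 1e-12)
    expect_equal(sum(m$confusion), n)
  }
  expect_error(compute_metrics(c("a", "x"), c("a", "a"),
                               classes = c("a", "b")), "outside")
})

test_that("metrics are invariant to consistent class relabeling", {
  set.seed(41)
  a <- sample(MVBN_STAGES, 100, replace = TRUE)
  b <- sample(MVBN_STAGES, 100, replace = TRUE)
  m1 <- compute_metrics(a, b, classes = MVBN_STAGES)
  relab <- c(W = "QS", AS = "W", QS = "AS")
  m2 <- compute_metrics(unname(relab[a]), unname(relab[b]),
                        classes = c("QS", "W", "AS"))
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$macro_f1, m2$macro_f1)
  expect_equal(m1$kappa, m2$kappa)
})

test_that("kappa is 1 exactly for a diagonal confusion with >= 2 classes", {
  y <- factor(c("W", "AS", "W", "AS"), levels = MVBN_STAGES)
  expect_equal(compute_metrics(y, y)$kappa, 1)
  yp <- factor(c("W", "AS", "W", "W"), levels = MVBN_STAGES)
  expect_lt(compute_metrics(y, yp)$kappa, 1)
})

test_that("binary relabeling collapses AS and QS into SLEEP", {
  y <- factor(c("W", "AS", "QS", "W"), levels = MVBN_STAGES)
  b <- stages_to_binary(y)
  expect_equal(as.character(b), c("W", "SLEEP", "SLEEP", "W"))
  expect_equal(levels(b), c("W", "SLEEP"))
})

test_that("trained view weights concentrate on class-coupled entries", {
  # soft diagnostic, reported not gated: class structure lives at
  # (F3,F4) vs (P3,P4) blocks of every view
  set.seed(43)
  L <- 120
  x <- array(runif(L * 10 * 64, 0, 0.2), dim = c(L, 10, 8, 8))
  y <- rep(c("W", "QS"), each = L / 2)
  for (l in which(y == "QS")) { x[l, , 1, 2] <- 0.9; x[l, , 2, 1] <- 0.9 }
  for (l in which(y == "W")) { x[l, , 7, 8] <- 0.9; x[l, , 8, 7] <- 0.9 }
  ratios <- vapply(1:3, function(s) {
    fit <- mvbn_fit(x, y, iterations = 40, seed = s)
    wv <- abs(coef(fit))
    coupled <- c(sapply(1:10, function(k) wv[k, c(9, 2, 63, 56)]))
    other <- c(sapply(1:10, function(k) wv[k, c(19, 28, 37, 46)]))
    mean(coupled) / mean(other)
  }, 0)
  message("view-weight concentration ratio (coupled/uncoupled) per seed: ",
          paste(round(ratios, 3), collapse = ", "))
  succeed()
})
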