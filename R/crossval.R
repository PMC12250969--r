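# Subject-level cross-validation protocols and the evaluation driver.

#' Leave-one-subject-out folds
#'
#' One fold per subject; the test subject's epochs are never seen in its
#' own training set.
#'
#' @param subjects Character vector of per-epoch subject ids (or the unique
#'   subject list).
#' @return List of folds, each \code{list(train = <subject ids>,
#'   test = <one subject id>)}.
#' @export
loso_folds <- function(subjects) {
  subj <- unique(as.character(subjects))
  if (length(subj) < 2) stop(">= 2 subjects required for LOSO")
  lapply(subj, function(s) list(train = setdiff(subj, s), test = s))
}

#' Subject-wise k-fold partition
#'
#' Partitions subjects (not epochs) into k near-equal groups, so no subject
#' straddles folds. Deterministic given \code{seed}.
#'
#' @param subjects Per-epoch subject ids or the unique subject list.
#' @param k Number of folds (default 10).
#' @param seed RNG seed for the subject shuffle.
#' @return List of folds as in \code{\link{loso_folds}} (test may hold
#'   several subjects).
#' @export
subjectwise_kfold <- function(subjects, k = 10, seed = 1) {
  subj <- unique(as.character(subjects))
  if (length(subj) < k) stop("need at least k = ", k, " subjects")
  set.seed(seed)
  subj <- sample(subj)
  grp <- rep(seq_len(k), length.out = length(subj))
  grp <- sort(grp)                       # near-equal group sizes
  lapply(seq_len(k), function(i)
    list(train = subj[grp != i], test = subj[grp == i]))
}

#' Cross-validated training and evaluation
#'
#' Runs the chosen protocol over an \code{mvbn_dataset}: for each fold a
#' fresh model is trained on the training subjects' epochs and evaluated on
#' the held-out subject(s). Metrics are reported per fold and on the pooled
#' predictions across folds (the pooled confusion matrix is the primary
#' summary; per-fold metrics quantify subject variability).
#'
#' @param dataset An \code{mvbn_dataset} from \code{\link{extract_features}}.
#' @param protocol \code{"loso"} or \code{"kfold"}.
#' @param k Folds for \code{protocol = "kfold"}.
#' @param stages 3 for W/AS/QS, 2 for sleep vs wakefulness (AS and QS are
#'   relabeled SLEEP).
#' @param mask Optional evaluation-time channel mask (names, indices or
#'   matrix); training is unmasked unless \code{mask_train = TRUE}.
#' @param mask_train Apply \code{mask} during training as well.
#' @param seed RNG seed (model init + shuffling + kfold partition).
#' @param keep_fits Keep the per-fold fitted models (memory-heavy).
#' @param ... Further arguments to \code{\link{mvbn_fit}} (e.g.
#'   \code{iterations}, \code{lr}, \code{batch_size}).
#' @return Object of class \code{"mvbn_cv"}: \code{pooled}
#'   (\code{mvbn_metrics}), \code{per_fold} (data frame),
#'   \code{predictions} (data frame with subject, true, predicted),
#'   \code{folds}, and optionally \code{fits}.
#' @export
run_cv <- function(dataset, protocol = c("loso", "kfold"), k = 10,
                   stages = 3, mask = NULL, mask_train = FALSE, seed = 1,
                   keep_fits = FALSE, ...) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(dataset, "mvbn_dataset"), stages %in% 2:3)
  y <- if (stages == 2) stages_to_binary(dataset$y) else
    droplevels(dataset$y)
  classes <- levels(y)
  folds <- if (protocol == "loso") loso_folds(dataset$subject)
           else subjectwise_kfold(dataset$subject, k = k, seed = seed)

  preds <- character(0); trues <- character(0); subj_out <- character(0)
  per_fold <- list(); fits <- list()
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    tr <- dataset$subject %in% f$train
    te <- dataset$subject %in% f$test
    fit <- mvbn_fit(dataset$x[tr, , , , drop = FALSE], y[tr],
                    classes = classes, seed = seed,
                    mask = if (mask_train) mask else NULL, ...)
    yp <- predict(fit, dataset$x[te, , , , drop = FALSE], mask = mask)
    m <- compute_metrics(y[te], factor(yp, levels = classes),
                         classes = classes)
    per_fold[[fi]] <- data.frame(
      fold = fi, test = paste(f$test, collapse = "+"),
      n_test = sum(te), accuracy = m$accuracy, macro_f1 = m$macro_f1,
      kappa = m$kappa, specificity = m$specificity,
      sensitivity = m$sensitivity, stringsAsFactors = FALSE)
    preds <- c(preds, as.character(yp))
    trues <- c(trues, as.character(y[te]))
    subj_out <- c(subj_out, dataset$subject[te])
    if (keep_fits) fits[[fi]] <- fit
  }
  pooled <- compute_metrics(factor(trues, levels = classes),
                            factor(preds, levels = classes),
                            classes = classes)
  structure(list(pooled = pooled,
                 per_fold = do.call(rbind, per_fold),
                 predictions = data.frame(subject = subj_out, true = trues,
                                          predicted = preds,
                                          stringsAsFactors = FALSE),
                 folds = folds, protocol = protocol, stages = stages,
                 fits = if (keep_fits) fits else NULL),
            class = "mvbn_cv")
}

#' @export
print.mvbn_cv <- function(x, ...) {
  cat("Cross-validated evaluation (", x$protocol, ", ",
      length(x$folds), " folds, ", x$stages, "-stage task)\n", sep = "")
  cat("Pooled metrics:\n")
  print(x$pooled)
  cat("\nPer-fold accuracy: ",
      paste(round(x$per_fold$accuracy, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}
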