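# Model fitting: Adam + cross-entropy on multi-view tensors.

#' Fit the multi-view network classifier
#'
#' Trains the attention weights, conv stack and linear stack jointly with
#' Adam on the cross-entropy loss. One "iteration" is one pass over the
#' training set (default 150). Fully deterministic given \code{seed}: the
#' seed drives parameter initialization and the per-iteration shuffling.
#'
#' @param x Training tensors: an L x N x C x C array or an
#'   \code{mvbn_dataset} (whose \code{x}/\code{y} are then used).
#' @param y Stage labels: factor or character; ignored when \code{x} is an
#'   \code{mvbn_dataset}. At least 2 classes must be present.
#' @param classes Class level order; defaults to the levels present.
#' @param iterations Passes over the training set.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed RNG seed.
#' @param class_weights If \code{TRUE}, weight the loss by inverse class
#'   frequency.
#' @param freeze_view_weights If \code{TRUE}, keep the attention weights at
#'   their initial value.
#' @param mask Optional training-time channel mask (names, indices or
#'   C x C matrix).
#' @param net Optional pre-initialized \code{\link{mvbn_net}} (e.g. to
#'   continue training); otherwise one is created from \code{seed}.
#' @return Object of class \code{"mvbn_fit"} with elements \code{net}
#'   (trained parameters), \code{classes}, \code{loss_trace},
#'   \code{config}, \code{view_spec} (when available).
#' @examples
#' \donttest{
#' ds <- generate_dataset(synth_spec(n_subjects = 2, epochs_per_class = 5))
#' feats <- extract_features(lapply(ds$recordings, preprocess_recording))
#' fit <- mvbn_fit(feats, iterations = 10, seed = 1)
#' print(fit)
#' }
#' @export
mvbn_fit <- function(x, y = NULL, classes = NULL, iterations = 150,
                     lr = 1e-3, batch_size = 64, seed = 1,
                     class_weights = FALSE, freeze_view_weights = FALSE,
                     mask = NULL, net = NULL) {
  view_spec <- NULL
  if (inherits(x, "mvbn_dataset")) {
    y <- x$y
    view_spec <- x$view_spec
    x <- x$x
  }
  if (is.null(y)) stop("labels y are required")
  y <- droplevels(factor(y, levels = classes %||% unique(as.character(y))))
  if (nlevels(y) < 2) stop("training data must contain at least 2 classes")
  d <- dim(x)
  if (length(d) != 4) stop("x must be an L x N x C x C array")
  if (d[1] != length(y)) stop("length of y must match dim(x)[1]")
  stopifnot(iterations >= 1, batch_size >= 1)

  if (is.null(net))
    net <- mvbn_net(n_views = d[2], n_channels = d[3],
                    n_classes = nlevels(y), seed = seed)
  else if (!is.null(seed)) set.seed(seed)
  if (net$n_classes != nlevels(y))
    stop("net has ", net$n_classes, " output classes but y has ", nlevels(y))

  X <- .flatten_input(x)
  yi <- as.integer(y) - 1L
  n <- length(yi)
  order <- t(vapply(seq_len(iterations), function(i) sample.int(n),
                    integer(n)))
  cw <- if (class_weights) {
    tb <- tabulate(yi + 1L, nlevels(y))
    n / (nlevels(y) * pmax(tb, 1))
  } else rep(1, nlevels(y))

  res <- cpp_train(net$params, X, yi, order, as.integer(batch_size),
                   lr, 0.9, 0.999, 1e-8, cw,
                   isTRUE(freeze_view_weights),
                   .mask_vec(mask, d[3]))
  net$params <- res$params
  structure(list(net = net, classes = levels(y),
                 loss_trace = as.numeric(res$loss_trace),
                 config = list(iterations = iterations, lr = lr,
                               batch_size = batch_size, seed = seed,
                               class_weights = class_weights,
                               freeze_view_weights = freeze_view_weights,
                               mask = mask),
                 view_spec = view_spec, n = n),
            class = "mvbn_fit")
}

#' @export
print.mvbn_fit <- function(x, ...) {
  cat("Multi-view network sleep-stage classifier\n")
  cat("  classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  cat("  trained on ", x$n, " epochs, ", x$config$iterations,
      " iterations (final loss ", signif(tail(x$loss_trace, 1), 4), ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.mvbn_fit <- function(object, ...) {
  wv <- coef(object)
  s <- list(classes = object$classes, n = object$n,
            config = object$config,
            loss_initial = object$loss_trace[1],
            loss_final = tail(object$loss_trace, 1),
            view_weight_norms = apply(wv, 1, function(w) mean(abs(w))),
            view_spec = object$view_spec)
  class(s) <- "summary.mvbn_fit"
  s
}

#' @export
print.summary.mvbn_fit <- function(x, ...) {
  cat("Multi-view network classifier (", length(x$classes), " classes, ",
      x$n, " training epochs)\n", sep = "")
  cat("  loss: ", signif(x$loss_initial, 4), " -> ",
      signif(x$loss_final, 4), " over ", x$config$iterations,
      " iterations\n", sep = "")
  cat("  mean |view weight| per view:\n")
  nm <- if (!is.null(x$view_spec))
    paste(x$view_spec$measure, x$view_spec$band, sep = ":")
  else paste0("view", seq_along(x$view_weight_norms))
  print(stats::setNames(round(x$view_weight_norms, 4), nm))
  invisible(x)
}

#' Extract learned attention weights
#'
#' Returns the trained view-weight tensor as an N x C^2 matrix (one
#' flattened C x C weight matrix per view). Larger absolute weights mark
#' channel pairs the model found informative for staging.
#'
#' @param object An \code{mvbn_fit}.
#' @param ... Unused.
#' @return N x C^2 numeric matrix.
#' @export
coef.mvbn_fit <- function(object, ...) object$net$params$Wv

#' Predict sleep stages for new epochs
#'
#' @param object An \code{mvbn_fit}.
#' @param newdata L x N x C x C array, single N x C x C epoch, or
#'   \code{mvbn_dataset}.
#' @param type \code{"class"} (factor), \code{"prob"} (softmax matrix) or
#'   \code{"logits"}.
#' @param mask Optional evaluation-time channel mask.
#' @param ... Unused.
#' @return Factor of length L, or an L x n_classes matrix.
#' @export
predict.mvbn_fit <- function(object, newdata, type = c("class", "prob",
                                                       "logits"),
                             mask = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "mvbn_dataset")) newdata <- newdata$x
  logits <- mvbn_forward(object$net, newdata, mask = mask)
  if (type == "logits") return(t(logits))
  p <- apply(logits, 2, function(z) { e <- exp(z - max(z)); e / sum(e) })
  if (type == "prob") {
    p <- t(p)
    colnames(p) <- object$classes
    return(p)
  }
  factor(object$classes[apply(p, 2, which.max)], levels = object$classes)
}

#' Plot the training loss trace
#'
#' @param x An \code{mvbn_fit}.
#' @param ... Passed to \code{plot}.
#' @export
plot.mvbn_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "iteration (pass over training set)",
                 ylab = "mean cross-entropy loss", ...)
  invisible(x)
}

#' @importFrom utils tail
NULL
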