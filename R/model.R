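# Model construction, attention and masking operations, and forward passes.
#
# The network: per-view attention (softmax over the 64 entries of
# relu(W_k o G_k)), an optional channel mask applied to the connectivity
# matrices themselves (so masked channels can never influence the output),
# a three-layer CNN (16@3x3, 32@3x3, 64@2x2; stride 1, no padding, ReLU)
# and a five-layer linear stack 576/256/128/64/n_classes (ReLU on hidden
# layers). On an 8x8 input the conv spatial maps are 6x6 -> 4x4 -> 3x3,
# so the flatten width is 64*3*3 = 576.

#' Initialize a multi-view network classifier
#'
#' View-attention weights start at all ones (initial attention is then just
#' the normalized networks); conv and linear layers use uniform fan-in
#' initialization, \code{U(-1, 1)/sqrt(fan_in)}.
#'
#' @param n_views Number of connectivity views N (default 10).
#' @param n_channels Number of EEG channels C; the conv stack requires 8.
#' @param n_classes 2 (sleep vs wake) or 3 (W/AS/QS).
#' @param seed Optional RNG seed for reproducible initialization.
#' @return Object of class \code{"mvbn_net"}.
#' @export
mvbn_net <- function(n_views = 10, n_channels = 8, n_classes = 3,
                     seed = NULL) {
  if (n_channels != 8)
    stop("the conv stack (3x3, 3x3, 2x2 kernels) requires 8 channels")
  if (!n_classes %in% 2:3) stop("n_classes must be 2 or 3")
  if (!is.null(seed)) set.seed(seed)
  init_m <- function(nr, nc)
    matrix(stats::runif(nr * nc, -1, 1) / sqrt(nc), nr, nc)
  init_v <- function(nr, fan_in) stats::runif(nr, -1, 1) / sqrt(fan_in)
  params <- list(
    Wv = matrix(1, n_views, n_channels^2),
    K1 = init_m(16, n_views * 9), b1 = init_v(16, n_views * 9),
    K2 = init_m(32, 16 * 9),      b2 = init_v(32, 16 * 9),
    K3 = init_m(64, 32 * 4),      b3 = init_v(64, 32 * 4),
    A1 = init_m(576, 576),        c1 = init_v(576, 576),
    A2 = init_m(256, 576),        c2 = init_v(256, 576),
    A3 = init_m(128, 256),        c3 = init_v(128, 256),
    A4 = init_m(64, 128),         c4 = init_v(64, 128),
    A5 = init_m(n_classes, 64),   c5 = init_v(n_classes, 64)
  )
  structure(list(params = params, n_views = n_views,
                 n_channels = n_channels, n_classes = n_classes),
            class = "mvbn_net")
}

#' @export
print.mvbn_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("Multi-view network classifier: ", x$n_views, " views x ",
      x$n_channels, "x", x$n_channels, " -> conv 16/32/64 -> linear ",
      "576/256/128/64/", x$n_classes, " (", np, " parameters)\n", sep = "")
  invisible(x)
}

#' Build a channel mask matrix
#'
#' An all-ones C x C matrix with the rows and columns of the masked
#' channels set to zero; applied to every connectivity view it removes all
#' edges touching those channels, emulating electrode dropout or
#' low-quality channels.
#'
#' @param channels Channels to mask: channel names (e.g. \code{c("T3",
#'   "T4")}) or 1-based indices. Empty means no masking.
#' @param C Number of channels.
#' @param channel_labels Label set used to resolve names.
#' @return C x C 0/1 matrix.
#' @export
make_mask <- function(channels = character(), C = 8,
                      channel_labels = MVBN_CHANNELS) {
  if (is.character(channels)) {
    idx <- match(channels, channel_labels)
    if (anyNA(idx))
      stop("unknown channel(s): ",
           paste(channels[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(channels)
    if (length(idx) && (min(idx) < 1 || max(idx) > C))
      stop("channel index out of range 1..", C)
  }
  m <- matrix(1, C, C)
  m[idx, ] <- 0
  m[, idx] <- 0
  m
}

#' Apply a channel mask to a multi-view tensor
#'
#' Every view is multiplied elementwise by the same C x C mask.
#'
#' @param G N x C x C array (or a single C x C matrix).
#' @param mask C x C mask from \code{\link{make_mask}}.
#' @return Masked tensor, same shape.
#' @export
apply_mask <- function(G, mask) {
  if (is.matrix(G)) return(G * mask)
  d <- dim(G)
  if (length(d) != 3 || !all(d[2:3] == dim(mask)))
    stop("shape mismatch between tensor and mask")
  out <- G
  for (k in seq_len(d[1])) out[k, , ] <- G[k, , ] * mask
  out
}

#' Data-driven attention over connectivity views
#'
#' For each view k, computes \code{relu(W[k] o G[k])} elementwise and
#' normalizes with a softmax over the view's C^2 entries, so each output
#' view sums to 1. With all-one weights and a constant positive view the
#' output is uniform (1/C^2 per entry).
#'
#' @param G N x C x C tensor of connectivity views.
#' @param W N x C x C array of attention weights (or an N x C^2 matrix,
#'   one flattened view per row).
#' @return N x C x C tensor of attention-normalized views.
#' @export
apply_attention <- function(G, W) {
  d <- dim(G)
  if (is.matrix(W)) {
    if (!all(dim(W) == c(d[1], d[2] * d[3]))) stop("shape mismatch")
    W <- array(apply(W, 1, identity), dim = c(d[2], d[3], d[1]))
    W <- aperm(W, c(3, 1, 2))
  }
  if (!all(dim(W) == d)) stop("shape mismatch between G and W")
  out <- G
  for (k in seq_len(d[1])) {
    h <- pmax(W[k, , ] * G[k, , ], 0)
    e <- exp(h - max(h))
    out[k, , ] <- e / sum(e)
  }
  out
}

# Flatten tensors into the (N*C*C) x L column layout used by the C++ code:
# within a sample, view k occupies rows (k-1)*C^2 + 1 .. k*C^2 in
# column-major C x C order.
.flatten_input <- function(x) {
  d <- dim(x)
  if (length(d) == 3) {                      # single epoch N x C x C
    matrix(as.vector(aperm(x, c(2, 3, 1))), ncol = 1)
  } else if (length(d) == 4) {               # batch L x N x C x C
    matrix(as.vector(aperm(x, c(3, 4, 2, 1))), nrow = prod(d[2:4]))
  } else stop("input must be an N x C x C or L x N x C x C array")
}

.mask_vec <- function(mask, C = 8) {
  if (is.null(mask)) return(rep(1, C * C))
  if (is.character(mask) || (is.numeric(mask) && is.null(dim(mask))))
    mask <- make_mask(mask, C)
  as.vector(mask)
}

#' Forward pass of the network
#'
#' Computes class logits for one epoch tensor or a batch. The default
#' engine is the compiled implementation; \code{engine = "reference"} runs
#' an independent plain-R implementation (loops, no shared code) that also
#' exposes every intermediate activation via \code{hidden = TRUE} — useful
#' for inspecting the conv shape contract (16x6x6, 32x4x4, 64x3x3).
#'
#' @param net An \code{mvbn_net} or \code{mvbn_fit} object.
#' @param G N x C x C array (single epoch) or L x N x C x C batch.
#' @param mask Optional mask: C x C matrix, channel names, or indices.
#' @param engine \code{"compiled"} or \code{"reference"}.
#' @param hidden If \code{TRUE} (reference engine, single epoch), return
#'   intermediate activations as well.
#' @return Logits matrix (n_classes x L), or a list when
#'   \code{hidden = TRUE}.
#' @export
mvbn_forward <- function(net, G, mask = NULL,
                         engine = c("compiled", "reference"),
                         hidden = FALSE) {
  engine <- match.arg(engine)
  p <- if (inherits(net, "mvbn_fit")) net$net$params else net$params
  if (length(dim(G)) == 3 && dim(G)[1] != nrow(p$Wv) ||
      length(dim(G)) == 4 && dim(G)[2] != nrow(p$Wv))
    stop("view count of G does not match the model's view weights")
  if (engine == "compiled" && !hidden) {
    X <- .flatten_input(G)
    return(cpp_forward(p, X, .mask_vec(mask)))
  }
  if (length(dim(G)) == 4) {
    return(vapply(seq_len(dim(G)[1]), function(l)
      drop(mvbn_forward(net, G[l, , , ], mask, engine = "reference")),
      numeric(length(p$c5))))
  }
  .forward_reference(p, G, mask, hidden)
}

# Independent R implementation of the forward pass (explicit loops).
.forward_reference <- function(p, G, mask, hidden = FALSE) {
  N <- dim(G)[1]; C <- dim(G)[2]
  maskm <- matrix(.mask_vec(mask, C), C, C)
  Gm <- apply_mask(G, maskm)
  W <- array(0, dim = c(N, C, C))
  for (k in seq_len(N)) W[k, , ] <- matrix(p$Wv[k, ], C, C)
  att <- apply_attention(Gm, W)

  conv_ref <- function(inp, K, b, kh, kw) {
    ci <- dim(inp)[1]; H <- dim(inp)[2]; Wd <- dim(inp)[3]
    co <- nrow(K)
    oh <- H - kh + 1; ow <- Wd - kw + 1
    out <- array(0, dim = c(co, oh, ow))
    for (f in seq_len(co)) for (r in seq_len(oh)) for (cc in seq_len(ow)) {
      acc <- b[f]
      for (ch in seq_len(ci)) for (dr in seq_len(kh)) for (dc in seq_len(kw))
        acc <- acc + K[f, (ch - 1) + ci * ((dr - 1) + kh * (dc - 1)) + 1] *
          inp[ch, r + dr - 1, cc + dc - 1]
      out[f, r, cc] <- acc
    }
    pmax(out, 0)
  }
  z1 <- conv_ref(att, p$K1, p$b1, 3, 3)
  z2 <- conv_ref(z1, p$K2, p$b2, 3, 3)
  z3 <- conv_ref(z2, p$K3, p$b3, 2, 2)
  f <- numeric(length(z3))
  for (ch in 1:dim(z3)[1]) for (rr in 1:dim(z3)[2]) for (rc in 1:dim(z3)[3])
    f[(ch - 1) + 64 * ((rr - 1) + 3 * (rc - 1)) + 1] <- z3[ch, rr, rc]
  h1 <- pmax(p$A1 %*% f + p$c1, 0)
  h2 <- pmax(p$A2 %*% h1 + p$c2, 0)
  h3 <- pmax(p$A3 %*% h2 + p$c3, 0)
  h4 <- pmax(p$A4 %*% h3 + p$c4, 0)
  logits <- p$A5 %*% h4 + p$c5
  if (!hidden) return(logits)
  list(attention = att, conv1 = z1, conv2 = z2, conv3 = z3,
       flatten = f, logits = drop(logits))
}

#' Loss and gradients at a parameter point
#'
#' Returns the cross-entropy loss, the gradient for every parameter, and
#' the gradient of the loss with respect to the input tensor itself (useful
#' for verifying that masked entries receive exactly zero gradient).
#'
#' @param net An \code{mvbn_net} or \code{mvbn_fit}.
#' @param G L x N x C x C batch (or single N x C x C epoch).
#' @param y Integer class labels in 1..n_classes (or a factor).
#' @param mask Optional mask (matrix, names or indices).
#' @return List with \code{loss}, \code{grads} (named list), and
#'   \code{input_grad} (same shape as \code{G}).
#' @export
mvbn_gradients <- function(net, G, y, mask = NULL) {
  p <- if (inherits(net, "mvbn_fit")) net$net$params else net$params
  if (length(dim(G)) == 3) G <- array(G, dim = c(1, dim(G)))
  X <- .flatten_input(G)
  if (is.factor(y)) y <- as.integer(y)
  ncls <- length(p$c5)
  if (any(y < 1 | y > ncls)) stop("labels must lie in 1..", ncls)
  out <- cpp_loss_grads(p, X, as.integer(y) - 1L, .mask_vec(mask),
                        rep(1, ncls))
  d <- dim(G)
  ig <- aperm(array(out$input_grad, dim = c(d[3], d[4], d[2], d[1])),
              c(4, 3, 1, 2))
  list(loss = out$loss, grads = out$grads, input_grad = ig)
}
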