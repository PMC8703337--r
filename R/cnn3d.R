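# A compact 3D convolutional network for S x S x L reflectance patches:
# C1 (two 3D kernels) -> ReLU -> C2 (four 3D kernels) -> ReLU -> flatten ->
# fully connected (ReLU) -> linear -> softmax over the two seed groups.
# Trained by SGD with momentum on the softmax cross-entropy. Implemented with
# im2col matrix multiplication so the whole network runs on BLAS.

# Precompute the im2col index map for a valid 3D convolution over an input of
# shape (d1, d2, d3, C): a P x K matrix of linear indices, P output positions,
# K = k1*k2*k3*C kernel taps.
.im2col_map <- function(dims, kern) {
  d1 <- dims[1L]; d2 <- dims[2L]; d3 <- dims[3L]; C <- dims[4L]
  k1 <- kern[1L]; k2 <- kern[2L]; k3 <- kern[3L]
  o1 <- d1 - k1 + 1L; o2 <- d2 - k2 + 1L; o3 <- d3 - k3 + 1L
  if (o1 < 1L || o2 < 1L || o3 < 1L)
    stop("patch smaller than the receptive field")
  pos <- as.matrix(expand.grid(i = seq_len(o1), j = seq_len(o2),
                               l = seq_len(o3)))
  tap <- as.matrix(expand.grid(a = seq_len(k1) - 1L, b = seq_len(k2) - 1L,
                               c = seq_len(k3) - 1L, ch = seq_len(C) - 1L))
  lin <- function(i, j, l, ch) ((ch * d3 + (l - 1L)) * d2 + (j - 1L)) * d1 + i
  P <- nrow(pos); K <- nrow(tap)
  M <- matrix(0L, P, K)
  for (k in seq_len(K))
    M[, k] <- lin(pos[, 1L] + tap[k, 1L], pos[, 2L] + tap[k, 2L],
                  pos[, 3L] + tap[k, 3L], tap[k, 4L])
  list(map = M, P = P, K = K, out_dims = c(o1, o2, o3))
}

# forward one conv layer: X (n x in_size) -> list(out (n x P*F), cols)
.conv_forward <- function(X, map, W, b) {
  n <- nrow(X)
  cols <- X[, as.vector(map$map), drop = FALSE]   # n x (P*K), P fastest
  dim(cols) <- NULL
  mat <- matrix(cols, n * map$P, map$K)           # (n*P) x K
  out <- sweep(mat %*% W, 2L, b, "+")             # (n*P) x F
  list(out = out, mat = mat)
}

# backward through a conv layer; returns gradients and (optionally) dX
.conv_backward <- function(dOut, fwd, map, W, n, in_size, need_dx = TRUE) {
  dW <- crossprod(fwd$mat, dOut)
  db <- colSums(dOut)
  dX <- NULL
  if (need_dx) {
    dmat <- dOut %*% t(W)                         # (n*P) x K
    dX <- matrix(0, n, in_size)
    for (k in seq_len(map$K)) {
      dk <- matrix(dmat[, k], n, map$P)
      tgt <- map$map[, k]
      dX[, tgt] <- dX[, tgt] + dk
    }
  }
  list(dW = dW, db = db, dX = dX)
}

#' Initialize the 3D CNN
#'
#' @param S odd spatial patch size.
#' @param L spectral bands per patch.
#' @param kernel 3D kernel extent \code{c(spatial, spatial, spectral)} shared
#'   by both convolution layers.
#' @param n_filters filter counts for C1 and C2.
#' @param fc_width width of the hidden fully connected layer.
#' @param rng_seed seed for the (He-scaled Gaussian) weight initialization.
#' @return object of class \code{"cnn3d"}.
#' @export
cnn3d_init <- function(S, L, kernel = c(3L, 3L, 7L), n_filters = c(2L, 4L),
                       fc_width = 128L, rng_seed = 1L) {
  m1 <- .im2col_map(c(S, S, L, 1L), kernel)
  m2 <- .im2col_map(c(m1$out_dims, n_filters[1L]), kernel)
  flat <- m2$P * n_filters[2L]
  with_rng_seed(rng_seed, {
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
    structure(list(
      S = S, L = L, kernel = kernel, n_filters = n_filters,
      fc_width = fc_width, m1 = m1, m2 = m2, flat = flat,
      W1 = he(m1$K, n_filters[1L]), b1 = numeric(n_filters[1L]),
      W2 = he(m2$K, n_filters[2L]), b2 = numeric(n_filters[2L]),
      Wf = he(flat, fc_width), bf = numeric(fc_width),
      Wo = he(fc_width, 2L), bo = numeric(2L)),
      class = "cnn3d")
  })
}

# full forward pass; returns softmax probabilities and caches for backprop
.cnn_forward <- function(net, X, keep_cache = FALSE) {
  n <- nrow(X)
  c1 <- .conv_forward(X, net$m1, net$W1, net$b1)
  a1 <- pmax(c1$out, 0)                                  # (n*P1) x F1
  # reorder (n, P1, F1) -> (n, P1*F1) channel-last flat vector for conv2
  x2 <- matrix(0, n, net$m1$P * net$n_filters[1L])
  for (f in seq_len(net$n_filters[1L]))
    x2[, (f - 1L) * net$m1$P + seq_len(net$m1$P)] <- matrix(a1[, f], n, net$m1$P)
  c2 <- .conv_forward(x2, net$m2, net$W2, net$b2)
  a2 <- pmax(c2$out, 0)                                  # (n*P2) x F2
  flat <- matrix(0, n, net$flat)
  for (f in seq_len(net$n_filters[2L]))
    flat[, (f - 1L) * net$m2$P + seq_len(net$m2$P)] <- matrix(a2[, f], n, net$m2$P)
  h <- pmax(sweep(flat %*% net$Wf, 2L, net$bf, "+"), 0)  # n x fc
  logits <- sweep(h %*% net$Wo, 2L, net$bo, "+")         # n x 2
  mx <- pmax(logits[, 1L], logits[, 2L])
  ez <- exp(logits - mx)
  probs <- ez / rowSums(ez)
  out <- list(probs = probs)
  if (keep_cache)
    out <- c(out, list(c1 = c1, a1 = a1, x2 = x2, c2 = c2, a2 = a2,
                       flat = flat, h = h, n = n))
  out
}

# one SGD step on a batch; y is 0/1 (1 = hs). Returns updated net+velocity.
.cnn_backward_update <- function(net, vel, X, y, lr, momentum) {
  fw <- .cnn_forward(net, X, keep_cache = TRUE)
  n <- fw$n
  dlogits <- fw$probs
  dlogits[cbind(seq_len(n), y + 1L)] <- dlogits[cbind(seq_len(n), y + 1L)] - 1
  dlogits <- dlogits / n
  dWo <- crossprod(fw$h, dlogits); dbo <- colSums(dlogits)
  dh <- dlogits %*% t(net$Wo)
  dh[fw$h <= 0] <- 0
  dWf <- crossprod(fw$flat, dh); dbf <- colSums(dh)
  dflat <- dh %*% t(net$Wf)                              # n x flat
  da2 <- matrix(0, n * net$m2$P, net$n_filters[2L])
  for (f in seq_len(net$n_filters[2L]))
    da2[, f] <- as.vector(dflat[, (f - 1L) * net$m2$P + seq_len(net$m2$P)])
  da2[fw$a2 <= 0] <- 0
  g2 <- .conv_backward(da2, fw$c2, net$m2, net$W2, n,
                       in_size = ncol(fw$x2), need_dx = TRUE)
  dx2 <- g2$dX                                           # n x (P1*F1)
  da1 <- matrix(0, n * net$m1$P, net$n_filters[1L])
  for (f in seq_len(net$n_filters[1L]))
    da1[, f] <- as.vector(dx2[, (f - 1L) * net$m1$P + seq_len(net$m1$P)])
  da1[fw$a1 <= 0] <- 0
  g1 <- .conv_backward(da1, fw$c1, net$m1, net$W1, n,
                       in_size = ncol(X), need_dx = FALSE)

  upd <- function(nm, grad) {
    vel[[nm]] <<- momentum * vel[[nm]] - lr * grad
    net[[nm]] <<- net[[nm]] + vel[[nm]]
  }
  upd("W1", g1$dW); upd("b1", g1$db)
  upd("W2", g2$dW); upd("b2", g2$db)
  upd("Wf", dWf);   upd("bf", dbf)
  upd("Wo", dWo);   upd("bo", dbo)
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(n), y + 1L)], 1e-12)))
  list(net = net, vel = vel, loss = loss)
}

#' Predict group probabilities for patches
#'
#' @param object a trained \code{cnn3d}.
#' @param patches matrix (samples x \code{S*S*L}) from
#'   \code{\link{extract_subcubes}}.
#' @param batch prediction batch size.
#' @param ... unused.
#' @return matrix (samples x 2) of softmax probabilities, columns
#'   \code{control}, \code{hs}.
#' @export
predict.cnn3d <- function(object, patches, batch = 1024L, ...) {
  if (!is.null(object$center))
    patches <- (patches - object$center) / object$scale
  n <- nrow(patches)
  probs <- matrix(NA_real_, n, 2L,
                  dimnames = list(NULL, c("control", "hs")))
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    probs[s:e, ] <- .cnn_forward(object, patches[s:e, , drop = FALSE])$probs
  }
  probs
}

#' Train the 3D CNN on labeled sub-cube patches
#'
#' SGD with momentum on the softmax cross-entropy, shuffling each epoch from
#' a seed-derived stream. After every epoch the validation accuracy is
#' evaluated; the best-so-far weights are kept and training stops early when
#' no improvement is seen for \code{patience} epochs. Two runs with the same
#' data, order and \code{rng_seed} produce identical predictions.
#'
#' @param train_patches,train_groups training patches and labels
#'   (\code{"control"}/\code{"hs"}).
#' @param val_patches,val_groups validation set used for model selection.
#' @param S,L patch geometry (must match the patch columns).
#' @param lr,momentum,batch,epochs,patience SGD hyperparameters.
#' @param kernel,n_filters,fc_width architecture knobs (see
#'   \code{\link{cnn3d_init}}).
#' @param rng_seed seed for initialization and shuffling.
#' @param verbose print one line per epoch?
#' @return the trained \code{cnn3d} (best validation weights), with a
#'   \code{history} data frame attached.
#' @export
cnn3d_train <- function(train_patches, train_groups, val_patches, val_groups,
                        S, L, lr = 0.01, momentum = 0.9, batch = 128L,
                        epochs = 50L, patience = 5L, kernel = c(3L, 3L, 7L),
                        n_filters = c(2L, 4L), fc_width = 128L,
                        rng_seed = 1L, verbose = FALSE) {
  if (length(unique(train_groups)) < 2L)
    stop("degenerate single-class training set")
  net <- cnn3d_init(S, L, kernel, n_filters, fc_width, rng_seed)
  # standardize inputs with training statistics (kept on the model for
  # prediction); unscaled reflectance makes SGD with momentum overshoot
  net$center <- mean(train_patches)
  net$scale <- stats::sd(train_patches)
  if (!is.finite(net$scale) || net$scale <= 0) net$scale <- 1
  train_patches <- (train_patches - net$center) / net$scale
  vel <- list(W1 = 0 * net$W1, b1 = 0 * net$b1, W2 = 0 * net$W2,
              b2 = 0 * net$b2, Wf = 0 * net$Wf, bf = 0 * net$bf,
              Wo = 0 * net$Wo, bo = 0 * net$bo)
  y <- as.integer(train_groups == "hs")
  yv <- as.integer(val_groups == "hs")
  n <- nrow(train_patches)
  best <- list(acc = -Inf, net = net, epoch = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(), val_acc = numeric())
  stale <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_rng_seed(rng_seed + 1000L * ep, sample.int(n))
    losses <- numeric(0)
    for (s in seq(1L, n, by = batch)) {
      sel <- ord[s:min(s + batch - 1L, n)]
      step <- .cnn_backward_update(net, vel, train_patches[sel, , drop = FALSE],
                                   y[sel], lr, momentum)
      net <- step$net; vel <- step$vel
      losses <- c(losses, step$loss)
    }
    vp <- predict.cnn3d(net, val_patches)
    vacc <- mean((vp[, "hs"] > 0.5) == (yv == 1L))
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   val_acc = vacc))
    if (verbose)
      .log_line(sprintf("epoch %d: loss %.4f, val acc %.4f", ep,
                        mean(losses), vacc))
    if (vacc > best$acc + 1e-12) {
      best <- list(acc = vacc, net = net, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  out <- best$net
  out$history <- hist
  out$best_epoch <- best$epoch
  out
}
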