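## A small convolutional network for mel-spectrogram classification,
## implemented directly on BLAS matrix operations. Activations for a batch
## of B images (H x W, C channels) are stored as a (B*H*W) x C matrix with
## rows ordered (sample, then column-major pixel); 'same' 3x3 convolutions
## become nine shifted matrix multiplications via precomputed index maps.

## per-offset pixel index map with zero-padding (0 marks out-of-bounds)
conv_shift_map <- function(H, W, dy, dx) {
  r <- rep(seq_len(H), times = W)
  c <- rep(seq_len(W), each = H)
  sr <- r + dy; sc <- c + dx
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  idx <- ifelse(ok, (sc - 1L) * H + sr, 0L)
  as.integer(idx)
}

## expand a local pixel map to global batch rows; out-of-bounds rows point
## to the shared zero row (B*HW + 1)
global_rows <- function(idx, B, HW) {
  base <- rep((seq_len(B) - 1L) * HW, each = length(idx))
  g <- base + rep(idx, times = B)
  g[rep(idx == 0L, times = B)] <- B * HW + 1L
  g
}

cnn_init_layer <- function(type, ...) c(list(type = type), list(...))

## He-initialized parameters for the fixed architecture
cnn_init <- function(H, W, filters, dense, n_class = 2L, seed = 1L) {
  with_seed(seed, {
    layers <- list()
    cin <- 1L
    h <- H; w <- W
    for (f in filters) {
      sd_w <- sqrt(2 / (9 * cin))
      layers[[length(layers) + 1L]] <- cnn_init_layer(
        "conv",
        W = lapply(1:9, function(o) matrix(stats::rnorm(cin * f, sd = sd_w), cin, f)),
        b = numeric(f), H = h, Wd = w,
        offsets = expand.grid(dy = -1:1, dx = -1:1))
      layers[[length(layers) + 1L]] <- cnn_init_layer(
        "bn", gamma = rep(1, f), beta = numeric(f),
        run_mean = numeric(f), run_var = rep(1, f), eps = 1e-5, momentum = 0.9)
      layers[[length(layers) + 1L]] <- cnn_init_layer("relu")
      layers[[length(layers) + 1L]] <- cnn_init_layer("pool", H = h, Wd = w)
      h <- h %/% 2L; w <- w %/% 2L
      cin <- f
    }
    n_feat <- h * w * cin
    layers[[length(layers) + 1L]] <- cnn_init_layer(
      "flatten", H = h, Wd = w, C = cin)
    layers[[length(layers) + 1L]] <- cnn_init_layer(
      "dense", W = matrix(stats::rnorm(n_feat * dense, sd = sqrt(2 / n_feat)),
                          n_feat, dense), b = numeric(dense))
    layers[[length(layers) + 1L]] <- cnn_init_layer("relu")
    layers[[length(layers) + 1L]] <- cnn_init_layer(
      "dense", W = matrix(stats::rnorm(dense * n_class, sd = sqrt(2 / dense)),
                          dense, n_class), b = numeric(n_class))
    layers
  })
}

cnn_forward <- function(layers, X, B, train = TRUE) {
  cache <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    if (L$type == "conv") {
      HW <- L$H * L$Wd
      Xp <- rbind(X, 0)
      Y <- matrix(0, B * HW, ncol(L$W[[1]]))
      rows_list <- vector("list", 9)
      for (o in 1:9) {
        g <- global_rows(conv_shift_map(L$H, L$Wd, L$offsets$dy[o], L$offsets$dx[o]),
                         B, HW)
        rows_list[[o]] <- g
        Y <- Y + Xp[g, , drop = FALSE] %*% L$W[[o]]
      }
      Y <- sweep(Y, 2, L$b, "+")
      cache[[li]] <- list(Xp = Xp, rows = rows_list)
      X <- Y
    } else if (L$type == "bn") {
      if (train) {
        mu <- colMeans(X)
        v <- colMeans(X^2) - mu^2
        layers[[li]]$run_mean <- L$momentum * L$run_mean + (1 - L$momentum) * mu
        layers[[li]]$run_var <- L$momentum * L$run_var + (1 - L$momentum) * v
      } else {
        mu <- L$run_mean; v <- L$run_var
      }
      xhat <- sweep(sweep(X, 2, mu), 2, sqrt(v + L$eps), "/")
      cache[[li]] <- list(xhat = xhat, v = v)
      X <- sweep(sweep(xhat, 2, L$gamma, "*"), 2, L$beta, "+")
    } else if (L$type == "relu") {
      cache[[li]] <- list(mask = X > 0)
      X <- X * cache[[li]]$mask
    } else if (L$type == "pool") {
      H2 <- L$H %/% 2L; W2 <- L$Wd %/% 2L
      HW <- L$H * L$Wd
      r <- rep(seq_len(H2), times = W2); c <- rep(seq_len(W2), each = H2)
      maps <- list(
        (2L * c - 2L) * L$H + 2L * r - 1L,
        (2L * c - 2L) * L$H + 2L * r,
        (2L * c - 1L) * L$H + 2L * r - 1L,
        (2L * c - 1L) * L$H + 2L * r)
      gmaps <- lapply(maps, function(m) global_rows(m, B, HW))
      M <- lapply(gmaps, function(g) X[g, , drop = FALSE])
      Y <- M[[1]]; arg <- matrix(1L, nrow(Y), ncol(Y))
      for (k in 2:4) {
        upd <- M[[k]] > Y
        Y[upd] <- M[[k]][upd]
        arg[upd] <- k
      }
      cache[[li]] <- list(gmaps = gmaps, arg = arg, n_in = nrow(X))
      X <- Y
    } else if (L$type == "flatten") {
      HW <- L$H * L$Wd
      A <- array(X, dim = c(HW, B, L$C))
      X <- t(matrix(aperm(A, c(1, 3, 2)), nrow = HW * L$C, ncol = B))
      cache[[li]] <- list(HW = HW, C = L$C)
    } else if (L$type == "dense") {
      cache[[li]] <- list(X = X)
      X <- sweep(X %*% L$W, 2, L$b, "+")
    }
  }
  list(out = X, cache = cache, layers = layers)
}

cnn_backward <- function(layers, cache, dY, B) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    L <- layers[[li]]
    if (L$type == "conv") {
      HW <- L$H * L$Wd
      dW <- vector("list", 9)
      Xp <- cache[[li]]$Xp
      dYp <- rbind(dY, 0)
      dXp <- matrix(0, B * HW, ncol(Xp))
      for (o in 1:9) {
        g <- cache[[li]]$rows[[o]]
        dW[[o]] <- t(Xp[g, , drop = FALSE]) %*% dY
        ## transpose of a zero-padded shift is the opposite shift
        gT <- global_rows(conv_shift_map(L$H, L$Wd, -L$offsets$dy[o],
                                         -L$offsets$dx[o]), B, HW)
        dXp <- dXp + dYp[gT, , drop = FALSE] %*% t(L$W[[o]])
      }
      grads[[li]] <- list(W = dW, b = colSums(dY))
      dY <- dXp
    } else if (L$type == "bn") {
      xhat <- cache[[li]]$xhat
      v <- cache[[li]]$v
      N <- nrow(xhat)
      dgamma <- colSums(dY * xhat)
      dbeta <- colSums(dY)
      dxhat <- sweep(dY, 2, L$gamma, "*")
      dX <- sweep(dxhat - matrix(colMeans(dxhat), N, ncol(dY), byrow = TRUE) -
                    sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
                  2, sqrt(v + L$eps), "/")
      grads[[li]] <- list(gamma = dgamma, beta = dbeta)
      dY <- dX
    } else if (L$type == "relu") {
      dY <- dY * cache[[li]]$mask
    } else if (L$type == "pool") {
      dX <- matrix(0, cache[[li]]$n_in, ncol(dY))
      for (k in 1:4) {
        mask <- cache[[li]]$arg == k
        g <- cache[[li]]$gmaps[[k]]
        ok <- g <= cache[[li]]$n_in
        dX[g[ok], ] <- dX[g[ok], , drop = FALSE] + (dY * mask)[ok, , drop = FALSE]
      }
      dY <- dX
    } else if (L$type == "flatten") {
      HW <- cache[[li]]$HW; C <- cache[[li]]$C
      A <- array(t(dY), dim = c(HW, C, B))
      dY <- matrix(aperm(A, c(1, 3, 2)), nrow = HW * B, ncol = C)
    } else if (L$type == "dense") {
      X <- cache[[li]]$X
      grads[[li]] <- list(W = t(X) %*% dY, b = colSums(dY))
      dY <- dY %*% t(L$W)
    }
  }
  grads
}

## Adam update over the nested parameter lists
cnn_adam <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (li in seq_along(layers)) {
    if (is.null(grads[[li]])) next
    for (nm in names(grads[[li]])) {
      g <- grads[[li]][[nm]]
      w <- layers[[li]][[nm]]
      key <- paste0(li, ".", nm)
      if (is.null(state[[key]])) {
        state[[key]] <- list(m = if (is.list(g)) lapply(g, function(x) x * 0) else g * 0,
                             v = if (is.list(g)) lapply(g, function(x) x * 0) else g * 0)
      }
      if (is.list(g)) {
        for (o in seq_along(g)) {
          r <- upd(w[[o]], g[[o]], state[[key]]$m[[o]], state[[key]]$v[[o]])
          w[[o]] <- r$w; state[[key]]$m[[o]] <- r$m; state[[key]]$v[[o]] <- r$v
        }
      } else {
        r <- upd(w, g, state[[key]]$m, state[[key]]$v)
        w <- r$w; state[[key]]$m <- r$m; state[[key]]$v <- r$v
      }
      layers[[li]][[nm]] <- w
    }
  }
  list(layers = layers, state = state)
}

## stack a list of H x W images into the (B*H*W) x 1 activation layout
cnn_stack <- function(images) {
  matrix(unlist(lapply(images, as.numeric), use.names = FALSE), ncol = 1)
}

cnn_predict_logits <- function(model, images, batch = 64L) {
  n <- length(images)
  out <- matrix(NA_real_, n, 2)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(n, s + batch - 1L)
    X <- (cnn_stack(images[idx]) - model$norm$mean) / model$norm$sd
    fw <- cnn_forward(model$layers, X, length(idx), train = FALSE)
    out[idx, ] <- fw$out
  }
  out
}

softmax_ce <- function(logits, y) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  loss <- -mean(log(pmax(p[cbind(seq_len(nrow(p)), y)], 1e-12)))
  dY <- p
  dY[cbind(seq_len(nrow(p)), y)] <- dY[cbind(seq_len(nrow(p)), y)] - 1
  list(loss = loss, dY = dY / nrow(p), p = p)
}

#' Train the convolutional distress classifier on mel-spectrogram images
#'
#' Architecture: three blocks of (3x3 'same' convolution, batch
#' normalization, ReLU, 2x2 max pooling) with 16/32/64 filters, one dense
#' layer of 64 units and a 2-way softmax output, trained with Adam on
#' cross-entropy. Inputs are standardized with the training set's global
#' mean and SD. Training stops early when the validation loss has not
#' improved for `patience` epochs; the best-validation weights are kept.
#'
#' @param images list of equally sized numeric matrices (mel spectrograms).
#' @param labels factor or character vector with levels `cry`/`distress`
#'   (any two classes work; the second level is the positive class).
#' @param split list with `train`/`validation` index vectors (see
#'   [make_split()]); when `NULL`, a seeded 80/20 split is drawn.
#' @param seed integer seed (weight init, shuffling, split).
#' @param epochs maximum training epochs.
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs).
#' @param filters convolution filter counts per block.
#' @param dense dense-layer width.
#' @param verbose print per-epoch losses?
#' @return object of class `cnn_model` with the trained layers, the input
#'   normalization, class levels, split and the per-epoch loss history.
#' @export
train_cnn <- function(images, labels, split = NULL, seed = 1L,
                      epochs = cs_default("cnn_epochs"),
                      batch = cs_default("cnn_batch"),
                      lr = cs_default("cnn_lr"),
                      patience = cs_default("cnn_patience"),
                      filters = cs_default("cnn_filters"),
                      dense = cs_default("cnn_dense"),
                      verbose = FALSE) {
  labels <- factor(labels)
  cs_assert(nlevels(labels) == 2, "need exactly two classes")
  cs_assert(length(images) == length(labels), "images/labels length mismatch")
  if (is.null(split)) split <- make_split(length(images), seed = seed)
  tr <- split$train; va <- split$validation
  cs_assert(nlevels(droplevels(labels[tr])) == 2,
            "single-class training set refused")
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  Xtr_flat <- cnn_stack(images[tr])
  norm <- list(mean = mean(Xtr_flat), sd = stats::sd(Xtr_flat))
  y <- as.integer(labels)

  layers <- cnn_init(H, W, filters, dense, seed = cs_subseed(seed, "init"))
  state <- list()
  best <- list(loss = Inf, layers = layers)
  history <- tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                            val_loss = numeric(0))
  t_adam <- 0
  wait <- 0
  for (ep in seq_len(epochs)) {
    ord <- with_seed(cs_subseed(seed, paste0("epoch", ep)), sample(tr))
    tl <- 0; nb <- 0
    for (s in seq(1L, length(ord), by = batch)) {
      idx <- ord[s:min(length(ord), s + batch - 1L)]
      if (length(idx) < 2) next
      X <- (cnn_stack(images[idx]) - norm$mean) / norm$sd
      fw <- cnn_forward(layers, X, length(idx), train = TRUE)
      layers <- fw$layers                  # running BN stats
      sm <- softmax_ce(fw$out, y[idx])
      grads <- cnn_backward(layers, fw$cache, sm$dY, length(idx))
      t_adam <- t_adam + 1
      au <- cnn_adam(layers, grads, state, lr, t_adam)
      layers <- au$layers; state <- au$state
      tl <- tl + sm$loss; nb <- nb + 1
    }
    model_tmp <- list(layers = layers, norm = norm)
    lv <- cnn_predict_logits(model_tmp, images[va])
    vl <- softmax_ce(lv, y[va])$loss
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = ep, train_loss = tl / max(nb, 1), val_loss = vl))
    if (verbose) message(sprintf("epoch %d: train %.4f val %.4f", ep, tl / nb, vl))
    if (vl < best$loss - 1e-5) {
      best <- list(loss = vl, layers = layers)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  structure(list(layers = best$layers, norm = norm, levels = levels(labels),
                 split = split, history = history, input_dim = c(H, W)),
            class = "cnn_model")
}

#' Predict classes with a trained convolutional model
#'
#' @param object a `cnn_model`.
#' @param newdata list of spectrogram matrices.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return factor of predicted classes, or a probability matrix.
#' @export
predict.cnn_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  logits <- cnn_predict_logits(object, newdata)
  z <- logits - apply(logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  factor(object$levels[max.col(p)], levels = object$levels)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model: %dx%d input, %d epochs trained, best val loss %.4f>\n",
              x$input_dim[1], x$input_dim[2], nrow(x$history),
              min(x$history$val_loss)))
  invisible(x)
}
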