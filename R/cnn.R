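#' Configuration of the desk-scale convolutional classifier
#'
#' The classifier is a small LeNet-style network: a stack of
#' `conv(k x k, ReLU) -> maxpool(p x p)` blocks (one per entry of
#' `conv_filters`), then flatten, a ReLU dense layer, and a two-unit softmax
#' head — five processing layers plus the two-class output in the default
#' configuration. Filter counts per layer are configuration, not constants.
#'
#' @param input_size `(H, W, channels)` of the network input; thermograms
#'   are resized to this shape by [preprocess_for_cnn()].
#' @param conv_filters integer vector, one filter count per conv block.
#' @param kernel_size convolution kernel side, pixels.
#' @param pool_size max-pooling window side (and stride), pixels.
#' @param dense_units units in the hidden dense layer.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed integer seed controlling weight initialization and batch
#'   shuffling.
#' @param split_fractions `(train, validation, test)` fractions, positive,
#'   summing to 1.
#' @param t_low,t_high temperature window (degC) mapped linearly onto
#'   `[0, 1]` when grids are converted to network input. A fixed window is
#'   used (rather than per-image min-max) because absolute temperature is
#'   itself diagnostic.
#' @return A list of class `"cnn_config"`.
#' @export
cnn_config <- function(input_size = c(32L, 32L, 1L),
                       conv_filters = c(16L, 16L),
                       kernel_size = 3L, pool_size = 2L,
                       dense_units = 32L, epochs = 10L, batch_size = 8L,
                       learning_rate = 3e-3, seed = 1L,
                       split_fractions = c(0.6, 0.2, 0.2),
                       t_low = 22, t_high = 40) {
  cfg <- list(input_size = as.integer(input_size),
              conv_filters = as.integer(conv_filters),
              kernel_size = as.integer(kernel_size),
              pool_size = as.integer(pool_size),
              dense_units = as.integer(dense_units),
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, seed = as.integer(seed),
              split_fractions = split_fractions,
              t_low = t_low, t_high = t_high)
  stopifnot(length(cfg$input_size) == 3L, all(cfg$input_size >= 1L),
            cfg$epochs >= 1L, cfg$batch_size >= 1L, cfg$kernel_size >= 1L,
            cfg$pool_size >= 1L, all(cfg$conv_filters >= 1L),
            cfg$t_low < cfg$t_high,
            length(cfg$split_fractions) == 3L, all(cfg$split_fractions > 0),
            abs(sum(cfg$split_fractions) - 1) < 1e-8)
  structure(cfg, class = "cnn_config")
}

# ---- index machinery -------------------------------------------------------
# Activations are stored as N x (h*w*c) matrices with linear cell index
# i + (j-1)*h + (ch-1)*h*w (row-major image, column-major storage).

conv_indices <- function(h, w, ch, k) {
  oh <- h - k + 1L; ow <- w - k + 1L
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  idx <- matrix(0L, oh * ow, k * k * ch)
  q <- 0L
  for (c0 in seq_len(ch)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    # column order must match patch index di + (dj-1)*k + (c0-1)*k*k
    q0 <- di + (dj - 1L) * k + (c0 - 1L) * k * k
    idx[, q0] <- (oi + di - 1L) + (oj + dj - 2L) * h + (c0 - 1L) * h * w
  }
  list(idx = idx, oh = oh, ow = ow)
}

pool_indices <- function(oh, ow, f, p) {
  ph <- oh %/% p; pw <- ow %/% p
  pi_ <- rep(seq_len(ph), times = pw * f)
  pj <- rep(rep(seq_len(pw), each = ph), times = f)
  ch <- rep(seq_len(f), each = ph * pw)
  idx <- matrix(0L, ph * pw * f, p * p)
  q <- 0L
  for (dj in seq_len(p)) for (di in seq_len(p)) {
    q <- q + 1L
    idx[, q] <- ((pi_ - 1L) * p + di) + ((pj - 1L) * p + dj - 1L) * oh +
      (ch - 1L) * oh * ow
  }
  list(idx = idx, ph = ph, pw = pw)
}

#' Build an untrained convolutional classifier
#'
#' Instantiates the architecture described in [cnn_config()] with
#' He-initialized weights drawn from `config$seed`.
#'
#' @param config a [cnn_config()].
#' @return An object of class `"cnn_model"`.
#' @export
cnn_build <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  h <- config$input_size[1]; w <- config$input_size[2]
  ch <- config$input_size[3]
  k <- config$kernel_size; p <- config$pool_size
  set.seed(config$seed)
  layers <- list()
  for (f in config$conv_filters) {
    if (h < k || w < k)
      stop("input too small for the configured conv/pool stack", call. = FALSE)
    ci <- conv_indices(h, w, ch, k)
    if (ci$oh < p || ci$ow < p)
      stop("input too small for the configured conv/pool stack", call. = FALSE)
    pi_ <- pool_indices(ci$oh, ci$ow, f, p)
    fan_in <- k * k * ch
    layers[[length(layers) + 1L]] <- list(
      W = matrix(stats::rnorm(fan_in * f, 0, sqrt(2 / fan_in)), fan_in, f),
      b = rep(0, f), conv = ci, pool = pi_, ch_in = ch,
      h_in = h, w_in = w)
    h <- pi_$ph; w <- pi_$pw; ch <- f
  }
  flat <- h * w * ch
  du <- config$dense_units
  model <- list(config = config, layers = layers, flat = flat,
                Wd = matrix(stats::rnorm(flat * du, 0, sqrt(2 / flat)), flat, du),
                bd = rep(0, du),
                Wo = matrix(stats::rnorm(du * 2, 0, sqrt(2 / du)), du, 2),
                bo = rep(0, 2),
                center = NULL,   # per-pixel training mean, set by cnn_train
                trained = FALSE, history = NULL)
  class(model) <- "cnn_model"
  model
}

#' Number of trainable parameters of a convolutional classifier
#' @param model a `cnn_model`.
#' @return Integer parameter count.
#' @export
cnn_n_params <- function(model) {
  n <- length(model$Wd) + length(model$bd) + length(model$Wo) + length(model$bo)
  for (l in model$layers) n <- n + length(l$W) + length(l$b)
  n
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cnn_model: input %dx%dx%d, conv %s (k=%d, pool=%d), dense %d, %d params, %s>\n",
              cfg$input_size[1], cfg$input_size[2], cfg$input_size[3],
              paste(cfg$conv_filters, collapse = "-"), cfg$kernel_size,
              cfg$pool_size, cfg$dense_units, cnn_n_params(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

cnn_forward <- function(model, X, keep_cache = FALSE) {
  N <- nrow(X)
  cache <- list(acts = list(), cols = list(), argcol = list())
  A <- X
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    ohow <- l$conv$oh * l$conv$ow
    kkc <- ncol(l$conv$idx)
    f <- length(l$b)
    Acols <- A[, as.vector(l$conv$idx), drop = FALSE]
    dim(Acols) <- c(N * ohow, kkc)
    Z <- Acols %*% l$W
    Z <- Z + rep(l$b, each = N * ohow)
    Z[Z < 0] <- 0
    dim(Z) <- c(N, ohow * f)
    # max pooling with argmax bookkeeping
    pidx <- l$pool$idx
    M2 <- nrow(pidx)
    best <- Z[, pidx[, 1L], drop = FALSE]
    arg <- matrix(1L, N, M2)
    for (q in seq_len(ncol(pidx))[-1L]) {
      Bq <- Z[, pidx[, q], drop = FALSE]
      upd <- Bq > best
      best[upd] <- Bq[upd]
      arg[upd] <- q
    }
    if (keep_cache) {
      cellmat <- rep(seq_len(M2), each = N)
      cache$cols[[li]] <- Acols
      cache$acts[[li]] <- Z
      cache$argcol[[li]] <- matrix(pidx[cbind(cellmat, as.vector(arg))], N, M2)
    }
    A <- best
  }
  F1 <- A %*% model$Wd
  F1 <- F1 + rep(model$bd, each = N)
  F1[F1 < 0] <- 0
  logits <- F1 %*% model$Wo
  logits <- logits + rep(model$bo, each = N)
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  probs <- cbind(e1, e2) / (e1 + e2)
  if (keep_cache) {
    cache$flat_in <- A
    cache$F1 <- F1
    cache$probs <- probs
  }
  list(probs = probs, cache = cache)
}

cnn_backward <- function(model, X, Y, fw) {
  N <- nrow(X); cache <- fw$cache
  grads <- list(layers = vector("list", length(model$layers)))
  dlog <- (fw$probs - Y) / N
  grads$Wo <- crossprod(cache$F1, dlog)
  grads$bo <- colSums(dlog)
  dF1 <- tcrossprod(dlog, model$Wo)
  dF1[cache$F1 <= 0] <- 0
  grads$Wd <- crossprod(cache$flat_in, dF1)
  grads$bd <- colSums(dF1)
  dA <- tcrossprod(dF1, model$Wd)
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    ohow <- l$conv$oh * l$conv$ow
    kkc <- ncol(l$conv$idx)
    f <- length(l$b)
    # through max pool: scatter into pre-pool activation (windows disjoint)
    dZ <- matrix(0, N, ohow * f)
    argcol <- cache$argcol[[li]]
    li_ <- (argcol - 1L) * N + seq_len(N)     # recycles down columns
    dZ[as.vector(li_)] <- as.vector(dA)
    # through ReLU
    dZ[cache$acts[[li]] <= 0] <- 0
    dim(dZ) <- c(N * ohow, f)
    grads$layers[[li]] <- list(W = crossprod(cache$cols[[li]], dZ),
                               b = colSums(dZ))
    if (li > 1L) {
      dAcols <- tcrossprod(dZ, l$W)           # (N*ohow) x kkc
      dA <- matrix(0, N, l$h_in * l$w_in * l$ch_in)
      dim(dAcols) <- c(N, ohow * kkc)
      for (q in seq_len(kkc)) {
        cols <- l$conv$idx[, q]
        dA[, cols] <- dA[, cols] +
          dAcols[, ((q - 1L) * ohow + 1L):(q * ohow), drop = FALSE]
      }
    }
  }
  grads
}

adam_init <- function(model) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  st <- list(t = 0,
             m = list(Wd = zero_like(model$Wd), bd = zero_like(model$bd),
                      Wo = zero_like(model$Wo), bo = zero_like(model$bo),
                      layers = lapply(model$layers, function(l)
                        list(W = zero_like(l$W), b = zero_like(l$b)))))
  st$v <- st$m
  st
}

adam_step <- function(model, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  corr1 <- 1 - beta1^st$t; corr2 <- 1 - beta2^st$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (nm in c("Wd", "bd", "Wo", "bo")) {
    u <- upd(model[[nm]], grads[[nm]], st$m[[nm]], st$v[[nm]])
    model[[nm]] <- u$p; st$m[[nm]] <- u$m; st$v[[nm]] <- u$v
  }
  for (li in seq_along(model$layers)) {
    for (nm in c("W", "b")) {
      u <- upd(model$layers[[li]][[nm]], grads$layers[[li]][[nm]],
               st$m$layers[[li]][[nm]], st$v$layers[[li]][[nm]])
      model$layers[[li]][[nm]] <- u$p
      st$m$layers[[li]][[nm]] <- u$m; st$v$layers[[li]][[nm]] <- u$v
    }
  }
  list(model = model, st = st)
}

ce_loss <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}

as_input_matrix <- function(x, config) {
  d <- config$input_size
  D <- prod(d)
  if (is.list(x)) {
    X <- t(vapply(x, function(img) {
      stopifnot(length(img) == D)
      as.vector(img)
    }, numeric(D)))
  } else if (is.array(x) && length(dim(x)) >= 2 && length(x) == D) {
    X <- matrix(as.vector(x), 1L, D)
  } else if (is.matrix(x) && ncol(x) == D) {
    X <- x
  } else {
    stop("input does not match the configured input size", call. = FALSE)
  }
  X
}

#' Convert a temperature grid to network input
#'
#' For a single-channel configuration the temperatures are mapped linearly
#' from the window `[t_low, t_high]` onto `[0, 1]` (clipped); for a
#' three-channel configuration the pseudocolor rendering is used. Masked
#' cells map to 0. The grid is resized to the configured input size by
#' nearest-neighbour sampling, whose index map has an exact inverse used
#' when explanation masks are carried back to grid coordinates.
#'
#' @param grid a [thermogram].
#' @param config a [cnn_config()].
#' @return An `H x W` matrix (1 channel) or `H x W x 3` array (3 channels)
#'   of values in `[0, 1]`.
#' @export
preprocess_for_cnn <- function(grid, config) {
  stopifnot(inherits(grid, "thermogram"), inherits(config, "cnn_config"))
  if (!any(grid$mask)) stop("empty grid", call. = FALSE)
  h <- config$input_size[1]; w <- config$input_size[2]
  if (config$input_size[3] == 1L) {
    u <- (grid$values - config$t_low) / (config$t_high - config$t_low)
    u <- pmin(pmax(u, 0), 1)
    u[!grid$mask] <- 0
    resize_nearest(u, h, w)
  } else {
    img <- render_pseudocolor(grid, config$t_low, config$t_high)
    out <- array(0, c(h, w, 3L))
    for (c0 in 1:3) out[, , c0] <- resize_nearest(img[, , c0], h, w)
    out
  }
}

#' Train the convolutional classifier
#'
#' Minimizes categorical cross-entropy with Adam, in shuffled mini-batches,
#' recording per-epoch training and validation loss/accuracy. Training is
#' deterministic given the configuration seed.
#'
#' @param model an untrained (or previously trained) `cnn_model`.
#' @param x training inputs: a list of image arrays, or an `N x D` matrix of
#'   flattened images.
#' @param y integer labels in `{0, 1}`.
#' @param validation optional `list(x =, y =)` held-out set.
#' @return The trained `cnn_model`, with `$history` (data.frame: epoch,
#'   loss, accuracy, val_loss, val_accuracy).
#' @export
cnn_train <- function(model, x, y, validation = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  X <- as_input_matrix(x, cfg)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  stopifnot(length(y) == nrow(X), all(y %in% 0:1))
  Y <- cbind(1 - y, y)
  # input normalization, part of the fitted model: (1) remove each image's
  # mean level, so the per-patient baseline body temperature is not a
  # nuisance and the network sees within-image contrast; (2) center on the
  # per-pixel training mean, which removes the large common component that
  # otherwise dominates early gradients
  X <- X - rowMeans(X)
  model$center <- colMeans(X)
  X <- sweep(X, 2, model$center)
  st <- adam_init(model)
  hist <- NULL
  eval_split <- function(X, Y) {
    fw <- cnn_forward(model, X)
    c(loss = ce_loss(fw$probs, Y),
      acc = mean((fw$probs[, 2] >= 0.5) == (Y[, 2] == 1)))
  }
  for (ep in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, ep, 3L))
    ord <- sample(nrow(X))
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      fw <- cnn_forward(model, Xb, keep_cache = TRUE)
      grads <- cnn_backward(model, Xb, Yb, fw)
      u <- adam_step(model, grads, st, cfg$learning_rate)
      model <- u$model; st <- u$st
    }
    tr <- eval_split(X, Y)
    va <- c(loss = NA_real_, acc = NA_real_)
    if (!is.null(validation)) {
      Xv <- as_input_matrix(validation$x, cfg)
      Xv <- sweep(Xv - rowMeans(Xv), 2, model$center)
      Yv <- cbind(1 - validation$y, validation$y)
      va <- eval_split(Xv, Yv)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tr["loss"],
                                   accuracy = tr["acc"], val_loss = va["loss"],
                                   val_accuracy = va["acc"],
                                   row.names = NULL))
  }
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Predict with the convolutional classifier
#'
#' @param model a trained `cnn_model`.
#' @param x a [thermogram] (preprocessed automatically), a single image
#'   array, a list of either, or an `N x D` matrix.
#' @return A data.frame with `probability_sick` (softmax positive-class
#'   output) and `label` (`1` iff `probability_sick >= 0.5`; the tie goes to
#'   the positive class).
#' @export
cnn_predict <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  if (!model$trained) stop("model has not been trained", call. = FALSE)
  if (inherits(x, "thermogram")) x <- preprocess_for_cnn(x, model$config)
  if (is.list(x) && length(x) && inherits(x[[1]], "thermogram"))
    x <- lapply(x, preprocess_for_cnn, config = model$config)
  X <- as_input_matrix(x, model$config)
  if (!is.null(model$center)) X <- sweep(X - rowMeans(X), 2, model$center)
  p <- cnn_forward(model, X)$probs[, 2]
  data.frame(probability_sick = p, label = as.integer(p >= 0.5))
}

#' Split indices into train/validation/test sets
#'
#' Stratified by label so each split keeps both classes where possible.
#'
#' @param y labels.
#' @param fractions `(train, validation, test)` positive fractions summing
#'   to 1.
#' @param seed integer seed.
#' @return A list of integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(y, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  set.seed(as.integer(seed))
  out <- list(train = integer(), validation = integer(), test = integer())
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    n <- length(idx)
    n_tr <- min(round(fractions[1] * n), n)
    n_va <- min(round(fractions[2] * n), n - n_tr)
    out$train <- c(out$train, idx[seq_len(n_tr)])
    out$validation <- c(out$validation,
                        idx[seq_len(n_va) + n_tr])
    out$test <- c(out$test, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  lapply(out, sort)
}
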