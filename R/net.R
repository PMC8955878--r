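#' Build a small temporal convolutional network
#'
#' One trunk, two possible heads. The trunk convolves along the time axis of
#' an `ns x channels` window (channels are input channels):
#' conv(24 filters, width 3, ReLU) -> max-pool(2) -> conv(12 filters, width
#' 3, ReLU) -> global average pool -> dense(24, ReLU). The exercise head is
#' a dense softmax layer over the six exercise classes; the anomaly head is
#' a single sigmoid unit scoring a window between 0 (anomaly) and 1
#' (correct exercising). Both heads share the trunk topology at equal `ns`,
#' so trunk weights are transferable between the two tasks (warm start).
#' The default net has ~2,100 parameters — small enough for microcontroller
#' deployment footprints.
#'
#' @param task `"exercise"` (6-way softmax) or `"anomaly"` (scalar sigmoid).
#' @param ns window length in samples, >= 10.
#' @param n_channels input channels (10 for the full glove; fewer under
#'   sensor ablation).
#' @param filters convolution filter counts for the two conv layers.
#' @param dense width of the dense trunk layer.
#' @param seed optional integer seed for weight initialization.
#' @return Object of class `glove_net` with untrained (He-initialized)
#'   weights.
#' @export
build_net <- function(task = c("exercise", "anomaly"), ns,
                      n_channels = 10L, filters = c(24L, 12L), dense = 24L,
                      seed = NULL) {
  task <- match.arg(task)
  if (ns < 10L) stop("ns must be >= 10", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  width <- 3L
  l1 <- ns - width + 1L
  l2 <- l1 %/% 2L
  l3 <- l2 - width + 1L
  if (l3 < 1L) stop("window too short for the trunk topology", call. = FALSE)
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  n_out <- if (task == "exercise") 6L else 1L
  params <- list(
    W1 = he(width * n_channels, filters[1L]), b1 = numeric(filters[1L]),
    W2 = he(width * filters[1L], filters[2L]), b2 = numeric(filters[2L]),
    W3 = he(filters[2L], dense), b3 = numeric(dense),
    W4 = he(dense, n_out), b4 = numeric(n_out))
  structure(
    list(task = task, ns = as.integer(ns), n_channels = as.integer(n_channels),
         width = width, filters = as.integer(filters), dense = as.integer(dense),
         dims = c(l1 = l1, l2 = l2, l3 = l3),
         labels = if (task == "exercise") exercise_labels() else NULL,
         params = params, scaler = NULL, trained = FALSE),
    class = "glove_net")
}

#' @export
print.glove_net <- function(x, ...) {
  cat(sprintf(
    "<glove_net> task %s | input %d x %d | conv(%d)-pool-conv(%d)-gap-dense(%d) | %d params | %s\n",
    x$task, x$ns, x$n_channels, x$filters[1L], x$filters[2L], x$dense,
    n_params(x), if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of trainable parameters
#' @param net a `glove_net`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  sum(vapply(net$params, length, integer(1L)))
}

# --- internal forward / backward machinery ---------------------------------
# Batches are 3-D arrays (batch, time, channel). Convolutions are computed
# as a single matrix product on an im2col layout: rows index (batch, time),
# columns index (tap, channel) with channel fastest.

im2col <- function(x, width) {
  d <- dim(x)                       # (B, L, C)
  lout <- d[2L] - width + 1L
  cols <- vector("list", width)
  for (j in seq_len(width)) {
    cols[[j]] <- matrix(x[, j:(j + lout - 1L), , drop = FALSE],
                        nrow = d[1L] * lout)
  }
  do.call(cbind, cols)              # (B*lout, width*C)
}

col2im <- function(dxc, d, width) { # inverse scatter-add of im2col
  lout <- d[2L] - width + 1L
  cc <- d[3L]
  dx <- array(0, dim = d)
  for (j in seq_len(width)) {
    block <- array(dxc[, ((j - 1L) * cc + 1L):(j * cc), drop = FALSE],
                   dim = c(d[1L], lout, cc))
    dx[, j:(j + lout - 1L), ] <- dx[, j:(j + lout - 1L), , drop = FALSE] + block
  }
  dx
}

net_forward <- function(net, x, training = FALSE) {
  p <- net$params
  b <- dim(x)[1L]
  w <- net$width
  l1 <- net$dims[["l1"]]; l2 <- net$dims[["l2"]]; l3 <- net$dims[["l3"]]
  f1 <- net$filters[1L]; f2 <- net$filters[2L]

  xc1 <- im2col(x, w)                                   # (B*l1, w*C)
  z1 <- sweep(xc1 %*% p$W1, 2L, p$b1, "+")
  a1 <- pmax(z1, 0)
  a1arr <- array(a1, dim = c(b, l1, f1))
  odd <- a1arr[, seq.int(1L, 2L * l2, by = 2L), , drop = FALSE]
  even <- a1arr[, seq.int(2L, 2L * l2, by = 2L), , drop = FALSE]
  pool <- pmax(odd, even)                               # (B, l2, f1)
  xc2 <- im2col(pool, w)                                # (B*l3, w*f1)
  z2 <- sweep(xc2 %*% p$W2, 2L, p$b2, "+")
  a2 <- pmax(z2, 0)
  a2arr <- array(a2, dim = c(b, l3, f2))
  gap <- colMeans(aperm(a2arr, c(2L, 1L, 3L)), dims = 1L) # (B, f2)
  if (!is.matrix(gap)) gap <- matrix(gap, nrow = b)
  z3 <- sweep(gap %*% p$W3, 2L, p$b3, "+")
  a3 <- pmax(z3, 0)
  z4 <- sweep(a3 %*% p$W4, 2L, p$b4, "+")
  out <- if (net$task == "exercise") {
    e <- exp(z4 - apply(z4, 1L, max))
    e / rowSums(e)
  } else {
    1 / (1 + exp(-z4))
  }
  if (!training) return(out)
  list(out = out, x = x, xc1 = xc1, z1 = z1, a1arr = a1arr,
       odd = odd, even = even, pool = pool, xc2 = xc2, z2 = z2,
       gap = gap, z3 = z3, a3 = a3)
}

# gradient of the loss w.r.t. all parameters; dz4 = (prob - target) / B
net_backward <- function(net, cache, dz4) {
  p <- net$params
  b <- dim(cache$x)[1L]
  w <- net$width
  l1 <- net$dims[["l1"]]; l2 <- net$dims[["l2"]]; l3 <- net$dims[["l3"]]
  f1 <- net$filters[1L]; f2 <- net$filters[2L]

  gW4 <- crossprod(cache$a3, dz4); gb4 <- colSums(dz4)
  da3 <- dz4 %*% t(p$W4)
  dz3 <- da3 * (cache$z3 > 0)
  gW3 <- crossprod(cache$gap, dz3); gb3 <- colSums(dz3)
  dgap <- dz3 %*% t(p$W3)                                # (B, f2)
  # GAP spread: each time position receives dgap / l3
  da2arr <- aperm(array(dgap / l3, dim = c(b, f2, l3)), c(1L, 3L, 2L))
  dz2 <- matrix(da2arr, nrow = b * l3) * (cache$z2 > 0)
  gW2 <- crossprod(cache$xc2, dz2); gb2 <- colSums(dz2)
  dxc2 <- dz2 %*% t(p$W2)
  dpool <- col2im(dxc2, c(b, l2, f1), w)                 # (B, l2, f1)
  sel <- cache$odd >= cache$even                          # ties to first
  da1arr <- array(0, dim = c(b, l1, f1))
  da1arr[, seq.int(1L, 2L * l2, by = 2L), ] <- dpool * sel
  da1arr[, seq.int(2L, 2L * l2, by = 2L), ] <- dpool * !sel
  dz1 <- matrix(da1arr, nrow = b * l1) * (cache$z1 > 0)
  gW1 <- crossprod(cache$xc1, dz1); gb1 <- colSums(dz1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration for the convolutional networks
#'
#' Adam with learning rate 0.001; categorical cross-entropy for the 6-way
#' exercise task, binary cross-entropy for the anomaly task. Epoch and
#' batch-size defaults are package choices.
#'
#' @param epochs passes over `steps_per_epoch` sampled batches.
#' @param batch_size windows per batch.
#' @param steps_per_epoch batches drawn per epoch.
#' @param learning_rate Adam step size.
#' @param seed master seed for batch sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 12L, batch_size = 64L,
                         steps_per_epoch = 60L, learning_rate = 0.001,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a convolutional network on session files
#'
#' Each training batch is constructed by repeatedly sampling a file
#' uniformly from the training set and a uniform random valid start index
#' within it, then slicing an `ns`-long window — matching the file-level
#' training protocol (windows never span file boundaries, and test files
#' never enter training). The scaler must have been fitted on the training
#' files only. For the anomaly task the trunk can be warm-started from a
#' trained exercise net.
#'
#' @param net a `glove_net` from [build_net()].
#' @param train_files list of entries, each `list(id =, features =, label =)`
#'   where `features` is an unscaled feature matrix and `label` is an
#'   exercise name (exercise task) or 1 correct / 0 anomaly (anomaly task).
#' @param config a [train_config()].
#' @param scaler `scaler_params` fitted on these training files.
#' @param init_from optional trained `glove_net` whose trunk weights
#'   initialize this one.
#' @param forbid optional character vector of file ids that must not appear
#'   in `train_files` (leakage guard); any overlap is an error.
#' @return The trained `glove_net`, with the scaler attached and an
#'   attribute `loss_trace` (mean batch loss per epoch).
#' @export
train_net <- function(net, train_files, config = train_config(),
                      scaler = NULL, init_from = NULL, forbid = NULL) {
  stopifnot(inherits(net, "glove_net"))
  ids <- vapply(train_files, function(f) as.character(f$id), character(1L))
  if (!is.null(forbid) && length(intersect(ids, forbid))) {
    stop("leakage: test files present in the training set: ",
         paste(intersect(ids, forbid), collapse = ", "), call. = FALSE)
  }
  if (is.null(scaler)) {
    scaler <- fit_scaler(do.call(rbind, lapply(train_files, `[[`, "features")))
  }
  if (!is.null(init_from)) {
    stopifnot(inherits(init_from, "glove_net"),
              init_from$ns == net$ns,
              init_from$n_channels == net$n_channels)
    for (k in c("W1", "b1", "W2", "b2", "W3", "b3")) {
      net$params[[k]] <- init_from$params[[k]]
    }
  }
  ns <- net$ns
  feats <- lapply(train_files, function(f) apply_scaler(f$features, scaler))
  lens <- vapply(feats, nrow, integer(1L))
  usable <- which(lens >= ns)
  if (!length(usable)) stop("no training file long enough for ns", call. = FALSE)
  labels <- lapply(train_files, `[[`, "label")
  if (net$task == "exercise") {
    targets <- vapply(labels, function(l) match(l, exercise_labels()),
                      integer(1L))
    if (anyNA(targets)) stop("unknown exercise label in training set",
                             call. = FALSE)
  } else {
    targets <- vapply(labels, function(l) as.numeric(l), numeric(1L))
    if (any(!targets %in% c(0, 1))) {
      stop("anomaly labels must be 0 (anomaly) or 1 (correct)", call. = FALSE)
    }
  }
  set.seed(config$seed)
  opt <- adam_init(net$params)
  bsz <- config$batch_size
  k <- net$n_channels
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    losses <- numeric(config$steps_per_epoch)
    for (step in seq_len(config$steps_per_epoch)) {
      fi <- usable[sample.int(length(usable), bsz, replace = TRUE)]
      x <- array(0, dim = c(bsz, ns, k))
      for (b in seq_len(bsz)) {
        f <- feats[[fi[b]]]
        st <- sample.int(nrow(f) - ns + 1L, 1L)
        x[b, , ] <- f[st:(st + ns - 1L), ]
      }
      fwd <- net_forward(net, x, training = TRUE)
      if (net$task == "exercise") {
        y <- matrix(0, bsz, 6L)
        y[cbind(seq_len(bsz), targets[fi])] <- 1
        losses[step] <- -mean(log(pmax(fwd$out[y == 1], 1e-12)))
      } else {
        y <- matrix(targets[fi], ncol = 1L)
        pr <- pmin(pmax(fwd$out, 1e-12), 1 - 1e-12)
        losses[step] <- -mean(y * log(pr) + (1 - y) * log(1 - pr))
      }
      dz4 <- (fwd$out - y) / bsz
      grads <- net_backward(net, fwd, dz4)
      upd <- adam_step(net$params, grads, opt, config$learning_rate)
      net$params <- upd$params
      opt <- upd$state
    }
    trace[ep] <- mean(losses)
  }
  net$scaler <- scaler
  net$trained <- TRUE
  attr(net, "loss_trace") <- trace
  net
}

check_window_shape <- function(net, m) {
  if (is.matrix(m)) {
    if (!identical(dim(m), c(net$ns, net$n_channels))) {
      stop(sprintf("window shape %d x %d does not match net input %d x %d",
                   nrow(m), ncol(m), net$ns, net$n_channels), call. = FALSE)
    }
    return(array(m, dim = c(1L, net$ns, net$n_channels)))
  }
  d <- dim(m)
  if (length(d) != 3L || d[2L] != net$ns || d[3L] != net$n_channels) {
    stop("window array does not match net input shape", call. = FALSE)
  }
  m
}

#' Class probabilities for scaled windows
#'
#' @param model a trained (or at least built) exercise `glove_net`.
#' @param m_scaled one scaled window matrix (`ns x channels`) or a 3-D batch
#'   array; scale with the model's own scaler.
#' @param chunk internal batch size for large inputs.
#' @return Probability matrix (`windows x 6`), columns in
#'   [exercise_labels()] order, rows summing to 1. The argmax column is the
#'   predicted exercise.
#' @export
predict_exercise <- function(model, m_scaled, chunk = 4096L) {
  stopifnot(model$task == "exercise")
  x <- check_window_shape(model, m_scaled)
  out <- net_predict_chunked(model, x, chunk)
  colnames(out) <- exercise_labels()
  out
}

#' Anomaly score for scaled windows
#'
#' @param model a trained anomaly `glove_net`.
#' @param m_scaled scaled window matrix or 3-D batch array.
#' @param chunk internal batch size.
#' @return Numeric vector of scores in `[0, 1]`; 1 means correct exercising.
#' @export
predict_anomaly <- function(model, m_scaled, chunk = 4096L) {
  stopifnot(model$task == "anomaly")
  x <- check_window_shape(model, m_scaled)
  as.numeric(net_predict_chunked(model, x, chunk))
}

net_predict_chunked <- function(net, x, chunk) {
  n <- dim(x)[1L]
  if (n <= chunk) return(net_forward(net, x, training = FALSE))
  pieces <- lapply(split(seq_len(n), ceiling(seq_len(n) / chunk)),
                   function(ix) {
                     net_forward(net, x[ix, , , drop = FALSE],
                                 training = FALSE)
                   })
  do.call(rbind, pieces)
}

#' Binarize an anomaly score
#'
#' Scores at or above the threshold count as correct exercising (ties go to
#' correct).
#'
#' @param score numeric scores in `[0, 1]`.
#' @param threshold decision threshold, default 0.5.
#' @return Integer vector of 0 (anomaly) / 1 (correct).
#' @export
binarize_anomaly <- function(score, threshold = 0.5) {
  as.integer(score >= threshold)
}
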