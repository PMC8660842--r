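# Minimal feed-forward network plug-in. Implements the fixed deep-MLP
# architecture used for the spectrum-class task: four hidden layers
# (250, 250, 8, 4 neurons, ReLU) and a one-neuron sigmoid output, trained
# with Adam on binary cross-entropy, mini-batches of 36, learning rate
# 0.001 with decay 1e-6, 100 epochs, random-normal initialization.

#' MLP configuration
#'
#' Echoes the fixed architecture and optimizer settings.
#'
#' @param hidden hidden-layer widths.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr learning rate.
#' @param decay per-step learning-rate decay.
#' @param seed integer seed.
#' @return an mlpConfig list.
#' @export
mlpConfig <- function(hidden = c(250L, 250L, 8L, 4L), epochs = 100L,
                      batch_size = 36L, lr = 0.001, decay = 1e-6,
                      seed = 1L) {
  structure(list(hidden = as.integer(hidden), output = 1L,
                 activations = c(rep("relu", length(hidden)), "sigmoid"),
                 loss = "binary_crossentropy", optimizer = "adam",
                 initializer = "random_normal",
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, decay = decay, seed = as.integer(seed)),
            class = "mlpConfig")
}

.mlpForward <- function(net, X) {
  a <- X
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}

#' Train the feed-forward network plug-in
#'
#' @param X features; rows = molecules.
#' @param y POS/NEG labels.
#' @param cfg an \code{\link{mlpConfig}}.
#' @return a \linkS4class{SpectrumModel} with algorithm "mlp"; the
#'   predicted class is POS when the sigmoid output is at least 0.5.
#' @export
trainMLP <- function(X, y, cfg = mlpConfig()) {
  inp <- .featureInput(X)
  y <- .asLabelFactor(y)
  stopifnot(length(y) == nrow(inp$vals))
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class")
  Xm <- inp$vals
  storage.mode(Xm) <- "double"
  t01 <- as.numeric(y == "POS")
  sizes <- c(ncol(Xm), cfg$hidden, cfg$output)
  L <- length(sizes) - 1L
  set.seed(cfg$seed)
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = 0.05),
           sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(Xm)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- Xm[idx, , drop = FALSE]
      tb <- t01[idx]
      # forward pass, caching activations
      act <- vector("list", L + 1L); act[[1]] <- xb
      for (l in seq_len(L)) {
        z <- sweep(act[[l]] %*% W[[l]], 2, b[[l]], "+")
        act[[l + 1]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
      }
      # backward pass; sigmoid + BCE gives (out - t) at the output
      delta <- (act[[L + 1]] - tb) / length(idx)
      step <- step + 1L
      lr_t <- cfg$lr / (1 + cfg$decay * step)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(act[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * (act[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr_t * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr_t * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  net <- list(W = W, b = b)
  imp <- matrix(numeric(0), 0, 0)
  new("SpectrumModel", algorithm = "mlp", fit = net,
      config = unclass(cfg), featureNames = colnames(inp$vals),
      provenance = inp$prov, oobAccuracy = NA_real_, importances = imp,
      seed = cfg$seed)
}
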