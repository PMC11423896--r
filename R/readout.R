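#' Sparse readout configuration
#'
#' Hyperparameters of the L1-regularized multinomial linear readout trained
#' on frozen features: plain minibatch SGD on the cross-entropy loss with a
#' proximal (soft-thresholding) L1 step and a one-cycle learning-rate
#' schedule (cosine ramp from `initial_lr` to `max_lr` over the first
#' `pct_start` fraction of steps, then cosine anneal down to
#' `initial_lr/100`).
#'
#' @param l1_lambda L1 penalty weight (>= 0); reference value 1e-5.
#' @param epochs training epochs (reference 10).
#' @param batch_size minibatch size (reference 512; capped at n).
#' @param max_lr,initial_lr,pct_start one-cycle schedule (reference 0.05,
#'   0.001, 0.3).
#' @param k top-k used for accuracy downstream (reference 5; desk-scale
#'   worlds use 1-2).
#' @param seed integer seed for init and shuffling.
#' @return list of class `readout_config`.
#' @export
readout_config <- function(l1_lambda = 1e-5, epochs = 10L, batch_size = 512L,
                           max_lr = 0.05, initial_lr = 0.001, pct_start = 0.3,
                           k = 1L, seed = 1L) {
  if (l1_lambda < 0) stop("l1_lambda must be >= 0")
  if (pct_start <= 0 || pct_start >= 1) stop("pct_start must be in (0, 1)")
  if (k < 1) stop("k must be >= 1")
  structure(list(l1_lambda = l1_lambda, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), max_lr = max_lr,
                 initial_lr = initial_lr, pct_start = pct_start,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "readout_config")
}

onecycle_lr <- function(step, total, max_lr, initial_lr, pct_start) {
  up <- max(1, floor(total * pct_start))
  final_lr <- initial_lr / 100
  if (step <= up) {
    frac <- step / up
    initial_lr + (max_lr - initial_lr) * (1 - cos(pi * frac)) / 2
  } else {
    frac <- (step - up) / max(1, total - up)
    final_lr + (max_lr - final_lr) * (1 + cos(pi * frac)) / 2
  }
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Train a sparse linear readout on frozen features
#'
#' Minimizes cross-entropy + lambda * sum|w| by proximal SGD under the
#' one-cycle schedule; the backbone producing `features` is untouched.
#' Weight sparsity (fraction with |w| < 0.001) is recorded in the training
#' log.
#'
#' @param features stimulus x unit matrix (typically the penultimate
#'   post-rectification stage).
#' @param labels category label per stimulus (>= 2 categories, each with
#'   >= 2 stimuli).
#' @param config a [readout_config()].
#' @return object of class `readout_head`: `weights` (category x feature),
#'   `bias`, `levels`, and a per-epoch `log`.
#' @export
train_sparse_readout <- function(features, labels, config) {
  stopifnot(inherits(config, "readout_config"))
  stopifnot_finite(features, "readout features")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 categories")
  if (any(table(labels) < 2)) stop("each category needs >= 2 training stimuli")
  n <- nrow(features); p <- ncol(features); K <- nlevels(labels)
  y <- as.integer(labels)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  B <- min(config$batch_size, n)
  steps_per_epoch <- ceiling(n / B)
  total <- steps_per_epoch * config$epochs
  lam <- config$l1_lambda

  with_seed(config$seed, {
    W <- matrix(stats::rnorm(K * p, sd = 0.01), K, p)
    b <- numeric(K)
    log <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0),
                      sparsity = numeric(0))
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (s in seq_len(steps_per_epoch)) {
        step <- step + 1L
        ix <- ord[((s - 1L) * B + 1L):min(s * B, n)]
        Xb <- features[ix, , drop = FALSE]
        Sc <- Xb %*% t(W) + matrix(b, length(ix), K, byrow = TRUE)
        P <- softmax_rows(Sc)
        lr <- onecycle_lr(step, total, config$max_lr, config$initial_lr,
                          config$pct_start)
        G <- (P - Y[ix, , drop = FALSE]) / length(ix)
        W <- W - lr * (t(G) %*% Xb)
        b <- b - lr * colSums(G)
        if (lam > 0) W <- sign(W) * pmax(abs(W) - lr * lam, 0)
        ep_loss <- ep_loss - sum(log(pmax(P[cbind(seq_along(ix), y[ix])], 1e-12)))
      }
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n, lr = lr,
                                   sparsity = mean(abs(W) < 0.001)))
    }
    structure(list(weights = W, bias = b, levels = levels(labels),
                   config = config, log = log),
              class = "readout_head")
  })
}

#' @export
print.readout_head <- function(x, ...) {
  cat(sprintf("<readout_head> %d categories x %d features; final loss %.4f, sparsity %.1f%%\n",
              nrow(x$weights), ncol(x$weights),
              utils::tail(x$log$loss, 1), 100 * utils::tail(x$log$sparsity, 1)))
  invisible(x)
}

#' Weight sparsity of a readout head
#' @param head a `readout_head`.
#' @param tol magnitude threshold counted as zero (default 0.001).
#' @return fraction of weights with |w| < tol.
#' @export
readout_sparsity <- function(head, tol = 0.001) mean(abs(head$weights) < tol)

#' Per-category top-k accuracy of a readout
#'
#' Fraction of each category's stimuli whose true label is among the k
#' highest-scoring categories; score ties are broken deterministically by
#' ascending category index.
#'
#' @param head a `readout_head`.
#' @param features stimulus x unit matrix.
#' @param labels true labels.
#' @param k top-k (must be <= number of categories).
#' @return named per-category accuracy vector (fractions in `[0, 1]`).
#' @export
topk_accuracy_per_category <- function(head, features, labels, k) {
  K <- nrow(head$weights)
  if (k > K) stop("k exceeds the number of categories")
  labels <- factor(labels, levels = head$levels)
  if (anyNA(labels)) stop("labels outside the readout's categories")
  S <- features %*% t(head$weights) + matrix(head$bias, nrow(features), K, byrow = TRUE)
  hit <- vapply(seq_len(nrow(S)), function(i) {
    topk <- order(-S[i, ], seq_len(K))[seq_len(k)]
    as.integer(labels[i]) %in% topk
  }, logical(1))
  acc <- tapply(hit, labels, mean)[head$levels]
  stats::setNames(as.numeric(acc), head$levels)
}
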