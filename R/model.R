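## Feedforward classifier: input -> four 256-unit ReLU hidden layers ->
## 2-unit softmax, trained by mini-batch ADAM on cross-entropy with L2
## regularization over all weights and biases,
##
##   H = -(1/n) sum_i log y_{i, class(i)}  +  lambda * sum (w^2 + theta^2),
##
## with early stopping on validation accuracy. The linear variant drops all
## hidden layers (input -> 2-unit softmax) and exposes a per-amino-acid
## weight map for interpretation.

#' Training configuration
#'
#' Defaults follow the grid-searched settings for 7-residue triads:
#' regularization 2.5e-6, starting learning rate 6e-4, mini-batch 128.
#'
#' @param lambda L2 coefficient (>= 0), applied to all weights and biases.
#' @param learning_rate ADAM starting learning rate.
#' @param batch_size Mini-batch size; default 128.
#' @param eval_every Batches between validation checkpoints ("iterations"
#'   in the training history).
#' @param patience Checkpoints without validation-accuracy improvement
#'   before training stops.
#' @param tol Minimum accuracy improvement that counts; default 1e-4.
#' @param max_checkpoints Hard cap on checkpoints.
#' @param hidden Hidden layer widths; default `c(256, 256, 256, 256)`. Use
#'   `integer(0)` for the linear model.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return List of class `train_config`.
#' @export
train_config <- function(lambda = 2.5e-6, learning_rate = 6e-4,
                         batch_size = 128L, eval_every = 50L,
                         patience = 20L, tol = 1e-4,
                         max_checkpoints = 200L,
                         hidden = c(256L, 256L, 256L, 256L), seed = 1L) {
  abort_if(lambda < 0, "lambda must be >= 0")
  abort_if(learning_rate <= 0, "learning_rate must be > 0")
  abort_if(batch_size < 1, "batch_size must be >= 1")
  structure(list(lambda = lambda, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience), tol = tol,
                 max_checkpoints = as.integer(max_checkpoints),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize network parameters
#'
#' Weights are drawn from a fan-in-scaled uniform distribution
#' U(-1/sqrt(fan_in), 1/sqrt(fan_in)); biases start at zero.
#'
#' @param input_size Input vector length (arity * L * 20).
#' @param hidden Hidden layer widths (empty for the linear model).
#' @param output_size Number of classes; default 2.
#' @param seed Integer RNG seed.
#' @return List of class `mlp_params` with `weights` (list of matrices,
#'   previous-layer x next-layer) and `biases` (list of vectors).
#' @export
mlp_init <- function(input_size, hidden = c(256L, 256L, 256L, 256L),
                     output_size = 2L, seed = 1L) {
  sizes <- c(input_size, hidden, output_size)
  with_seed(seed, {
    weights <- biases <- vector("list", length(sizes) - 1L)
    for (l in seq_along(weights)) {
      lim <- 1 / sqrt(sizes[l])
      weights[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L],
                                          -lim, lim),
                             sizes[l], sizes[l + 1L])
      biases[[l]] <- numeric(sizes[l + 1L])
    }
    structure(list(weights = weights, biases = biases, sizes = sizes),
              class = "mlp_params")
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## forward pass keeping every post-activation (a[[1]] = input,
## a[[L+1]] = softmax output)
mlp_forward_full <- function(params, x) {
  nl <- length(params$weights)
  a <- vector("list", nl + 1L)
  a[[1L]] <- x
  for (l in seq_len(nl)) {
    z <- a[[l]] %*% params$weights[[l]] +
      rep(params$biases[[l]], each = nrow(x))
    a[[l + 1L]] <- if (l < nl) pmax(z, 0) else softmax_rows(z)
  }
  a
}

#' Forward pass: class probabilities
#'
#' Each hidden layer applies an affine map followed by ReLU; the output
#' layer applies an affine map followed by softmax.
#'
#' @param params `mlp_params`.
#' @param x Input matrix (samples x input_size) or a single vector.
#' @return Matrix (samples x 2) of class probabilities; column 1 is
#'   non-binding (label 0), column 2 binding (label 1). Rows sum to 1.
#' @export
mlp_forward <- function(params, x) {
  stopifnot(inherits(params, "mlp_params"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  abort_if(ncol(x) != params$sizes[1L],
           "input has %d columns, network expects %d", ncol(x),
           params$sizes[1L])
  p <- mlp_forward_full(params, x)[[length(params$weights) + 1L]]
  colnames(p) <- c("nonbinding", "binding")
  p
}

#' Training loss: cross-entropy plus L2 penalty
#'
#' Mean negative log predicted probability of the true class, plus
#' `lambda` times the sum of squared weights and biases.
#'
#' @param params `mlp_params`.
#' @param x Input matrix.
#' @param y Integer labels (0/1).
#' @param lambda L2 coefficient (>= 0).
#' @return Non-negative scalar.
#' @export
mlp_loss <- function(params, x, y, lambda = 0) {
  abort_if(lambda < 0, "lambda must be >= 0")
  abort_if(length(y) == 0L, "empty batch")
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  p <- mlp_forward(params, x)
  nll <- -mean(log(pmax(p[cbind(seq_along(y), y + 1L)],
                        .Machine$double.xmin)))
  nll + lambda * (sum(vapply(params$weights, function(w) sum(w^2), 0)) +
                    sum(vapply(params$biases, function(b) sum(b^2), 0)))
}

## backprop: returns gradients (same shapes as params) and the batch loss
mlp_gradients <- function(params, x, y, lambda = 0) {
  n <- nrow(x)
  nl <- length(params$weights)
  a <- mlp_forward_full(params, x)
  p <- a[[nl + 1L]]
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y + 1L)],
                         .Machine$double.xmin))) +
    lambda * (sum(vapply(params$weights, function(w) sum(w^2), 0)) +
                sum(vapply(params$biases, function(b) sum(b^2), 0)))
  yhot <- matrix(0, n, ncol(p))
  yhot[cbind(seq_len(n), y + 1L)] <- 1
  dz <- (p - yhot) / n
  gw <- gb <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    gw[[l]] <- crossprod(a[[l]], dz) + 2 * lambda * params$weights[[l]]
    gb[[l]] <- colSums(dz) + 2 * lambda * params$biases[[l]]
    if (l > 1L) dz <- (dz %*% t(params$weights[[l]])) * (a[[l]] > 0)
  }
  list(weights = gw, biases = gb, loss = loss)
}

#' Train the feedforward classifier
#'
#' Mini-batch gradient descent with ADAM (beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8) on the cross-entropy + L2 loss. Every `cfg$eval_every`
#' batches a checkpoint records the mean training-batch loss and the
#' validation accuracy; training stops when the validation accuracy has
#' not improved by more than `cfg$tol` for `cfg$patience` consecutive
#' checkpoints (or at `cfg$max_checkpoints`), and the parameters with the
#' best validation accuracy are returned.
#'
#' @param split A `split_dataset` (see [split_dataset()]), or any list with
#'   `train` and `validation` encoded datasets.
#' @param cfg A [train_config()].
#' @return List of class `mlp_fit`: `params` (best-on-validation
#'   `mlp_params`), `history` (data.frame: `iteration`, `train_loss`,
#'   `val_accuracy`), `best` (checkpoint index and accuracy), `config`.
#' @export
mlp_train <- function(split, cfg = train_config()) {
  xtr <- split$train$x; ytr <- split$train$y
  xva <- split$validation$x; yva <- split$validation$y
  abort_if(length(ytr) == 0L || length(yva) == 0L,
           "train and validation sets must be non-empty")
  storage.mode(xtr) <- "double"
  storage.mode(xva) <- "double"
  params <- mlp_init(ncol(xtr), hidden = cfg$hidden, seed = cfg$seed)
  nl <- length(params$weights)
  m <- v <- list(weights = lapply(params$weights, function(w) w * 0),
                 biases = lapply(params$biases, function(b) b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(xtr)
  history <- list()
  best_acc <- -Inf; best_params <- params; best_iter <- 0L
  wait <- 0L; ckpt <- 0L; done <- FALSE
  loss_acc <- 0; loss_k <- 0L

  with_seed(cfg$seed + 1L, {
    while (!done) {
      perm <- sample.int(n)
      nb <- max(1L, n %/% cfg$batch_size)
      for (bi in seq_len(nb)) {
        rows <- perm[((bi - 1L) * cfg$batch_size + 1L):
                       min(bi * cfg$batch_size, n)]
        g <- mlp_gradients(params, xtr[rows, , drop = FALSE], ytr[rows],
                           cfg$lambda)
        abort_if(!is.finite(g$loss),
                 "training diverged (non-finite loss) at batch %d", step + 1L)
        loss_acc <- loss_acc + g$loss; loss_k <- loss_k + 1L
        step <- step + 1L
        c1 <- 1 - b1^step; c2 <- 1 - b2^step
        for (part in c("weights", "biases")) {
          for (l in seq_len(nl)) {
            gr <- g[[part]][[l]]
            m[[part]][[l]] <- b1 * m[[part]][[l]] + (1 - b1) * gr
            v[[part]][[l]] <- b2 * v[[part]][[l]] + (1 - b2) * gr^2
            params[[part]][[l]] <- params[[part]][[l]] -
              cfg$learning_rate * (m[[part]][[l]] / c1) /
              (sqrt(v[[part]][[l]] / c2) + eps)
          }
        }
        if (step %% cfg$eval_every == 0L) {
          ckpt <- ckpt + 1L
          acc <- mean((mlp_forward(params, xva)[, 2L] > 0.5) == yva)
          history[[ckpt]] <- c(iteration = ckpt,
                               train_loss = loss_acc / loss_k,
                               val_accuracy = acc)
          loss_acc <- 0; loss_k <- 0L
          if (acc > best_acc + cfg$tol) {
            best_acc <- acc; best_params <- params; best_iter <- ckpt
            wait <- 0L
          } else {
            wait <- wait + 1L
          }
          if (wait >= cfg$patience || ckpt >= cfg$max_checkpoints) {
            done <- TRUE
            break
          }
        }
      }
    }
  })
  history <- as.data.frame(do.call(rbind, history))
  structure(list(params = best_params, history = history,
                 best = list(iteration = best_iter,
                             val_accuracy = best_acc),
                 config = cfg),
            class = "mlp_fit")
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("mlp_fit: layers %s, %d checkpoints, best val accuracy %.4f (ckpt %d)\n",
              paste(x$params$sizes, collapse = "-"), nrow(x$history),
              x$best$val_accuracy, x$best$iteration))
  invisible(x)
}

#' Predict binding probabilities
#'
#' @param object An `mlp_fit`.
#' @param x Input matrix or `encoded_dataset`.
#' @param ... Unused.
#' @return Numeric vector of binding probabilities (softmax output for
#'   label 1).
#' @export
predict.mlp_fit <- function(object, x, ...) {
  if (inherits(x, "encoded_dataset")) x <- x$x
  mlp_forward(object$params, x)[, 2L]
}

#' Train the linear (no-hidden-layer) model
#'
#' Identical training protocol with architecture input -> 2-unit softmax:
#' multinomial logistic regression. The binding decision is then a linear
#' combination of per-position, per-amino-acid contributions, which is what
#' makes the weight map of [linear_weight_map()] interpretable — and what
#' the full network's margin over this model measures (nonlinearity of the
#' binding signal).
#'
#' @param split A `split_dataset`.
#' @param cfg A [train_config()]; its `hidden` field is ignored.
#' @return An `mlp_fit` whose params have a single weight matrix
#'   (input_size x 2).
#' @export
train_linear <- function(split, cfg = train_config()) {
  cfg$hidden <- integer(0)
  mlp_train(split, cfg)
}

#' Per-amino-acid weight map of the linear model
#'
#' For each amino-acid type and each output class, sums the connection
#' weights of that amino acid's input node over all `arity * L` sequence
#' positions; the resulting 20 x 2 table roughly represents each amino
#' acid's contribution toward binding (positive favors the class).
#'
#' @param params Linear `mlp_params` (no hidden layers).
#' @param arity Fragments per tuple.
#' @param length Fragment length L.
#' @return 20 x 2 numeric matrix, rows named by amino acid, columns
#'   `binding` and `nonbinding`.
#' @export
linear_weight_map <- function(params, arity, length) {
  stopifnot(inherits(params, "mlp_params"))
  abort_if(base::length(params$weights) != 1L,
           "linear_weight_map needs a model without hidden layers")
  w <- params$weights[[1L]]
  abort_if(nrow(w) != arity * length * 20L,
           "weight matrix rows (%d) do not match arity %d x L %d x 20",
           nrow(w), arity, length)
  aa_of_row <- rep_len(AA_ALPHABET, nrow(w))
  m <- rowsum(w, group = factor(aa_of_row, levels = AA_ALPHABET))
  out <- cbind(binding = m[, 2L], nonbinding = m[, 1L])
  rownames(out) <- AA_ALPHABET
  out
}

#' Save a fitted model as a versioned JSON checkpoint
#'
#' @param fit An `mlp_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mlp_fit"))
  obj <- list(format = "peptriad-checkpoint", version = 1L,
              sizes = fit$params$sizes,
              weights = fit$params$weights, biases = fit$params$biases,
              config = unclass(fit$config), history = fit$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [write_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return An `mlp_fit` (history restored; `best` not tracked).
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  abort_if(!identical(obj$format, "peptriad-checkpoint"),
           "%s is not a peptriad checkpoint", path)
  sizes <- as.integer(obj$sizes)
  weights <- lapply(seq_len(length(sizes) - 1L), function(l)
    matrix(obj$weights[[l]], sizes[l], sizes[l + 1L]))
  params <- structure(list(weights = weights,
                           biases = lapply(obj$biases, as.numeric),
                           sizes = sizes),
                      class = "mlp_params")
  structure(list(params = params, history = as.data.frame(obj$history),
                 best = NULL, config = do.call(train_config, obj$config)),
            class = "mlp_fit")
}
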