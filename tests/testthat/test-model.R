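## tiny hand-checkable networks plus training smoke tests; full-scale
## training behaviour is exercised by the acceptance suite

zero_params <- function(sizes) {
  p <- mlp_init(sizes[1], hidden = sizes[-c(1, length(sizes))],
                output_size = sizes[length(sizes)], seed = 1)
  p$weights <- lapply(p$weights, function(w) w * 0)
  p$biases <- lapply(p$biases, function(b) b * 0)
  p
}

test_that("forward pass is a ReLU/softmax network", {
  ## all-zero parameters: symmetric softmax, 0.5/0.5 everywhere
  p0 <- zero_params(c(6, 4, 2))
  pr <- mlp_forward(p0, matrix(rnorm(30), 5, 6))
  expect_equal(unname(pr), matrix(0.5, 5, 2))
  ## rows always sum to 1
  p <- mlp_init(6, hidden = c(4, 3), seed = 2)
  pr <- mlp_forward(p, matrix(rnorm(60, sd = 3), 10, 6))
  expect_equal(unname(rowSums(pr)), rep(1, 10), tolerance = 1e-9)
  expect_true(all(pr > 0 & pr < 1))
  ## 2-node toy network against a pencil-and-paper forward pass
  p <- zero_params(c(2, 2, 2))
  p$weights[[1]] <- matrix(c(1, -1, 0.5, 2), 2, 2)   # columns are units
  p$biases[[1]] <- c(-0.5, 1)
  p$weights[[2]] <- matrix(c(1, 0, -1, 1), 2, 2)
  p$biases[[2]] <- c(0.2, -0.2)
  x <- matrix(c(1, 2), 1, 2)
  h <- pmax(c(1 * 1 + 2 * -1 - 0.5, 1 * 0.5 + 2 * 2 + 1), 0)  # (0, 5.5)
  z <- c(h[1] * 1 + h[2] * 0 + 0.2, h[1] * -1 + h[2] * 1 - 0.2) # (0.2, 5.3)
  want <- exp(z) / sum(exp(z))
  expect_equal(unname(mlp_forward(p, x)[1, ]), want)
  expect_error(mlp_forward(p, matrix(0, 1, 3)), "expects")
})

test_that("loss is mean NLL plus the L2 penalty", {
  ## perfectly confident correct prediction, no penalty: loss ~ 0
  p <- zero_params(c(2, 2))
  p$weights[[1]] <- matrix(c(-50, 50, 50, -50), 2, 2)
  x <- diag(2)
  expect_lt(mlp_loss(p, x, c(1L, 0L), 0), 1e-10)
  ## uniform predictor: ln 2 per sample
  p0 <- zero_params(c(4, 2))
  expect_equal(mlp_loss(p0, matrix(rnorm(12), 3, 4), c(0L, 1L, 0L), 0), log(2))
  ## random small parameters: matches a term-by-term recomputation
  set.seed(19)
  p <- mlp_init(5, hidden = c(3), seed = 19)
  x <- matrix(rnorm(20), 4, 5)
  y <- c(0L, 1L, 1L, 0L)
  lambda <- 0.01
  probs <- mlp_forward(p, x)
  nll <- -mean(log(probs[cbind(1:4, y + 1)]))
  l2 <- sum(unlist(p$weights)^2) + sum(unlist(p$biases)^2)
  expect_equal(mlp_loss(p, x, y, lambda), nll + lambda * l2)
  expect_error(mlp_loss(p, x, y, -1), ">= 0")
})

test_that("analytic gradients match central finite differences", {
  set.seed(8)
  p <- mlp_init(6, hidden = c(4, 3), seed = 8)
  x <- matrix(rnorm(30), 5, 6)
  y <- sample(0:1, 5, TRUE)
  lambda <- 0.003
  g <- peptriad:::mlp_gradients(p, x, y, lambda)
  num <- oracle_fd_gradients(p, x, y, lambda)
  for (part in c("weights", "biases")) {
    for (l in seq_along(g[[part]])) {
      a <- as.numeric(g[[part]][[l]])
      b <- as.numeric(num[[part]][[l]])
      rel <- abs(a - b) / pmax(abs(a) + abs(b), 1e-8)
      expect_lt(max(rel), 1e-5)
    }
  }
})

test_that("single-sample loss decreases under a small learning rate", {
  set.seed(10)
  p <- mlp_init(4, hidden = c(3), seed = 10)
  x <- matrix(rnorm(4), 1, 4)
  y <- 1L
  losses <- numeric(30)
  for (it in 1:30) {
    losses[it] <- mlp_loss(p, x, y, 0)
    g <- peptriad:::mlp_gradients(p, x, y, 0)
    for (part in c("weights", "biases"))
      for (l in seq_along(p[[part]]))
        p[[part]][[l]] <- p[[part]][[l]] - 0.05 * g[[part]][[l]]
  }
  expect_true(all(diff(losses) <= 1e-12))
})

small_split <- function(n = 1200, seed = 1, noise = 0) {
  spec <- pattern_spec(n_binding = n / 2, n_nonbinding = n / 2,
                       noise = noise, seed = seed)
  split_dataset(encode_tuples(simulate_pattern_dataset(spec)), seed = seed)
}

## additive, linearly separable toy task: binding iff fragment 1's center
## residue is alanine
additive_split <- function(n, seed) {
  set.seed(seed)
  x <- matrix(0L, n, 420)
  y <- sample(0:1, n, TRUE)
  for (i in 1:n) {
    letters_i <- sample(2:20, 21, TRUE)
    if (y[i] == 1) letters_i[4] <- 1L
    x[i, (0:20) * 20 + letters_i] <- 1L
  }
  ds <- structure(list(x = x, y = y, id = as.character(1:n), arity = 3L,
                       length = 7L), class = "encoded_dataset")
  split_dataset(ds, seed = seed)
}

test_that("training is reproducible and learns separable data", {
  sp <- additive_split(2000, seed = 33)
  cfg <- train_config(hidden = c(32, 32), eval_every = 10, patience = 5,
                      max_checkpoints = 40, learning_rate = 3e-3, seed = 3)
  fit1 <- mlp_train(sp, cfg)
  fit2 <- mlp_train(sp, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$params$weights, fit2$params$weights)
  m <- classification_metrics(predict(fit1, sp$test), sp$test$y)
  expect_gt(m$accuracy, 0.95)
  ## training loss drops from its starting level
  expect_lt(fit1$history$train_loss[nrow(fit1$history)],
            fit1$history$train_loss[1])
})

test_that("the linear model solves additive patterns but not combination rules", {
  sp <- additive_split(2000, seed = 34)
  cfg <- train_config(eval_every = 20, patience = 10, max_checkpoints = 60,
                      learning_rate = 1e-2, seed = 4)
  fit <- train_linear(sp, cfg)
  expect_equal(length(fit$params$weights), 1L)
  expect_equal(dim(fit$params$weights[[1]]), c(420L, 2L))
  m <- classification_metrics(predict(fit, sp$test), sp$test$y)
  expect_gt(m$accuracy, 0.95)
  ## combination-dependent rule: linear stays near chance
  sp2 <- small_split(1600, seed = 22)
  fit2 <- train_linear(sp2, cfg)
  m2 <- classification_metrics(predict(fit2, sp2$test), sp2$test$y)
  expect_lt(m2$accuracy, 0.62)
})

test_that("the linear weight map sums positional weights per amino acid", {
  p <- zero_params(c(420, 2))
  expect_equal(unname(linear_weight_map(p, 3, 7)),
               matrix(0, 20, 2))
  ## weight only on (A, position 1) toward the binding node
  p$weights[[1]][1, 2] <- 1.0
  wm <- linear_weight_map(p, 3, 7)
  expect_equal(unname(wm["A", "binding"]), 1.0)
  expect_equal(sum(wm != 0), 1L)
  ## random weights: matches index-by-index summation
  set.seed(12)
  p$weights[[1]] <- matrix(rnorm(840), 420, 2)
  wm <- linear_weight_map(p, 3, 7)
  for (aa_i in c(1L, 7L, 20L)) {
    rows <- (0:20) * 20 + aa_i
    expect_equal(unname(wm[aa_i, "binding"]), sum(p$weights[[1]][rows, 2]))
    expect_equal(unname(wm[aa_i, "nonbinding"]), sum(p$weights[[1]][rows, 1]))
  }
  deep <- mlp_init(420, hidden = c(8), seed = 1)
  expect_error(linear_weight_map(deep, 3, 7), "without hidden layers")
})

test_that("checkpoints round-trip weights and config through JSON", {
  sp <- small_split(400, seed = 25)
  cfg <- train_config(hidden = c(8), eval_every = 5, patience = 2,
                      max_checkpoints = 8, seed = 6)
  fit <- mlp_train(sp, cfg)
  path <- tempfile(fileext = ".json")
  write_checkpoint(fit, path)
  back <- read_checkpoint(path)
  expect_equal(back$params$weights, fit$params$weights)
  expect_equal(back$params$biases, fit$params$biases)
  expect_equal(predict(back, sp$test), predict(fit, sp$test))
})
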