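test_that("tiny network forward pass yields proper class probabilities", {
  cfg <- model_config(depth = "tiny", input_size = 32, seed = 3)
  model <- build_model(cfg)
  set.seed(1)
  imgs <- lapply(1:4, function(i) matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  pred <- predict_network(model, imgs)
  expect_equal(dim(pred$probabilities), c(4L, 5L))
  expect_true(all(is.finite(pred$probabilities)))
  expect_equal(rowSums(pred$probabilities), rep(1, 4), tolerance = 1e-6)
  expect_true(all(pred$labels %in% DR_GRADES))
})

test_that("a gradient step on a small batch reduces the training loss", {
  # dropout 0 and delta 0 make one full-batch step exact gradient descent
  cfg <- model_config(depth = "tiny", input_size = 16, dropout = 0,
                      pooling = list(delta = 0), beta = 0.1,
                      learning_rate = 1e-3, momentum = 0, batch_size = 8,
                      seed = 5)
  model <- build_model(cfg)
  set.seed(2)
  imgs <- lapply(1:8, function(i) matrix(sample(0:255, 256, TRUE), 16, 16))
  labs <- rep(DR_GRADES, length.out = 8)
  eval_loss <- function() {
    x <- fundusdr:::prepare_batch(imgs, 16)
    fw <- fundusdr:::model_forward(model, x, training = FALSE)
    p <- fundusdr:::softmax_rows(fw$logits)
    y <- match(labs, model$classes)
    -mean(log(p[cbind(seq_len(8), y)])) +
      balance_loss(fw$pool_weights, cfg$beta)
  }
  before <- eval_loss()
  train_network(model, imgs, labs, epochs = 1, seed = 7)
  expect_lt(eval_loss(), before)
})

test_that("training is deterministic and logs one loss row per epoch", {
  set.seed(4)
  imgs <- lapply(1:10, function(i) matrix(sample(0:255, 256, TRUE), 16, 16))
  labs <- rep(c("NoDR", "PDR"), 5)
  run <- function() {
    cfg <- model_config(depth = "tiny", input_size = 16, batch_size = 5,
                        learning_rate = 0.01, epochs = 3, seed = 9)
    m <- build_model(cfg)
    train_network(m, imgs, labs, seed = 11)
  }
  m1 <- run(); m2 <- run()
  expect_equal(nrow(m1$history), 3)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)
  expect_true(all(is.finite(m1$history$loss)))
  expect_error(train_network(build_model(model_config(input_size = 16)),
                             list(), character(0)), "empty")
})

test_that("penultimate features have the head width and drive the SVM", {
  cfg <- model_config(depth = "tiny", input_size = 32, seed = 3)
  model <- build_model(cfg)
  set.seed(5)
  imgs <- lapply(1:6, function(i) matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  ft <- extract_features(model, imgs)
  expect_equal(nrow(ft), 6)
  expect_true(all(is.finite(ft)))
  expect_true(all(ft >= -1 & ft <= 1))   # post-activation features
})

test_that("gradients stay finite through a full backward pass", {
  cfg <- model_config(depth = "tiny", input_size = 16, seed = 8)
  model <- build_model(cfg)
  set.seed(6)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  fw <- fundusdr:::model_forward(model, x, training = TRUE)
  p <- fundusdr:::softmax_rows(fw$logits)
  dy <- p; dy[cbind(1:3, c(1L, 2L, 3L))] <- dy[cbind(1:3, c(1L, 2L, 3L))] - 1
  dweights <- fundusdr:::balance_loss_grad(fw$pool_weights, 0.1)
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    dy <- fundusdr:::layer_backward(ly, fw$caches[[i]], dy, TRUE,
                                    dweights = if (ly$type == "pool") dweights)
  }
  expect_true(all(is.finite(dy)))
})
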