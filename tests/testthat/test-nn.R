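# The training engine: analytic gradients against numerical differentiation,
# seeded reproducibility, and the early-stopping mechanism.

loss_of <- function(arch, params, x, y) {
  probs <- eegsent:::nn_forward(arch, params, x)$acts[["softmax"]]
  mean(-log(probs[cbind(y + 1L, seq_along(y))]))
}

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(11)
  for (builder in list(function() build_base_model(c(17, 17, 3)),
                       function() build_opt_model(c(17, 17, 3), drop_prob = 0))) {
    arch <- builder()
    params <- eegsent:::init_params(arch)
    x <- array(rnorm(17 * 17 * 3 * 4), c(17, 17, 3, 4))
    y <- c(0L, 1L, 1L, 0L)
    fw <- eegsent:::nn_forward(arch, params, x, training = TRUE)
    # training=TRUE only adds caches here (no dropout active), so the
    # analytic gradients apply to the deterministic loss below
    gr <- eegsent:::nn_backward(arch, params, fw, y)
    eps <- 1e-6
    for (nm in names(gr)) {
      w <- params[[nm]]$W
      for (ii in sample(length(w), 3)) {
        pp <- params
        pp[[nm]]$W[ii] <- w[ii] + eps
        up <- loss_of(arch, pp, x, y)
        pp[[nm]]$W[ii] <- w[ii] - eps
        dn <- loss_of(arch, pp, x, y)
        expect_equal(gr[[nm]]$W[ii], (up - dn) / (2 * eps), tolerance = 1e-4)
      }
      pp <- params
      pp[[nm]]$b[1] <- params[[nm]]$b[1] + eps
      up <- loss_of(arch, pp, x, y)
      pp[[nm]]$b[1] <- params[[nm]]$b[1] - eps
      dn <- loss_of(arch, pp, x, y)
      expect_equal(gr[[nm]]$b[1], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("dropout scales by the keep probability and masks gradients", {
  arch <- build_opt_model(c(17, 17, 3), drop_prob = 0.5)
  params <- eegsent:::init_params(arch)
  x <- array(rnorm(17 * 17 * 3 * 2), c(17, 17, 3, 2))
  set.seed(3)
  fw <- eegsent:::nn_forward(arch, params, x, training = TRUE)
  mask <- fw$acts[["dropout"]] != 0
  kept <- fw$acts[["dropout"]][mask]
  src <- fw$acts[["pool2"]][mask]
  expect_equal(kept, src / 0.5)
  # evaluation mode applies no mask
  fe <- eegsent:::nn_forward(arch, params, x, training = FALSE)
  expect_equal(fe$acts[["dropout"]], fe$acts[["pool2"]])
})

test_that("training is reproducible under a fixed seed", {
  ft <- small_tensor()
  n <- length(ft$labels)
  spl <- kfold_split(n, k = 5, seed = 3)[[1]]
  cfg <- train_config(epochs = 4, batch_size = 16, seed = 99)
  f1 <- train_model(build_base_model(), ft, spl, cfg)
  f2 <- train_model(build_base_model(), ft, spl, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$traces, f2$traces)
  f3 <- train_model(build_base_model(), ft, spl,
                    train_config(epochs = 4, batch_size = 16, seed = 100))
  expect_false(identical(f1$params, f3$params))
})

test_that("early stopping fires after the patience window and keeps the best", {
  ft <- small_tensor()
  spl <- kfold_split(length(ft$labels), k = 5, seed = 3)[[1]]
  cfg <- train_config(epochs = 100, batch_size = 32,
                      early_stop_patience = 3, seed = 7)
  fit <- train_model(build_base_model(), ft, spl, cfg)
  expect_lt(fit$stopped_epoch, 100)
  expect_equal(fit$stopped_epoch - fit$best_epoch, 3)
  expect_equal(fit$best_val_accuracy, max(fit$traces$val_accuracy))
})

test_that("mismatched tensor and architecture shapes are rejected", {
  ft <- small_tensor()
  spl <- kfold_split(length(ft$labels), k = 5, seed = 3)[[1]]
  expect_error(train_model(build_base_model(c(17, 17, 8)), ft, spl,
                           train_config(epochs = 1)),
               "do not match")
})

test_that("learning-rate outside the reference interval warns", {
  expect_warning(train_config(learning_rate = 1e-3), "interval")
  expect_silent(train_config(learning_rate = 5e-5))
})

test_that("predictions break probability ties toward class 0", {
  ft <- small_tensor()
  spl <- kfold_split(length(ft$labels), k = 5, seed = 3)[[1]]
  fit <- train_model(build_base_model(), ft, spl,
                     train_config(epochs = 1, batch_size = 32, seed = 1))
  pr <- predict(fit, ft, spl$test)
  expect_equal(pr$pred, ifelse(pr$prob1 > 0.5, 1L, 0L))
})
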