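# Training engine for the declarative architectures: Glorot-initialized
# weights, minibatch Adam on the softmax cross-entropy, inverted dropout,
# and early stopping on validation accuracy with best-weight restoration.
# All randomness (initialization, batch shuffling, dropout masks) is drawn
# from R's RNG, so a fixed seed reproduces training exactly on a fixed BLAS.

#' Training configuration
#'
#' Defaults follow the reference regime: Adam (`beta1` 0.9, `beta2` 0.999),
#' learning rate 1e-4 (values outside `[1e-5, 1e-4]` are accepted with a
#' warning), 100 epochs, batch size 200, Glorot weight / zero bias
#' initialization, cross-entropy loss, and early stopping after 10
#' consecutive epochs without a new best validation accuracy.
#'
#' @param learning_rate Adam step size.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param early_stop_patience consecutive validation checks (one per epoch)
#'   without improvement before stopping; `Inf` disables early stopping.
#' @param early_stop_min_epochs burn-in: epochs that must complete before
#'   early stopping may trigger. The default 1 is the plain reading of the
#'   reference regime; small datasets with few optimizer steps per epoch can
#'   need a burn-in because heavy dropout delays the first validation
#'   improvement past the patience window (see the methods vignette).
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100, batch_size = 200,
                         beta1 = 0.9, beta2 = 0.999,
                         early_stop_patience = 10,
                         early_stop_min_epochs = 1, seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            early_stop_patience >= 1, early_stop_min_epochs >= 1)
  if (learning_rate < 1e-5 || learning_rate > 1e-4)
    warning("learning_rate ", learning_rate,
            " is outside the reference interval [1e-5, 1e-4]")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2,
                 early_stop_patience = early_stop_patience,
                 early_stop_min_epochs = early_stop_min_epochs,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Glorot-uniform parameter initialization; biases zero.
init_params <- function(arch, shapes = infer_shapes(arch)) {
  params <- list()
  for (l in arch$layers) {
    if (l$kind == "conv") {
      cin <- shapes[[l$inputs[1]]][3]
      fan_in <- l$kernel[1] * l$kernel[2] * cin
      fan_out <- l$kernel[1] * l$kernel[2] * l$filters
      lim <- sqrt(6 / (fan_in + fan_out))
      params[[l$name]] <- list(
        W = array(stats::runif(fan_in * l$filters, -lim, lim),
                  c(l$kernel[1], l$kernel[2], cin, l$filters)),
        b = numeric(l$filters))
    } else if (l$kind == "fully_connected") {
      fin <- prod(shapes[[l$inputs[1]]])
      lim <- sqrt(6 / (fin + l$filters))
      params[[l$name]] <- list(
        W = matrix(stats::runif(fin * l$filters, -lim, lim), fin, l$filters),
        b = numeric(l$filters))
    }
  }
  params
}

# Forward pass over the layer DAG. Returns activations by layer name plus
# the caches backward needs (pool argmaxes, dropout masks).
nn_forward <- function(arch, params, x, training = FALSE) {
  acts <- list(); cache <- list()
  for (l in arch$layers) {
    a <- switch(l$kind,
      input = x,
      conv = {
        cf <- conv_fwd(acts[[l$inputs]], params[[l$name]]$W,
                       params[[l$name]]$b, identical(l$padding, "same"))
        if (training) cache[[l$name]] <- cf$A
        cf$y
      },
      relu = relu_fwd(acts[[l$inputs]]),
      maxpool = {
        mp <- maxpool_fwd(acts[[l$inputs]])
        cache[[l$name]] <- mp$idx
        mp$y
      },
      depth_concat = {
        ins <- acts[l$inputs]
        out <- ins[[1]]
        for (a in ins[-1]) out <- chan_concat2(out, a)
        out
      },
      dropout = {
        a0 <- acts[[l$inputs]]
        if (training && l$drop_prob > 0) {
          keep <- 1 - l$drop_prob
          mask <- array(stats::runif(length(a0)) < keep, dim(a0))
          cache[[l$name]] <- mask
          a0 * mask / keep
        } else a0
      },
      fully_connected = {
        a0 <- acts[[l$inputs]]
        af <- matrix(a0, prod(dim(a0)[1:3]), dim(a0)[4])
        crossprod(params[[l$name]]$W, af) + params[[l$name]]$b
      },
      softmax = {
        z <- acts[[l$inputs]]
        z <- sweep(z, 2, apply(z, 2, max))
        e <- exp(z)
        sweep(e, 2, colSums(e), "/")
      })
    acts[[l$name]] <- a
  }
  list(acts = acts, cache = cache)
}

# Backward pass from the softmax cross-entropy. `y` is an integer vector of
# 0/1 labels for the batch. Returns gradients for every learnable layer.
nn_backward <- function(arch, params, fw, y) {
  acts <- fw$acts
  layers <- arch$layers
  nl <- length(layers)
  grads <- list()
  dact <- list()

  probs <- acts[[layers[[nl]]$name]]          # softmax is the sink
  n <- ncol(probs)
  dz <- probs
  dz[cbind(y + 1L, seq_len(n))] <- dz[cbind(y + 1L, seq_len(n))] - 1
  dact[[layers[[nl]]$inputs]] <- dz / n       # gradient at the fc output

  # gradient buffers are freshly allocated by the backward kernels, so
  # accumulation can mutate them in place
  add_grad <- function(name, g) {
    if (is.null(dact[[name]])) dact[[name]] <<- g
    else invisible(inplace_add(dact[[name]], g))
  }

  for (i in rev(seq_len(nl - 1))) {
    l <- layers[[i]]
    dy <- dact[[l$name]]
    if (is.null(dy) || l$kind == "input") next
    switch(l$kind,
      conv = {
        need_dx <- arch$layers[[l$inputs]]$kind != "input"
        g <- conv_bwd(acts[[l$inputs]], params[[l$name]]$W, dy,
                      identical(l$padding, "same"), fw$cache[[l$name]],
                      need_dx)
        grads[[l$name]] <- list(W = g$dw, b = g$db)
        if (need_dx) add_grad(l$inputs, g$dx)
      },
      relu = add_grad(l$inputs, relu_bwd(acts[[l$name]], dy)),
      maxpool = add_grad(l$inputs,
                         maxpool_bwd(fw$cache[[l$name]], dy,
                                     dim(acts[[l$inputs]]))),
      depth_concat = {
        off <- 1L
        for (nm in l$inputs) {
          nc <- dim(acts[[nm]])[3]
          add_grad(nm, chan_slice(dy, off, nc))
          off <- off + nc
        }
      },
      dropout = {
        mask <- fw$cache[[l$name]]
        if (is.null(mask)) add_grad(l$inputs, dy)
        else add_grad(l$inputs, dy * mask / (1 - l$drop_prob))
      },
      fully_connected = {
        a0 <- acts[[l$inputs]]
        af <- matrix(a0, prod(dim(a0)[1:3]), dim(a0)[4])
        grads[[l$name]] <- list(W = af %*% t(dy), b = rowSums(dy))
        add_grad(l$inputs, array(params[[l$name]]$W %*% dy, dim(a0)))
      })
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, t, cfg, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- cfg$beta1 * s$mW + (1 - cfg$beta1) * g$W
    s$vW <- cfg$beta2 * s$vW + (1 - cfg$beta2) * g$W^2
    s$mb <- cfg$beta1 * s$mb + (1 - cfg$beta1) * g$b
    s$vb <- cfg$beta2 * s$vb + (1 - cfg$beta2) * g$b^2
    c1 <- 1 - cfg$beta1^t; c2 <- 1 - cfg$beta2^t
    params[[nm]]$W <- params[[nm]]$W -
      cfg$learning_rate * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b -
      cfg$learning_rate * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Feature tensor images (N x 16 x h x w) -> engine layout (h, w, 16, N).
tensor_to_input <- function(images, idx = seq_len(dim(images)[1])) {
  aperm(images[idx, , , , drop = FALSE], c(3, 4, 2, 1))
}

# Predicted class-1 probability and cross-entropy loss on a set.
nn_eval <- function(arch, params, x, y, batch = 512) {
  n <- dim(x)[4]
  p1 <- numeric(n); loss <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    probs <- nn_forward(arch, params,
                        x[, , , s:e, drop = FALSE])$acts[["softmax"]]
    p1[s:e] <- probs[2, ]
    py <- probs[cbind(y[s:e] + 1L, seq_len(e - s + 1))]
    loss <- loss + sum(-log(pmax(py, 1e-12)))
  }
  pred <- ifelse(p1 > 0.5, 1L, 0L)          # ties at 0.5 go to class 0
  list(prob1 = p1, pred = pred,
       accuracy = mean(pred == y), loss = loss / n)
}

#' Train a network on one cross-validation fold
#'
#' Runs minibatch Adam on the learning partition, checks accuracy on the
#' validation partition once per epoch, stops early after
#' `early_stop_patience` epochs without a new best validation accuracy, and
#' returns the weights of the best-validation epoch.
#'
#' @param arch a `cnn_arch` from [build_base_model()] / [build_opt_model()].
#' @param tensor a `feature_tensor`.
#' @param split a fold from [kfold_split()] (fields `learn`, `val`, `test`),
#'   or a list with at least `learn` and `val` index vectors.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return An `eeg_cnn_fit`: `params` (best weights), `arch`, `traces`
#'   (per-epoch validation accuracy/loss), `best_epoch`, `stopped_epoch`.
#' @export
train_model <- function(arch, tensor, split, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(arch, "cnn_arch"), inherits(tensor, "feature_tensor"))
  d <- dim(tensor$images)
  in_shape <- arch$layers[["input"]]$shape
  if (!identical(as.integer(d[c(3, 4, 2)]), as.integer(in_shape)))
    stop("tensor images ", paste(d[c(3, 4, 2)], collapse = "x"),
         " do not match architecture input ",
         paste(in_shape, collapse = "x"), call. = FALSE)

  x_learn <- tensor_to_input(tensor$images, split$learn)
  y_learn <- tensor$labels[split$learn]
  x_val <- tensor_to_input(tensor$images, split$val)
  y_val <- tensor$labels[split$val]
  n <- length(y_learn)

  with_seed(cfg$seed, {
    params <- init_params(arch)
    state <- adam_init(params)
    t <- 0
    best <- list(acc = -Inf, params = params, epoch = 0)
    stale <- 0
    traces <- data.frame(epoch = integer(), val_accuracy = numeric(),
                         val_loss = numeric())
    stopped <- cfg$epochs
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = cfg$batch_size)) {
        bi <- ord[s:min(s + cfg$batch_size - 1, n)]
        fw <- nn_forward(arch, params, x_learn[, , , bi, drop = FALSE],
                         training = TRUE)
        probs <- fw$acts[["softmax"]]
        py <- probs[cbind(y_learn[bi] + 1L, seq_along(bi))]
        batch_loss <- mean(-log(pmax(py, 1e-12)))
        if (!is.finite(batch_loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        grads <- nn_backward(arch, params, fw, y_learn[bi])
        t <- t + 1
        upd <- adam_step(params, grads, state, t, cfg)
        params <- upd$params; state <- upd$state
      }
      ev <- nn_eval(arch, params, x_val, y_val)
      traces <- rbind(traces, data.frame(epoch = ep, val_accuracy = ev$accuracy,
                                         val_loss = ev$loss))
      if (verbose)
        message(sprintf("epoch %3d  val_acc %.4f  val_loss %.4f",
                        ep, ev$accuracy, ev$loss))
      if (ev$accuracy > best$acc) {
        best <- list(acc = ev$accuracy, params = params, epoch = ep)
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= cfg$early_stop_patience &&
            ep >= (cfg$early_stop_min_epochs %||% 1)) { stopped <- ep; break }
      }
    }
    structure(list(arch = arch, params = best$params, traces = traces,
                   best_epoch = best$epoch, best_val_accuracy = best$acc,
                   stopped_epoch = stopped, cfg = cfg),
              class = "eeg_cnn_fit")
  })
}

#' Predict class probabilities and labels
#'
#' @param object an `eeg_cnn_fit`.
#' @param tensor a `feature_tensor`.
#' @param idx optional epoch indices (default: all).
#' @param ... unused.
#' @return Data frame with `prob1` (class-1 probability) and `pred`
#'   (predicted label; the 0.5 tie goes to class 0).
#' @export
predict.eeg_cnn_fit <- function(object, tensor, idx = NULL, ...) {
  if (is.null(idx)) idx <- seq_len(dim(tensor$images)[1])
  x <- tensor_to_input(tensor$images, idx)
  ev <- nn_eval(object$arch, object$params, x, tensor$labels[idx])
  data.frame(prob1 = ev$prob1, pred = ev$pred)
}

#' @export
print.eeg_cnn_fit <- function(x, ...) {
  cat(sprintf("<eeg_cnn_fit> %s: best val accuracy %.4f at epoch %d (stopped %d)\n",
              x$arch$name, x$best_val_accuracy, x$best_epoch, x$stopped_epoch))
  invisible(x)
}
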