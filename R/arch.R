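# Declarative CNN architecture descriptions. An architecture is an acyclic
# graph of layer specs from one input to one softmax, stored in topological
# order; output shapes and learnable-parameter counts are derived from the
# description alone, independently of the training engine, so the printed
# layer tables can be verified without instantiating weights.

LAYER_KINDS <- c("input", "conv", "relu", "maxpool", "depth_concat",
                 "dropout", "fully_connected", "softmax")

layer_spec <- function(name, kind, inputs = character(), filters = NULL,
                       kernel = NULL, stride = 1L, padding = "valid",
                       drop_prob = NULL, shape = NULL) {
  kind <- match.arg(kind, LAYER_KINDS)
  if (kind %in% c("conv", "fully_connected") &&
      (is.null(filters) || filters < 1))
    stop("layer ", name, ": filters must be >= 1", call. = FALSE)
  if (kind == "conv" && is.null(kernel))
    stop("layer ", name, ": conv needs a kernel size", call. = FALSE)
  if (kind == "depth_concat" && length(inputs) < 2)
    stop("layer ", name, ": depth_concat needs >= 2 inputs", call. = FALSE)
  list(name = name, kind = kind, inputs = inputs,
       filters = if (!is.null(filters)) as.integer(filters),
       kernel = if (!is.null(kernel)) as.integer(kernel),
       stride = as.integer(stride), padding = padding,
       drop_prob = drop_prob, shape = shape)
}

new_arch <- function(name, layers) {
  names(layers) <- vapply(layers, `[[`, "", "name")
  seen <- character()
  for (l in layers) {
    if (any(!l$inputs %in% seen))
      stop("layer ", l$name, " references undefined input(s): ",
           paste(setdiff(l$inputs, seen), collapse = ", "), call. = FALSE)
    seen <- c(seen, l$name)
  }
  arch <- structure(list(name = name, layers = layers), class = "cnn_arch")
  infer_shapes(arch)  # validate the graph eagerly
  arch
}

# Convenience: chain constructor where each layer feeds the previous one
# unless `inputs` is given explicitly.
chain <- function(...) {
  specs <- list(...)
  prev <- character()
  for (i in seq_along(specs)) {
    if (length(specs[[i]]$inputs) == 0 && specs[[i]]$kind != "input")
      specs[[i]]$inputs <- prev
    prev <- specs[[i]]$name
  }
  specs
}

#' Baseline two-convolution architecture
#'
#' Input `[17,17,16]` -> Conv1 (10 filters 5x5, valid) -> ReLU -> 2x2/2 max
#' pool -> Conv2 (20 filters 3x3, valid) -> ReLU -> 2x2/2 max pool -> fully
#' connected (2) -> softmax. Total learnable parameters: 5,992.
#'
#' @param input_shape `(height, width, channels)` of the feature images.
#' @return A `cnn_arch`.
#' @export
build_base_model <- function(input_shape = c(17, 17, 16)) {
  new_arch("base", chain(
    layer_spec("input", "input", shape = as.integer(input_shape)),
    layer_spec("conv1", "conv", filters = 10, kernel = c(5, 5)),
    layer_spec("relu1", "relu"),
    layer_spec("pool1", "maxpool", kernel = c(2, 2), stride = 2),
    layer_spec("conv2", "conv", filters = 20, kernel = c(3, 3)),
    layer_spec("relu2", "relu"),
    layer_spec("pool2", "maxpool", kernel = c(2, 2), stride = 2),
    layer_spec("fc", "fully_connected", filters = 2),
    layer_spec("softmax", "softmax")))
}

#' Optimized inception-style architecture
#'
#' A channel-mixing 1x1 convolution (Conv0, 8 filters) follows the input;
#' two convolution modules each run a stacked pair of 3x3 convolutions
#' (5x5-equivalent receptive field) in one path while a skip routes the first
#' 3x3's output directly to a depth concatenation, after which a 1x1
#' convolution linearly recombines the stacked channels; 2x2/2 max pooling
#' follows each module and a dropout layer (drop probability 0.95, as
#' printed) precedes the 2-unit fully connected layer and softmax. Total
#' learnable parameters: 3,876.
#'
#' Note: the published layer table prints Conv1c's output size as
#' `[15,15,16]`, which is inconsistent with its own filter count (10) and
#' parameter count (170 = 10*(16+1)); this reconstruction uses 10 output
#' channels, as required for Conv2a's printed 910 parameters.
#'
#' @param input_shape `(height, width, channels)` of the feature images.
#' @param drop_prob dropout drop probability before the fully connected
#'   layer.
#' @return A `cnn_arch`.
#' @export
build_opt_model <- function(input_shape = c(17, 17, 16), drop_prob = 0.95) {
  new_arch("opt", c(
    chain(
      layer_spec("input", "input", shape = as.integer(input_shape)),
      layer_spec("conv0", "conv", filters = 8, kernel = c(1, 1)),
      layer_spec("relu0", "relu"),
      layer_spec("conv1a", "conv", filters = 8, kernel = c(3, 3)),
      layer_spec("relu1a", "relu"),
      layer_spec("conv1b", "conv", filters = 8, kernel = c(3, 3),
                 padding = "same"),
      layer_spec("relu1b", "relu")),
    list(
      layer_spec("concat1", "depth_concat", inputs = c("relu1a", "relu1b"))),
    chain(
      layer_spec("conv1c", "conv", filters = 10, kernel = c(1, 1),
                 inputs = "concat1"),
      layer_spec("relu1c", "relu"),
      layer_spec("pool1", "maxpool", kernel = c(2, 2), stride = 2),
      layer_spec("conv2a", "conv", filters = 10, kernel = c(3, 3)),
      layer_spec("relu2a", "relu"),
      layer_spec("conv2b", "conv", filters = 10, kernel = c(3, 3),
                 padding = "same"),
      layer_spec("relu2b", "relu")),
    list(
      layer_spec("concat2", "depth_concat", inputs = c("relu2a", "relu2b"))),
    chain(
      layer_spec("conv2c", "conv", filters = 20, kernel = c(1, 1),
                 inputs = "concat2"),
      layer_spec("relu2c", "relu"),
      layer_spec("pool2", "maxpool", kernel = c(2, 2), stride = 2),
      layer_spec("dropout", "dropout", drop_prob = drop_prob),
      layer_spec("fc", "fully_connected", filters = 2),
      layer_spec("softmax", "softmax"))))
}

#' Infer the output shape of every layer
#'
#' Valid convolutions shrink each spatial dimension by `kernel - 1`; same
#' padding preserves it; 2x2 stride-2 pooling floors each dimension by half;
#' depth concatenation sums channels; the fully connected layer flattens to
#' `[1, 1, units]`.
#'
#' @param arch a `cnn_arch`.
#' @return Named list mapping layer name to `(height, width, channels)`.
#' @export
infer_shapes <- function(arch) {
  stopifnot(inherits(arch, "cnn_arch"))
  shapes <- list()
  for (l in arch$layers) {
    ins <- shapes[l$inputs]
    out <- switch(l$kind,
      input = l$shape,
      conv = {
        s <- ins[[1]]
        if (l$padding == "same") c(s[1], s[2], l$filters)
        else c(s[1] - l$kernel[1] + 1, s[2] - l$kernel[2] + 1, l$filters)
      },
      maxpool = {
        s <- ins[[1]]
        c(floor(s[1] / l$stride), floor(s[2] / l$stride), s[3])
      },
      depth_concat = {
        sp <- vapply(ins, function(s) s[1:2], numeric(2))
        if (any(sp != sp[, 1]))
          stop("layer ", l$name, ": concat inputs differ in spatial size",
               call. = FALSE)
        c(ins[[1]][1:2], sum(vapply(ins, `[`, 0, 3)))
      },
      fully_connected = c(1, 1, l$filters),
      ins[[1]])  # relu, dropout, softmax
    if (any(out < 1))
      stop("layer ", l$name, ": non-positive output dimension (",
           paste(out, collapse = "x"), ")", call. = FALSE)
    shapes[[l$name]] <- as.integer(out)
  }
  shapes
}

#' Count learnable parameters
#'
#' Convolution: `filters * (kh * kw * in_channels + 1)`; fully connected:
#' `units * (in_features + 1)`; all other layer kinds contribute 0.
#'
#' @param arch a `cnn_arch`.
#' @param layer optional layer name; if given, that layer's count is returned
#'   as an integer.
#' @return A `param_count` (list with `per_layer` and `total`) or an integer.
#' @export
count_parameters <- function(arch, layer = NULL) {
  shapes <- infer_shapes(arch)
  per <- vapply(arch$layers, function(l) {
    if (l$kind == "conv") {
      cin <- shapes[[l$inputs[1]]][3]
      l$filters * (l$kernel[1] * l$kernel[2] * cin + 1)
    } else if (l$kind == "fully_connected") {
      l$filters * (prod(shapes[[l$inputs[1]]]) + 1)
    } else 0
  }, numeric(1))
  if (!is.null(layer)) {
    if (!layer %in% names(per)) stop("no layer named ", layer, call. = FALSE)
    return(as.integer(per[[layer]]))
  }
  structure(list(per_layer = per[per > 0], total = sum(per)),
            class = "param_count")
}

#' @export
print.param_count <- function(x, ...) {
  for (n in names(x$per_layer))
    cat(sprintf("  %-8s %s\n", n, format(x$per_layer[[n]], big.mark = ",")))
  cat(sprintf("  total    %s\n", format(x$total, big.mark = ",")))
  invisible(x)
}

#' @export
print.cnn_arch <- function(x, ...) {
  shapes <- infer_shapes(x)
  pc <- count_parameters(x)
  cat(sprintf("<cnn_arch> %s (%s learnable parameters)\n", x$name,
              format(pc$total, big.mark = ",")))
  cat(sprintf("  %-9s %-16s %-14s %s\n", "layer", "num, size", "output",
              "params"))
  for (l in x$layers) {
    sz <- if (!is.null(l$kernel))
      sprintf("%s[%s]", if (!is.null(l$filters)) paste0(l$filters, ", ") else "",
              paste(l$kernel, collapse = ", "))
    else if (!is.null(l$filters)) as.character(l$filters)
    else "-"
    p <- if (l$name %in% names(pc$per_layer)) pc$per_layer[[l$name]]
    cat(sprintf("  %-9s %-16s [%s] %s\n", l$name, sz,
                paste(shapes[[l$name]], collapse = ", "),
                if (is.null(p)) "" else format(p, big.mark = ",")))
  }
  invisible(x)
}

#' Serialize an architecture to JSON (and back)
#'
#' @param arch a `cnn_arch`.
#' @param path file path.
#' @export
write_arch_json <- function(arch, path) {
  jsonlite::write_json(list(name = arch$name,
                            layers = lapply(unname(arch$layers), function(l)
                              Filter(Negate(is.null), l))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_arch_json
#' @export
read_arch_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(j$layers, function(l)
    layer_spec(l$name, l$kind, inputs = unlist(l$inputs) %||% character(),
               filters = l$filters, kernel = unlist(l$kernel),
               stride = l$stride %||% 1L, padding = l$padding %||% "valid",
               drop_prob = l$drop_prob, shape = unlist(l$shape)))
  new_arch(j$name, layers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
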