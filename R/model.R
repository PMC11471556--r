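#' Instantiate a model from an architecture graph
#'
#' Allocates seeded random weights for every parameterized node (He
#' initialization for convolutions and fully-connected layers, unit
#' scale/zero shift for batch normalization) plus running statistics for
#' normalization layers.
#'
#' @param graph an [architecture_graph].
#' @param seed integer seed for the initialization.
#' @return An object of class `leaf_model`.
#' @export
init_model <- function(graph, seed = 1L) {
  shapes <- infer_shapes(graph)
  weights <- list()
  with_seed(seed, {
    for (nd in graph$nodes) {
      in_shape <- if (nd$kind == "input") NULL else shapes[[nd$inputs[1]]]
      w <- switch(nd$kind,
        convolution = {
          cin <- in_shape[3]; k <- nd$filter
          sd <- sqrt(2 / (k * k * cin))
          list(W = array(stats::rnorm(k * k * cin * nd$depth, sd = sd),
                         c(k, k, cin, nd$depth)),
               b = numeric(nd$depth))
        },
        grouped_convolution = {
          cin <- in_shape[3]; k <- nd$filter
          sd <- sqrt(2 / (k * k))
          list(W = array(stats::rnorm(k * k * cin, sd = sd), c(k, k, cin)),
               b = numeric(cin))
        },
        batch_norm = {
          ch <- if (length(in_shape) == 1L) in_shape else in_shape[3]
          list(gamma = rep(1, ch), beta = numeric(ch),
               run_mean = numeric(ch), run_var = rep(1, ch))
        },
        fully_connected = {
          sd <- sqrt(2 / in_shape)
          list(W = matrix(stats::rnorm(in_shape * nd$depth, sd = sd),
                          in_shape, nd$depth),
               b = numeric(nd$depth))
        },
        self_attention = {
          d <- in_shape; dk <- nd$key_width
          sd <- sqrt(1 / d)
          list(Wq = matrix(stats::rnorm(d * dk, sd = sd), d, dk), bq = numeric(dk),
               Wk = matrix(stats::rnorm(d * dk, sd = sd), d, dk), bk = numeric(dk),
               Wv = matrix(stats::rnorm(d * dk, sd = sd), d, dk), bv = numeric(dk),
               Wo = matrix(stats::rnorm(dk * d, sd = sqrt(1 / dk)), dk, d),
               bo = numeric(d))
        },
        NULL)
      if (!is.null(w)) weights[[nd$name]] <- w
    }
  })
  structure(list(graph = graph, weights = weights, seed = seed),
            class = "leaf_model")
}

#' @export
print.leaf_model <- function(x, ...) {
  cat("<leaf_model> based on:\n")
  print(x$graph)
  invisible(x)
}

# Forward pass through the graph.
#
# x: N x H x W x 3 array (channels last). Returns the output of the final
# node, with the activation of `tap` (if given) attached as attribute
# "tap". When `keep = TRUE` all activations and layer caches are kept for
# backpropagation; otherwise activations are freed as soon as all their
# consumers have run, bounding memory at full scale.
model_forward <- function(model, x, training = FALSE, tap = NULL,
                          keep = FALSE) {
  g <- model$graph
  nodes <- g$nodes
  consumers <- integer(length(nodes)); names(consumers) <- names(nodes)
  for (nd in nodes) for (p in nd$inputs)
    consumers[[p]] <- consumers[[p]] + 1L
  acts <- new.env(parent = emptyenv())
  caches <- if (keep) new.env(parent = emptyenv()) else NULL
  tap_val <- NULL
  out <- NULL
  for (nd in nodes) {
    inp <- lapply(nd$inputs, function(n) get(n, envir = acts))
    w <- model$weights[[nd$name]]
    val <- switch(nd$kind,
      input = x,
      convolution = {
        v <- conv_fwd(inp[[1]], w$W, w$b, nd$stride %||% 1L, cache = keep)
        if (keep) { assign(nd$name, attr(v, "cache"), envir = caches); attr(v, "cache") <- NULL }
        v
      },
      grouped_convolution = {
        v <- dwconv_fwd(inp[[1]], w$W, w$b, nd$stride %||% 1L, cache = keep)
        if (keep) { assign(nd$name, attr(v, "cache"), envir = caches); attr(v, "cache") <- NULL }
        v
      },
      relu = relu_fwd(inp[[1]]),
      batch_norm = {
        r <- bn_fwd(inp[[1]], w$gamma, w$beta, w$run_mean, w$run_var, training)
        if (training) {
          model$weights[[nd$name]]$run_mean <- r$run_mean
          model$weights[[nd$name]]$run_var <- r$run_var
        }
        if (keep) assign(nd$name, r$cache, envir = caches)
        r$y
      },
      max_pool = {
        v <- maxpool_fwd(inp[[1]], nd$filter, nd$stride %||% 1L, cache = keep)
        if (keep) { assign(nd$name, attr(v, "cache"), envir = caches); attr(v, "cache") <- NULL }
        v
      },
      global_avg_pool = gap_fwd(inp[[1]]),
      addition = Reduce(`+`, inp),
      flatten = flatten_fwd(inp[[1]]),
      self_attention = attention_fwd(inp[[1]], w),
      fully_connected = fc_fwd(inp[[1]], w$W, w$b),
      softmax = softmax_rows(inp[[1]]),
      output = inp[[1]],
      stop("unknown node kind: ", nd$kind)
    )
    assign(nd$name, val, envir = acts)
    if (!is.null(tap) && nd$name == tap) tap_val <- val
    out <- val
    if (!keep) {
      for (p in nd$inputs) {
        consumers[[p]] <- consumers[[p]] - 1L
        if (consumers[[p]] == 0L && !(!is.null(tap) && p == tap))
          rm(list = p, envir = acts)
      }
    }
  }
  attr(out, "tap") <- tap_val
  attr(out, "acts") <- if (keep) acts else NULL
  attr(out, "caches") <- caches
  attr(out, "model") <- model # carries updated BN running stats
  out
}

# Backward pass. `dlogits` is the gradient at the *input* of the softmax
# node (i.e. at the fully-connected logits), which the training loop
# computes analytically as (p - y)/N for cross-entropy. Returns a named
# list of weight gradients.
model_backward <- function(model, fwd, dlogits) {
  g <- model$graph
  nodes <- g$nodes
  acts <- attr(fwd, "acts")
  caches <- attr(fwd, "caches")
  grads_out <- new.env(parent = emptyenv()) # gradient wrt each node's output
  wgrads <- list()
  # seed: gradient at the fc node output (softmax input)
  softmax_nd <- Filter(function(n) n$kind == "softmax", nodes)[[1]]
  assign(softmax_nd$inputs[1], dlogits, envir = grads_out)
  stop_at <- softmax_nd$inputs[1]
  seen_stop <- FALSE
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    if (!seen_stop) {
      if (nd$name == stop_at) seen_stop <- TRUE
      if (nd$name != stop_at) next
    }
    if (!exists(nd$name, envir = grads_out)) next
    dout <- get(nd$name, envir = grads_out)
    rm(list = nd$name, envir = grads_out)
    w <- model$weights[[nd$name]]
    push <- function(parent, dx) {
      if (exists(parent, envir = grads_out))
        assign(parent, get(parent, envir = grads_out) + dx, envir = grads_out)
      else assign(parent, dx, envir = grads_out)
    }
    switch(nd$kind,
      input = NULL,
      convolution = {
        r <- conv_bwd(dout, w$W, get(nd$name, envir = caches))
        wgrads[[nd$name]] <- list(W = r$dW, b = r$db)
        push(nd$inputs[1], r$dx)
      },
      grouped_convolution = {
        r <- dwconv_bwd(dout, w$W, get(nd$name, envir = caches))
        wgrads[[nd$name]] <- list(W = r$dW, b = r$db)
        push(nd$inputs[1], r$dx)
      },
      relu = push(nd$inputs[1],
                  relu_bwd(dout, get(nd$inputs[1], envir = acts))),
      batch_norm = {
        r <- bn_bwd(dout, w$gamma, get(nd$name, envir = caches))
        wgrads[[nd$name]] <- list(gamma = r$dgamma, beta = r$dbeta)
        push(nd$inputs[1], r$dx)
      },
      max_pool = push(nd$inputs[1],
                      maxpool_bwd(dout, get(nd$name, envir = caches))),
      global_avg_pool = push(nd$inputs[1],
                             gap_bwd(dout,
                                     dim(get(nd$inputs[1], envir = acts)))),
      addition = for (p in nd$inputs) push(p, dout),
      flatten = {
        xin <- get(nd$inputs[1], envir = acts)
        dx <- dout
        if (!is.matrix(xin)) dim(dx) <- dim(xin)
        push(nd$inputs[1], dx)
      },
      self_attention = {
        xin <- get(nd$inputs[1], envir = acts)
        r <- attention_bwd(dout, xin, w)
        wgrads[[nd$name]] <- list(Wq = r$dWq, bq = r$dbq, Wk = r$dWk,
                                  bk = r$dbk, Wv = r$dWv, bv = r$dbv,
                                  Wo = r$dWo, bo = r$dbo)
        push(nd$inputs[1], r$dx)
      },
      fully_connected = {
        xin <- get(nd$inputs[1], envir = acts)
        r <- fc_bwd(dout, xin, w$W)
        wgrads[[nd$name]] <- list(W = r$dW, b = r$db)
        push(nd$inputs[1], r$dx)
      },
      stop("unexpected node in backward pass: ", nd$kind)
    )
  }
  wgrads
}

# stack a list of H x W x 3 images into an N x side x side x 3 batch,
# resizing (with a warning) on shape mismatch
stack_images <- function(images, side) {
  n <- length(images)
  x <- array(0, c(n, side, side, 3L))
  warned <- FALSE
  for (i in seq_len(n)) {
    im <- images[[i]]
    if (dim(im)[1] != side || dim(im)[2] != side) {
      if (!warned) {
        warning("resizing image(s) to the model input side (", side, ")",
                call. = FALSE)
        warned <- TRUE
      }
      im <- resize_image(im, side)
    }
    x[i, , , ] <- im
  }
  x
}

#' Forward a batch of images through a model
#'
#' @param model a `leaf_model`.
#' @param images list of `H x W x 3` arrays (resized to the model input side
#'   if needed, with a warning).
#' @return `N x K` matrix of class probabilities (rows sum to 1).
#' @export
predict_model <- function(model, images) {
  side <- model$graph$input_shape[1]
  x <- stack_images(images, side)
  out <- model_forward(model, x, training = FALSE)
  attributes(out) <- attributes(out)["dim"]
  out
}
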