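#' Architecture graphs
#'
#' An `architecture_graph` is a directed acyclic graph of layer
#' specifications. Nodes are stored in topological (insertion) order; each
#' node records its kind, hyperparameters and parent node names. The graph
#' supports forward shape inference, layer enumeration and
#' learnable-parameter counting without allocating any weights.
#'
#' @name architecture_graph
NULL

new_graph <- function(input_shape, num_classes, name = "net") {
  g <- list(nodes = list(), input_shape = input_shape,
            num_classes = num_classes, name = name)
  class(g) <- "architecture_graph"
  g
}

add_node <- function(g, name, kind, inputs, ...) {
  if (name %in% names(g$nodes)) stop("duplicate node name: ", name, call. = FALSE)
  missing_in <- setdiff(inputs, names(g$nodes))
  if (kind != "input" && length(missing_in))
    stop("unknown parent(s): ", paste(missing_in, collapse = ", "), call. = FALSE)
  g$nodes[[name]] <- c(list(name = name, kind = kind, inputs = inputs),
                       list(...))
  g
}

#' @describeIn architecture_graph Number of layers: every node of every kind
#'   (input, convolution, activation, normalization, pooling, addition,
#'   flatten, attention, fully-connected, softmax, output) counts as one.
#' @param graph an `architecture_graph`.
#' @export
count_layers <- function(graph) {
  stopifnot(inherits(graph, "architecture_graph"))
  length(graph$nodes)
}

#' Forward shape inference
#'
#' Walks the graph in topological order computing each node's output shape
#' (`c(H, W, C)` for spatial nodes, a width for vector nodes). Addition
#' nodes require shape-identical inputs.
#'
#' @param graph an `architecture_graph`.
#' @return named list of shapes.
#' @export
infer_shapes <- function(graph) {
  shapes <- list()
  for (nd in graph$nodes) {
    inp <- lapply(nd$inputs, function(n) shapes[[n]])
    s <- switch(nd$kind,
      input = graph$input_shape,
      convolution = {
        k <- nd$filter; st <- nd$stride %||% 1L; p <- k %/% 2L
        c(conv_out_len(inp[[1]][1], k, st, p),
          conv_out_len(inp[[1]][2], k, st, p), nd$depth)
      },
      grouped_convolution = {
        k <- nd$filter; st <- nd$stride %||% 1L; p <- k %/% 2L
        c(conv_out_len(inp[[1]][1], k, st, p),
          conv_out_len(inp[[1]][2], k, st, p), inp[[1]][3])
      },
      relu = inp[[1]],
      batch_norm = inp[[1]],
      max_pool = {
        k <- nd$filter; st <- nd$stride %||% 1L; p <- k %/% 2L
        c(conv_out_len(inp[[1]][1], k, st, p),
          conv_out_len(inp[[1]][2], k, st, p), inp[[1]][3])
      },
      global_avg_pool = inp[[1]][3],
      addition = {
        for (s2 in inp[-1])
          if (!identical(s2, inp[[1]]))
            stop("addition node `", nd$name, "` has shape-mismatched inputs (",
                 paste(inp[[1]], collapse = "x"), " vs ",
                 paste(s2, collapse = "x"), ")", call. = FALSE)
        inp[[1]]
      },
      flatten = prod(inp[[1]]),
      self_attention = {
        if (length(inp[[1]]) != 1L)
          stop("self_attention `", nd$name, "` expects a flat input", call. = FALSE)
        inp[[1]]
      },
      fully_connected = nd$depth,
      softmax = inp[[1]],
      output = inp[[1]],
      stop("unknown node kind: ", nd$kind, call. = FALSE)
    )
    shapes[[nd$name]] <- s
  }
  shapes
}

node_learnables <- function(nd, in_shape) {
  switch(nd$kind,
    convolution = {
      cin <- in_shape[3]
      nd$filter^2 * cin * nd$depth + nd$depth
    },
    grouped_convolution = {
      # channel-wise: groups = input channels, one filter per channel
      cin <- in_shape[3]
      nd$filter^2 * cin + cin
    },
    batch_norm = {
      ch <- if (length(in_shape) == 1L) in_shape else in_shape[3]
      2 * ch
    },
    fully_connected = in_shape * nd$depth + nd$depth,
    self_attention = {
      d <- in_shape; dk <- nd$key_width
      3 * (d * dk + dk) + dk * d + d
    },
    0
  )
}

#' @describeIn architecture_graph Total learnable parameters: weights,
#'   biases and normalization scale/shift summed over all nodes, shapes
#'   inferred from the input.
#' @export
count_learnables <- function(graph) {
  shapes <- infer_shapes(graph)
  tot <- 0
  for (nd in graph$nodes) {
    in_shape <- if (nd$kind == "input") NULL else shapes[[nd$inputs[1]]]
    p <- tryCatch(node_learnables(nd, in_shape), error = function(e)
      stop("shape inference failed at node `", nd$name, "`: ",
           conditionMessage(e), call. = FALSE))
    tot <- tot + p
  }
  tot
}

#' @describeIn architecture_graph Width of the self-attention feature tap
#'   (the deep-feature dimensionality the model exports).
#' @export
extract_feature_width <- function(graph) {
  att <- Filter(function(n) n$kind == "self_attention", graph$nodes)
  if (!length(att))
    stop("graph has no self_attention node", call. = FALSE)
  shapes <- infer_shapes(graph)
  as.integer(shapes[[att[[1]]$name]])
}

#' Tabular summary of an architecture graph
#'
#' One row per node: name, kind, inferred output shape and learnable count.
#'
#' @param graph an `architecture_graph`.
#' @return a `data.frame`.
#' @export
graph_summary <- function(graph) {
  shapes <- infer_shapes(graph)
  rows <- lapply(graph$nodes, function(nd) {
    in_shape <- if (nd$kind == "input") NULL else shapes[[nd$inputs[1]]]
    data.frame(
      name = nd$name, kind = nd$kind,
      output_shape = paste(shapes[[nd$name]], collapse = "x"),
      learnables = node_learnables(nd, in_shape),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.architecture_graph <- function(x, ...) {
  cat(sprintf("<architecture_graph> %s: %d layers, %.1f M learnables, input %s, %d classes\n",
              x$name, count_layers(x), count_learnables(x) / 1e6,
              paste(x$input_shape, collapse = "x"), x$num_classes))
  invisible(x)
}

#' Serialize an architecture graph to a JSON layer list
#'
#' @param graph an `architecture_graph`.
#' @param path optional file; when omitted the JSON string is returned.
#' @export
graph_to_json <- function(graph, path = NULL) {
  s <- graph_summary(graph)
  nodes <- lapply(seq_along(graph$nodes), function(i) {
    nd <- graph$nodes[[i]]
    c(nd[setdiff(names(nd), "inputs")],
      list(inputs = I(nd$inputs), output_shape = s$output_shape[i],
           learnables = s$learnables[i]))
  })
  js <- jsonlite::toJSON(list(name = graph$name,
                              input_shape = graph$input_shape,
                              num_classes = graph$num_classes,
                              layers = nodes),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
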