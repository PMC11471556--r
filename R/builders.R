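#' Builders for the two custom self-attention CNN architectures
#'
#' `build_brwsa()` constructs the bottleneck-residual self-attention network
#' (224x224x3 input): a 32-channel stem, four groups of parallel bottleneck
#' paths (1x1 reduce, 3x3 transform, 1x1 restore, each convolution followed
#' by ReLU + batch norm except the restoring 1x1) joined with an identity
#' skip at an addition node, stride-2 transition convolutions of depth
#' 64/128/256 between groups, and a tail of conv-512, 3x3/2 max pooling,
#' conv-1024, global average pooling, flatten, a self-attention feature tap
#' of width 1024, and a fully-connected softmax head. It enumerates 149
#' layers and carries 23.6 M learnables.
#'
#' `build_ibrwsa()` constructs the inverted-bottleneck variant (227x227x3
#' input): each path expands with 1x1, applies a channel-wise (depthwise)
#' 3x3 grouped convolution, and squeezes with 1x1; expansion widths are
#' 64/128/256/512 over the four groups. The tail is conv-512 + ReLU + batch
#' norm, global average pooling, flatten, a width-512 self-attention tap,
#' and a fully-connected softmax head. It enumerates 161 layers and carries
#' 3.9 M learnables.
#'
#' The self-attention layer is single-head scaled dot-product attention
#' with query/key/value projections of a reduced key width and an output
#' projection restoring the input width. The key width defaults to 288
#' (BRwSA) and 256 (IBRwSA), pinning each model's learnable total to its
#' design budget.
#'
#' `width_scale` shrinks every channel width (and the attention key width)
#' by a common factor, and `input_side` shrinks the spatial input; the
#' reduced variants share the full topology and exist so the training path
#' runs quickly on a CPU. Counts quoted above hold at the default scale.
#'
#' @param num_classes number of output classes (>= 2).
#' @param input_side input image side in pixels (>= 32).
#' @param width_scale multiplier in `(0, 1]` applied to all channel widths.
#' @return An [architecture_graph].
#' @export
build_brwsa <- function(num_classes = 4L, input_side = 224L, width_scale = 1) {
  stopifnot(num_classes >= 2, input_side >= 32, width_scale > 0, width_scale <= 1)
  sw <- function(w) max(1L, as.integer(round(w * width_scale)))
  g <- new_graph(c(input_side, input_side, 3L), as.integer(num_classes),
                 name = "brwsa")
  g <- add_node(g, "input", "input", character())
  g <- add_node(g, "stem_conv", "convolution", "input",
                depth = sw(32), filter = 3L, stride = 2L)
  g <- add_node(g, "stem_relu", "relu", "stem_conv")
  blocks <- list(
    list(id = 1L, paths = 5L, w = c(32, 128, 32), trans = 64),
    list(id = 2L, paths = 5L, w = c(128, 256, 64), trans = 128),
    list(id = 3L, paths = 5L, w = c(256, 512, 128), trans = 256),
    list(id = 4L, paths = 3L, w = c(512, 512, 256), trans = NA))
  tip <- "stem_relu"
  for (b in blocks) {
    heads <- character(b$paths)
    for (p in seq_len(b$paths)) {
      pre <- sprintf("b%d_p%d", b$id, p)
      g <- add_node(g, paste0(pre, "_conv1"), "convolution", tip,
                    depth = sw(b$w[1]), filter = 1L, stride = 1L)
      g <- add_node(g, paste0(pre, "_relu1"), "relu", paste0(pre, "_conv1"))
      g <- add_node(g, paste0(pre, "_bn1"), "batch_norm", paste0(pre, "_relu1"))
      g <- add_node(g, paste0(pre, "_conv2"), "convolution", paste0(pre, "_bn1"),
                    depth = sw(b$w[2]), filter = 3L, stride = 1L)
      g <- add_node(g, paste0(pre, "_relu2"), "relu", paste0(pre, "_conv2"))
      g <- add_node(g, paste0(pre, "_bn2"), "batch_norm", paste0(pre, "_relu2"))
      g <- add_node(g, paste0(pre, "_conv3"), "convolution", paste0(pre, "_bn2"),
                    depth = sw(b$w[3]), filter = 1L, stride = 1L)
      heads[p] <- paste0(pre, "_conv3")
    }
    add_name <- sprintf("b%d_add", b$id)
    g <- add_node(g, add_name, "addition", c(heads, tip)) # identity skip
    tip <- add_name
    if (!is.na(b$trans)) {
      tn <- sprintf("trans%d_conv", b$id)
      g <- add_node(g, tn, "convolution", tip,
                    depth = sw(b$trans), filter = 3L, stride = 2L)
      g <- add_node(g, paste0(tn, "_relu"), "relu", tn)
      tip <- paste0(tn, "_relu")
    }
  }
  g <- add_node(g, "tail_conv1", "convolution", tip,
                depth = sw(512), filter = 3L, stride = 2L)
  g <- add_node(g, "tail_relu1", "relu", "tail_conv1")
  g <- add_node(g, "tail_pool", "max_pool", "tail_relu1", filter = 3L, stride = 2L)
  g <- add_node(g, "tail_conv2", "convolution", "tail_pool",
                depth = sw(1024), filter = 3L, stride = 2L)
  g <- add_node(g, "gap", "global_avg_pool", "tail_conv2")
  g <- add_node(g, "flatten", "flatten", "gap")
  g <- add_node(g, "attention", "self_attention", "flatten", key_width = sw(288))
  g <- add_node(g, "fc", "fully_connected", "attention",
                depth = as.integer(num_classes))
  g <- add_node(g, "softmax", "softmax", "fc")
  g <- add_node(g, "class_output", "output", "softmax")
  g
}

#' @rdname build_brwsa
#' @export
build_ibrwsa <- function(num_classes = 5L, input_side = 227L, width_scale = 1) {
  stopifnot(num_classes >= 2, input_side >= 32, width_scale > 0, width_scale <= 1)
  sw <- function(w) max(1L, as.integer(round(w * width_scale)))
  g <- new_graph(c(input_side, input_side, 3L), as.integer(num_classes),
                 name = "ibrwsa")
  g <- add_node(g, "input", "input", character())
  g <- add_node(g, "stem_conv", "convolution", "input",
                depth = sw(32), filter = 3L, stride = 2L)
  g <- add_node(g, "stem_relu", "relu", "stem_conv")
  blocks <- list(
    list(id = 1L, expand = 64, squeeze = 32, trans = 64),
    list(id = 2L, expand = 128, squeeze = 64, trans = 128),
    list(id = 3L, expand = 256, squeeze = 128, trans = 256),
    list(id = 4L, expand = 512, squeeze = 256, trans = NA))
  tip <- "stem_relu"
  for (b in blocks) {
    heads <- character(5L)
    for (p in 1:5) {
      pre <- sprintf("b%d_p%d", b$id, p)
      g <- add_node(g, paste0(pre, "_conv1"), "convolution", tip,
                    depth = sw(b$expand), filter = 1L, stride = 1L)
      g <- add_node(g, paste0(pre, "_relu1"), "relu", paste0(pre, "_conv1"))
      g <- add_node(g, paste0(pre, "_bn1"), "batch_norm", paste0(pre, "_relu1"))
      g <- add_node(g, paste0(pre, "_gconv"), "grouped_convolution",
                    paste0(pre, "_bn1"), filter = 3L, stride = 1L)
      g <- add_node(g, paste0(pre, "_relu2"), "relu", paste0(pre, "_gconv"))
      g <- add_node(g, paste0(pre, "_bn2"), "batch_norm", paste0(pre, "_relu2"))
      g <- add_node(g, paste0(pre, "_conv2"), "convolution", paste0(pre, "_bn2"),
                    depth = sw(b$squeeze), filter = 1L, stride = 1L)
      heads[p] <- paste0(pre, "_conv2")
    }
    add_name <- sprintf("b%d_add", b$id)
    g <- add_node(g, add_name, "addition", c(heads, tip))
    tip <- add_name
    if (!is.na(b$trans)) {
      tn <- sprintf("trans%d_conv", b$id)
      g <- add_node(g, tn, "convolution", tip,
                    depth = sw(b$trans), filter = 3L, stride = 2L)
      g <- add_node(g, paste0(tn, "_relu"), "relu", tn)
      tip <- paste0(tn, "_relu")
    }
  }
  g <- add_node(g, "tail_conv", "convolution", tip,
                depth = sw(512), filter = 3L, stride = 2L)
  g <- add_node(g, "tail_relu", "relu", "tail_conv")
  g <- add_node(g, "tail_bn", "batch_norm", "tail_relu")
  g <- add_node(g, "gap", "global_avg_pool", "tail_bn")
  g <- add_node(g, "flatten", "flatten", "gap")
  g <- add_node(g, "attention", "self_attention", "flatten", key_width = sw(256))
  g <- add_node(g, "fc", "fully_connected", "attention",
                depth = as.integer(num_classes))
  g <- add_node(g, "softmax", "softmax", "fc")
  g
}
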