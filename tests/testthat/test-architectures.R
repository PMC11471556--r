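test_that("BRwSA builder matches its printed layer and parameter totals", {
  g <- build_brwsa(4)
  expect_identical(count_layers(g), 149L)
  expect_equal(round(count_learnables(g) / 1e6, 1), 23.6)
  expect_identical(extract_feature_width(g), 1024L)
})

test_that("IBRwSA builder matches its printed layer and parameter totals", {
  g <- build_ibrwsa(5)
  expect_identical(count_layers(g), 161L)
  expect_equal(round(count_learnables(g) / 1e6, 1), 3.9)
  expect_identical(extract_feature_width(g), 512L)
})

test_that("graph construction rejects bad edges and duplicate names", {
  g <- leafsight:::new_graph(c(8, 8, 3), 2)
  g <- leafsight:::add_node(g, "input", "input", character())
  expect_error(leafsight:::add_node(g, "fc", "fully_connected", "nope",
                                    depth = 2L), "unknown parent")
  expect_error(leafsight:::add_node(g, "input", "input", character()),
               "duplicate")
})

test_that("toy graphs count layers and learnables in closed form", {
  g <- leafsight:::new_graph(c(8, 8, 3), 2)
  g <- leafsight:::add_node(g, "input", "input", character())
  g <- leafsight:::add_node(g, "conv", "convolution", "input",
                            depth = 32L, filter = 3L, stride = 1L)
  g <- leafsight:::add_node(g, "relu", "relu", "conv")
  g <- leafsight:::add_node(g, "gap", "global_avg_pool", "relu")
  g <- leafsight:::add_node(g, "flatten", "flatten", "gap")
  g <- leafsight:::add_node(g, "fc", "fully_connected", "flatten", depth = 2L)
  g <- leafsight:::add_node(g, "softmax", "softmax", "fc")
  g <- leafsight:::add_node(g, "out", "output", "softmax")
  expect_identical(count_layers(g), 8L)
  # conv 3x3 3->32 (896) + fc 32->2 (66)
  expect_identical(count_learnables(g), 3 * 3 * 3 * 32 + 32 + 32 * 2 + 2)

  # depthwise convolution: one filter per channel
  gd <- leafsight:::new_graph(c(8, 8, 64), 2)
  gd <- leafsight:::add_node(gd, "input", "input", character())
  gd <- leafsight:::add_node(gd, "dw", "grouped_convolution", "input",
                             filter = 3L, stride = 1L)
  expect_identical(count_learnables(gd), 3 * 3 * 64 + 64)

  # attention width 8 with key width 4: 3*(8*4+4) + 4*8 + 8
  ga <- leafsight:::new_graph(c(2, 2, 2), 2)
  ga <- leafsight:::add_node(ga, "input", "input", character())
  ga <- leafsight:::add_node(ga, "flatten", "flatten", "input")
  ga <- leafsight:::add_node(ga, "att", "self_attention", "flatten",
                             key_width = 4L)
  expect_identical(extract_feature_width(ga), 8L)
  expect_identical(count_learnables(ga), 3 * (8 * 4 + 4) + 4 * 8 + 8)
  expect_error(extract_feature_width(build_brwsa(4)), NA)
})

test_that("every grouped convolution in IBRwSA is channel-wise", {
  g <- build_ibrwsa(5)
  shapes <- infer_shapes(g)
  gnodes <- Filter(function(n) n$kind == "grouped_convolution", g$nodes)
  expect_length(gnodes, 20L) # 5 paths x 4 blocks
  for (nd in gnodes) {
    cin <- shapes[[nd$inputs[1]]][3]
    # output channels equal input channels: one group per channel
    expect_identical(shapes[[nd$name]][3], cin)
  }
})

test_that("shape inference validates addition nodes and reduced variants scale", {
  g <- leafsight:::new_graph(c(8, 8, 3), 2)
  g <- leafsight:::add_node(g, "input", "input", character())
  g <- leafsight:::add_node(g, "c1", "convolution", "input",
                            depth = 4L, filter = 3L, stride = 1L)
  g <- leafsight:::add_node(g, "c2", "convolution", "input",
                            depth = 8L, filter = 3L, stride = 1L)
  g <- leafsight:::add_node(g, "add", "addition", c("c1", "c2"))
  expect_error(infer_shapes(g), "shape-mismatched")

  for (builder in list(build_brwsa, build_ibrwsa)) {
    rg <- builder(3, input_side = 32, width_scale = 1 / 16)
    expect_identical(count_layers(rg), count_layers(builder(3)))
    expect_lt(count_learnables(rg), count_learnables(builder(3)) / 50)
    expect_error(infer_shapes(rg), NA)
  }
})

test_that("graph summaries and JSON serialization enumerate every node", {
  g <- build_brwsa(4)
  s <- graph_summary(g)
  expect_identical(nrow(s), 149L)
  expect_equal(sum(s$learnables), count_learnables(g))
  js <- jsonlite::fromJSON(graph_to_json(g))
  expect_identical(nrow(js$layers), 149L)
  expect_identical(js$name, "brwsa")
})
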