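# hand-built fitness context with full control over the holdout split
manual_ctx <- function(z, labels, train, val) {
  structure(list(z = z, labels = labels, train = train, val = sort(val),
                 m = ncol(z)), class = "fitness_context")
}

test_that("cost formula matches hand arithmetic to 1e-12", {
  # two distant clusters, 20 train + 10 holdout points, one holdout point
  # mislabeled so KNN accuracy is exactly 0.9
  m <- 1536L
  n <- 30L
  z <- matrix(0, n, m)
  labels <- c(rep(0L, 15), rep(1L, 15))
  z[labels == 0L, 1] <- -10; z[labels == 1L, 1] <- 10
  train <- c(1:10, 16:25)
  val <- c(11:15, 26:30)
  labels[11] <- 1L # sits at -10 but is labeled 1: always misclassified
  ctx <- manual_ctx(z, labels, train, val)
  cfg <- hlo_config(knn_k = 3L)

  mask100 <- integer(m); mask100[1:100] <- 1L
  expect_equal(hlo_fitness(mask100, ctx, cfg),
               0.82 * 0.1 + 0.02 * (100 / 1536), tolerance = 1e-12)

  # all features selected, accuracy 1 on a clean labeling
  labels[11] <- 0L
  ctx2 <- manual_ctx(z, labels, train, val)
  expect_equal(hlo_fitness(rep(1L, m), ctx2, cfg), 0.02, tolerance = 1e-12)

  # all-zero mask: worst error, no feature penalty
  expect_equal(hlo_fitness(integer(m), ctx2, cfg), 0.82, tolerance = 1e-12)
})

test_that("initialization seeds valid, evaluated knowledge databases", {
  cfg <- hlo_config(n_solutions = 10L, seed = 4L)
  count_ones <- function(bits) sum(bits) / length(bits)
  st1 <- leafsight:::with_seed(cfg$seed,
    initialize_population(8L, count_ones, cfg))
  st2 <- leafsight:::with_seed(cfg$seed,
    initialize_population(8L, count_ones, cfg))
  expect_identical(st1, st2)
  expect_length(st1$population, 10L)
  for (ind in st1$population) {
    expect_true(all(ind$bits %in% c(0L, 1L)))
    expect_equal(ind$cost, count_ones(ind$bits))
  }
  pop_costs <- vapply(st1$population, `[[`, numeric(1), "cost")
  expect_equal(st1$skd[[1]]$cost, min(pop_costs))
  # each individual's IKD starts with its own solution
  for (i in 1:10)
    expect_identical(st1$ikd[[i]][[1]]$bits, st1$population[[i]]$bits)
})

test_that("bit generation routes REL, IL and SL by the configured rates", {
  cfg <- hlo_config(pi = 0.85, pr = 0.1)
  ikd <- list(list(bits = rep(1L, 4), cost = 0.1))
  skd <- list(list(bits = rep(0L, 4), cost = 0.05))
  set.seed(1)
  expect_identical(generate_bit(2L, ikd, skd, cfg, rand = 0.5), 1L)  # IL
  expect_identical(generate_bit(2L, ikd, skd, cfg, rand = 0.9), 0L)  # SL
  rel <- replicate(50, generate_bit(2L, ikd, skd, cfg, rand = 0.05))
  expect_true(all(rel %in% c(0L, 1L)))
  expect_true(length(unique(rel)) == 2L) # fresh random bits, not copies
  expect_error(generate_bit(1L, list(), skd, cfg), "non-empty")
})

test_that("knowledge updates keep sorted, capped, deduplicated databases", {
  cfg <- hlo_config(g = 2L, h = 2L)
  st <- list(ikd = list(list(list(bits = c(1L, 1L), cost = 0.3),
                             list(bits = c(0L, 1L), cost = 0.5))),
             skd = list(list(bits = c(1L, 1L), cost = 0.3)))
  # worse than all entries, IKD full: unchanged
  st2 <- update_knowledge(st, 1L, c(0L, 0L), 0.9, cfg)
  expect_identical(st2$ikd[[1]], st$ikd[[1]])
  # better than SKD best: becomes SKD[0]
  st3 <- update_knowledge(st, 1L, c(1L, 0L), 0.1, cfg)
  expect_equal(st3$skd[[1]]$cost, 0.1)
  expect_identical(st3$skd[[1]]$bits, c(1L, 0L))
  # duplicate bits are kept once
  st4 <- update_knowledge(st3, 1L, c(1L, 0L), 0.1, cfg)
  expect_identical(st4$skd, st3$skd)
  expect_identical(st4$ikd[[1]], st3$ikd[[1]])
})

test_that("relearning clears only the stagnated individual's IKD", {
  cfg <- hlo_config(seed = 2L)
  fit <- function(bits) mean(bits)
  set.seed(9)
  st <- initialize_population(6L, fit, cfg)
  before_best <- st$skd[[1]]$cost
  st2 <- relearn(st, 3L, 6L, fit, cfg)
  expect_length(st2$ikd[[3]], 1L)
  expect_lte(st2$skd[[1]]$cost, before_best) # global best never regresses
  expect_identical(st2$ikd[[1]], st$ikd[[1]])
})

test_that("selection traces are monotone and reproducible; 0 iterations degenerate", {
  fx <- make_feature_matrix(n = 80, classes = 2, informative = 3,
                            redundant = 2, noise = 10, effect_size = 3,
                            seed = 5)
  cfg <- hlo_config(iterations = 25L, knn_k = 3L, seed = 6L)
  r1 <- select_features(fx$features, cfg)
  expect_true(all(diff(r1$trace) <= 0))
  r2 <- select_features(fx$features, cfg)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$trace, r2$trace)
  expect_equal(r1$reduced$values,
               fx$features$values[, r1$selected, drop = FALSE],
               ignore_attr = TRUE)

  # the final cost never exceeds the all-ones baseline
  ctx <- r1$context
  all_ones <- hlo_fitness(rep(1L, ncol(fx$features$values)), ctx, cfg)
  expect_lte(r1$cost, all_ones + 1e-12)

  cfg0 <- hlo_config(iterations = 0L, knn_k = 3L, seed = 6L)
  r0 <- select_features(fx$features, cfg0)
  expect_length(r0$trace, 0L)
  expect_true(all(r0$mask %in% c(0L, 1L)))

  d <- tidy(r1)
  expect_identical(nrow(d), 25L)
  expect_s3_class(autoplot(r1), "ggplot")
})

test_that("small-m selection reaches the exhaustive optimum in most seeds", {
  m <- 8L
  fx <- make_feature_matrix(n = 60, classes = 2, informative = 2,
                            redundant = 2, noise = 4, effect_size = 2.5,
                            seed = 8)
  cfg_base <- hlo_config(iterations = 60L, knn_k = 3L, n_solutions = 10L)
  hits <- 0L
  for (seed in 1:5) {
    cfg <- cfg_base; cfg$seed <- seed
    res <- select_features(fx$features, cfg)
    # exhaustive oracle over all 2^m masks on the same fitness landscape
    best <- Inf
    for (code in 0:(2^m - 1)) {
      bits <- as.integer(intToBits(code)[1:m])
      best <- min(best, hlo_fitness(bits, res$context, cfg))
    }
    if (abs(res$cost - best) < 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("hyperparameter tuning finds grid minima through binary encoding", {
  cfg <- hlo_config(iterations = 10L, seed = 3L)
  one <- tune_hyperparameters(list(lr = 0.1), function(p) p$lr, cfg)
  expect_equal(one$best$lr, 0.1)

  cfg2 <- hlo_config(iterations = 50L, seed = 4L)
  grid <- list(lr = c(0.1, 0.2), momentum = c(0.5, 0.9))
  obj <- function(p) (p$lr - 0.2)^2 + (p$momentum - 0.5)^2
  res <- tune_hyperparameters(grid, obj, cfg2)
  expect_equal(res$best, list(lr = 0.2, momentum = 0.5))

  flat <- tune_hyperparameters(grid, function(p) 1, cfg2)
  expect_equal(flat$objective, 1)

  nf <- tune_hyperparameters(list(a = c(1, 2)),
                             function(p) if (p$a == 1) Inf else 0.5, cfg2)
  expect_equal(nf$best$a, 2)
})
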