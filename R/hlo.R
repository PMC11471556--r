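#' Configuration for improved Human Learning Optimization
#'
#' Defaults follow the reference search settings: a population of 10
#' bit-string solutions evolved for 100 generations, random-exploration
#' probability `pr = 0.1`, individual-learning probability `pi - pr` with
#' `pi = 0.85` (social learning fills the rest), a 10-nearest-neighbour
#' holdout wrapper fitness with 30 % validation data, and the cost weights
#' `rho = 0.82` on the classification error and `sigma_feat = 0.02` on the
#' selected-feature fraction.
#'
#' @param n_solutions population size.
#' @param iterations number of generations.
#' @param pi cumulative probability bound of individual learning.
#' @param pr probability of random-exploration learning (`0 < pr < pi < 1`).
#' @param knn_k neighbours used by the wrapper fitness.
#' @param holdout_ratio validation fraction of the wrapper fitness.
#' @param rho weight of the error term in the cost.
#' @param sigma_feat weight of the selected-feature fraction in the cost.
#' @param g individual knowledge database (IKD) size per individual.
#' @param h social knowledge database (SKD) size.
#' @param stagnation_window generations without personal-best improvement
#'   before an individual's IKD is cleared by the relearning operator.
#' @param seed integer seed.
#' @return A list of class `hlo_config`.
#' @export
hlo_config <- function(n_solutions = 10L, iterations = 100L, pi = 0.85,
                       pr = 0.1, knn_k = 10L, holdout_ratio = 0.3,
                       rho = 0.82, sigma_feat = 0.02, g = 3L, h = 3L,
                       stagnation_window = 10L, seed = 1L) {
  stopifnot(pr > 0, pr < pi, pi < 1, holdout_ratio > 0, holdout_ratio < 1,
            knn_k >= 1, rho >= 0, sigma_feat >= 0, n_solutions >= 2,
            g >= 1, h >= 1, stagnation_window >= 1, iterations >= 0)
  structure(list(n_solutions = as.integer(n_solutions),
                 iterations = as.integer(iterations), pi = pi, pr = pr,
                 knn_k = as.integer(knn_k), holdout_ratio = holdout_ratio,
                 rho = rho, sigma_feat = sigma_feat, g = as.integer(g),
                 h = as.integer(h),
                 stagnation_window = as.integer(stagnation_window),
                 seed = as.integer(seed)),
            class = "hlo_config")
}

#' Holdout KNN wrapper fitness context
#'
#' Draws a single stratified train/holdout split of the feature matrix and
#' pre-computes z-scoring statistics on the training part, so every mask
#' evaluation during a selection run sees the same fitness landscape.
#'
#' @param features a [feature_matrix()].
#' @param cfg an [hlo_config()].
#' @return A list of class `fitness_context`.
#' @export
fitness_context <- function(features, cfg = hlo_config()) {
  stopifnot(inherits(features, "feature_matrix"))
  n <- nrow(features$values)
  with_seed(derive_seed(cfg$seed, "holdout"), {
    val <- integer()
    for (k in sort(unique(features$labels))) {
      idx <- sample(which(features$labels == k))
      n_val <- max(1L, round(cfg$holdout_ratio * length(idx)))
      val <- c(val, idx[seq_len(n_val)])
    }
    train <- setdiff(seq_len(n), val)
    mu <- colMeans(features$values[train, , drop = FALSE])
    sd <- apply(features$values[train, , drop = FALSE], 2L, stats::sd)
    sd[sd < 1e-12] <- 1
    z <- sweep(sweep(features$values, 2L, mu), 2L, sd, "/")
    structure(list(z = z, labels = features$labels, train = train,
                   val = sort(val), m = ncol(features$values)),
              class = "fitness_context")
  })
}

#' Wrapper fitness of a feature mask
#'
#' `COST = rho * ERROR + sigma_feat * (selected / m)` where
#' `ERROR = 1 - ACCURACY` of a k-nearest-neighbour classifier (Euclidean
#' distance on z-scored columns) fit on the context's training part and
#' scored on its holdout part, restricted to the columns the mask selects.
#' An all-zero mask leaves the classifier undefined and is assigned the
#' worst error (cost `rho`).
#'
#' @param bits 0/1 vector of length `m` (the feature-inclusion mask).
#' @param ctx a [fitness_context()].
#' @param cfg an [hlo_config()].
#' @return The scalar cost.
#' @export
hlo_fitness <- function(bits, ctx, cfg = hlo_config()) {
  stopifnot(length(bits) == ctx$m, all(bits %in% c(0, 1)))
  sel <- which(bits == 1)
  if (!length(sel)) return(cfg$rho)
  k <- min(cfg$knn_k, length(ctx$train))
  pred <- class::knn(ctx$z[ctx$train, sel, drop = FALSE],
                     ctx$z[ctx$val, sel, drop = FALSE],
                     factor(ctx$labels[ctx$train]), k = k)
  acc <- mean(pred == factor(ctx$labels[ctx$val],
                             levels = levels(factor(ctx$labels[ctx$train]))))
  cfg$rho * (1 - acc) + cfg$sigma_feat * (length(sel) / ctx$m)
}

# knowledge-database helpers: entries are lists(bits, cost) kept sorted
# ascending by cost, capped at `cap`, without duplicate bit patterns
kd_insert <- function(kd, bits, cost, cap) {
  for (e in kd) if (identical(e$bits, bits)) return(kd)
  if (length(kd) >= cap && cost >= kd[[length(kd)]]$cost) return(kd)
  kd[[length(kd) + 1L]] <- list(bits = bits, cost = cost)
  kd <- kd[order(vapply(kd, `[[`, numeric(1), "cost"))]
  if (length(kd) > cap) kd <- kd[seq_len(cap)]
  kd
}

#' Initialize an HLO population and knowledge state
#'
#' Bits are sampled uniformly over `{0, 1}`; every individual is evaluated,
#' its IKD is seeded with its own solution, and the SKD with the best `h`
#' solutions overall.
#'
#' @param m bit-string length.
#' @param fitness_fn function of a bit vector returning a cost.
#' @param cfg an [hlo_config()].
#' @return A list with `population` (list of `list(bits, cost)`), `ikd`
#'   (per-individual lists) and `skd`.
#' @export
initialize_population <- function(m, fitness_fn, cfg = hlo_config()) {
  pop <- vector("list", cfg$n_solutions)
  ikd <- vector("list", cfg$n_solutions)
  skd <- list()
  for (i in seq_len(cfg$n_solutions)) {
    bits <- sample(c(0L, 1L), m, replace = TRUE)
    cost <- fitness_fn(bits)
    pop[[i]] <- list(bits = bits, cost = cost)
    ikd[[i]] <- kd_insert(list(), bits, cost, cfg$g)
    skd <- kd_insert(skd, bits, cost, cfg$h)
  }
  list(population = pop, ikd = ikd, skd = skd)
}

#' Generate one bit by the HLO operator mix
#'
#' With probability `pr` the bit is fresh random exploration; with
#' probability `pi - pr` it is copied from a uniformly chosen entry of the
#' individual's IKD (individual learning); otherwise from a uniformly
#' chosen SKD entry (social learning).
#'
#' @param j bit index.
#' @param ikd_i the individual's IKD (non-empty list).
#' @param skd the SKD (non-empty list).
#' @param cfg an [hlo_config()].
#' @param rand uniform draw in `[0, 1)` deciding the operator; two further
#'   draws are taken internally for the choice of entry/bit.
#' @return A bit in `{0, 1}`.
#' @export
generate_bit <- function(j, ikd_i, skd, cfg = hlo_config(),
                         rand = stats::runif(1)) {
  if (!length(ikd_i) || !length(skd))
    stop("knowledge databases must be non-empty", call. = FALSE)
  if (rand < cfg$pr) {
    if (stats::runif(1) < 0.5) 0L else 1L
  } else if (rand < cfg$pi) {
    e <- ikd_i[[sample.int(length(ikd_i), 1L)]]
    e$bits[j]
  } else {
    e <- skd[[sample.int(length(skd), 1L)]]
    e$bits[j]
  }
}

#' Insert an evaluated candidate into the knowledge state
#'
#' The candidate enters the individual's IKD if the IKD is not full or the
#' candidate beats its worst entry, and likewise the SKD; both stay sorted
#' ascending by cost and deduplicate identical bit patterns.
#'
#' @param state list with `ikd` and `skd` as produced by
#'   [initialize_population()].
#' @param i individual index.
#' @param bits,cost the evaluated candidate.
#' @param cfg an [hlo_config()].
#' @return The updated state.
#' @export
update_knowledge <- function(state, i, bits, cost, cfg = hlo_config()) {
  state$ikd[[i]] <- kd_insert(state$ikd[[i]], bits, cost, cfg$g)
  state$skd <- kd_insert(state$skd, bits, cost, cfg$h)
  state
}

#' Relearning: clear a stagnated individual's IKD
#'
#' The IKD is wiped and re-seeded with a freshly sampled evaluated random
#' solution; the SKD is untouched, so the global best never regresses.
#'
#' @param state knowledge state.
#' @param i individual index.
#' @param m bit-string length.
#' @param fitness_fn fitness function.
#' @param cfg an [hlo_config()].
#' @return The updated state.
#' @export
relearn <- function(state, i, m, fitness_fn, cfg = hlo_config()) {
  bits <- sample(c(0L, 1L), m, replace = TRUE)
  cost <- fitness_fn(bits)
  state$ikd[[i]] <- kd_insert(list(), bits, cost, cfg$g)
  state$skd <- kd_insert(state$skd, bits, cost, cfg$h)
  state
}

# Core improved-HLO loop over an arbitrary fitness function. Returns the
# final state, the best solution and the per-generation best-cost trace.
hlo_run <- function(m, fitness_fn, cfg) {
  with_seed(cfg$seed, {
    state <- initialize_population(m, fitness_fn, cfg)
    trace <- numeric(cfg$iterations)
    stag <- integer(cfg$n_solutions)
    pbest <- vapply(state$ikd, function(kd) kd[[1]]$cost, numeric(1))
    for (it in seq_len(cfg$iterations)) {
      for (i in seq_len(cfg$n_solutions)) {
        draws <- stats::runif(m)
        bits <- integer(m)
        for (j in seq_len(m))
          bits[j] <- generate_bit(j, state$ikd[[i]], state$skd, cfg, draws[j])
        cost <- fitness_fn(bits)
        state <- update_knowledge(state, i, bits, cost, cfg)
        state$population[[i]] <- list(bits = bits, cost = cost)
        if (state$ikd[[i]][[1]]$cost < pbest[i] - 1e-15) {
          pbest[i] <- state$ikd[[i]][[1]]$cost
          stag[i] <- 0L
        } else {
          stag[i] <- stag[i] + 1L
        }
        if (stag[i] >= cfg$stagnation_window) {
          state <- relearn(state, i, m, fitness_fn, cfg)
          pbest[i] <- state$ikd[[i]][[1]]$cost
          stag[i] <- 0L
        }
      }
      trace[it] <- state$skd[[1]]$cost
    }
    list(state = state, best = state$skd[[1]], trace = trace)
  })
}

# Bayesian-inference refinement: a per-bit Beta(1,1) posterior over
# inclusion is updated from the SKD members weighted by rank (best member
# weighted h, worst weighted 1); bits with posterior mean > 0.5 are kept.
# Falls back to the best SKD member if the thresholded mask scores worse.
bayes_refine <- function(skd, fitness_fn) {
  h <- length(skd)
  w <- rev(seq_len(h))
  bits_mat <- do.call(rbind, lapply(skd, `[[`, "bits"))
  alpha <- 1 + colSums(bits_mat * w)
  beta <- 1 + colSums((1 - bits_mat) * w)
  mask <- as.integer(alpha / (alpha + beta) > 0.5)
  cost <- fitness_fn(mask)
  if (cost <= skd[[1]]$cost) list(bits = mask, cost = cost) else skd[[1]]
}

#' Select features with improved Human Learning Optimization
#'
#' Runs the binary HLO loop (individual/social/random-exploration learning
#' with stagnation-triggered relearning) against the holdout-KNN wrapper
#' fitness, then applies a Bayesian-inference refinement over the social
#' knowledge database to pick the final mask.
#'
#' @param features a [feature_matrix()] with at least `2 * knn_k` rows.
#' @param cfg an [hlo_config()].
#' @return A list of class `hlo_result`: `mask` (0/1 vector), `cost`,
#'   `reduced` (the [feature_matrix()] restricted to selected columns),
#'   `trace` (per-generation best cost, non-increasing), `selected`
#'   (column indices) and `context`.
#' @export
select_features <- function(features, cfg = hlo_config()) {
  stopifnot(inherits(features, "feature_matrix"))
  if (nrow(features$values) < 2 * cfg$knn_k)
    stop("need at least 2 * knn_k samples", call. = FALSE)
  ctx <- fitness_context(features, cfg)
  fit <- function(bits) hlo_fitness(bits, ctx, cfg)
  run <- hlo_run(ctx$m, fit, cfg)
  best <- if (cfg$iterations > 0L)
    with_seed(derive_seed(cfg$seed, "refine"), bayes_refine(run$state$skd, fit))
  else run$best
  sel <- which(best$bits == 1)
  reduced <- feature_matrix(features$values[, sel, drop = FALSE],
                            features$labels, features$tags[sel])
  structure(list(mask = best$bits, cost = best$cost, reduced = reduced,
                 trace = run$trace, selected = sel, context = ctx,
                 cfg = cfg),
            class = "hlo_result")
}

#' @export
print.hlo_result <- function(x, ...) {
  cat(sprintf("<hlo_result> %d/%d features selected, final cost %.4f\n",
              length(x$selected), length(x$mask), x$cost))
  invisible(x)
}

#' Tidy the selection trace
#'
#' @param x an `hlo_result`.
#' @param ... unused.
#' @return a tibble with `generation` and `best_cost`.
#' @export
tidy.hlo_result <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$trace), best_cost = x$trace)
}

#' @rdname tidy.hlo_result
#' @export
glance.hlo_result <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected), m = length(x$mask),
                 cost = x$cost,
                 generations = length(x$trace))
}

#' Plot the best-cost trace of a selection run
#'
#' @param object an `hlo_result`.
#' @param ... unused.
#' @export
autoplot.hlo_result <- function(object, ...) {
  d <- tidy.hlo_result(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$best_cost)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best cost",
                  title = "HLO feature-selection trace")
}

#' Hyperparameter tuning by binary-encoded HLO
#'
#' Encodes each grid axis index as a binary sub-string, concatenates the
#' sub-strings into the HLO solution, and minimizes the objective over the
#' visited grid combinations (decoded indices wrap modulo the axis length).
#' Non-finite objective values are assigned the worst cost.
#'
#' @param grid named list of candidate vectors (each non-empty).
#' @param objective function taking one named combination (a list) and
#'   returning a scalar to minimize.
#' @param cfg an [hlo_config()].
#' @return A list with `best` (the winning combination), `objective` value
#'   and the cost `trace`.
#' @export
tune_hyperparameters <- function(grid, objective, cfg = hlo_config()) {
  stopifnot(length(grid) >= 1, all(lengths(grid) >= 1))
  n_bits <- pmax(1L, ceiling(log2(lengths(grid))))
  m <- sum(n_bits)
  decode <- function(bits) {
    out <- vector("list", length(grid)); names(out) <- names(grid)
    pos <- 0L
    for (a in seq_along(grid)) {
      bb <- bits[pos + seq_len(n_bits[a])]
      pos <- pos + n_bits[a]
      idx <- sum(bb * 2^(seq_along(bb) - 1L)) %% length(grid[[a]])
      out[[a]] <- grid[[a]][idx + 1L]
    }
    out
  }
  fit <- function(bits) {
    v <- objective(decode(bits))
    if (!is.finite(v)) 1e18 else v
  }
  run <- hlo_run(m, fit, cfg)
  list(best = decode(run$best$bits), objective = run$best$cost,
       trace = run$trace)
}
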