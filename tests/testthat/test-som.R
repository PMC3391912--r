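som_grid_records <- function() {
  # the standard 9x9 (T, sigma) grid with a smooth synthetic m surface
  g <- expand.grid(T = seq(10, 50, 5), sigma = seq(10, 50, 5))
  g$m <- 0.02 + 0.001 * (g$T - 10) / 5 - 0.0005 * abs(g$sigma - 35) / 5
  g
}

test_that("input normalisation is a unit-scaled bijection", {
  recs <- data.frame(T = c(10, 30, 50), sigma = c(20, 20, 20),
                     m = c(0.1, 0.5, 0.3))
  sc <- normalize_inputs(recs)
  expect_equal(sc$x[, "T"], c(0, 0.5, 1))
  expect_true(all(sc$x[, "sigma"] == 0))  # constant column guard
  # round trip on non-constant columns
  back <- termitory:::.unscale_inputs(sc$x, sc)
  expect_equal(back[, "T"], recs$T, tolerance = 1e-12)
  expect_equal(back[, "m"], recs$m, tolerance = 1e-12)
  expect_error(normalize_inputs(recs[1, ]), "at least 2")
})

test_that("SOM distance is the Euclidean norm and symmetric", {
  expect_equal(som_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(som_distance(c(0, 0, 0), c(1, 1, 1)), sqrt(3))
  set.seed(2)
  a <- runif(3); b <- runif(3)
  expect_equal(som_distance(a, b), som_distance(b, a))
  expect_error(som_distance(1:2, 1:3), "length")
})

test_that("training contracts onto a single repeated input vector", {
  x <- matrix(rep(c(0.3, 0.7, 0.2), each = 500), 500, 3)
  som <- train_som(x, som_config(rows = 3, cols = 3, n_iter = 500,
                                 rng_seed = 5))
  bmu <- termitory:::.som_bmu(som$weights, c(0.3, 0.7, 0.2))
  expect_lt(som_distance(som$weights[bmu, ], c(0.3, 0.7, 0.2)), 1e-3)
  expect_lte(som$qe_end, som$qe_start)
})

test_that("a zero learning rate leaves the weights untouched", {
  x <- matrix(runif(30), 10, 3)
  cfg <- som_config(rows = 2, cols = 3, n_iter = 50, alpha0 = 0,
                    alpha_min = 0, rng_seed = 3)
  set.seed(3)
  W0 <- matrix(runif(6 * 3, 0, 0.1), 6, 3)
  som <- train_som(x, cfg)
  expect_equal(som$weights, W0)
})

test_that("one winner update strictly reduces the winner's distance", {
  set.seed(6)
  for (rep in 1:20) {
    w <- runif(3); x <- runif(3)
    ah <- runif(1, 0.01, 0.99)  # alpha * h in (0, 1)
    w2 <- w + ah * (x - w)
    expect_lt(som_distance(w2, x), som_distance(w, x))
  }
})

test_that("the trained 6x7 map carries 42 prototypes and reduces error", {
  recs <- som_grid_records()
  sc <- normalize_inputs(recs)
  som <- train_som(sc, som_config(n_iter = 2000, rng_seed = 11))
  expect_equal(dim(som$weights), c(42L, 3L))
  expect_lte(som$qe_end, som$qe_start)
  # reproducible with the same seed
  som2 <- train_som(sc, som_config(n_iter = 2000, rng_seed = 11))
  expect_identical(som$weights, som2$weights)
})

test_that("Ward clustering yields singletons at k = n and non-decreasing merges", {
  recs <- som_grid_records()
  som <- train_som(normalize_inputs(recs),
                   som_config(n_iter = 2000, rng_seed = 13))
  cl <- ward_cluster(som, k = 42)
  expect_equal(sort(unique(cl$cluster)), 1:42)
  expect_false(is.unsorted(cl$hclust$height))

  cl8 <- ward_cluster(som, k = 8)
  expect_equal(length(unique(cl8$cluster)), 8L)
  expect_error(ward_cluster(som, k = 0), "k")
  expect_error(ward_cluster(som, k = 43), "k")
})

test_that("two separated prototype blobs split exactly at k = 2", {
  # plant prototypes directly and compare against exhaustive 2-partition
  # minimisation of within-cluster variance
  set.seed(9)
  blob <- rbind(matrix(runif(12, 0, 0.05), 4, 3),
                matrix(runif(18, 0.9, 0.95), 6, 3))
  som <- train_som(matrix(0.5, 2, 3),
                   som_config(rows = 2, cols = 5, n_iter = 1, rng_seed = 1))
  som$weights <- blob
  cl <- ward_cluster(som, k = 2)
  expect_equal(length(unique(cl$cluster[1:4])), 1L)
  expect_equal(length(unique(cl$cluster[5:10])), 1L)
  expect_false(cl$cluster[1] == cl$cluster[5])

  # exhaustive oracle over all 2-partitions of 10 nodes
  wss <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(scale(blob[idx, , drop = FALSE], scale = FALSE)^2)
  }
  best <- NULL
  for (code in 1:(2^9 - 1)) {
    a <- which(bitwAnd(2^(0:9), code * 2) > 0)  # subsets containing node 1
    a <- union(1L, a)
    b <- setdiff(1:10, a)
    if (length(b) == 0) next
    tot <- wss(a) + wss(b)
    if (is.null(best) || tot < best$tot) best <- list(a = sort(a), tot = tot)
  }
  expect_equal(best$a, 1:4)  # oracle agrees: blobs are the optimum
})

test_that("records project onto their best-matching node's cluster", {
  recs <- som_grid_records()
  sc <- normalize_inputs(recs)
  som <- train_som(sc, som_config(n_iter = 3000, rng_seed = 17))
  cl <- ward_cluster(som, k = 8)
  proj <- project_clusters(recs, som, cl)
  expect_equal(nrow(proj), 81L)
  expect_true(all(proj$cluster %in% 1:8))

  # a record equal to a prototype maps to that node
  w <- som$weights[20, ]
  rec <- as.data.frame(as.list(stats::setNames(
    termitory:::.unscale_inputs(matrix(w, 1), som$scaling)[1, ],
    c("T", "sigma", "m"))))
  p1 <- project_clusters(rec, som, cl)
  expect_equal(p1$node, 20L)
  expect_equal(p1$cluster, cl$cluster[20])

  # identical records, identical clusters; full (T, sigma) table covered
  p2 <- project_clusters(rbind(recs[5, ], recs[5, ]), som, cl)
  expect_equal(p2$cluster[1], p2$cluster[2])
  tab <- cluster_table(proj)
  expect_equal(dim(tab), c(9L, 9L))
  expect_false(anyNA(tab))
})
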