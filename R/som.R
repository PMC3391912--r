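# Kohonen self-organizing map over (T, sigma, m) records, followed by Ward
# clustering of the trained prototypes. The SOM is the classic online
# algorithm: per presentation the best-matching unit (minimum Euclidean
# distance between input and weight vector) and its map neighbourhood move
# towards the input, w(t+1) = w(t) + alpha(t) * h(t) * (x - w(t)), with a
# decreasing learning rate alpha(t).

#' SOM training configuration
#'
#' @param rows,cols Map dimensions (default 6 x 7).
#' @param n_iter Number of training presentations (default 10000).
#' @param alpha0,alpha_min Learning rate decays linearly from \code{alpha0}
#'   (default 0.5) to \code{alpha_min} (default 0.01) over \code{n_iter}.
#' @param radius0 Initial neighbourhood radius (map-grid distance); defaults
#'   to \code{max(rows, cols) / 2}, decaying linearly to 1.
#' @param rng_seed Seed for weight initialisation and presentation order, or
#'   \code{NULL} to use the current stream.
#' @return A validated list of class \code{som_config}.
#' @export
som_config <- function(rows = 6L, cols = 7L, n_iter = 10000L, alpha0 = 0.5,
                       alpha_min = 0.01, radius0 = NULL, rng_seed = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L ||
      rows * cols < 2L)
    stop("map must have at least 2 nodes", call. = FALSE)
  if (n_iter < 1L) stop("`n_iter` must be >= 1", call. = FALSE)
  if (alpha0 < 0 || alpha0 > 1 || alpha_min < 0 || alpha_min > alpha0)
    stop("need 0 <= alpha_min <= alpha0 <= 1", call. = FALSE)
  if (is.null(radius0)) radius0 <- max(rows, cols) / 2
  structure(list(rows = rows, cols = cols, n_iter = as.integer(n_iter),
                 alpha0 = alpha0, alpha_min = alpha_min,
                 radius0 = as.numeric(radius0),
                 rng_seed = if (is.null(rng_seed)) NULL else
                   as.integer(rng_seed)),
            class = "som_config")
}

#' Min-max normalisation of SOM input records
#'
#' Scales each input parameter to \[0, 1\]. Without scaling, parameters on
#' the raw T and sigma ranges (tens) would swamp the slope m (order 0.01–1)
#' in the Euclidean distance. A constant column maps to all zeros.
#'
#' @param records Matrix or data frame of input records (rows = records,
#'   columns = parameters, e.g. \code{T}, \code{sigma}, \code{m}).
#' @return List of class \code{som_scaling}: \code{x} (scaled matrix),
#'   \code{min} and \code{range} per column (range 1 for constant columns,
#'   recorded as 0-range via attribute \code{constant}).
#' @export
normalize_inputs <- function(records) {
  x <- as.matrix(records)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L)
    stop("need at least 2 records to normalise", call. = FALSE)
  mins <- apply(x, 2L, min)
  rng <- apply(x, 2L, max) - mins
  const <- rng == 0
  div <- ifelse(const, 1, rng)
  scaled <- sweep(sweep(x, 2L, mins, "-"), 2L, div, "/")
  scaled[, const] <- 0
  structure(list(x = scaled, min = mins, range = rng, constant = const),
            class = "som_scaling")
}

# inverse of normalize_inputs for non-constant columns
.unscale_inputs <- function(scaled, scaling) {
  div <- ifelse(scaling$constant, 1, scaling$range)
  sweep(sweep(scaled, 2L, div, "*"), 2L, scaling$min, "+")
}

.scale_with <- function(x, scaling) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  div <- ifelse(scaling$constant, 1, scaling$range)
  out <- sweep(sweep(x, 2L, scaling$min, "-"), 2L, div, "/")
  out[, scaling$constant] <- 0
  out
}

#' Euclidean distance between a weight vector and an input vector
#'
#' @param weight,x Numeric vectors of equal length.
#' @return The Euclidean norm of \code{x - weight}.
#' @export
#' @examples
#' som_distance(c(0, 0, 0), c(1, 1, 1))  # sqrt(3)
som_distance <- function(weight, x) {
  if (length(weight) != length(x))
    stop("`weight` and `x` must have the same length", call. = FALSE)
  sqrt(sum((as.numeric(x) - as.numeric(weight))^2))
}

# map-grid positions of the nodes, row-major (node index = (r-1)*cols + c)
.som_node_xy <- function(rows, cols) {
  cbind(r = rep(seq_len(rows), each = cols), c = rep(seq_len(cols), rows))
}

# best-matching unit: minimum Euclidean distance, ties to the lowest index
.som_bmu <- function(weights, x) {
  d2 <- colSums((t(weights) - x)^2)
  which.min(d2)
}

#' Train a self-organizing map
#'
#' Online Kohonen training on unit-scaled input vectors. Per presentation a
#' record is drawn uniformly, its best-matching unit (BMU; minimum Euclidean
#' distance, ties to the lowest node index) found, and the BMU and its
#' Gaussian map neighbourhood updated by
#' \code{w <- w + alpha * h * (x - w)}. The learning rate decays linearly
#' from \code{alpha0} to \code{alpha_min} and the neighbourhood radius from
#' \code{radius0} to 1 over \code{n_iter} presentations.
#'
#' @param x Numeric matrix of scaled input vectors (rows = records), e.g.
#'   the \code{x} element of \code{\link{normalize_inputs}}, or a
#'   \code{som_scaling} object.
#' @param config A \code{\link{som_config}}.
#' @return Object of class \code{som_grid}: list with \code{weights}
#'   (\code{rows*cols x P} matrix, row-major node order), \code{rows},
#'   \code{cols}, \code{node_xy}, \code{scaling} (when a \code{som_scaling}
#'   was supplied), \code{qe_start}/\code{qe_end} (mean quantization error
#'   before/after training) and \code{config}.
#' @export
train_som <- function(x, config = som_config()) {
  scaling <- NULL
  if (inherits(x, "som_scaling")) {
    scaling <- x
    x <- x$x
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) stop("no input vectors", call. = FALSE)
  stopifnot(inherits(config, "som_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  n_nodes <- config$rows * config$cols
  P <- ncol(x)
  # small random initial weights
  W <- matrix(runif(n_nodes * P, 0, 0.1), n_nodes, P)
  xy <- .som_node_xy(config$rows, config$cols)

  qe <- function(W) {
    mean(vapply(seq_len(nrow(x)), function(i) {
      sqrt(min(colSums((t(W) - x[i, ])^2)))
    }, numeric(1L)))
  }
  qe_start <- qe(W)

  n_iter <- config$n_iter
  frac <- if (n_iter > 1L) (seq_len(n_iter) - 1L) / (n_iter - 1L) else 0
  alphas <- config$alpha0 + (config$alpha_min - config$alpha0) * frac
  radii <- config$radius0 + (1 - config$radius0) * frac
  for (t in seq_len(n_iter)) {
    xi <- x[sample.int(nrow(x), 1L), ]
    bmu <- .som_bmu(W, xi)
    d2 <- (xy[, 1L] - xy[bmu, 1L])^2 + (xy[, 2L] - xy[bmu, 2L])^2
    h <- exp(-d2 / (2 * radii[t]^2))
    W <- W + alphas[t] * h * (matrix(xi, n_nodes, P, byrow = TRUE) - W)
  }

  structure(
    list(weights = W, rows = config$rows, cols = config$cols, node_xy = xy,
         scaling = scaling, qe_start = qe_start, qe_end = qe(W),
         config = config),
    class = "som_grid"
  )
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d map, P=%d, quantization error %.4f -> %.4f\n",
              x$rows, x$cols, ncol(x$weights), x$qe_start, x$qe_end))
  invisible(x)
}

#' Ward clustering of SOM prototypes
#'
#' Agglomerative clustering of the trained weight vectors under Ward's
#' minimum-variance criterion (\code{stats::hclust}, \code{"ward.D2"} on
#' Euclidean distances), cut into \code{k} clusters.
#'
#' @param som A trained \code{\link{train_som}} map.
#' @param k Number of clusters, \code{1 <= k <=} node count (default 8).
#' @return Object of class \code{som_clusters}: list with \code{cluster}
#'   (integer vector, one id in \code{1..k} per node), \code{k} and the
#'   \code{hclust} tree.
#' @export
ward_cluster <- function(som, k = 8L) {
  stopifnot(inherits(som, "som_grid"))
  n <- nrow(som$weights)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n)
    stop("`k` must be in [1, number of nodes]", call. = FALSE)
  hc <- stats::hclust(stats::dist(som$weights), method = "ward.D2")
  if (is.unsorted(hc$height))
    warning("Ward merge heights are not non-decreasing")
  cl <- if (k == 1L) rep(1L, n) else unname(stats::cutree(hc, k = k))
  structure(list(cluster = as.integer(cl), k = k, hclust = hc),
            class = "som_clusters")
}

#' Project records onto SOM clusters
#'
#' Maps each (T, sigma, m) record to its best-matching node and reports that
#' node's Ward cluster, giving the partition of the (T, sigma) parameter
#' plane by slope regime.
#'
#' @param records Data frame with the same parameter columns the map was
#'   trained on (e.g. \code{T}, \code{sigma}, \code{m}).
#' @param som A trained \code{som_grid} carrying its \code{scaling} (i.e.
#'   trained on a \code{som_scaling} object).
#' @param clusters A \code{\link{ward_cluster}} result for \code{som}.
#' @return \code{records} with added integer columns \code{node} and
#'   \code{cluster}.
#' @export
project_clusters <- function(records, som, clusters) {
  stopifnot(inherits(som, "som_grid"), inherits(clusters, "som_clusters"))
  if (is.null(som$scaling))
    stop("`som` must carry input scaling (train on normalize_inputs())",
         call. = FALSE)
  x <- .scale_with(records[, names(som$scaling$min), drop = FALSE],
                   som$scaling)
  node <- vapply(seq_len(nrow(x)), function(i) .som_bmu(som$weights, x[i, ]),
                 integer(1L))
  records$node <- node
  records$cluster <- clusters$cluster[node]
  records
}

#' Wide (T x sigma) cluster table
#'
#' @param projected Output of \code{\link{project_clusters}} with columns
#'   \code{T}, \code{sigma} and \code{cluster}.
#' @return Integer matrix with one row per T value and one column per sigma
#'   value, holding cluster ids.
#' @export
cluster_table <- function(projected) {
  stopifnot(all(c("T", "sigma", "cluster") %in% names(projected)))
  Ts <- sort(unique(projected$T))
  Ss <- sort(unique(projected$sigma))
  out <- matrix(NA_integer_, length(Ts), length(Ss),
                dimnames = list(T = Ts, sigma = Ss))
  out[cbind(match(projected$T, Ts), match(projected$sigma, Ss))] <-
    projected$cluster
  out
}
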