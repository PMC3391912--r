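# Territory-size analysis: extraction, rank-size aggregation over replicates,
# and the two-segment semi-log slope m of the large-territory regime.

#' Territory sizes of a grid
#'
#' Counts active + inactive cells per territory label. Territory size is a
#' cell count, not a hull area; the convex hull is visualization-only (see
#' \code{\link{convex_hull}}).
#'
#' @param grid A \code{cell_grid} with seeded territories.
#' @return Integer vector of length \code{N} (one entry per label, named by
#'   label); labels with no cells report 0.
#' @export
territory_sizes <- function(grid) {
  .check_grid(grid)
  N <- nrow(grid$seed_pos)
  occ <- grid$label[grid$state != .EMPTY]
  out <- tabulate(occ, nbins = N)
  names(out) <- seq_len(N)
  out
}

#' Replicate-averaged rank-size distribution
#'
#' Sorts each replicate's territory sizes in descending order and averages
#' rank-wise across replicates, giving the mean territory size \code{<A>} at
#' each rank.
#'
#' @param size_maps List of per-replicate size vectors (all of the same
#'   length \code{N}), e.g. outputs of \code{\link{territory_sizes}}.
#' @return Object of class \code{rank_size_dist}: list with \code{ranks}
#'   (\code{1..N}), \code{mean_size} (non-increasing) and
#'   \code{n_replicates}.
#' @export
#' @examples
#' rank_size_distribution(list(c(4, 2), c(6, 2)))$mean_size  # 5, 2
rank_size_distribution <- function(size_maps) {
  if (!is.list(size_maps) || length(size_maps) == 0L)
    stop("`size_maps` must be a non-empty list of size vectors", call. = FALSE)
  len <- vapply(size_maps, length, integer(1L))
  if (length(unique(len)) != 1L)
    stop("all replicates must have the same number of territories",
         call. = FALSE)
  N <- len[1L]
  ranked <- vapply(size_maps, function(s) sort(as.numeric(s),
                                               decreasing = TRUE),
                   numeric(N))
  mean_size <- if (N == 1L) mean(ranked) else rowMeans(ranked)
  structure(
    list(ranks = seq_len(N), mean_size = as.numeric(mean_size),
         n_replicates = length(size_maps)),
    class = "rank_size_dist"
  )
}

#' @export
print.rank_size_dist <- function(x, ...) {
  cat(sprintf("<rank_size_dist> N=%d ranks, %d replicate(s), <A> in [%.2f, %.2f]\n",
              length(x$ranks), x$n_replicates,
              min(x$mean_size), max(x$mean_size)))
  invisible(x)
}

#' Two-segment semi-log slope of a rank-size distribution
#'
#' The descending rank-size curve separates into a front region (the
#' larger-sized territories, which carry the climate signal) and a rear
#' region (the smaller territories, governed by early-stage competition). On
#' the semi-log scale (natural log of mean size vs linear rank) both regions
#' are close to linear. For every candidate breakpoint \code{b} in
#' \code{2..N-2} two least-squares lines are fitted to ranks \code{1..b} and
#' \code{b+1..N}; the breakpoint minimising the total residual sum of squares
#' wins (smallest \code{b} on ties). \code{m_front}, the absolute front
#' slope, is the statistic of interest: larger \code{m} means greater size
#' inequality among the large territories.
#'
#' @param dist A \code{\link{rank_size_distribution}} object, or a numeric
#'   vector of mean sizes in descending rank order.
#' @return Object of class \code{slope_fit}: list with \code{breakpoint},
#'   \code{m_front}, \code{m_rear} (absolute slopes, per rank) and \code{sse}.
#' @export
#' @examples
#' y <- exp(c(5 - 0.2 * (1:10), 3.2 - 0.01 * (1:20)))
#' fit_two_segment_slope(y)
fit_two_segment_slope <- function(dist) {
  y <- if (inherits(dist, "rank_size_dist")) dist$mean_size
       else as.numeric(dist)
  if (anyNA(y)) stop("mean sizes contain NA", call. = FALSE)
  if (any(y == 0)) {
    warning("dropping zero-size ranks before log transform")
    y <- y[y != 0]
  }
  if (any(y < 0)) stop("mean sizes must be positive", call. = FALSE)
  N <- length(y)
  if (N < 4L)
    stop("need at least 4 positive mean sizes for a two-segment fit",
         call. = FALSE)
  ly <- log(y)
  x <- seq_len(N)
  best <- NULL
  for (b in 2:(N - 2L)) {
    f <- stats::lm.fit(cbind(1, x[1:b]), ly[1:b])
    r <- stats::lm.fit(cbind(1, x[(b + 1L):N]), ly[(b + 1L):N])
    sse <- sum(f$residuals^2) + sum(r$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(breakpoint = b,
                   m_front = abs(unname(f$coefficients[2L])),
                   m_rear = abs(unname(r$coefficients[2L])),
                   sse = sse)
    }
  }
  structure(best, class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> breakpoint=%d m_front=%.4f m_rear=%.4f sse=%.4g\n",
              x$breakpoint, x$m_front, x$m_rear, x$sse))
  invisible(x)
}

#' Convex hull of territory member cells
#'
#' Convex polygon containing a territory's cell centres, as used to draw
#' territories. Degenerate inputs are allowed: a single cell yields a
#' one-vertex polygon, collinear cells a two-vertex segment.
#'
#' @param cells An \code{n x 2} matrix of (row, col) cell coordinates.
#' @return Matrix of hull vertices (counter-clockwise), columns
#'   \code{row, col}.
#' @export
convex_hull <- function(cells) {
  cells <- matrix(as.numeric(cells), ncol = 2L)
  if (nrow(cells) == 0L) stop("empty cell set", call. = FALSE)
  cells <- unique(cells)
  idx <- grDevices::chull(cells[, 2L], cells[, 1L])  # x = col, y = row
  out <- cells[idx, , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Convex hulls of every territory in a grid
#'
#' @param grid A \code{cell_grid}.
#' @return Named list (by label) of hull vertex matrices; territories with no
#'   cells are omitted.
#' @export
territory_hulls <- function(grid) {
  .check_grid(grid)
  occ <- which(grid$state != .EMPTY)
  labs <- grid$label[occ]
  out <- list()
  for (lb in sort(unique(labs))) {
    out[[as.character(lb)]] <- convex_hull(.lin_to_coord(occ[labs == lb],
                                                         grid$L))
  }
  out
}
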