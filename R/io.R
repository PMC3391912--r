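# Plain-text I/O: grid snapshots as integer matrices, landscape as a float
# matrix, CSV tables for sweep and SOM outputs, optional PNG render.

#' Export a simulation snapshot
#'
#' Writes the state and label layers as whitespace-separated integer
#' matrices (\code{<prefix>_state.txt}, \code{<prefix>_label.txt}), the
#' landscape as a float matrix (\code{<prefix>_landscape.txt}) when
#' available, and the per-cycle census as CSV
#' (\code{<prefix>_census.csv}: cycle, territory, size). With
#' \code{png = TRUE} also renders the territories (one colour each, empty
#' cells dark) to \code{<prefix>.png}.
#'
#' @param result A \code{territory_sim} from \code{\link{run_simulation}},
#'   or a bare \code{cell_grid}.
#' @param prefix Output path prefix (directories are created).
#' @param png Also write a PNG render (default \code{FALSE}).
#' @return Invisibly, the character vector of files written.
#' @export
export_snapshot <- function(result, prefix, png = FALSE) {
  grid <- if (inherits(result, "territory_sim")) result$final_grid else result
  .check_grid(grid)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(mat, path) {
    utils::write.table(mat, path, row.names = FALSE, col.names = FALSE)
    path
  }
  files <- c(files, wr(grid$state, paste0(prefix, "_state.txt")))
  files <- c(files, wr(grid$label, paste0(prefix, "_label.txt")))
  if (inherits(result, "territory_sim")) {
    files <- c(files, wr(format(result$landscape, digits = 17),
                         paste0(prefix, "_landscape.txt")))
    hist <- result$size_history
    if (nrow(hist) > 0) {
      census <- data.frame(
        cycle = rep(seq_len(nrow(hist)), each = ncol(hist)),
        territory = rep(seq_len(ncol(hist)), nrow(hist)),
        size = as.integer(t(hist)))
      p <- paste0(prefix, "_census.csv")
      utils::write.csv(census, p, row.names = FALSE)
      files <- c(files, p)
    }
  }
  if (isTRUE(png)) {
    p <- paste0(prefix, ".png")
    ok <- tryCatch({
      grDevices::png(p, width = 600, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot_grid(grid)
      TRUE
    }, error = function(e) {
      warning("PNG render failed: ", conditionMessage(e))
      FALSE
    })
    if (ok) files <- c(files, p)
  }
  invisible(files)
}

#' Read a grid snapshot back
#'
#' @param prefix The prefix used by \code{\link{export_snapshot}}.
#' @return A \code{cell_grid} (without \code{seed_pos}, which is not part of
#'   the snapshot; the label layer determines territory membership).
#' @export
read_snapshot <- function(prefix) {
  state <- as.matrix(utils::read.table(paste0(prefix, "_state.txt")))
  label <- as.matrix(utils::read.table(paste0(prefix, "_label.txt")))
  dimnames(state) <- dimnames(label) <- NULL
  storage.mode(state) <- "integer"
  storage.mode(label) <- "integer"
  g <- new_cell_grid(nrow(state))
  g$state <- state
  g$label <- label
  g
}

#' Plot a cell grid
#'
#' Territories in one colour each (inactive cells lighter, active darker),
#' empty cells near-black — the usual way these seasonal patterns are
#' inspected.
#'
#' @param grid A \code{cell_grid}.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot_grid <- function(grid, ...) {
  .check_grid(grid)
  N <- max(grid$label)
  z <- grid$label
  z[grid$state == .EMPTY] <- 0L
  cols <- c("grey10", grDevices::hcl.colors(max(N, 1L), "Spectral"))
  graphics::image(seq_len(grid$L), seq_len(grid$L), t(z[grid$L:1, ]),
                  col = cols, axes = FALSE, xlab = "", ylab = "",
                  useRaster = TRUE, ...)
  invisible(grid)
}

#' Write sweep results as CSV
#'
#' @param result A \code{\link{run_sweep}} result.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_sweep_csv <- function(result, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' Write a rank-size distribution as CSV
#'
#' @param dist A \code{\link{rank_size_distribution}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_rank_size_csv <- function(dist, path) {
  stopifnot(inherits(dist, "rank_size_dist"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(rank = dist$ranks, mean_size = dist$mean_size),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write SOM prototypes and clusters as CSV
#'
#' One row per node: map position, weight vector, Ward cluster id.
#'
#' @param som A trained \code{som_grid}.
#' @param clusters Matching \code{\link{ward_cluster}} result.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_som_csv <- function(som, clusters, path) {
  stopifnot(inherits(som, "som_grid"), inherits(clusters, "som_clusters"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  W <- som$weights
  nm <- if (!is.null(som$scaling)) names(som$scaling$min)
        else paste0("p", seq_len(ncol(W)))
  df <- data.frame(node_row = som$node_xy[, 1L], node_col = som$node_xy[, 2L])
  for (j in seq_len(ncol(W))) df[[paste0("w_", nm[j])]] <- W[, j]
  df$cluster <- clusters$cluster
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
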