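#' Simulation configuration
#'
#' Bundles and validates all parameters of one seasonal simulation.
#'
#' @param L Lattice side length in cells (default 200).
#' @param N Number of founding pairs / territory seeds (default 30).
#' @param T_summer Summer duration in synchronous iteration rounds
#'   (default 36, the summer duration of New Orleans, Louisiana).
#' @param sigma Percent of each territory's cells retained after winter
#'   shrinkage, in (0, 100] (default 20, the field contraction estimate for
#'   the Formosan subterranean termite).
#' @param n_react Cells reactivated per territory after shrinkage
#'   (default 5).
#' @param n_cycles Maximum number of summer–winter cycles (default 50).
#' @param steady_tol Relative change in total termite-cell count between
#'   consecutive post-summer censuses below which the run is declared steady
#'   (default 0.01).
#' @param rng_seed Master random seed for the run, or \code{NULL} to use the
#'   current R random number stream.
#' @return A validated list of class \code{sim_config}.
#' @seealso \code{\link{run_simulation}}, \code{\link{read_sim_config}}
#' @export
#' @examples
#' sim_config(L = 50, N = 10, T_summer = 10, sigma = 30, rng_seed = 1)
sim_config <- function(L = 200L, N = 30L, T_summer = 36L, sigma = 20,
                       n_react = 5L, n_cycles = 50L, steady_tol = 0.01,
                       rng_seed = NULL) {
  cfg <- list(L = as.integer(L), N = as.integer(N),
              T_summer = as.integer(T_summer), sigma = as.numeric(sigma),
              n_react = as.integer(n_react), n_cycles = as.integer(n_cycles),
              steady_tol = as.numeric(steady_tol),
              rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A \code{sim_config} to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  bad <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  with(cfg, {
    if (is.na(L) || L < 1) bad("L must be >= 1")
    if (is.na(N) || N < 1 || N > L^2) bad("N must be in [1, L^2]")
    if (is.na(T_summer) || T_summer < 0) bad("T_summer must be >= 0")
    if (is.na(sigma) || sigma <= 0 || sigma > 100)
      bad("sigma must be in (0, 100]")
    if (is.na(n_react) || n_react < 1) bad("n_react must be >= 1")
    if (is.na(n_cycles) || n_cycles < 0) bad("n_cycles must be >= 0")
    if (is.na(steady_tol) || steady_tol < 0) bad("steady_tol must be >= 0")
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> L=%d N=%d T_summer=%d sigma=%g n_react=%d n_cycles=%d steady_tol=%g seed=%s\n",
    x$L, x$N, x$T_summer, x$sigma, x$n_react, x$n_cycles, x$steady_tol,
    if (is.null(x$rng_seed)) "<stream>" else x$rng_seed))
  invisible(x)
}

#' Read a simulation configuration from JSON or YAML
#'
#' The file holds a flat mapping whose keys mirror the \code{\link{sim_config}}
#' arguments; missing keys fall back to the defaults. Format is selected by
#' extension (\code{.json} vs \code{.yml}/\code{.yaml}).
#'
#' @param path Path to the configuration file.
#' @return A validated \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, call. = FALSE))
  # YAML 1.1 reads a bare key `N` as boolean; undo that (N is the only
  # config field colliding with the yes/no literals)
  names(raw)[names(raw) %in% c("FALSE", "F")] <- "N"
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}
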