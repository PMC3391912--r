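# Summer growth rules.
#
# Each synchronous round every active cell makes one growth attempt: it
# samples one empty Moore neighbour with probability proportional to that
# neighbour's P_trans, and the attempt then succeeds with probability
# P_trans(target). Two territories can never share a site; when several
# successful attempts collide on one target, a single winner is drawn
# uniformly. A cell with no empty Moore neighbour is "stopped" — it can never
# grow again and turns inactive; so does any active cell surrounded by at
# least 7 inactive neighbours. A failed attempt or a lost conflict leaves the
# source active: it simply did not grow this round and may try again, which
# keeps the colonisation front alive until territories enclose themselves or
# collide with neighbours.

#' Propose one growth attempt from an active cell
#'
#' Samples a target among the empty Moore neighbours of \code{source} with
#' probability proportional to the landscape's \code{P_trans}, then draws the
#' Bernoulli success of tunneling into it. Used as the single-cell reference
#' of the rule applied synchronously by \code{\link{summer_step}}.
#'
#' @param grid A \code{cell_grid}.
#' @param land A \code{landscape} matrix of the same size.
#' @param source Integer coordinate \code{c(row, col)} of an active cell.
#' @return A list of class \code{growth_proposal} with elements
#'   \code{source}, \code{target} (coordinate, or \code{NULL} when no empty
#'   neighbour exists), \code{outcome} (\code{"success_pending"} or
#'   \code{"stopped"}) and \code{blocked} (\code{TRUE} when the cell had no
#'   empty Moore neighbour and can never grow again).
#' @export
#' @examples
#' set.seed(1)
#' g <- new_cell_grid(5)
#' g$state[3, 3] <- cell_states()["active"]; g$label[3, 3] <- 1L
#' land <- generate_landscape(5)
#' propose_growth(g, land, c(3, 3))
propose_growth <- function(grid, land, source) {
  .check_grid(grid)
  .check_landscape(land, grid$L)
  L <- grid$L
  lin <- .coord_to_lin(as.integer(source), L)
  if (grid$state[lin] != .ACTIVE)
    stop("`source` is not an active cell", call. = FALSE)
  nb <- .nbr_table(L)[lin, ]
  nb <- nb[!is.na(nb)]
  empty <- nb[grid$state[nb] == .EMPTY]
  if (length(empty) == 0L) {
    return(structure(list(source = as.integer(source), target = NULL,
                          outcome = "stopped", blocked = TRUE),
                     class = "growth_proposal"))
  }
  w <- land[empty]
  tgt <- if (length(empty) == 1L) empty else {
    if (all(w == 0)) empty[sample.int(length(empty), 1L)]
    else empty[sample.int(length(empty), 1L, prob = w)]
  }
  ok <- runif(1L) < land[tgt]
  structure(
    list(source = as.integer(source),
         target = as.integer(.lin_to_coord(tgt, L)[1L, ]),
         outcome = if (ok) "success_pending" else "stopped",
         blocked = FALSE),
    class = "growth_proposal"
  )
}

#' Resolve target conflicts among successful growth proposals
#'
#' Territories can never share a site: when several pending proposals aim at
#' the same target cell, one proposer is chosen uniformly at random (each of
#' k competitors wins with probability 1/k; for two competitors this is the
#' coin flip of the interaction rule). Losers have their outcome set to
#' \code{"stopped"} for this round.
#'
#' @param proposals List of \code{growth_proposal} objects with outcome
#'   \code{"success_pending"}.
#' @return The list with losers' \code{outcome} replaced by
#'   \code{"stopped"}; winners keep \code{"success_pending"}. Each element
#'   gains a logical field \code{won}.
#' @export
resolve_conflicts <- function(proposals) {
  if (length(proposals) == 0L) return(proposals)
  bad <- vapply(proposals, function(p) !identical(p$outcome, "success_pending"),
                logical(1L))
  if (any(bad))
    stop("all proposals must have outcome \"success_pending\"", call. = FALSE)
  key <- vapply(proposals, function(p) paste(p$target, collapse = ","),
                character(1L))
  r <- runif(length(proposals))
  o <- order(key, r)
  first <- !duplicated(key[o])
  won <- logical(length(proposals))
  won[o][first] <- TRUE
  for (i in seq_along(proposals)) {
    proposals[[i]]$won <- won[i]
    if (!won[i]) proposals[[i]]$outcome <- "stopped"
  }
  proposals
}

#' Apply state-changing rules
#'
#' Turns inactive (i) every cell listed in \code{stopped} and (ii) every
#' active cell currently surrounded by at least 7 inactive Moore neighbours.
#' Both conditions are evaluated on the grid as passed in (a single
#' synchronous change). Labels are untouched.
#'
#' @param grid A \code{cell_grid}.
#' @param stopped Coordinates of stopped active cells: an \code{n x 2}
#'   integer matrix (possibly with zero rows).
#' @return The updated grid.
#' @export
apply_state_changes <- function(grid, stopped = matrix(integer(0), 0L, 2L)) {
  .check_grid(grid)
  L <- grid$L
  stopped <- matrix(as.integer(stopped), ncol = 2L)
  if (nrow(stopped) > 0L) {
    lin <- (stopped[, 2L] - 1L) * L + stopped[, 1L]
    if (any(grid$state[lin] != .ACTIVE))
      stop("`stopped` must refer to active cells", call. = FALSE)
  } else lin <- integer(0)
  act <- which(grid$state == .ACTIVE)
  seven <- integer(0)
  if (length(act)) {
    nb <- .nbr_table(L)[act, , drop = FALSE]
    ok <- !is.na(nb)
    sv <- matrix(NA_integer_, length(act), 8L)
    sv[ok] <- grid$state[nb[ok]]
    seven <- act[rowSums(sv == .INACTIVE, na.rm = TRUE) >= 7L]
  }
  grid$state[c(lin, seven)] <- .INACTIVE
  grid
}

#' One synchronous summer round
#'
#' All active cells propose a growth attempt simultaneously; conflicting
#' successes are resolved uniformly; each winning target becomes an active
#' cell of the proposer's territory; finally blocked cells (no empty Moore
#' neighbour at the start of the round) and actives enclosed by 7+ inactive
#' neighbours turn inactive. The total number of termite cells never
#' decreases during summer. Uses the current R random number stream.
#'
#' Internally the round is fully vectorised; it is distributionally the
#' composition of \code{\link{propose_growth}} over all active cells,
#' \code{\link{resolve_conflicts}} and \code{\link{apply_state_changes}}.
#'
#' @param grid A \code{cell_grid}.
#' @param land Matching \code{landscape}.
#' @return The updated grid.
#' @export
summer_step <- function(grid, land) {
  .check_grid(grid)
  .check_landscape(land, grid$L)
  L <- grid$L
  A <- which(grid$state == .ACTIVE)
  n <- length(A)
  if (n == 0L) return(grid)

  nbt <- .nbr_table(L)
  NB <- nbt[A, , drop = FALSE]
  ok <- !is.na(NB)
  sNB <- matrix(NA_integer_, n, 8L)
  sNB[ok] <- grid$state[NB[ok]]
  W <- matrix(0, n, 8L)
  em <- ok & sNB == .EMPTY
  W[em] <- land[NB[em]]
  has_empty <- rowSums(em) > 0L
  rs <- rowSums(W)

  # target choice: inverse-CDF over the 8 weighted columns; cells whose empty
  # neighbours all have P_trans == 0 fall back to a uniform choice
  tgt <- rep(NA_integer_, n)
  if (any(has_empty)) {
    zw <- has_empty & rs == 0
    if (any(zw)) {
      W[zw, ] <- em[zw, , drop = FALSE] * 1.0
      rs <- rowSums(W)
    }
    u <- runif(n) * rs
    cum <- numeric(n)
    sel <- integer(n)
    for (j in seq_len(8L)) {
      cum <- cum + W[, j]
      pick <- has_empty & sel == 0L & u <= cum
      sel[pick] <- j
    }
    left <- has_empty & sel == 0L  # floating-point guard
    if (any(left)) sel[left] <- max.col(W[left, , drop = FALSE], "last")
    ii <- which(has_empty)
    tgt[ii] <- NB[cbind(ii, sel[ii])]
  }

  succ <- rep(FALSE, n)
  ii <- which(!is.na(tgt))
  if (length(ii)) succ[ii] <- runif(length(ii)) < land[tgt[ii]]

  winner <- integer(0)
  wi <- which(succ)
  if (length(wi)) {
    tv <- tgt[wi]
    r <- runif(length(wi))
    o <- order(tv, r)
    winner <- wi[o][!duplicated(tv[o])]
  }
  if (length(winner)) {
    grid$state[tgt[winner]] <- .ACTIVE
    grid$label[tgt[winner]] <- grid$label[A[winner]]
  }

  # state changes: blocked cells stop for good; 7-inactive enclosure is
  # evaluated on the post-growth state in the same synchronous change
  stopped_lin <- A[!has_empty]
  A2 <- which(grid$state == .ACTIVE)
  seven <- integer(0)
  if (length(A2)) {
    NB2 <- nbt[A2, , drop = FALSE]
    ok2 <- !is.na(NB2)
    sv <- matrix(NA_integer_, length(A2), 8L)
    sv[ok2] <- grid$state[NB2[ok2]]
    seven <- A2[rowSums(sv == .INACTIVE, na.rm = TRUE) >= 7L]
  }
  grid$state[c(stopped_lin, seven)] <- .INACTIVE
  grid
}

#' Run a full summer season
#'
#' Applies \code{\link{summer_step}} \code{T_summer} times. \code{T_summer}
#' is the climate variable T: the number of synchronous iteration rounds the
#' colony is active per year (T = 36 matches the summer duration of New
#' Orleans, Louisiana).
#'
#' @param grid A \code{cell_grid}.
#' @param land Matching \code{landscape}.
#' @param T_summer Number of rounds, \code{>= 0}.
#' @return The grid after \code{T_summer} rounds.
#' @export
run_summer <- function(grid, land, T_summer) {
  if (!is.numeric(T_summer) || length(T_summer) != 1L || is.na(T_summer) ||
      T_summer < 0)
    stop("`T_summer` must be a single integer >= 0", call. = FALSE)
  for (i in seq_len(as.integer(T_summer))) grid <- summer_step(grid, land)
  grid
}
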