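test_that("a lone empty neighbour with P_trans = 1 is always colonised", {
  g <- multi_territory_grid(3, list(rbind(c(2, 2))), "active")
  # surround the active cell with inactive cells except one empty site
  for (rc in list(c(1, 1), c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1),
                  c(3, 2))) {
    g$state[rc[1], rc[2]] <- cell_states()[["inactive"]]
    g$label[rc[1], rc[2]] <- 1L
  }
  land <- flat_landscape(3, 1)
  set.seed(1)
  p <- propose_growth(g, land, c(2, 2))
  expect_equal(p$outcome, "success_pending")
  expect_equal(p$target, c(3L, 3L))
  expect_false(p$blocked)
})

test_that("targets are sampled proportionally to P_trans", {
  # two empty neighbours with P 0.9 and 0.1; the rest inactive
  g <- new_cell_grid(3)
  g$state[] <- cell_states()[["inactive"]]; g$label[] <- 1L
  g$state[2, 2] <- cell_states()[["active"]]
  g$state[1, 2] <- 0L; g$label[1, 2] <- 0L   # top
  g$state[3, 2] <- 0L; g$label[3, 2] <- 0L   # bottom
  land <- flat_landscape(3, 0)
  land[1, 2] <- 0.9; land[3, 2] <- 0.1
  set.seed(99)
  n <- 1e4
  top <- 0L
  for (i in seq_len(n)) {
    p <- propose_growth(g, land, c(2, 2))
    if (identical(p$target, c(1L, 2L))) top <- top + 1L
  }
  expect_equal(top / n, 0.9, tolerance = 0.025)
})

test_that("a fully enclosed active cell is blocked and stopped", {
  g <- new_cell_grid(3)
  g$state[] <- cell_states()[["inactive"]]; g$label[] <- 1L
  g$state[2, 2] <- cell_states()[["active"]]
  p <- propose_growth(g, flat_landscape(3), c(2, 2))
  expect_equal(p$outcome, "stopped")
  expect_true(p$blocked)
  expect_null(p$target)
  expect_error(propose_growth(g, flat_landscape(3), c(1, 1)), "active")
})

test_that("conflict resolution picks a single uniform winner", {
  mk <- function(src) structure(list(source = src, target = c(5L, 5L),
                                     outcome = "success_pending",
                                     blocked = FALSE),
                                class = "growth_proposal")
  # single proposal always wins
  r <- resolve_conflicts(list(mk(c(4L, 4L))))
  expect_true(r[[1]]$won)
  expect_equal(r[[1]]$outcome, "success_pending")

  set.seed(3)
  n <- 4000
  wins2 <- 0L
  for (i in seq_len(n)) {
    r <- resolve_conflicts(list(mk(c(4L, 4L)), mk(c(6L, 6L))))
    expect_equal(sum(vapply(r, `[[`, logical(1), "won")), 1L)
    if (r[[1]]$won) wins2 <- wins2 + 1L
  }
  expect_equal(wins2 / n, 0.5, tolerance = 0.03)

  expect_error(resolve_conflicts(list(structure(
    list(source = c(1L, 1L), target = NULL, outcome = "stopped",
         blocked = TRUE), class = "growth_proposal"))), "success_pending")
  expect_identical(resolve_conflicts(list()), list())
})

test_that("state changes inactivate stopped cells and 7-enclosed actives", {
  # active centre with exactly 7 inactive neighbours -> inactive
  g <- new_cell_grid(3)
  g$state[] <- cell_states()[["inactive"]]; g$label[] <- 1L
  g$state[2, 2] <- cell_states()[["active"]]
  g$state[3, 3] <- 0L; g$label[3, 3] <- 0L
  out <- apply_state_changes(g)
  expect_equal(out$state[2, 2], cell_states()[["inactive"]])
  expect_equal(out$label[2, 2], 1L)  # labels untouched

  # 8 empty neighbours, not stopped -> stays active
  g2 <- single_seed_grid(3, 2, 2)
  out2 <- apply_state_changes(g2)
  expect_equal(out2$state[2, 2], cell_states()[["active"]])

  # explicitly stopped cell becomes inactive
  out3 <- apply_state_changes(g2, stopped = rbind(c(2L, 2L)))
  expect_equal(out3$state[2, 2], cell_states()[["inactive"]])

  # stopped must point at active cells
  expect_error(apply_state_changes(g2, stopped = rbind(c(1L, 1L))), "active")
})

test_that("a summer round grows monotonically and respects exclusivity", {
  # zero active cells: fixed point
  g0 <- new_cell_grid(5)
  expect_identical(summer_step(g0, flat_landscape(5))$state, g0$state)

  # single seed on an all-1 landscape: exactly one new cell per round
  set.seed(2)
  g <- single_seed_grid(9)
  out <- summer_step(g, flat_landscape(9, 1))
  expect_equal(sum(out$state != 0L), 2L)

  # monotone count and label/state consistency across random grids
  set.seed(10)
  for (rep in 1:5) {
    g <- place_seeds(new_cell_grid(20), 4)
    land <- generate_landscape(20)
    for (s in 1:15) {
      before <- sum(g$state != 0L)
      g <- summer_step(g, land)
      expect_gte(sum(g$state != 0L), before)
      expect_true(all((g$label == 0L) == (g$state == 0L)))
    }
  }
})

test_that("run_summer applies exactly T synchronous rounds", {
  set.seed(5)
  g <- single_seed_grid(30)
  land <- flat_landscape(30, 1)
  expect_identical(run_summer(g, land, 0), g)

  # on an all-1 landscape each round adds exactly one cell per active front
  # until self-contact, so early counts identify the number of rounds
  set.seed(5)
  out <- run_summer(g, land, 36)
  set.seed(5)
  ref <- g
  for (i in 1:36) ref <- summer_step(ref, land)
  expect_identical(out, ref)
  expect_error(run_summer(g, land, -1), "T_summer")
})
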