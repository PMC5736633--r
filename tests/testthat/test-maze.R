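test_that("default maze topology satisfies its structural invariants", {
  mz <- default_maze
  deg <- lengths(mz$adjacency)
  expect_true(all(deg >= 1 & deg <= 3))
  expect_equal(sum(mz$cells$kind == "intersection"), 3)
  expect_equal(unname(c("dead_end", "corridor", "intersection")[deg]),
               mz$cells$kind)
  for (i in seq_along(mz$adjacency))
    for (j in mz$adjacency[[i]])
      expect_true(i %in% mz$adjacency[[j]])
  expect_false(mz$cells$kind[mz$start] == "intersection")

  path <- seqnav:::shortest_cell_path(mz)
  expect_false(anyNA(path))
  # three alleys of two cells plus two junctions between start and goal
  expect_equal(sum(mz$cells$kind[path] != "intersection"), 6)
  expect_equal(sum(mz$cells$kind[path] == "intersection"), 2)
  expect_lte(length(path) - 1, protocol_spec()$trial_cap_steps)
  # the direct route turns left then right at the two junctions crossed
  turns <- mz$guided_path[mz$guided_path %in% c("L", "R")]
  expect_equal(turns, c("L", "R"))
})

test_that("observation reports the local cell shape", {
  mz <- default_maze
  for (i in seq_len(nrow(mz$cells))) {
    pose <- ego_pose(i, 0)
    sym <- switch(mz$cells$kind[i], corridor = "I", dead_end = "u",
                  intersection = "Y")
    expect_equal(observe(mz, pose), sym)
  }
  expect_error(observe(mz, ego_pose(99, 0)), "unknown cell")
})

test_that("available actions match the openings at each pose", {
  mz <- default_maze
  # corridor entered along the alley: forward or reverse
  p <- step_pose(mz, start_pose(mz), "F")$pose
  expect_equal(available_actions(mz, p), c("F", "U"))
  # every junction entered along any incident edge offers three options
  for (y in which(mz$cells$kind == "intersection"))
    for (from in mz$adjacency[[y]]) {
      h <- atan2(mz$cells$y[y] - mz$cells$y[from],
                 mz$cells$x[y] - mz$cells$x[from])
      av <- available_actions(mz, ego_pose(y, h))
      expect_equal(length(av), 3)
      expect_true("U" %in% av)
    }
  # dead end entered normally: only the reverse move
  pose <- start_pose(mz)
  for (a in c("F", "F", "R", "F")) pose <- step_pose(mz, pose, a)$pose
  expect_equal(mz$cells$kind[pose$cell], "dead_end")
  expect_equal(available_actions(mz, pose), "U")
})

test_that("stepping is consistent with the offered actions everywhere", {
  mz <- default_maze
  # enumerate all reachable poses (cell, came-from) and check every offered
  # action executes and lands on a neighbour
  for (cell in seq_len(nrow(mz$cells)))
    for (from in mz$adjacency[[cell]]) {
      h <- atan2(mz$cells$y[cell] - mz$cells$y[from],
                 mz$cells$x[cell] - mz$cells$x[from])
      pose <- ego_pose(cell, h)
      for (a in available_actions(mz, pose)) {
        st <- step_pose(mz, pose, a)
        expect_true(st$pose$cell %in% mz$adjacency[[cell]])
        expect_equal(st$at_goal, st$pose$cell == mz$goal)
      }
    }
  expect_error(step_pose(mz, start_pose(mz), "L"), "not available")
})

test_that("two successive U-turns in a corridor return to the start pose", {
  mz <- default_maze
  pose <- step_pose(mz, start_pose(mz), "F")$pose # corridor, mid-alley
  there <- step_pose(mz, pose, "U")$pose
  back <- step_pose(mz, there, "U")$pose
  expect_equal(back$cell, pose$cell)
  expect_equal(back$heading, pose$heading, tolerance = 1e-12)
})

test_that("discretization recovers the decisions of rendered trajectories", {
  mz <- default_maze
  # direct-path trajectory: junction decisions are left then right
  path <- seqnav:::shortest_cell_path(mz)
  samples <- data.frame(t_s = seq_along(path),
                        x_cm = mz$cells$x[path], y_cm = mz$cells$y[path])
  d <- discretize_trajectory(samples, mz)
  expect_equal(d$action[d$observation == "Y"], c("L", "R"))

  # a stationary cluster yields no decisions
  still <- data.frame(t_s = 1:5, x_cm = rep(mz$cells$x[1], 5),
                      y_cm = rep(mz$cells$y[1], 5))
  expect_equal(nrow(discretize_trajectory(still, mz)), 0)

  # samples far outside the maze are dropped with a warning
  bad <- rbind(samples, data.frame(t_s = 99, x_cm = 500, y_cm = 500))
  expect_warning(discretize_trajectory(bad, mz), "dropped")

  # round trip: simulated free paths, rendered to centroid coordinates with
  # jitter, reproduce the original action sequence exactly
  sim <- simulate_agents("mf", mf_fixture_params, mz, short_protocol,
                         n_agents = 1, seed = 42, return_actions = TRUE)
  set.seed(7)
  checked <- 0
  for (tr in sim$actions[[1]]) {
    if (any(tr$guided)) next
    rec <- seqnav:::reconstruct_trial(mz, tr$actions, tr$guided)
    cells <- c(rec$cell, mz$goal)
    samples <- data.frame(t_s = seq_along(cells),
                          x_cm = mz$cells$x[cells] + runif(length(cells), -2, 2),
                          y_cm = mz$cells$y[cells] + runif(length(cells), -2, 2))
    d <- discretize_trajectory(samples, mz)
    expect_equal(d$action, rec$action)
    checked <- checked + 1
  }
  expect_gt(checked, 3)
})

test_that("maze config files round trip and malformed configs are rejected", {
  mz <- default_maze
  f <- withr::local_tempfile(fileext = ".tsv")
  write_maze(mz, f)
  mz2 <- read_maze(f)
  expect_equal(mz2$cells, mz$cells)
  expect_equal(mz2$adjacency, mz$adjacency)
  expect_equal(mz2$guided_path, mz$guided_path)

  cfg <- read.delim(f)
  cfg$neighbours[1] <- "2;3;4;5" # four neighbours
  expect_error(build_default_maze(config = cfg), "structure error")
})
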