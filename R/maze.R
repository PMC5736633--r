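#' @useDynLib seqnav, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm qlnorm pnorm pt qt cor p.adjust wilcox.test
#'   setNames
#' @importFrom utils read.delim write.table read.csv write.csv modifyList
"_PACKAGE"

# Egocentric action alphabet, canonical order.  Codes 0:3 are shared with the
# C++ engine; the null memory token is coded 4.
ACTIONS <- c("F", "L", "R", "U")

# cell kinds by neighbour count: 1 -> dead_end, 2 -> corridor, 3 -> intersection
KIND_LEVELS <- c(corridor = 0L, dead_end = 1L, intersection = 2L)
OBS_SYMBOLS <- c(corridor = "I", dead_end = "u", intersection = "Y")

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Build the discretized triple-Y maze
#'
#' Constructs the discrete cell map of the triple-Y water maze: a departure
#' alley joining the first Y junction, a central stem to the second junction,
#' a goal alley (platform at its end), a third Y junction hanging off the
#' incorrect branch of the second junction, and dead-end alleys closing the
#' remaining branches.  Every 41 cm alley is discretized into two cells of
#' roughly one movement step (19.6 cm/s for 1.05 s = 20.58 cm) so that a 60 s
#' trial corresponds to 57 discrete steps.  The fastest route from departure
#' to goal is the two-turn sequence left-then-right.
#'
#' @param config Optional maze-definition \code{data.frame} with columns
#'   \code{id}, \code{kind}, \code{x_cm}, \code{y_cm}, \code{neighbours}
#'   (semicolon-separated ids), \code{start}, \code{goal} (logical flags), as
#'   read by \code{\link{read_maze}}.  When \code{NULL} the default triple-Y
#'   topology is built.
#' @param step_length_cm Nominal length of one movement step in cm.
#' @return An object of class \code{maze_graph}: a list with \code{cells}
#'   (data.frame of id, kind, x, y), \code{adjacency} (list of integer
#'   vectors), \code{start}, \code{goal}, \code{step_length_cm},
#'   \code{start_heading} (radians) and \code{guided_path} (the egocentric
#'   action sequence of the correct route, used for guided returns).
#' @examples
#' mz <- build_default_maze()
#' sum(mz$cells$kind == "intersection")  # three Y junctions
#' @export
build_default_maze <- function(config = NULL, step_length_cm = 20.58) {
  if (is.null(config)) {
    u <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))
    Y1 <- c(0, 0); Y2 <- c(41, 0); Y3 <- Y2 + 41 * u(60)
    inner <- 10.25; outer <- 30.75
    coords <- rbind(
      outer * u(120),        # 1 departure end (start)
      inner * u(120),        # 2 departure inner
      Y1,                    # 3 junction Y1
      inner * u(240),        # 4 dead-end alley 1 inner
      outer * u(240),        # 5 dead-end alley 1 end
      c(inner, 0),           # 6 stem inner
      c(outer, 0),           # 7 stem outer
      Y2,                    # 8 junction Y2
      Y2 + inner * u(-60),   # 9 goal alley inner
      Y2 + outer * u(-60),   # 10 goal alley end (platform)
      Y2 + inner * u(60),    # 11 connector inner
      Y2 + outer * u(60),    # 12 connector outer
      Y3,                    # 13 junction Y3
      Y3 + inner * u(0),     # 14 dead-end alley 2 inner
      Y3 + outer * u(0),     # 15 dead-end alley 2 end
      Y3 + inner * u(120),   # 16 dead-end alley 3 inner
      Y3 + outer * u(120)    # 17 dead-end alley 3 end
    )
    edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(3, 6), c(6, 7),
                   c(7, 8), c(8, 9), c(9, 10), c(8, 11), c(11, 12), c(12, 13),
                   c(13, 14), c(14, 15), c(13, 16), c(16, 17))
    n <- nrow(coords)
    adjacency <- lapply(seq_len(n), function(i)
      sort(unique(as.integer(
        c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])))))
    start <- 1L; goal <- 10L
  } else {
    n <- nrow(config)
    if (!all(config$id == seq_len(n)))
      stop("maze config: cell ids must be 1..n in order")
    coords <- cbind(config$x_cm, config$y_cm)
    adjacency <- lapply(strsplit(as.character(config$neighbours), ";"),
                        function(s) sort(as.integer(s)))
    start <- which(config$start)
    goal <- which(config$goal)
    if (length(start) != 1L || length(goal) != 1L)
      stop("maze config: exactly one start and one goal cell required")
  }

  deg <- lengths(adjacency)
  if (any(deg < 1L | deg > 3L))
    stop("maze structure error: every cell must have 1-3 neighbours")
  for (i in seq_along(adjacency))
    for (j in adjacency[[i]])
      if (!(i %in% adjacency[[j]]))
        stop("maze structure error: adjacency is not symmetric (",
             i, " -> ", j, ")")
  kind <- c("dead_end", "corridor", "intersection")[deg]
  if (!is.null(config) && !all(kind == as.character(config$kind)))
    stop("maze config: declared kind inconsistent with neighbour count")

  mz <- structure(list(
    cells = data.frame(id = seq_len(n), kind = kind,
                       x = coords[, 1], y = coords[, 2]),
    adjacency = adjacency,
    start = as.integer(start), goal = as.integer(goal),
    step_length_cm = step_length_cm
  ), class = "maze_graph")

  # initial heading: from the departure cell toward its single neighbour
  first_nb <- adjacency[[mz$start]][1]
  mz$start_heading <- atan2(coords[first_nb, 2] - coords[mz$start, 2],
                            coords[first_nb, 1] - coords[mz$start, 1])

  if (is.na(shortest_cell_path(mz)[1]))
    stop("maze structure error: goal not reachable from start")
  mz$guided_path <- guided_action_path(mz)
  mz
}

#' @export
print.maze_graph <- function(x, ...) {
  cat("Discretized maze:", nrow(x$cells), "cells (",
      sum(x$cells$kind == "intersection"), "Y junctions ),",
      "start", x$start, "-> goal", x$goal, "\n")
  invisible(x)
}

#' Egocentric pose
#'
#' A pose is a cell together with a heading (radians, allocentric) along the
#' edge just traversed.  Poses resolve the egocentric actions F/L/R/U.
#'
#' @param cell Cell id.
#' @param heading Heading angle in radians.
#' @return An object of class \code{ego_pose}.
#' @export
ego_pose <- function(cell, heading) {
  structure(list(cell = as.integer(cell), heading = as.numeric(heading)),
            class = "ego_pose")
}

#' Initial pose at the departure cell
#' @param maze A \code{maze_graph}.
#' @export
start_pose <- function(maze) ego_pose(maze$start, maze$start_heading)

#' Sensory observation at a pose
#'
#' The sensory input encodes only the local shape of the maze: \code{"I"} for
#' corridors, \code{"u"} for dead ends, \code{"Y"} for intersections.
#'
#' @param maze A \code{maze_graph}.
#' @param pose An \code{ego_pose}.
#' @return One of \code{"I"}, \code{"u"}, \code{"Y"}.
#' @export
observe <- function(maze, pose) {
  if (pose$cell < 1 || pose$cell > nrow(maze$cells))
    stop("unknown cell id: ", pose$cell)
  unname(OBS_SYMBOLS[maze$cells$kind[pose$cell]])
}

# classify each neighbour of `cell` relative to `heading`;
# returns named int vector: targets for classes F/L/R/B that exist
classify_neighbours <- function(maze, cell, heading) {
  out <- c(F = NA_integer_, L = NA_integer_, R = NA_integer_, B = NA_integer_)
  for (j in maze$adjacency[[cell]]) {
    ang <- atan2(maze$cells$y[j] - maze$cells$y[cell],
                 maze$cells$x[j] - maze$cells$x[cell])
    rel <- wrap_angle(ang - heading)
    cls <- if (abs(rel) < pi / 4) "F"
    else if (rel >= pi / 4 && rel < 3 * pi / 4) "L"
    else if (rel <= -pi / 4 && rel > -3 * pi / 4) "R"
    else "B"
    out[cls] <- j
  }
  out
}

#' Available egocentric actions at a pose
#'
#' F/L/R are available when an opening exists in the corresponding egocentric
#' direction; U (reverse along the arrival edge) is available everywhere the
#' agent has somewhere behind it.  At a dead end entered normally only U is
#' offered; at a dead end already faced toward its single opening (the
#' departure pose) only F is offered, so that every offered action maps to a
#' distinct cell transition.
#'
#' @param maze A \code{maze_graph}.
#' @param pose An \code{ego_pose}.
#' @return Character vector of actions, canonical order F, L, R, U.
#' @export
available_actions <- function(maze, pose) {
  cl <- classify_neighbours(maze, pose$cell, pose$heading)
  if (maze$cells$kind[pose$cell] == "dead_end")
    return(if (!is.na(cl["B"])) "U" else "F")
  c(names(cl[c("F", "L", "R")])[!is.na(cl[c("F", "L", "R")])], "U")
}

#' Take one egocentric step
#'
#' Moves the agent one cell in the egocentric direction of \code{action}.  U
#' reverses the heading and moves back one cell (at a dead end, onto the
#' single neighbour).
#'
#' @param maze A \code{maze_graph}.
#' @param pose An \code{ego_pose}.
#' @param action One of \code{"F"}, \code{"L"}, \code{"R"}, \code{"U"}.
#' @return A list with the new \code{pose} and \code{at_goal} flag.
#' @export
step_pose <- function(maze, pose, action) {
  if (!(action %in% available_actions(maze, pose)))
    stop("action ", action, " not available at cell ", pose$cell)
  cl <- classify_neighbours(maze, pose$cell, pose$heading)
  tgt <- if (action == "U") {
    if (!is.na(cl["B"])) cl[["B"]] else maze$adjacency[[pose$cell]][1]
  } else cl[[action]]
  h <- atan2(maze$cells$y[tgt] - maze$cells$y[pose$cell],
             maze$cells$x[tgt] - maze$cells$x[pose$cell])
  list(pose = ego_pose(tgt, h), at_goal = tgt == maze$goal)
}

# BFS shortest path start -> goal as cell ids; NA if unreachable
shortest_cell_path <- function(maze) {
  n <- nrow(maze$cells)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  q <- maze$start; seen[maze$start] <- TRUE
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    if (v == maze$goal) break
    for (j in maze$adjacency[[v]])
      if (!seen[j]) { seen[j] <- TRUE; prev[j] <- v; q <- c(q, j) }
  }
  if (!seen[maze$goal]) return(NA_integer_)
  path <- maze$goal
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  path
}

# egocentric action sequence along the shortest start -> goal path
guided_action_path <- function(maze) {
  cells <- shortest_cell_path(maze)
  pose <- start_pose(maze)
  acts <- character(0)
  for (k in 2:length(cells)) {
    cl <- classify_neighbours(maze, pose$cell, pose$heading)
    a <- names(cl)[match(cells[k], cl)]
    if (is.na(a)) stop("guided path inference failed at cell ", pose$cell)
    if (a == "B") a <- "U"
    acts <- c(acts, a)
    pose <- step_pose(maze, pose, a)$pose
  }
  acts
}

# Sequence-error zone: the cells beyond the incorrect branch of the final
# junction on the direct path (in the default maze, the whole incorrect
# y-maze).  Entering it on a free trial reveals a failed turn sequence;
# hesitations on the departure side are not scored as sequence errors.
maze_error_zone <- function(maze) {
  path <- shortest_cell_path(maze)
  junctions <- path[maze$cells$kind[path] == "intersection"]
  if (length(junctions) == 0) return(integer(0))
  cut <- junctions[length(junctions)]
  n <- nrow(maze$cells)
  comp <- function(from) {
    seen <- rep(FALSE, n); seen[cut] <- TRUE  # block the junction
    q <- from; seen[from] <- TRUE
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (j in maze$adjacency[[v]])
        if (!seen[j]) { seen[j] <- TRUE; q <- c(q, j) }
    }
    which(seen)
  }
  ok <- unique(c(comp(maze$start), comp(maze$goal), cut))
  setdiff(seq_len(n), ok)
}

# plain-list representation consumed by the C++ engine; `path` marks the
# cells an error-free trial may visit (everything outside the error zone)
maze_for_engine <- function(maze) {
  list(x = maze$cells$x, y = maze$cells$y,
       nb = maze$adjacency,
       kind = unname(KIND_LEVELS[maze$cells$kind]),
       start = maze$start, goal = maze$goal,
       guided = match(maze$guided_path, ACTIONS) - 1L,
       path = setdiff(seq_len(nrow(maze$cells)), maze_error_zone(maze)),
       start_heading = maze$start_heading)
}

# regular 2D grid over the maze bounding box at one-step resolution,
# used as the support of the path-integration beliefs
maze_grid <- function(maze, resolution_cm = maze$step_length_cm) {
  xr <- range(maze$cells$x); yr <- range(maze$cells$y)
  gx <- seq(xr[1], xr[2], by = resolution_cm)
  gy <- seq(yr[1], yr[2], by = resolution_cm)
  if (max(gx) < xr[2]) gx <- c(gx, max(gx) + resolution_cm)
  if (max(gy) < yr[2]) gy <- c(gy, max(gy) + resolution_cm)
  g <- expand.grid(x = gx, y = gy)
  list(gx = g$x, gy = g$y)
}

#' Discretize a continuous trajectory into a decision sequence
#'
#' Assigns each tracked sample to the nearest cell centroid, collapses
#' consecutive repeats, and infers the egocentric action of every cell
#' transition from the running heading, yielding the discrete decisions a
#' learning model can be fitted to.
#'
#' @param samples \code{data.frame} with columns \code{t_s}, \code{x_cm},
#'   \code{y_cm} (time-ordered).
#' @param maze A \code{maze_graph}.
#' @return A \code{data.frame} with columns \code{step}, \code{cell},
#'   \code{observation}, \code{available}, \code{action} (empty when the
#'   trajectory never leaves a cell).  Samples farther than one step length
#'   from every centroid are dropped with a warning.
#' @export
discretize_trajectory <- function(samples, maze) {
  cx <- maze$cells$x; cy <- maze$cells$y
  nearest <- vapply(seq_len(nrow(samples)), function(i) {
    d2 <- (cx - samples$x_cm[i])^2 + (cy - samples$y_cm[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > maze$step_length_cm) NA_integer_ else j
  }, integer(1))
  if (anyNA(nearest)) {
    warning(sum(is.na(nearest)), " sample(s) farther than one step length ",
            "from every cell centroid; dropped")
    nearest <- nearest[!is.na(nearest)]
  }
  cells <- rle(nearest)$values
  empty <- data.frame(step = integer(0), cell = integer(0),
                      observation = character(0), available = character(0),
                      action = character(0))
  if (length(cells) < 2) return(empty)

  heading <- atan2(cy[cells[2]] - cy[cells[1]], cx[cells[2]] - cx[cells[1]])
  pose <- ego_pose(cells[1], heading)
  out <- empty
  for (k in 2:length(cells)) {
    av <- available_actions(maze, pose)
    cl <- classify_neighbours(maze, pose$cell, pose$heading)
    a <- names(cl)[match(cells[k], cl)]
    if (is.na(a)) {
      warning("non-adjacent cell transition at step ", k - 1, "; dropped")
      next
    }
    if (a == "B") a <- "U"
    out <- rbind(out, data.frame(
      step = k - 1L, cell = pose$cell,
      observation = observe(maze, pose),
      available = paste(av, collapse = ","), action = a))
    pose <- step_pose(maze, pose, a)$pose
  }
  out
}
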