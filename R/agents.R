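# The four candidate learning agents: model-based RL over a growing
# transition tree, model-free actor-critic with an action memory of n past
# actions (n = 3 default, n = 0 memoryless control), and Bayesian path
# integration.  Granular operations live here as pure functions on plain R
# states (the unit-test surface); `run_agent_r()` is the R reference engine
# mirroring the compiled one step for step.

#' Softmax action-selection policy
#'
#' Numerically stable softmax over the available actions:
#' \eqn{P(a_i) = e^{\beta v_i} / \sum_j e^{\beta v_j}} with the maximum value
#' subtracted before exponentiation (\eqn{\beta} up to 200 would otherwise
#' overflow).  With \eqn{\beta = 0} the policy is uniform.
#'
#' @param values Numeric vector of per-action values (named by action).
#' @param beta Inverse temperature, \eqn{\beta \ge 0}.
#' @return Probability vector over the same actions, summing to 1.
#' @export
softmax_policy <- function(values, beta) {
  if (length(values) == 0) stop("empty available action set")
  e <- exp(beta * (values - max(values)))
  e / sum(e)
}

# ------------------------------------------------------------ model-based

#' Initial model-based state
#'
#' The model-based agent grows a rooted tree of task states: each trial
#' starts at the root, and every untried (node, action) pair spawns a new
#' node (after a U-turn the agent is not aware it may have returned to a
#' known node, so the graph never closes cycles).
#'
#' @return An \code{mb_state}: list with \code{child} (node x action ids),
#'   \code{T} (transition strengths), \code{R} (reward flags), \code{V}
#'   (state values), \code{depth} and \code{current}.
#' @export
mb_state <- function() {
  structure(list(
    child = matrix(NA_integer_, 1, 4, dimnames = list(NULL, ACTIONS)),
    T = matrix(0, 1, 4, dimnames = list(NULL, ACTIONS)),
    R = 0L, V = 0, depth = 0L, current = 1L
  ), class = "mb_state")
}

#' Record one transition in the model-based tree
#'
#' A never-tried action appends a new node with transition strength
#' \eqn{T = \eta}; a repeated action reinforces it,
#' \eqn{T \leftarrow T + \eta(1 - T)}.  The reward flag of the attained node
#' is set when the platform is found there.
#'
#' @param state An \code{mb_state}.
#' @param action One of F/L/R/U.
#' @param params Named parameters with \code{eta}.
#' @param reward_found Logical: did this step attain the goal?
#' @return The updated \code{mb_state} (current node advanced).
#' @export
mb_observe_transition <- function(state, action, params, reward_found = FALSE) {
  k <- state$current
  eta <- params[["eta"]]
  if (is.na(state$child[k, action])) {
    state$child <- rbind(state$child, NA_integer_)
    state$T <- rbind(state$T, 0)
    state$R <- c(state$R, as.integer(reward_found))
    state$V <- c(state$V, 0)
    state$depth <- c(state$depth, state$depth[k] + 1L)
    m <- length(state$V)
    state$child[k, action] <- m
    state$T[k, action] <- eta
    state$current <- m
  } else {
    state$T[k, action] <- state$T[k, action] +
      eta * (1 - state$T[k, action])
    m <- state$child[k, action]
    if (reward_found) state$R[m] <- 1L
    state$current <- m
  }
  state
}

#' Propagate reward value through the transition tree
#'
#' Repeats \eqn{V(N) \leftarrow \max(R(N), V(N),
#' \max_i \gamma T(N, a_i, N') V(N'))} over all nodes until the largest
#' change falls below \code{tol}.  Values are monotonically non-decreasing
#' across sweeps and stay in [0, 1].
#'
#' @param state An \code{mb_state}.
#' @param gamma Discount factor in [0, 1].
#' @param tol Convergence tolerance.
#' @return The updated \code{mb_state}.
#' @export
mb_value_iteration <- function(state, gamma, tol = 1e-6) {
  n <- length(state$V)
  ord <- order(state$depth, decreasing = TRUE)
  for (sweep in 1:1000) {
    mx <- 0
    for (N in ord) {
      best <- max(as.numeric(state$R[N]), state$V[N])
      for (a in ACTIONS) {
        c2 <- state$child[N, a]
        if (!is.na(c2)) best <- max(best, gamma * state$T[N, a] * state$V[c2])
      }
      mx <- max(mx, best - state$V[N])
      state$V[N] <- best
    }
    if (mx < tol) break
  }
  state
}

#' Action values at the current node
#'
#' \eqn{Q(N_k, a_i)} is 0 for a never-tried action, else
#' \eqn{\gamma T(N_k, a_i, N') V(N')}.
#'
#' @param state An \code{mb_state} (value iteration assumed current).
#' @param gamma Discount factor.
#' @return Named numeric vector of Q values over F/L/R/U.
#' @export
mb_action_values <- function(state, gamma) {
  k <- state$current
  q <- setNames(numeric(4), ACTIONS)
  for (a in ACTIONS) {
    c2 <- state$child[k, a]
    if (!is.na(c2)) q[a] <- gamma * state$T[k, a] * state$V[c2]
  }
  q
}

# ------------------------------------------------------------ model-free

MF_NULL <- "-" # null token padding the action memory

#' Initial model-free (actor-critic) state
#'
#' @param n Action-memory size (3 default; 0 is the memoryless control).
#' @return An \code{mf_state}: critic values \code{V}, actor preferences
#'   \code{p} (keyed maps defaulting to 0), memory buffer, and \code{n}.
#' @export
mf_state <- function(n = 3) {
  structure(list(n = as.integer(n), V = numeric(0), p = numeric(0),
                 memory = rep(MF_NULL, n)),
            class = "mf_state")
}

#' Encode the augmented state key
#'
#' The model-free state is the concatenation of the sensory input with the
#' last \code{n} performed actions, \eqn{s^t = (I^t, a^{t-1}, \dots,
#' a^{t-n})}; with \eqn{n = 0} the key is the observation alone.
#'
#' @param observation One of "I", "u", "Y".
#' @param memory Character vector of the last n actions, most recent first,
#'   padded with the null token \code{"-"}.
#' @return A deterministic injective key string.
#' @export
mf_encode_state <- function(observation, memory = character(0)) {
  paste(c(observation, memory), collapse = "|")
}

mf_get <- function(map, key) {
  v <- map[key]
  if (is.na(v)) 0 else unname(v)
}

#' Actor-critic temporal-difference update
#'
#' Computes the reward prediction error
#' \eqn{\delta = r + \gamma V(s') - V(s)} (with \eqn{V(s') = 0} on terminal
#' transitions) and nudges both the critic value and the actor preference by
#' \eqn{\eta\delta}.
#'
#' @param state An \code{mf_state}.
#' @param s State key at decision time.
#' @param a Chosen action.
#' @param r Reward in \{0, 1\}.
#' @param s_next Next state key, or \code{NULL} for a terminal transition.
#' @param params Named parameters with \code{eta} and \code{gamma}.
#' @return The updated \code{mf_state}, with the prediction error in
#'   attribute \code{"delta"}.
#' @export
mf_td_update <- function(state, s, a, r, s_next, params) {
  v_next <- if (is.null(s_next)) 0 else mf_get(state$V, s_next)
  delta <- r + params[["gamma"]] * v_next - mf_get(state$V, s)
  state$V[s] <- mf_get(state$V, s) + params[["eta"]] * delta
  pk <- paste(s, a, sep = "@")
  state$p[pk] <- mf_get(state$p, pk) + params[["eta"]] * delta
  attr(state, "delta") <- delta
  state
}

mf_preferences <- function(state, s, actions) {
  vapply(actions, function(a) mf_get(state$p, paste(s, a, sep = "@")),
         numeric(1))
}

# -------------------------------------------------------- path integration

#' Initial path-integration state
#'
#' Position belief \eqn{P^t(Pos)} and goal belief \eqn{P(Goal)} are discrete
#' distributions over a regular grid covering the maze.  The position belief
#' starts as a point mass at the departure point; the goal belief starts
#' uniform and is learned.
#'
#' @param grid List with \code{gx}, \code{gy} grid-point coordinates (cm).
#' @param origin Length-2 numeric: the departure coordinates.
#' @return A \code{pi_state}.
#' @export
pi_state <- function(grid, origin) {
  G <- length(grid$gx)
  s <- structure(list(gx = grid$gx, gy = grid$gy,
                      pos = numeric(G), goal = rep(1 / G, G),
                      mu = as.numeric(origin), t = 0L),
                 class = "pi_state")
  s$pos[which.min((s$gx - origin[1])^2 + (s$gy - origin[2])^2)] <- 1
  s
}

#' Propagate the position belief after one step
#'
#' The dead-reckoned position advances by \code{displacement}; the belief
#' becomes an isotropic Gaussian centred there with standard deviation
#' \eqn{\sigma = \sigma_0 t} (growing with elapsed steps \eqn{t}), evaluated
#' on the grid and renormalized.  \eqn{\sigma = 0} yields a point mass.
#'
#' @param state A \code{pi_state}.
#' @param displacement Length-2 numeric (dx, dy) in cm.
#' @param params Named parameters with \code{sigma0}.
#' @return The updated \code{pi_state}.
#' @export
pi_propagate <- function(state, displacement, params) {
  state$mu <- state$mu + as.numeric(displacement)
  state$t <- state$t + 1L
  sigma <- params[["sigma0"]] * state$t
  G <- length(state$gx)
  if (sigma <= 1e-9) {
    state$pos <- numeric(G)
    state$pos[which.min((state$gx - state$mu[1])^2 +
                          (state$gy - state$mu[2])^2)] <- 1
    return(state)
  }
  w <- exp(-((state$gx - state$mu[1])^2 + (state$gy - state$mu[2])^2) /
             (2 * sigma^2))
  if (sum(w) <= 0) {
    state$pos <- numeric(G)
    state$pos[which.min((state$gx - state$mu[1])^2 +
                          (state$gy - state$mu[2])^2)] <- 1
  } else state$pos <- w / sum(w)
  state
}

#' Update the goal belief on goal attainment
#'
#' \eqn{P(Goal) \leftarrow (1 - \eta) P(Goal) + \eta P^t(Pos)}, applied every
#' time the platform is reached (freely or guided).
#'
#' @param state A \code{pi_state}.
#' @param params Named parameters with \code{eta}.
#' @return The updated \code{pi_state}.
#' @export
pi_update_goal <- function(state, params) {
  state$goal <- (1 - params[["eta"]]) * state$goal +
    params[["eta"]] * state$pos
  state
}

#' Distribution of goal-ward directions
#'
#' For every ordered pair of grid points (Pos, Goal), Pos != Goal, the pair's
#' bearing \eqn{atan2(Goal - Pos)} is assigned to the nearest candidate
#' direction, and the pair mass \eqn{P(Pos) P(Goal)} accumulated; the result
#' is normalized over the candidates.  Zero total mass (e.g. a still-uniform
#' goal belief with symmetric candidates) falls back to uniform.
#'
#' @param state A \code{pi_state}.
#' @param candidate_angles Numeric vector of allocentric angles (radians),
#'   one per available egocentric action.
#' @return Probability vector over the candidates.
#' @export
pi_direction_distribution <- function(state, candidate_angles) {
  G <- length(state$gx)
  nav <- length(candidate_angles)
  acc <- numeric(nav)
  tot <- 0
  ca <- cos(candidate_angles); sa <- sin(candidate_angles)
  for (i in seq_len(G)) {
    if (state$pos[i] <= 1e-9) next  # negligible mass, mirrors the engine
    for (j in seq_len(G)) {
      if (i == j) next
      w <- state$pos[i] * state$goal[j]
      if (w <= 0) next
      A <- atan2(state$gy[j] - state$gy[i], state$gx[j] - state$gx[i])
      cc <- ca * cos(A) + sa * sin(A)
      k <- which.max(cc)
      acc[k] <- acc[k] + w
      tot <- tot + w
    }
  }
  if (tot > 0) acc / tot else rep(1 / nav, nav)
}

# ------------------------------------------------- unified R reference run

params_vector <- function(params) {
  p <- c(eta = 0, beta = 0, gamma = 0, sigma0 = 0)
  p[names(params)] <- unlist(params)
  p
}

# R reference engine: same step-for-step semantics as the compiled engine
# (one code path for forced replay and free simulation; one uniform from the
# RNG per free decision with >= 2 options).  Used on short fixtures to
# cross-check the compiled path.
run_agent_r <- function(model, params, maze, protocol,
                        forced = NULL, n_agents = 1, return_actions = FALSE,
                        n_memory = 3) {
  par <- params_vector(params)
  eta <- par[["eta"]]; beta <- par[["beta"]]
  gamma <- par[["gamma"]]; sigma0 <- par[["sigma0"]]
  replay <- !is.null(forced)
  n_trials <- if (replay) length(forced) else
    protocol$trials_per_session * protocol$sessions_per_day * protocol$max_days
  cap <- protocol$trial_cap_steps
  kind_code <- KIND_LEVELS[maze$cells$kind]
  obs_sym <- OBS_SYMBOLS[maze$cells$kind]
  cx <- maze$cells$x; cy <- maze$cells$y
  if (replay) n_agents <- 1

  grid <- if (model == "pi") maze_grid(maze) else NULL

  onpath <- !(seq_len(nrow(maze$cells)) %in% maze_error_zone(maze))
  loglik <- 0; ndec <- 0L
  steps_out <- matrix(0, n_agents, n_trials)
  success_out <- matrix(FALSE, n_agents, n_trials)
  offpath_out <- matrix(FALSE, n_agents, n_trials)
  agent_actions <- vector("list", n_agents)

  for (ag in seq_len(n_agents)) {
    mbs <- if (model == "mb") mb_state() else NULL
    mfs <- if (model %in% c("mf", "mf0")) mf_state(n_memory) else NULL
    pis <- NULL
    trial_actions <- vector("list", n_trials)

    for (tr in seq_len(n_trials)) {
      if (model == "mb") {
        mbs$current <- 1L
        mbs <- mb_value_iteration(mbs, gamma)
      } else if (model %in% c("mf", "mf0")) {
        mfs$memory <- rep(MF_NULL, mfs$n)
      } else {
        pis <- pi_state_keep_goal(pis, grid, c(cx[maze$start], cy[maze$start]))
      }
      pose <- start_pose(maze)
      guided_phase <- FALSE; reached <- FALSE; offpath <- FALSE
      free_steps <- 0L; guided_idx <- 0L; rec_idx <- 0L
      acts_rec <- integer(0); guided_rec <- logical(0)
      fa <- if (replay) forced[[tr]]$actions else NULL
      fg <- if (replay) forced[[tr]]$guided else NULL

      repeat {
        if (replay) {
          if (rec_idx >= length(fa)) break
          if (fg[rec_idx + 1] && !guided_phase) {
            guided_phase <- TRUE
            pose <- start_pose(maze)
            if (model == "mb") mbs$current <- 1L
            else if (model %in% c("mf", "mf0")) mfs$memory <- rep(MF_NULL, mfs$n)
            else pis <- pi_state_keep_goal(pis, grid,
                                           c(cx[maze$start], cy[maze$start]))
          }
        }

        av <- available_actions(maze, pose)
        cl <- classify_neighbours(maze, pose$cell, pose$heading)
        tgts <- vapply(av, function(a)
          if (a == "U") {
            if (!is.na(cl["B"])) cl[["B"]] else maze$adjacency[[pose$cell]][1]
          } else cl[[a]], integer(1))

        s_cur <- NULL
        if (model == "mb") {
          v <- unname(mb_action_values(mbs, gamma)[av])
        } else if (model %in% c("mf", "mf0")) {
          s_cur <- mf_encode_state(obs_sym[pose$cell], mfs$memory)
          v <- unname(mf_preferences(mfs, s_cur, av))
        } else {
          angs <- atan2(cy[tgts] - cy[pose$cell], cx[tgts] - cx[pose$cell])
          v <- pi_direction_distribution(pis, angs)
        }
        p <- softmax_policy(v, beta)

        if (replay) {
          rec_idx <- rec_idx + 1L
          a <- ACTIONS[fa[rec_idx] + 1]
          ki <- match(a, av)
          if (is.na(ki))
            stop("decision not available at trial ", tr, ", step ", rec_idx)
          if (!fg[rec_idx]) {
            loglik <- loglik + log(max(p[ki], 1e-12))
            ndec <- ndec + 1L
          }
        } else if (guided_phase) {
          guided_idx <- guided_idx + 1L
          a <- maze$guided_path[guided_idx]
          ki <- match(a, av)
        } else {
          if (length(av) == 1) ki <- 1L
          else {
            u <- runif(1); cum <- 0; ki <- length(av)
            for (k in seq_along(av)) {
              cum <- cum + p[k]
              if (u <= cum) { ki <- k; break }
            }
          }
          a <- av[ki]
        }

        if (return_actions) {
          acts_rec <- c(acts_rec, match(a, ACTIONS) - 1L)
          guided_rec <- c(guided_rec, guided_phase)
        }

        tgt <- tgts[[ki]]
        h <- atan2(cy[tgt] - cy[pose$cell], cx[tgt] - cx[pose$cell])
        dx <- cx[tgt] - cx[pose$cell]; dy <- cy[tgt] - cy[pose$cell]
        pose <- ego_pose(tgt, h)
        if (!guided_phase && !onpath[tgt]) offpath <- TRUE
        reached <- tgt == maze$goal
        r <- as.numeric(reached)

        if (model == "mb") {
          mbs <- mb_observe_transition(mbs, a, c(eta = eta), reached)
        } else if (model %in% c("mf", "mf0")) {
          mfs$memory <- mf_push(mfs$memory, a)
          s2 <- if (reached) NULL else mf_encode_state(obs_sym[tgt], mfs$memory)
          mfs <- mf_td_update(mfs, s_cur, a, r, s2,
                              c(eta = eta, gamma = gamma))
          if (reached) {
            # terminal bookkeeping only: s2 intentionally NULL
          }
        } else {
          pis <- pi_propagate(pis, c(dx, dy), c(sigma0 = sigma0))
          if (reached) pis <- pi_update_goal(pis, c(eta = eta))
        }

        if (!guided_phase) free_steps <- free_steps + 1L
        if (reached) break
        if (!replay && !guided_phase && free_steps >= cap) {
          guided_phase <- TRUE
          guided_idx <- 0L
          pose <- start_pose(maze)
          if (model == "mb") mbs$current <- 1L
          else if (model %in% c("mf", "mf0")) mfs$memory <- rep(MF_NULL, mfs$n)
          else pis <- pi_state_keep_goal(pis, grid,
                                         c(cx[maze$start], cy[maze$start]))
        }
      }

      steps_out[ag, tr] <- free_steps
      success_out[ag, tr] <- reached && !guided_phase
      offpath_out[ag, tr] <- offpath
      if (return_actions)
        trial_actions[[tr]] <- list(actions = acts_rec, guided = guided_rec)
    }
    agent_actions[[ag]] <- trial_actions
  }

  if (replay) return(list(loglik = loglik, n_decisions = ndec))
  out <- list(steps = steps_out, success = success_out,
              offpath = offpath_out)
  if (return_actions) out$actions <- agent_actions
  out
}

# reset the position belief/time but keep the learned goal belief
pi_state_keep_goal <- function(pis, grid, origin) {
  fresh <- pi_state(grid, origin)
  if (!is.null(pis)) fresh$goal <- pis$goal
  fresh
}

mf_push <- function(memory, a) {
  n <- length(memory)
  if (n == 0) return(memory)
  c(a, memory[-n])
}

#' One action-selection step of any agent (unified interface)
#'
#' Computes the per-action values of the given model state for the available
#' actions, applies the softmax policy, and samples an action (one uniform
#' draw when two or more actions are available).  Used by the simulation and
#' (with forcing) the likelihood replay, which share this policy computation.
#'
#' @param model One of \code{"mb"}, \code{"mf"}, \code{"mf0"}, \code{"pi"}.
#' @param state The model state (\code{mb_state}, \code{mf_state} or
#'   \code{pi_state}).
#' @param observation Sensory symbol at the current pose.
#' @param available Character vector of available actions.
#' @param params Named parameter vector.
#' @param candidate_angles For the path-integration model, the allocentric
#'   angles of the available actions.
#' @return List with \code{action} (sampled) and \code{probs} (full
#'   probability vector over \code{available}).
#' @export
agent_act <- function(model, state, observation, available, params,
                      candidate_angles = NULL) {
  if (length(available) == 0) stop("empty available action set")
  par <- params_vector(params)
  v <- switch(model,
    mb = unname(mb_action_values(state, par[["gamma"]])[available]),
    mf = ,
    mf0 = unname(mf_preferences(
      state, mf_encode_state(observation, state$memory), available)),
    pi = pi_direction_distribution(state, candidate_angles),
    stop("unknown model: ", model))
  p <- softmax_policy(v, par[["beta"]])
  ki <- if (length(available) == 1) 1L else {
    u <- runif(1); cum <- 0; k_pick <- length(available)
    for (k in seq_along(available)) {
      cum <- cum + p[k]
      if (u <= cum) { k_pick <- k; break }
    }
    k_pick
  }
  list(action = available[ki], probs = setNames(p, available))
}
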