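# Free-running simulation under the training protocol, latency curves, and
# model comparison against observed behaviour by mean-squared error with
# nonparametric tests.

#' Training protocol specification
#'
#' Defaults follow the water-maze training schedule: four sessions of four
#' trials per day for up to six days; agents move at 19.6 cm/s with a 1.05 s
#' simulation step, so the 60 s trial limit corresponds to 57 steps, after
#' which the agent is placed back at the departure point and guided to the
#' platform (rewarded R = 1, like a free arrival).
#'
#' @param trials_per_session,sessions_per_day,max_days Protocol counts.
#' @param step_duration_s Duration of one simulation step (s).
#' @param speed_cm_s Moving speed (cm/s).
#' @param trial_time_limit_s Trial limit (s).
#' @return A \code{protocol_spec} list; \code{trial_cap_steps} is derived as
#'   \code{floor(trial_time_limit_s / step_duration_s)}.
#' @export
protocol_spec <- function(trials_per_session = 4L, sessions_per_day = 4L,
                          max_days = 6L, step_duration_s = 1.05,
                          speed_cm_s = 19.6, trial_time_limit_s = 60) {
  structure(list(
    trials_per_session = as.integer(trials_per_session),
    sessions_per_day = as.integer(sessions_per_day),
    max_days = as.integer(max_days),
    step_duration_s = step_duration_s,
    speed_cm_s = speed_cm_s,
    trial_time_limit_s = trial_time_limit_s,
    trial_cap_steps = as.integer(floor(trial_time_limit_s / step_duration_s))
  ), class = "protocol_spec")
}

n_trials_total <- function(protocol)
  protocol$trials_per_session * protocol$sessions_per_day * protocol$max_days

#' Simulate freely choosing agents under the protocol
#'
#' Runs \code{n_agents} independent agents with one parameter set through the
#' full training protocol.  Unsuccessful trials end with a guided return
#' (learning updates applied, final reward 1).  Latency is steps times the
#' step duration for successful trials and the 60 s limit otherwise.
#'
#' @param model One of \code{"mb"}, \code{"mf"}, \code{"mf0"}, \code{"pi"}.
#' @param params Named parameter list/vector within bounds.
#' @param maze A \code{maze_graph}.
#' @param protocol A \code{\link{protocol_spec}}.
#' @param n_agents Number of agents (100 matches the evaluation procedure).
#' @param seed Optional integer seed.
#' @param return_actions Keep the full per-trial action sequences.
#' @param engine \code{"cpp"} (default) or \code{"r"} (reference).
#' @return A \code{simulation} object: matrices \code{steps}, \code{success},
#'   \code{latency} (agents x trials), the protocol, and optionally
#'   \code{actions}.
#' @export
simulate_agents <- function(model, params, maze,
                            protocol = protocol_spec(), n_agents = 100,
                            seed = NULL, return_actions = FALSE,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_bounds(params, model)
  if (!is.null(seed)) set.seed(seed)
  n_memory <- if (model == "mf0") 0L else 3L
  res <- if (engine == "cpp") {
    engine_run(model_code(model), n_memory, params_vector(params),
               maze_for_engine(maze), unclass(protocol),
               n_agents = as.integer(n_agents),
               return_actions = return_actions,
               gridL = if (model == "pi") maze_grid(maze) else NULL)
  } else {
    run_agent_r(engine_model_name(model), params, maze, protocol,
                n_agents = n_agents, return_actions = return_actions,
                n_memory = n_memory)
  }
  latency <- ifelse(res$success, res$steps * protocol$step_duration_s,
                    protocol$trial_time_limit_s)
  # a trial is *correct* when the goal is reached freely without entering
  # the incorrect y-maze (a committed wrong-turn sequence); the exploitation
  # criterion counts correct trials, not wandering within-limit arrivals
  correct <- res$success & !res$offpath
  out <- list(model = model, params = params, steps = res$steps,
              success = res$success, correct = correct, latency = latency,
              protocol = protocol)
  if (return_actions) out$actions <- res$actions
  structure(out, class = "simulation")
}

#' Mean latency curve of a simulation
#'
#' @param sim A \code{simulation} or an agents x trials latency matrix.
#' @param protocol A \code{\link{protocol_spec}} (taken from \code{sim} when
#'   available).
#' @param by \code{"trial"} (default) or \code{"session"} aggregation.
#' @return A \code{latency_curve}: list with \code{mean}, \code{sd},
#'   \code{n_agents}, \code{by}.
#' @export
latency_curve <- function(sim, protocol = NULL, by = c("trial", "session")) {
  by <- match.arg(by)
  if (inherits(sim, "simulation")) {
    protocol <- sim$protocol
    lat <- sim$latency
  } else lat <- as.matrix(sim)
  if (is.null(protocol)) protocol <- protocol_spec()
  if (by == "session") {
    ses <- rep(seq_len(ncol(lat) / protocol$trials_per_session),
               each = protocol$trials_per_session)
    lat <- t(apply(lat, 1, function(r) tapply(r, ses, mean)))
  }
  structure(list(mean = colMeans(lat),
                 sd = apply(lat, 2, stats::sd),
                 n_agents = nrow(lat), by = by),
            class = "latency_curve")
}

curve_values <- function(x) {
  if (inherits(x, "latency_curve")) x$mean else as.numeric(x)
}

#' Mean-squared error between two latency curves
#'
#' @param sim,observed Latency curves (\code{latency_curve} objects or
#'   numeric vectors), aligned to the same trials.
#' @return Mean over trials of the squared latency difference (s^2).
#' @export
curve_mse <- function(sim, observed) {
  a <- curve_values(sim); b <- curve_values(observed)
  if (length(a) != length(b))
    stop("alignment error: curves have lengths ", length(a), " and ",
         length(b))
  mean((a - b)^2)
}

#' Pairwise model comparison of per-subject MSEs
#'
#' Two-sided Mann-Whitney U tests on the per-subject mean-squared errors of
#' every model pair, Benjamini-Hochberg corrected over the pairwise family.
#' The reported direction is the model with the lower median MSE.
#'
#' @param mse_table \code{data.frame} or matrix, rows = subjects, columns =
#'   models, entries = latency-curve MSE (s^2).
#' @return \code{data.frame} with columns \code{model_a}, \code{model_b},
#'   \code{lower} (direction), \code{p}, \code{q}.
#' @export
compare_models_mse <- function(mse_table) {
  m <- as.matrix(mse_table)
  if (ncol(m) < 2) stop("need at least two models to compare")
  if (nrow(m) < 2) {
    warning("fewer than 2 subjects; tests skipped")
    return(data.frame(model_a = character(0), model_b = character(0),
                      lower = character(0), p = numeric(0), q = numeric(0)))
  }
  pairs <- utils::combn(colnames(m), 2)
  res <- data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
                    lower = NA_character_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- m[, pairs[1, i]]; b <- m[, pairs[2, i]]
    res$p[i] <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    res$lower[i] <- if (stats::median(a) <= stats::median(b))
      pairs[1, i] else pairs[2, i]
  }
  res$p[is.na(res$p)] <- 1
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Days to the exploitation criterion
#'
#' A subject reaches criterion after performing at least 75\% correct trials
#' during one training day followed by at least one 100\% correct session the
#' next day; the criterion day is that following day.  A correct trial is a
#' free (unguided) arrival without entry into the incorrect y-maze.
#'
#' @param success Logical vector of per-trial correct-trial indicators
#'   (protocol order), or an agents x trials matrix.
#' @param protocol A \code{\link{protocol_spec}}.
#' @return Integer day (or vector of days for a matrix input); \code{NA} when
#'   the criterion is never met.
#' @export
days_to_criterion <- function(success, protocol = protocol_spec()) {
  if (is.matrix(success))
    return(apply(success, 1, days_to_criterion, protocol = protocol))
  tpd <- protocol$trials_per_session * protocol$sessions_per_day
  days <- matrix(success, nrow = tpd)  # column = day
  n_days <- ncol(days)
  for (d in seq_len(n_days - 1)) {
    if (mean(days[, d]) >= 0.75) {
      sessions <- matrix(days[, d + 1], nrow = protocol$trials_per_session)
      if (any(colSums(sessions) == protocol$trials_per_session))
        return(d + 1L)
    }
  }
  NA_integer_
}
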