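# Trial-by-trial maximum-likelihood fitting: a subject's recorded decisions
# are replayed through a model with teacher forcing (the model is forced to
# make the same decision as the subject, while the probability it assigned to
# that decision is accumulated), and the parameters maximizing the summed log
# probability are found by restarted differential evolution.

#' Per-model parameter bounds
#'
#' The reinforcement-learning models have learning rate \eqn{\eta \in [0,1]},
#' inverse temperature \eqn{\beta \in [0,200]} and discount
#' \eqn{\gamma \in [0,1]}; path integration replaces \eqn{\gamma} by the
#' noise-growth rate \eqn{\sigma_0 \in [0,1]} and bounds
#' \eqn{\eta \in [0.001, 1]}.
#'
#' @param model One of \code{"mb"}, \code{"mf"}, \code{"mf0"}, \code{"pi"}.
#' @return A 2 x k matrix (rows lower/upper) with parameter columns.
#' @export
param_bounds <- function(model) {
  if (model == "pi")
    return(matrix(c(0.001, 1, 0, 200, 0, 1), 2,
                  dimnames = list(c("lower", "upper"),
                                  c("eta", "beta", "sigma0"))))
  matrix(c(0, 1, 0, 200, 0, 1), 2,
         dimnames = list(c("lower", "upper"), c("eta", "beta", "gamma")))
}

check_bounds <- function(params, model) {
  b <- param_bounds(model)
  for (nm in colnames(b)) {
    v <- params[[nm]]
    if (is.null(v) || is.na(v))
      stop("parameter ", nm, " missing for model ", model)
    if (v < b["lower", nm] || v > b["upper", nm])
      stop("parameter ", nm, " = ", v, " outside bounds [",
           b["lower", nm], ", ", b["upper", nm], "]")
  }
  invisible(TRUE)
}

# decision_sequence data.frame -> per-trial action/guided lists for the engine
decisions_to_trials <- function(decisions) {
  if (nrow(decisions) == 0) return(list())
  key <- interaction(decisions$day, decisions$session, decisions$trial,
                     drop = TRUE, lex.order = TRUE)
  lapply(split(decisions, key), function(d) {
    d <- d[order(d$step), ]
    list(actions = match(d$action, ACTIONS) - 1L,
         guided = as.logical(d$guided))
  })
}

#' Forced-choice log-likelihood of a decision sequence
#'
#' Replays the subject's decisions through the model: at every step the
#' model's action probabilities are computed, the subject's decision
#' \eqn{d^t} is forced, and \eqn{\log p(a^t = d^t)} is accumulated over free
#' (non-guided) steps, each probability floored at 1e-12 before the log.
#' Learning updates are applied exactly as in free running; guided steps
#' update the model but are not decisions and do not enter the sum.
#'
#' @param model One of \code{"mb"}, \code{"mf"}, \code{"mf0"}, \code{"pi"}.
#' @param params Named parameter list/vector (within bounds).
#' @param decisions A decision-sequence \code{data.frame} (see
#'   \code{\link{read_decisions}}).
#' @param maze A \code{maze_graph}.
#' @param protocol A \code{\link{protocol_spec}}.
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (reference).
#' @return The summed log-likelihood (0 for an empty sequence), with the
#'   number of scored decisions in attribute \code{"n_decisions"}.
#' @export
sequence_log_likelihood <- function(model, params, decisions, maze,
                                    protocol = protocol_spec(),
                                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_bounds(params, model)
  trials <- decisions_to_trials(decisions)
  if (length(trials) == 0)
    return(structure(0, n_decisions = 0L))
  n_memory <- if (model == "mf0") 0L else 3L
  res <- if (engine == "cpp") {
    engine_run(model_code(model), n_memory, params_vector(params),
               maze_for_engine(maze), unclass(protocol), forced_ = trials,
               gridL = if (model == "pi") maze_grid(maze) else NULL)
  } else {
    run_agent_r(engine_model_name(model), params, maze, protocol,
                forced = trials, n_memory = n_memory)
  }
  structure(res$loglik, n_decisions = res$n_decisions)
}

model_code <- function(model) {
  switch(model, mb = 0L, mf = 1L, mf0 = 1L, pi = 2L,
         stop("unknown model: ", model))
}
engine_model_name <- function(model) {
  if (model == "mf0") "mf" else model
}

#' Fit model parameters to a decision sequence by maximum likelihood
#'
#' Global stochastic search (rand/1/bin differential evolution, restarted
#' from independent random populations) maximizing
#' \code{\link{sequence_log_likelihood}} within the printed per-model bounds.
#' The best parameter vector across restarts is returned.  Reproducible given
#' \code{seed}.
#'
#' @param model One of \code{"mb"}, \code{"mf"}, \code{"mf0"}, \code{"pi"}.
#' @param decisions A decision-sequence \code{data.frame}.
#' @param maze A \code{maze_graph}.
#' @param protocol A \code{\link{protocol_spec}}.
#' @param bounds Bounds matrix as from \code{\link{param_bounds}}.
#' @param control List: \code{pop_size} (20), \code{generations} (200),
#'   \code{n_restarts} (10), differential weight \code{F} (0.7), crossover
#'   \code{CR} (0.9).  Smaller budgets are appropriate for benchmarking runs.
#' @param seed Integer seed for the search.
#' @return A \code{fit_result}: list with \code{model}, \code{params},
#'   \code{log_lik}, \code{n_decisions} and optimizer \code{diagnostics}.
#' @export
fit_parameters <- function(model, decisions, maze,
                           protocol = protocol_spec(),
                           bounds = param_bounds(model),
                           control = list(), seed = 1) {
  ctrl <- modifyList(list(pop_size = 20, generations = 200, n_restarts = 10,
                          F = 0.7, CR = 0.9), control)
  trials <- decisions_to_trials(decisions)
  lo <- bounds["lower", ]; up <- bounds["upper", ]
  k <- length(lo)
  n_memory <- if (model == "mf0") 0L else 3L
  mzL <- maze_for_engine(maze)
  grid <- if (model == "pi") maze_grid(maze) else NULL
  obj <- function(x) {
    names(x) <- colnames(bounds)
    res <- engine_run(model_code(model), n_memory, params_vector(as.list(x)),
                      mzL, unclass(protocol), forced_ = trials, gridL = grid)
    res$loglik
  }

  set.seed(seed)
  best <- NULL
  restart_best <- numeric(ctrl$n_restarts)
  n_eval <- 0L
  for (rs in seq_len(ctrl$n_restarts)) {
    np <- ctrl$pop_size
    pop <- matrix(runif(np * k, lo, up), np, k, byrow = TRUE)
    fit <- apply(pop, 1, obj)
    n_eval <- n_eval + np
    for (g in seq_len(ctrl$generations)) {
      for (i in seq_len(np)) {
        r <- sample(setdiff(seq_len(np), i), 3)
        mut <- pop[r[1], ] + ctrl$F * (pop[r[2], ] - pop[r[3], ])
        mut <- pmin(pmax(mut, lo), up)
        jr <- sample.int(k, 1)
        cross <- runif(k) < ctrl$CR
        cross[jr] <- TRUE
        cand <- ifelse(cross, mut, pop[i, ])
        f <- obj(cand)
        n_eval <- n_eval + 1L
        if (is.finite(f) && f >= fit[i]) { pop[i, ] <- cand; fit[i] <- f }
      }
    }
    ib <- which.max(fit)
    restart_best[rs] <- fit[ib]
    if (is.null(best) || fit[ib] > best$log_lik)
      best <- list(params = setNames(as.numeric(pop[ib, ]), colnames(bounds)),
                   log_lik = fit[ib])
  }
  if (is.null(best) || !is.finite(best$log_lik))
    stop("fitting error: optimizer budget exhausted without a finite ",
         "likelihood")
  ll <- sequence_log_likelihood(model, as.list(best$params), decisions, maze,
                                protocol)
  structure(list(model = model, params = best$params,
                 log_lik = as.numeric(ll),
                 n_decisions = attr(ll, "n_decisions"),
                 diagnostics = list(restart_best = restart_best,
                                    n_eval = n_eval, seed = seed,
                                    control = ctrl)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit of model", x$model, ": logLik =", format(x$log_lik, digits = 6),
      "over", x$n_decisions, "decisions\n  params:",
      paste(names(x$params), round(x$params, 4), sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Per-subject model selection by likelihood
#'
#' Among the three models able to learn the correct path (model-based RL,
#' path integration, and model-free RL with action memory), returns the one
#' with the highest forced-choice log-likelihood on the identical decision
#' sequence.  The memoryless control, if present, is reported in the table
#' but excluded from selection.  Exact ties (all models have three free
#' parameters, so parameter count never discriminates) are broken by the
#' fixed order mf, pi, mb and flagged.
#'
#' @param fits Named list of \code{fit_result} objects for one subject.
#' @return List with \code{model} (selected), \code{table} (per-model
#'   log-likelihoods) and \code{tie} flag.
#' @export
select_model_per_subject <- function(fits) {
  nd <- unique(vapply(fits, function(f) f$n_decisions, numeric(1)))
  if (length(nd) != 1)
    stop("consistency error: fits computed on different decision sequences")
  tab <- data.frame(
    model = vapply(fits, function(f) f$model, character(1)),
    log_lik = vapply(fits, function(f) f$log_lik, numeric(1)),
    n_params = vapply(fits, function(f) length(f$params), numeric(1)),
    row.names = NULL)
  eligible <- tab[tab$model %in% c("mf", "pi", "mb"), ]
  if (nrow(eligible) == 0) stop("no sequence-capable model among fits")
  pref <- match(eligible$model, c("mf", "pi", "mb"))
  eligible <- eligible[order(-eligible$log_lik, pref), ]
  tie <- nrow(eligible) > 1 &&
    isTRUE(all.equal(eligible$log_lik[1], eligible$log_lik[2]))
  list(model = eligible$model[1], table = tab, tie = tie)
}
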