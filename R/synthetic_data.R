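# Synthetic-data generators: behavioural cohorts produced by known agents
# under the training protocol (ground truth stored for recovery scoring),
# and c-Fos density tables with planted rank-correlation blocks, hub wiring
# and parameter-density couplings via a Gaussian copula.

#' Specification of a synthetic behavioural cohort
#'
#' Per-subject true parameters are drawn uniformly from windows of
#' behaviourally plausible values (defaults for the memory-based model are
#' centred on eta = 0.3, beta = 5, gamma = 0.9, the regime recovered from
#' well-trained animals); identical true values across subjects would make
#' rank-agreement recovery metrics degenerate.
#'
#' @param n_subjects Number of subjects (default 15, the group size of the
#'   behavioural study).
#' @param model Generating model: \code{"mb"}, \code{"mf"}, \code{"mf0"} or
#'   \code{"pi"}.
#' @param param_ranges Named list of c(lower, upper) windows; defaults per
#'   model.
#' @param protocol A \code{\link{protocol_spec}}.
#' @param seed Integer seed (full determinism).
#' @return A \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 15, model = "mf", param_ranges = NULL,
                        protocol = protocol_spec(), seed = 1) {
  if (is.null(param_ranges)) {
    param_ranges <- switch(model,
      mf = , mf0 = list(eta = c(0.15, 0.45), beta = c(2, 10),
                        gamma = c(0.85, 0.95)),
      mb = list(eta = c(0.3, 0.8), beta = c(5, 15), gamma = c(0.7, 0.95)),
      pi = list(eta = c(0.3, 0.8), beta = c(5, 15), sigma0 = c(0.05, 0.3)),
      stop("unknown model: ", model))
  }
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 param_ranges = param_ranges, protocol = protocol,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# rebuild the full per-step record of one trial from its action codes
reconstruct_trial <- function(maze, actions, guided) {
  n <- length(actions)
  cell <- integer(n); obs <- character(n); avail <- character(n)
  rew <- integer(n)
  pose <- start_pose(maze)
  for (t in seq_len(n)) {
    if (guided[t] && (t == 1 || !guided[t - 1])) pose <- start_pose(maze)
    cell[t] <- pose$cell
    obs[t] <- observe(maze, pose)
    avail[t] <- paste(available_actions(maze, pose), collapse = ",")
    st <- step_pose(maze, pose, ACTIONS[actions[t] + 1])
    rew[t] <- as.integer(st$at_goal)
    pose <- st$pose
  }
  data.frame(step = seq_len(n), cell = cell, observation = obs,
             available = avail, action = ACTIONS[actions + 1],
             reward = rew, guided = guided)
}

#' Generate a synthetic behavioural cohort
#'
#' Runs each subject's generating agent freely through the full protocol
#' (timeout trials end with a guided return, rewarded like a free arrival)
#' and emits per-subject decision sequences, latency curves, free-success
#' indicators, days to the exploitation criterion, and the true parameters.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param maze A \code{maze_graph}.
#' @return List with \code{decisions} (list of decision-sequence data
#'   frames), \code{latency}, \code{success} and \code{correct}
#'   (subjects x trials; correct = free arrival by the direct path),
#'   \code{days_to_criterion} (computed on correct trials),
#'   \code{true_params} (data.frame) and \code{spec}.
#' @export
generate_behaviour <- function(spec, maze = build_default_maze()) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  ranges <- spec$param_ranges
  true_params <- as.data.frame(lapply(ranges, function(r)
    runif(n, r[1], r[2])))
  rownames(true_params) <- paste0("s", seq_len(n))

  n_tr <- n_trials_total(spec$protocol)
  decisions <- vector("list", n)
  latency <- matrix(NA_real_, n, n_tr,
                    dimnames = list(rownames(true_params), NULL))
  success <- matrix(NA, n, n_tr, dimnames = dimnames(latency))
  correct <- matrix(NA, n, n_tr, dimnames = dimnames(latency))
  tps <- spec$protocol$trials_per_session
  spd <- spec$protocol$sessions_per_day
  for (i in seq_len(n)) {
    sim <- simulate_agents(spec$model, as.list(true_params[i, ]), maze,
                           spec$protocol, n_agents = 1,
                           return_actions = TRUE)
    latency[i, ] <- sim$latency[1, ]
    success[i, ] <- sim$success[1, ]
    correct[i, ] <- sim$correct[1, ]
    trs <- sim$actions[[1]]
    recs <- lapply(seq_along(trs), function(tr) {
      d <- reconstruct_trial(maze, trs[[tr]]$actions, trs[[tr]]$guided)
      cbind(subject = rownames(true_params)[i],
            day = (tr - 1) %/% (tps * spd) + 1L,
            session = ((tr - 1) %/% tps) %% spd + 1L,
            trial = (tr - 1) %% tps + 1L, d)
    })
    decisions[[i]] <- do.call(rbind, recs)
  }
  names(decisions) <- rownames(true_params)
  list(decisions = decisions, latency = latency, success = success,
       correct = correct,
       days_to_criterion = days_to_criterion(correct, spec$protocol),
       true_params = true_params, spec = spec)
}

#' Specification of a synthetic c-Fos table
#'
#' Describes the rank-correlation structure planted in a generated density
#' table: blocks of mutually correlated regions, an optional hub region
#' wired into several blocks, and couplings between a region's density and a
#' subject-level model parameter.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param regions Region names (default the 34 quantified regions).
#' @param blocks List of \code{list(regions =, rho =)} within-block target
#'   Spearman correlations.
#' @param hub Optional \code{list(region =, blocks =, rho =)}: index vector
#'   \code{blocks} names the blocks the hub is wired into.
#' @param couplings Optional list of \code{list(region =, param =, rho =)}
#'   rank couplings to true parameters (applied by
#'   \code{\link{generate_coupled_dataset}}).
#' @param sdlog Log-scale dispersion of the density marginals.
#' @param group Group label of the generated subjects.
#' @param seed Integer seed.
#' @return A \code{fos_spec}.
#' @export
fos_spec <- function(n_subjects = 15, regions = fos_regions(),
                     blocks = list(), hub = NULL, couplings = NULL,
                     sdlog = 0.4, group = "exploitation", seed = 1) {
  for (b in blocks)
    if (abs(b$rho) >= 1) stop("block target rho must be in (-1, 1)")
  if (!is.null(hub) && abs(hub$rho) >= 1)
    stop("hub target rho must be in (-1, 1)")
  for (cp in couplings %||% list())
    if (abs(cp$rho) >= 1) stop("coupling strength must be in (-1, 1)")
  structure(list(n_subjects = as.integer(n_subjects), regions = regions,
                 blocks = blocks, hub = hub, couplings = couplings,
                 sdlog = sdlog, group = group, seed = as.integer(seed)),
            class = "fos_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# latent normal correlation target: Spearman rho -> Pearson r of the copula
rho_to_latent <- function(rho) 2 * sin(pi * rho / 6)

build_latent_sigma <- function(spec) {
  m <- length(spec$regions)
  S <- diag(m)
  dimnames(S) <- list(spec$regions, spec$regions)
  for (b in spec$blocks) {
    idx <- match(b$regions, spec$regions)
    r <- rho_to_latent(b$rho)
    S[idx, idx] <- r
    diag(S)[idx] <- 1
  }
  if (!is.null(spec$hub)) {
    hi <- match(spec$hub$region, spec$regions)
    r <- rho_to_latent(spec$hub$rho)
    for (bi in spec$hub$blocks) {
      idx <- match(spec$blocks[[bi]]$regions, spec$regions)
      S[hi, idx] <- r
      S[idx, hi] <- r
    }
  }
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    warning("target correlation structure not positive semi-definite; ",
            "nearest-PSD repair applied")
    vals <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    S <- stats::cov2cor(S)
    dimnames(S) <- list(spec$regions, spec$regions)
  }
  S
}

latent_to_density <- function(Z, spec) {
  m <- length(spec$regions)
  # cosmetic region-specific means (order 10^2..10^3 positives per mm^2)
  mu <- exp(seq(log(100), log(1000), length.out = m))
  d <- sapply(seq_len(m), function(j)
    stats::qlnorm(stats::pnorm(Z[, j]), meanlog = log(mu[j]),
                  sdlog = spec$sdlog))
  colnames(d) <- spec$regions
  rownames(d) <- paste0("s", seq_len(nrow(Z)))
  d
}

#' Generate a synthetic c-Fos density table
#'
#' Samples a latent multivariate normal with the block/hub correlation
#' structure (Spearman targets converted to latent Pearson via
#' \eqn{r = 2\sin(\pi\rho/6)}) and maps it through monotone log-normal
#' marginals to plausible density scales, so the planted Spearman structure
#' is preserved exactly in distribution.
#'
#' @param spec A \code{\link{fos_spec}}.
#' @return List with \code{table} (a \code{fos_table}) and \code{truth}
#'   (block membership, hub, achieved latent correlation).
#' @export
generate_fos_table <- function(spec) {
  set.seed(spec$seed)
  S <- build_latent_sigma(spec)
  Z <- MASS::mvrnorm(spec$n_subjects, mu = rep(0, ncol(S)), Sigma = S)
  d <- latent_to_density(Z, spec)
  truth <- list(
    blocks = lapply(spec$blocks, function(b) b$regions),
    hub = spec$hub$region,
    block_of = block_labels(spec),
    latent_sigma = S)
  list(table = fos_table(d, rep(spec$group, spec$n_subjects)),
       truth = truth)
}

block_labels <- function(spec) {
  lab <- setNames(rep(0L, length(spec$regions)), spec$regions)
  for (bi in seq_along(spec$blocks))
    lab[spec$blocks[[bi]]$regions] <- bi
  lab
}

#' Generate matched behaviour and c-Fos data with planted couplings
#'
#' Runs \code{\link{generate_behaviour}}, then generates the c-Fos table
#' with selected regions' latent values rank-coupled to each subject's true
#' parameter at the stated strength and sign before the monotone transform.
#'
#' @param cohort A \code{\link{cohort_spec}}.
#' @param fos A \code{\link{fos_spec}} whose \code{couplings} reference
#'   parameters of the cohort's model.
#' @param maze A \code{maze_graph}.
#' @return List with \code{behaviour}, \code{table}, and \code{truth}
#'   (including the planted couplings).
#' @export
generate_coupled_dataset <- function(cohort, fos,
                                     maze = build_default_maze()) {
  if (fos$n_subjects != cohort$n_subjects)
    stop("cohort and fos specs must have the same number of subjects")
  behaviour <- generate_behaviour(cohort, maze)
  set.seed(fos$seed)
  S <- build_latent_sigma(fos)
  Z <- MASS::mvrnorm(fos$n_subjects, mu = rep(0, ncol(S)), Sigma = S)
  n <- fos$n_subjects
  for (cp in fos$couplings %||% list()) {
    pv <- behaviour$true_params[[cp$param]]
    if (is.null(pv)) stop("coupling references unknown parameter ", cp$param)
    zp <- stats::qnorm((rank(pv, ties.method = "average") - 0.5) / n)
    j <- match(cp$region, fos$regions)
    Z[, j] <- cp$rho * zp + sqrt(1 - cp$rho^2) * Z[, j]
  }
  d <- latent_to_density(Z, fos)
  truth <- list(blocks = lapply(fos$blocks, function(b) b$regions),
                hub = fos$hub$region, couplings = fos$couplings,
                block_of = block_labels(fos))
  list(behaviour = behaviour,
       table = fos_table(d, rep(fos$group, n)),
       truth = truth)
}
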