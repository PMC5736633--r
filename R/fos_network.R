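# c-Fos functional-connectivity stage: density normalization, Spearman
# correlation matrices, three-tier thresholded co-activation graphs, hub
# identification with leave-one-out robustness, Markov clustering, and
# correlation of fitted learning parameters with regional densities.

#' The 34 quantified brain regions
#'
#' Abbreviated names of the regions in which c-Fos positive cell densities
#' are quantified: prefrontal/cingulate/retrosplenial/parietal/entorhinal and
#' auditory cortices, dorsal and ventral striatal regions, dopaminergic
#' nuclei, dorsal and ventral hippocampal subfields, and cerebellar lobules,
#' hemispheres and nuclei.
#'
#' @return Character vector of length 34.
#' @export
fos_regions <- function() {
  c("PrL", "IL", "Cg1", "Cg2", "RSD", "RSG", "Par", "PPar", "MEC", "Au1",
    "DMS", "DLS", "AcbC", "AcbSh", "VTA", "SNc",
    "dCA1", "dCA2", "dCA3", "dDG", "vCA1", "vCA3", "vDG",
    "Lob4_5", "Lob6", "Lob7", "Lob9", "Lob10",
    "Sim", "Crus1", "Crus2", "DentN", "FastN", "IntN")
}

#' c-Fos density table
#'
#' @param densities Numeric matrix, rows = subjects (rownames = ids),
#'   columns = regions; non-negative, no missing cells.
#' @param group Character/factor vector of group labels per subject (e.g.
#'   exploitation, swim-control, cage-control).
#' @param cohort Immunohistochemical cohort label per subject (normalization
#'   is performed within cohorts); recycled if length 1.
#' @param normalization Provenance string (\code{"raw"} for raw counts).
#' @return A \code{fos_table}.
#' @export
fos_table <- function(densities, group, cohort = 1L,
                      normalization = "raw") {
  densities <- as.matrix(densities)
  if (anyNA(densities)) stop("fos table has missing cells")
  if (any(densities < 0)) stop("fos densities must be non-negative")
  if (length(group) != nrow(densities))
    stop("group labels do not match subjects")
  if (is.null(rownames(densities)))
    rownames(densities) <- paste0("s", seq_len(nrow(densities)))
  structure(list(densities = densities,
                 group = as.character(group),
                 cohort = rep_len(as.character(cohort), nrow(densities)),
                 normalization = normalization),
            class = "fos_table")
}

#' @export
print.fos_table <- function(x, ...) {
  cat("c-Fos table:", nrow(x$densities), "subjects x", ncol(x$densities),
      "regions (", x$normalization, ")\n  groups:",
      paste(names(table(x$group)), table(x$group), sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

#' Combine c-Fos tables (e.g. experimental + control groups)
#' @param ... \code{fos_table} objects with identical regions and
#'   normalization provenance.
#' @export
combine_fos <- function(...) {
  tabs <- list(...)
  regions <- colnames(tabs[[1]]$densities)
  for (t in tabs)
    if (!identical(colnames(t$densities), regions))
      stop("region sets differ between tables")
  fos_table(do.call(rbind, lapply(tabs, function(t) t$densities)),
            unlist(lapply(tabs, function(t) t$group)),
            unlist(lapply(tabs, function(t) t$cohort)),
            tabs[[1]]$normalization)
}

#' Normalize densities to a control group
#'
#' Within each immunohistochemical cohort, each region's raw count is divided
#' by the same region's mean raw count of the control group and expressed as
#' a percentage (\code{mode = "percent"}), or the control mean is subtracted
#' (\code{mode = "difference"}, used in robustness analyses).  Regions whose
#' control mean is zero are flagged and excluded with a warning.
#'
#' @param raw A \code{fos_table} of raw densities containing both the
#'   experimental and the control subjects.
#' @param control_group Group label of the control subjects.
#' @param mode \code{"percent"} (default) or \code{"difference"}.
#' @return A normalized \code{fos_table} (all subjects, normalization
#'   provenance updated).
#' @export
normalize_density <- function(raw, control_group,
                              mode = c("percent", "difference")) {
  mode <- match.arg(mode)
  d <- raw$densities
  out <- d
  drop_regions <- character(0)
  for (ch in unique(raw$cohort)) {
    in_ch <- raw$cohort == ch
    ctrl <- in_ch & raw$group == control_group
    if (!any(ctrl))
      stop("no subjects of control group '", control_group,
           "' in cohort ", ch)
    cm <- colMeans(d[ctrl, , drop = FALSE])
    if (mode == "percent") {
      zero <- cm == 0
      drop_regions <- union(drop_regions, colnames(d)[zero])
      out[in_ch, ] <- 100 * sweep(d[in_ch, , drop = FALSE], 2, cm, "/")
    } else {
      out[in_ch, ] <- sweep(d[in_ch, , drop = FALSE], 2, cm, "-")
    }
  }
  if (length(drop_regions)) {
    warning("zero control mean; region(s) excluded: ",
            paste(drop_regions, collapse = ", "))
    out <- out[, setdiff(colnames(out), drop_regions), drop = FALSE]
  }
  res <- fos_table(pmax(out, 0), raw$group, raw$cohort,
                   normalization = paste0(mode, "_of_", control_group))
  if (mode == "difference") res$densities <- out  # differences may be negative
  res
}

#' Spearman correlation matrix of one group
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between the
#' regional densities of the subjects in \code{group}.
#'
#' @param table A \code{fos_table}.
#' @param group Group label (default: use all subjects).
#' @return Symmetric regions x regions matrix with unit diagonal; pairs
#'   involving a constant region are \code{NA} (with a warning).
#' @export
spearman_matrix <- function(table, group = NULL) {
  d <- table$densities
  if (!is.null(group)) d <- d[table$group == group, , drop = FALSE]
  if (nrow(d) < 5) stop("need at least 5 subjects for correlation")
  constant <- apply(d, 2, function(x) stats::sd(x) == 0)
  m <- suppressWarnings(stats::cor(d, method = "spearman"))
  if (any(constant)) {
    warning("constant region(s), correlations undefined: ",
            paste(colnames(d)[constant], collapse = ", "))
    m[constant, ] <- NA; m[, constant] <- NA
  }
  diag(m) <- 1
  attr(m, "n_subjects") <- nrow(d)
  m
}

#' Critical Spearman correlation for a two-tailed significance level
#'
#' The smallest correlation (two decimal places) significant at
#' \code{alpha} under the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} with \eqn{n-2} degrees of freedom,
#' obtained by inverting the critical t quantile:
#' \eqn{\rho_c = t_c / \sqrt{n - 2 + t_c^2}}.  At \eqn{n = 15} this gives the
#' three network tiers 0.51 (\eqn{p \le 0.05}), 0.64 (\eqn{p \le 0.01}) and
#' 0.73 (\eqn{p \le 0.002}).
#'
#' @param n_subjects Sample size (at least 5).
#' @param alpha_two_tailed Two-tailed significance level.
#' @return The critical \eqn{\rho}, rounded to 2 decimal places.
#' @export
critical_rho <- function(n_subjects, alpha_two_tailed) {
  if (n_subjects < 5) stop("need at least 5 subjects")
  tc <- stats::qt(1 - alpha_two_tailed / 2, df = n_subjects - 2)
  round(tc / sqrt(n_subjects - 2 + tc^2), 2)
}

#' Threshold a correlation matrix into a co-activation graph
#'
#' Undirected graph with an edge wherever \eqn{\rho \ge} \code{rho_min}
#' (positive correlations only; negative correlations are not considered).
#' Edge weights carry the source \eqn{\rho}.
#'
#' @param matrix Correlation matrix from \code{\link{spearman_matrix}}.
#' @param rho_min Threshold in (0, 1].
#' @return An \code{igraph} graph with graph attribute \code{rho_min}.
#' @export
threshold_graph <- function(matrix, rho_min) {
  if (rho_min <= 0 || rho_min > 1) stop("rho_min must be in (0, 1]")
  a <- matrix
  a[is.na(a)] <- 0
  a[a < rho_min] <- 0
  diag(a) <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::set_graph_attr(g, "rho_min", rho_min)
  g
}

#' Degree and betweenness centrality
#'
#' Degree counts the regions a region is significantly correlated to (edges
#' of the binarized graph); betweenness is standard shortest-path
#' betweenness on the unweighted graph, splitting evenly across equal-length
#' geodesics.
#'
#' @param graph An \code{igraph} graph from \code{\link{threshold_graph}}.
#' @return \code{data.frame} with \code{region}, \code{degree},
#'   \code{betweenness}.
#' @export
graph_centrality <- function(graph) {
  data.frame(region = igraph::V(graph)$name,
             degree = as.numeric(igraph::degree(graph)),
             betweenness = as.numeric(igraph::betweenness(graph,
                                                          weights = NA)),
             row.names = NULL)
}

#' Build the three-tier networks of a group
#'
#' @param table A normalized \code{fos_table}.
#' @param group Group label (default all subjects).
#' @param alphas Named two-tailed significance levels of the tiers.
#' @return Named list of \code{igraph} graphs (low/main/high confidence).
#' @export
build_tier_graphs <- function(table, group = NULL,
                              alphas = c(low = 0.05, main = 0.01,
                                         high = 0.002)) {
  m <- spearman_matrix(table, group)
  n <- attr(m, "n_subjects")
  lapply(alphas, function(a) threshold_graph(m, critical_rho(n, a)))
}

percentile_rank <- function(x) 100 * rank(x, ties.method = "average") /
  length(x)

#' Identify hub regions across the three confidence tiers
#'
#' A region is a candidate hub when it ranks strictly above the given
#' percentile for both degree and betweenness in each of the three
#' confidence-level networks (average ranks for ties).
#'
#' @param graphs Named list of the three tier graphs (same node set).
#' @param percentile Rank percentile that must be exceeded (default 80).
#' @return A \code{hub_report}: list with \code{hubs} (character vector) and
#'   \code{ranks} (per-tier percentile ranks per region).
#' @export
identify_hubs <- function(graphs, percentile = 80) {
  if (any(vapply(graphs, function(g) igraph::ecount(g) == 0, logical(1))))
    warning("empty tier graph: no hubs can be identified")
  regions <- igraph::V(graphs[[1]])$name
  pass <- matrix(TRUE, length(regions), length(graphs),
                 dimnames = list(regions, names(graphs)))
  ranks <- list()
  for (tn in seq_along(graphs)) {
    ct <- graph_centrality(graphs[[tn]])
    pd <- percentile_rank(ct$degree)
    pb <- percentile_rank(ct$betweenness)
    pass[, tn] <- pd > percentile & pb > percentile
    ranks[[names(graphs)[tn]]] <-
      data.frame(region = ct$region, degree_pct = pd, betweenness_pct = pb)
  }
  structure(list(hubs = regions[rowSums(pass) == ncol(pass)],
                 pass = pass, ranks = ranks, percentile = percentile),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat("Hubs (>", x$percentile, "th percentile, all tiers): ",
      if (length(x$hubs)) paste(x$hubs, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' Leave-one-out hub robustness
#'
#' Repeats the full hub-identification procedure (correlation matrix,
#' critical thresholds at n-1, three tier graphs, percentile conjunction)
#' with each subject of the group removed in turn.
#'
#' @param table A normalized \code{fos_table}.
#' @param group Group label (default all subjects).
#' @param alphas Tier significance levels.
#' @param percentile Hub percentile.
#' @return \code{data.frame} with \code{region}, \code{hub_count},
#'   \code{n_networks}.
#' @export
leave_one_out_hubs <- function(table, group = NULL,
                               alphas = c(low = 0.05, main = 0.01,
                                          high = 0.002),
                               percentile = 80) {
  keep <- if (is.null(group)) rep(TRUE, nrow(table$densities)) else
    table$group == group
  idx <- which(keep)
  if (length(idx) < 6) stop("need at least 6 subjects for leave-one-out")
  regions <- colnames(table$densities)
  counts <- setNames(numeric(length(regions)), regions)
  for (i in idx) {
    sub <- fos_table(table$densities[setdiff(idx, i), , drop = FALSE],
                     table$group[setdiff(idx, i)],
                     table$cohort[setdiff(idx, i)], table$normalization)
    hubs <- identify_hubs(build_tier_graphs(sub, NULL, alphas), percentile)
    counts[hubs$hubs] <- counts[hubs$hubs] + 1
  }
  data.frame(region = regions, hub_count = as.numeric(counts),
             n_networks = length(idx), row.names = NULL)
}

#' Markov clustering of the main-tier network
#'
#' Markov Cluster Algorithm on the correlation-weighted adjacency matrix with
#' unit self-loops: alternate expansion (matrix squaring) and inflation
#' (elementwise power \code{inflation}, column renormalization) until the
#' flow matrix is idempotent.  Every node is assigned to exactly one cluster
#' (attractor overlap resolved to the first attractor in node order).
#'
#' @param graph The main-tier (\eqn{p \le 0.01}) \code{igraph} graph.
#' @param inflation Inflation parameter (default 2.1).
#' @param max_iter Iteration cap.
#' @param tol Idempotence tolerance.
#' @return Named integer vector of cluster ids (1-based, by first member).
#' @export
mcl_clusters <- function(graph, inflation = 2.1, max_iter = 200,
                         tol = 1e-8) {
  a <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = FALSE))
  n <- nrow(a)
  diag(a) <- 1  # unit self-loops
  m <- sweep(a, 2, colSums(a), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m            # expansion
    m2 <- m2^inflation       # inflation
    m2[m2 < 1e-12] <- 0
    cs <- colSums(m2)
    cs[cs == 0] <- 1
    m2 <- sweep(m2, 2, cs, "/")
    if (max(abs(m2 - m)) < tol) { m <- m2; converged <- TRUE; break }
    m <- m2
  }
  if (!converged)
    warning("MCL did not reach idempotence within ", max_iter,
            " iterations; returning current partition")
  attractors <- which(diag(m) > 1e-6)
  owners <- lapply(seq_len(n), function(j) attractors[m[attractors, j] > 1e-6])
  # merge attractor systems sharing any attracted node
  comp <- seq_along(attractors)
  names(comp) <- attractors
  for (ow in owners) {
    if (length(ow) > 1) {
      cls <- unique(comp[as.character(ow)])
      comp[comp %in% cls] <- cls[1]
    }
  }
  cluster <- integer(n)
  for (j in seq_len(n)) {
    ow <- owners[[j]]
    cluster[j] <- if (length(ow) == 0) -j else comp[as.character(ow[1])]
  }
  cluster <- as.integer(factor(cluster, levels = unique(cluster)))
  names(cluster) <- igraph::V(graph)$name
  cluster
}

spearman_test <- function(x, y) {
  n <- length(x)
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Correlate fitted learning parameters with regional densities
#'
#' Spearman correlation (t approximation, consistent with the network
#' thresholds) between each fitted parameter and each region's normalized
#' density across subjects, Benjamini-Hochberg corrected within each
#' parameter across the region family.  Constant parameters (or regions)
#' yield undefined correlations and are excluded.
#'
#' @param params \code{data.frame}/matrix, rows = subjects (rownames = ids
#'   matching the table), columns = parameters (e.g. eta, beta, gamma).
#' @param table A normalized \code{fos_table} restricted to the same
#'   subjects.
#' @param regions Regions to test (default all).
#' @param alpha Significance level on the q values.
#' @return \code{data.frame} with \code{parameter}, \code{region},
#'   \code{rho}, \code{p}, \code{q}, \code{significant}.
#' @export
param_fos_correlation <- function(params, table,
                                  regions = colnames(table$densities),
                                  alpha = 0.05) {
  params <- as.matrix(params)
  d <- table$densities[, regions, drop = FALSE]
  if (nrow(params) != nrow(d))
    stop("consistency error: subjects differ between parameters and table")
  if (!is.null(rownames(params)) &&
      !identical(rownames(params), rownames(d)))
    stop("consistency error: subject ids differ between parameters and table")
  out <- do.call(rbind, lapply(colnames(params), function(pn) {
    res <- t(vapply(regions, function(rg)
      spearman_test(params[, pn], d[, rg]), numeric(2)))
    df <- data.frame(parameter = pn, region = regions,
                     rho = res[, 1], p = res[, 2], row.names = NULL)
    df$q <- NA_real_
    ok <- !is.na(df$p)
    df$q[ok] <- stats::p.adjust(df$p[ok], method = "BH")
    df
  }))
  out$significant <- !is.na(out$q) & out$q < alpha
  out
}
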