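# Readers and writers binding the pipeline stages: decision sequences and
# c-Fos tables as TSV/CSV, maze definitions as TSV, network graphs as edge
# lists and GraphML, and JSON reports.  All round trips are lossless; schema
# violations name the offending column/row.

DECISION_COLUMNS <- c("subject", "day", "session", "trial", "step", "cell",
                      "observation", "available", "action", "reward",
                      "guided")

#' Write / read a decision sequence
#'
#' Tab-separated, one row per decision step with columns subject, day,
#' session, trial, step, cell, observation, available (comma-separated),
#' action, reward, guided.
#'
#' @param decisions Decision-sequence \code{data.frame}.
#' @param path File path.
#' @return \code{read_decisions} returns the validated \code{data.frame}.
#' @export
write_decisions <- function(decisions, path) {
  write.table(decisions[, DECISION_COLUMNS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decisions
#' @export
read_decisions <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(DECISION_COLUMNS, names(d))
  if (length(missing))
    stop("decision file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(!d$action %in% ACTIONS)
  if (length(bad))
    stop("decision file ", path, ": invalid action at row ", bad[1])
  av <- strsplit(d$available, ",")
  bad <- which(!mapply(function(a, s) a %in% s, d$action, av))
  if (length(bad))
    stop("decision file ", path, ": action not in available set at row ",
         bad[1])
  if (!all(d$reward %in% c(0L, 1L)))
    stop("decision file ", path, ": column reward must be 0/1")
  d$guided <- as.logical(d$guided)
  d
}

#' Write / read a c-Fos density table
#'
#' CSV with columns subject, group, cohort followed by one column per
#' region.
#'
#' @param table A \code{fos_table}.
#' @param path File path.
#' @return \code{read_fos} returns a \code{fos_table}.
#' @export
write_fos <- function(table, path) {
  df <- data.frame(subject = rownames(table$densities),
                   group = table$group, cohort = table$cohort,
                   table$densities, check.names = FALSE)
  attr(df, "normalization") <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fos
#' @param normalization Provenance string recorded on the read table.
#' @export
read_fos <- function(path, normalization = "raw") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("subject", "group", "cohort"))
    if (!col %in% names(df))
      stop("fos file ", path, ": missing column ", col)
  regions <- setdiff(names(df), c("subject", "group", "cohort"))
  m <- as.matrix(df[, regions, drop = FALSE])
  if (!is.numeric(m))
    stop("fos file ", path, ": non-numeric region column ",
         regions[which(!apply(df[, regions, drop = FALSE], 2,
                              is.numeric))[1]])
  rownames(m) <- df$subject
  fos_table(m, df$group, df$cohort, normalization)
}

#' Write / read a maze definition
#'
#' TSV with columns id, kind, x_cm, y_cm, neighbours (semicolon-separated
#' ids), start, goal.
#'
#' @param maze A \code{maze_graph}.
#' @param path File path.
#' @return \code{read_maze} returns a \code{maze_graph} built from the file.
#' @export
write_maze <- function(maze, path) {
  df <- data.frame(
    id = maze$cells$id, kind = maze$cells$kind,
    x_cm = maze$cells$x, y_cm = maze$cells$y,
    neighbours = vapply(maze$adjacency, paste, character(1), collapse = ";"),
    start = maze$cells$id == maze$start,
    goal = maze$cells$id == maze$goal)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_maze
#' @param step_length_cm Step length passed to
#'   \code{\link{build_default_maze}}.
#' @export
read_maze <- function(path, step_length_cm = 20.58) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("id", "kind", "x_cm", "y_cm", "neighbours", "start", "goal")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("maze file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  build_default_maze(config = df, step_length_cm = step_length_cm)
}

#' Export a network graph
#'
#' Writes the graph as a tab-separated edge list (with rho weights) and,
#' optionally, GraphML with per-node degree, betweenness, hub flag and
#' cluster id attributes.
#'
#' @param graph An \code{igraph} graph from \code{\link{threshold_graph}}.
#' @param edgelist_path Path of the edge-list TSV (\code{NULL} to skip).
#' @param graphml_path Path of the GraphML file (\code{NULL} to skip).
#' @param hubs Optional character vector of hub regions.
#' @param clusters Optional named cluster vector from
#'   \code{\link{mcl_clusters}}.
#' @export
export_graph <- function(graph, edgelist_path = NULL, graphml_path = NULL,
                         hubs = NULL, clusters = NULL) {
  ct <- graph_centrality(graph)
  g <- igraph::set_vertex_attr(graph, "degree", value = ct$degree)
  g <- igraph::set_vertex_attr(g, "betweenness", value = ct$betweenness)
  if (!is.null(hubs))
    g <- igraph::set_vertex_attr(g, "hub",
                                 value = igraph::V(g)$name %in% hubs)
  if (!is.null(clusters))
    g <- igraph::set_vertex_attr(g, "cluster",
                                 value = as.integer(clusters[igraph::V(g)$name]))
  if (!is.null(edgelist_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("region_a", "region_b")
    write.table(el, edgelist_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(g)
}

#' Write a JSON report
#'
#' @param x A list (e.g. fit results, test reports).
#' @param path File path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
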