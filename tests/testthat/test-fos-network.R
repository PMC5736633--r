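toy_fos <- function() {
  # 6 subjects (3 experimental, 3 control), 3 regions, one cohort
  d <- rbind(c(10, 30, 60), c(12, 18, 45), c(8, 22, 75),
             c(10, 20, 30), c(12, 18, 32), c(8, 22, 28))
  colnames(d) <- c("A", "B", "C")
  fos_table(d, c(rep("exploitation", 3), rep("swim", 3)))
}

test_that("density normalization divides by the control-group mean per region", {
  raw <- toy_fos()
  norm <- normalize_density(raw, "swim")
  # control means are (10, 20, 30); a raw value equal to the mean gives 100
  expect_equal(unname(norm$densities[1, "A"]), 100)
  expect_equal(unname(norm$densities[1, "B"]), 150)  # 100 * 30 / 20
  # controls normalized to themselves average 100 in every region
  expect_equal(unname(colMeans(norm$densities[norm$group == "swim", ])),
               c(100, 100, 100))
  expect_match(norm$normalization, "percent_of_swim")

  diff <- normalize_density(raw, "swim", mode = "difference")
  expect_equal(unname(diff$densities[1, "B"]), 10)

  zero <- raw
  zero$densities[4:6, "C"] <- 0
  expect_warning(nz <- normalize_density(zero, "swim"), "excluded")
  expect_false("C" %in% colnames(nz$densities))
})

test_that("Spearman matrices are rank-based, symmetric, unit-diagonal", {
  d <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(5, 4, 3, 2, 1), d = c(3, 1, 2, 5, 4))
  ft <- fos_table(d, rep("g", 5))
  m <- spearman_matrix(ft)
  expect_equal(unname(m["a", "b"]), 1)      # monotone invariance
  expect_equal(unname(m["a", "c"]), -1)
  expect_equal(unname(m["a", "d"]), 0.6)    # hand rank computation
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))

  dc <- cbind(d, e = rep(7, 5))
  expect_warning(mc <- spearman_matrix(fos_table(dc, rep("g", 5))),
                 "constant")
  expect_true(all(is.na(mc["e", c("a", "b", "c", "d")])))

  expect_error(spearman_matrix(fos_table(d[1:4, ], rep("g", 4))),
               "at least 5")
})

test_that("critical correlations shrink with sample size and significance level", {
  expect_error(critical_rho(4, 0.05), "at least 5")
  expect_gt(critical_rho(15, 0.002), critical_rho(15, 0.01))
  expect_gt(critical_rho(15, 0.01), critical_rho(15, 0.05))
  expect_gt(critical_rho(10, 0.01), critical_rho(20, 0.01))
  # the critical value is significant at alpha under the t approximation
  for (n in c(10, 15, 25)) {
    rc <- critical_rho(n, 0.01) + 0.005  # undo the 2 dp rounding
    t <- rc * sqrt((n - 2) / (1 - rc^2))
    expect_lte(2 * pt(-t, n - 2), 0.01)
  }
})

test_that("thresholded graphs keep only positive supra-threshold edges, nested", {
  m <- diag(4)
  rownames(m) <- colnames(m) <- c("A", "B", "C", "D")
  m["A", "B"] <- m["B", "A"] <- 0.7
  m["C", "D"] <- m["D", "C"] <- -0.9     # negative: never an edge
  g64 <- threshold_graph(m, 0.64)
  g73 <- threshold_graph(m, 0.73)
  expect_equal(igraph::ecount(g64), 1)
  expect_equal(igraph::ecount(g73), 0)
  expect_equal(igraph::E(g64)$weight, 0.7)
  expect_error(threshold_graph(m, 0), "rho_min")

  set.seed(2)
  r <- matrix(runif(100, -1, 1), 10)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  rownames(r) <- colnames(r) <- letters[1:10]
  edges <- function(g) apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  e51 <- edges(threshold_graph(r, 0.51))
  e64 <- edges(threshold_graph(r, 0.64))
  e73 <- edges(threshold_graph(r, 0.73))
  expect_true(all(e73 %in% e64))
  expect_true(all(e64 %in% e51))
})

test_that("centrality matches known graphs", {
  path <- diag(3)
  rownames(path) <- colnames(path) <- c("A", "B", "C")
  path["A", "B"] <- path["B", "A"] <- 0.9
  path["B", "C"] <- path["C", "B"] <- 0.9
  ct <- graph_centrality(threshold_graph(path, 0.5))
  expect_equal(ct$degree, c(1, 2, 1))
  expect_equal(ct$betweenness, c(0, 1, 0))

  k4 <- matrix(0.9, 4, 4)
  diag(k4) <- 1
  rownames(k4) <- colnames(k4) <- LETTERS[1:4]
  expect_equal(graph_centrality(threshold_graph(k4, 0.5))$betweenness,
               rep(0, 4))

  star <- diag(5)
  rownames(star) <- colnames(star) <- c("hub", "l1", "l2", "l3", "l4")
  star["hub", 2:5] <- star[2:5, "hub"] <- 0.9
  cs <- graph_centrality(threshold_graph(star, 0.5))
  expect_equal(cs$degree[1], 4)
  expect_equal(cs$betweenness[2:5], rep(0, 4))
})

test_that("hub identification demands the percentile conjunction in all tiers", {
  flat <- matrix(0.8, 6, 6)
  diag(flat) <- 1
  rownames(flat) <- colnames(flat) <- LETTERS[1:6]
  tiers <- lapply(c(0.51, 0.64, 0.73), function(r) threshold_graph(flat, r))
  names(tiers) <- c("low", "main", "high")
  expect_equal(identify_hubs(tiers)$hubs, character(0)) # all tied: no hubs

  # a node above threshold in two tiers but not the third is not a hub
  star <- diag(6)
  rownames(star) <- colnames(star) <- LETTERS[1:6]
  star["A", 2:6] <- star[2:6, "A"] <- 0.7    # strong star in low/main only
  star["B", "C"] <- star["C", "B"] <- 0.74   # the only high-tier edge
  tiers2 <- lapply(c(low = 0.51, main = 0.64, high = 0.73),
                   function(r) threshold_graph(star, r))
  h2 <- identify_hubs(tiers2)
  expect_false("A" %in% h2$hubs)
  expect_true(all(h2$pass["A", c("low", "main")]))
  expect_false(h2$pass["A", "high"])
})

test_that("leave-one-out evaluates one network per held-out subject", {
  g <- generate_fos_table(fos_spec(n_subjects = 15, seed = 9))
  loo <- suppressWarnings(leave_one_out_hubs(g$table))
  expect_equal(unique(loo$n_networks), 15)
  expect_equal(nrow(loo), 34)
  # pure noise: the modal outcome is no hub at all
  expect_lt(max(loo$hub_count), 8)
})

test_that("Markov clustering respects components and isolates", {
  m <- diag(7)
  rownames(m) <- colnames(m) <- letters[1:7]
  m[1:3, 1:3] <- 0.9; m[4:6, 4:6] <- 0.9 # two triangles, one isolate
  diag(m) <- 1
  g <- threshold_graph(m, 0.5)
  cl <- mcl_clusters(g)
  expect_equal(length(unique(cl)), 3)
  expect_equal(length(unique(cl[1:3])), 1)
  expect_equal(length(unique(cl[4:6])), 1)
  expect_false(cl[7] %in% cl[1:6])
})

test_that("parameter-density correlations handle degenerate inputs", {
  g <- generate_fos_table(fos_spec(n_subjects = 13, seed = 4))
  tab <- g$table
  set.seed(1)
  pars <- cbind(eta = runif(13), beta = runif(13), gamma = rep(0.9, 13))
  rownames(pars) <- rownames(tab$densities)
  res <- param_fos_correlation(pars, tab)
  # constant parameter: correlations undefined, nothing flagged
  expect_true(all(is.na(res$rho[res$parameter == "gamma"])))
  expect_false(any(res$significant[res$parameter == "gamma"]))
  expect_equal(nrow(res), 3 * 34)

  bad <- pars[1:12, ]
  expect_error(param_fos_correlation(bad, tab), "consistency error")
})

test_that("a planted negative density-parameter coupling is flagged", {
  cs <- cohort_spec(13, "mf", protocol = short_protocol, seed = 2)
  fs <- fos_spec(n_subjects = 13,
                 couplings = list(list(region = "dCA1", param = "beta",
                                       rho = -0.9)), seed = 2)
  cd <- generate_coupled_dataset(cs, fs, default_maze)
  res <- param_fos_correlation(as.matrix(cd$behaviour$true_params), cd$table)
  hit <- res[res$region == "dCA1" & res$parameter == "beta", ]
  expect_true(hit$significant)
  expect_lt(hit$rho, 0)
  # nothing else crosses the threshold
  expect_lte(sum(res$significant), 2)
})
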