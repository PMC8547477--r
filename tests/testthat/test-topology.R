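# build a cooccurrence_network from an igraph graph with unit |rho|
net_from_igraph <- function(g, rho = 0.5) {
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- paste0("N", seq_len(igraph::vcount(g)))
  cooccurrence_network(
    data.frame(otu = ids),
    data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
               rho = rho, padj = 0.001))
}

test_that("modularity from detect_modules equals the direct formula", {
  set.seed(1)
  g <- igraph::sample_gnp(40, 0.15)
  net <- net_from_igraph(g)
  for (gamma in c(1, 8)) {
    part <- detect_modules(net, resolution = gamma, seed = 2,
                           n_restarts = 3)
    expect_equal(part$modularity,
                 modularity_direct(net, part$membership, gamma),
                 tolerance = 1e-10)
    expect_true(part$modularity >= -0.5 && part$modularity <= 1)
    expect_equal(sum(part$sizes), igraph::vcount(g))
  }
  # one-module partition at gamma = 1 has Q exactly 0
  one <- stats::setNames(rep(1L, 40), net$nodes$otu)
  expect_identical(modularity_direct(net, one, 1), 0)
  expect_error(detect_modules(net, resolution = 0), "positive")
})

test_that("planted partitions are recovered with high NMI", {
  set.seed(3)
  g <- igraph::sample_sbm(200, pref.matrix = matrix(c(0.3, 0.01,
                                                      0.01, 0.3), 2),
                          block.sizes = c(100, 100))
  net <- net_from_igraph(g)
  part <- detect_modules(net, resolution = 1, seed = 4, n_restarts = 5)
  truth <- rep(1:2, each = 100)
  nmi <- igraph::compare(part$membership[net$nodes$otu], truth,
                         method = "nmi")
  expect_gt(nmi, 0.9)
})

test_that("raising the resolution never grows the largest module", {
  set.seed(5)
  g <- igraph::sample_sbm(120, pref.matrix = matrix(c(0.3, 0.02, 0.02,
                                                      0.02, 0.3, 0.02,
                                                      0.02, 0.02, 0.3), 3),
                          block.sizes = c(40, 40, 40))
  net <- net_from_igraph(g)
  largest <- vapply(c(1, 2, 4, 8), function(gamma)
    detect_modules(net, resolution = gamma, seed = 6,
                   n_restarts = 3)$sizes[1], integer(1))
  expect_true(all(diff(largest) <= 0))
})

test_that("PageRank matches symmetry and the dense linear solve", {
  # cycle: uniform scores
  cyc <- net_from_igraph(igraph::make_ring(8))
  pr <- pagerank_scores(cyc)
  expect_equal(unname(pr), rep(1 / 8, 8), tolerance = 1e-10)
  expect_equal(sum(pr), 1, tolerance = 1e-12)

  # star: hub above leaves, equal to the dense solve
  star <- net_from_igraph(igraph::make_star(5, mode = "undirected"))
  prs <- pagerank_scores(star, damping = 0.85)
  hub <- names(which.max(prs))
  expect_true(all(prs[hub] > prs[setdiff(names(prs), hub)]))

  dense_solve <- function(net, d = 0.85) {
    g <- as_igraph(net)
    A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    n <- nrow(A)
    W <- A / rowSums(A)               # row-stochastic transition
    x <- solve(diag(n) - d * t(W), rep((1 - d) / n, n))
    stats::setNames(x / sum(x), igraph::V(g)$name)
  }
  expect_equal(prs, dense_solve(star)[names(prs)], tolerance = 1e-10)

  set.seed(7)
  g <- igraph::sample_gnp(50, 0.2)
  g <- igraph::induced_subgraph(g, which(igraph::degree(g) > 0))
  net <- net_from_igraph(g)
  expect_equal(pagerank_scores(net), dense_solve(net), tolerance = 1e-8)
  expect_error(pagerank_scores(net, damping = 1.2), "damping")
})

test_that("degree stats obey the handshake lemma and regime diagnostics", {
  set.seed(8)
  g <- igraph::sample_gnp(80, 0.1)
  g <- igraph::induced_subgraph(g, which(igraph::degree(g) > 0))
  net <- net_from_igraph(g)
  ds <- degree_stats(net, seed = 1)
  expect_equal(sum(ds$degrees), 2 * nrow(net$edges))
  expect_equal(sum(ds$er_reference), 2 * nrow(net$edges))

  # ER graphs: power law not favoured in the majority of seeds
  favoured <- vapply(1:20, function(s) {
    set.seed(s)
    ge <- igraph::sample_gnp(150, 0.05)
    ge <- igraph::induced_subgraph(ge, which(igraph::degree(ge) > 0))
    d <- degree_stats(net_from_igraph(ge), seed = s)
    isTRUE(d$loglik_ratio > 0 && !is.na(d$lr_p) && d$lr_p < 0.1)
  }, logical(1))
  expect_lt(mean(favoured), 0.5)

  # Barabasi-Albert: fitted exponent in the scale-free regime
  alphas <- vapply(1:5, function(s) {
    set.seed(s)
    gb <- igraph::sample_pa(400, m = 3, directed = FALSE)
    degree_stats(net_from_igraph(gb), seed = s)$power_law$alpha
  }, numeric(1))
  expect_gt(mean(alphas >= 2 & alphas <= 3.5), 0.5)
})

test_that("module summaries census edges, taxa and sizes consistently", {
  sim <- generate_community(n_paddy = 120, n_nonpaddy = 0, n_otus = 40,
                            module_sizes = c(14, 14),
                            env_gradient_strength = 0,
                            depth_range = c(30000, 30000), seed = 13)
  fit <- sparcc(sim$table, seed = 1)
  ids <- colnames(sim$table)
  sel <- which(upper.tri(fit$rho) & abs(fit$rho) > 0.35, arr.ind = TRUE)
  net <- cooccurrence_network(
    data.frame(otu = ids,
               abundance = colMeans(relative_abundance(sim$table))),
    data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
               rho = fit$rho[sel], padj = 0.001))
  part <- detect_modules(net, resolution = 1, seed = 2)
  ms <- module_summary(net, part,
                       taxonomy = attr(sim$table, "taxonomy"))
  expect_equal(sum(ms$modules$percent), 100, tolerance = 1e-9)
  expect_equal(sum(ms$modules$n_nodes), nrow(net$nodes))
  expect_equal(sum(ms$taxon_census$Freq), nrow(net$nodes))
  # planted antagonism: between-module edges more often negative
  expect_gt(ms$edge_signs["between_negative_fraction"],
            ms$edge_signs["within_negative_fraction"])
})

test_that("keystones are the top PageRank nodes of each module", {
  star <- net_from_igraph(igraph::make_star(6, mode = "undirected"))
  pr <- pagerank_scores(star)
  part <- detect_modules(star, resolution = 1, seed = 1)
  expect_warning(ks <- identify_keystones(part, pr, top_n = 1,
                                          n_modules = 2),
                 regexp = NA)
  expect_equal(ks$otu[1], names(which.max(pr)))

  # two components, keystone lists disjoint
  g <- igraph::disjoint_union(igraph::make_star(5, mode = "undirected"),
                              igraph::make_star(5, mode = "undirected"))
  net <- net_from_igraph(g)
  part2 <- detect_modules(net, resolution = 1, seed = 2)
  pr2 <- pagerank_scores(net)
  ks2 <- identify_keystones(part2, pr2, top_n = 3, n_modules = 2)
  expect_length(intersect(ks2$otu[ks2$module == 1],
                          ks2$otu[ks2$module == 2]), 0)
})

test_that("a hub with triple connectivity tops its module's PageRank", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    # module of 20 nodes, baseline degree ~3, one node wired to 9 extras
    g <- igraph::sample_gnp(20, 3 / 19)
    extra <- setdiff(sample(2:20, 12), integer(0))[1:9]
    g <- igraph::add_edges(g, as.vector(rbind(1, extra)))
    g <- igraph::simplify(g)
    pr <- pagerank_scores(net_from_igraph(g))
    names(which.max(pr)) == "N1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("interplay windows count, degenerate and null behaviour", {
  n <- 60
  pr <- stats::setNames(sort(stats::runif(n), decreasing = TRUE),
                        paste0("N", 1:n))
  iw <- interplay_windows(pr, pr, window = 15)
  expect_equal(nrow(iw$windows), n - 15 + 1)
  expect_true(all(abs(iw$windows$r - 1) < 1e-12))

  mean_abs_r <- mean(vapply(1:50, function(s) {
    set.seed(s)
    a <- stats::setNames(stats::runif(n), paste0("N", 1:n))
    b <- stats::setNames(stats::runif(n), paste0("N", 1:n))
    mean(abs(interplay_windows(a, b, window = 25)$windows$r))
  }, numeric(1)))
  expect_lt(mean_abs_r, 2 / sqrt(25))
  expect_error(interplay_windows(pr, pr, window = 100), "window")
})

test_that("module ratio indices track constructed gradients", {
  sim <- generate_community(n_paddy = 60, n_nonpaddy = 0, n_otus = 30,
                            module_sizes = c(10, 10),
                            env_gradient_strength = 0,
                            depth_range = c(20000, 20000), seed = 17)
  tab <- sim$table
  ids <- colnames(tab)
  mod <- sim$truth$module_assignment
  memb <- stats::setNames(ifelse(mod == "M1", 1L, ifelse(mod == "M2", 2L,
                                                         3L)), ids)
  part <- structure(list(membership = memb, modularity = NA,
                         resolution = 1,
                         sizes = as.integer(sort(table(memb),
                                                 decreasing = TRUE))),
                    class = "module_partition")
  net <- cooccurrence_network(data.frame(otu = ids),
                              data.frame(from = ids[1], to = ids[2],
                                         rho = 0.5, padj = 0.001))
  ra <- relative_abundance(tab)
  obs_ratio <- rowSums(ra[, mod == "M1"]) / rowSums(ra[, mod == "M2"])
  md <- sim$metadata
  md$tracker <- rank(obs_ratio)          # monotone in the true ratio
  md_groups <- attr(md, "groups")
  attr(md, "groups") <- c(md_groups, tracker = "edaphic")
  mrc <- module_ratio_correlations(net, part, tab, md)
  row <- mrc$correlations[mrc$correlations$index == "abundance_ratio" &
                            mrc$correlations$variable == "tracker", ]
  expect_gt(row$rho, 0.99)
  # permuted variable: small correlation
  set.seed(1)
  md$tracker <- sample(md$tracker)
  mrc2 <- module_ratio_correlations(net, part, tab, md)
  row2 <- mrc2$correlations[mrc2$correlations$index == "abundance_ratio" &
                              mrc2$correlations$variable == "tracker", ]
  expect_lt(abs(row2$rho), 0.4)
  expect_true(all(abs(mrc2$correlations$rho) <= 1))
})
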