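test_that("every metric gives zero distance for identical samples", {
  m <- matrix(c(5L, 3L, 2L, 5L, 3L, 2L), 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  tab <- otu_table(m)
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  assoc <- structure(diag(3), dimnames = list(c("A", "B", "C"),
                                              c("A", "B", "C")),
                     class = c("taxa_association", "matrix"))
  for (met in c("bray", "chao_jaccard", "unifrac_u", "unifrac_w",
                "tina_u", "tina_w")) {
    D <- beta_distance(tab, met, tree = tr, assoc = assoc)
    expect_equal(max(abs(as.matrix(D))), 0, tolerance = 1e-12,
                 label = met)
  }
})

test_that("disjoint single-OTU samples on a star tree give UniFrac 1", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,R:1);")
  tr <- ape::root(tr, outgroup = "R", resolve.root = TRUE)
  m <- matrix(c(4L, 0L, 0L, 0L, 0L, 6L, 0L, 0L), 2, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B", "C", "R")))
  tab <- otu_table(m)
  D <- beta_distance(tab, "unifrac_u", tree = tr)
  expect_equal(as.matrix(D)["S1", "S2"], 1)
})

test_that("UniFrac agrees with the phyloseq implementation", {
  set.seed(8)
  tr <- random_tree(25, seed = 8)
  m <- matrix(stats::rpois(6 * 25, 4), 6, 25,
              dimnames = list(paste0("S", 1:6), tr$tip.label))
  m[m < 2] <- 0L
  m[rowSums(m) == 0, 1] <- 3L
  tab <- otu_table(m)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(unclass(tab)), taxa_are_rows = TRUE),
    phyloseq::phy_tree(tr))
  Du <- beta_distance(tab, "unifrac_u", tree = tr)
  Dw <- beta_distance(tab, "unifrac_w", tree = tr)
  expect_equal(as.matrix(Du),
               as.matrix(phyloseq::UniFrac(ps, weighted = FALSE)),
               tolerance = 1e-10)
  expect_equal(as.matrix(Dw),
               as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                           normalized = TRUE)),
               tolerance = 1e-10)
})

test_that("weighted TINA with identity association is cosine similarity", {
  set.seed(3)
  m <- matrix(stats::rpois(5 * 8, 6) + 1L, 5, 8,
              dimnames = list(paste0("S", 1:5), paste0("O", 1:8)))
  tab <- otu_table(m)
  ids <- colnames(m)
  assoc <- structure(diag(8), dimnames = list(ids, ids),
                     class = c("taxa_association", "matrix"))
  D <- as.matrix(beta_distance(tab, "tina_w", assoc = assoc))
  ra <- relative_abundance(tab)
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  for (j in 1:4) for (k in (j + 1):5) {
    expect_equal(D[j, k], 1 - cosine(ra[j, ], ra[k, ]), tolerance = 1e-10)
  }
})

test_that("association matrix separates planted modules", {
  sim <- generate_community(n_paddy = 80, n_nonpaddy = 0, n_otus = 30,
                            module_sizes = c(10, 10),
                            env_gradient_strength = 0,
                            depth_range = c(20000, 20000), seed = 12)
  s <- taxa_association_matrix(sim$table)
  expect_equal(unclass(s), t(unclass(s)))
  expect_equal(unname(diag(s)), rep(1, ncol(s)))
  mod <- sim$truth$module_assignment[colnames(s)]
  m1 <- mod == "M1"
  within <- s[m1, m1][upper.tri(s[m1, m1])]
  between <- s[m1, mod == "M2"]
  expect_gt(mean(within), mean(between))
  # perfectly co-varying OTUs approach association 1
  expect_gt(max(within), 0.5)
})

test_that("constant OTUs are dropped from the association with a warning", {
  m <- matrix(c(5L, 4L, 3L, 2L, 1L, 2L, 3L, 4L, 2L, 2L, 2L, 2L), 4, 3,
              dimnames = list(paste0("S", 1:4), c("A", "B", "C")))
  expect_warning(s <- taxa_association_matrix(otu_table(m)), "constant")
  expect_equal(ncol(s), 2)
})

test_that("PCoA recovers planar configurations and collinear geometry", {
  # points on a line: first axis carries all positive eigenvalue mass
  x <- c(0, 1, 3, 7)
  D <- stats::dist(x)
  pc <- pcoa_ordination(D, 1)
  ev <- pc$eigenvalues
  expect_equal(sum(ev[ev > 1e-10] > 0), 1)
  expect_equal(pc$fraction_explained[1], 1, tolerance = 1e-10)

  set.seed(4)
  X <- matrix(stats::rnorm(20), 10, 2)
  D2 <- stats::dist(X)
  pc2 <- pcoa_ordination(D2, 2)
  # recovered configuration matches up to rotation/reflection
  pr <- vegan::procrustes(X, pc2$coordinates, symmetric = TRUE)
  expect_lt(pr$ss, 1e-8)
  # permuting samples permutes coordinates identically
  perm <- c(3, 1, 2, 5, 4, 7, 6, 10, 9, 8)
  pc3 <- pcoa_ordination(stats::dist(X[perm, ]), 2)
  pr2 <- vegan::procrustes(pc2$coordinates[perm, ], pc3$coordinates,
                           symmetric = TRUE)
  expect_lt(pr2$ss, 1e-8)
})

test_that("PERMANOVA separates constructed clusters and not duplicates", {
  set.seed(5)
  X <- rbind(matrix(stats::rnorm(20, 0), 10), matrix(stats::rnorm(20, 8), 10))
  D <- stats::dist(X)
  g <- rep(c("a", "b"), each = 10)
  fit <- permanova(D, g, n_perm = 199, seed = 1)
  expect_gt(fit$R2, 0.5)
  expect_equal(fit$p, 1 / 200)

  # identical distributions in both groups: R2 near zero
  Y <- rbind(X[1:10, ], X[1:10, ])
  fit2 <- permanova(stats::dist(Y), rep(c("a", "b"), each = 10),
                    n_perm = 99, seed = 2)
  expect_lt(fit2$R2, 0.05)
  expect_error(permanova(D, rep("a", 20)), "2 groups")
})

test_that("adonis ranking orders variables by planted effect size", {
  set.seed(6)
  sim <- generate_community(n_paddy = 60, n_nonpaddy = 0, n_otus = 40,
                            module_sizes = c(10, 10),
                            env_gradient_strength = 2,
                            depth_range = c(10000, 10000), phylo_signal = 0,
                            seed = 21)
  D <- beta_distance(sim$table, "bray")
  md <- sim$metadata
  md$noise_var <- stats::rnorm(nrow(md))
  rk <- suppressWarnings(
    adonis_r2_ranking(D, md, c("pH", "MAT", "noise_var"), n_perm = 99,
                      seed = 3))
  expect_setequal(rk$variable, c("pH", "MAT", "noise_var"))
  expect_equal(rk$R2, sort(rk$R2, decreasing = TRUE))
  # a no-effect variable ranks below the planted drivers
  expect_false(rk$variable[1] == "noise_var")
})

test_that("variation partitioning localizes orthogonal drivers", {
  set.seed(7)
  n <- 60
  e1 <- stats::rnorm(n); e2 <- stats::rnorm(n); e3 <- stats::rnorm(n)
  # community responds to all three orthogonal drivers
  Y <- cbind(e1, e2, e3) %*% matrix(stats::rnorm(30), 3) +
    matrix(stats::rnorm(n * 10, 0, 0.3), n)
  D <- stats::dist(Y)
  md <- sample_metadata(data.frame(
    sample_id = paste0("S", 1:n),
    soil_type = rep(c("paddy", "nonpaddy"), length.out = n),
    region = "TaihuPlain",
    pH = e1, latitude = e2, MAT = e3))
  vp <- variation_partition(D, md)
  total <- sum(vp$unique) + sum(vp$pairwise_shared) + vp$threeway_shared +
    vp$residual
  expect_equal(total, 1, tolerance = 1e-6)
  expect_true(all(vp$unique > 0.05))
  expect_true(all(abs(vp$pairwise_shared) < 0.08))
})

test_that("a duplicated variable moves R2 into the shared fraction", {
  set.seed(8)
  n <- 50
  e1 <- stats::rnorm(n)
  Y <- cbind(e1) %*% matrix(stats::rnorm(8), 1) +
    matrix(stats::rnorm(n * 8, 0, 0.3), n)
  md <- sample_metadata(data.frame(
    sample_id = paste0("S", 1:n),
    soil_type = "paddy", region = "TaihuPlain",
    pH = e1, latitude = e1 + stats::rnorm(n, 0, 1e-4),
    MAT = stats::rnorm(n)))
  vp <- variation_partition(stats::dist(Y), md)
  shared_12 <- vp$pairwise_shared[["edaphic+geographic"]]
  expect_gt(shared_12, 0.3)
  expect_lt(vp$unique[["edaphic"]], 0.1)
})

test_that("core microbiota segments partition the union", {
  set.seed(9)
  tabs <- lapply(1:4, function(r) {
    m <- matrix(stats::rpois(6 * 10, 2), 6, 10,
                dimnames = list(paste0("R", r, "S", 1:6), paste0("O", 1:10)))
    m[, 1] <- m[, 1] + 1L        # OTU O1 present everywhere
    m[rowSums(m) == 0, 2] <- 1L
    otu_table(m)
  })
  names(tabs) <- paste0("reg", 1:4)
  cm <- core_microbiota(tabs, occupancy = 1)
  expect_true(all(vapply(cm$cores, function(s) "O1" %in% s, TRUE)))
  expect_equal(sum(cm$segments$count), cm$union_size)
  expect_equal(sum(cm$segments$percent), 100, tolerance = 1e-9)
  full <- cm$segments$segment[grepl("reg1&reg2&reg3&reg4",
                                    cm$segments$segment)]
  expect_length(full, 1)
  # an OTU absent from one region is excluded from the 4-way core
  m <- unclass(tabs$reg2); m[, "O1"] <- 0L
  m[rowSums(m) == 0, 2] <- 1L
  tabs$reg2 <- otu_table(m)
  cm2 <- core_microbiota(tabs, occupancy = 1)
  expect_false("O1" %in% Reduce(intersect, cm2$cores))
})

test_that("enrichment ratios handle one-sided presence and exact ranks", {
  # one OTU fully separating the groups: exact two-sided p = 0.1 at 3 vs 3
  m <- matrix(0L, 6, 3, dimnames = list(paste0("S", 1:6),
                                        c("sep", "only_paddy", "fill")))
  m[, "sep"] <- c(10L, 20L, 30L, 40L, 50L, 60L)
  m[1:3, "only_paddy"] <- c(5L, 5L, 5L)
  m[, "fill"] <- 100L
  md <- sample_metadata(data.frame(
    sample_id = paste0("S", 1:6),
    soil_type = rep(c("paddy", "nonpaddy"), each = 3),
    region = "TaihuPlain"))
  er <- enrichment_ratio(otu_table(m), md)
  expect_equal(er$p[er$otu == "sep"], 0.1)
  op <- er[er$otu == "only_paddy", ]
  expect_true(is.finite(op$ratio) && op$ratio > 1e3)
})
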