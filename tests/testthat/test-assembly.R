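test_that("betaMNTD forced cases and brute-force oracle agreement", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.3):0.2,(C:0.2,D:0.2):0.3);")
  # identical communities
  m <- matrix(c(3L, 2L, 0L, 0L, 3L, 2L, 0L, 0L), 2, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B", "C", "D")))
  expect_equal(max(as.matrix(beta_mntd(otu_table(m), tr))), 0)

  # two single-OTU communities at known tip distance
  tr2 <- ape::read.tree(text = "(A:0.3,B:0.3);")
  m2 <- matrix(c(5L, 0L, 0L, 4L), 2, 2, byrow = TRUE,
               dimnames = list(c("S1", "S2"), c("A", "B")))
  expect_equal(as.matrix(beta_mntd(otu_table(m2), tr2))["S1", "S2"], 0.6)

  # random fixtures vs naive double loop and picante
  set.seed(10)
  for (i in 1:10) {
    tr3 <- random_tree(15, seed = 20 + i)
    m3 <- matrix(stats::rpois(5 * 15, 2), 5, 15,
                 dimnames = list(paste0("S", 1:5), tr3$tip.label))
    m3[rowSums(m3) == 0, 1] <- 1L
    tab <- otu_table(m3)
    got <- as.matrix(beta_mntd(tab, tr3))
    D <- ape::cophenetic.phylo(tr3)[colnames(m3), colnames(m3)]
    p <- unclass(tab) / rowSums(unclass(tab))
    for (j in 1:4) for (k in (j + 1):5) {
      pj <- which(m3[j, ] > 0); pk <- which(m3[k, ] > 0)
      naive <- 0.5 * (
        sum(vapply(pj, function(a) p[j, a] * min(D[a, pk]), numeric(1))) +
        sum(vapply(pk, function(b) p[k, b] * min(D[b, pj]), numeric(1))))
      expect_equal(got[j, k], naive, tolerance = 1e-10)
    }
    ref <- as.matrix(picante::comdistnt(unclass(tab), D,
                                        abundance.weighted = TRUE))
    expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("betaNTI is calibrated under its own taxa-shuffle null", {
  set.seed(5)
  tr <- random_tree(60, seed = 5)
  m <- matrix(stats::rpois(12 * 60, 4), 12, 60,
              dimnames = list(sprintf("S%02d", 1:12), tr$tip.label))
  m[m < 3] <- 0L
  m[rowSums(m) == 0, 1] <- 2L
  bn <- beta_nti(otu_table(m), tr, n_null = 199, seed = 2)
  z <- bn$betanti[upper.tri(bn$betanti)]
  expect_gte(mean(abs(z) < 2, na.rm = TRUE), 0.9)
})

test_that("clade-confined communities show phylogenetic clustering", {
  set.seed(7)
  tr <- random_tree(150, seed = 7)
  cl <- cutree(stats::hclust(stats::as.dist(
    ape::cophenetic.phylo(tr))), k = 20)
  sizes <- sort(table(cl), decreasing = TRUE)
  ok <- which(sizes >= 8)
  clade_tips <- names(cl)[cl == names(sizes)[ok[length(ok)]]]
  m <- matrix(0L, 8, 150, dimnames = list(sprintf("S%d", 1:8),
                                          tr$tip.label))
  for (i in 1:8) {
    picks <- sample(clade_tips, 6)
    m[i, picks] <- stats::rpois(6, 6) + 1L
  }
  bn <- beta_nti(otu_table(m), tr, n_null = 199, seed = 3)
  z <- bn$betanti[upper.tri(bn$betanti)]
  expect_gt(mean(z < -2, na.rm = TRUE), 0.5)
})

test_that("betaNTI is invariant to rescaling the tree", {
  tr <- random_tree(30, seed = 9)
  m <- matrix(stats::rpois(6 * 30, 3), 6, 30,
              dimnames = list(paste0("S", 1:6), tr$tip.label))
  m[rowSums(m) == 0, 1] <- 1L
  tab <- otu_table(m)
  b1 <- beta_nti(tab, tr, n_null = 99, seed = 4)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 3
  b2 <- beta_nti(tab, tr2, n_null = 99, seed = 4)
  expect_equal(b1$betanti, b2$betanti, tolerance = 1e-10)
})

test_that("Raup-Crick is bounded, self-consistent and detects extremes", {
  set.seed(7)
  # tables produced by the index's own null assembly process
  pool_freq <- stats::runif(40, 0.3, 0.8)
  pool_ab <- stats::runif(40, 0.5, 1.5)
  pool_ab <- pool_ab / sum(pool_ab)
  draw_null_table <- function(n) {
    m <- t(vapply(seq_len(n), function(i)
      paddynet:::null_assemblage(sample(13:20, 1), 400, pool_freq, pool_ab),
      integer(40)))
    dimnames(m) <- list(paste0("S", seq_len(n)), paste0("O", 1:40))
    otu_table(m)
  }
  tab <- draw_null_table(20)
  rc <- raup_crick_bray(tab, n_null = 199, seed = 1)
  v <- rc[upper.tri(rc)]
  expect_true(all(v >= -1 & v <= 1))
  expect_gte(mean(abs(v) < 0.95), 0.9)

  # disjoint specialist samples from a large shared pool: RC -> +1
  m2 <- matrix(0L, 2, 40, dimnames = list(c("T1", "T2"), paste0("O", 1:40)))
  m2[1, 1:8] <- 50L
  m2[2, 33:40] <- 50L
  big <- rbind(unclass(draw_null_table(8)), m2)
  rc2 <- raup_crick_bray(otu_table(big), n_null = 199, seed = 2)
  expect_gt(rc2["T1", "T2"], 0.9)
})

test_that("assembly classification follows the threshold rules", {
  expect_equal(classify_assembly(-3, 0)$labels, "homogeneous selection")
  expect_equal(classify_assembly(3, 0)$labels, "variable selection")
  expect_equal(classify_assembly(1, 0.99)$labels, "dispersal limitation")
  expect_equal(classify_assembly(-1, -0.99)$labels,
               "homogenizing dispersal")
  expect_equal(classify_assembly(0, 0)$labels, "drift")
  cl <- classify_assembly(c(-3, 0, 2.5, NA), c(0, 0.99, 0, 0))
  expect_equal(sum(cl$fractions), 100)
  expect_equal(cl$n_skipped, 1L)
})

test_that("NST separates copied communities from null-drawn ones", {
  set.seed(8)
  # deterministic group: near-copies of one narrow 8-species community
  base <- integer(30)
  base[1:8] <- stats::rmultinom(1, 2000, stats::rexp(8) + 0.05)[, 1] + 1L
  det <- t(vapply(1:6, function(i) {
    x <- base
    j <- sample(8, 2)
    x[j] <- x[j] + 1L
    x
  }, integer(30)))
  dimnames(det) <- list(paste0("D", 1:6), paste0("O", 1:30))
  # stochastic group: i.i.d. draws from a shared pool
  pool <- stats::rexp(30) + 0.05
  sto <- t(vapply(1:6, function(i) {
    chosen <- sample.int(30, 15, prob = rep(0.5, 30))
    x <- integer(30)
    x[chosen] <- 1L
    x[chosen] <- x[chosen] + stats::rmultinom(1, 1985, pool[chosen])[, 1]
    x
  }, integer(30)))
  dimnames(sto) <- list(paste0("R", 1:6), paste0("O", 1:30))
  tab <- otu_table(rbind(det, sto))
  res <- stochasticity_ratio(tab, rep(c("det", "sto"), each = 6),
                             reps = 99, seed = 3)
  expect_true(all(res$NST >= 0 & res$NST <= 1))
  expect_lt(res$NST[res$group == "det"], res$NST[res$group == "sto"])
  expect_gt(res$NST[res$group == "sto"], 0.5)
})
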