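test_that("MDLP accepts a forced separation and refuses noise", {
  set.seed(1)
  x <- c(stats::rnorm(50, 0, 0.5), stats::rnorm(50, 5, 0.5))
  y <- rep(c("a", "b"), each = 50)
  cuts <- mdlp_discretize(x, y)
  left_max <- max(x[1:50]); right_min <- min(x[51:100])
  expect_length(cuts, 1)
  expect_true(cuts > left_max && cuts <= right_min)

  # independent labels: no accepted cut in at least 90% of draws
  none <- vapply(1:50, function(s) {
    set.seed(s)
    length(mdlp_discretize(stats::rnorm(100),
                           sample(rep(1:2, 50)))) == 0
  }, logical(1))
  expect_gte(mean(none), 0.9)

  # multi-threshold signal yields strictly increasing cuts
  set.seed(2)
  x3 <- c(stats::rnorm(40, 0, 0.3), stats::rnorm(40, 3, 0.3),
          stats::rnorm(40, 6, 0.3))
  y3 <- rep(c("a", "b", "c"), each = 40)
  cuts3 <- mdlp_discretize(x3, y3)
  expect_gte(length(cuts3), 2)
  expect_true(all(diff(cuts3) > 0))
  expect_error(mdlp_discretize(c(1, NA, 3), c("a", "b", "a")), "finite")
})

test_that("the MDLP criterion matches brute-force entropy arithmetic", {
  # tiny fixture evaluable by hand: x sorted, y = a a b b
  x <- c(1, 2, 3, 4)
  y <- c("a", "a", "b", "b")
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  # best cut at 2.5: gain = Ent(S) - 0 = 1 bit
  N <- 4; k <- 2
  delta <- log2(3^k - 2) - (k * ent(y) - 1 * ent(y[1:2]) - 1 * ent(y[3:4]))
  accept <- (ent(y) - 0) > (log2(N - 1) + delta) / N
  cuts <- mdlp_discretize(x, y)
  if (accept) expect_equal(cuts, 2.5) else expect_length(cuts, 0)
})

test_that("mutual information matches direct enumeration", {
  mi_direct <- function(a, b) {
    out <- 0
    for (va in unique(a)) for (vb in unique(b)) {
      pab <- mean(a == va & b == vb)
      if (pab > 0) out <- out + pab * log2(pab / (mean(a == va) *
                                                    mean(b == vb)))
    }
    out
  }
  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(paddynet:::mi_bits(a, b), mi_direct(a, b),
                 tolerance = 1e-12)
  }
})

test_that("mRMR prefers relevance and penalizes redundancy", {
  set.seed(4)
  y <- rep(1:4, 25)
  X <- cbind(copy_of_y = y,
             weak = ifelse(y <= 2, 1L, 2L)[sample(100)],
             indep = sample(1:3, 100, replace = TRUE))
  expect_equal(mrmr_select(X, y, 1), 1L)

  # two identical informative features and a weaker independent one:
  # the duplicate is penalized out of the top 2
  noisy <- y
  flip <- sample(100, 25)
  noisy[flip] <- sample(1:4, 25, replace = TRUE)
  weak2 <- ifelse(y %in% c(1, 2), 1L, 2L)
  weak2[sample(100, 10)] <- sample(1:2, 10, replace = TRUE)
  X2 <- cbind(f_dup1 = noisy, f_dup2 = noisy, f_weak = weak2)
  sel <- mrmr_select(X2, y, 2)
  expect_equal(sel[1], 1L)
  expect_equal(sel[2], 3L)
  expect_length(mrmr_select(X2, y, 10), 3)
})

test_that("planted functional dependence is predictable from OTUs only", {
  set.seed(5)
  n <- 150; p <- 25
  # target fraction is exactly the sum of two parent fractions: the
  # common renormalization preserves f1 = f2 + f3 on the observed scale
  z <- matrix(stats::rnorm(n * (p - 1)), n, p - 1)
  mu <- stats::rnorm(p - 1, 0, 0.8)
  mu[1:2] <- 2                            # abundant parents
  lam <- exp(sweep(z, 2, mu, "+"))
  fr0 <- lam / rowSums(lam)
  f1 <- fr0[, 1] + fr0[, 2]
  fr <- cbind(f1, fr0) / (1 + f1)
  m <- t(vapply(seq_len(n),
                function(i) stats::rmultinom(1, 50000, fr[i, ])[, 1],
                integer(p)))
  tab <- otu_table(m, paste0("S", 1:n), sprintf("OTU%02d", 1:p))
  md <- sample_metadata(data.frame(
    sample_id = rownames(tab),
    soil_type = rep(c("paddy", "nonpaddy"), length.out = n),
    region = "TaihuPlain",
    pH = stats::rnorm(n), MAT = stats::rnorm(n),
    latitude = stats::rnorm(n)))
  res <- fit_models(tab, md, targets = "OTU01", cv = 5, num_trees = 500,
                    seed = 6)
  expect_gt(res$pseudo_r2_otu, 0.5)
  expect_lt(res$pseudo_r2_env, 0.2)
  # the true parents appear among the reported predictors
  expect_true(any(c("OTU02", "OTU03") %in%
                    strsplit(res$selected_otu, ",")[[1]]))
})

test_that("pure-noise targets are not predictable (no leakage)", {
  set.seed(7)
  r2s <- vapply(1:5, function(s) {
    nul <- generate_null_community(n_samples = 40, n_otus = 20,
                                   depth = 10000, seed = 300 + s)
    md <- nul$metadata
    md$pH <- stats::rnorm(40)
    attr(md, "groups") <- c(pH = "edaphic")
    res <- fit_models(nul$table, md,
                      targets = colnames(nul$table)[1], cv = 5,
                      num_trees = 300, seed = s)
    res$pseudo_r2_otu
  }, numeric(1))
  expect_lte(stats::median(r2s), 0.1)
})

test_that("model comparison reports medians and paired significance", {
  res <- data.frame(otu = paste0("O", 1:12), occupancy = 12,
                    pseudo_r2_otu = seq(0.5, 0.83, length.out = 12),
                    pseudo_r2_env = seq(0.1, 0.2, length.out = 12))
  class(res) <- c("rf_model_result", "data.frame")
  cmp <- compare_models(res)
  expect_equal(cmp$median_otu, stats::median(res$pseudo_r2_otu))
  # all differences positive: smallest attainable two-sided p for n = 12
  expect_equal(cmp$p, stats::wilcox.test(res$pseudo_r2_otu,
                                         res$pseudo_r2_env,
                                         paired = TRUE)$p.value)
  # invariant to row order
  cmp2 <- compare_models(res[sample(12), ])
  expect_equal(cmp$p, cmp2$p)
  expect_error(compare_models(res[1:5, ]), "10")
})

test_that("occupancy filtering and defaults follow the modeling contract", {
  sim <- generate_community(n_paddy = 30, n_nonpaddy = 0, n_otus = 25,
                            module_sizes = c(8, 8),
                            depth_range = c(3000, 3000), seed = 11)
  m <- unclass(sim$table)
  m[, 1] <- 0L
  m[1:5, 1] <- 1L                      # occupancy 5 < 10
  tab <- otu_table(m)
  res <- fit_models(tab, sim$metadata,
                    targets = colnames(tab)[1:4],
                    occupancy_min = 10L, cv = 3, num_trees = 100,
                    seed = 2)
  expect_false(colnames(tab)[1] %in% res$otu)
  expect_true(all(res$occupancy >= 10))
})
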