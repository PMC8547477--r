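# fixtures shared across the suite; everything is generated in code

small_table <- function() {
  otu_table(matrix(c(5, 0, 1, 2, 0, 7), nrow = 3, byrow = TRUE),
            sample_ids = c("S1", "S2", "S3"), otu_ids = c("A", "B"))
}

# symmetric block + noise correlation matrix (entry-level noise sd = sigma)
block_noise_matrix <- function(n, k, rho = 0.8, sigma = 0.1, seed = 1) {
  set.seed(seed)
  C <- matrix(0, n, n)
  C[1:k, 1:k] <- rho
  C[(k + 1):(2 * k), (k + 1):(2 * k)] <- rho
  E <- matrix(stats::rnorm(n * n, 0, sigma * sqrt(2)), n)
  E <- (E + t(E)) / 2
  M <- pmin(pmax(C + E, -1), 1)
  diag(M) <- 1
  M
}

# counts with one OTU pair co-varying only inside one sample group
group_driven_pair <- function(n_per_group = 40, n_groups = 3, p = 30,
                              depth = 20000, strength = 2, seed = 1) {
  set.seed(seed)
  n <- n_per_group * n_groups
  grp <- rep(LETTERS[seq_len(n_groups)], each = n_per_group)
  z <- matrix(stats::rnorm(n * p), n, p)
  shared <- stats::rnorm(n)
  inA <- grp == "A"
  z[inA, 1] <- z[inA, 1] * 0.3 + shared[inA] * strength
  z[inA, 2] <- z[inA, 2] * 0.3 + shared[inA] * strength
  lam <- exp(sweep(z, 2, stats::rnorm(p, 0, 1), "+"))
  fr <- lam / rowSums(lam)
  m <- t(vapply(seq_len(n),
                function(i) stats::rmultinom(1, depth, fr[i, ])[, 1],
                integer(p)))
  list(table = otu_table(m, sprintf("S%03d", seq_len(n)),
                         sprintf("OTU%02d", seq_len(p))),
       groups = stats::setNames(grp, sprintf("S%03d", seq_len(n))))
}

# an independent, step-by-step oracle for the two-stage BH procedure
tsbh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  # plain BH adjusted p by explicit sort / cummin (no p.adjust)
  bh <- function(pv) {
    o <- order(pv)
    adj <- pv[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  adj1 <- bh(p)
  r1 <- sum(adj1 <= alpha / (1 + alpha))
  m0 <- m - r1
  if (m0 == 0) return(rep(0, m))
  pmin(1, adj1 * m0 / m)
}

random_tree <- function(n, seed = 1) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- sprintf("OTU%03d", seq_len(n))
  tr
}
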