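#' Beta mean nearest-taxon distance (betaMNTD)
#'
#' For samples j and k, the abundance-weighted mean of the phylogenetic
#' distance from each OTU present in one sample to its nearest taxon in the
#' other, averaged over both directions:
#' betaMNTD(j,k) = 1/2 [ sum_a p_aj min_{b in k} d(a,b)
#'                     + sum_b p_bk min_{a in j} d(a,b) ].
#' The unweighted form replaces abundances by 1/S within each sample.
#'
#' @param table An \code{otu_table} (all OTUs must be tree tips).
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param weighted Abundance-weighted (default) or presence-based.
#' @return A \code{dist} in branch-length units.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  m <- unclass(table)
  miss <- setdiff(colnames(m), tree$tip.label)
  if (length(miss)) stop("OTUs missing from tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  D <- ape::cophenetic.phylo(tree)[colnames(m), colnames(m)]
  bmntd_from_dist(m, D, weighted)
}

# core betaMNTD given a species-by-species distance matrix
bmntd_from_dist <- function(m, D, weighted = TRUE) {
  n <- nrow(m)
  p <- if (weighted) m / rowSums(m) else {
    pa <- (m > 0) * 1
    pa / rowSums(pa)
  }
  pres <- m > 0
  # dmin[[k]][a] = distance from OTU a to its nearest taxon present in k
  dmin <- lapply(seq_len(n), function(k) {
    sub <- D[, pres[k, ], drop = FALSE]
    apply(sub, 1, min)
  })
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    out[j, k] <- out[k, j] <-
      0.5 * (sum(p[j, ] * dmin[[k]]) + sum(p[k, ] * dmin[[j]]))
  }
  stats::as.dist(out)
}

#' Beta nearest-taxon index (betaNTI)
#'
#' Z-score of observed betaMNTD against a taxa-shuffle null that permutes
#' the tip labels of the tree (equivalently the rows and columns of the
#' phylogenetic distance matrix) \code{n_null} times. |betaNTI| < 2 is
#' consistent with the null; betaNTI < -2 signals phylogenetic clustering
#' beyond chance (homogeneous selection), betaNTI > 2 overdispersion
#' (variable selection).
#'
#' @param table,tree,weighted As in \code{\link{beta_mntd}}.
#' @param n_null Null permutations (at least 99).
#' @param seed Integer seed.
#' @return List: \code{betanti} (matrix, NA where the null sd is zero),
#'   \code{betamntd} (observed \code{dist}), \code{n_null}.
#' @export
beta_nti <- function(table, tree, n_null = 999L, seed = 1L,
                     weighted = TRUE) {
  if (n_null < 99) stop("n_null must be at least 99")
  m <- unclass(table)
  miss <- setdiff(colnames(m), tree$tip.label)
  if (length(miss)) stop("OTUs missing from tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  D <- ape::cophenetic.phylo(tree)[colnames(m), colnames(m)]
  obs <- as.matrix(bmntd_from_dist(m, D, weighted))
  set.seed(derive_seed(seed, "beta_nti"))
  S <- ncol(m)
  sum1 <- matrix(0, nrow(m), nrow(m))
  sum2 <- matrix(0, nrow(m), nrow(m))
  for (b in seq_len(n_null)) {
    perm <- sample(S)
    nullv <- as.matrix(bmntd_from_dist(m, D[perm, perm], weighted))
    sum1 <- sum1 + nullv
    sum2 <- sum2 + nullv^2
  }
  mu <- sum1 / n_null
  sdv <- sqrt(pmax(sum2 / n_null - mu^2, 0) * n_null / (n_null - 1))
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NA_real_
  diag(z) <- 0
  list(betanti = z, betamntd = stats::as.dist(obs), n_null = n_null)
}

# draw one null assemblage: fixed richness, species chosen with probability
# proportional to occurrence frequency, abundances filled multinomially
# proportional to the pool's mean relative abundances
null_assemblage <- function(richness, total, freq, relab) {
  S <- length(freq)
  chosen <- sample.int(S, richness, prob = freq)
  x <- integer(S)
  x[chosen] <- 1L
  extra <- total - richness
  if (extra > 0) {
    pr <- relab[chosen]
    if (sum(pr) <= 0) pr <- rep(1, length(chosen))
    x[chosen] <- x[chosen] + stats::rmultinom(1, extra, pr)[, 1]
  }
  x
}

#' Modified Raup-Crick index on Bray-Curtis (RC.bray)
#'
#' For each sample pair, \code{n_null} pairs of null communities are
#' assembled by drawing each sample's observed richness with selection
#' probability proportional to occurrence frequency and filling to the
#' observed total abundance proportionally to mean relative abundance. The
#' index is the fraction of null Bray-Curtis values below the observed one
#' (half weight for ties), rescaled to [-1, 1].
#'
#' @param table An \code{otu_table}.
#' @param n_null Null draws per pair (at least 99).
#' @param seed Integer seed.
#' @return Symmetric matrix in [-1, 1] with zero diagonal.
#' @export
raup_crick_bray <- function(table, n_null = 999L, seed = 1L) {
  if (n_null < 99) stop("n_null must be at least 99")
  m <- unclass(table)
  storage.mode(m) <- "double"
  n <- nrow(m)
  freq <- colMeans(m > 0)
  relab <- colMeans(m / rowSums(m))
  rich <- rowSums(m > 0)
  tot <- rowSums(m)
  bray <- function(x, y) sum(abs(x / sum(x) - y / sum(y))) / 2
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  set.seed(derive_seed(seed, "raup_crick"))
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    obs <- bray(m[j, ], m[k, ])
    less <- ties <- 0L
    for (b in seq_len(n_null)) {
      xj <- null_assemblage(rich[j], tot[j], freq, relab)
      xk <- null_assemblage(rich[k], tot[k], freq, relab)
      bc <- bray(xj, xk)
      if (bc < obs) less <- less + 1L
      else if (bc == obs) ties <- ties + 1L
    }
    rc <- ((less + 0.5 * ties) / n_null - 0.5) * 2
    out[j, k] <- out[k, j] <- rc
  }
  out
}

#' Classify assembly processes from betaNTI and RC.bray
#'
#' betaNTI < -2: homogeneous selection; betaNTI > 2: variable selection;
#' otherwise RC.bray > 0.95: dispersal limitation; RC.bray < -0.95:
#' homogenizing dispersal; otherwise drift.
#'
#' @param betanti,rc_bray Matched matrices (or vectors) of pair values.
#' @return List: \code{labels} (character, same shape; NA inputs skipped
#'   and counted), \code{fractions} (percent per process over classified
#'   pairs), \code{n_skipped}.
#' @export
classify_assembly <- function(betanti, rc_bray) {
  b <- as.vector(if (is.matrix(betanti)) betanti[upper.tri(betanti)]
                 else betanti)
  r <- as.vector(if (is.matrix(rc_bray)) rc_bray[upper.tri(rc_bray)]
                 else rc_bray)
  stopifnot(length(b) == length(r))
  lab <- ifelse(b < -2, "homogeneous selection",
         ifelse(b > 2, "variable selection",
         ifelse(r > 0.95, "dispersal limitation",
         ifelse(r < -0.95, "homogenizing dispersal", "drift"))))
  skipped <- is.na(b) | is.na(r)
  lab[skipped] <- NA_character_
  lv <- c("homogeneous selection", "variable selection",
          "dispersal limitation", "homogenizing dispersal", "drift")
  fr <- 100 * table(factor(lab, levels = lv)) / sum(!skipped)
  list(labels = lab, fractions = fr, n_skipped = sum(skipped))
}

#' Normalized stochasticity ratio (NST)
#'
#' Within each group, observed pairwise similarities C (one minus the chosen
#' dissimilarity) are compared with the expectation E under a null assembly
#' model (fixed observed richness, selection probability proportional to
#' occurrence frequency, abundances proportional to the group pool, as in
#' the Raup-Crick null; the \code{"pp"} variant draws richness free by
#' occupancy-weighted presence sampling). The pairwise stochasticity ratio
#' is E/C when C > E and C/E otherwise, so 1 means indistinguishable from
#' the null and 0 means fully deterministic; the group NST is the mean over
#' pairs, with a bootstrap standard error over pairs.
#'
#' The species pool (occurrence frequencies and mean relative abundances)
#' defaults to the regional pool estimated over all samples of the table, so
#' that a group of near-identical communities occupying a narrow slice of
#' the region is recognized as deterministic; \code{pool = "group"} restricts
#' the pool to each group's own samples.
#'
#' @param table An \code{otu_table}.
#' @param groups Factor over samples (each group needs at least 3 samples).
#' @param null_algorithm \code{"pf"} (proportional abundance, fixed
#'   richness; default) or \code{"pp"} (richness free).
#' @param pool \code{"regional"} (default) or \code{"group"}.
#' @param metric \code{"bray"} or \code{"jaccard"}.
#' @param reps Null replicates for the expectation.
#' @param n_boot Bootstrap resamples for the SE.
#' @param seed Integer seed.
#' @return Data frame per group: NST, SE, n_pairs, n_skipped.
#' @export
stochasticity_ratio <- function(table, groups, null_algorithm = c("pf", "pp"),
                                metric = c("bray", "jaccard"), reps = 199L,
                                n_boot = 200L, pool = c("regional", "group"),
                                seed = 1L) {
  null_algorithm <- match.arg(null_algorithm)
  metric <- match.arg(metric)
  pool <- match.arg(pool)
  m <- unclass(table)
  storage.mode(m) <- "double"
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(m))
  dis <- function(x, y) {
    if (metric == "bray") sum(abs(x / sum(x) - y / sum(y))) / 2
    else { a <- x > 0; b <- y > 0; 1 - sum(a & b) / sum(a | b) }
  }
  set.seed(derive_seed(seed, "nst"))
  rows <- list()
  for (gl in levels(droplevels(groups))) {
    idx <- which(groups == gl)
    if (length(idx) < 3) stop("group '", gl, "' has fewer than 3 samples")
    sub <- m[idx, , drop = FALSE]
    src <- if (pool == "regional") m else sub
    freq <- colMeans(src > 0)
    relab <- colMeans(src / rowSums(src))
    rich <- rowSums(sub > 0)
    tot <- rowSums(sub)
    ns <- length(idx)
    # null similarity expectation per pair
    pairs <- utils::combn(ns, 2)
    Esum <- numeric(ncol(pairs))
    for (b in seq_len(reps)) {
      nulls <- lapply(seq_len(ns), function(i) {
        if (null_algorithm == "pf")
          null_assemblage(rich[i], tot[i], freq, relab)
        else {
          x <- stats::rbinom(length(freq), 1, freq)
          if (!any(x == 1)) x[sample.int(length(freq), 1)] <- 1L
          extra <- tot[i] - sum(x)
          if (extra > 0) {
            pr <- relab * x
            if (sum(pr) <= 0) pr <- x
            x <- x + stats::rmultinom(1, extra, pr)[, 1]
          }
          x
        }
      })
      Esum <- Esum + vapply(seq_len(ncol(pairs)), function(q)
        1 - dis(nulls[[pairs[1, q]]], nulls[[pairs[2, q]]]), numeric(1))
    }
    E <- Esum / reps
    C <- vapply(seq_len(ncol(pairs)), function(q)
      1 - dis(sub[pairs[1, q], ], sub[pairs[2, q], ]), numeric(1))
    valid <- E > 0 & C > 0
    st <- ifelse(C > E, E / C, C / E)[valid]
    nst <- mean(st)
    se <- if (length(st) > 1) {
      bs <- vapply(seq_len(n_boot), function(b)
        mean(st[sample.int(length(st), replace = TRUE)]), numeric(1))
      stats::sd(bs)
    } else NA_real_
    rows[[gl]] <- data.frame(group = gl, NST = nst, SE = se,
                             n_pairs = length(st),
                             n_skipped = sum(!valid),
                             null_algorithm = null_algorithm,
                             reps = reps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
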