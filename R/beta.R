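#' Inter-taxon association matrix for interaction-adjusted beta diversity
#'
#' \code{corr_profile_cosine} (the default of the interaction-adjusted index
#' family): s_ab is the cosine similarity between rows a and b of the
#' inter-OTU Spearman correlation matrix of relative abundances.
#' \code{sparcc} uses the SparCC correlation matrix directly.
#'
#' @param table An \code{otu_table} with at least 3 samples.
#' @param method \code{"corr_profile_cosine"} or \code{"sparcc"}.
#' @param ... Passed to \code{\link{sparcc}} for that method.
#' @return Symmetric association matrix with unit diagonal, class
#'   \code{"taxa_association"}; constant OTUs are dropped with a warning.
#' @export
taxa_association_matrix <- function(table,
                                    method = c("corr_profile_cosine",
                                               "sparcc"), ...) {
  method <- match.arg(method)
  if (nrow(table) < 3) stop("need at least 3 samples")
  ra <- relative_abundance(table)
  const <- apply(ra, 2, function(x) stats::var(x) == 0)
  if (any(const)) {
    warning("dropping ", sum(const), " constant OTU(s)")
    ra <- ra[, !const, drop = FALSE]
  }
  if (method == "corr_profile_cosine") {
    r <- stats::cor(ra, method = "spearman")
    nrm <- sqrt(rowSums(r^2))
    s <- (r %*% t(r)) / outer(nrm, nrm)
  } else {
    tab <- unclass(table)[, !const, drop = FALSE]
    s <- sparcc(tab, ...)$rho
  }
  s <- pmin(pmax((s + t(s)) / 2, -1), 1)
  diag(s) <- 1
  structure(s, method = method, class = c("taxa_association", "matrix"))
}

#' Beta-diversity distance matrices
#'
#' Metrics: Bray-Curtis and the abundance-based Chao-Jaccard estimator
#' (count-based); unweighted and normalized weighted UniFrac (phylogenetic);
#' unweighted and weighted interaction-adjusted TINA indices. Weighted TINA
#' similarity between samples j and k is
#' \deqn{(\sum_{ab} p_{aj} p_{bk} s_{ab}) /
#'       \sqrt{(\sum_{ab} p_{aj} p_{bj} s_{ab})(\sum_{ab} p_{ak} p_{bk} s_{ab})}}
#' and the distance is one minus the similarity; unweighted TINA replaces
#' abundances by normalized presence/absence profiles.
#'
#' @param table An \code{otu_table}.
#' @param metric One of \code{"bray"}, \code{"chao_jaccard"},
#'   \code{"unifrac_u"}, \code{"unifrac_w"}, \code{"tina_u"},
#'   \code{"tina_w"}.
#' @param tree Rooted \code{phylo} (required for UniFrac).
#' @param assoc \code{taxa_association} matrix (required for TINA), ids
#'   covering the table's OTUs.
#' @param chao_correction Include the Chao unseen-species correction term in
#'   the Chao-Jaccard estimator (off by default).
#' @return A \code{dist} object (metric label in attribute \code{"metric"}).
#' @export
beta_distance <- function(table, metric = c("bray", "chao_jaccard",
                                            "unifrac_u", "unifrac_w",
                                            "tina_u", "tina_w"),
                          tree = NULL, assoc = NULL,
                          chao_correction = FALSE) {
  metric <- match.arg(metric)
  ra <- relative_abundance(table)
  D <- switch(metric,
    bray = vegan::vegdist(ra, method = "bray"),
    chao_jaccard = chao_jaccard_dist(unclass(table), chao_correction),
    unifrac_u = unifrac_dist(unclass(table), tree, weighted = FALSE),
    unifrac_w = unifrac_dist(unclass(table), tree, weighted = TRUE),
    tina_u = tina_dist(ra, assoc, weighted = FALSE),
    tina_w = tina_dist(ra, assoc, weighted = TRUE))
  attr(D, "metric") <- metric
  D
}

tina_dist <- function(ra, assoc, weighted) {
  if (is.null(assoc)) stop("TINA metrics need an association matrix")
  if (!all(colnames(ra) %in% colnames(assoc)))
    stop("association matrix does not cover the table's OTUs")
  s <- unclass(assoc)[colnames(ra), colnames(ra)]
  p <- if (weighted) ra else {
    pa <- (ra > 0) * 1
    pa / rowSums(pa)
  }
  G <- p %*% s %*% t(p)             # G_jk = sum_ab p_aj p_bk s_ab
  d <- diag(G)
  if (any(d <= 0)) stop("invalid association matrix: non-positive ",
                        "self-association energy")
  sim <- G / sqrt(outer(d, d))
  stats::as.dist(1 - sim)
}

chao_jaccard_dist <- function(m, correction = FALSE) {
  n <- nrow(m)
  ra <- m / rowSums(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    shared <- m[j, ] > 0 & m[k, ] > 0
    U <- sum(ra[j, shared])
    V <- sum(ra[k, shared])
    if (correction && any(shared)) {
      nj <- sum(m[j, ]); nk <- sum(m[k, ])
      f1k <- sum(shared & m[k, ] == 1); f2k <- max(sum(shared & m[k, ] == 2), 1)
      f1j <- sum(shared & m[j, ] == 1); f2j <- max(sum(shared & m[j, ] == 2), 1)
      U <- min(U + (nk - 1) / nk * f1k / (2 * f2k) *
                 sum(ra[j, shared & m[k, ] == 1]), 1)
      V <- min(V + (nj - 1) / nj * f1j / (2 * f2j) *
                 sum(ra[k, shared & m[j, ] == 1]), 1)
    }
    sim <- if (U + V - U * V > 0) U * V / (U + V - U * V) else 0
    D[j, k] <- D[k, j] <- 1 - sim
  }
  stats::as.dist(D)
}

# branch-wise UniFrac; weighted version uses the normalized form whose
# scaling term is the abundance-weighted distance of tips to the root
unifrac_dist <- function(m, tree, weighted) {
  if (is.null(tree)) stop("UniFrac needs a tree")
  if (!ape::is.rooted(tree)) stop("UniFrac needs a rooted tree")
  miss <- setdiff(colnames(m), tree$tip.label)
  if (length(miss)) stop("OTUs missing from tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  tree <- ape::keep.tip(tree, colnames(m))
  inc <- branch_tip_incidence(tree)            # edges x tips (logical)
  inc <- inc[, colnames(m), drop = FALSE]
  bl <- tree$edge.length
  n <- nrow(m)
  ra <- m / rowSums(m)
  P <- inc %*% t(ra)                           # edges x samples branch mass
  O <- (inc %*% t(m > 0)) > 0                  # presence under branch
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (weighted) {
    tipdepth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    names(tipdepth) <- tree$tip.label
    rootdist <- as.numeric(ra %*% tipdepth[colnames(m)])
  }
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    if (weighted) {
      D[j, k] <- sum(bl * abs(P[, j] - P[, k])) / (rootdist[j] + rootdist[k])
    } else {
      uni <- O[, j] | O[, k]
      D[j, k] <- sum(bl * (O[, j] != O[, k])) / sum(bl * uni)
    }
    D[k, j] <- D[j, k]
  }
  stats::as.dist(D)
}

branch_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  inc <- matrix(FALSE, nedge, ntip,
                dimnames = list(NULL, tree$tip.label))
  # postorder accumulation of descendant tips per edge
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(ord))) {
    par <- ord[r, 1]; chi <- ord[r, 2]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  for (r in seq_len(nedge)) inc[r, desc[[tree$edge[r, 2]]]] <- TRUE
  inc
}

#' Principal coordinates analysis
#'
#' Classical scaling of a distance matrix via the double-centred Gower
#' matrix. Negative eigenvalues are reported, not corrected; per-axis
#' explained fractions are relative to the positive eigenvalue mass.
#'
#' @param D A \code{dist} or symmetric matrix.
#' @param n_axes Number of axes to return.
#' @return List: \code{coordinates} (samples x axes), \code{eigenvalues}
#'   (all, including negatives), \code{fraction_explained} per returned axis.
#' @export
pcoa_ordination <- function(D, n_axes = 2L) {
  D <- stats::as.dist(D)
  n <- attr(D, "Size")
  # cmdscale warns when the spectrum has negative eigenvalues; those are
  # part of this function's return value, not a problem to warn about
  fit <- suppressWarnings(stats::cmdscale(D, k = n - 1, eig = TRUE))
  ev <- fit$eig
  pos <- sum(ev[ev > 0])
  rank <- ncol(fit$points)
  if (n_axes > rank) {
    warning("n_axes exceeds rank ", rank, "; truncated")
    n_axes <- rank
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCoA", seq_len(n_axes))
  list(coordinates = coords, eigenvalues = ev,
       fraction_explained = ev[seq_len(n_axes)] / pos)
}

#' PERMANOVA on a distance matrix
#'
#' Single-factor permutational multivariate ANOVA (the adonis pseudo-F test)
#' with raw unrestricted label permutations.
#'
#' @param D A \code{dist}.
#' @param groups Factor of group labels, one per sample.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with \code{R2}, \code{F}, \code{p}.
#' @export
permanova <- function(D, groups, n_perm = 999L, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(D) ~ g,
                        data = data.frame(g = groups),
                        permutations = n_perm)
  list(R2 = fit$R2[1], F = fit$F[1], p = fit$`Pr(>F)`[1])
}

#' Per-variable PERMANOVA R-squared ranking
#'
#' One single-variable PERMANOVA per metadata variable, sorted by
#' decreasing R-squared. Constant variables are skipped with a warning.
#'
#' @param D A \code{dist}.
#' @param metadata Data frame aligned with \code{D}'s samples.
#' @param variables Column names to test.
#' @param n_perm,seed Passed to each test.
#' @return Data frame (variable, R2, F, p) sorted by descending R2.
#' @export
adonis_r2_ranking <- function(D, metadata, variables, n_perm = 999L,
                              seed = 1L) {
  rows <- lapply(variables, function(v) {
    x <- metadata[[v]]
    if (length(unique(x)) < 2) {
      warning("variable '", v, "' is constant; skipped")
      return(NULL)
    }
    set.seed(derive_seed(seed, paste0("adonis_", v)))
    fit <- vegan::adonis2(stats::as.dist(D) ~ x,
                          data = data.frame(x = x), permutations = n_perm)
    data.frame(variable = v, R2 = fit$R2[1], F = fit$F[1],
               p = fit$`Pr(>F)`[1])
  })
  out <- do.call(rbind, rows)
  out[order(-out$R2), , drop = FALSE]
}

#' Variation partitioning across edaphic, geographic and climatic variables
#'
#' Distance-based redundancy analysis partitioning of a community distance
#' matrix over the three environmental variable groups, with unique and
#' shared adjusted R-squared fractions by inclusion-exclusion over the seven
#' subset models (negative adjusted fractions are reported as-is).
#'
#' @param D A \code{dist} of the community.
#' @param metadata A \code{sample_metadata} aligned with \code{D}.
#' @param groups Group names to partition over (exactly 3).
#' @return List: \code{unique} (named), \code{pairwise_shared},
#'   \code{threeway_shared}, \code{residual}, \code{total_explained}, and
#'   the underlying \code{vegan::varpart} object as \code{"fit"}.
#' @export
variation_partition <- function(D, metadata,
                                groups = c("edaphic", "geographic",
                                           "climatic")) {
  stopifnot(length(groups) == 3)
  Xs <- lapply(groups, function(g) {
    X <- env_variables(metadata, g)
    X <- X[, vapply(X, function(x) stats::var(x) > 0, TRUE), drop = FALSE]
    if (ncol(X) == 0) stop("group '", g, "' has no non-constant variables")
    X
  })
  fit <- vegan::varpart(stats::as.dist(D), Xs[[1]], Xs[[2]], Xs[[3]])
  fr <- fit$part$indfract$Adj.R.square
  names(fr) <- rownames(fit$part$indfract)
  out <- list(unique = stats::setNames(fr[1:3], groups),
              pairwise_shared = stats::setNames(
                fr[4:6], c(paste(groups[1], groups[2], sep = "+"),
                           paste(groups[2], groups[3], sep = "+"),
                           paste(groups[1], groups[3], sep = "+"))),
              threeway_shared = unname(fr[7]),
              residual = unname(fr[8]),
              total_explained = sum(fr[1:7]))
  attr(out, "fit") <- fit
  out
}

#' Core microbiota per region and their intersections
#'
#' An OTU belongs to a region's core when present in at least
#' \code{occupancy} of that region's samples (the survey convention is 1, i.e. 100%
#' occupancy). All Venn segments of the set system are reported.
#'
#' @param tables Named list of per-region \code{otu_table}s.
#' @param occupancy Occupancy fraction in (0, 1].
#' @return List: \code{cores} (per-region OTU id vectors), \code{segments}
#'   (data frame of all non-empty membership patterns with counts and
#'   percentage of the union), \code{union_size}.
#' @export
core_microbiota <- function(tables, occupancy = 1) {
  stopifnot(occupancy > 0, occupancy <= 1)
  if (is.null(names(tables))) names(tables) <- paste0("R", seq_along(tables))
  cores <- lapply(tables, function(tb) {
    if (nrow(tb) == 0) stop("empty region table")
    occ <- colMeans(unclass(tb) > 0)
    colnames(tb)[occ >= occupancy]
  })
  univ <- unique(unlist(cores))
  memb <- vapply(cores, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1,
                                         dimnames = list(NULL, names(cores)))
  pattern <- apply(memb, 1, function(z)
    paste(names(cores)[z], collapse = "&"))
  counts <- table(pattern)
  segments <- data.frame(segment = names(counts),
                         count = as.integer(counts),
                         percent = 100 * as.integer(counts) / length(univ))
  segments <- segments[order(-segments$count), ]
  list(cores = cores, segments = segments, union_size = length(univ))
}

#' Paddy-to-nonpaddy enrichment ratios with Wilcoxon tests
#'
#' Per-OTU ratio of mean relative abundance in paddy over nonpaddy samples
#' (a pseudo-fraction of 1e-6 replaces zero denominators), a two-sided
#' Wilcoxon rank-sum test per OTU, and BH-adjusted p-values across OTUs.
#'
#' @param table An \code{otu_table} containing both soil types.
#' @param metadata Matching \code{sample_metadata}.
#' @return Data frame (otu, mean_paddy, mean_nonpaddy, ratio, p, padj);
#'   OTUs absent everywhere are dropped.
#' @export
enrichment_ratio <- function(table, metadata) {
  md <- metadata[rownames(table), , drop = FALSE]
  if (nlevels(droplevels(md$soil_type)) < 2)
    stop("both soil types must be present")
  ra <- relative_abundance(table)
  keep <- colSums(ra) > 0
  ra <- ra[, keep, drop = FALSE]
  paddy <- md$soil_type == "paddy"
  mp <- colMeans(ra[paddy, , drop = FALSE])
  mn <- colMeans(ra[!paddy, , drop = FALSE])
  pvals <- vapply(seq_len(ncol(ra)), function(a)
    suppressWarnings(stats::wilcox.test(ra[paddy, a],
                                        ra[!paddy, a])$p.value),
    numeric(1))
  data.frame(otu = colnames(ra), mean_paddy = mp, mean_nonpaddy = mn,
             ratio = mp / ifelse(mn > 0, mn, 1e-6),
             p = pvals, padj = stats::p.adjust(pvals, "BH"),
             row.names = NULL)
}
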