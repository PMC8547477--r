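#' Degree distribution and scale-free diagnostics
#'
#' Fits a discrete power law to the degree sequence by maximum likelihood
#' (x_min chosen by the Kolmogorov-Smirnov criterion), fits a geometric
#' (discrete exponential) tail on the same x_min, reports the
#' log-likelihood ratio with a Vuong-style normal p-value, and simulates an
#' Erdos-Renyi reference graph with the same node and edge counts.
#'
#' @param net A \code{cooccurrence_network} or \code{igraph} graph.
#' @param seed Seed for the Erdos-Renyi reference.
#' @return List: \code{degrees}, \code{power_law} (alpha, x_min, KS p from
#'   \code{igraph::fit_power_law}), \code{loglik_ratio} (positive favours
#'   the power law over the exponential), \code{lr_p}, and
#'   \code{er_reference} (degree sequence of the reference graph).
#' @export
degree_stats <- function(net, seed = 1L) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  if (igraph::vcount(g) < 10) stop("need at least 10 nodes")
  deg <- igraph::degree(g)
  pl <- igraph::fit_power_law(deg[deg > 0], implementation = "plfit")
  lr <- powerlaw_vs_exponential(deg[deg > 0], pl$xmin, pl$alpha)
  set.seed(seed)
  er <- igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
  list(degrees = deg,
       power_law = list(alpha = pl$alpha, x_min = pl$xmin,
                        ks_p = pl$KS.p),
       loglik_ratio = lr$R, lr_p = lr$p,
       er_reference = igraph::degree(er))
}

# Vuong-style LR comparison of discrete power law vs geometric on the tail
powerlaw_vs_exponential <- function(deg, xmin, alpha) {
  x <- deg[deg >= xmin]
  n <- length(x)
  if (n < 5 || length(unique(x)) < 2) return(list(R = NA_real_, p = NA_real_))
  # power-law log-likelihood at the fitted alpha (Hurwitz zeta normalizer)
  hz <- sum((xmin + 0:20000)^(-alpha))
  ll_pl <- -alpha * log(x) - log(hz)
  # geometric on x - xmin, MLE
  phat <- 1 / (mean(x) - xmin + 1)
  ll_ex <- (x - xmin) * log(1 - phat) + log(phat)
  d <- ll_pl - ll_ex
  R <- sum(d)
  sd_d <- stats::sd(d)
  p <- if (sd_d == 0) 1 else
    2 * stats::pnorm(-abs(R) / (sqrt(n) * sd_d))
  list(R = R, p = p)
}

#' Detect network modules by resolution-tuned modularity optimization
#'
#' Louvain-style greedy optimization of the resolution-scaled modularity
#' Q(gamma) = sum_c [e_c / m - gamma (d_c / 2m)^2], run \code{n_restarts}
#' times with different internal orderings, keeping the best partition.
#' Edge weights are \code{|rho|}; correlation signs are ignored for
#' partitioning and kept for reporting.
#'
#' @param net A \code{cooccurrence_network} or weighted \code{igraph}.
#' @param resolution Resolution gamma (> 0); the survey convention is 8.
#' @param seed Integer seed.
#' @param n_restarts Restarts (best Q kept).
#' @return List of class \code{"module_partition"}: \code{membership}
#'   (named, module ids renumbered by decreasing size), \code{modularity},
#'   \code{resolution}, \code{sizes} (descending).
#' @export
detect_modules <- function(net, resolution = 8, seed = 1L,
                           n_restarts = 10L) {
  if (resolution <= 0) stop("resolution must be positive")
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, paste0("louvain", r)))
    cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
    q <- igraph::modularity(g, igraph::membership(cl), weights = w,
                            resolution = resolution)
    if (is.null(best) || q > best$q)
      best <- list(q = q, membership = igraph::membership(cl))
  }
  memb <- best$membership
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  memb <- relabel[as.character(memb)]
  names(memb) <- igraph::V(g)$name
  structure(list(membership = memb, modularity = best$q,
                 resolution = resolution,
                 sizes = as.integer(sizes)),
            class = "module_partition")
}

#' Resolution-scaled modularity by direct formula evaluation
#'
#' Q(gamma) = sum_c [e_c / m - gamma (d_c / 2m)^2] over modules c, with
#' weighted edge mass e_c and weighted degree sum d_c.
#'
#' @param net Network or \code{igraph}.
#' @param membership Named or ordered module assignment.
#' @param resolution Resolution gamma.
#' @return Numeric Q.
#' @export
modularity_direct <- function(net, membership, resolution = 1) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
  if (!is.null(names(membership)))
    membership <- membership[igraph::V(g)$name]
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- sum(w)
  same <- membership[el[, 1]] == membership[el[, 2]]
  e_c <- tapply(w[same], membership[el[same, 1]], sum)
  d <- rep(0, igraph::vcount(g))
  for (r in seq_len(nrow(el))) {
    d[el[r, 1]] <- d[el[r, 1]] + w[r]
    d[el[r, 2]] <- d[el[r, 2]] + w[r]
  }
  d_c <- tapply(d, membership, sum)
  e_full <- stats::setNames(rep(0, length(d_c)), names(d_c))
  if (length(e_c)) e_full[names(e_c)] <- e_c
  sum(e_full / m - resolution * (d_c / (2 * m))^2)
}

#' PageRank scores on the undirected co-occurrence graph
#'
#' Random walk with restart on the undirected graph, edge weights
#' \code{|rho|}; scores sum to one.
#'
#' @param net Network or \code{igraph}.
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param tol Convergence tolerance.
#' @return Named numeric vector of PageRank scores.
#' @export
pagerank_scores <- function(net, damping = 0.85, tol = 1e-12) {
  if (damping <= 0 || damping >= 1) stop("damping must be in (0, 1)")
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  pr <- igraph::page_rank(g, damping = damping,
                          weights = igraph::E(g)$weight)$vector
  pr
}

#' Per-module summary of a partitioned network
#'
#' Modules ranked by size, percentage of the network, within/between
#' negative-edge fractions, per-module taxon census at a chosen rank, and a
#' per-phylum Wilcoxon comparison of node abundances between the top two
#' modules (BH-adjusted).
#'
#' @param net A \code{cooccurrence_network}.
#' @param partition A \code{module_partition}.
#' @param taxonomy Optional named per-OTU lineage strings (defaults to the
#'   table's taxonomy carried on the nodes if present).
#' @param tax_rank Rank index in the semicolon-separated lineage (2 =
#'   phylum).
#' @return List: \code{modules} (data frame), \code{edge_signs} (within /
#'   between negative-edge fractions), \code{taxon_census},
#'   \code{top2_phylum_tests}.
#' @export
module_summary <- function(net, partition, taxonomy = NULL, tax_rank = 2L) {
  memb <- partition$membership[net$nodes$otu]
  if (anyNA(memb)) stop("partition does not cover the network")
  n <- nrow(net$nodes)
  sizes <- sort(table(memb), decreasing = TRUE)
  modules <- data.frame(module = as.integer(names(sizes)),
                        n_nodes = as.integer(sizes),
                        percent = 100 * as.integer(sizes) / n)
  e <- net$edges
  within <- memb[e$from] == memb[e$to]
  edge_signs <- c(
    within_negative_fraction = if (any(within))
      mean(e$sign[within] == "negative") else NA_real_,
    between_negative_fraction = if (any(!within))
      mean(e$sign[!within] == "negative") else NA_real_)
  taxon_census <- NULL
  top2_tests <- NULL
  if (!is.null(taxonomy)) {
    rank_of <- function(ids) vapply(strsplit(taxonomy[ids], ";"),
                                    function(z) trimws(z[tax_rank] %||% "NA"),
                                    character(1))
    taxon_census <- as.data.frame(table(
      module = memb, taxon = rank_of(net$nodes$otu)))
    taxon_census <- taxon_census[taxon_census$Freq > 0, ]
    top2 <- as.integer(names(sizes)[seq_len(min(2, length(sizes)))])
    if (length(top2) == 2) {
      ids1 <- net$nodes$otu[memb == top2[1]]
      ids2 <- net$nodes$otu[memb == top2[2]]
      ab <- stats::setNames(net$nodes$abundance, net$nodes$otu)
      phyla <- union(rank_of(ids1), rank_of(ids2))
      rows <- lapply(phyla, function(ph) {
        x <- ab[ids1[rank_of(ids1) == ph]]
        y <- ab[ids2[rank_of(ids2) == ph]]
        if (length(x) < 2 || length(y) < 2) return(NULL)
        data.frame(phylum = ph, n1 = length(x), n2 = length(y),
                   p = suppressWarnings(stats::wilcox.test(x, y)$p.value))
      })
      top2_tests <- do.call(rbind, rows)
      if (!is.null(top2_tests))
        top2_tests$padj <- stats::p.adjust(top2_tests$p, "BH")
    }
  }
  list(modules = modules, edge_signs = edge_signs,
       taxon_census = taxon_census, top2_phylum_tests = top2_tests)
}

#' Identify keystone taxa by within-module PageRank ranking
#'
#' @param partition A \code{module_partition}.
#' @param scores Named PageRank vector (from \code{\link{pagerank_scores}}).
#' @param top_n Keystones per module (all nodes returned, with a warning,
#'   for modules smaller than \code{top_n}).
#' @param n_modules Number of top modules (by size) to report.
#' @param abundance Optional named abundance vector to attach.
#' @return Data frame (module, otu, pagerank, rank_in_module, abundance)
#'   plus a global ranking in attribute \code{"global"}.
#' @export
identify_keystones <- function(partition, scores, top_n = 5L,
                               n_modules = 2L, abundance = NULL) {
  stopifnot(top_n >= 1)
  memb <- partition$membership
  mods <- seq_len(min(n_modules, length(partition$sizes)))
  rows <- lapply(mods, function(mod) {
    ids <- names(memb)[memb == mod]
    if (length(ids) < top_n)
      warning("module ", mod, " smaller than top_n; returning all nodes")
    ids <- ids[order(-scores[ids])][seq_len(min(top_n, length(ids)))]
    data.frame(module = mod, otu = ids, pagerank = scores[ids],
               rank_in_module = seq_along(ids),
               abundance = if (is.null(abundance)) NA_real_
                           else abundance[ids], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  glob <- data.frame(otu = names(sort(scores, decreasing = TRUE)),
                     pagerank = sort(scores, decreasing = TRUE),
                     row.names = NULL)
  attr(out, "global") <- glob
  out
}

#' Sliding-window interplay between node influence and environmental
#' explainability
#'
#' Nodes are ranked (by abundance or PageRank), and within every stride-1
#' window of \code{window} successive nodes the Pearson correlation between
#' PageRank and environmental Pseudo-R-squared is computed. For selected
#' windows, linear fits of Pseudo-R-squared on PageRank are returned with
#' and without "peripheral" nodes (lowest PageRank quantile within the
#' window).
#'
#' @param pagerank,pseudo_r2,rank_value Named, aligned numeric vectors;
#'   \code{rank_value} orders the nodes (descending).
#' @param window Window width.
#' @param fit_windows List of 2-vectors of rank positions to fit (defaults
#'   to the conventional 1-100, 51-150, 100-200 when enough nodes exist).
#' @param peripheral_quantile PageRank quantile below which a node counts as
#'   peripheral within a window (default 0.1).
#' @return List: \code{windows} (data frame: start, end, r, p),
#'   \code{fits} (per fit window: slope, intercept, r2 with and without
#'   peripheral nodes), \code{n_nodes}.
#' @export
interplay_windows <- function(pagerank, pseudo_r2,
                              rank_value = NULL, window = 100L,
                              fit_windows = NULL,
                              peripheral_quantile = 0.1) {
  stopifnot(length(pagerank) == length(pseudo_r2))
  n <- length(pagerank)
  if (window > n) stop("window exceeds node count")
  if (anyNA(pseudo_r2)) stop("environmental Pseudo-R2 missing for some nodes")
  ord <- order(-(rank_value %||% pagerank))
  pr <- pagerank[ord]
  r2 <- pseudo_r2[ord]
  starts <- seq_len(n - window + 1)
  wins <- lapply(starts, function(s) {
    i <- s:(s + window - 1)
    if (stats::sd(pr[i]) == 0 || stats::sd(r2[i]) == 0)
      return(data.frame(start = s, end = s + window - 1,
                        r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(pr[i], r2[i])
    data.frame(start = s, end = s + window - 1,
               r = unname(ct$estimate), p = ct$p.value)
  })
  wins <- do.call(rbind, wins)
  if (is.null(fit_windows)) {
    fit_windows <- Filter(function(wi) wi[2] <= n,
                          list(c(1, 100), c(51, 150), c(100, 200)))
  }
  fits <- lapply(fit_windows, function(wi) {
    i <- wi[1]:wi[2]
    all_fit <- suppressWarnings(stats::lm(r2[i] ~ pr[i]))
    thr <- stats::quantile(pr[i], peripheral_quantile)
    keep <- pr[i] > thr
    core_fit <- if (sum(keep) > 2) stats::lm(r2[i][keep] ~ pr[i][keep])
                else NULL
    list(window = wi,
         all = c(slope = unname(stats::coef(all_fit)[2]),
                 intercept = unname(stats::coef(all_fit)[1]),
                 r2 = suppressWarnings(summary(all_fit)$r.squared)),
         without_peripheral = if (is.null(core_fit)) NULL else
           c(slope = unname(stats::coef(core_fit)[2]),
             intercept = unname(stats::coef(core_fit)[1]),
             r2 = suppressWarnings(summary(core_fit)$r.squared)),
         n_peripheral = sum(!keep))
  })
  list(windows = wins, fits = fits, n_nodes = n)
}

#' Module abundance-ratio correlations with environment and ordination axes
#'
#' Per sample, the ratio of summed relative abundance of module-1 OTUs over
#' module-2 OTUs (plus degree-weighted and PageRank-weighted variants), and
#' Spearman correlations (BH-adjusted) of each ratio against every
#' environmental variable and the first two PCoA axes.
#'
#' @param net A \code{cooccurrence_network}.
#' @param partition A \code{module_partition}.
#' @param table Full \code{otu_table} (samples to correlate over).
#' @param metadata Matching \code{sample_metadata}.
#' @param pcoa_axes Optional samples x 2 coordinate matrix.
#' @param scores Optional named PageRank vector for the PR-weighted ratio.
#' @return List: \code{ratios} (per-sample data frame), \code{correlations}
#'   (data frame: index, variable, rho, p, padj).
#' @export
module_ratio_correlations <- function(net, partition, table, metadata,
                                      pcoa_axes = NULL, scores = NULL) {
  memb <- partition$membership
  m1 <- intersect(names(memb)[memb == 1], colnames(table))
  m2 <- intersect(names(memb)[memb == 2], colnames(table))
  if (!length(m1) || !length(m2)) stop("top two modules not found")
  ra <- relative_abundance(table)
  deg <- stats::setNames(net$nodes$degree, net$nodes$otu)
  wsum <- function(ids, w = NULL) {
    x <- ra[, ids, drop = FALSE]
    if (!is.null(w)) x <- sweep(x, 2, w[ids], "*")
    rowSums(x)
  }
  safe_ratio <- function(a, b) a / ifelse(b > 0, b, 1e-6)
  ratios <- data.frame(
    sample_id = rownames(ra),
    abundance_ratio = safe_ratio(wsum(m1), wsum(m2)),
    degree_weighted_ratio = safe_ratio(wsum(m1, deg), wsum(m2, deg)))
  if (!is.null(scores))
    ratios$pagerank_weighted_ratio <- safe_ratio(wsum(m1, scores),
                                                 wsum(m2, scores))
  vars <- env_variables(metadata[rownames(ra), , drop = FALSE])
  if (!is.null(pcoa_axes)) {
    vars$PCoA1 <- pcoa_axes[rownames(ra), 1]
    vars$PCoA2 <- pcoa_axes[rownames(ra), 2]
  }
  idx_cols <- setdiff(names(ratios), "sample_id")
  rows <- list()
  for (ix in idx_cols) for (v in names(vars)) {
    ct <- suppressWarnings(stats::cor.test(ratios[[ix]], vars[[v]],
                                           method = "spearman"))
    rows[[length(rows) + 1]] <- data.frame(index = ix, variable = v,
                                           rho = unname(ct$estimate),
                                           p = ct$p.value)
  }
  corr <- do.call(rbind, rows)
  corr$padj <- stats::p.adjust(corr$p, "BH")
  list(ratios = ratios, correlations = corr)
}
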