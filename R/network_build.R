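#' Construct a co-occurrence network object
#'
#' @param nodes Data frame with at least \code{otu}; typically also
#'   \code{abundance}, \code{enrichment_ratio}, later \code{degree},
#'   \code{module}, \code{pagerank}.
#' @param edges Data frame with \code{from}, \code{to}, \code{rho},
#'   \code{padj}; \code{sign} is derived from \code{rho}.
#' @param provenance Named list recording thresholds, filters and seeds.
#' @return List of class \code{"cooccurrence_network"}.
#' @export
cooccurrence_network <- function(nodes, edges, provenance = list()) {
  stopifnot(is.data.frame(nodes), "otu" %in% names(nodes))
  assert_unique(nodes$otu, "network nodes")
  if (nrow(edges)) {
    stopifnot(all(c("from", "to", "rho") %in% names(edges)))
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes$otu))
      stop("edge endpoints missing from node table")
    # canonical undirected order, no duplicate edges
    key <- ifelse(edges$from < edges$to,
                  paste(edges$from, edges$to), paste(edges$to, edges$from))
    if (anyDuplicated(key)) stop("duplicate undirected edges")
    edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  } else {
    edges <- data.frame(from = character(), to = character(),
                        rho = numeric(), padj = numeric(),
                        sign = character())
  }
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$otu))
  nodes$degree <- as.integer(deg[nodes$otu])
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (%.1f%% negative)\n",
              nrow(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) 100 * mean(x$edges$sign == "negative") else 0))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' Edge weight is \code{|rho|}; the signed correlation and its sign are kept
#' as edge attributes, node attributes are carried across.
#'
#' @param net A \code{cooccurrence_network}.
#' @return An undirected \code{igraph} graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  g
}

#' Write a network as GraphML or an edge-list TSV
#'
#' @param net A \code{cooccurrence_network}.
#' @param path Output path.
#' @param format \code{"graphml"} (node and edge attributes preserved) or
#'   \code{"edge_tsv"} (one edge per line: source, target, rho, padj, sign).
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    utils::write.table(net$edges[, intersect(c("from", "to", "rho", "padj",
                                               "sign"), names(net$edges))],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a co-occurrence network back from GraphML
#'
#' Inverse of \code{\link{write_network}} for the GraphML format; node and
#' edge attributes are restored.
#'
#' @param path GraphML file written by \code{write_network}.
#' @return A \code{cooccurrence_network}.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  names(nodes)[names(nodes) == "name"] <- "otu"
  nodes$id <- NULL
  nodes$degree <- NULL
  edges <- igraph::as_data_frame(g, what = "edges")
  edges$weight <- NULL
  edges$sign <- NULL
  cooccurrence_network(nodes, edges)
}

#' Build a thresholded co-occurrence network for one soil type
#'
#' Follows the survey design's two-scale filter: a fixed-size random subsample per
#' region determines which OTUs are retained (occupancy filter), relative
#' abundances are recomputed on the filtered OTU set, but the correlation
#' matrix itself is computed on \emph{all} samples of the soil type.
#'
#' @param table \code{otu_table} restricted to one soil type.
#' @param metadata Matching \code{sample_metadata} (used for regions).
#' @param n_subsample_per_region Samples drawn per region for the occupancy
#'   filter (survey default 13).
#' @param min_occupancy Minimum presences among the subsampled set for an
#'   OTU to be kept (survey default 9).
#' @param r_cut Correlation magnitude cutoff (e.g. from
#'   \code{\link{rmt_threshold}}).
#' @param p_cut Adjusted p-value cutoff (survey default 0.001).
#' @param use_all_samples If \code{TRUE} (study behaviour) correlations use
#'   all samples of the soil type; if \code{FALSE}, only the subsample.
#' @param enrichment Optional per-OTU enrichment ratio to attach to nodes.
#' @param sparcc_args List of overrides for \code{\link{sparcc}}.
#' @param n_boot Bootstrap count for edge p-values.
#' @param seed Integer seed.
#' @return A \code{cooccurrence_network}; the SparCC fit and p-values are
#'   attached as attributes \code{"fit"} and \code{"pvalues"}.
#' @export
build_network <- function(table, metadata, n_subsample_per_region = 13L,
                          min_occupancy = 9L, r_cut, p_cut = 0.001,
                          use_all_samples = TRUE, enrichment = NULL,
                          sparcc_args = list(), n_boot = 999L, seed = 1L) {
  md <- metadata[rownames(table), , drop = FALSE]
  set.seed(derive_seed(seed, "network_subsample"))
  sub_ids <- unlist(lapply(split(md$sample_id, md$region), function(ids) {
    if (length(ids) < n_subsample_per_region)
      stop("region with fewer than ", n_subsample_per_region, " samples")
    sample(ids, n_subsample_per_region)
  }), use.names = FALSE)
  occ <- colSums(unclass(table)[sub_ids, , drop = FALSE] > 0)
  keep <- occ >= min_occupancy
  if (!any(keep)) stop("occupancy filter removed every OTU")
  kept <- unclass(table)[, keep, drop = FALSE]
  corr_tab <- if (use_all_samples) kept else kept[sub_ids, , drop = FALSE]
  fit <- do.call(sparcc, c(list(counts = corr_tab,
                                seed = derive_seed(seed, "network_sparcc")),
                           sparcc_args))
  pv <- do.call(sparcc_pvalues,
                c(list(counts = corr_tab, rho_obs = fit$rho, n_boot = n_boot,
                       seed = derive_seed(seed, "network_pvalues")),
                  sparcc_args[intersect(names(sparcc_args), "pseudocount")]))
  padj <- tsbh_fdr(pv)
  sel <- which(upper.tri(fit$rho) & abs(fit$rho) >= r_cut & padj < p_cut,
               arr.ind = TRUE)
  ids <- colnames(kept)
  edges <- data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
                      rho = fit$rho[sel], padj = padj[sel])
  # node abundance: mean over regions of the region-mean relative abundance
  ra <- relative_abundance(kept)
  reg_mean <- apply(ra, 2, function(x) tapply(x, md$region, mean))
  abund <- if (is.matrix(reg_mean)) colMeans(reg_mean) else reg_mean
  nodes <- data.frame(otu = ids, abundance = as.numeric(abund[ids]))
  nodes$enrichment_ratio <-
    if (!is.null(enrichment)) as.numeric(enrichment[ids]) else NA_real_
  net <- cooccurrence_network(nodes, edges, provenance = list(
    r_cut = r_cut, p_cut = p_cut, min_occupancy = min_occupancy,
    n_subsample_per_region = n_subsample_per_region,
    use_all_samples = use_all_samples, n_boot = n_boot, seed = seed,
    n_otus_kept = length(ids)))
  attr(net, "fit") <- fit
  attr(net, "pvalues") <- pv
  attr(net, "padj") <- padj
  net
}
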