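#' Omission score: SparCC correlation without a sample subset
#'
#' Recomputes SparCC on the retained samples and returns the correlation of
#' the requested OTU pair. With an empty omission set this equals the
#' original correlation (up to the estimator's own Monte Carlo stream; use
#' the same seed and parameters for exact identity).
#'
#' @param counts Counts matrix or \code{otu_table}.
#' @param edge Length-2 vector of OTU ids (or column indices).
#' @param omit Sample ids (or row indices) to leave out.
#' @param ... Passed to \code{\link{sparcc}} (e.g. \code{n_iter},
#'   \code{seed}).
#' @return The omission score, a correlation in [-1, 1].
#' @export
omission_score <- function(counts, edge, omit = NULL, ...) {
  m <- unclass(counts)
  keep <- setdiff(rownames(m) %||% seq_len(nrow(m)), omit)
  if (length(keep) < 10) stop("fewer than 10 samples retained")
  sub <- m[keep, , drop = FALSE]
  cols <- if (is.character(edge)) match(edge, colnames(m)) else edge
  if (anyNA(cols)) stop("edge OTUs not found")
  if (any(colSums(sub[, cols, drop = FALSE]) == 0))
    stop("edge OTU absent from all retained samples")
  present <- colSums(sub) > 0
  present[cols] <- TRUE
  sub <- sub[, present, drop = FALSE]
  fit <- sparcc(sub, ...)
  new_cols <- match(colnames(m)[cols], colnames(sub))
  fit$rho[new_cols[1], new_cols[2]]
}

#' Omission-score permutation test for edge specificity
#'
#' For every network edge, the omission score (OS) after removing one sample
#' group's samples is compared with OS values from random same-size
#' omission sets. The signed attenuation r = sign(rho) * OS orders scores so
#' that smaller means more attenuated relative to the original sign; the
#' permutation p-value is the add-one-smoothed fraction of random sets at
#' least as attenuating as the group. P-values are TSBH-adjusted across the
#' edge family per group, and an edge is labelled specific for a group when
#' the ratio OS / |rho_original| is below 1 and the adjusted p is below
#' \code{alpha}.
#'
#' Random omission sets are drawn once per group size and shared across
#' edges: SparCC is a whole-matrix estimator, so one recomputation per
#' omission set serves every edge, which is what makes 500 random sets
#' tractable. Results are deterministic given the seed.
#'
#' @param counts Counts matrix or \code{otu_table} covering the network's
#'   OTUs.
#' @param net A \code{cooccurrence_network} (its edges define the family).
#' @param groups Named factor assigning each sample to a group (soil type or
#'   region).
#' @param n_random Random omission sets per group size (survey default 500).
#' @param alpha Label cutoff on the adjusted p-value.
#' @param abs_variant If \code{TRUE}, order scores by |OS| instead of the
#'   signed attenuation.
#' @param sparcc_args Overrides for the SparCC recomputations (default
#'   \code{n_iter = 5}).
#' @param seed Integer seed.
#' @return Data frame of class \code{"edge_specificity"}: edge, group, OS,
#'   ratio, p, padj, label.
#' @export
edge_specificity_test <- function(counts, net, groups, n_random = 500L,
                                  alpha = 0.05, abs_variant = FALSE,
                                  sparcc_args = list(n_iter = 5L),
                                  seed = 1L) {
  if (n_random < 100) stop("n_random must be at least 100")
  sparcc_args <- sparcc_args[setdiff(names(sparcc_args), "seed")]
  m <- unclass(counts)
  storage.mode(m) <- "double"
  groups <- as.factor(groups)
  if (!is.null(names(groups))) groups <- groups[rownames(m)]
  stopifnot(length(groups) == nrow(m))
  if (any(table(groups) >= nrow(m))) stop("a group contains all samples")
  edges <- net$edges
  if (!nrow(edges)) stop("network has no edges")
  ei <- cbind(match(edges$from, colnames(m)), match(edges$to, colnames(m)))
  if (anyNA(ei)) stop("network OTUs missing from counts")
  rho_orig <- edges$rho
  sgn <- sign(rho_orig)

  run_sparcc <- function(keep_idx, tag) {
    sub <- m[keep_idx, , drop = FALSE]
    ok <- colSums(sub) > 0
    fit <- do.call(sparcc, c(list(counts = sub[, ok, drop = FALSE],
                                  seed = derive_seed(seed, tag)),
                             sparcc_args))
    full <- matrix(NA_real_, ncol(m), ncol(m))
    full[ok, ok] <- fit$rho
    full[ei]
  }

  group_levels <- levels(droplevels(groups))
  group_sizes <- table(groups)[group_levels]
  # one pool of random omission OS vectors per distinct group size
  rand_os <- list()
  for (gs in unique(as.integer(group_sizes))) {
    set.seed(derive_seed(seed, paste0("omission_sets_", gs)))
    sets <- lapply(seq_len(n_random), function(b)
      sample(nrow(m), gs))
    osb <- vapply(seq_along(sets), function(b)
      run_sparcc(setdiff(seq_len(nrow(m)), sets[[b]]),
                 paste0("rand_", gs, "_", b)),
      numeric(nrow(edges)))
    if (!is.matrix(osb)) osb <- matrix(osb, nrow = nrow(edges))
    rand_os[[as.character(gs)]] <- osb        # edges x n_random
  }

  out <- list()
  for (gl in group_levels) {
    keep <- which(groups != gl)
    os_g <- run_sparcc(keep, paste0("group_", gl))
    osb <- rand_os[[as.character(sum(groups == gl))]]
    if (abs_variant) {
      stat_g <- abs(os_g); stat_b <- abs(osb)
    } else {
      stat_g <- sgn * os_g; stat_b <- sgn * osb
    }
    pv <- (1 + rowSums(stat_b < stat_g, na.rm = TRUE)) / (1 + n_random)
    padj <- tsbh_fdr(pv, alpha = alpha)
    ratio <- os_g / abs(rho_orig)
    out[[gl]] <- data.frame(
      from = edges$from, to = edges$to, group = gl,
      rho_original = rho_orig, OS = os_g, ratio = ratio,
      p = pv, padj = padj,
      label = ifelse(ratio < 1 & padj < alpha, "specific", "nonspecific"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("edge_specificity", "data.frame")
  res
}

#' Census of strengthened and weakened associations between soil types
#'
#' For every edge of the paddy network, compares |rho| in paddy samples with
#' |rho| recomputed on nonpaddy samples (from the nonpaddy network when the
#' pair is present there, otherwise by SparCC recomputation on the nonpaddy
#' table). Optionally repeats the comparison restricted to each region's
#' samples; the per-region strengthened sets give the overlap census.
#'
#' @param net_paddy,net_nonpaddy \code{cooccurrence_network}s.
#' @param counts_paddy,counts_nonpaddy Count tables for the two soil types.
#' @param metadata Optional \code{sample_metadata} covering both tables;
#'   required for \code{per_region = TRUE}.
#' @param per_region Also classify within each region.
#' @param sparcc_args,seed SparCC recomputation controls.
#' @return List: \code{edges} (per-edge data frame with classification
#'   \code{strengthened}/\code{weakened}/\code{tie}/\code{absent}),
#'   \code{counts}, and with \code{per_region} a \code{region_counts} table
#'   plus \code{overlap_segments} of per-region strengthened sets.
#' @export
strengthened_weakened_census <- function(net_paddy, net_nonpaddy,
                                         counts_paddy, counts_nonpaddy,
                                         metadata = NULL,
                                         per_region = FALSE,
                                         sparcc_args = list(n_iter = 5L),
                                         seed = 1L) {
  edges <- net_paddy$edges
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  np_rho <- stats::setNames(net_nonpaddy$edges$rho,
                            key(net_nonpaddy$edges$from,
                                net_nonpaddy$edges$to))
  sparcc_args <- sparcc_args[setdiff(names(sparcc_args), "seed")]
  rho_for <- function(counts, sub_ids = NULL) {
    m <- unclass(counts)
    if (!is.null(sub_ids)) m <- m[sub_ids, , drop = FALSE]
    ok <- colSums(m) > 0 & apply(m, 2, function(x) stats::var(x) > 0)
    fit <- do.call(sparcc, c(list(counts = m[, ok, drop = FALSE],
                                  seed = derive_seed(seed, "census")),
                             sparcc_args))
    list(rho = fit$rho, ids = colnames(m)[ok])
  }
  np_all <- rho_for(counts_nonpaddy)
  classify <- function(rp, rn) {
    ifelse(is.na(rn), "absent",
           ifelse(abs(rp) > abs(rn), "strengthened",
                  ifelse(abs(rp) < abs(rn), "weakened", "tie")))
  }
  rn <- np_rho[key(edges$from, edges$to)]
  need <- is.na(rn)
  if (any(need)) {
    i1 <- match(edges$from, np_all$ids)
    i2 <- match(edges$to, np_all$ids)
    ok <- need & !is.na(i1) & !is.na(i2)
    rn[ok] <- np_all$rho[cbind(i1[ok], i2[ok])]
  }
  edges_out <- data.frame(from = edges$from, to = edges$to,
                          rho_paddy = edges$rho, rho_nonpaddy = unname(rn),
                          class = unname(classify(edges$rho, rn)),
                          row.names = NULL)
  counts <- table(factor(edges_out$class,
                         levels = c("strengthened", "weakened", "tie",
                                    "absent")))
  out <- list(edges = edges_out, counts = counts)
  if (per_region) {
    if (is.null(metadata)) stop("per_region census needs metadata")
    regions <- levels(droplevels(metadata$region))
    strengthened_sets <- list()
    region_counts <- list()
    for (rg in regions) {
      pid <- intersect(rownames(counts_paddy),
                       metadata$sample_id[metadata$region == rg])
      nid <- intersect(rownames(counts_nonpaddy),
                       metadata$sample_id[metadata$region == rg])
      rp_f <- rho_for(counts_paddy, pid)
      rn_f <- rho_for(counts_nonpaddy, nid)
      get_rho <- function(f, a, b) {
        i <- match(a, f$ids); j <- match(b, f$ids)
        bad <- is.na(i) | is.na(j)
        i[bad] <- 1L; j[bad] <- 1L
        r <- f$rho[cbind(i, j)]
        r[bad] <- NA_real_
        r
      }
      rpv <- get_rho(rp_f, edges$from, edges$to)
      rnv <- get_rho(rn_f, edges$from, edges$to)
      cls <- ifelse(is.na(rpv) | is.na(rnv), "absent",
                    classify(rpv, rnv))
      region_counts[[rg]] <- table(factor(cls,
        levels = c("strengthened", "weakened", "tie", "absent")))
      strengthened_sets[[rg]] <- key(edges$from, edges$to)[
        !is.na(cls) & cls == "strengthened"]
    }
    univ <- unique(unlist(strengthened_sets))
    memb <- vapply(strengthened_sets, function(s) univ %in% s,
                   logical(length(univ)))
    if (length(univ) == 1L)
      memb <- matrix(memb, nrow = 1, dimnames = list(NULL, regions))
    pattern <- apply(memb, 1, function(z) paste(regions[z], collapse = "&"))
    out$region_counts <- do.call(rbind, region_counts)
    out$overlap_segments <- as.data.frame(table(pattern),
                                          stringsAsFactors = FALSE)
  }
  out
}
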