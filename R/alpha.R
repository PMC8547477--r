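#' Alpha-diversity profile
#'
#' Computes, per sample: observed OTUs, bias-corrected Chao1, ACE (Chao &
#' Lee, rare-OTU cutoff 10), Shannon entropy in nats, Pielou evenness,
#' Good's coverage, and (when a tree is supplied) Faith's phylogenetic
#' diversity as the total branch length of the rooted subtree spanning the
#' observed tips.
#'
#' Chao1 uses the bias-corrected form S_obs + F1 (F1 - 1) / (2 (F2 + 1)),
#' which is defined when no doubletons are present. Pielou evenness is
#' undefined (NA) for samples with a single observed OTU.
#'
#' @param table An \code{otu_table} (integer counts; the estimators use
#'   singleton and doubleton counts).
#' @param tree Optional rooted \code{phylo} covering all OTUs; required for
#'   \code{faith_pd}.
#' @return Data frame with one row per sample.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  m <- unclass(table)
  out <- data.frame(sample_id = rownames(m),
                    observed_otus = NA_real_, chao1 = NA_real_,
                    ace = NA_real_, shannon = NA_real_,
                    pielou_evenness = NA_real_, goods_coverage = NA_real_)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    x <- x[x > 0]
    S <- length(x)
    N <- sum(x)
    F1 <- sum(x == 1)
    F2 <- sum(x == 2)
    p <- x / N
    sh <- -sum(p * log(p))
    out$observed_otus[i] <- S
    out$chao1[i] <- S + F1 * (F1 - 1) / (2 * (F2 + 1))
    out$ace[i] <- ace_estimate(x)
    out$shannon[i] <- sh
    out$pielou_evenness[i] <- if (S > 1) sh / log(S) else NA_real_
    out$goods_coverage[i] <- 1 - F1 / N
  }
  if (!is.null(tree)) {
    missing_tips <- setdiff(colnames(m), tree$tip.label)
    if (length(missing_tips))
      stop("OTUs missing from tree: ",
           paste(utils::head(missing_tips, 5), collapse = ", "))
    pd <- picante::pd(m, tree, include.root = TRUE)
    out$faith_pd <- pd$PD[match(rownames(m), rownames(pd))]
  }
  out
}

# ACE abundance-based coverage estimator, rare cutoff 10 (Chao & Lee)
ace_estimate <- function(x, rare_cutoff = 10L) {
  rare <- x[x <= rare_cutoff]
  S_abund <- sum(x > rare_cutoff)
  S_rare <- length(rare)
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  if (N_rare == 0) return(S_abund)
  if (F1 == N_rare) return(NA_real_)        # all rare reads are singletons
  C_ace <- 1 - F1 / N_rare
  Fi <- tabulate(rare, nbins = rare_cutoff)
  g2 <- max(S_rare / C_ace * sum(seq_len(rare_cutoff) *
                                   (seq_len(rare_cutoff) - 1) * Fi) /
              (N_rare * (N_rare - 1)) - 1, 0)
  S_abund + S_rare / C_ace + F1 / C_ace * g2
}
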