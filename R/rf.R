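#' MDLP discretization cut points (Fayyad-Irani criterion)
#'
#' Recursive binary splitting of a numeric predictor against a class label:
#' candidate cuts are midpoints between adjacent distinct values, the best
#' cut minimizes the weighted class entropy, and a split is accepted only
#' when its information gain exceeds
#' [log2(N-1) + log2(3^k - 2) - k Ent(S) + k1 Ent(S1) + k2 Ent(S2)] / N.
#'
#' @param x Numeric predictor (finite).
#' @param y_class Class labels (at least 2 classes overall).
#' @return Strictly increasing numeric vector of cut points (possibly
#'   empty: single bin).
#' @export
mdlp_discretize <- function(x, y_class) {
  if (!all(is.finite(x))) stop("non-finite predictor values")
  y <- as.integer(as.factor(y_class))
  if (length(unique(y)) < 2) stop("y_class needs at least 2 classes")
  ord <- order(x)
  sort(mdlp_recurse(x[ord], y[ord]))
}

ent_bits <- function(y) {
  p <- tabulate(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

mdlp_recurse <- function(x, y) {     # x sorted ascending, y aligned
  N <- length(x)
  if (N < 4) return(numeric(0))
  distinct <- which(diff(x) > 0)
  if (!length(distinct)) return(numeric(0))
  ES <- ent_bits(y)
  k <- length(unique(y))
  best <- NULL
  for (i in distinct) {
    e1 <- ent_bits(y[1:i])
    e2 <- ent_bits(y[(i + 1):N])
    wE <- (i * e1 + (N - i) * e2) / N
    if (is.null(best) || wE < best$wE)
      best <- list(i = i, wE = wE, e1 = e1, e2 = e2)
  }
  gain <- ES - best$wE
  k1 <- length(unique(y[1:best$i]))
  k2 <- length(unique(y[(best$i + 1):N]))
  delta <- log2(3^k - 2) - (k * ES - k1 * best$e1 - k2 * best$e2)
  if (gain <= (log2(N - 1) + delta) / N) return(numeric(0))
  cut <- (x[best$i] + x[best$i + 1]) / 2
  c(mdlp_recurse(x[1:best$i], y[1:best$i]),
    cut,
    mdlp_recurse(x[(best$i + 1):N], y[(best$i + 1):N]))
}

# mutual information in bits between two integer-coded vectors
mi_bits <- function(a, b) {
  ka <- max(a); kb <- max(b)
  joint <- tabulate(a + ka * (b - 1L), nbins = ka * kb) / length(a)
  pa <- tabulate(a, nbins = ka) / length(a)
  pb <- tabulate(b, nbins = kb) / length(b)
  pij <- matrix(joint, ka, kb)
  num <- pij / outer(pa, pb)
  sum(pij[pij > 0] * log2(num[pij > 0]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy selection maximizing I(f; y) minus the mean mutual information
#' with already-selected features, all in bits from empirical joint
#' frequencies over discretized values. Ties break toward the lower feature
#' index.
#'
#' @param X_disc Integer-coded matrix (samples x features).
#' @param y_disc Integer-coded response vector.
#' @param k Number of features to select.
#' @return Integer vector of selected column indices, in selection order,
#'   of length \code{min(k, ncol(X_disc))}.
#' @export
mrmr_select <- function(X_disc, y_disc, k) {
  stopifnot(k >= 1)
  p <- ncol(X_disc)
  y <- as.integer(as.factor(y_disc))
  rel <- vapply(seq_len(p), function(j)
    mi_bits(as.integer(X_disc[, j]), y), numeric(1))
  k <- min(k, p)
  selected <- integer(0)
  red_sum <- numeric(p)
  for (step in seq_len(k)) {
    score <- rel - if (length(selected)) red_sum / length(selected) else 0
    score[selected] <- -Inf
    j <- which.max(score)
    selected <- c(selected, j)
    if (step < k) {
      mi_j <- vapply(seq_len(p), function(q)
        if (q %in% selected) 0
        else mi_bits(as.integer(X_disc[, q]), as.integer(X_disc[, j])),
        numeric(1))
      red_sum <- red_sum + mi_j
    }
  }
  selected
}

# discretize a continuous response into quantile classes for MDLP/mRMR
quantile_classes <- function(y, n_classes = 4L) {
  br <- unique(stats::quantile(y, seq(0, 1, length.out = n_classes + 1)))
  if (length(br) < 3) br <- unique(c(min(y), stats::median(y), max(y)))
  if (length(br) < 3) return(NULL)
  as.integer(cut(y, breaks = br, include.lowest = TRUE))
}

# code a continuous column by MDLP cuts (single bin -> all ones)
apply_cuts <- function(x, cuts) {
  if (!length(cuts)) return(rep(1L, length(x)))
  as.integer(findInterval(x, cuts) + 1L)
}

#' Fit OTU-based and environment-based predictive models per target OTU
#'
#' For every OTU with occupancy at least \code{occupancy_min}, two
#' cross-validated ensemble regressions of its relative abundance are fit:
#' M_OTU on the relative abundances of all other OTUs and M_ENV on the
#' environmental variables. Inside each training fold the predictors are
#' MDLP-discretized against the quantile-binned response and reduced to at
#' most \code{k_vars} by mRMR (no leakage into the held-out fold); the
#' ensemble (bagged regression trees via \pkg{ranger}) is then fit on the
#' continuous values of the selected predictors. Pseudo-R2 is one minus the
#' cross-validated mean squared error normalized by the response variance.
#'
#' @param table An \code{otu_table}.
#' @param metadata Matching \code{sample_metadata} (environmental
#'   predictors taken from all variable groups).
#' @param targets Optional OTU ids to model (default: all passing the
#'   occupancy filter).
#' @param occupancy_min Minimum number of samples with a nonzero count
#'   (survey default 10).
#' @param k_vars Maximum selected predictors (survey default 20).
#' @param cv \code{"loo"} or an integer number of folds.
#' @param num_trees Trees per ensemble (at least 500 by contract).
#' @param n_classes Quantile classes for response discretization.
#' @param seed Integer seed.
#' @return Data frame of class \code{"rf_model_result"}: otu, occupancy,
#'   pseudo_r2_otu, pseudo_r2_env, selected_otu, selected_env
#'   (comma-separated, from a whole-data selection pass, for reporting
#'   only).
#' @export
fit_models <- function(table, metadata, targets = NULL,
                       occupancy_min = 10L, k_vars = 20L, cv = 5L,
                       num_trees = 500L, n_classes = 4L, seed = 1L) {
  stopifnot(occupancy_min >= 2)
  if (nrow(table) < 20) stop("need at least 20 samples")
  ra <- relative_abundance(table)
  occ <- colSums(unclass(table) > 0)
  eligible <- colnames(table)[occ >= occupancy_min]
  if (is.null(targets)) targets <- eligible
  targets <- intersect(targets, eligible)
  env <- as.matrix(env_variables(metadata[rownames(table), , drop = FALSE]))
  n <- nrow(ra)
  folds <- if (identical(cv, "loo")) seq_len(n) else {
    set.seed(derive_seed(seed, "rf_folds"))
    sample(rep(seq_len(as.integer(cv)), length.out = n))
  }
  cv_pseudo_r2 <- function(y, X, tag) {
    vy <- stats::var(y)
    if (vy == 0) return(list(r2 = NA_real_, sel = character(0)))
    pred <- rep(NA_real_, n)
    for (f in unique(folds)) {
      tr <- folds != f
      ycl <- quantile_classes(y[tr], n_classes)
      Xtr <- X[tr, , drop = FALSE]
      sel_j <- seq_len(ncol(X))
      if (!is.null(ycl)) {
        Xd <- vapply(seq_len(ncol(Xtr)), function(j)
          apply_cuts(Xtr[, j], mdlp_recurse_sorted(Xtr[, j], ycl)),
          integer(sum(tr)))
        informative <- which(apply(Xd, 2, max) > 1L)
        if (length(informative)) {
          sel_local <- mrmr_select(Xd[, informative, drop = FALSE], ycl,
                                   k_vars)
          sel_j <- informative[sel_local]
        }
      }
      sel_j <- sel_j[seq_len(min(length(sel_j), k_vars))]
      dtr <- data.frame(y = y[tr], Xtr[, sel_j, drop = FALSE])
      fit <- ranger::ranger(y ~ ., data = dtr, num.trees = num_trees,
                            seed = derive_seed(seed, paste0(tag, f)),
                            num.threads = 1)
      dte <- data.frame(X[!tr, sel_j, drop = FALSE])
      names(dte) <- names(dtr)[-1]
      pred[!tr] <- stats::predict(fit, data = dte)$predictions
    }
    # reporting-only selection on the whole data
    ycl_all <- quantile_classes(y, n_classes)
    sel_names <- character(0)
    if (!is.null(ycl_all)) {
      Xd <- vapply(seq_len(ncol(X)), function(j)
        apply_cuts(X[, j], mdlp_recurse_sorted(X[, j], ycl_all)),
        integer(n))
      informative <- which(apply(Xd, 2, max) > 1L)
      if (length(informative))
        sel_names <- colnames(X)[informative[
          mrmr_select(Xd[, informative, drop = FALSE], ycl_all, k_vars)]]
    }
    list(r2 = 1 - mean((pred - y)^2) / vy, sel = sel_names)
  }
  rows <- lapply(targets, function(otu) {
    y <- ra[, otu]
    if (stats::var(y) == 0) return(NULL)
    Xo <- ra[, setdiff(colnames(ra), otu), drop = FALSE]
    mo <- cv_pseudo_r2(y, Xo, paste0("otu_", otu))
    me <- cv_pseudo_r2(y, env, paste0("env_", otu))
    data.frame(otu = otu, occupancy = occ[otu],
               pseudo_r2_otu = mo$r2, pseudo_r2_env = me$r2,
               selected_otu = paste(mo$sel, collapse = ","),
               selected_env = paste(me$sel, collapse = ","),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no modelable targets (zero-variance responses)")
  class(out) <- c("rf_model_result", "data.frame")
  out
}

# MDLP on unsorted data (sorts once, then recurses)
mdlp_recurse_sorted <- function(x, y) {
  ord <- order(x)
  sort(mdlp_recurse(x[ord], as.integer(y)[ord]))
}

#' Compare OTU-based and environment-based model accuracies
#'
#' Paired Wilcoxon signed-rank test on the per-OTU difference of
#' cross-validated Pseudo-R2 between M_OTU and M_ENV, with BH adjustment
#' when several groupings (e.g. occupancy strata) are tested.
#'
#' @param results An \code{rf_model_result}.
#' @param group Optional factor over the rows defining strata.
#' @return Data frame: group, n, median_otu, median_env, statistic, p,
#'   padj.
#' @export
compare_models <- function(results, group = NULL) {
  df <- as.data.frame(results)
  df <- df[!is.na(df$pseudo_r2_otu) & !is.na(df$pseudo_r2_env), ]
  if (nrow(df) < 10) stop("need at least 10 modeled OTUs")
  g <- if (is.null(group)) factor(rep("all", nrow(df))) else as.factor(group)
  rows <- lapply(levels(g), function(gl) {
    d <- df[g == gl, ]
    dd <- d$pseudo_r2_otu - d$pseudo_r2_env
    p <- if (all(dd == 0)) 1 else
      suppressWarnings(stats::wilcox.test(d$pseudo_r2_otu,
                                          d$pseudo_r2_env,
                                          paired = TRUE)$p.value)
    data.frame(group = gl, n = nrow(d),
               median_otu = stats::median(d$pseudo_r2_otu),
               median_env = stats::median(d$pseudo_r2_env),
               p = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, "BH")
  out
}
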