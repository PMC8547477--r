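#' SparCC correlations from compositional count data
#'
#' Estimates correlations between latent "basis" abundances from counts by
#' inverting log-ratio variances. Each outer iteration resamples fractions
#' from a Dirichlet posterior with the pseudocount as prior mass, computes
#' the variation matrix t_ab = var(log(f_a/f_b)), solves the basis variances
#' under the sparsity assumption, and iteratively excludes the most strongly
#' correlated pairs before re-solving. The reported rho is the elementwise
#' median over outer iterations.
#'
#' @param counts An \code{otu_table} or counts matrix, samples x OTUs.
#' @param n_iter Outer Dirichlet-resampling iterations (median taken).
#' @param n_excl_iter Strong-pair exclusion rounds per iteration.
#' @param excl_threshold Only pairs with \code{|rho|} above this are
#'   candidates for exclusion.
#' @param pseudocount Mass added to every count before normalizing to
#'   fractions (survey default 1e-6); scalar or one value per sample.
#' @param resample If \code{TRUE} (default) fractions are resampled each
#'   outer iteration from a Dirichlet with concentration
#'   \code{counts + dirichlet_prior}; if \code{FALSE} the pseudocount
#'   fractions \code{(x + pseudocount) / sum} are used, making the estimator
#'   a deterministic function of the counts (the form under which scale
#'   invariance of compositions holds exactly).
#' @param dirichlet_prior Prior mass per cell for the resampling draw. The
#'   default 1 is the resampling prior of the original algorithm; priors
#'   near zero are not usable here because a zero count then implies a
#'   log-fraction variance of trigamma(prior), which diverges and erases
#'   the correlations of any OTU with zeros.
#' @param seed Integer seed.
#' @return List of class \code{"sparcc_fit"}: \code{rho} (correlations, unit
#'   diagonal), \code{basis_variance} (median basis variances),
#'   \code{logratio_variance} (last iteration's t matrix), \code{n_clipped}
#'   (count of negative solved variances clipped).
#' @export
sparcc <- function(counts, n_iter = 20L, n_excl_iter = 10L,
                   excl_threshold = 0.1, pseudocount = 1e-6,
                   resample = TRUE, dirichlet_prior = 1, seed = 1L) {
  m <- unclass(counts)
  storage.mode(m) <- "double"
  p <- ncol(m)
  if (p < 4) stop("SparCC needs at least 4 OTUs")
  if (any(m < 0)) stop("negative counts")
  if (any(colSums(m) == 0))
    stop("OTU(s) with zero counts everywhere; filter before SparCC")
  set.seed(seed)
  if (!resample) n_iter <- 1L
  rhos <- array(NA_real_, c(p, p, n_iter))
  omegas <- matrix(NA_real_, p, n_iter)
  n_clipped <- 0L
  t_last <- NULL
  for (it in seq_len(n_iter)) {
    f <- if (resample) dirichlet_fractions(m, dirichlet_prior) else
      mean_fractions(m, pseudocount)
    lf <- log(f)
    v <- apply(lf, 2, stats::var)
    cv <- stats::cov(lf)
    tmat <- outer(v, v, "+") - 2 * cv          # var(log f_a - log f_b)
    diag(tmat) <- 0
    sol <- solve_basis(tmat, n_excl_iter, excl_threshold)
    rhos[, , it] <- sol$rho
    omegas[, it] <- sol$omega2
    n_clipped <- n_clipped + sol$n_clipped
    t_last <- tmat
  }
  rho <- apply(rhos, c(1, 2), stats::median)
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  ids <- colnames(m) %||% paste0("OTU", seq_len(p))
  dimnames(rho) <- list(ids, ids)
  structure(list(rho = rho,
                 basis_variance = apply(omegas, 1, stats::median),
                 logratio_variance = t_last,
                 n_clipped = n_clipped),
            class = "sparcc_fit")
}

# one Dirichlet draw of fractions per sample (prior may be per-sample)
dirichlet_fractions <- function(m, prior) {
  shape <- m + prior                # recycles a per-sample prior by row
  g <- matrix(stats::rgamma(length(shape), shape = as.numeric(shape)),
              nrow(m), ncol(m))
  g <- pmax(g, .Machine$double.xmin)
  g / rowSums(g)
}

mean_fractions <- function(m, pseudocount) {
  f <- m + pseudocount
  f / rowSums(f)
}

# Solve basis variances from the variation matrix under the sparsity
# assumption, with iterative exclusion of the strongest pairs.
solve_basis <- function(tmat, n_excl_iter, excl_threshold) {
  p <- ncol(tmat)
  M <- matrix(1, p, p)
  diag(M) <- p - 2
  excluded <- matrix(FALSE, p, p)
  n_clipped <- 0L
  compute <- function() {
    tm <- tmat
    tm[excluded] <- 0
    omega2 <- solve(M, rowSums(tm))
    if (any(omega2 <= 0)) {
      n_clipped <<- n_clipped + sum(omega2 <= 0)
      omega2[omega2 <= 0] <- min(omega2[omega2 > 0], 1e-6)
    }
    om <- sqrt(omega2)
    rho <- (outer(omega2, omega2, "+") - tmat) / (2 * outer(om, om))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    list(rho = rho, omega2 = omega2)
  }
  sol <- compute()
  for (k in seq_len(n_excl_iter)) {
    cand <- abs(sol$rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    ij <- arrayInd(which.max(cand), dim(cand))
    i <- ij[1]; j <- ij[2]
    if (cand[i, j] <= excl_threshold) break
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    sol <- compute()
  }
  list(rho = sol$rho, omega2 = sol$omega2, n_clipped = n_clipped)
}

#' Bootstrap p-values for SparCC correlations
#'
#' The null shuffles each OTU's counts independently across samples, which
#' preserves every marginal abundance distribution while destroying
#' co-variation, and recomputes SparCC on each shuffled table. Two-sided
#' p-values use the add-one permutation convention.
#'
#' @param counts Counts matrix or \code{otu_table}.
#' @param rho_obs Observed SparCC correlation matrix.
#' @param n_boot Number of null tables (minimum 99).
#' @param n_iter Outer SparCC iterations per null table (fewer than the
#'   observed fit is customary; the null needs far less precision).
#' @param pseudocount,seed Passed to \code{\link{sparcc}}.
#' @return Symmetric matrix of p-values in (0, 1], unit-free, diagonal 1.
#' @export
sparcc_pvalues <- function(counts, rho_obs, n_boot = 999L, n_iter = 5L,
                           pseudocount = 1e-6, seed = 1L) {
  if (n_boot < 99) stop("n_boot must be at least 99")
  m <- unclass(counts)
  storage.mode(m) <- "double"
  set.seed(derive_seed(seed, "sparcc_boot"))
  exceed <- matrix(0L, ncol(m), ncol(m))
  for (b in seq_len(n_boot)) {
    mb <- apply(m, 2, sample)
    fit <- sparcc(mb, n_iter = n_iter, pseudocount = pseudocount,
                  seed = derive_seed(seed, paste0("boot", b)))
    exceed <- exceed + (abs(fit$rho) >= abs(rho_obs))
  }
  pv <- (1 + exceed) / (1 + n_boot)
  diag(pv) <- 1
  dimnames(pv) <- dimnames(rho_obs)
  pv
}

#' Two-stage Benjamini-Hochberg (TSBH) adjusted p-values
#'
#' Stage one estimates the number of true nulls m0 by counting BH rejections
#' at level alpha/(1+alpha); stage two rescales BH-adjusted p-values by
#' m0/m. For a symmetric p-value matrix the upper triangle is the family and
#' the result is mirrored back.
#'
#' @param pvalues Numeric vector, or symmetric matrix whose upper triangle
#'   is the tested family.
#' @param alpha Nominal FDR level used in the stage-one null-count estimate.
#' @return Adjusted p-values with the shape of the input.
#' @export
tsbh_fdr <- function(pvalues, alpha = 0.05) {
  if (is.matrix(pvalues)) {
    ut <- upper.tri(pvalues)
    adj <- tsbh_fdr(pvalues[ut], alpha = alpha)
    out <- pvalues
    out[ut] <- adj
    out <- t(out)
    out[ut] <- adj
    out <- t(out)
    diag(out) <- 1
    return(out)
  }
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  alpha1 <- alpha / (1 + alpha)
  r1 <- sum(stats::p.adjust(p, "BH") <= alpha1)
  m0 <- m - r1
  if (m0 == 0) return(rep(0, m))   # stage one rejected everything
  pmin(1, (m0 / m) * stats::p.adjust(p, "BH"))
}
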