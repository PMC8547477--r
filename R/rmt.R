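#' Random-matrix-theory correlation threshold
#'
#' Scans candidate thresholds; for each, entries with \code{|rho|} below the
#' candidate are zeroed, isolated rows are removed, and the eigenvalue
#' spectrum is unfolded through a monotone spline fit to the empirical
#' spectral CDF. The nearest-neighbour spacing distribution (NNSD) of the
#' unfolded spectrum is compared, by chi-square distance on 20 bins over
#' s in [0, 3], with the Poisson law exp(-s) and the Wigner-Dyson (GOE)
#' surmise (pi s / 2) exp(-pi s^2 / 4). Dense correlated noise follows GOE;
#' once the threshold isolates modular signal the spacings become Poisson.
#' The selected threshold is the smallest candidate whose NNSD is closer to
#' Poisson than to GOE.
#'
#' @param rho Symmetric correlation matrix (unit diagonal), at least 50 x 50.
#' @param t_min,t_max,step Candidate threshold grid.
#' @param n_knots Spline knots for the unfolding (default 10).
#' @param min_edges Minimum retained off-diagonal pairs for a candidate's
#'   spectrum to be considered meaningful; defaults to the matrix dimension.
#' @return List of class \code{"rmt_threshold"}: \code{threshold}, and
#'   \code{trace}, a data frame with one row per candidate (threshold,
#'   n_edges, chi2 distance to Poisson and to GOE, validity flag).
#' @export
rmt_threshold <- function(rho, t_min = 0.2, t_max = 0.8, step = 0.05,
                          n_knots = 10L, min_edges = nrow(rho)) {
  if (step <= 0) stop("step must be positive")
  if (nrow(rho) < 50) stop("matrix must be at least 50 x 50 for RMT spectra")
  cands <- seq(t_min, t_max, by = step)
  trace <- data.frame(threshold = cands, n_edges = NA_integer_,
                      d_poisson = NA_real_, d_goe = NA_real_, valid = FALSE)
  for (k in seq_along(cands)) {
    A <- rho
    A[abs(A) < cands[k]] <- 0
    diag(A) <- 1
    deg <- rowSums(A != 0) - 1
    A <- A[deg > 0, deg > 0, drop = FALSE]
    n_edges <- sum(A[upper.tri(A)] != 0)
    trace$n_edges[k] <- n_edges
    if (nrow(A) < 20 || n_edges < min_edges) next
    s <- nnsd(eigen(A, symmetric = TRUE, only.values = TRUE)$values, n_knots)
    if (is.null(s)) next
    d <- nnsd_distances(s)
    trace$d_poisson[k] <- d["poisson"]
    trace$d_goe[k] <- d["goe"]
    trace$valid[k] <- TRUE
  }
  hit <- which(trace$valid & trace$d_poisson < trace$d_goe)
  if (!length(hit))
    stop("no Poisson transition found in [", t_min, ", ", t_max,
         "]; widen the candidate range or inspect the trace")
  structure(list(threshold = cands[hit[1]], trace = trace),
            class = "rmt_threshold")
}

# unfolded nearest-neighbour spacings of an eigenvalue spectrum
nnsd <- function(ev, n_knots = 10L) {
  ev <- sort(ev)
  n <- length(ev)
  if (n < 20) return(NULL)
  ecdf_y <- (seq_len(n) - 0.5) / n
  # monotone spline through the empirical spectral CDF at evenly spaced knots
  knots <- unique(stats::quantile(ev, probs = seq(0, 1, length.out = n_knots)))
  if (length(knots) < 4) return(NULL)
  ky <- stats::approx(ev, ecdf_y, xout = knots, ties = "ordered", rule = 2)$y
  sf <- stats::splinefun(knots, ky, method = "hyman")
  unfolded <- n * sf(ev)
  s <- diff(unfolded)
  s <- s[is.finite(s) & s >= 0]
  if (length(s) < 10) return(NULL)
  s / mean(s)
}

# chi-square distances of an observed NNSD to Poisson and GOE laws
nnsd_distances <- function(s, n_bins = 20L, s_max = 3) {
  breaks <- seq(0, s_max, length.out = n_bins + 1)
  obs <- hist(pmin(s, s_max - 1e-12), breaks = breaks, plot = FALSE)$counts
  obs <- obs / sum(obs)
  cdf_pois <- function(x) 1 - exp(-x)
  cdf_goe <- function(x) 1 - exp(-pi * x^2 / 4)
  e_pois <- diff(cdf_pois(breaks)); e_pois <- e_pois / sum(e_pois)
  e_goe <- diff(cdf_goe(breaks)); e_goe <- e_goe / sum(e_goe)
  chi2 <- function(o, e) sum((o - e)^2 / pmax(e, 1e-12))
  c(poisson = chi2(obs, e_pois), goe = chi2(obs, e_goe))
}
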