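#' Derive a per-stage seed from a global seed
#'
#' All stochastic stages of the pipeline draw their own seed from one global
#' seed plus the stage name, so that adding or reordering stages never
#' silently shifts another stage's random stream.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. \code{"sparcc"}).
#' @return A single integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  bytes <- utf8ToInt(stage)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer((h + abs(as.numeric(seed)) * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run configuration container
#'
#' Bundles the global seed and the tunables of every pipeline stage with
#' their defaults, and round-trips losslessly through JSON.
#'
#' @param seed Integer global seed.
#' @param ... Named overrides of the defaults (see source for the full list).
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    rarefy_depth = 40000L, rarefy_reps = 10L,
    sparcc_n_iter = 20L, sparcc_n_excl_iter = 10L,
    sparcc_excl_threshold = 0.1, sparcc_pseudocount = 1e-6,
    sparcc_n_boot = 999L,
    network_p_cut = 0.001, network_min_occupancy = 9L,
    network_n_subsample_per_region = 13L,
    rmt_t_min = 0.2, rmt_t_max = 0.8, rmt_step = 0.05,
    modularity_resolution = 8L, pagerank_damping = 0.85,
    keystone_top_n = 5L, interplay_window = 100L,
    specificity_n_random = 500L, specificity_alpha = 0.05,
    assembly_n_null = 999L, nst_reps = 999L,
    rf_occupancy_min = 10L, rf_k_vars = 20L, rf_num_trees = 500L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path File path for the JSON serialization.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

## integer-safe assertion helpers used across readers
assert_unique <- function(x, what) {
  if (anyDuplicated(x)) stop("duplicate ", what, ": ",
                             paste(unique(x[duplicated(x)]), collapse = ", "))
  invisible(x)
}
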