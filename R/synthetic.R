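#' Generate a synthetic paddy/nonpaddy survey with known ground truth
#'
#' Emulates the statistical structure the downstream analyses assume, at the
#' target survey's design scale by default: 99 paddy and 79 nonpaddy samples across
#' four rice-growing regions, sequencing depths of at least 40,000 reads,
#' latent log-normal basis abundances carrying a planted correlation
#' structure organized into two mutually antagonistic modules,
#' region-separated environmental gradients with Gaussian taxon responses,
#' and (optionally) phylogenetic signal in the environmental optima and
#' habitat preference, evolved by Brownian motion along a simulated
#' pure-birth tree.
#'
#' The generative model is the one SparCC inverts: per sample, latent
#' log-abundances are multivariate normal with the planted correlation
#' matrix (repaired to the nearest positive semidefinite correlation matrix
#' by eigenvalue clipping; the recorded truth is post-repair), environmental
#' and habitat terms shift the log scale, fractions are the exponentials
#' renormalized, and counts are multinomial at a depth drawn uniformly from
#' \code{depth_range}.
#'
#' @param n_paddy,n_nonpaddy Samples per soil type, split as evenly as
#'   possible across \code{regions}.
#' @param n_otus Number of OTUs.
#' @param module_sizes Integer vector (length 2) of planted module sizes.
#' @param within_module_rho Planted correlation inside each module.
#' @param between_module_rho Planted (negative) correlation across the two
#'   modules.
#' @param env_gradient_strength Multiplier on every environmental and
#'   habitat effect; 0 removes all environment/region/soil signal.
#' @param depth_range Length-2 integer vector of sequencing depths.
#' @param phylo_signal Brownian variance of trait evolution; 0 draws optima
#'   independently of the tree.
#' @param latent_sd Standard deviation of the idiosyncratic (per sample,
#'   per OTU) latent log-abundance fluctuations around the planted
#'   correlation structure. 1 reproduces typical overdispersed community
#'   data; small values give communities dominated by their deterministic
#'   (environmental) component, useful when an experiment needs the
#'   environmental filter to be the leading source of variation.
#' @param regions Region names (study regions by default).
#' @param seed Integer seed.
#' @return List with \code{table} (\code{otu_table}), \code{metadata}
#'   (\code{sample_metadata}), \code{tree} (unit-height \code{phylo}) and
#'   \code{truth} (planted basis correlation, module assignment,
#'   environmental effects, habitat preferences, design).
#' @export
generate_community <- function(n_paddy = 99L, n_nonpaddy = 79L,
                               n_otus = 150L, module_sizes = c(30L, 30L),
                               within_module_rho = 0.7,
                               between_module_rho = -0.4,
                               env_gradient_strength = 1,
                               depth_range = c(40000L, 100000L),
                               phylo_signal = 0.5, latent_sd = 1,
                               regions = c("SanjiangPlain", "LianghuPlain",
                                           "TaihuPlain", "HaniTerrace"),
                               seed = 1L) {
  stopifnot(length(module_sizes) == 2, sum(module_sizes) <= n_otus,
            abs(within_module_rho) < 1, abs(between_module_rho) < 1,
            length(depth_range) == 2, depth_range[1] <= depth_range[2])
  set.seed(derive_seed(seed, "generate_community"))
  n <- n_paddy + n_nonpaddy
  otu_ids <- sprintf("OTU%03d", seq_len(n_otus))

  ## design: soil types split across regions as evenly as possible
  reg <- c(rep(regions, length.out = n_paddy),
           rep(regions, length.out = n_nonpaddy))
  soil <- rep(c("paddy", "nonpaddy"), c(n_paddy, n_nonpaddy))
  sample_ids <- sprintf("%s_%s_%03d", ifelse(soil == "paddy", "P", "N"),
                        abbreviate(reg, 3), seq_len(n))

  ## planted correlation target, PSD-repaired
  module <- rep("background", n_otus)
  module[seq_len(module_sizes[1])] <- "M1"
  module[module_sizes[1] + seq_len(module_sizes[2])] <- "M2"
  C <- diag(n_otus)
  for (lab in c("M1", "M2")) {
    idx <- which(module == lab)
    C[idx, idx] <- within_module_rho
  }
  C[module == "M1", module == "M2"] <- between_module_rho
  C[module == "M2", module == "M1"] <- between_module_rho
  diag(C) <- 1
  C <- psd_repair_correlation(C)

  ## tree and (possibly phylogenetically conserved) traits
  tree <- ape::rphylo(n_otus, birth = 1, death = 0)
  tree$tip.label <- otu_ids
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_otus)]
  tree$edge.length <- tree$edge.length / max(depths)

  ## environmental gradients: region means spaced 2 within-region SDs apart
  env_vars <- c("pH", "moisture", "total_C",
                "latitude", "elevation", "MAT", "MAP")
  n_reg <- length(regions)
  region_means <- sapply(env_vars, function(v)
    sample(2 * (seq_len(n_reg) - (n_reg + 1) / 2)))   # spacing 2, sd 1
  rownames(region_means) <- regions
  env <- sapply(env_vars, function(v)
    region_means[reg, v] + stats::rnorm(n))
  # paddy management floods the soil: shift moisture in paddy samples
  env[, "moisture"] <- env[, "moisture"] + 2 * (soil == "paddy")
  rownames(env) <- sample_ids

  ## per-OTU responses: one driver variable each, Gaussian response curve
  driver <- env_vars[1 + (seq_len(n_otus) - 1) %% length(env_vars)]
  if (phylo_signal > 0) {
    raw_opt <- sapply(env_vars, function(v)
      ape::rTraitCont(tree, model = "BM", sigma = sqrt(phylo_signal)))
    raw_opt <- scale(raw_opt)
    optimum <- 3 * raw_opt[cbind(seq_len(n_otus), match(driver, env_vars))]
    hab_raw <- as.numeric(scale(ape::rTraitCont(
      tree, model = "BM", sigma = sqrt(phylo_signal))))
  } else {
    optimum <- stats::runif(n_otus, -4, 4)
    hab_raw <- stats::rnorm(n_otus)
  }
  strength <- stats::runif(n_otus, 0.5, 1.5)
  habitat_pref <- hab_raw            # >0 favoured in paddy, <0 in nonpaddy

  ## latent log-abundances
  mu <- stats::rnorm(n_otus, 0, 1.5)
  z <- latent_sd * matrix(stats::rnorm(n * n_otus), n, n_otus) %*% chol(C)
  env_term <- env_gradient_strength * (
    t(strength * exp(-0.5 * (t(env[, driver]) - optimum)^2)) +
      outer(soil == "paddy", habitat_pref))
  loglam <- sweep(z, 2, mu, "+") + env_term
  frac <- exp(loglam - apply(loglam, 1, max))
  frac <- frac / rowSums(frac)

  depth <- sample(seq(depth_range[1], depth_range[2]), n, replace = TRUE)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, depth[i], frac[i, ])[, 1],
                     integer(n_otus)))
  lineage <- paste0("k__Bacteria;p__Phylum", 1 + (seq_len(n_otus) - 1) %% 8,
                    ";c__;o__;f__;g__;s__")
  table <- otu_table(counts, sample_ids, otu_ids, taxonomy = lineage)

  metadata <- sample_metadata(data.frame(
    sample_id = sample_ids, soil_type = soil, region = reg,
    as.data.frame(env), check.names = FALSE))

  truth <- list(
    basis_correlation = `dimnames<-`(C, list(otu_ids, otu_ids)),
    latent_log_abundance = `dimnames<-`(loglam, list(sample_ids, otu_ids)),
    module_assignment = stats::setNames(module, otu_ids),
    env_effects = data.frame(otu = otu_ids, driver = driver,
                             optimum = optimum, strength = strength,
                             habitat_pref = habitat_pref),
    phylo_signal = phylo_signal,
    env_gradient_strength = env_gradient_strength,
    region_means = region_means,
    design = data.frame(sample_id = sample_ids, soil_type = soil,
                        region = reg, depth = depth))
  list(table = table, metadata = metadata, tree = tree, truth = truth)
}

#' Repair a symmetric matrix to the nearest positive semidefinite
#' correlation matrix by eigenvalue clipping
#'
#' @param C Symmetric matrix with unit diagonal.
#' @param eps Floor for eigenvalues.
#' @return PSD correlation matrix (unit diagonal restored by rescaling).
#' @export
psd_repair_correlation <- function(C, eps = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (all(e$values >= 0)) return(C)
  if (mean(e$values < -1e-6) > 0.5)
    stop("correlation target too far from positive semidefinite to repair")
  v <- pmax(e$values, eps)
  S <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(S))
  S / outer(d, d)
}

#' Generate a structureless null community
#'
#' Independent log-normal basis abundances, no planted correlation and no
#' environmental effect; metadata assigns two arbitrary balanced groups and
#' round-robin regions, for type-I-error suites.
#'
#' @param n_samples,n_otus,depth Dimensions of the table.
#' @param seed Integer seed.
#' @return List with \code{table} and \code{metadata} (with a
#'   \code{group} column holding the arbitrary balanced labels).
#' @export
generate_null_community <- function(n_samples = 200L, n_otus = 60L,
                                    depth = 40000L, seed = 1L) {
  set.seed(derive_seed(seed, "generate_null_community"))
  mu <- stats::rnorm(n_otus, 0, 1.5)
  loglam <- sweep(matrix(stats::rnorm(n_samples * n_otus), n_samples), 2,
                  mu, "+")
  frac <- exp(loglam - apply(loglam, 1, max))
  frac <- frac / rowSums(frac)
  counts <- t(vapply(seq_len(n_samples),
                     function(i) stats::rmultinom(1, depth, frac[i, ])[, 1],
                     integer(n_otus)))
  ids <- sprintf("S%03d", seq_len(n_samples))
  table <- otu_table(counts, ids, sprintf("OTU%03d", seq_len(n_otus)))
  soil <- rep(c("paddy", "nonpaddy"), length.out = n_samples)
  metadata <- sample_metadata(data.frame(
    sample_id = ids, soil_type = soil,
    region = rep(c("SanjiangPlain", "LianghuPlain", "TaihuPlain",
                   "HaniTerrace"), length.out = n_samples)))
  metadata$group <- rep(c("A", "B"), length.out = n_samples)
  list(table = table, metadata = metadata)
}
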