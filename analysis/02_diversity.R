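#!/usr/bin/env Rscript
# Stage 2: alpha diversity (with rarefaction replicates), beta diversity
# across count-based, phylogenetic and interaction-adjusted metrics, PCoA,
# PERMANOVA by soil type and region, per-variable adonis R2 ranking,
# variation partitioning over edaphic/geographic/climatic groups, core
# microbiota and paddy/nonpaddy enrichment ratios.

library(paddynet)

data_dir <- "results/data"
out <- "results/diversity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- read_run_config(file.path(data_dir, "config.json"))$seed

tab <- read_otu_table(file.path(data_dir, "otu_table.tsv"))
md <- read_metadata(file.path(data_dir, "metadata.tsv"))
tree <- read_newick(file.path(data_dir, "tree.nwk"))

## alpha diversity, averaged over rarefaction replicates
depth <- min(rowSums(tab))
reps <- rarefy_table(tab, depth, reps = 10, seed = derive_seed(seed, "rare"))
alphas <- lapply(reps, alpha_diversity, tree = tree)
alpha_mean <- Reduce(`+`, lapply(alphas, function(a) as.matrix(a[, -1]))) /
  length(alphas)
alpha_df <- data.frame(sample_id = alphas[[1]]$sample_id, alpha_mean)
write.table(alpha_df, file.path(out, "alpha_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("alpha: mean observed OTUs %.1f, Shannon %.2f at depth %d",
                mean(alpha_df$observed_otus), mean(alpha_df$shannon), depth))

## beta diversity across the metric family
assoc <- taxa_association_matrix(tab)
dists <- list(
  bray = beta_distance(tab, "bray"),
  chao_jaccard = beta_distance(tab, "chao_jaccard"),
  unifrac_u = beta_distance(tab, "unifrac_u", tree = tree),
  unifrac_w = beta_distance(tab, "unifrac_w", tree = tree),
  tina_u = beta_distance(tab, "tina_u", assoc = assoc),
  tina_w = beta_distance(tab, "tina_w", assoc = assoc))
for (nm in names(dists))
  write.table(as.matrix(dists[[nm]]),
              file.path(out, paste0("dist_", nm, ".tsv")),
              sep = "\t", quote = FALSE)

## ordination + PERMANOVA per metric
perm <- lapply(names(dists), function(nm) {
  pc <- pcoa_ordination(dists[[nm]], 2)
  if (nm == "bray")
    write.table(data.frame(sample_id = rownames(pc$coordinates),
                           pc$coordinates),
                file.path(out, "pcoa_bray.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  soil <- permanova(dists[[nm]], md$soil_type, n_perm = 999,
                    seed = derive_seed(seed, paste0("perm_s_", nm)))
  reg <- permanova(dists[[nm]], md$region, n_perm = 999,
                   seed = derive_seed(seed, paste0("perm_r_", nm)))
  message(sprintf(
    "%-12s axis1+2 %.1f%%  soil R2=%.3f (p=%.3g)  region R2=%.3f (p=%.3g)",
    nm, 100 * sum(pc$fraction_explained), soil$R2, soil$p, reg$R2, reg$p))
  list(metric = nm, axis_fraction = pc$fraction_explained,
       soil = soil, region = reg)
})
jsonlite::write_json(perm, file.path(out, "permanova.json"),
                     auto_unbox = TRUE, digits = NA)

## which environmental variables structure the community most
vars <- names(attr(md, "groups"))
rk <- adonis_r2_ranking(dists$bray, md, vars, n_perm = 999,
                        seed = derive_seed(seed, "adonis_rank"))
write.table(rk, file.path(out, "adonis_ranking.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("top adonis R2 variables: ",
        paste(head(rk$variable, 3), collapse = ", "))

## unique vs shared explanatory power of the three variable groups
vp <- variation_partition(dists$bray, md)
jsonlite::write_json(vp[c("unique", "pairwise_shared", "threeway_shared",
                          "residual", "total_explained")],
                     file.path(out, "varpart.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("varpart unique R2: edaphic %.3f geographic %.3f climatic %.3f",
                vp$unique[1], vp$unique[2], vp$unique[3]))

## core microbiota of paddy soils per region
paddy_ids <- md$sample_id[md$soil_type == "paddy"]
tabs <- lapply(split(paddy_ids, droplevels(md[paddy_ids, "region"])),
               function(ids) otu_table(unclass(tab)[ids, , drop = FALSE]))
core <- core_microbiota(tabs, occupancy = 1)
jsonlite::write_json(list(union_size = core$union_size,
                          segments = core$segments),
                     file.path(out, "core_venn.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("core microbiota union %d OTUs; 4-region core %d",
                core$union_size,
                sum(core$segments$count[
                  core$segments$segment ==
                    paste(names(tabs), collapse = "&")])))

## paddy vs nonpaddy enrichment
er <- enrichment_ratio(tab, md)
write.table(er, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d/%d OTUs differentially abundant at FDR 0.05",
                sum(er$padj < 0.05), nrow(er)))
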