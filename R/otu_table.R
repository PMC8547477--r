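#' Construct and validate an OTU count table
#'
#' The canonical orientation throughout the package is samples as rows and
#' OTUs as columns, the "community matrix" convention of \pkg{vegan}.
#'
#' @param counts Non-negative integer matrix, samples x OTUs.
#' @param sample_ids,otu_ids Optional id vectors; default to dimnames.
#' @param taxonomy Optional per-OTU lineage string (semicolon-separated
#'   ranks); may be \code{NULL}.
#' @return An integer matrix of class \code{"otu_table"} with a
#'   \code{"taxonomy"} attribute.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts), taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("id lists inconsistent with matrix dimensions")
  assert_unique(sample_ids, "sample ids")
  assert_unique(otu_ids, "OTU ids")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and complete")
  if (any(counts < 0)) stop("negative counts")
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("samples with zero total counts: ",
         paste(sample_ids[rs == 0], collapse = ", "))
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != ncol(counts))
      stop("taxonomy length must equal number of OTUs")
    names(taxonomy) <- otu_ids
  }
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(counts, taxonomy = taxonomy, class = c("otu_table", "matrix"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs (total %.3g reads)\n",
              nrow(x), ncol(x), sum(as.numeric(x))))
  invisible(x)
}

#' Per-sample relative abundances
#'
#' @param table An \code{otu_table} (or plain counts matrix, samples x OTUs).
#' @return Numeric matrix of row-normalized fractions.
#' @export
relative_abundance <- function(table) {
  m <- unclass(table)
  attr(m, "taxonomy") <- NULL
  storage.mode(m) <- "double"
  sweep(m, 1, rowSums(m), "/")
}

#' Read an OTU table from a classic tab-separated file
#'
#' Accepts both orientations; \code{orientation} declares whether rows of the
#' file are OTUs (the classic BIOM-style TSV, possibly with a leading
#' \code{#OTU ID} header and trailing taxonomy column) or samples.
#'
#' @param path File path.
#' @param orientation \code{"otus_as_rows"} (default, BIOM-style) or
#'   \code{"samples_as_rows"}.
#' @return An \code{otu_table}, samples x OTUs.
#' @export
read_otu_table <- function(path, orientation = c("otus_as_rows",
                                                 "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^# ", lines)]          # comment lines, not header
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  taxcol <- grepl("^taxonomy$", names(df), ignore.case = TRUE)
  if (any(taxcol)) {
    taxonomy <- as.character(df[[which(taxcol)[1]]])
    df <- df[, !taxcol, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- ids
  if (orientation == "otus_as_rows") {
    m <- t(m)
    # taxonomy column followed the OTU rows
    return(otu_table(m, taxonomy = taxonomy))
  }
  otu_table(m)
}

#' Write an OTU table as a BIOM-style classic TSV (OTUs as rows)
#'
#' @param table An \code{otu_table}.
#' @param path Output path.
#' @export
write_otu_table <- function(table, path) {
  m <- t(unclass(table))
  df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE)
  tax <- attr(table, "taxonomy")
  if (!is.null(tax)) df$taxonomy <- tax
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata rows carry the sample id, the \code{soil_type} and \code{region}
#' factors, and numeric environmental variables assigned to exactly one of
#' the groups edaphic / geographic / climatic via \code{group_map}.
#'
#' @param path TSV path with a \code{sample_id} column.
#' @param group_map Named character vector mapping each environmental
#'   variable name to \code{"edaphic"}, \code{"geographic"} or
#'   \code{"climatic"}.
#' @return A \code{data.frame} of class \code{"sample_metadata"} with a
#'   \code{"groups"} attribute holding the map.
#' @export
read_metadata <- function(path, group_map = default_group_map()) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df, group_map)
}

#' @rdname read_metadata
#' @param df Data frame with columns \code{sample_id}, \code{soil_type},
#'   \code{region} and the mapped environmental variables.
#' @export
sample_metadata <- function(df, group_map = default_group_map()) {
  need <- c("sample_id", "soil_type", "region")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  assert_unique(df$sample_id, "sample ids")
  ok_soil <- c("paddy", "nonpaddy")
  if (!all(df$soil_type %in% ok_soil))
    stop("soil_type must be one of ", paste(ok_soil, collapse = "/"),
         "; got: ", paste(setdiff(df$soil_type, ok_soil), collapse = ", "))
  env_vars <- setdiff(names(df), need)
  unknown <- setdiff(env_vars, names(group_map))
  if (length(unknown))
    stop("variables not declared in group_map: ",
         paste(unknown, collapse = ", "))
  for (v in env_vars) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    if (anyNA(x))
      stop("non-numeric value for '", v, "' in sample ",
           df$sample_id[which(is.na(x))[1]])
    df[[v]] <- x
  }
  df$soil_type <- factor(df$soil_type, levels = ok_soil)
  df$region <- factor(df$region)
  rownames(df) <- df$sample_id
  structure(df, groups = group_map[env_vars],
            class = c("sample_metadata", "data.frame"))
}

#' Default variable-to-group map for the survey's environmental variables
#' @export
default_group_map <- function() {
  c(moisture = "edaphic", pH = "edaphic", conductivity = "edaphic",
    total_C = "edaphic", total_N = "edaphic", total_P = "edaphic",
    C_N = "edaphic", C_P = "edaphic", N_P = "edaphic",
    available_P = "edaphic", clay = "edaphic", silt = "edaphic",
    sand = "edaphic",
    latitude = "geographic", longitude = "geographic",
    elevation = "geographic",
    MAT = "climatic", MAP = "climatic", MMT = "climatic", MMP = "climatic",
    soil_temperature = "climatic", air_temperature = "climatic")
}

#' Environmental variables of a metadata table, optionally by group
#'
#' @param metadata A \code{sample_metadata}.
#' @param group Optional group name to subset to.
#' @return Numeric data frame of environmental variables.
#' @export
env_variables <- function(metadata, group = NULL) {
  gm <- attr(metadata, "groups")
  vars <- names(gm)
  if (!is.null(group)) vars <- vars[gm == group]
  as.data.frame(metadata)[, vars, drop = FALSE]
}

#' Read a rooted Newick tree
#'
#' @param path Newick file path.
#' @return An \code{ape} \code{phylo} object; errors if unrooted.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (!ape::is.rooted(tr)) stop("tree in ", path, " is not rooted")
  assert_unique(tr$tip.label, "tip labels")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths")
  tr
}

#' Rarefy an OTU table by subsampling reads without replacement
#'
#' Each replicate draws \code{depth} reads per sample from the observed reads
#' (multivariate hypergeometric), the read-subsampling model of rarefaction.
#' Samples shallower than \code{depth} are dropped with a warning.
#'
#' @param table An \code{otu_table}.
#' @param depth Target reads per sample.
#' @param reps Number of replicate tables.
#' @param seed Integer seed.
#' @return A list of \code{reps} rarefied \code{otu_table}s.
#' @export
rarefy_table <- function(table, depth, reps = 10L, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  rs <- rowSums(table)
  keep <- rs >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) shallower than depth ", depth,
            " dropped: ", paste(rownames(table)[!keep], collapse = ", "))
    table <- otu_table(unclass(table)[keep, , drop = FALSE],
                       taxonomy = attr(table, "taxonomy"))
  }
  if (nrow(table) == 0) stop("no samples at or above depth ", depth)
  set.seed(seed)
  lapply(seq_len(reps), function(r) {
    m <- apply(unclass(table), 1, function(x) {
      reads <- rep.int(seq_along(x), x)
      tabulate(sample(reads, depth, replace = FALSE), nbins = length(x))
    })
    otu_table(t(m), sample_ids = rownames(table), otu_ids = colnames(table),
              taxonomy = attr(table, "taxonomy"))
  })
}
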