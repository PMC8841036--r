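# Domain types and tabular I/O.
#
# The universal substrate is the count table: a samples x ASVs matrix of
# non-negative integer read counts with unique row (sample) and column (ASV)
# names.  Samples-as-rows follows community-ecology convention (vegan and
# friends) and matches every per-sample operation downstream.  All files are
# plain TSV with a header row; the first column holds identifiers.

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

SOIL_NUTRIENTS <- c("TC", "TN", "DOC", "DON", "NO3", "NH4")
SOIL_VARIABLES <- c(SOIL_NUTRIENTS, "moisture", "pH", "clay", "silt", "sand")

#' Validate a count table
#'
#' Checks the count-table contract: a numeric matrix of non-negative,
#' integer-valued counts with unique non-empty sample (row) and ASV (column)
#' names and at least one sample and one ASV.
#'
#' @param counts A samples x ASVs matrix.
#' @return The validated matrix, invisibly coerced to storage mode double
#'   with integral values.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_("count table must be a numeric matrix (samples x ASVs)")
  }
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop_("count table needs at least 1 sample and 1 ASV")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_("count table must have sample rownames and ASV colnames")
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop_("duplicate sample identifier(s): %s",
                         paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stop_("duplicate ASV identifier(s): %s",
                         paste(unique(dup), collapse = ", "))
  if (anyNA(counts)) stop_("count table contains missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("non-integer or negative count at sample '%s', ASV '%s' (value %s)",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
          format(counts[bad[1, , drop = FALSE]]))
  }
  counts
}

#' Validate sample metadata
#'
#' Metadata carries the design factors: `sample_id`, `plot`, `layer`
#' (one of S, M, D for surface, middle, deep) and `time` (ordered sampling
#' occasions).
#'
#' @param metadata A data frame with columns sample_id, plot, layer, time.
#' @param counts Optional count table; if given, every sample in the table
#'   must have exactly one metadata row.
#' @return The validated data frame with layer as a factor with levels S, M, D.
#' @export
validate_metadata <- function(metadata, counts = NULL) {
  need <- c("sample_id", "plot", "layer", "time")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop_("metadata missing column(s): %s",
                          paste(miss, collapse = ", "))
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup)) stop_("duplicate metadata sample_id(s): %s",
                         paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(as.character(metadata$layer)), c("S", "M", "D"))
  if (length(bad)) stop_("layer values outside {S, M, D}: %s",
                         paste(bad, collapse = ", "))
  metadata$layer <- factor(as.character(metadata$layer), levels = c("S", "M", "D"))
  metadata$plot <- factor(metadata$plot)
  metadata$time <- factor(metadata$time)
  if (!is.null(counts)) {
    missing_samples <- setdiff(rownames(counts), metadata$sample_id)
    if (length(missing_samples)) {
      stop_("sample(s) in count table missing from metadata: %s",
            paste(missing_samples, collapse = ", "))
    }
  }
  metadata
}

#' Validate a soil physicochemical table
#'
#' @param soil Data frame with sample_id plus the 11 soil variables
#'   (TC, TN, DOC, DON, NO3, NH4, moisture, pH, clay, silt, sand).
#' @param texture_tol Allowed deviation of clay + silt + sand from 100.
#' @return The validated data frame.
#' @export
validate_soil <- function(soil, texture_tol = 1) {
  if (!"sample_id" %in% names(soil)) stop_("soil table missing sample_id")
  present <- intersect(SOIL_VARIABLES, names(soil))
  conc <- intersect(SOIL_NUTRIENTS, names(soil))
  for (v in conc) {
    if (any(soil[[v]] < 0, na.rm = TRUE)) stop_("negative concentration in %s", v)
  }
  if (all(c("clay", "silt", "sand") %in% present)) {
    tot <- soil$clay + soil$silt + soil$sand
    off <- which(abs(tot - 100) > texture_tol)
    if (length(off)) {
      stop_("clay + silt + sand is %.2f (not 100 +/- %g) for sample %s",
            tot[off[1]], texture_tol, soil$sample_id[off[1]])
    }
  }
  soil
}

read_id_table <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a count table from TSV
#'
#' First column is the sample identifier; remaining columns are ASVs.
#'
#' @param path TSV file path.
#' @return A validated samples x ASVs count matrix.
#' @export
read_count_table <- function(path) {
  df <- read_id_table(path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    x <- vals[[j]]
    if (is.character(x)) {
      xn <- suppressWarnings(as.numeric(x))
      if (anyNA(xn) && !anyNA(x)) {
        i <- which(is.na(xn))[1]
        stop_("non-numeric count '%s' at row %d, column '%s'",
              x[i], i, names(vals)[j])
      }
      vals[[j]] <- xn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  bad <- which(m != round(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("non-integer count '%s' at row %d ('%s'), column '%s'",
          format(m[bad[1, , drop = FALSE]]), bad[1, 1],
          ids[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  validate_count_table(m)
}

#' Write a count table to TSV
#' @param counts Count matrix.
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table (asv_id, lineage) from TSV
#'
#' Lineages are semicolon-delimited ordered ranks domain -> genus; empty
#' ranks are allowed and reported as unclassified.  ASVs absent from the
#' table are treated as fully unclassified.
#'
#' @param path TSV file path.
#' @return Data frame with columns asv_id, lineage.
#' @export
read_taxonomy <- function(path) {
  df <- read_id_table(path)
  names(df)[1:2] <- c("asv_id", "lineage")
  dup <- df$asv_id[duplicated(df$asv_id)]
  if (length(dup)) stop_("duplicate taxonomy asv_id(s): %s",
                         paste(unique(dup), collapse = ", "))
  df
}

#' Split lineages into a rank matrix
#'
#' @param taxonomy Taxonomy data frame (asv_id, lineage).
#' @return Character matrix, one row per ASV, columns
#'   domain/phylum/class/order/family/genus; empty or missing ranks become
#'   "unclassified".
#' @export
lineage_ranks <- function(taxonomy) {
  parts <- strsplit(as.character(taxonomy$lineage), ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-z]__", "", p)          # tolerate silva-style rank prefixes
    out <- rep("unclassified", length(TAXONOMIC_RANKS))
    n <- min(length(p), length(out))
    keep <- nzchar(p[seq_len(n)])
    out[seq_len(n)][keep] <- p[seq_len(n)][keep]
    out
  }, character(length(TAXONOMIC_RANKS))))
  rownames(m) <- taxonomy$asv_id
  colnames(m) <- TAXONOMIC_RANKS
  m
}

#' Taxon name of each ASV at one rank
#'
#' @param taxonomy Taxonomy data frame.
#' @param asv_ids ASV identifiers to look up (defaults to the table's own).
#' @param rank One of domain, phylum, class, order, family, genus.
#' @return Named character vector; ASVs without a lineage are "unclassified".
#' @export
taxon_at_rank <- function(taxonomy, asv_ids = taxonomy$asv_id, rank = "phylum") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  ranks <- lineage_ranks(taxonomy)
  out <- rep("unclassified", length(asv_ids))
  names(out) <- asv_ids
  hit <- intersect(asv_ids, rownames(ranks))
  out[hit] <- ranks[hit, rank]
  out
}

#' Per-rank unclassified proportions
#'
#' For each taxonomic rank, the fraction of ASVs whose lineage is
#' unclassified at that rank (per-rank tallies are this package's own
#' convention).
#'
#' @param counts Count matrix (defines the ASV universe).
#' @param taxonomy Taxonomy data frame.
#' @return Named numeric vector over ranks, each in \[0, 1\].
#' @export
unclassified_proportions <- function(counts, taxonomy) {
  tax <- vapply(TAXONOMIC_RANKS, function(r)
    taxon_at_rank(taxonomy, colnames(counts), r), character(ncol(counts)))
  colMeans(tax == "unclassified")
}

#' Load a full dataset bundle
#'
#' Reads and cross-validates counts, metadata, and (optionally) taxonomy and
#' soil tables.  Every sample in the count table must appear in the metadata;
#' ASVs missing from the taxonomy trigger a warning and are treated as fully
#' unclassified downstream.  Sample and ASV order is preserved from file.
#'
#' @param count_path,metadata_path,taxonomy_path,soil_path TSV file paths;
#'   taxonomy and soil are optional (NULL).
#' @return List with elements counts, metadata, taxonomy, soil.
#' @export
load_dataset <- function(count_path, metadata_path,
                         taxonomy_path = NULL, soil_path = NULL) {
  counts <- read_count_table(count_path)
  metadata <- validate_metadata(read_id_table(metadata_path), counts)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    taxonomy <- read_taxonomy(taxonomy_path)
    miss <- setdiff(colnames(counts), taxonomy$asv_id)
    if (length(miss)) {
      warn_("%d ASV(s) missing from taxonomy (treated as unclassified), e.g. %s",
            length(miss), miss[1])
    }
  }
  soil <- NULL
  if (!is.null(soil_path)) {
    soil <- validate_soil(read_id_table(soil_path))
    miss <- setdiff(rownames(counts), soil$sample_id)
    if (length(miss)) {
      stop_("sample(s) missing from soil table: %s", paste(miss, collapse = ", "))
    }
  }
  list(counts = counts, metadata = metadata, taxonomy = taxonomy, soil = soil)
}

#' Relative abundance
#'
#' `per_sample`: each sample's counts divided by its total (rows sum to 1).
#' `dataset_total`: one fraction per ASV, its total reads over the grand
#' total (sums to 1 over ASVs) — the basis on which rare/abundant taxa are
#' defined.
#'
#' @param counts Count matrix.
#' @param basis "per_sample" or "dataset_total".
#' @return A matrix (per_sample) or named vector (dataset_total) of fractions.
#' @export
relative_abundance <- function(counts, basis = c("per_sample", "dataset_total")) {
  basis <- match.arg(basis)
  validate_count_table(counts)
  if (basis == "per_sample") {
    tot <- rowSums(counts)
    zero <- rownames(counts)[tot == 0]
    if (length(zero)) stop_("all-zero sample(s): %s", paste(zero, collapse = ", "))
    sweep(counts, 1, tot, "/")
  } else {
    grand <- sum(counts)
    if (grand == 0) stop_("count table has no reads")
    colSums(counts) / grand
  }
}
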