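# Rarefaction, rare/abundant partitioning, vertical rare-proportion
# statistics and layer-enrichment (ternary) classification.

#' Rarefy a count table to even depth
#'
#' Each retained sample is subsampled without replacement (a multivariate
#' hypergeometric draw, via [vegan::rrarefy()]) to exactly `depth` reads.
#' Samples with fewer total reads than `depth` are dropped with a warning
#' naming them.  Deterministic per seed.
#'
#' @param counts Count matrix.
#' @param depth Target reads per sample (>= 1).
#' @param seed RNG seed.
#' @return Rarefied count matrix whose rows all sum to `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1) {
  validate_count_table(counts)
  if (depth < 1) stop_("rarefaction depth must be >= 1")
  tot <- rowSums(counts)
  drop <- rownames(counts)[tot < depth]
  if (length(drop) == nrow(counts)) {
    stop_("all samples have fewer than %d reads", depth)
  }
  if (length(drop)) {
    warn_("dropping %d sample(s) below depth %d: %s",
          length(drop), depth, paste(drop, collapse = ", "))
  }
  keep <- counts[tot >= depth, , drop = FALSE]
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(keep, depth),
    # vegan warns whenever the smallest nonzero count exceeds 1; that is
    # routine for aggregated ASV tables and not a usage error here
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(out) <- "double"
  validate_count_table(out)
}

#' Classify ASVs as rare / intermediate / abundant
#'
#' Classes are defined on dataset-total relative abundance: rare strictly
#' below `rare_threshold` (default 0.01%), abundant strictly above
#' `abundant_threshold` (default 0.1%), intermediate otherwise.  The
#' partition is exhaustive and exclusive.
#'
#' @param counts Count matrix.
#' @param rare_threshold,abundant_threshold Fractions,
#'   0 < rare < abundant < 1.
#' @return Data frame: asv_id, dataset_fraction, class.
#' @export
classify_abundance <- function(counts, rare_threshold = 1e-4,
                               abundant_threshold = 1e-3) {
  if (!(rare_threshold > 0 && rare_threshold < abundant_threshold &&
        abundant_threshold < 1)) {
    stop_("need 0 < rare_threshold < abundant_threshold < 1")
  }
  frac <- relative_abundance(counts, "dataset_total")
  cls <- ifelse(frac < rare_threshold, "rare",
                ifelse(frac > abundant_threshold, "abundant", "intermediate"))
  data.frame(asv_id = names(frac), dataset_fraction = unname(frac),
             class = unname(cls), stringsAsFactors = FALSE)
}

#' Per-sample rare-taxon proportions
#'
#' For each sample: the proportion of its observed richness contributed by
#' rare-class ASVs, and the proportion of its reads in rare-class ASVs,
#' with the sample's layer/time labels attached.
#'
#' @param counts Count matrix (the one the classes were computed on).
#' @param classes Output of [classify_abundance()].
#' @param metadata Sample metadata.
#' @return Data frame: sample_id, layer, time, rare_richness_prop,
#'   rare_reads_prop.
#' @export
rare_proportions <- function(counts, classes, metadata) {
  if (!setequal(classes$asv_id, colnames(counts))) {
    stop_("classes were not computed on this count table")
  }
  metadata <- validate_metadata(metadata, counts)
  rare <- classes$asv_id[classes$class == "rare"]
  tot <- rowSums(counts)
  zero <- rownames(counts)[tot == 0]
  if (length(zero)) stop_("sample(s) with zero reads: %s",
                          paste(zero, collapse = ", "))
  present <- counts > 0
  rr <- rowSums(present[, colnames(counts) %in% rare, drop = FALSE]) /
    rowSums(present)
  ra <- rowSums(counts[, colnames(counts) %in% rare, drop = FALSE]) / tot
  md <- metadata[match(rownames(counts), metadata$sample_id), ]
  data.frame(sample_id = rownames(counts),
             layer = md$layer, time = md$time,
             rare_richness_prop = unname(rr),
             rare_reads_prop = unname(ra),
             stringsAsFactors = FALSE)
}

#' Layer-enrichment classification of ASVs
#'
#' Per ASV, a Kruskal-Wallis test of per-sample relative abundance across
#' the three soil layers, BH-FDR corrected across ASVs.  ASVs with
#' q < `q_cutoff` are assigned the layer with the highest mean relative
#' abundance (S, M or D); the rest are U (unclassified/even).  Mean relative
#' abundances per layer, normalized to sum 1, are returned as ternary-plot
#' coordinates.  `times` optionally restricts the test to a subset of
#' sampling occasions.
#'
#' @param counts Count matrix.
#' @param metadata Sample metadata.
#' @param q_cutoff BH-FDR significance cutoff (default 0.05).
#' @param times Optional character vector of time levels to keep.
#' @return Data frame: asv_id, class, statistic, p, q, and ternary
#'   coordinates S_mean, M_mean, D_mean.
#' @export
enrichment_classify <- function(counts, metadata, q_cutoff = 0.05,
                                times = NULL) {
  metadata <- validate_metadata(metadata, counts)
  md <- metadata[match(rownames(counts), metadata$sample_id), ]
  if (!is.null(times)) {
    keep <- md$time %in% times
    counts <- counts[keep, , drop = FALSE]
    md <- md[keep, , drop = FALSE]
  }
  layer <- droplevels(md$layer)
  n_per <- table(layer)
  if (length(n_per) < 3 || any(n_per < 2)) {
    stop_("each of the three layers needs >= 2 samples")
  }
  ra <- relative_abundance(counts, "per_sample")
  res <- apply(ra, 2, function(x) {
    if (length(unique(x)) == 1L) return(c(stat = NA_real_, p = 1))
    kt <- stats::kruskal.test(x, layer)
    c(stat = unname(kt$statistic), p = kt$p.value)
  })
  q <- stats::p.adjust(res["p", ], method = "BH")
  means <- vapply(levels(layer), function(l)
    colMeans(ra[layer == l, , drop = FALSE]), numeric(ncol(ra)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(colnames(ra), levels(layer)))
  tern <- means / pmax(rowSums(means), .Machine$double.eps)
  top <- colnames(means)[max.col(means, ties.method = "first")]
  cls <- ifelse(q < q_cutoff, top, "U")
  data.frame(asv_id = colnames(counts), class = cls,
             statistic = res["stat", ], p = res["p", ], q = unname(q),
             S_mean = tern[, "S"], M_mean = tern[, "M"], D_mean = tern[, "D"],
             row.names = NULL, stringsAsFactors = FALSE)
}
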