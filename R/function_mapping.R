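# Rule-based assignment of taxa to functional groups, in a deliberate
# miniature of the FAPROTAX idea: each rule maps an exact taxon name at a
# stated rank to a functional-group label.  A taxon may map to several
# groups and a group may have several rules; matching is case-insensitive.

#' Read a functional-rules table
#'
#' Two-column TSV: `pattern` ("rank:Name", e.g. "phylum:Desulfobacterota")
#' and `group`.
#'
#' @param path TSV file path.
#' @return Validated rules data frame (rank, name, group).
#' @export
read_function_rules <- function(path) {
  df <- read_id_table(path)
  names(df)[1:2] <- c("pattern", "group")
  function_rules(df)
}

#' Construct/validate functional rules
#'
#' @param rules Data frame with columns pattern ("rank:Name") and group.
#' @return Data frame with columns rank, name, group.
#' @export
function_rules <- function(rules) {
  if (nrow(rules) == 0) stop_("empty rules table")
  if (any(!nzchar(rules$pattern))) stop_("empty rule pattern")
  parts <- strsplit(as.character(rules$pattern), ":", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) stop_("malformed pattern '%s' (want rank:Name)",
                         rules$pattern[bad[1]])
  out <- data.frame(rank = vapply(parts, `[`, "", 1),
                    name = vapply(parts, `[`, "", 2),
                    group = as.character(rules$group),
                    stringsAsFactors = FALSE)
  badr <- setdiff(unique(out$rank), TAXONOMIC_RANKS)
  if (length(badr)) stop_("unknown rank(s) in rules: %s",
                          paste(badr, collapse = ", "))
  out
}

#' Map ASVs to functional groups
#'
#' An ASV contributes its counts to every group with a rule matching its
#' lineage at the rule's rank (exact, case-insensitive); no normalization
#' across groups.  Unassigned ASVs are tallied.
#'
#' @param counts Count matrix.
#' @param taxonomy Taxonomy data frame.
#' @param rules Rules from [function_rules()] / [read_function_rules()].
#' @return List: group_profile (samples x groups count matrix),
#'   assignments (asv_id, group), assigned_asv_fraction,
#'   assigned_read_fraction.
#' @export
map_functions <- function(counts, taxonomy, rules) {
  if (nrow(rules) == 0) stop_("empty rules table")
  asvs <- colnames(counts)
  assign_list <- list()
  for (r in unique(rules$rank)) {
    tax <- tolower(taxon_at_rank(taxonomy, asvs, r))
    sub <- rules[rules$rank == r, ]
    for (i in seq_len(nrow(sub))) {
      hit <- asvs[tax == tolower(sub$name[i])]
      if (length(hit)) {
        assign_list[[length(assign_list) + 1L]] <-
          data.frame(asv_id = hit, group = sub$group[i],
                     stringsAsFactors = FALSE)
      }
    }
  }
  assignments <- if (length(assign_list)) {
    unique(do.call(rbind, assign_list))
  } else data.frame(asv_id = character(0), group = character(0))
  groups <- sort(unique(rules$group))
  profile <- matrix(0, nrow(counts), length(groups),
                    dimnames = list(rownames(counts), groups))
  for (g in groups) {
    members <- assignments$asv_id[assignments$group == g]
    if (length(members)) {
      profile[, g] <- rowSums(counts[, members, drop = FALSE])
    }
  }
  list(group_profile = profile,
       assignments = assignments,
       assigned_asv_fraction = length(unique(assignments$asv_id)) / length(asvs),
       assigned_read_fraction =
         sum(counts[, unique(assignments$asv_id), drop = FALSE]) / sum(counts))
}

#' Per-taxon attribution of each functional group
#'
#' For each group, the percentage of its reads contributed by each taxon at
#' the chosen rank; percentages per group sum to 100.  Groups with zero
#' reads are flagged (NA percentage).
#'
#' @param counts Count matrix used in [map_functions()].
#' @param mapping Result of [map_functions()].
#' @param taxonomy Taxonomy data frame.
#' @param rank Attribution rank (default "phylum").
#' @return Data frame: group, taxon, reads, percent.
#' @export
function_attribution <- function(counts, mapping, taxonomy, rank = "phylum") {
  tax <- taxon_at_rank(taxonomy, colnames(counts), rank)
  asv_reads <- colSums(counts)
  out <- lapply(colnames(mapping$group_profile), function(g) {
    members <- mapping$assignments$asv_id[mapping$assignments$group == g]
    if (!length(members)) {
      return(data.frame(group = g, taxon = NA_character_, reads = 0,
                        percent = NA_real_, stringsAsFactors = FALSE))
    }
    reads <- tapply(asv_reads[members], tax[members], sum)
    total <- sum(reads)
    data.frame(group = g, taxon = names(reads), reads = as.numeric(reads),
               percent = if (total > 0) 100 * as.numeric(reads) / total
                         else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
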