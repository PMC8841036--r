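# Co-occurrence networks: abundance/occurrence filtering, Spearman
# correlation with BH-FDR, signed thresholded graph, topology metrics,
# greedy modularity modules, Zi-Pi node roles and keystone identification.

#' Filter a count table for network construction
#'
#' Retains ASVs whose relative abundance over the (optionally subset)
#' dataset is strictly above `abundance_threshold` AND that are present
#' (count > 0) in strictly more than `occurrence_threshold` of the samples.
#'
#' @param counts Count matrix.
#' @param abundance_threshold Dataset-relative-abundance cut (default 0.005,
#'   i.e. 0.5%).
#' @param occurrence_threshold Occupancy cut as a fraction of samples
#'   (default 0.5).
#' @param samples Optional character vector of sample ids to subset first
#'   (e.g. one soil layer's communities).
#' @return The filtered count matrix (subset samples x surviving ASVs).
#' @export
filter_for_network <- function(counts, abundance_threshold = 0.005,
                               occurrence_threshold = 0.5, samples = NULL) {
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(counts))
    if (length(miss)) stop_("unknown sample(s): %s", paste(miss, collapse = ", "))
    counts <- counts[samples, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop_("empty sample subset")
  frac <- colSums(counts) / sum(counts)
  occ <- colMeans(counts > 0)
  pass_a <- frac > abundance_threshold
  pass_o <- occ > occurrence_threshold
  keep <- pass_a & pass_o
  if (!any(keep)) {
    stop_("no ASVs survive filtering (%d pass abundance > %g, %d pass occurrence > %g)",
          sum(pass_a), abundance_threshold, sum(pass_o), occurrence_threshold)
  }
  counts[, keep, drop = FALSE]
}

#' Spearman correlation matrix between ASVs
#'
#' Ranks use average ties; rho is the Pearson correlation of ranks.
#' Two-sided P from the t approximation with n - 2 df.  ASVs constant
#' across samples get NA rho/P off-diagonal (flagged; they can never pass
#' the network gates).
#'
#' @param counts Count matrix (samples x ASVs), >= 4 samples.
#' @return List: rho (unit diagonal), p (NA diagonal), both ASV x ASV.
#' @export
spearman_matrix <- function(counts) {
  n <- nrow(counts)
  if (n < 4) stop_("need >= 4 samples for correlation")
  ranks <- apply(counts, 2, rank)
  rho <- suppressWarnings(stats::cor(ranks))
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  p[is.na(rho)] <- NA
  diag(p) <- NA
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] with method "BH").
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values, same length and order.
#' @export
fdr_bh <- function(p_values) {
  ok <- p_values[!is.na(p_values)]
  if (any(ok < 0 | ok > 1)) stop_("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Build a signed co-occurrence network
#'
#' An undirected edge is kept iff |rho| >= `rho_min` and q <= `q_max`
#' (q = BH-adjusted p over the upper triangle, unless `use_raw_p`).
#' Edge sign is the sign of rho.  Isolated nodes are excluded.
#'
#' @param rho,p Matrices from [spearman_matrix()].
#' @param rho_min Minimum |rho| (default 0.8).
#' @param q_max Maximum adjusted p (default 0.001).
#' @param abundances Optional named dataset relative abundances for the nodes.
#' @param use_raw_p If TRUE gate on the raw p instead of the BH-adjusted
#'   value (sensitivity analysis).
#' @return Object of class "cooc_network": nodes (asv_id, rel_abundance),
#'   edges (asv_a, asv_b, rho, q, sign).
#' @export
build_network <- function(rho, p, rho_min = 0.8, q_max = 0.001,
                          abundances = NULL, use_raw_p = FALSE) {
  if (!all(dim(rho) == dim(p))) stop_("rho and p are not conformable")
  if (rho_min <= 0 || rho_min > 1) stop_("rho_min must be in (0, 1]")
  ids <- colnames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pv <- p[ut]
  qv <- if (use_raw_p) pv else fdr_bh(pv)
  rv <- rho[ut]
  keep <- !is.na(rv) & !is.na(qv) & abs(rv) >= rho_min & qv <= q_max
  edges <- data.frame(asv_a = ids[ut[keep, 1]], asv_b = ids[ut[keep, 2]],
                      rho = rv[keep], q = qv[keep],
                      sign = ifelse(rv[keep] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  node_ids <- sort(unique(c(edges$asv_a, edges$asv_b)))
  ab <- if (is.null(abundances)) rep(NA_real_, length(node_ids)) else
    unname(abundances[node_ids])
  net <- list(nodes = data.frame(asv_id = node_ids, rel_abundance = ab,
                                 stringsAsFactors = FALSE),
              edges = edges)
  class(net) <- "cooc_network"
  net
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("Co-occurrence network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges (",
      sum(x$edges$sign == "+"), "positive /",
      sum(x$edges$sign == "-"), "negative )\n")
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("asv_a", "asv_b")],
                                directed = FALSE,
                                vertices = net$nodes$asv_id)
}

#' Detect network modules by greedy modularity maximization
#'
#' Fast-greedy community detection on the unweighted, unsigned graph.
#'
#' @param net A cooc_network.
#' @param seed RNG seed (the algorithm is deterministic; the seed fixes any
#'   internal tie-breaking).
#' @return List: membership (named integer vector over nodes), modularity,
#'   n_modules.
#' @export
detect_modules <- function(net, seed = 1) {
  if (nrow(net$nodes) == 0) stop_("empty network")
  g <- as_igraph(net)
  comm <- with_seed(seed, igraph::cluster_fast_greedy(g))
  # cut the merge tree at the modularity maximum ourselves: the stock
  # membership can return a suboptimal cut on degenerate graphs (e.g. one
  # clique, where the single-community partition at Q = 0 is optimal)
  steps <- min(which.max(comm$modularity) - 1L, nrow(igraph::merges(comm)))
  memb <- igraph::cut_at(comm, steps = steps)
  memb <- stats::setNames(as.integer(memb), igraph::V(g)$name)
  list(membership = memb,
       modularity = igraph::modularity(g, memb),
       n_modules = length(unique(memb)))
}

#' Whole-network topology metrics
#'
#' Node/edge counts, positive/negative link counts, average degree 2E/N,
#' connectance 2E/(N(N-1)), largest-component fraction, and modularity of
#' the detected partition.
#'
#' @param net A cooc_network.
#' @param modules Optional result of [detect_modules()]; computed if NULL.
#' @param seed Seed forwarded to module detection.
#' @return Named list of metrics.
#' @export
network_metrics <- function(net, modules = NULL, seed = 1) {
  if (nrow(net$nodes) == 0 || nrow(net$edges) == 0) stop_("empty network")
  modules <- modules %||% detect_modules(net, seed)
  n <- nrow(net$nodes); e <- nrow(net$edges)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  list(n_nodes = n, n_edges = e,
       n_positive = sum(net$edges$sign == "+"),
       n_negative = sum(net$edges$sign == "-"),
       average_degree = 2 * e / n,
       connectance = if (n > 1) 2 * e / (n * (n - 1)) else NA_real_,
       largest_component_fraction = max(comp$csize) / n,
       modularity = modules$modularity,
       n_modules = modules$n_modules)
}

#' Zi-Pi node roles and keystone classification
#'
#' Zi is the within-module degree z-score: the node's within-module degree
#' standardized against the within-module degrees of its module's members
#' (defined as 0 when the module has < 3 members or zero spread).  Pi is the
#' participation coefficient 1 - sum_t (k_it / k_i)^2 over modules t.
#' Roles: module hub (Zi > zi_threshold, Pi <= pi_threshold), connector
#' (Zi <= zi_threshold, Pi > pi_threshold), network hub (both exceeded),
#' else peripheral.  Keystones are the non-peripheral nodes.
#'
#' @param net A cooc_network.
#' @param modules Result of [detect_modules()] (every node must be assigned).
#' @param zi_threshold,pi_threshold Role cutoffs (defaults 2.5 and 0.62).
#' @return Data frame: asv_id, degree, module, within_degree, Zi, Pi, role,
#'   keystone.
#' @export
zi_pi <- function(net, modules, zi_threshold = 2.5, pi_threshold = 0.62) {
  memb <- modules$membership
  ids <- net$nodes$asv_id
  miss <- setdiff(ids, names(memb))
  if (length(miss)) stop_("node(s) missing module assignment: %s",
                          paste(miss, collapse = ", "))
  memb <- memb[ids]
  adj <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  adj[cbind(net$edges$asv_a, net$edges$asv_b)] <- 1L
  adj[cbind(net$edges$asv_b, net$edges$asv_a)] <- 1L
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  # k_it: edges from node i into module t
  k_to_mod <- vapply(mods, function(t)
    rowSums(adj[, memb == t, drop = FALSE]), numeric(length(ids)))
  if (is.null(dim(k_to_mod))) k_to_mod <- matrix(k_to_mod, nrow = length(ids))
  within <- k_to_mod[cbind(seq_along(ids), match(memb, mods))]
  Zi <- vapply(seq_along(ids), function(i) {
    members <- which(memb == memb[i])
    if (length(members) < 3) return(0)
    w <- within[members]
    s <- stats::sd(w)
    if (s == 0) 0 else (within[i] - mean(w)) / s
  }, numeric(1))
  Pi <- 1 - rowSums((k_to_mod / pmax(k, 1))^2)
  Pi[k == 0] <- 0
  role <- ifelse(Zi > zi_threshold & Pi > pi_threshold, "network hub",
          ifelse(Zi > zi_threshold, "module hub",
          ifelse(Pi > pi_threshold, "connector", "peripheral")))
  data.frame(asv_id = ids, degree = unname(k), module = unname(memb),
             within_degree = unname(within), Zi = Zi, Pi = unname(Pi),
             role = role, keystone = role != "peripheral",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shared-node counts across networks
#'
#' Node-set intersections for every pair of networks and for the full set.
#'
#' @param nets Named list of >= 2 cooc_network objects.
#' @return Data frame: networks (label), n_shared.
#' @export
compare_networks <- function(nets) {
  if (length(nets) < 2) stop_("need >= 2 networks")
  nm <- names(nets) %||% paste0("net", seq_along(nets))
  sets <- lapply(nets, function(n) n$nodes$asv_id)
  pairs <- utils::combn(seq_along(sets), 2)
  out <- data.frame(
    networks = apply(pairs, 2, function(ij) paste(nm[ij], collapse = " & ")),
    n_shared = apply(pairs, 2, function(ij)
      length(intersect(sets[[ij[1]]], sets[[ij[2]]]))),
    stringsAsFactors = FALSE)
  rbind(out, data.frame(networks = paste(nm, collapse = " & "),
                        n_shared = length(Reduce(intersect, sets))))
}
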