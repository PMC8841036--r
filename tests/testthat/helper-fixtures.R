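# Small in-code fixtures shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# counts matrix with dimnames from a plain matrix (existing names win)
cm <- function(m, samples = rownames(m) %||% paste0("s", seq_len(nrow(m))),
               asvs = colnames(m) %||% paste0("a", seq_len(ncol(m)))) {
  dimnames(m) <- list(samples, asvs)
  m
}

# balanced two-factor toy metadata
toy_metadata <- function(n_per_cell = 2, layers = c("S", "M", "D"),
                         times = c("T1", "T2")) {
  g <- expand.grid(rep = seq_len(n_per_cell), layer = layers, time = times,
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("s%02d", seq_len(nrow(g))),
             plot = g$rep, layer = g$layer, time = g$time,
             stringsAsFactors = FALSE)
}

# hand-built co-occurrence network from an edge list
make_net <- function(edges, ids = NULL) {
  ids <- ids %||% sort(unique(unlist(edges)))
  ed <- data.frame(asv_a = vapply(edges, `[`, "", 1),
                   asv_b = vapply(edges, `[`, "", 2),
                   rho = 0.9, q = 1e-4, sign = "+", stringsAsFactors = FALSE)
  net <- list(nodes = data.frame(asv_id = ids, rel_abundance = NA_real_),
              edges = ed)
  class(net) <- "cooc_network"
  net
}

# independent closed-form pseudo-F for a one-factor grouping, straight from
# the distance matrix (no Gower projection): used as the PERMANOVA oracle.
pseudo_f_oracle <- function(d, groups) {
  n <- length(groups)
  a <- length(unique(groups))
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- sum(vapply(unique(groups), function(g) {
    idx <- which(groups == g)
    dd <- d[idx, idx, drop = FALSE]
    sum(dd[upper.tri(dd)]^2) / length(idx)
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# exhaustive one-factor PERMANOVA P over all assignments of n1 samples to
# group 1 (complement to group 2), identity included
exhaustive_permanova_p <- function(d, groups) {
  n <- length(groups)
  n1 <- sum(groups == unique(groups)[1])
  f_obs <- pseudo_f_oracle(d, groups)
  combs <- utils::combn(n, n1)
  f_all <- apply(combs, 2, function(idx) {
    g <- rep(2L, n); g[idx] <- 1L
    pseudo_f_oracle(d, g)
  })
  mean(f_all >= f_obs - 1e-12)
}
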