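# Bray-Curtis dissimilarity, principal coordinates analysis, PERMANOVA and
# the Mantel test, implemented from first principles on the distance
# matrix.  The variance partition follows the classic pseudo-F construction:
# Gower-center the matrix of -d^2/2, then read sums of squares off traces of
# projected matrices, permuting sample labels for the null.

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum x + sum y), equivalently
#' sum|x - y| / sum(x + y); values lie in \[0, 1\].
#'
#' @param counts Count (or abundance) matrix, samples as rows.
#' @return Symmetric matrix with zero diagonal and sample dimnames.
#' @export
bray_curtis <- function(counts) {
  tot <- rowSums(counts)
  zero <- rownames(counts)[tot == 0]
  if (length(zero)) stop_("all-zero sample(s): %s", paste(zero, collapse = ", "))
  man <- as.matrix(stats::dist(counts, method = "manhattan"))
  d <- man / outer(tot, tot, "+")
  diag(d) <- 0
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}

validate_distance <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-10 ||
      max(abs(diag(d))) > 1e-12) {
    stop_("distance matrix must be symmetric with zero diagonal")
  }
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  d
}

# Gower-centered matrix G = (I - 11'/n) (-d^2/2) (I - 11'/n)
gower_center <- function(d) {
  a <- -0.5 * d^2
  rc <- rowMeans(a)
  sweep(sweep(a, 1, rc), 2, rc) + mean(a)
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centered squared-distance matrix.
#' Coordinates are eigenvectors scaled by sqrt(eigenvalue) for positive
#' eigenvalues only; negative eigenvalues (the non-Euclidean share of the
#' dissimilarity) are reported, not corrected.
#'
#' @param d Distance matrix.
#' @return Object of class "pcoa_result": coordinates (samples x positive
#'   axes), eigenvalues (all, descending), prop_explained (per positive
#'   axis, of the positive total).
#' @export
pcoa <- function(d) {
  d <- validate_distance(d)
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1], 0) * 1e-9)
  coords <- matrix(0, nrow(d), length(pos),
                   dimnames = list(rownames(d),
                                   if (length(pos)) paste0("PCo", seq_along(pos))))
  if (length(pos)) {
    coords[] <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  }
  out <- list(coordinates = coords, eigenvalues = ev,
              prop_explained = ev[pos] / sum(ev[pos]),
              trace = sum(diag(G)))
  class(out) <- "pcoa_result"
  out
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("Principal coordinates analysis:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "positive axes\n")
  cat("First axes explain:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 3)),
             collapse = ", "), "\n")
  neg <- sum(x$eigenvalues[x$eigenvalues < 0])
  if (neg < 0) cat(sprintf("Negative eigenvalue share: %.3f\n",
                           abs(neg) / sum(abs(x$eigenvalues))))
  invisible(x)
}

# Design columns for one formula term (e.g. "layer" or "layer:time") as
# cell-membership indicators; rank handling is left to QR downstream, so
# single-level factors contribute no new rank rather than erroring.
term_indicator <- function(label, data) {
  vars <- strsplit(label, ":", fixed = TRUE)[[1]]
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop_("unknown factor(s) in formula: %s",
                          paste(miss, collapse = ", "))
  f <- interaction(lapply(vars, function(v) factor(data[[v]])), drop = TRUE)
  # manual indicator columns: model.matrix() rejects single-level factors,
  # which here must simply contribute zero additional rank
  vapply(levels(f), function(l) as.numeric(f == l), numeric(length(f)))
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Sequential (Type I) partition of the distance-based sum of squares among
#' the formula terms, with pseudo-F per term against the residual and P from
#' free permutation of sample labels:
#' P = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations).
#'
#' @param d Distance matrix with sample names.
#' @param metadata Sample metadata containing the formula factors.
#' @param formula One-sided formula over metadata columns, terms in the
#'   order they should enter (default ~ layer + time + layer:time).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed RNG seed.
#' @return Object of class "permanova": a data frame with one row per term
#'   plus Residuals and Total (df, SS, MS, F, r2, P).
#' @export
permanova <- function(d, metadata, formula = ~ layer + time + layer:time,
                      n_permutations = 999, seed = 1) {
  d <- validate_distance(d)
  if (n_permutations < 1) stop_("n_permutations must be >= 1")
  md <- metadata[match(rownames(d), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop_("metadata missing samples present in d")
  labels <- attr(stats::terms(formula), "term.labels")
  n <- nrow(d)
  G <- gower_center(d)
  ss_total <- sum(diag(G))

  X <- matrix(1, n, 1)
  H_prev <- hat_matrix(X)
  rank_prev <- 1L
  dH <- list(); dfs <- integer(0)
  for (lab in labels) {
    X <- cbind(X, term_indicator(lab, md))
    q <- qr(X)
    df_j <- q$rank - rank_prev
    H_j <- hat_matrix(X)
    if (df_j == 0L) {
      lv <- term_indicator(lab, md)
      if (ncol(lv) >= 2) {
        stop_("term '%s' is confounded with earlier terms", lab)
      }
      # single-level factor: no variation to attribute
    }
    dH[[lab]] <- H_j - H_prev
    dfs <- c(dfs, df_j)
    H_prev <- H_j
    rank_prev <- q$rank
  }
  R <- diag(n) - H_prev
  df_res <- n - rank_prev
  if (df_res == 0L) stop_("zero residual degrees of freedom")

  stat <- function(Gm) {
    ss <- vapply(dH, function(h) sum(h * Gm), numeric(1))
    ss_res <- sum(R * Gm)
    f <- (ss / pmax(dfs, 1)) / (ss_res / df_res)
    f[dfs == 0] <- NA_real_
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat(G)

  # equality up to floating rounding counts as exceedance, so permutations
  # that merely relabel within groups reproduce the observed F exactly
  eps <- 1e-8 * pmax(abs(obs$f), 1)
  exceed <- rep(0L, length(labels))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(n)
      fp <- stat(G[perm, perm])$f
      exceed <- exceed + (!is.na(fp) & !is.na(obs$f) & fp >= obs$f - eps)
    }
  })
  P <- (1 + exceed) / (1 + n_permutations)
  P[dfs == 0] <- NA_real_

  out <- data.frame(
    term = c(labels, "Residuals", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(obs$ss, obs$ss_res, ss_total),
    MS = c(obs$ss / pmax(dfs, 1), obs$ss_res / df_res, NA),
    F = c(obs$f, NA, NA),
    r2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    P = c(P, NA, NA),
    row.names = NULL, stringsAsFactors = FALSE)
  out$MS[out$term != "Residuals" & c(dfs, 1, 1) == 0] <- NA
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("permanova", "data.frame")
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", attr(x, "n_permutations"), " permutations)\n", sep = "")
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 4); df$MS <- signif(df$MS, 4)
  df$F <- signif(df$F, 4); df$r2 <- round(df$r2, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Mantel test
#'
#' Pearson correlation of the strictly-upper-triangle entries of two
#' distance matrices over the same samples; one-sided (greater) P by
#' simultaneous row/column permutation of the second matrix.
#'
#' @param d1,d2 Distance matrices over identical sample sets.
#' @param n_permutations Number of permutations (default 999).
#' @param seed RNG seed.
#' @return List: r, p, n_permutations.  r is NA (flagged, p NA) if either
#'   matrix has zero variance off-diagonal.
#' @export
mantel <- function(d1, d2, n_permutations = 999, seed = 1) {
  d1 <- validate_distance(d1); d2 <- validate_distance(d2)
  if (!setequal(rownames(d1), rownames(d2))) {
    stop_("sample sets differ between the two matrices")
  }
  d2 <- d2[rownames(d1), rownames(d1)]
  v1 <- upper_tri(d1); v2 <- upper_tri(d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE,
                n_permutations = n_permutations))
  }
  r <- stats::cor(v1, v2)
  n <- nrow(d1)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      perm <- sample.int(n)
      stats::cor(v1, upper_tri(d2[perm, perm])) >= r
    }, logical(1)))
  })
  list(r = r, p = (1 + exceed) / (1 + n_permutations), degenerate = FALSE,
       n_permutations = n_permutations)
}

#' Write a distance matrix as square TSV
#' @param d Distance matrix.
#' @param path Output path.
#' @export
write_distance <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
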