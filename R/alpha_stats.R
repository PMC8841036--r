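# Alpha diversity, balanced two-way ANOVA with Tukey post-hoc, soil
# fertility index, and permutation-calibrated random-forest importance.

#' Alpha diversity per sample
#'
#' Observed richness S, Shannon entropy H (natural log) and Pielou evenness
#' J = H / ln(S).  J is undefined (NA, flagged) when S <= 1.
#'
#' @param counts Count matrix.
#' @return Data frame: sample_id, S, H, J, evenness_defined.
#' @export
alpha_diversity <- function(counts) {
  validate_count_table(counts)
  S <- rowSums(counts > 0)
  H <- apply(counts, 1, function(x) {
    p <- x[x > 0] / sum(x)
    if (!length(p)) return(0)
    -sum(p * log(p))
  })
  J <- ifelse(S > 1, H / log(S), NA_real_)
  data.frame(sample_id = rownames(counts), S = as.integer(S), H = unname(H),
             J = unname(J), evenness_defined = S > 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Balanced two-way ANOVA
#'
#' Crossed two-factor analysis of variance with interaction, for balanced
#' designs only (equal replication per cell, >= 2 per cell); under balance
#' the sums of squares are unambiguous.  F for each term is MS_term over
#' MS_residual.
#'
#' @param values Numeric response, one per sample.
#' @param metadata Sample metadata (rows matched to `values` by position
#'   via `sample_id`).
#' @param factors Character pair naming the two metadata factors
#'   (default layer, time).
#' @param sample_id Sample identifiers aligning `values` with metadata.
#' @return Data frame, one row per term (A, B, A:B, Residuals) with
#'   df, SS, MS, F, P; class "two_way_anova".
#' @export
two_way_anova <- function(values, metadata, factors = c("layer", "time"),
                          sample_id = metadata$sample_id) {
  stopifnot(length(factors) == 2)
  md <- metadata[match(sample_id, metadata$sample_id), ]
  f1 <- factor(md[[factors[1]]])
  f2 <- factor(md[[factors[2]]])
  if (anyNA(values) || anyNA(f1) || anyNA(f2)) stop_("missing values in input")
  cell_n <- table(f1, f2)
  if (length(unique(c(cell_n))) != 1L) {
    stop_("unbalanced design (unequal cell sizes); use a permutation-based alternative")
  }
  if (cell_n[1] < 2) stop_("need >= 2 replicates per cell")
  dat <- data.frame(y = values, A = f1, B = f2)
  fit <- stats::aov(y ~ A * B, data = dat)
  tab <- summary(fit)[[1]]
  ss_tot <- sum(tab[, "Sum Sq"])
  if (stats::var(values) == 0 ||
      tab["Residuals", "Sum Sq"] < 1e-10 * max(ss_tot, .Machine$double.eps)) {
    stop_("zero residual variance; F undefined")
  }
  out <- data.frame(
    term = c(factors[1], factors[2], paste(factors, collapse = ":"), "Residuals"),
    df = tab[, "Df"], SS = tab[, "Sum Sq"], MS = tab[, "Mean Sq"],
    F = tab[, "F value"], P = tab[, "Pr(>F)"],
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("two_way_anova", "data.frame")
  out
}

#' Tukey HSD post-hoc comparisons for one factor
#'
#' Pairwise mean differences with adjusted P from the studentized-range
#' distribution, on a one-way fit of the named factor.
#'
#' @param values Numeric response.
#' @param metadata Sample metadata.
#' @param factor_name Metadata factor to compare.
#' @param sample_id Sample identifiers aligning `values` with metadata.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame: comparison, diff, lwr, upr, p_adj, significant.
#' @export
tukey_posthoc <- function(values, metadata, factor_name = "layer",
                          sample_id = metadata$sample_id, alpha = 0.05) {
  md <- metadata[match(sample_id, metadata$sample_id), ]
  f <- droplevels(factor(md[[factor_name]]))
  if (nlevels(f) < 2) stop_("factor '%s' has fewer than 2 levels", factor_name)
  fit <- stats::aov(values ~ f)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$f
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Soil fertility index
#'
#' Per-sample sum of z-scores (across all samples) of the six nutrient
#' variables TC, TN, DOC, DON, NH4-N and NO3-N.  By construction the index
#' has mean 0 over the cohort; units are absorbed by the z-transform.
#'
#' @param soil Soil variables data frame.
#' @return Data frame: sample_id, fertility_index.
#' @export
fertility_index <- function(soil) {
  miss <- setdiff(SOIL_NUTRIENTS, names(soil))
  if (length(miss)) stop_("soil table missing nutrient(s): %s",
                          paste(miss, collapse = ", "))
  z <- vapply(SOIL_NUTRIENTS, function(v) {
    x <- soil[[v]]
    if (anyNA(x)) stop_("missing values in %s", v)
    s <- stats::sd(x)
    if (s == 0) stop_("nutrient variable %s has zero variance", v)
    (x - mean(x)) / s
  }, numeric(nrow(soil)))
  data.frame(sample_id = soil$sample_id, fertility_index = rowSums(z),
             stringsAsFactors = FALSE)
}

#' Random-forest importance with response-permutation significance
#'
#' Fits a regression forest of the response on the predictors and reports
#' each predictor's permutation importance (% increase in MSE).  Significance
#' is calibrated by refitting the forest on `n_response_permutations`
#' permuted copies of the response:
#' P = (1 + #\{null importance >= observed\}) / (1 + n_response_permutations).
#'
#' @param predictors Data frame or matrix of per-sample numeric predictors.
#' @param response Numeric response, one per sample.
#' @param n_trees Trees per forest (default 500).
#' @param n_response_permutations Null refits (default 99).
#' @param seed RNG seed; results are deterministic per seed.
#' @param mtry Variables tried per split; default the regression rule
#'   ceiling(p / 3).
#' @return Data frame: predictor, importance, p; plus attribute
#'   "r_squared" (forest pseudo-R2 of the observed fit).
#' @export
rf_importance <- function(predictors, response, n_trees = 500,
                          n_response_permutations = 99, seed = 1,
                          mtry = NULL) {
  x <- as.data.frame(predictors)
  if (nrow(x) < 10) stop_("need >= 10 samples")
  if (ncol(x) < 2) stop_("need >= 2 predictors")
  if (length(response) != nrow(x)) stop_("response length mismatch")
  if (stats::sd(response) == 0) stop_("constant response")
  mtry <- mtry %||% max(ceiling(ncol(x) / 3), 1)
  with_seed(seed, {
    fit <- randomForest::randomForest(x, response, ntree = n_trees,
                                      mtry = mtry, importance = TRUE)
    obs <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
    exceed <- rep(0L, ncol(x))
    for (b in seq_len(n_response_permutations)) {
      yb <- sample(response)
      fb <- randomForest::randomForest(x, yb, ntree = n_trees, mtry = mtry,
                                       importance = TRUE)
      nullb <- randomForest::importance(fb, type = 1, scale = TRUE)[, 1]
      exceed <- exceed + (nullb >= obs)
    }
    p <- (1 + exceed) / (1 + n_response_permutations)
    out <- data.frame(predictor = colnames(x), importance = unname(obs),
                      p = unname(p), stringsAsFactors = FALSE)
    attr(out, "r_squared") <- fit$rsq[length(fit$rsq)]
    out
  })
}
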