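test_that("diversity indices match closed forms", {
  m <- cm(matrix(c(10, 10, 10, 10,
                   100, 0, 0, 0,
                   97, 1, 1, 1), 3, 4, byrow = TRUE))
  div <- alpha_diversity(m)
  expect_equal(div$S, c(4L, 1L, 4L))
  expect_equal(div$J[1], 1)
  expect_true(is.na(div$J[2]))
  expect_false(div$evenness_defined[2])
  # closed-form oracle: -sum p log p, J = H / ln 4
  p <- c(97, 1, 1, 1) / 100
  H_oracle <- -sum(p * log(p))
  expect_equal(div$H[3], H_oracle, tolerance = 1e-12)
  expect_equal(div$J[3], H_oracle / log(4), tolerance = 1e-12)
  expect_equal(round(div$H[3], 5), 0.16770)
  expect_equal(round(div$J[3], 5), 0.12097)
  expect_true(all(div$H <= log(pmax(div$S, 2)) + 1e-12))
})

test_that("two-way ANOVA matches a direct cell-mean decomposition", {
  md <- toy_metadata(n_per_cell = 3, times = c("T1", "T2", "T3", "T4"))
  set.seed(17)
  y <- rnorm(nrow(md)) + 0.8 * (md$layer == "D") + 0.3 * (md$time == "T2")
  fit <- two_way_anova(y, md)

  # brute-force oracle from cell/marginal means
  A <- factor(md$layer); B <- factor(md$time)
  grand <- mean(y)
  nA <- table(A)[1]; nB <- table(B)[1]; r <- table(A, B)[1, 1]
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - grand)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - grand)^2))
  cell <- tapply(y, list(A, B), mean)
  ssCell <- r * sum((cell - grand)^2)
  ssAB <- ssCell - ssA - ssB
  ssTot <- sum((y - grand)^2)
  ssRes <- ssTot - ssCell
  expect_equal(fit$SS, c(ssA, ssB, ssAB, ssRes), tolerance = 1e-10)
  expect_equal(sum(fit$SS), ssTot, tolerance = 1e-9)
  dfRes <- fit$df[4]
  expect_equal(fit$F[1], (ssA / fit$df[1]) / (ssRes / dfRes), tolerance = 1e-10)
  expect_equal(sum(fit$df), nrow(md) - 1)
  expect_true(all(fit$P[1:3] >= 0 & fit$P[1:3] <= 1))
})

test_that("ANOVA rejects unbalanced designs and zero residual variance", {
  md <- toy_metadata(n_per_cell = 2)
  y <- rnorm(nrow(md))
  expect_error(two_way_anova(y[-1], md[-1, ], sample_id = md$sample_id[-1]),
               "unbalanced")
  expect_error(two_way_anova(rep(3, nrow(md)), md), "residual variance")
  # pure factor-A effects leave SS_B and SS_AB at zero
  y2 <- c(S = 1, M = 2, D = 3)[md$layer]
  expect_error(two_way_anova(y2, md), "residual variance")
  y3 <- y2 + rep(c(-0.01, 0.01), length.out = nrow(md))  # tiny within-cell noise
  fit <- two_way_anova(y3, md)
  expect_equal(fit$SS[2], 0, tolerance = 1e-20)
})

test_that("Tukey reduces to the pooled t-test with two groups", {
  md <- data.frame(sample_id = paste0("s", 1:10), plot = 1,
                   layer = rep(c("S", "D"), each = 5), time = "T1")
  set.seed(5)
  y <- rnorm(10) + (md$layer == "S")
  tk <- tukey_posthoc(y, md, "layer")
  tt <- t.test(y ~ md$layer, var.equal = TRUE)
  expect_equal(nrow(tk), 1)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)

  # one level shifted far away: its comparisons significant, the other not
  md3 <- toy_metadata(n_per_cell = 4, times = "T1")
  set.seed(6)
  y3 <- rnorm(nrow(md3), sd = 1) + 10 * (md3$layer == "D")
  tk3 <- tukey_posthoc(y3, md3, "layer")
  shifted <- grepl("D", tk3$comparison)
  expect_true(all(tk3$p_adj[shifted] < 0.001))
  expect_true(all(tk3$p_adj[!shifted] > 0.05))
  expect_error(tukey_posthoc(y, md[md$layer == "S", ],
                             "layer", sample_id = md$sample_id[md$layer == "S"]),
               "2 levels")
})

test_that("fertility index is the sum of nutrient z-scores", {
  soil <- data.frame(sample_id = paste0("s", 1:4),
                     TC = c(10, 12, 14, 16), TN = c(1, 2, 3, 4),
                     DOC = c(100, 120, 90, 110), DON = c(9, 11, 10, 14),
                     NO3 = c(5, 6, 7, 4), NH4 = c(2, 2.5, 3, 3.5))
  fi <- fertility_index(soil)
  oracle <- rowSums(scale(soil[, -1]))
  expect_equal(fi$fertility_index, unname(oracle), tolerance = 1e-12)
  expect_equal(mean(fi$fertility_index), 0, tolerance = 1e-12)

  # invariance to affine rescaling of any one variable
  soil2 <- soil; soil2$DOC <- soil2$DOC * 37 + 5
  expect_equal(fertility_index(soil2)$fertility_index, fi$fertility_index,
               tolerance = 1e-10)
  soil3 <- soil; soil3$TN <- 2
  expect_error(fertility_index(soil3), "TN")
})

test_that("random-forest importance recovers a planted signal", {
  hits <- vapply(1:5, function(s) {
    set.seed(100 + s)
    x <- data.frame(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
    y <- x$x1 + rnorm(100, sd = 0.1)
    rf <- rf_importance(x, y, n_trees = 100, n_response_permutations = 39,
                        seed = s)
    rf$importance[1] > max(rf$importance[-1]) && rf$p[1] <= 0.05
  }, logical(1))
  expect_true(all(hits))
})

test_that("random-forest importance is deterministic per seed", {
  set.seed(77)
  x <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  y <- rnorm(30)
  r1 <- rf_importance(x, y, n_trees = 50, n_response_permutations = 9, seed = 2)
  r2 <- rf_importance(x, y, n_trees = 50, n_response_permutations = 9, seed = 2)
  expect_identical(r1, r2)
  expect_error(rf_importance(x, rep(1, 30)), "constant")
  expect_error(rf_importance(x[1:5, ], y[1:5]), "10 samples")
})
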