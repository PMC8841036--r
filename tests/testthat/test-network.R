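test_that("network filtering applies strict abundance and occurrence gates", {
  # 4 samples; a1 at 0.6% in 3/4 samples -> kept; a2 at 0.6% in 2/4 -> dropped
  tot <- 10000
  m <- cm(matrix(0, 4, 5), asvs = paste0("a", 1:5))
  m[, "a1"] <- c(80, 80, 80, 0)        # 240/40000 = 0.6%, occ 3/4
  m[, "a2"] <- c(120, 120, 0, 0)       # 0.6%, occ 2/4 (exactly 50%)
  m[, "a3"] <- c(10, 10, 10, 10)       # 0.1%: fails abundance
  m[, "a4"] <- c(60, 60, 60, 60)       # 0.6%, occ 4/4 -> kept
  m[, "a5"] <- tot - rowSums(m)        # filler, abundant + ubiquitous
  f <- filter_for_network(m, 0.005, 0.5)
  expect_setequal(colnames(f), c("a1", "a4", "a5"))
  expect_error(filter_for_network(m, 0.99, 0.99), "no ASVs survive")
})

test_that("Spearman correlations follow the rank formula", {
  m <- cm(cbind(x = c(1, 2, 3), y = c(3, 1, 2), z = c(10, 20, 30)))
  sp <- spearman_matrix(rbind(m, cm(matrix(c(4, 4, 40), 1, 3), samples = "s4",
                                    asvs = c("x", "y", "z"))))
  # ties-free triple formula on 4 points: compare to cor(..., "spearman")
  expect_equal(sp$rho, cor(rbind(m, c(4, 4, 40)), method = "spearman"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(sp$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sp$rho, t(sp$rho))

  # the canonical 1 - 6*sum(d^2)/(n(n^2-1)) evaluation, n = 4
  xr <- rank(c(1, 2, 3, 4)); yr <- rank(c(3, 1, 2, 4))
  rho_hand <- 1 - 6 * sum((xr - yr)^2) / (4 * 15)
  m4 <- cm(cbind(x = c(1, 2, 3, 4), y = c(3, 1, 2, 4)))
  expect_equal(spearman_matrix(m4)$rho["x", "y"], rho_hand, tolerance = 1e-12)

  # monotone pair: rho exactly 1, p = 0
  m5 <- cm(cbind(x = 1:5, y = c(2, 4, 8, 16, 32), w = c(5, 1, 4, 2, 3)))
  sp5 <- spearman_matrix(m5)
  expect_equal(sp5$rho["x", "y"], 1)
  expect_equal(sp5$p["x", "y"], 0)

  # constant ASV: flagged NA
  m6 <- cm(cbind(x = 1:4, k = rep(2, 4)))
  expect_true(is.na(spearman_matrix(m6)$rho["x", "k"]))
  expect_error(spearman_matrix(m6[1:3, ]), ">= 4 samples")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(c(0.005, 0.049, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(fdr_bh(0.3), 0.3)
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("edge gates keep exactly the qualifying correlations with signs", {
  ids <- paste0("a", 1:4)
  rho <- diag(4); dimnames(rho) <- list(ids, ids)
  p <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  set_pair <- function(i, j, r, pv) {
    rho[i, j] <<- r; rho[j, i] <<- r; p[i, j] <<- pv; p[j, i] <<- pv
  }
  set_pair(1, 2, 0.85, 0.0001)   # kept +
  set_pair(1, 3, -0.85, 0.0001)  # kept -
  set_pair(2, 3, 0.85, 0.5)      # fails q
  set_pair(3, 4, 0.5, 0.0001)    # fails rho
  set_pair(2, 4, 0.2, 0.9)
  set_pair(1, 4, 0.1, 0.9)
  net <- build_network(rho, p, rho_min = 0.8, q_max = 0.01, use_raw_p = TRUE)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("+", "-"))
  expect_false("a4" %in% net$nodes$asv_id)  # isolated node excluded
  # every emitted edge re-satisfies both gates
  expect_true(all(abs(net$edges$rho) >= 0.8 & net$edges$q <= 0.01))
  # raising rho_min never increases the edge count
  for (r in c(0.5, 0.8, 0.9, 0.99)) {
    n_r <- nrow(build_network(rho, p, r, 0.01, use_raw_p = TRUE)$edges)
    if (r > 0.5) expect_lte(n_r, n_prev)
    n_prev <- n_r
  }
})

test_that("network metrics follow their formulas", {
  tri <- make_net(list(c("a", "b"), c("b", "c"), c("a", "c")))
  mt <- network_metrics(tri)
  expect_equal(mt$average_degree, 2)
  expect_equal(mt$connectance, 1)
  expect_equal(mt$n_negative, 0)
  expect_equal(mt$largest_component_fraction, 1)

  two <- make_net(list(c("a", "b"), c("c", "d")))
  mt2 <- network_metrics(two)
  expect_equal(mt2$average_degree, 1)
  expect_equal(mt2$connectance, 1 / 3)
  expect_equal(mt2$largest_component_fraction, 0.5)
})

test_that("greedy modularity splits planted cliques and is deterministic", {
  clique <- function(tag) {
    v <- paste0(tag, 1:5)
    utils::combn(v, 2, simplify = FALSE)
  }
  net <- make_net(c(clique("x"), clique("y"), list(c("x1", "y1"))))
  mods <- detect_modules(net, seed = 1)
  expect_equal(mods$n_modules, 2)
  expect_gt(mods$modularity, 0.3)
  split <- split(names(mods$membership), mods$membership)
  expect_true(all(vapply(split, function(s)
    length(unique(substr(s, 1, 1))) == 1, logical(1))))
  expect_identical(detect_modules(net, seed = 1), mods)

  single <- make_net(clique("z"))
  expect_equal(detect_modules(single)$n_modules, 1)
})

test_that("Zi and Pi follow their definitions and flag keystones", {
  clique <- function(tag) utils::combn(paste0(tag, 1:5), 2, simplify = FALSE)
  # connector node c0 with 2 edges into each clique
  edges <- c(clique("x"), clique("y"),
             list(c("c0", "x1"), c("c0", "x2"), c("c0", "y1"), c("c0", "y2")))
  net <- make_net(edges)
  mods <- detect_modules(net, seed = 1)
  topo <- zi_pi(net, mods)

  # within-module degree sums: sum_t k_it = k_i (via Pi construction)
  expect_true(all(topo$Pi >= 0 & topo$Pi < 1))
  c0 <- topo[topo$asv_id == "c0", ]
  expect_equal(c0$degree, 4)
  # 2/2 split across two modules: Pi = 1 - (0.25 + 0.25) = 0.5 when c0 sits
  # in one of the cliques' modules; with its own module Pi stays the sweep max
  expect_equal(c0$Pi, max(topo$Pi))
  expect_true(c0$Pi %in% c(0.5))
  # pure within-module nodes have Pi = 0
  pure <- topo$asv_id %in% c("x3", "x4", "x5", "y3", "y4", "y5")
  expect_true(all(topo$Pi[pure] == 0))
  # roles consistent with thresholds, keystone = non-peripheral
  expect_true(all((topo$role == "peripheral") == !topo$keystone))
  expect_true(all(topo$role[topo$Zi <= 2.5 & topo$Pi <= 0.62] == "peripheral"))

  bad_mods <- mods
  bad_mods$membership <- mods$membership[-1]
  expect_error(zi_pi(net, bad_mods), "missing module")
})

test_that("network comparison counts shared nodes by set arithmetic", {
  n1 <- make_net(list(c("a", "b"), c("b", "c")))          # a b c
  n2 <- make_net(list(c("b", "c"), c("c", "d")))          # b c d
  n3 <- make_net(list(c("c", "e")))                       # c e
  out <- compare_networks(list(S = n1, M = n2, D = n3))
  expect_equal(out$n_shared[out$networks == "S & M"], 2)
  expect_equal(out$n_shared[out$networks == "S & D"], 1)
  expect_equal(out$n_shared[out$networks == "M & D"], 1)
  expect_equal(out$n_shared[out$networks == "S & M & D"], 1)
  same <- compare_networks(list(a = n1, b = n1))
  expect_equal(same$n_shared, c(3, 3))
  expect_error(compare_networks(list(n1)), ">= 2")
})

test_that("planted modules are recovered from simulated counts", {
  ds <- simulate_dataset(simulation_params(n_asvs = 300, library_size = 20000,
                                           seed = 41))
  samp <- ds$metadata$sample_id[ds$metadata$layer == "S"]
  f <- filter_for_network(ds$counts, samples = samp)
  sp <- spearman_matrix(f)
  net <- build_network(sp$rho, sp$p)
  mods <- detect_modules(net, seed = 1)
  gt <- ds$ground_truth$modules
  common <- intersect(names(gt), names(mods$membership))
  expect_gte(length(common), 20)
  expect_gte(mclust::adjustedRandIndex(gt[common], mods$membership[common]), 0.9)
})
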