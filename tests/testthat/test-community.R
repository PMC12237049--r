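test_that("Bray-Curtis matches hand arithmetic and its boundary cases", {
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(2, 0, 0), c(0, 1, 3)), 1)
  expect_equal(bray_curtis(c(2, 1, 0), c(1, 1, 1)), 2 / 6)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "length")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("Bray-Curtis is symmetric, bounded, and scale-invariant", {
  set.seed(42)
  for (i in 1:20) {
    x <- rgamma(6, 2); y <- rgamma(6, 2)
    d <- bray_curtis(x, y)
    expect_equal(d, bray_curtis(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
    c1 <- runif(1, 0.1, 10)
    expect_equal(bray_curtis(c1 * x, c1 * y), d)
  }
})

test_that("dissimilarity matrix agrees with the vegan reference to 1e-10", {
  for (s in 1:10) {
    M <- random_community(n = 5 + s %% 3, p = 4 + s %% 4, seed = s)
    D <- community_dissimilarity(M)
    ref <- as.matrix(vegan::vegdist(M, method = "bray"))
    expect_lt(max(abs(D - ref)), 1e-10)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
  }
})

test_that("PERMANOVA pseudo-F matches the vegan partition on random data", {
  for (s in 1:5) {
    M <- random_community(8, 5, seed = 100 + s)
    groups <- rep(c("a", "b"), each = 4)
    D <- community_dissimilarity(M)
    ours <- permanova(D, groups, n_perm = 99, seed = 1)
    ref <- vegan::adonis2(as.dist(D) ~ g,
                          data = data.frame(g = groups), permutations = 99)
    expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
  }
})

test_that("PERMANOVA handles no-structure and complete-separation limits", {
  # identical samples in both groups: zero dissimilarity everywhere
  D0 <- matrix(0, 6, 6)
  res0 <- permanova(D0, rep(c("a", "b"), 3), n_perm = 99, seed = 1)
  expect_equal(res0$pseudo_F, 0)
  expect_gte(res0$p_value, 0.99)

  # two tight, fully separated clusters of 4
  M <- rbind(matrix(rep(c(100, 1, 1), each = 4), 4) +
               matrix(runif(12, 0, 0.1), 4),
             matrix(rep(c(1, 1, 100), each = 4), 4) +
               matrix(runif(12, 0, 0.1), 4))
  rownames(M) <- paste0("S", 1:8)
  D <- community_dissimilarity(M)
  res <- permanova(D, rep(c("a", "b"), each = 4), n_perm = 999, seed = 2)
  expect_lt(res$p_value, 0.05)
})

test_that("Monte-Carlo PERMANOVA p agrees with exhaustive enumeration at n = 6", {
  for (s in 1:3) {
    M <- random_community(6, 4, seed = 200 + s)
    groups <- rep(c("a", "b"), each = 3)
    D <- community_dissimilarity(M)
    p_exact <- permanova_exact_p(D, groups)
    p_mc <- permanova(D, groups, n_perm = 4999, seed = s)$p_value
    # binomial error of the Monte-Carlo estimate around the exact value
    se <- sqrt(p_exact * (1 - p_exact) / 4999)
    expect_lt(abs(p_mc - p_exact), 4 * se + 2 / 5000)
  }
})

test_that("PERMANOVA rejects degenerate groupings", {
  D <- community_dissimilarity(random_community(5, 3, seed = 9))
  expect_error(permanova(D, c("a", "a", "a", "a", "b"), 99), "at least 2")
  expect_error(permanova(D, rep("a", 5), 99), "2 groups")
})

test_that("MDS embeds equidistant points as an equilateral triangle and tracks ranks", {
  D3 <- matrix(0.5, 3, 3); diag(D3) <- 0
  emb <- mds_embed(D3, refine = FALSE)
  d_emb <- dist(emb$points)
  expect_lt(diff(range(d_emb)) / mean(d_emb), 1e-8)

  # duplicate samples land on coincident points
  M <- random_community(5, 4, seed = 31)
  M <- rbind(M, M[1, , drop = FALSE])
  rownames(M)[6] <- "S1dup"
  D <- community_dissimilarity(M)
  emb2 <- mds_embed(D, refine = FALSE)
  expect_lt(sqrt(sum((emb2$points[1, ] - emb2$points[6, ])^2)), 1e-8)

  # clustered synthetic data: embedding distances rank-correlate with D
  set.seed(8)
  centers <- rbind(c(100, 5, 5), c(5, 100, 5), c(5, 5, 100))
  M2 <- centers[rep(1:3, each = 4), ] + matrix(rgamma(36, 2, 0.5), 12, 3)
  rownames(M2) <- paste0("S", 1:12)
  D2 <- community_dissimilarity(M2)
  emb3 <- mds_embed(D2)
  rho <- cor(as.vector(as.dist(D2)), as.vector(dist(emb3$points)),
             method = "spearman")
  expect_gt(rho, 0.95)
  expect_error(mds_embed(matrix(0, 2, 2)), "3 samples")
})

test_that("similarity network links strictly below threshold and labels clusters deterministically", {
  M <- random_community(6, 4, seed = 77)
  D <- community_dissimilarity(M)

  tiny <- build_similarity_network(D, threshold = 1e-12)
  expect_equal(nrow(tiny$edges), 0)
  expect_equal(tiny$n_clusters, 6)

  all_in <- build_similarity_network(D, threshold = 1)
  if (all(D[upper.tri(D)] < 1)) expect_equal(all_in$n_clusters, 1)

  # strictness at the threshold: an edge exactly at 0.25 is excluded
  Dx <- matrix(c(0, 0.25, 0.25, 0), 2, 2)
  rownames(Dx) <- colnames(Dx) <- c("A", "B")
  Dx3 <- rbind(cbind(Dx, C = c(0.8, 0.8)), C = c(0.8, 0.8, 0))
  colnames(Dx3) <- rownames(Dx3)
  net <- build_similarity_network(Dx3, threshold = 0.25)
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$n_clusters, 3)
  expect_error(build_similarity_network(D, threshold = 0), "0, 1")
})

test_that("raising the threshold never splits an existing component", {
  M <- random_community(10, 5, seed = 55)
  D <- community_dissimilarity(M)
  thresholds <- sort(runif(8, 0.05, 0.95))
  prev <- NULL
  for (th in thresholds) {
    net <- build_similarity_network(D, th)
    if (!is.null(prev)) {
      # every pair together at the lower threshold stays together
      for (i in 1:9) for (j in (i + 1):10) {
        if (prev[i] == prev[j]) {
          expect_true(unname(net$membership[i] == net$membership[j]))
        }
      }
    }
    prev <- net$membership
  }
})

test_that("a distinct deep layer community forms its own network cluster", {
  cfg <- layer_config(seed = 3, speed = 0)
  cfg$layer_center_m <- 460
  cfg$layer_width_m <- 25
  ds <- generate_scenario(cfg)
  ft <- cell_flux_table(ds$counts)
  cm <- community_matrix(ft, ds$trap_samples)
  keep <- rowSums(cm$matrix) > 0
  D <- community_dissimilarity(cm$matrix[keep, ])
  meta <- cm$meta[keep, ]
  net <- build_similarity_network(D, 0.25, meta)
  # deep samples (dominated by the layer taxon) never share a cluster with
  # shallow samples (layer taxon absent)
  deep <- meta$depth_m >= 440
  shallow <- meta$depth_m <= 300
  expect_true(length(intersect(net$membership[deep],
                               net$membership[shallow])) == 0)
})

test_that("cluster compositions average member samples and sum to one", {
  M <- rbind(c(60, 40), c(40, 60))
  rownames(M) <- c("A", "B"); colnames(M) <- c("t1", "t2")
  D <- community_dissimilarity(M)
  net <- build_similarity_network(D, threshold = 1)
  comp <- network_cluster_composition(net, M, display_min = 0)
  expect_equal(unname(comp[1, ]), c(0.5, 0.5))

  # single-sample cluster returns that sample's relative composition
  net0 <- build_similarity_network(D, threshold = 1e-12)
  comp0 <- network_cluster_composition(net0, M, display_min = 0)
  expect_equal(unname(comp0[1, ]), c(0.6, 0.4))

  # pooling below the display threshold keeps row sums at 1
  M2 <- random_community(6, 8, seed = 5)
  D2 <- community_dissimilarity(M2)
  net2 <- build_similarity_network(D2, 0.6)
  comp2 <- network_cluster_composition(net2, M2, display_min = 0.05)
  expect_equal(unname(rowSums(comp2)), rep(1, nrow(comp2)))
  comp_nopool <- network_cluster_composition(net2, M2, display_min = 0)
  expect_equal(unname(rowSums(comp_nopool)), rep(1, nrow(comp_nopool)))
})
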