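test_that("connectivity features concatenate output and input synapse counts", {
  cn <- connectome(toy_edges(list("A", "B", 5), list("C", "A", 2),
                             list("B", "C", 1)))
  F <- connectivity_features(cn, c("A", "B"))
  a <- F["A", ]
  expect_equal(sum(a != 0), 2)
  expect_equal(unname(a[["out:B"]]), 5)
  expect_equal(unname(a[["in:C"]]), 2)

  # identical partners and counts give identical rows
  twin <- connectome(toy_edges(list("X", "T", 3), list("Y", "T", 3),
                               list("S", "X", 2), list("S", "Y", 2)))
  Ft <- connectivity_features(twin, c("X", "Y"))
  expect_equal(unname(as.matrix(Ft)["X", setdiff(colnames(Ft), c("out:X", "out:Y", "in:X", "in:Y"))]),
               unname(as.matrix(Ft)["Y", setdiff(colnames(Ft), c("out:X", "out:Y", "in:X", "in:Y"))]))

  # isolated cells are excluded and reported
  iso <- connectome(toy_edges(list("A", "B", 1)),
                    cells = tibble::tibble(id = c("A", "B", "Z")))
  expect_message(Fi <- connectivity_features(iso, c("A", "Z")), "excluded")
  expect_equal(attr(Fi, "excluded"), "Z")
  expect_false("Z" %in% rownames(Fi))
})

test_that("influence features transpose seed-by-target scores and keep zero rows", {
  scores <- matrix(c(1, 2, 0, 3, 0, 0), nrow = 3, ncol = 2,
                   dimnames = list(paste0("seed", 1:3), paste0("eff", 1:2)))
  F <- influence_features(scores)
  expect_equal(dim(F), c(2, 3))
  expect_equal(F["eff1", "seed2"], scores["seed2", "eff1"])
  scores_na <- scores
  scores_na[1, 1] <- NA
  expect_error(influence_features(scores_na), "missing")
})

test_that("cosine similarity matches hand computation and is permutation-invariant", {
  F <- rbind(u = c(1, 1), v = c(1, 0), w = c(0, 2))
  S <- cosine_similarity(F)
  expect_equal(S["u", "v"], 0.7071, tolerance = 1e-4)
  expect_equal(S["v", "w"], 0)
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(S, t(S))

  # brute-force oracle on random nonnegative features
  G <- withr::with_seed(1, matrix(stats::runif(60), nrow = 6))
  SG <- cosine_similarity(G)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(SG[i, j],
                 sum(G[i, ] * G[j, ]) / sqrt(sum(G[i, ]^2) * sum(G[j, ]^2)),
                 tolerance = 1e-12)
  }
  expect_true(all(SG >= 0 & SG <= 1))

  # permuting feature columns leaves similarity unchanged
  perm <- withr::with_seed(2, sample(ncol(G)))
  expect_equal(cosine_similarity(G[, perm]), SG)

  expect_error(cosine_similarity(rbind(c(1, 1), c(0, 0))), "zero-norm")
})

test_that("2-D embedding is deterministic and keeps identical cells adjacent", {
  blobs <- make_blobs(rbind(c(0, 0), c(8, 8)), n_each = 30, seed = 3)
  feats <- cbind(blobs$coords, blobs$coords[, 1] + 1)  # 3 features
  c1 <- embed_2d(feats, rng_seed = 5, metric = "euclidean")
  c2 <- embed_2d(feats, rng_seed = 5, metric = "euclidean")
  expect_identical(c1, c2)
  expect_equal(dim(c1), c(60, 2))

  # two cells with identical features land in each other's immediate vicinity
  feats2 <- feats
  feats2[2, ] <- feats2[1, ]
  cc <- embed_2d(feats2, rng_seed = 5, metric = "euclidean")
  d <- as.matrix(stats::dist(cc))
  diag(d) <- Inf
  expect_lte(d[1, 2], stats::quantile(d[is.finite(d)], 0.01))

  expect_error(embed_2d(feats[1:14, ]), "at least 15")
})

test_that("adaptive dendrogram cut recovers blob structure at deep_split 4", {
  two <- make_blobs(rbind(c(0, 0), c(10, 0)), n_each = 20, spread = 0.5, seed = 1)
  cut2 <- cut_clusters(two$coords)
  expect_equal(attr(cut2, "k"), 2)
  expect_equal(adjusted_rand(cut2$cluster, two$membership), 1)

  one <- make_blobs(rbind(c(0, 0)), n_each = 40, spread = 0.5, seed = 2)
  cut1 <- cut_clusters(one$coords)
  expect_equal(attr(cut1, "k"), 1)

  three <- make_blobs(rbind(c(0, 0), c(12, 0), c(6, 10)), n_each = 15,
                      spread = 0.5, seed = 3)
  cut3 <- cut_clusters(three$coords)
  expect_equal(attr(cut3, "k"), 3)
  expect_equal(adjusted_rand(cut3$cluster, three$membership), 1)

  expect_error(cut_clusters(two$coords, min_size = 1000), "min_size")
  # defaults follow the documented configuration
  expect_equal(formals(cut_clusters)$deep_split, 4)
})

test_that("cluster labels are invariant to row permutation up to relabelling", {
  blobs <- make_blobs(rbind(c(0, 0), c(10, 0), c(5, 9)), n_each = 12, seed = 4)
  cut_a <- cut_clusters(blobs$coords)
  perm <- withr::with_seed(5, sample(nrow(blobs$coords)))
  cut_b <- cut_clusters(blobs$coords[perm, ])
  merged <- merge(cut_a, cut_b, by = "id")
  expect_equal(adjusted_rand(merged$cluster.x, merged$cluster.y), 1)
})

test_that("supercluster lumping is a user-supplied many-to-one mapping", {
  assignment <- tibble::tibble(id = letters[1:6], cluster = c(1, 1, 2, 2, 3, 3))
  lookup <- tibble::tibble(cluster = c(1, 2, 3),
                           supercluster = c("walk", "walk", "fly"))
  out <- assign_superclusters(assignment, lookup)
  expect_equal(out$supercluster, c("walk", "walk", "walk", "walk", "fly", "fly"))
})

test_that("group influence summaries have the documented shape and normalisation", {
  bp <- generate_body_plan(rng_seed = 6)
  gt <- bp$ground_truth$cells
  wmr <- rescale_to_stability(build_weight_matrix(bp$connectome))
  parts <- unique(stats::na.omit(gt$body_part))
  sensors <- lapply(parts, function(p) {
    gt$id[!is.na(gt$body_part) & gt$body_part == p & gt$role == "sensor"]
  })
  names(sensors) <- paste0(parts, "_sensors")
  bridge <- gt[gt$role %in% c("AN-like", "DN-like"), ]
  assignment <- tibble::tibble(
    id = bridge$id,
    cluster = as.integer(factor(bridge$role)),
    supercluster = bridge$role
  )
  m <- group_influence_summary(wmr, assignment, sensors,
                               direction = "onto_clusters")
  expect_equal(dim(m), c(2, length(sensors)))
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(apply(m, 1, max) == 1))  # minmax rows hit 1

  expect_message(
    group_influence_summary(wmr, assignment,
                            c(sensors, list(empty = character(0)))),
    "empty"
  )
})

test_that("cross-cluster influence is pool-size normalised and detects asymmetric bridges", {
  # planted one-way bridge: cluster g drives cluster h, not vice versa
  edges <- toy_edges(
    list("g1", "g2", 5), list("g2", "g1", 5),
    list("h1", "h2", 5), list("h2", "h1", 5),
    list("g1", "h1", 4), list("g2", "h2", 4)
  )
  cn <- connectome(edges)
  wmr <- rescale_to_stability(build_weight_matrix(cn))
  assignment <- tibble::tibble(
    id = c("g1", "g2", "h1", "h2"),
    cluster = c(1, 1, 2, 2),
    supercluster = c("g", "g", "h", "h")
  )
  m <- cross_cluster_influence(wmr, assignment)
  expect_equal(dim(m), c(2, 2))
  expect_gt(m["g", "h"], m["h", "g"])
  expect_named(attr(m, "self"), c("g", "h"))

  # no connecting path: off-diagonals floor at 0
  cn2 <- connectome(toy_edges(list("a1", "a2", 3), list("a2", "a1", 3),
                              list("b1", "b2", 3), list("b2", "b1", 3)))
  wm2 <- rescale_to_stability(build_weight_matrix(cn2))
  asg2 <- tibble::tibble(id = c("a1", "a2", "b1", "b2"),
                         cluster = c(1, 1, 2, 2),
                         supercluster = c("a", "a", "b", "b"))
  m2 <- cross_cluster_influence(wm2, asg2)
  expect_equal(unname(m2["a", "b"]), 0)
  expect_equal(unname(m2["b", "a"]), 0)

  expect_error(cross_cluster_influence(wmr, assignment[assignment$supercluster == "g", ]),
               "at least 2")
})

test_that("planted effector groups are recovered end to end from influence profiles", {
  # three effector groups with distinct AN/DN influence profiles: the
  # features -> cosine -> embed -> cut pipeline must recover the planted
  # memberships (high within-group, low between-group similarity).
  n_seeds <- 12
  n_per_group <- 18
  withr::with_seed(10, {
    base <- diag(3)[rep(1:3, each = 4), ]      # seed blocks per group
    profiles <- do.call(rbind, lapply(1:3, function(g) {
      t(replicate(n_per_group,
                  base[, g] * stats::runif(n_seeds, 8, 20) +
                    stats::runif(n_seeds, 0, 0.6)))
    }))
  })
  rownames(profiles) <- paste0("eff", seq_len(nrow(profiles)))
  truth <- rep(1:3, each = n_per_group)
  S <- cosine_similarity(profiles)
  within <- mean(S[outer(truth, truth, `==`) & row(S) != col(S)])
  between <- mean(S[outer(truth, truth, `!=`)])
  expect_gt(within, 0.8)
  expect_lt(between, 0.2)

  coords <- embed_2d(profiles, rng_seed = 2)
  cut <- cut_clusters(coords)
  expect_gte(adjusted_rand(cut$cluster, truth), 0.9)
})
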