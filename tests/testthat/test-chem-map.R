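test_that("reaction featurization concatenates per-component blocks", {
  cfg <- fingerprint_config(n_bits = 1024)
  rec <- data.frame(
    sub_a = "NCCc1c[nH]c2ccccc12", sub_b = "O=Cc1ccccc1",
    catalyst = "O=C(Nc1ccccc1)NC", cocatalyst = "OC(=O)c1ccccc1",
    solvent = "toluene", stringsAsFactors = FALSE
  )
  x <- featurize_reactions(rec, cfg)
  expect_equal(dim(x), c(1, 5 * 1024))
  expect_gt(sum(x), 0)

  # absent co-catalyst gives an all-zero block
  rec2 <- rec; rec2$cocatalyst <- NA_character_
  x2 <- featurize_reactions(rec2, cfg)
  block2 <- 1024 + seq_len(1024)
  expect_equal(sum(x2[, block2]), 0)

  # records identical except the co-catalyst differ only inside its block
  rec3 <- rec; rec3$cocatalyst <- "CC(=O)O"
  x3 <- featurize_reactions(rec3, cfg)
  diff_cols <- which(as.matrix(x) != as.matrix(x3))
  expect_true(all(diff_cols %in% block2))
  expect_gt(length(diff_cols), 0)

  # pure function: byte-identical on repeated calls
  expect_identical(as.matrix(featurize_reactions(rec, cfg)), as.matrix(x))

  # unparseable SMILES names the component
  bad <- rec; bad$sub_b <- "xx(("
  expect_error(featurize_reactions(bad, cfg), "sub_b")
})

test_that("map embedding is deterministic and preserves duplicates/clusters", {
  set.seed(10)
  base <- matrix(stats::rbinom(30 * 64, 1, 0.3), nrow = 30)
  x <- base[c(1:30, 1), ]  # row 31 duplicates row 1

  m1 <- embed_map(x, pca_dims = 10, perplexity = 5, seed = 4)
  m2 <- embed_map(x, pca_dims = 10, perplexity = 5, seed = 4)
  expect_identical(m1$coords, m2$coords)

  # duplicates coincide after the exact PCA stage
  expect_lt(sqrt(sum((m1$pca_coords[31, ] - m1$pca_coords[1, ])^2)), 1e-6)

  expect_error(embed_map(x[1:2, ], perplexity = 1), "at least 3")
  expect_error(embed_map(x, perplexity = 30), "perplexity")

  # three well-separated fingerprint clusters stay separated on the map
  set.seed(11)
  centers <- matrix(stats::rbinom(3 * 256, 1, 0.5), nrow = 3)
  labels <- rep(1:3, each = 25)
  clustered <- centers[labels, ]
  flip <- matrix(stats::runif(length(clustered)) < 0.02, nrow = nrow(clustered))
  clustered <- abs(clustered - flip)  # small intra-cluster Hamming noise
  m <- embed_map(clustered, pca_dims = 20, perplexity = 8, seed = 5)
  expect_gt(mean_silhouette(m$coords, labels), 0.5)
})

test_that("farthest point sampling is greedy maximin with stable ties", {
  expect_equal(farthest_point_sample(matrix(c(0, 1, 10)), 2), c(3, 1))

  set.seed(12)
  pts <- matrix(stats::rnorm(40), ncol = 2)
  expect_setequal(farthest_point_sample(pts, 20), 1:20)
  expect_error(farthest_point_sample(pts, 21), "between 1 and")

  # per-step agreement with the brute-force oracle on random clouds
  for (rep in 1:5) {
    set.seed(100 + rep)
    cloud <- matrix(stats::rnorm(100), ncol = 2)
    expect_identical(farthest_point_sample(cloud, 10), fps_oracle(cloud, 10))
  }

  # permutation equivariance up to the deterministic tie-break
  set.seed(13)
  cloud <- matrix(stats::rnorm(60), ncol = 2)
  perm <- sample.int(30)
  sel <- farthest_point_sample(cloud, 8)
  sel_perm <- farthest_point_sample(cloud[perm, ], 8)
  expect_setequal(perm[sel_perm], sel)
})

test_that("panel selection returns k unique, diverse, reproducible pairs", {
  ls <- small_landscape()
  cross <- expand.grid(sub_a = ls$sub_a, sub_b = ls$sub_b,
                       stringsAsFactors = FALSE)
  # duplicated records collapse to unique pairs before selection
  recs <- cross[rep(seq_len(nrow(cross)), 2), ]

  p1 <- select_panel(recs, k = 20, perplexity = 10, seed = 6)
  expect_equal(nrow(p1), 20)
  expect_equal(anyDuplicated(paste(p1$sub_a, p1$sub_b)), 0)

  p2 <- select_panel(recs, k = 20, perplexity = 10, seed = 6)
  expect_identical(as.data.frame(p1), as.data.frame(p2))

  expect_error(select_panel(cross, k = nrow(cross) + 1), "unique substrate pairs")

  # diversity: mean nearest-neighbor distance beats random subsets
  map <- attr(p1, "map")
  coords <- map$coords
  nn_mean <- function(idx) {
    d <- as.matrix(stats::dist(coords[idx, ]))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  fps_nn <- nn_mean(p1$map_index)
  set.seed(14)
  rand_nn <- mean(replicate(100, nn_mean(sample.int(nrow(coords), 20))))
  expect_gte(fps_nn, rand_nn)

  # fingerprint-space (Jaccard) selection: deterministic, no map involved
  pf1 <- select_panel(recs, k = 20, space = "fingerprint")
  pf2 <- select_panel(recs, k = 20, space = "fingerprint")
  expect_identical(as.data.frame(pf1), as.data.frame(pf2))
  expect_equal(nrow(pf1), 20)
})

test_that("distance-matrix FPS matches the greedy maximin definition", {
  set.seed(15)
  pts <- matrix(stats::rnorm(80), ncol = 2)
  D <- as.matrix(stats::dist(pts))
  sel <- farthest_point_sample_dist(D, 12)
  expect_equal(anyDuplicated(sel), 0)
  # after the start point, each pick maximizes the min distance to the set
  for (i in 2:12) {
    chosen <- sel[seq_len(i - 1L)]
    mind <- apply(D[, chosen, drop = FALSE], 1, min)
    mind[chosen] <- -Inf
    expect_equal(sel[i], unname(which.max(mind)))
  }
})
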