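# restricted-growth-string enumeration of all set partitions of n items
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(code, maxc) {
    if (length(code) == n) {
      out[[length(out) + 1L]] <<- code
      return(invisible())
    }
    for (c in 0:(maxc + 1L)) rec(c(code, c), max(maxc, c))
  }
  rec(integer(0), -1L)
  out
}

test_that("Laplacian spectra match closed forms and count components", {
  expect_equal(laplacian_spectrum(path3_net(), "unnormalized"), c(0, 1, 3),
               tolerance = 1e-10)
  expect_equal(laplacian_spectrum(k2_net(), "unnormalized"), c(0, 2),
               tolerance = 1e-10)
  for (v in c("unnormalized", "sym", "rw")) {
    ev <- laplacian_spectrum(two_triangles_net(), v)
    expect_equal(sum(abs(ev) < 1e-9), 2L)    # one zero per component
  }
  # isolated node: zero-degree convention keeps a zero eigenvalue
  net <- net_from_edges(3L, list(c(1, 2)))
  expect_equal(sum(abs(laplacian_spectrum(net, "sym")) < 1e-9), 2L)

  tab <- spectrum_table(path3_net(), "unnormalized")
  expect_equal(tab$index, 0:2)
  expect_equal(tab$eigenvalue, c(0, 1, 3), tolerance = 1e-10)
})

test_that("zero-eigenvalue multiplicity equals component count (random graphs)", {
  set.seed(5)
  for (rep in 1:25) {
    net <- random_net(sample(4:10, 1), stats::runif(1, 0.15, 0.6))
    ncomp <- igraph::components(as_igraph(net))$no
    ev <- laplacian_spectrum(net, "unnormalized")
    expect_equal(sum(abs(ev) < 1e-8), ncomp)
  }
})

test_that("spectral clustering recovers components exactly and honors k bounds", {
  net <- two_triangles_net()
  for (v in c("unnormalized", "sym", "rw")) {
    p <- spectral_clustering(net, 2, v, seed = 3)
    expect_equal(unname(p$labels), c(0, 0, 0, 1, 1, 1))
  }
  pN <- spectral_clustering(net, 6, "unnormalized", seed = 1)
  expect_equal(sort(unname(pN$labels)), 0:5)      # every node its own cluster
  expect_error(spectral_clustering(net, 7, "unnormalized"), "k <= N")
})

test_that("HOPE-Katz embedding factorizes the hand-inverted Katz matrix", {
  # K2, beta = 0.1: S = (I - bA)^{-1} bA computed by 2x2 inversion
  S <- matrix(c(0.0101, 0.1010, 0.1010, 0.0101), 2)
  emb <- embed_network(k2_net(), "hope_katz", d = 2, beta = 0.1)
  V <- emb$vectors
  e <- eigen(S)
  gram_expected <- e$vectors %*% diag(abs(e$values)) %*% t(e$vectors)
  expect_equal(V %*% t(V), gram_expected, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(embed_network(k2_net(), "hope_katz", d = 1, beta = 1.5),
               "diverges")
})

test_that("Laplacian eigenmap separates components along the Fiedler vector", {
  emb <- embed_network(two_triangles_net(), "laplacian_eigenmap", d = 1)
  v <- emb$vectors[, 1]
  expect_lt(max(abs(v[1:3] - v[1])), 1e-8)        # constant per component
  expect_lt(max(abs(v[4:6] - v[4])), 1e-8)
  expect_lt(v[1] * v[4], 0)                       # opposite signs
  # full-rank HOPE embedding at d = N is legal
  expect_silent(embed_network(k3_net(), "hope_katz", d = 3, beta = 0.1))
  expect_error(embed_network(k3_net(), "laplacian_eigenmap", d = 3), "N-1")
})

test_that("embedded clustering recovers components and is seed-deterministic", {
  net <- two_triangles_net()
  p <- embedded_clustering(net, "laplacian_eigenmap", d = 1, k = 2, seed = 9)
  expect_equal(unname(p$labels), c(0, 0, 0, 1, 1, 1))
  p2 <- embedded_clustering(net, "laplacian_eigenmap", d = 1, k = 2, seed = 9)
  expect_identical(p$labels, p2$labels)
})

test_that("Girvan-Newman removes the bridge of the barbell first", {
  net <- two_triangles_net(bridge = TRUE)
  # oracle: the bridge carries all 3x3 cross-component shortest paths
  g <- as_igraph(net)
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  ends <- igraph::as_edgelist(g, names = FALSE)
  bridge <- which(ends[, 1] == 3 & ends[, 2] == 4)
  expect_equal(eb[bridge], 9)
  expect_equal(max(eb[-bridge]) < 9, TRUE)

  p <- community_detect(net, "girvan_newman", k = 2)
  expect_equal(unname(p$labels), c(0, 0, 0, 1, 1, 1))
})

test_that("greedy modularity finds the Q-maximal partition of the barbell", {
  net <- two_triangles_net(bridge = TRUE)
  triangles <- c(0, 0, 0, 1, 1, 1)
  # exhaustive oracle over all 203 set partitions of 6 nodes
  qs <- vapply(all_set_partitions(6L), function(code) {
    modularity_score(net, partition_of(net, code))
  }, numeric(1L))
  best <- max(qs)
  expect_equal(modularity_score(net, partition_of(net, triangles)), best)

  p <- community_detect(net, "greedy_modularity")
  expect_equal(unname(p$labels), triangles)
})

test_that("label propagation and louvain respect components and seeds", {
  net <- two_triangles_net()
  p <- community_detect(net, "label_propagation", seed = 4)
  expect_equal(unname(p$labels), c(0, 0, 0, 1, 1, 1))
  l1 <- community_detect(net, "louvain", seed = 4)
  l2 <- community_detect(net, "louvain", seed = 4)
  expect_identical(l1$labels, l2$labels)
  expect_error(community_detect(net_from_A(matrix(0L, 3, 3)), "louvain"),
               "edge")
})

test_that("modularity matches hand values and the igraph cross-check", {
  net <- two_triangles_net(bridge = TRUE)
  expect_equal(modularity_score(net, partition_of(net, c(0, 0, 0, 1, 1, 1))),
               5 / 14)
  expect_equal(modularity_score(net, partition_of(net, rep(0, 6))), 0)
  expect_equal(modularity_score(k3_net(), partition_of(k3_net(), 0:2)), -1 / 3)

  set.seed(21)
  for (rep in 1:10) {
    rnet <- random_net(7L, 0.5)
    if (sum(rnet$A) == 0) next
    code <- sample(0:2, 7, replace = TRUE)
    expect_equal(modularity_score(rnet, partition_of(rnet, code)),
                 igraph::modularity(as_igraph(rnet), code + 1L),
                 tolerance = 1e-12)
  }
})

test_that("planted-partition generator honors degenerate probabilities and seed", {
  hard <- generate_planted_partition(2, 3, p_in = 1, p_out = 1e-9, seed = 1)
  expect_equal(hard$net$A, two_triangles_net()$A, ignore_attr = TRUE)
  a <- generate_planted_partition(4, 15, 0.9, 0.05, seed = 33)
  b <- generate_planted_partition(4, 15, 0.9, 0.05, seed = 33)
  expect_identical(a$net$A, b$net$A)
  expect_equal(a$membership, rep(0:3, each = 15))

  # within-block edge total over 100 seeds is binomial(100*b*C(s,2), p_in)
  blocks <- 2L; size <- 6L; p_in <- 0.7
  within <- vapply(1:100, function(s) {
    g <- generate_planted_partition(blocks, size, p_in, 0.1, seed = s)
    same <- outer(g$membership, g$membership, "==")
    sum(g$net$A[same & upper.tri(g$net$A)])
  }, numeric(1L))
  ntrials <- 100 * blocks * choose(size, 2)
  expect_lt(abs(sum(within) - ntrials * p_in),
            3 * sqrt(ntrials * p_in * (1 - p_in)))
})

test_that("adjusted Rand index agrees with the mclust reference", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(8)
  for (rep in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("partitions always use canonical contiguous labels", {
  set.seed(13)
  sb <- generate_planted_partition(3, 8, 0.85, 0.08, seed = 2)
  parts <- list(
    spectral_clustering(sb$net, 3, "sym", seed = 5),
    embedded_clustering(sb$net, "hope_katz", d = 4, k = 3, seed = 5),
    community_detect(sb$net, "louvain", seed = 5),
    community_detect(sb$net, "greedy_modularity", seed = 5),
    community_detect(sb$net, "label_propagation", seed = 5),
    community_detect(sb$net, "girvan_newman", seed = 5, k = 3)
  )
  for (p in parts) {
    expect_equal(sort(unique(unname(p$labels))), 0:(p$k - 1L))
    expect_equal(length(p$labels), 24L)
    # community partitions never score below the one-cluster baseline
    if (grepl("louvain|greedy|label|girvan", p$method)) {
      expect_gte(modularity_score(sb$net, p), 0)
    }
  }
})
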