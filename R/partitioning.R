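# Spectral clustering, embedded clustering, community extraction,
# modularity, and a planted-partition fixture generator.
#
# All partition-returning functions share two conventions:
#   * labels are canonical: clusters are renumbered 0..k-1 in order of
#     first node occurrence, so identical partitions compare equal;
#   * with equal seed every method returns identical labels.

new_partition <- function(cluster, labels, method, params, seed) {
  cl <- canonical_relabel(cluster)
  names(cl) <- labels
  structure(list(labels = cl, k = length(unique(cl)), method = method,
                 params = params, seed = as.integer(seed)),
            class = "pcn_partition")
}

canonical_relabel <- function(cluster) {
  first <- unique(cluster)
  match(cluster, first) - 1L
}

#' @export
print.pcn_partition <- function(x, ...) {
  cat(sprintf("pcn_partition: %d nodes in %d clusters (%s, seed %d)\n",
              length(x$labels), x$k, x$method, x$seed))
  cat("  cluster sizes:", paste(tabulate(x$labels + 1L), collapse = " "), "\n")
  invisible(x)
}

# --- Laplacians ------------------------------------------------------------

laplacian_matrix <- function(net, variant = c("unnormalized", "sym", "rw")) {
  variant <- match.arg(variant)
  A <- net$A
  storage.mode(A) <- "double"
  deg <- rowSums(A)
  if (variant == "unnormalized") return(diag(deg) - A)
  # normalized variants: isolated nodes keep a 0 diagonal entry so each
  # contributes a 0 eigenvalue, matching the unnormalized component count
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- -A * outer(dinv, dinv)
  diag(L) <- ifelse(deg > 0, 1, 0)
  L # L_sym; L_rw is similar to it (D^{-1/2} L_sym D^{1/2}) and shares its spectrum
}

#' Graph-Laplacian eigenvalue spectrum
#'
#' Eigenvalues of `L = D - A` (`"unnormalized"`),
#' `L_sym = I - D^{-1/2} A D^{-1/2}` (`"sym"`), or
#' `L_rw = I - D^{-1} A` (`"rw"`; similar to `L_sym`, identical
#' spectrum). The multiplicity of eigenvalue 0 equals the number of
#' connected components; in the normalized variants an isolated node
#' contributes eigenvalue 0 by the zero-degree convention.
#'
#' @param net a `contact_network` with at least 2 nodes.
#' @param variant Laplacian variant.
#' @return numeric vector of N eigenvalues in ascending order.
#' @export
laplacian_spectrum <- function(net, variant = c("unnormalized", "sym", "rw")) {
  stopifnot(inherits(net, "contact_network"), nrow(net$A) >= 2L)
  L <- laplacian_matrix(net, variant)
  sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
}

# --- k-means with a fixed contract ----------------------------------------
#
# k-means++ seeding, 10 restarts, Lloyd iterations, best total
# within-cluster sum of squares; fully determined by the seed.

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k == 1L) return(idx)
  d2 <- colSums((t(x) - x[idx[1L], ])^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      avail <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- avail[sample.int(length(avail), 1L)]
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, colSums((t(x) - x[idx[j], ])^2))
  }
  idx
}

kmeans_seeded <- function(x, k, seed, nstart = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k cannot exceed the number of nodes", call. = FALSE)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  if (k == n) return(seq_len(n))          # every node its own cluster
  if (k == 1L) return(rep(1L, n))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- x[kmeanspp_init(x, k), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("k-means failed for every restart (degenerate input?)",
                          call. = FALSE)
  best$cluster
}

# --- spectral clustering ---------------------------------------------------

spectral_coords <- function(net, k, variant) {
  L <- laplacian_matrix(net, variant)
  n <- nrow(L)
  e <- eigen(L, symmetric = TRUE)
  U <- e$vectors[, seq(n, n - k + 1L), drop = FALSE]  # k smallest, ascending
  if (variant == "sym") {
    nrm <- sqrt(rowSums(U^2))
    nrm[nrm == 0] <- 1
    U <- U / nrm
  } else if (variant == "rw") {
    deg <- rowSums(net$A)
    scale <- ifelse(deg > 0, 1 / sqrt(deg), 1)
    U <- U * scale
  }
  U
}

#' Spectral clustering of a contact network
#'
#' Embeds nodes in the eigenvectors of the k smallest Laplacian
#' eigenvalues (for the `"sym"` variant the embedding rows are scaled to
#' unit norm; for `"rw"` the symmetric eigenvectors are back-transformed
#' by `D^{-1/2}`) and clusters them with seeded k-means (k-means++
#' initialization, 10 restarts, best inertia).
#'
#' @param net a `contact_network`.
#' @param k number of clusters, `2 <= k <= N`.
#' @param variant Laplacian variant, see [laplacian_spectrum()].
#' @param seed RNG seed for k-means.
#' @return a `pcn_partition` with canonical 0-based cluster labels.
#' @export
spectral_clustering <- function(net, k,
                                variant = c("unnormalized", "sym", "rw"),
                                seed = 1L) {
  stopifnot(inherits(net, "contact_network"))
  variant <- match.arg(variant)
  n <- nrow(net$A)
  if (k < 2L || k > n) stop("need 2 <= k <= N", call. = FALSE)
  U <- spectral_coords(net, k, variant)
  cl <- kmeans_seeded(U, k, seed)
  new_partition(cl, net$labels, method = paste0("spectral_", variant),
                params = list(k = k, variant = variant), seed = seed)
}

# --- node embeddings -------------------------------------------------------

#' Low-dimensional node embedding
#'
#' `"laplacian_eigenmap"` uses eigenvectors 2..d+1 (ascending
#' eigenvalue) of the unnormalized Laplacian, the classical spectral
#' embedding with the constant eigenvector dropped. `"hope_katz"`
#' factorizes the Katz similarity matrix `S = (I - beta*A)^{-1} beta*A`
#' by truncated SVD and uses `U_d sqrt(Sigma_d)` as node coordinates, a
#' similarity-preserving embedding suited to dense contact graphs; it
#' requires `beta < 1/rho(A)` (spectral radius) for the Katz series to
#' converge.
#'
#' @param net a `contact_network`.
#' @param method `"laplacian_eigenmap"` or `"hope_katz"`.
#' @param d embedding dimension (`d <= N`; the eigenmap additionally
#'   needs `d <= N-1` since the constant eigenvector is dropped).
#' @param beta Katz attenuation factor.
#' @return `pcn_embedding`: list with `vectors` (N x d matrix, rows named
#'   by node label), `d`, `method`, `params`.
#' @export
embed_network <- function(net, method = c("laplacian_eigenmap", "hope_katz"),
                          d, beta = 0.05) {
  stopifnot(inherits(net, "contact_network"))
  method <- match.arg(method)
  A <- net$A
  storage.mode(A) <- "double"
  n <- nrow(A)
  if (d < 1L || d > n) stop("need 1 <= d <= N", call. = FALSE)

  if (method == "laplacian_eigenmap") {
    if (d > n - 1L) stop("laplacian_eigenmap needs d <= N-1", call. = FALSE)
    e <- eigen(laplacian_matrix(net, "unnormalized"), symmetric = TRUE)
    asc <- e$vectors[, rev(seq_len(n)), drop = FALSE]
    V <- asc[, seq(2L, d + 1L), drop = FALSE]
    # project out the trivial constant direction: a no-op for connected
    # graphs, but on disconnected ones the degenerate 0-eigenspace basis
    # returned by the solver may overlap the all-ones vector
    V <- scale(V, center = TRUE, scale = FALSE)
    nrm <- sqrt(colSums(V^2))
    for (j in which(nrm > 1e-12)) V[, j] <- V[, j] / nrm[j]
    attr(V, "scaled:center") <- NULL
    params <- list()
  } else {
    rho <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
    if (rho > 0 && beta >= 1 / rho) {
      stop(sprintf("Katz series diverges: beta = %g >= 1/rho(A) = %g",
                   beta, 1 / rho), call. = FALSE)
    }
    S <- solve(diag(n) - beta * A, beta * A)
    sv <- svd(S, nu = d, nv = 0L)
    V <- sv$u %*% diag(sqrt(sv$d[seq_len(d)]), nrow = d)
    params <- list(beta = beta)
  }
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(V))) {
    lead <- which.max(abs(V[, j]))
    if (V[lead, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- net$labels
  structure(list(vectors = V, d = as.integer(d), method = method,
                 params = params),
            class = "pcn_embedding")
}

#' Clustering in an embedding space
#'
#' Embeds the network with [embed_network()] and clusters the node
#' vectors with the same seeded k-means contract used by
#' [spectral_clustering()].
#'
#' @inheritParams embed_network
#' @param k number of clusters, `2 <= k <= N`.
#' @param seed RNG seed for k-means.
#' @return a `pcn_partition`.
#' @export
embedded_clustering <- function(net, method = c("laplacian_eigenmap", "hope_katz"),
                                d, k, seed = 1L, beta = 0.05) {
  method <- match.arg(method)
  n <- nrow(net$A)
  if (k < 2L || k > n) stop("need 2 <= k <= N", call. = FALSE)
  emb <- embed_network(net, method, d = d, beta = beta)
  cl <- kmeans_seeded(emb$vectors, k, seed)
  new_partition(cl, net$labels, method = paste0("embedded_", method),
                params = list(k = k, d = d, beta = beta), seed = seed)
}

# --- community extraction --------------------------------------------------

#' Community extraction
#'
#' Four community methods over the contact graph:
#' \describe{
#'   \item{louvain}{seeded Louvain modularity optimization at the given
#'     resolution.}
#'   \item{greedy_modularity}{Clauset-Newman-Moore greedy agglomeration.}
#'   \item{label_propagation}{asynchronous label propagation with seeded
#'     node order, run to convergence.}
#'   \item{girvan_newman}{repeatedly removes the edge of maximum edge
#'     betweenness (ties broken by lowest edge index) until the graph has
#'     at least `k` components; the components are the communities.}
#' }
#'
#' @param net a `contact_network` with at least one edge.
#' @param method community method.
#' @param seed RNG seed (Louvain and label propagation are stochastic;
#'   the others are deterministic but record the seed for provenance).
#' @param k target component count for `girvan_newman` (ignored otherwise).
#' @param resolution Louvain resolution parameter.
#' @return a `pcn_partition`.
#' @export
community_detect <- function(net,
                             method = c("louvain", "greedy_modularity",
                                        "label_propagation", "girvan_newman"),
                             seed = 1L, k = 2L, resolution = 1.0) {
  stopifnot(inherits(net, "contact_network"))
  method <- match.arg(method)
  if (sum(net$A) == 0) stop("community extraction needs at least one edge",
                            call. = FALSE)
  g <- as_igraph(net)
  cl <- switch(method,
    louvain = {
      set.seed(seed)
      igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
    },
    greedy_modularity = igraph::membership(igraph::cluster_fast_greedy(g)),
    label_propagation = {
      set.seed(seed)
      igraph::membership(igraph::cluster_label_prop(g))
    },
    girvan_newman = {
      if (k < 1L || k > nrow(net$A)) stop("need 1 <= k <= N", call. = FALSE)
      gg <- g
      while (igraph::components(gg)$no < k && igraph::ecount(gg) > 0L) {
        eb <- igraph::edge_betweenness(gg, directed = FALSE)
        gg <- igraph::delete_edges(gg, which(eb >= max(eb) - 1e-9)[1L])
      }
      igraph::components(gg)$membership
    }
  )
  params <- list(resolution = if (method == "louvain") resolution else NULL,
                 k = if (method == "girvan_newman") as.integer(k) else NULL)
  new_partition(as.integer(cl), net$labels, method = method,
                params = params[!vapply(params, is.null, logical(1L))],
                seed = seed)
}

#' Newman modularity of a partition
#'
#' `Q = sum_s [ e_s/m - (d_s/2m)^2 ]` where `e_s` is the number of edges
#' inside cluster s, `d_s` the total degree of its nodes and `m` the
#' number of edges in the graph.
#'
#' @param net a `contact_network` with at least one edge.
#' @param partition a `pcn_partition` of `net`.
#' @return scalar Q.
#' @export
modularity_score <- function(net, partition) {
  stopifnot(inherits(net, "contact_network"), inherits(partition, "pcn_partition"))
  check_partition_matches(net, partition)
  A <- net$A
  m <- sum(A) / 2
  if (m == 0) stop("modularity needs at least one edge", call. = FALSE)
  cl <- partition$labels
  deg <- rowSums(A)
  q <- 0
  for (s in unique(cl)) {
    members <- which(cl == s)
    e_s <- sum(A[members, members, drop = FALSE]) / 2
    d_s <- sum(deg[members])
    q <- q + e_s / m - (d_s / (2 * m))^2
  }
  q
}

check_partition_matches <- function(net, partition) {
  if (length(partition$labels) != length(net$labels) ||
      !identical(names(partition$labels), net$labels)) {
    stop("partition does not match the network's nodes", call. = FALSE)
  }
  invisible(TRUE)
}

# --- planted-partition fixture --------------------------------------------

#' Planted-partition (stochastic block model) fixture
#'
#' Generates a symmetric 0/1 adjacency with `blocks` equal groups of
#' `size` nodes; within-group pairs connect with probability `p_in`,
#' between-group pairs with `p_out`. The ground-truth membership is
#' returned for scoring clustering recovery (e.g. with
#' [adjusted_rand_index()]). Fully determined by `seed`.
#'
#' @param blocks number of planted groups.
#' @param size nodes per group.
#' @param p_in,p_out edge probabilities, `p_in > p_out`, both in \[0, 1\].
#' @param seed RNG seed.
#' @return list with `net` (a `contact_network`, labels `n0..`) and
#'   `membership` (integer ground-truth labels, 0-based).
#' @export
generate_planted_partition <- function(blocks, size, p_in, p_out, seed = 1L) {
  stopifnot(blocks >= 1L, size >= 1L,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  if (!(p_in > p_out)) stop("p_in must exceed p_out", call. = FALSE)
  n <- blocks * size
  membership <- rep(seq_len(blocks) - 1L, each = size)
  prob <- ifelse(outer(membership, membership, "=="), p_in, p_out)
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- as.integer(stats::runif(sum(up)) < prob[up])
  A <- A + t(A)
  net <- new_contact_network(paste0("n", seq_len(n) - 1L), A,
                             params = list(mode = "sbm", d_min = NA, d_max = NA,
                                           blocks = blocks, size = size,
                                           p_in = p_in, p_out = p_out,
                                           seed = as.integer(seed)))
  list(net = net, membership = membership)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table by the
#' closed-form Hubert-Arabie formula; 1 means identical partitions, 0 is
#' the expectation under random labelings.
#'
#' @param a,b label vectors of equal length (any label coding).
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  npairs <- choose(length(a), 2)
  expected <- ai * bj / npairs
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}

#' Laplacian spectrum table for export
#'
#' @param net a `contact_network`.
#' @param variant Laplacian variant, see [laplacian_spectrum()].
#' @return data.frame with `index` (0-based, ascending eigenvalue order)
#'   and `eigenvalue`.
#' @export
spectrum_table <- function(net, variant = c("unnormalized", "sym", "rw")) {
  ev <- laplacian_spectrum(net, variant)
  data.frame(index = seq_along(ev) - 1L, eigenvalue = ev)
}

#' Partition table for export
#'
#' @param net a `contact_network`.
#' @param partition a `pcn_partition` of `net`.
#' @return data.frame with `node_index`, `chain`, `res_seq`, `res_name`,
#'   `cluster`.
#' @export
partition_table <- function(net, partition) {
  check_partition_matches(net, partition)
  n <- length(net$labels)
  if (!is.null(net$nodes)) {
    data.frame(node_index = net$nodes$index, chain = net$nodes$chain,
               res_seq = net$nodes$res_seq, res_name = net$nodes$res_name,
               cluster = unname(partition$labels), stringsAsFactors = FALSE)
  } else {
    data.frame(node_index = seq_len(n) - 1L, chain = NA_character_,
               res_seq = NA_integer_, res_name = NA_character_,
               cluster = unname(partition$labels), stringsAsFactors = FALSE)
  }
}
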