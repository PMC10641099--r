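# Centrality analysis on contact networks.
#
# Shortest-path quantities (betweenness, BFS distances) are delegated to
# igraph; the surrounding normalizations follow the conventions below so
# that results are comparable across structures of different size:
#   degree      normalized by N-1
#   betweenness Brandes count over unordered pairs, normalized by
#               (N-1)(N-2)/2
#   closeness   per connected component, with the Wasserman-Faust
#               component-size correction so multi-chain or broken
#               structures do not crash or distort
#   eigenvector power iteration on A + I (the shift makes the iteration
#               convergent on bipartite components), unit Euclidean norm,
#               nonnegative sign convention

#' Node centrality of a contact network
#'
#' @param net a `contact_network`.
#' @param metric one of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"eigenvector"`.
#' @param tol convergence tolerance of the eigenvector power iteration
#'   (max absolute change between successive unit vectors).
#' @param max_iter iteration cap for the power iteration.
#' @return `pcn_centrality`: list with `metric`, `raw` and `normalized`
#'   named vectors, and `params` (for eigenvector: tolerance, iterations
#'   used and the Rayleigh-quotient eigenvalue).
#' @details Raw values are the unscaled quantities (row-sum degree,
#'   Brandes pair counts, inverse total distance, eigenvector scaled to
#'   max 1). Normalized values are size-corrected and are what the
#'   annotation writer maps onto structures by default. The eigenvector
#'   metric errors on an edgeless graph and reports the residual if the
#'   iteration fails to converge within `max_iter`.
#' @examples
#' net <- read_adjacency_file("0 1 0\n1 0 1\n0 1 0\n")
#' centrality(net, "degree")$raw
#' @export
centrality <- function(net, metric = c("degree", "betweenness",
                                       "closeness", "eigenvector"),
                       tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(net, "contact_network"))
  metric <- match.arg(metric)
  A <- net$A
  n <- nrow(A)
  params <- NULL

  if (metric == "degree") {
    raw <- rowSums(A)
    normalized <- if (n > 1L) raw / (n - 1L) else raw * 0
  } else if (metric == "betweenness") {
    g <- as_igraph(net)
    raw <- igraph::betweenness(g, directed = FALSE, weights = NULL)
    denom <- (n - 1) * (n - 2) / 2
    normalized <- if (denom > 0) raw / denom else raw * 0
  } else if (metric == "closeness") {
    g <- as_igraph(net)
    D <- igraph::distances(g)
    comp <- igraph::components(g)$membership
    raw <- normalized <- numeric(n)
    for (i in seq_len(n)) {
      members <- which(comp == comp[i])
      n_c <- length(members)
      s <- sum(D[i, members])
      if (n_c > 1L && s > 0) {
        raw[i] <- 1 / s
        normalized[i] <- ((n_c - 1) / s) * ((n_c - 1) / (n - 1))
      }
    }
  } else { # eigenvector
    if (sum(A) == 0) stop("eigenvector centrality undefined on an edgeless graph",
                          call. = FALSE)
    M <- A + diag(n)
    v <- rep(1, n) / sqrt(n)
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      w <- as.numeric(M %*% v)
      w <- w / sqrt(sum(w^2))
      if (max(abs(w - v)) < tol) {
        v <- w
        converged <- TRUE
        break
      }
      v <- w
    }
    lambda <- as.numeric(t(v) %*% A %*% v)
    if (!converged) {
      resid <- sqrt(sum((as.numeric(A %*% v) - lambda * v)^2))
      stop(sprintf(
        "eigenvector power iteration did not converge in %d iterations (residual %.3g)",
        max_iter, resid), call. = FALSE)
    }
    v <- abs(v) # nonnegative sign convention (entries are already >= 0)
    normalized <- v
    raw <- if (max(v) > 0) v / max(v) else v
    params <- list(tol = tol, max_iter = as.integer(max_iter),
                   iterations = iter, lambda = lambda)
  }

  names(raw) <- names(normalized) <- net$labels
  structure(list(metric = metric, raw = raw, normalized = normalized,
                 params = params),
            class = "pcn_centrality")
}

#' @export
print.pcn_centrality <- function(x, ...) {
  cat(sprintf("%s centrality over %d nodes (normalized range %.4f - %.4f)\n",
              x$metric, length(x$raw), min(x$normalized), max(x$normalized)))
  invisible(x)
}

#' Per-residue centrality table
#'
#' @param net a `contact_network`.
#' @param result a `pcn_centrality` computed on `net`.
#' @return data.frame with columns `node_index`, `chain`, `res_seq`,
#'   `res_name`, `raw`, `normalized` (chain/residue columns are `NA`
#'   for networks loaded from bare matrices).
#' @export
centrality_table <- function(net, result) {
  stopifnot(inherits(result, "pcn_centrality"))
  n <- length(net$labels)
  if (!is.null(net$nodes)) {
    data.frame(node_index = net$nodes$index, chain = net$nodes$chain,
               res_seq = net$nodes$res_seq, res_name = net$nodes$res_name,
               raw = unname(result$raw), normalized = unname(result$normalized),
               stringsAsFactors = FALSE)
  } else {
    data.frame(node_index = seq_len(n) - 1L, chain = NA_character_,
               res_seq = NA_integer_, res_name = NA_character_,
               raw = unname(result$raw), normalized = unname(result$normalized),
               stringsAsFactors = FALSE)
  }
}
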