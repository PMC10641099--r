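# Network cartography of clustered contact networks: the participation
# coefficient P and the intramodular connectivity z-score characterize
# how each residue's contacts distribute over the clusters of a
# partition (Guimera-Amaral style roles).

# edges from each node into each cluster: N x k matrix
within_cluster_degrees <- function(net, partition) {
  check_partition_matches(net, partition)
  cl <- unname(partition$labels)
  ks <- sort(unique(cl))
  kis <- vapply(ks, function(s) {
    rowSums(net$A[, cl == s, drop = FALSE])
  }, numeric(length(cl)))
  kis <- matrix(kis, nrow = length(cl))
  colnames(kis) <- as.character(ks)
  kis
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (kappa_is / k_i)^2`, where `kappa_is` counts node
#' i's edges into cluster s and `k_i` is its total degree. P is 0 when
#' all contacts stay in the node's own cluster and approaches `1 - 1/m`
#' when they spread evenly over m clusters. Isolated nodes (`k_i = 0`)
#' get `P_i = 0` by convention.
#'
#' @param net a `contact_network`.
#' @param partition a `pcn_partition` of `net`.
#' @return named numeric vector of P values in \[0, 1).
#' @export
participation_coefficient <- function(net, partition) {
  kis <- within_cluster_degrees(net, partition)
  k <- rowSums(net$A)
  p <- ifelse(k > 0, 1 - rowSums((kis / pmax(k, 1))^2), 0)
  names(p) <- net$labels
  p
}

#' Intramodular connectivity z-score
#'
#' `z_i = (kappa_i - mean_s kappa) / sd_s kappa`, where `kappa_i` is node
#' i's within-cluster degree and the mean and population (divide-by-n)
#' standard deviation are taken over the node's own cluster. Clusters
#' with zero spread (including singletons) give `z = 0` by convention,
#' keeping the value defined for every node.
#'
#' @inheritParams participation_coefficient
#' @return named numeric vector of z values.
#' @export
intramodular_zscore <- function(net, partition) {
  kis <- within_cluster_degrees(net, partition)
  cl <- unname(partition$labels)
  kappa <- kis[cbind(seq_along(cl), match(cl, sort(unique(cl))))]
  z <- numeric(length(cl))
  for (s in unique(cl)) {
    members <- which(cl == s)
    mu <- mean(kappa[members])
    sigma <- sqrt(mean((kappa[members] - mu)^2))
    z[members] <- if (sigma > 0) (kappa[members] - mu) / sigma else 0
  }
  names(z) <- net$labels
  z
}

#' z-P role table for one or more structures
#'
#' Long-format table combining total degree, within-cluster degree,
#' participation coefficient and intramodular z-score per node, over one
#' or several (structure, network, partition) triples — the data behind
#' comparative z-P plots.
#'
#' @param entries list of entries, each a list with elements
#'   `structure_label` (unique string), `net` (a `contact_network`) and
#'   `partition` (a `pcn_partition` of that network).
#' @return data.frame of class `NodeRoleRow` rows: `structure_label`,
#'   `node_index`, `chain`, `res_seq`, `cluster`, `k`, `kappa`, `P`, `z`.
#' @export
zp_table <- function(entries) {
  stopifnot(is.list(entries), length(entries) >= 1L)
  labs <- vapply(entries, function(e) e$structure_label, character(1L))
  if (anyDuplicated(labs)) stop("duplicate structure_label", call. = FALSE)
  out <- lapply(entries, function(e) {
    net <- e$net
    part <- e$partition
    p <- participation_coefficient(net, part)
    z <- intramodular_zscore(net, part)
    kis <- within_cluster_degrees(net, part)
    cl <- unname(part$labels)
    kappa <- kis[cbind(seq_along(cl), match(cl, sort(unique(cl))))]
    n <- length(net$labels)
    data.frame(
      structure_label = e$structure_label,
      node_index = if (!is.null(net$nodes)) net$nodes$index else seq_len(n) - 1L,
      chain = if (!is.null(net$nodes)) net$nodes$chain else NA_character_,
      res_seq = if (!is.null(net$nodes)) net$nodes$res_seq else NA_integer_,
      cluster = cl,
      k = unname(rowSums(net$A)),
      kappa = unname(kappa),
      P = unname(p),
      z = unname(z),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
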