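# Contact-network construction and the plain-text adjacency dialect.
#
# The adjacency file dialect is:
#   line 1 (optional on read): "# labels: <chain>:<res_seq><icode> ..."
#   then N lines of N space-separated 0/1 integers, trailing newline.

new_contact_network <- function(labels, A, nodes = NULL, params = "external") {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), length(labels) == nrow(A))
  dimnames(A) <- list(labels, labels)
  structure(list(labels = labels, A = A, nodes = nodes, params = params),
            class = "contact_network")
}

validate_contact_network <- function(net) {
  A <- net$A
  if (!isTRUE(all(A == t(A)))) stop("matrix not symmetric", call. = FALSE)
  if (!all(A %in% c(0, 1))) stop("matrix not binary", call. = FALSE)
  if (any(diag(A) != 0)) stop("nonzero diagonal", call. = FALSE)
  invisible(net)
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("contact_network: %d nodes, %d edges\n",
              nrow(x$A), sum(x$A) / 2))
  if (is.list(x$params)) {
    cat(sprintf("  built with mode=%s, window=[%.2f, %.2f] A, min_seq_sep=%d\n",
                x$params$mode %||% "?", x$params$d_min, x$params$d_max,
                x$params$min_seq_sep %||% 0L))
  } else {
    cat("  loaded from an external adjacency matrix\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the binary contact adjacency matrix
#'
#' Connects residue pair (i, j) iff their Euclidean distance lies in the
#' inclusive window `[d_min, d_max]` and, when both residues are on the
#' same chain, their author residue numbers differ by at least
#' `min_seq_sep`. The defaults (4-8 A on CA positions, no sequence
#' separation filter) are the classical contact-network window: the
#' lower cutoff excludes covalently bonded backbone neighbours, the
#' upper one keeps only significant non-covalent contacts.
#'
#' @param nodes a `pcn_nodes` data.frame from [extract_nodes()].
#' @param d_min,d_max inclusive distance thresholds in Angstrom.
#' @param min_seq_sep minimum |res_seq_i - res_seq_j| for same-chain
#'   contacts (0 disables the filter).
#' @return A `contact_network`: node table, symmetric 0/1 matrix `A` with
#'   zero diagonal, and the build parameters.
#' @export
build_adjacency <- function(nodes, d_min = 4, d_max = 8, min_seq_sep = 0L) {
  stopifnot(inherits(nodes, "data.frame"))
  if (nrow(nodes) < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (!(d_min < d_max)) stop("d_min must be < d_max", call. = FALSE)
  if (d_min < 0) stop("d_min must be >= 0", call. = FALSE)

  # fixed node order regardless of input order
  ord <- order(nodes$chain, nodes$res_seq, nodes$i_code)
  nodes <- nodes[ord, , drop = FALSE]
  nodes$index <- seq_len(nrow(nodes)) - 1L
  rownames(nodes) <- NULL

  D <- as.matrix(stats::dist(cbind(nodes$x, nodes$y, nodes$z)))
  A <- (D >= d_min & D <= d_max)
  if (min_seq_sep > 0L) {
    same_chain <- outer(nodes$chain, nodes$chain, "==")
    sep <- abs(outer(nodes$res_seq, nodes$res_seq, "-"))
    A <- A & (!same_chain | sep >= min_seq_sep)
  }
  storage.mode(A) <- "integer"
  diag(A) <- 0L
  params <- list(
    mode = attr(nodes, "representation") %||% "ca",
    d_min = d_min, d_max = d_max, min_seq_sep = as.integer(min_seq_sep)
  )
  net <- new_contact_network(nodes$label, A, nodes = nodes, params = params)
  validate_contact_network(net)
}

#' Serialize a contact network to the adjacency text dialect
#'
#' @param net a `contact_network`.
#' @return a single string: a `# labels:` header line followed by the
#'   0/1 matrix, one row per line, space separated, trailing newline.
#'   The output is deterministic byte-for-byte.
#' @export
write_adjacency_file <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  validate_contact_network(net)
  header <- paste("# labels:", paste(net$labels, collapse = " "))
  body <- apply(net$A, 1L, paste, collapse = " ")
  paste0(paste(c(header, body), collapse = "\n"), "\n")
}

#' Read a contact network from the adjacency text dialect
#'
#' Accepts the dialect written by [write_adjacency_file()]; the label
#' header is optional (labels default to `n0..n{N-1}`). The matrix must
#' be square, symmetric, strictly 0/1 and hollow; weighted matrices are
#' rejected rather than silently binarized.
#'
#' @param text the file contents (single string or vector of lines).
#' @return a `contact_network` with `params = "external"` and no
#'   coordinates.
#' @export
read_adjacency_file <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text <- text[nzchar(trimws(text))]
  labels <- NULL
  if (length(text) && grepl("^#", text[1L])) {
    hdr <- sub("^#\\s*labels:\\s*", "", text[1L])
    labels <- strsplit(trimws(hdr), "\\s+")[[1L]]
    text <- text[-1L]
  }
  if (!length(text)) stop("empty adjacency matrix", call. = FALSE)
  rows <- lapply(strsplit(trimws(text), "\\s+"), function(r) {
    v <- suppressWarnings(as.numeric(r))
    if (anyNA(v)) stop("matrix not numeric", call. = FALSE)
    v
  })
  n <- length(rows)
  if (any(lengths(rows) != n)) stop("matrix not square", call. = FALSE)
  A <- do.call(rbind, rows)
  if (!all(A %in% c(0, 1))) stop("matrix not binary", call. = FALSE)
  if (!isTRUE(all(A == t(A)))) stop("matrix not symmetric", call. = FALSE)
  if (any(diag(A) != 0)) stop("nonzero diagonal", call. = FALSE)
  storage.mode(A) <- "integer"
  if (is.null(labels)) labels <- paste0("n", seq_len(n) - 1L)
  if (length(labels) != n) stop("label count does not match matrix size", call. = FALSE)
  new_contact_network(labels, A, nodes = NULL, params = "external")
}

#' Upper-triangle contact pair list
#'
#' @param net a `contact_network`.
#' @return data.frame with columns `node_i`, `node_j` (labels), one row
#'   per contact, ordered by (i, j) node index; the data layer behind a
#'   contact-map plot.
#' @export
contact_pairs <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  idx <- which(upper.tri(net$A) & net$A == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(node_i = net$labels[idx[, 1L]],
             node_j = net$labels[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Convert a contact network to an igraph graph
#' @param net a `contact_network`.
#' @return an undirected igraph graph with vertex names = node labels.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  igraph::graph_from_adjacency_matrix(net$A, mode = "undirected")
}
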