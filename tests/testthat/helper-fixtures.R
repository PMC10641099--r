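# Shared fixtures and independent brute-force oracles.

net_from_A <- function(A, labels = paste0("n", seq_len(nrow(A)) - 1L)) {
  storage.mode(A) <- "integer"
  pcnet:::new_contact_network(labels, A)
}

net_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) {
    A[e[1L], e[2L]] <- 1L
    A[e[2L], e[1L]] <- 1L
  }
  net_from_A(A)
}

path3_net <- function() net_from_edges(3L, list(c(1, 2), c(2, 3)))
k2_net <- function() net_from_edges(2L, list(c(1, 2)))
k3_net <- function() net_from_edges(3L, list(c(1, 2), c(1, 3), c(2, 3)))

# two triangles {1,2,3} and {4,5,6}
two_triangles_net <- function(bridge = FALSE) {
  edges <- list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  if (bridge) edges <- c(edges, list(c(3, 4)))
  net_from_edges(6L, edges)
}

random_net <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- as.integer(stats::runif(sum(up)) < p)
  net_from_A(A + t(A))
}

partition_of <- function(net, labels0) {
  pcnet:::new_partition(as.integer(labels0), net$labels,
                        method = "fixed", params = list(), seed = 0L)
}

# ---- brute-force shortest-path oracles (independent of igraph) -----------

brute_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

enum_simple_paths <- function(A, s, t, maxlen) {
  res <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      res[[length(res) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) >= maxlen) return(invisible())
    for (w in which(A[v, ] == 1)) if (!(w %in% path)) rec(c(path, w))
  }
  rec(s)
  res
}

brute_betweenness <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  D <- brute_distances(A)
  if (n < 3) return(bc)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] < 2) next
    paths <- enum_simple_paths(A, s, t, maxlen = D[s, t] + 1)
    len <- vapply(paths, length, integer(1L))
    sp <- paths[len == D[s, t] + 1]
    for (p in sp) {
      inner <- p[-c(1L, length(p))]
      bc[inner] <- bc[inner] + 1 / length(sp)
    }
  }
  bc
}

brute_closeness_wf <- function(A) {
  n <- nrow(A)
  D <- brute_distances(A)
  out <- numeric(n)
  for (i in 1:n) {
    members <- which(is.finite(D[i, ]))
    n_c <- length(members)
    s <- sum(D[i, members])
    if (n_c > 1 && s > 0) out[i] <- ((n_c - 1) / s) * ((n_c - 1) / (n - 1))
  }
  out
}

# ---- PDB record builder ---------------------------------------------------

pdb_line <- function(serial, name, res_name, chain, res_seq, x, y, z,
                     alt = " ", i_code = " ", occ = 1, b = 0,
                     element = substr(trimws(name), 1, 1), het = FALSE) {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name, alt, res_name,
          chain, res_seq, i_code, x, y, z, occ, b, element)
}

tiny_pdb_text <- function() {
  paste0(paste(c(
    "HEADER    TEST STRUCTURE",
    pdb_line(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0, b = 12.0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0, b = 12.0),
    pdb_line(3, "CB", "ALA", "A", 1, 2.0, 1.0, 0.0, b = 12.0),
    pdb_line(4, "CA", "GLY", "A", 2, 4.0, 0.0, 0.0, b = 13.0),
    pdb_line(5, "CA", "SER", "A", 3, 8.0, 0.0, 0.0, alt = "A", b = 14.0),
    pdb_line(6, "CA", "SER", "A", 3, 8.5, 0.0, 0.0, alt = "B", b = 14.0),
    pdb_line(7, "OG", "SER", "A", 3, 9.0, 1.0, 0.0, alt = "A", b = 14.0),
    pdb_line(8, "O",  "HOH", "A", 101, 20.0, 20.0, 20.0, het = TRUE),
    "END"
  ), collapse = "\n"), "\n")
}
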