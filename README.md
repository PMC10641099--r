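# pcnet — protein contact networks in R

`pcnet` turns protein 3D structures into residue contact networks and
analyses them. It is aimed at structural bioinformaticians who want the
graph view of a protein — allosteric routes, structural communities,
connector residues — without stitching together a structure parser, a
graph library and a clustering stack by hand.

A contact network has one node per amino-acid residue, represented by
its alpha-carbon, beta-carbon, or heavy-atom centroid, and an edge for
every residue pair whose Euclidean distance lies in an inclusive window
[d_min, d_max] (default 4–8 Å: the lower cutoff removes covalent
backbone neighbours, the upper keeps first-shell contacts). On the
resulting binary adjacency matrix A the package computes:

* **centrality** — degree, betweenness, closeness (Wasserman–Faust
  component scaling), eigenvector (power iteration, unit norm);
* **spectral clustering** — k smallest eigenvectors of L = D − A,
  L_sym = I − D^{−1/2} A D^{−1/2}, or L_rw = I − D^{−1} A, plus seeded
  k-means (k-means++, 10 restarts);
* **embedded clustering** — Laplacian eigenmaps or Katz-index (HOPE
  style) truncated-SVD embeddings, S = (I − βA)^{−1} βA, coordinates
  U_d √Σ_d;
* **community extraction** — Louvain, greedy modularity
  (Clauset–Newman–Moore), label propagation, Girvan–Newman — scored by
  Newman modularity Q = Σ_s [e_s/m − (d_s/2m)²];
* **node roles** — participation coefficient
  P_i = 1 − Σ_s (κ_is/k_i)² and intramodular z-score
  z_i = (κ_i − μ_s)/σ_s per partition (Guimerà–Amaral cartography).

Networks come from PDB files (or the Protein Data Bank via
`fetch_pdb()`), from a plain-text adjacency dialect, or from two
synthetic generators (an ideal CA helix and a planted-partition
stochastic block model). Results export as TSV tables, edge lists, and
PDB files whose B-factor column carries the per-residue score for
coloring in any molecular viewer; every command-line run is journaled
as JSON-lines for provenance.

## Worked example

```r
library(pcnet)

pdb   <- generate_helix_fixture(30)                 # ideal CA-only helix
nodes <- extract_nodes(parse_structure(pdb), mode = "ca")
net   <- build_adjacency(nodes, d_min = 4, d_max = 8)
net
#> contact_network: 30 nodes, 81 edges
#>   built with mode=ca, window=[4.00, 8.00] A, min_seq_sep=0
```

81 edges is exactly the |i−j| ∈ {2, 3, 4} band: on the ideal helix,
sequence neighbours sit at ≈3.83 Å (below d_min) and separation-5 pairs
at ≈8.66 Å (above d_max).

```r
centrality(net, "betweenness")
#> betweenness centrality over 30 nodes (normalized range 0.0012 - 0.1238)

part <- spectral_clustering(net, k = 3, variant = "sym", seed = 1)
part
#> pcn_partition: 30 nodes in 3 clusters (spectral_sym, seed 1)
#>   cluster sizes: 9 11 10

head(zp_table(list(list(structure_label = "helix30", net = net,
                        partition = part))), 4)
#>   structure_label node_index chain res_seq cluster k kappa P          z
#> 1         helix30          0     A       1       0 3     3 0 -0.9486833
#> 2         helix30          1     A       2       0 3     3 0 -0.9486833
#> 3         helix30          2     A       3       0 4     4 0  0.0000000
#> 4         helix30          3     A       4       0 5     5 0  0.9486833
```

The spectral clusters are contiguous helix segments; P = 0 for interior
residues (all contacts intra-cluster) and z tracks how connected each
residue is within its own segment.

The same workflow is available from a shell via the thin wrapper
`inst/scripts/pcn`:

```sh
Rscript inst/scripts/pcn cluster --fixture helix:30 --method spectral \
    --k 3 --variant sym --seed 1 -o out/
```

which writes `out/pcn_edges.tsv`, `out/pcn_partition_spectral_sym.tsv`
and appends a run record to `out/pcn_journal.jsonl`.

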