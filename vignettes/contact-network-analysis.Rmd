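---
title: "Protein contact network analysis with pcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein contact network analysis with pcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnet)
```

## The model

A protein contact network (PCN) reduces a 3D protein structure to an
undirected graph: one node per amino-acid residue, one edge per
"significant contact". Each residue is represented by a single point —
its alpha-carbon (`ca`), its beta-carbon (`cb`, falling back to CA for
glycine), or the unweighted centroid of its heavy atoms (`centroid`) —
and two residues are in contact when their Euclidean distance lies in an
inclusive window $[d_{\min}, d_{\max}]$. The result is a binary,
symmetric, hollow adjacency matrix $A$ on which all downstream analysis
runs. The topological view trades geometric detail for robust,
cheaply computable descriptors of allosteric routes, structural cores
and inter-domain organisation.

The defaults are $d_{\min} = 4$ Å and $d_{\max} = 8$ Å on CA positions.
The lower cutoff excludes covalently bonded backbone neighbours
(consecutive CA pairs sit near 3.8 Å), the upper cutoff keeps only
first-shell non-covalent interactions; this is the classical PCN window
and both ends are user-settable. Comparisons are inclusive at both ends
so that results are bit-reproducible. An optional `min_seq_sep` filter
additionally removes same-chain pairs closer than a given separation in
sequence; it is off by default.

Structures are read from fixed-column PDB text. Only the first MODEL of
a multi-model (NMR) file is used; iterating over models is the caller's
loop. Where alternate locations exist, only alt-loc ' ' and 'A' atoms
are kept, so the network describes a single conformer. HETATM residues
— waters, ligands, and modified residues such as MSE — are excluded;
hydrogens never enter the centroid (their presence in deposited files is
too inconsistent to be meaningful). The centroid is the all-heavy-atom
mean; a side-chain-only centroid is a conceivable variant that we chose
not to implement. Author residue numbering and insertion codes are kept
as-is and participate in node ordering, which is always
(chain, residue number, insertion code), re-indexed 0..N−1.

Precomputed matrices can be supplied instead of a structure, in a small
plain-text dialect (`# labels:` header plus rows of space-separated
0/1). Weighted matrices are rejected rather than silently binarized:
failing loudly beats coercion the user did not ask for.

## Analyses

**Centrality.** Degree, betweenness, closeness and eigenvector
centrality, each reported raw and normalized. Degree is normalized by
$N-1$; betweenness is the Brandes pair-dependency count over unordered
pairs, normalized by $(N-1)(N-2)/2$; closeness is computed per connected
component and scaled by the Wasserman–Faust factor
$\frac{n_c-1}{\sum_j d(i,j)} \cdot \frac{n_c-1}{N-1}$, so multi-chain or
fragmented structures neither crash nor let small components dominate.
Eigenvector centrality is the principal eigenvector of $A$, computed by
power iteration from a fixed all-ones start for determinism, returned
with unit Euclidean norm and nonnegative sign. Numerically the
iteration runs on $A + I$: adjacency spectra of bipartite components
come in $\pm\lambda$ pairs and the unshifted iteration oscillates; the
shift leaves eigenvectors unchanged while making the dominant
eigenvalue strictly largest in magnitude. The iteration stops when the
unit vector changes by less than `tol` (default 1e-10) and errors with
the residual if `max_iter` is exceeded.

**Spectral clustering.** Eigenvectors of the $k$ smallest eigenvalues
of one of three Laplacians — $L = D - A$, $L_{sym} = I - D^{-1/2} A
D^{-1/2}$, $L_{rw} = I - D^{-1} A$ — clustered by k-means. For `sym`
the embedding rows are scaled to unit norm (Ng–Jordan–Weiss); for `rw`
the symmetric eigenvectors are back-transformed by $D^{-1/2}$. Isolated
nodes keep a zero diagonal entry in the normalized Laplacians, so the
multiplicity of eigenvalue 0 always equals the number of connected
components.

**Embedded clustering.** Two embeddings feed the same k-means:
*Laplacian eigenmaps* (eigenvectors 2..d+1 of $L$, ascending) and a
*Katz-index factorization* in the HOPE style: the similarity
$S = (I - \beta A)^{-1} \beta A$ is factorized by truncated SVD and
nodes take coordinates $U_d \sqrt{\Sigma_d}$. The Katz series only
converges for $\beta < 1/\rho(A)$; the default $\beta = 0.05$ is safe
for typical contact networks (spectral radius of order of the mean
degree, ≈ 6–15), and the bound is checked with a clear error.
Eigenmap columns are mean-centered and re-normalized: for a connected
graph this is an exact no-op (they are orthogonal to the constant
eigenvector already), but on disconnected graphs the eigensolver
returns an arbitrary basis of the degenerate 0-eigenspace, and the
projection restores the expected component-indicator structure.
Embedding column signs are fixed so the largest-magnitude entry is
positive, making results platform-stable.

**k-means contract.** All clusterings that need k-means use the same
seeded procedure: k-means++ initialization, Lloyd iterations, 10
restarts, best total within-cluster sum of squares. Labels are then
renumbered 0..k−1 by first node occurrence, so identical partitions are
identical objects regardless of method-internal label order, and equal
seeds give byte-equal outputs.

**Community extraction.** Louvain (seeded, resolution 1 by default),
Clauset–Newman–Moore greedy modularity, asynchronous label propagation
(seeded order), and Girvan–Newman edge removal. Girvan–Newman removes
the edge of maximum edge betweenness until at least `k` components
remain; ties (within 1e-9) break toward the lowest edge index, which
makes the algorithm deterministic. Partition quality is Newman's
$Q = \sum_s \left[ e_s/m - (d_s/2m)^2 \right]$.

**Node roles.** Given any partition, each node gets the
Guimerà–Amaral cartography coordinates: participation coefficient
$P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$, which is 0 when all of a node's
contacts stay in its own cluster and approaches $1 - 1/m$ under even
spread over $m$ clusters, and the intramodular z-score
$z_i = (\kappa_i - \mu_{s_i})/\sigma_{s_i}$ standardizing the
within-cluster degree against the node's own cluster. $\sigma$ is the
population (divide-by-n) standard deviation; degenerate cases map to 0
($P_i = 0$ for isolated nodes, $z_i = 0$ when $\sigma = 0$, including
singleton clusters), which keeps every downstream table and plot total.
The R1–R7 role-zone classification built on top of (z, P) in the
cartography literature is out of scope; the coordinates themselves are
the deliverable.

## A worked run

```{r example}
pdb <- generate_helix_fixture(30)          # ideal CA-only alpha-helix
nodes <- extract_nodes(parse_structure(pdb), mode = "ca")
net <- build_adjacency(nodes, d_min = 4, d_max = 8)
net
head(contact_pairs(net))

part <- spectral_clustering(net, k = 3, variant = "sym", seed = 1)
part
head(zp_table(list(list(structure_label = "helix30", net = net,
                        partition = part))))
```

On the ideal helix (2.3 Å radius, 100° turn, 1.5 Å rise per residue)
the contact band under the default window is exactly the residue pairs
with sequence separation 2, 3 or 4 — separations 1 (≈ 3.83 Å) and 5
(≈ 8.66 Å) fall outside [4, 8] — i.e. 81 contacts for 30 residues.

## The synthetic generators

Two generators make the whole test surface reproducible without
external files. `generate_helix_fixture()` emits an ideal poly-alanine
CA helix whose inter-residue distances are known in closed form; it
exercises parsing, node extraction, window thresholds and annotation,
but has none of the irregularities of real structures (missing atoms,
alternate conformers beyond the fixtures' synthetic ones, multiple
chains, broken numbering), so passing on it shows the machinery is
correct, not that any biological conclusion holds.
`generate_planted_partition()` draws a stochastic block model —
`blocks` groups of `size` nodes, within-group edge probability `p_in`,
between-group `p_out` — and returns the ground truth for scoring
recovery with the adjusted Rand index. The reference condition used
throughout the tests is 4 blocks × 15 nodes with `p_in = 0.9`,
`p_out = 0.05`: strong but not trivial block structure at the size of a
small protein domain. An SBM has independent edges and no geometric
constraints, which real contact networks (banded, nearly regular,
embedded in 3D) do not share; recovery there validates the clustering
pipeline, not its biological interpretation.

## Determinism and degenerate inputs

Every stochastic step (k-means, Louvain, label propagation, the SBM
generator) consumes an explicit seed and repeat calls are identical.
Edgeless graphs are rejected by eigenvector centrality, community
extraction and modularity; `k > N` and non-converging iterations raise
errors rather than warnings. Matrix files that are non-square,
asymmetric, non-binary or have a nonzero diagonal are each rejected
with a specific message. B-factor annotation clamps values to the
format's printable range [−99.99, 999.99] and refuses NaN. Annotation
assigns one value per residue, so re-annotating a file with its own
B-factors is byte-identical exactly when B is constant within each
residue (always true for CA traces).

## Problem sizes

The shipped test-and-verification surface uses 200 random graphs of at
most 7 nodes for the brute-force centrality cross-check, 100 random
graphs for the spectral component-count property, 100 planted-partition
seeds at 60 nodes for clustering recovery, and a 30-residue helix for
the end-to-end runs — sizes at which exhaustive oracles (all simple
paths, all 203 set partitions of 6 nodes) are feasible, chosen as the
package's own verification conditions.

## Command line

The installed script `inst/scripts/pcn` exposes the same workflow as
subcommands (`build`, `centrality`, `cluster`, `community`, `roles`,
`annotate`); every run appends a JSON-lines record — input, build
parameters, method, seed, output paths, package version — to a session
journal in the output directory, so sequences of analyses on the same
working directory stay auditable and re-runnable. Structures can also
be fetched from the Protein Data Bank by id (`fetch_pdb`), through an
injectable downloader that keeps the rest of the toolkit fully offline.

## Known limitations

No mmCIF input, no occupancy weighting, no biological-assembly
expansion; contact graphs are residue-level and unweighted by design;
embeddings do not include random-walk methods (node2vec-style); the
role-zone classification is not computed. Closeness and betweenness
treat multi-component graphs by the conventions above — users comparing
against tools that drop small components should expect scale
differences there.
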