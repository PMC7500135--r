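---
title: "Methods: shell-wise signal propagation and sketch-based phylogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shell-wise signal propagation and sketch-based phylogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic generators do and do not emulate, the numerical
choices, and the known limitations. Every empirical statement here is one
the test suite or the acceptance script computes itself.

# 1. Signal propagation in a PPI network

## Model

The network is a simple undirected graph: protein nodes, confidence-
filtered interaction edges, no weights retained after filtering. For a
seed protein $v$, breadth-first shells partition the reachable nodes by
shortest-path distance: $S(0) = \{v\}$, and $S(r)$ holds the nodes at
distance exactly $r$. A protein that reappears during network growth is
kept only at its first (shortest) distance, so the shells are disjoint by
construction. The empirical propagation profile is the shell-size
probability mass

$$|D(r)| = \frac{|S(r)|}{\sum_{r'} |S(r')|},$$

i.e. the probability that a protein reachable from the seed lies at
distance $r$. This is the only reading we found consistent with the
described qualitative behaviour — an initial exponential rise, saturation
at a radius $r_s$, then decay "owing to the contraction of the shells":
shell sizes in an expanding network grow geometrically until the finite
network runs out of new nodes, after which the shells shrink. The
saturation radius is defined as the **first index at which $|D(r)|$
attains its maximum**, the end of the rising regime; a constant profile
therefore has $r_s = 0$, and inserting the maximum earlier can only
decrease $r_s$ (a property the tests assert).

The rising regime is summarized two ways:

* **Empirical growth rate.** The least-squares slope of $\log |D(r)|$
  over $1 \le r \le r_s$. On a full $b$-ary tree rooted at the seed,
  $|S(r)| = b^r$, so the fitted slope equals $\ln b$ exactly; the
  acceptance suite checks this for $b \in \{2, 3\}$ at depth $\ge 5$
  within $\pm 0.05$. Fewer than two points (e.g. a hub whose first shell
  is already the maximum) leaves the slope undefined and the profile is
  flagged rather than failed.
* **Model profile.** In a locally tree-like network, following an edge
  leads to $(\langle k^2\rangle - \langle k\rangle)/\langle k\rangle$
  onward neighbours on average (the mean excess degree, or branching
  factor), so expected shell sizes grow like
  $\text{prefactor}\cdot\text{branching}^r$ with prefactor
  $\langle k^2\rangle/(\langle k^2\rangle - \langle k\rangle)$. The
  classical expansion rate $\alpha = \langle k^2\rangle/\langle k\rangle$
  is computed and reported alongside, but it is *not* used as the model
  base: the source formula for $|D(r)|$ is typographically corrupted
  (missing operators, ambiguous exponent sign), and only the excess-degree
  form is testable against closed forms (branching $= k-1$ exactly on
  $k$-regular graphs; empirical shell ratios on sparse random graphs track
  it within sampling noise). Degree moments are always taken over **all**
  nodes, isolated ones included; an edgeless network is a degenerate-
  statistics error, not a silent zero.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `score_threshold` | 0.4 | normalized confidence | conventional medium-confidence STRING cutoff used by the study |
| `r_max` | 8 | shells | the study's stated growth horizon; configurable |
| score scale | auto | — | STRING flat files store 0–1000 integers; any score > 1 triggers division by 1000, with `raw`/`normalized` overrides |

Seed proteins absent from the network are kept as isolated nodes with a
warning and produce flagged degenerate profiles (all mass at $r=0$), so a
batch analysis never aborts on one missing homolog. Each seed's profile is
computed over its reachable component only; the unreachable remainder is
excluded from the normalization.

# 2. The degree-constrained fixture, and an infeasibility

No edge list for the published 78-protein network is deposited, so the
package ships a generator for a synthetic stand-in constrained to the
printed numbers. Here the printed numbers turn out to be mutually
inconsistent: the eight hub degrees 55, 53, 39, 30, 29, 23, 22, 21 sum to
272, hub–hub edges can contribute at most $2\binom{8}{2} = 56$ of that
sum in a simple graph, so at least $272 - 56 = 216$ hub–nonhub edges are
required *in addition to* the 28 hub–hub edges — at least 244 edges in
total, contradicting the printed 216. Equivalently, the Erdős–Gállai
inequality fails at $k = 8$ for **every** assignment of the 160 residual
degree stubs; the test suite demonstrates this with igraph's independent
graphicality test on 100 random residual assignments. The published
network was most likely a multigraph (parallel evidence-channel edges in
the Cytoscape import), whose degrees exceed simple-graph degrees.

The fixture therefore reproduces the attainable constraints exactly —
**78 nodes, 216 edges, BatD at degree 55, and the strict printed hub
ranking** — and reduces the seven lower hub degrees minimally to the
feasibility boundary (hub sum 244): 55, 47, 34, 26, 25, 20, 19, 18
(`bat_fixture_degrees()`; `bat_hub_degrees()` still returns the printed
profile for reference). One acceptance test asserts the printed profile
faithfully and is expected to stay red; a companion green test proves the
infeasibility. The remaining 188 stubs go to 70 synthetic partner
proteins with truncated-geometric degrees (support 1–8, repaired to the
exact stub total) — a heavy-tailed remainder resembling interactome
degree data. Realization is a deterministic Havel–Hakimi construction
followed by seeded degree-preserving double-edge swaps; residual draws
that fail the graphicality check fail over to new internal seeds. We use
this instead of plain stub matching with rejection because at these
skewed degrees a rejection sampler essentially never accepts; the generic
`configuration` model in `gen_network()` keeps honest stub matching with
bounded retries.

What a green fixture test establishes: the counting constraints, the hub
ranking, determinism. What it does not: the real topology — in
particular, the fixture's diameter is tiny (BatD reaches 70.5% of the
network in one hop), so its saturation radii are 1–2 and are **not**
expected to reproduce the published $r_s = 4$, which arose from a much
larger STRING neighbourhood. Reproducing that number requires the real
STRING v10 *Pedobacter heparinus* links file and a homolog mapping table
(`read_mapping()` provides the interface); we document this as an
external reproduction rather than a CI test.

# 3. Alignment-free phylogenomics

## Sketching and distances

Each genome is reduced to its set of canonical k-mers (lexicographic
minimum of each A/C/G/T-only window and its reverse complement; windows
containing other symbols are skipped, and multi-record FASTA files are
joined with a single `N` so no window spans a record boundary). A seeded
64-bit non-cryptographic hash (FNV-1a with splitmix64 finalization,
truncated to 53 bits so every value is an exact double, implemented in
C++) maps k-mers to hash values, and the bottom-$s$ sketch keeps the $s$
smallest distinct values. The Jaccard index of two genomes is estimated
from the $s$ smallest values of the merged sketch (fraction present in
both), which is exact whenever $s \ge$ the union size — a property the
tests assert on random sequence pairs.

Two distance transforms are provided. Writing $w = 2j/(1+j)$ for the
estimated fraction of shared k-mers:

* `p_distance()` (pipeline default): $p = 1 - w^{1/k}$. A k-mer survives
  a substitution proportion $p$ with probability $(1-p)^k$, so this
  inversion recovers $p$ directly; the acceptance suite demonstrates
  recovery within $\pm 0.01$ (mean of 10 replicates) for
  $p \in \{0.01, 0.05, 0.10, 0.20\}$ at $L = 100$ kb, $k = 16$,
  $s = 5000$.
* `mash_distance()`: $d = -\frac{1}{k}\ln w$, the classical Poisson-model
  inversion. Note $d \to -\ln(1-p)$, which exceeds $p$ by
  $\approx p^2/2$ — 0.023 at $p = 0.20$ — so the log form cannot meet a
  $\pm 0.01$ recovery band at large $p$. Since the source describes its
  distances as *p*-distances (proportions of nucleotide differences), the
  p-form is the default and the log form is kept for comparability with
  Mash itself.

Disjoint sketches ($j = 0$) return a finite cap (default 1.0) rather than
infinity so distance matrices stay usable for tree building. An optional
Jukes–Cantor-style correction $-\frac{3}{4}\ln(1 - 4p/3)$ maps p-distances
to quantities proportional to substitution events; because the original
transform is only described as "proportional to the evolutionary
distance", the correction ships **off by default** and raw sketch
distances are the primary output. Defaults $k = 16$, $s = 5000$ are
desk-scale analogues of common sketching defaults; smaller $s$ trades
accuracy ($\mathrm{sd}(j) \approx \sqrt{j(1-j)/s}$) for speed.

## Tree building and branch support

`nj_tree()` is a standard Q-criterion neighbor joining with a
deterministic tie-break (lexicographically smallest pair of subtree
representative labels) and zero-clamping of negative branch lengths (the
count is reported). On additive matrices it recovers the generating
topology and path lengths to $10^{-9}$, which the acceptance suite checks
for 4–8 taxa. `bme_refine()` then hill-climbs over nearest-neighbor
interchanges, scoring each candidate with the balanced (Pauplin) length
$\sum_{i<j} d_{ij}\, 2^{1 - t_{ij}}$ ($t_{ij}$ = topological path length
between leaves; for three leaves this is $(d_{12}+d_{13}+d_{23})/2$),
accepting only strict improvements; an already-optimal tree is returned
unchanged (object-identical), otherwise branch lengths are re-estimated
by ordinary least squares on the path-incidence system, again with
negatives clamped. The search is NNI-only — no SPR — which suffices at
desk scale and matches the "improved neighbor-joining" framing of the
method it emulates.

REQ branch support: an internal branch splits the leaves into sides
$A\,|\,B$; a quartet $a_1 a_2 | b_1 b_2$ supports it when
$d(a_1,a_2) + d(b_1,b_2)$ is **strictly** smaller than both cross-pair
sums (ties count against — conservative and reproducible). Support is the
supporting fraction, enumerated exhaustively up to `max_quartets` per
branch and otherwise estimated from that many uniformly sampled quartets
under an explicit seed. Additive matrices force support 1.0 on every
internal branch (four-point condition); an all-equal matrix gives 0.0.
Supports are invariant under leaf-label permutation of the matrix.

# 4. Synthetic genomes

`simulate_genomes()` evolves a uniform-random root sequence along a guide
tree (or a star): on each branch an **exact fraction** $p$ of positions,
chosen without replacement, is substituted to a uniformly chosen
different base. Exact fractions (rather than i.i.d. per-site mutation)
make parent–child Hamming proportions equal $p$ by construction, so the
distance-recovery tests are sharp; leaf-pair differences equal path sums
minus multiple-hit overlap, which the tests bound. The generator does not
model indels, rate heterogeneity across sites, base-composition bias, or
back-mutation-aware distances — so green recovery tests establish
correctness of the estimator under the stated substitution model, not
robustness to genome rearrangement or repeat content. Substitution
proportions must stay below 0.75 (the correction's divergence point).

All generators route their randomness through one explicit seed per call
(default 42) and are byte-reproducible; every CLI command writes a
manifest (inputs, all configuration values, warning counts, package
version — no timestamps) sufficient to reproduce the run.

# 5. Numerical choices and degenerate inputs

* Filtering is inclusive ($\ge$ threshold) and idempotent; self-loops are
  dropped at read time and again defensively at graph construction, with
  logged counts.
* Hash values are truncated to 53 bits so sketch ordering is exact in
  double arithmetic on every platform.
* NJ Q-ties and BME ties resolve to the first candidate in a
  deterministic ordering, so identical inputs give identical trees.
* `saturation_radius` on an empty sequence, a seed absent from its
  network, fewer than 3 taxa for NJ, fewer than 4 leaves for REQ,
  non-symmetric matrices, $p \ge 0.75$ for the correction, and malformed
  input rows (reported with their line number) are all explicit errors or
  flagged degenerate results — never silent.

# 6. Known limitations

* The propagation analysis is purely topological: no edge weights, no
  diffusion dynamics, no centralities beyond degree.
* The fixture reproduces printed counting constraints only (and provably
  cannot reproduce all of them; see §2).
* REQ sampling error is $O(\sqrt{0.25/\text{max\_quartets}})$ per branch;
  exhaustive enumeration is quadratic in each side of the split.
* BME refinement can stop in an NNI-local optimum on non-additive
  matrices; only monotone non-increase of the balanced length is
  guaranteed there.
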