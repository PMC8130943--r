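---
title: "Methods: sample-specific network control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample-specific network control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

A cohort expression matrix describes many samples at once, but the
interactions that move *one* sample between attractors — a patient's
healthy and disease state, a cell's stem and differentiated state — are
sample-specific. `sscontrol` models each sample as a networked dynamical
system: nodes are genes, edges are the sample's significantly perturbed
co-expression relations intersected with a prior interaction scaffold
(the *state-transition network*), and the genes that must receive
external control signals for the network state to be steerable are that
sample's *driver genes*. The analysis is two-stage: a single-sample
network statistic turns one expression profile plus a reference
population into a per-sample graph; a structural control criterion turns
that graph into a minimum driver set.

Assumptions worth keeping in mind: co-expression edges are undirected
observations and are treated as *bidirected* candidates whose surviving
orientation(s) come from the reference network; the CSN/SSN null models
assume exchangeable samples and complete (imputed) expression vectors;
and the control criteria are purely structural — they use the topology,
never fitted dynamics.

# The construction statistics

**CSN.** For sample $k$ and genes $x,y$, two boxes collect the
$\lceil 0.1\,n \rceil$ samples nearest to the sample's own value on each
axis; the statistic $\rho^k_{xy} = n_{xy}/n - (n_x/n)(n_y/n)$ measures
excess co-occupancy of the intersection box. Under independence
$\rho^k_{xy}$ is approximately normal with mean 0 and
$\sigma = \sqrt{n_x n_y (n-n_x)(n-n_y)/(n^4(n-1))}$, which is exactly
the hypergeometric variance of $n_{xy}$ when the boxes are treated as
fixed margins. Two conventions had to be fixed here:

* the *symmetric* form $(n-n_x)(n-n_y)$ is used for the null standard
  deviation (with the default equal box sizes the distinction vanishes);
* the target sample itself is the box *center* and is not counted among
  its neighbors. Counting it forces $n_{xy} \ge 1$ and shifts the null
  mean upward by about $0.4\sigma$ at $n = 500$ (measured over 200
  Monte-Carlo replicates); with the center excluded the empirical mean
  and standard deviation match the analytic null within Monte-Carlo
  error, which is what the calibration test asserts.

The CSN edge cut defaults to $\alpha = 0.01$ (the convention of the
original cell-specific network literature); it is a parameter.

**SSN.** One new sample is added to an $n$-sample reference group and
the correlation perturbation
$\Delta PCC = |PCC_{n+1} - PCC_n|$ is standardized as
$Z = \Delta PCC / ((1 - PCC_n^2)/(n-1))$, exactly as the source formula
prints it (no square root in the denominator), with a one-sided
upper-tail normal p-value — $\Delta PCC$ is a magnitude, so only large
positive departures are evidence. Edges pass at $\alpha = 0.05$. A
reference correlation of $\pm 1$ degenerates the denominator; such edges
are flagged with a missing p-value rather than guessed. The paired
variant builds the tumor and matched-normal networks against the same
reference group and keeps edges significant in exactly one of the two
(XOR at 0.05). A matched normal sample is already a member of the
reference group; its perturbed estimate still appends it, following the
$n \to n+1$ rule mechanically.

**SPCC and LIONESS.** SPCC scores a pair in one sample as the product of
the two genes' z-scores. The *population* (divide-by-$n$) standard
deviation is used so that the scores of a pair average exactly to the
pair's Pearson correlation across samples — the identity the tests check
to $10^{-10}$; with the sample standard deviation it holds only
approximately. LIONESS interpolates between the all-sample and
leave-one-out Pearson estimates, $e^s = N(e^N - e^{N-s}) + e^{N-s}$.
Both are score-thresholded, not p-valued: the cut
$w = \mu(S) + 2\delta(S)$ is computed per sample over that sample's
*absolute* scores, and an edge passes when $|score| \ge w$. Treating
scores signed instead would make strong negative co-expression
invisible, which is why the absolute convention was chosen where the
source left it open.

**Candidate pairs and reference filtering.** By default candidate pairs
are the reference network's edges (the state-transition network is the
intersection of significant differential co-expression with prior
interactions, and all-pairs enumeration is quadratic in genes);
`all_pairs = TRUE` lifts the restriction. The reference filter treats a
surviving unordered edge as bidirected and keeps each orientation
present in the reference; it is idempotent and monotone, which is
property-tested. Optional network deconvolution maps the eigenvalues of
the (rescaled) symmetric score matrix through $\lambda/(1+\lambda)$ to
strip transitive contributions; the `scaling` parameter is the largest
*output* eigenvalue (the rescaling is chosen to make it so), default
0.5.

# The control criteria

* **MMS**: node-split maximum matching (out-copy/in-copy bipartite
  graph, igraph's matcher); drivers are nodes with unmatched in-copy,
  one arbitrary node when a perfect matching exists. Driver count is
  always $\max(N - |M^*|, 1)$.
* **MDS** and **NCUA** are both minimum set-cover instances (closed
  neighborhoods over nodes; incident edges over nodes — the latter is a
  minimum vertex cover of the bidirected graph). One exact
  branch-and-bound solver serves both: greedy incumbent, branching on
  the uncovered element with fewest covering sets, lower bound
  $\lceil \text{uncovered}/\max|S| \rceil$. Past a configurable node
  budget (`max_expand`, default $2\times10^5$) the incumbent is returned
  with `optimal = FALSE` — never silently.
* **DFVS**: exact cycle-branching search for a minimum feedback vertex
  set (trim in/out-degree-0 vertices, branch on the vertices of a
  shortest cycle), plus all source nodes (in-degree 0). Whether sources
  belong in the reported driver count is genuinely ambiguous in the
  field; they are included by default and `include_sources = FALSE` is
  exposed. Self-loops count as cycles.

Ties among multiple optima are resolved deterministically: the solver
returns its first optimum under lexicographic variable order.
Alternative optima are explored only through
`sample_driver_configurations()`, the Markov chain that swaps one driver
for one non-driver restoring the cover/matching condition, accepting
proposals with probability 0.5 (the acceptance rule is unspecified in
the source literature; 0.5 is the package default and a parameter).
A caveat the tests encode: single-swap moves do *not* connect all
minimum covers — the two alternating covers of an even cycle are
mutually unreachable — so the chain enumerates the swap-connected
component of the starting optimum, not necessarily every optimum.

All four solvers are certified against exhaustive-search minima on 100
random graphs of up to 12 nodes, with an independently hand-coded
augmenting-path matcher as the matching oracle, and every returned set
must pass `verify_driver_set()`, an independent certificate check.

# Pinning control simulation

Every node carries Lorenz dynamics with $a = 10$, $b = 8/3$, $q = 28$;
node $i$ receives $c\sum_j a_{ij} x_j$ on each state component, and
driver nodes receive the feedback $u_i = -k(x_i - \bar x)$ with
$k = 1000$ on all three components. The uncoupled equilibria are the
origin and $(\pm\sqrt{b(q-1)}, \pm\sqrt{b(q-1)}, q-1) =
(\pm 8.4853, \pm 8.4853, 27)$ — the closed form is implemented (some
sources round the first coordinates to 8.484). At $q = 28$ these
equilibria are classically unstable for the free node; high-gain pinning
is what pins trajectories to them, and uncontrolled nodes are expected
to stay chaotic (bounded, by dissipativity — a tested sanity check).

Numerical choices: `lsoda` with `rtol = atol = 1e-8` handles the
stiffness that $k = 1000$ introduces (halving the tolerances moves
terminal errors by less than $10^{-3}$, which is tested); $T = 5$ time
units suffices for the high-gain transient; initial states are uniform
on $[-20, 20]^3$ per seed. The coupling strength $c$ has no canonical
value; the default $1/\langle d_{in}\rangle$ keeps the aggregate
coupling input comparable to the node's own dynamics and is recorded on
the result. Control efficiency $|E|/|D|$ counts efficiently controlled
nodes over *all* nodes, so values above 1 are legitimate when few
drivers steer many nodes; the summary averages the 0.1, 0.2, …, 1.0
tolerance grid.

# The synthetic generator and what the tests show

The generator emulates the statistical structure the construction
statistics are built to detect, nothing more: a seeded random directed
scaffold (Erdős–Rényi or preferential attachment); genes marginally
Gaussian with standard deviation `noise_sd` (so `noise_sd = 0` is a
singular request and errors); a vertex-disjoint subset of scaffold edges
planted as bivariate-normal pairs at exactly $r_{base} = 0.8$; and, per
case sample, half of the planted pairs flipped to $r_{alt} = 0$ — a
strong co-expression collapsing to independence, the canonical
differential-edge event. Gold drivers are the endpoints of perturbed
edges, and synthetic drug combinations are labeled positive exactly when
they target a driver. Vertex-disjointness is what lets every planted
correlation be realized exactly; the price is that planted structure is
a matching, not a hub pattern.

What it does **not** emulate: count noise, dropout, library-size and
tumor-purity effects, hub-correlated modules, or any real biological
edge direction. Passing tests therefore certify the statistics, solvers
and plumbing under their own assumptions — they do not certify
performance on real bulk or single-cell data.

One empirical property of the design is worth stating plainly: a single
added sample moves a Pearson correlation over $n = 200$ references only
through its one-point influence, so the per-edge detection rate of an
$r: 0.8 \to 0$ flip by SSN at $\alpha = 0.05$ is about 40%, while
unperturbed edges fire at roughly the nominal rate. The recovery tests
assert this calibrated gap, not near-certain detection. Recovery is
nevertheless decisive at the cohort level: the acceptance benchmark
pools 5 replicate studies (50 genes, 200 references, 20 case samples
each — 100 samples total) and compares the pooled mean F-measure of
SSN+MDS and SSN+NCUA drivers against 100 uniform same-size random gene
sets; the one-sided z-scores land around 7–10, far beyond the 1.645
cut. The pooled size was chosen because a single 20-sample replicate
leaves the z estimate at the mercy of one random scaffold; five
replicates is the smallest pool whose verdict is stable, and it runs in
seconds.

# Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `box_fraction` | 0.1 | CSN box size as a fraction of samples |
| CSN `alpha` | 0.01 | CSN edge p-value cut |
| SSN `alpha` | 0.05 | SSN / paired-SSN edge p-value cut |
| score threshold | $\mu + 2\delta$ | SPCC/LIONESS cut on absolute scores, per sample |
| `scaling` | 0.5 | largest output eigenvalue after deconvolution |
| `k` | 1000 | pinning feedback gain |
| `c` | $1/\langle d_{in}\rangle$ | oscillator coupling strength |
| tolerances | 0.1–1.0 by 0.1 | control-efficiency grid |
| `n_reps` | 100 | randomization baseline repetitions |
| `accept_prob` | 0.5 | Markov-chain proposal acceptance |
| `max_expand` | $2\times10^5$ | exact-solver work budget |

# Known limitations

* Multiple-testing correction is deliberately off everywhere (raw 0.05
  cut-offs are the field convention for these statistics); a BH step can
  be applied by the user on the stored p-values.
* Alternative-optimum sampling exists only for MMS and NCUA; no theory
  is available for MDS/DFVS, and the chain covers one swap-connected
  component.
* The exact solvers are branch-and-bound, not LP-based; on dense
  networks beyond a few hundred nodes the work cap will trigger and
  results are flagged non-optimal rather than delayed indefinitely.
* Partial-correlation single-sample networks and edge-network dynamics
  are out of scope.
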