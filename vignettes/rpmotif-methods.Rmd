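---
title: "Repulsive parallel MCMC motif discovery: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repulsive parallel MCMC motif discovery: model, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpmotif)
```

## The problem

De novo motif discovery asks for short recurring sequence patterns —
transcription-factor binding sites, typically 8–15 bp — in a set of DNA
sequences such as ChIP-seq peak regions or promoters.  A single Gibbs motif
sampler explores the posterior of one motif model, but real sequence sets
contain *many* motifs, so the posterior is highly multimodal and a single
chain is quickly absorbed by one locally high-probability motif (often a
low-complexity repeat) and never leaves it.  `rpmotif` runs M complete
samplers ("replicas") as one interacting chain whose replicas repel each
other in motif-matrix space, so that different replicas are driven to occupy
different motifs; the bias introduced by the repulsion is afterwards removed
by importance weights, and the M × N sampled motif states are reduced to a
ranked list of distinct representative motifs.

## The ZOOPS model

Each input sequence $s_i^+$ of length $L_i$ is concatenated with its reverse
complement into $s_i = (s_i^+, s_i^-)$ of length $2L_i$, so both strands are
scanned symmetrically; candidate start sites are
$u_i \in \{1,\dots,L_i-K+1\} \cup \{L_i+1,\dots,2L_i-K+1\}$ — a window never
straddles the strand join.  Under the ZOOPS ("zero or one occurrence per
sequence") model each sequence carries a motif with indicator $z_i$; given
occupancy, a $K$-mer at $u_i$ follows the position probability matrix (PPM)
$\Theta = (\theta_1,\dots,\theta_K)$, all other letters follow the background
multinomial $\theta_0$.  The likelihood factorises into the background
probability of *all* letters of all concatenated sequences times, for each
occupied sequence, the ratio $\prod_k \theta_{k,\sigma}/\theta_{0,\sigma}$
over the occupied positions.  We keep this literal factorisation: the
background sufficient statistic used for the $\theta_0$ update is the total
letter count *net of motif-occupied positions* (the ratio's denominator), so
the two factors stay exactly consistent.

Priors: flat Dirichlet on every PPM column and on $\theta_0$
($\alpha_\sigma = \beta_{k,\sigma} = 1$ by default), uniform start sites
$p(u_i \mid K) = 1/(2(L_i-K+1))$, occupancy $p(z_i = 1 \mid K) = \gamma^K$
with $\gamma = 0.755$, and a uniform width prior on
$K \in \{8, \dots, 15\}$.  The geometric-in-$K$ occupancy prior penalises
long motifs and is the main quantity a planted motif has to beat: the prior
log-odds of occupancy at a specific site are about
$-\log\!\big(2(L-K+1)/\gamma^K\big) \approx -9$ nats for $L = 500$, $K = 8$,
while a perfectly conserved 8-mer in uniform background yields at most
$8\log 4 \approx 11$ nats.  Weakly conserved or long-sequence instances are
therefore *correctly* left undetected by the posterior; benchmark designs
that expect near-complete recovery must plant information-rich motifs whose
per-position odds against the local background composition are high (for
example a GC-rich box in AT-rich promoter-like background).

## The repulsive parallel sampler

The augmented target couples M copies of the posterior with a repulsion
factor
$$\pi_A(x_1,\dots,x_M \mid \beta) \propto \prod_{i=1}^M \pi(x_i)\,
\psi(\Theta_1,\dots,\Theta_M)^\beta,\qquad
\log\psi = \sum_{i=1}^M \min_{j<i} D(\Theta_i,\Theta_j),$$
with the first replica's term defined as zero (empty minimum), so
$\psi \ge 1$ and $\beta = 0$ recovers M independent chains.  The
dissimilarity $D$ slides the shorter PPM along the longer one over all
$|K_i - K_j| + 1$ contiguous offsets, takes the smallest Frobenius norm
between the aligned windows, adds a gap penalty $c\,|K_i - K_j|$
($c = 0.3$), and divides by $\min(K_i, K_j)$.  Reverse-complement
identity is *not* folded into $D$ (the strands are already concatenated in
the data), so a motif and its reverse complement can occupy two clusters —
users should expect such pairs in reports.

One iteration updates each replica in turn against the other replicas'
current PPMs:

1. **Sites.** $(z_i, u_i)$ for every sequence from the exact full
   conditional (absence mass $1-\gamma^K$ against all $2(L_i-K+1)$ site
   odds).  Sequences shorter than $K$ stay unoccupied.
2. **Background.** $\theta_0$ from its conjugate Dirichlet posterior on the
   net background counts.
3. **Motif matrix.** $\Theta$ from the full conditional
   $\prod_k \mathrm{Dir}(\theta_k;\,\beta_k + m_k)\times
   e^{\beta\min_{j\ne i} D(\Theta,\Theta_j)}$ — conjugate when $\beta = 0$,
   otherwise by coordinate-wise slice sampling (below).
4. **Width.** A reversible-jump move grows or shrinks one boundary column
   (side chosen uniformly), the new column drawn from its Dirichlet prior so
   the proposal density cancels the prior in the acceptance ratio; start
   sites shift by one for left-side moves so the retained columns stay
   aligned, and a proposal is rejected outright if it leaves the width prior
   support or an occupied site cannot accommodate the wider motif.

The severity follows the published default $\beta = 10 \sum_i z_i$,
recomputed per replica at every iteration (`dynamic10`); `zero` and
`constant:<value>` are available.  With the dynamic rule a replica that loses
its sites also loses its repulsion, so constant severities are the cleaner
choice for controlled experiments on the mechanism itself.

### Slice sampling the repelled PPM update

At $\beta > 0$ the conditional of $\Theta$ is a product of Dirichlet
densities times $e^{\beta \min_j D}$.  When $\beta\min_j D$ dominates — the
regime the method relies on — the conditional's mass sits *away* from the
count mode, so independence-type proposals drawn from the conjugate
Dirichlet essentially never land there; an early implementation built on
slice-rejection from the conjugate proposal could not reproduce the
separation mechanism at all.  The update therefore uses coordinate-wise
slice sampling (Neal stepping-out, initial width 0.1, at most 50 expansions,
then shrinkage): each coordinate $\theta_{\sigma,k}$ moves along the path
that rescales the other three entries of its column proportionally, whose
induced one-dimensional density is a Beta kernel times the repulsion factor.
This random-walk scheme handles both regimes and never needs an
out-of-slice fallback.  At $\beta = 0$ the update short-circuits to the
exact conjugate draw, which the test suite verifies distributionally.

### Importance-weight bias correction

Samples drawn at $\beta > 0$ over-represent separated ensembles.  Each kept
joint draw of all M replicas receives one shared weight; in the default
`exponent` mode the raw log-weight is $-\sum_i \beta_i \min_{j<i} D_{ij}$
evaluated with the severities in force when the draw was made — the exact
Radon–Nikodym factor between the sampled and the uncoupled target for
constant $\beta$, and the natural extension under the dynamic rule.  The
`literal` mode uses $1/\psi$ regardless of $\beta$.  For M = 2 the coupled
kernel targets $\pi_A$ exactly, and the weighted estimator is verified
against exhaustive enumeration in the acceptance tests.  Note that large
severities make the weights degenerate (a few ensembles carry almost all
mass); ranking by cluster weight remains usable, but weighted posterior-mean
PPMs can then be dominated by a single ensemble, which is why cluster
representatives (the likelihood-maximising member) are the quantity reported
for recovery.

### Initialisation

Each replica owns a deterministic RNG substream derived from the master
seed, so runs are bitwise reproducible and the `zero` policy reproduces M
independent Gibbs chains draw for draw (asserted in the tests against a
standalone reimplementation of the plain sampler).  A replica starts at
width `kmin` with its PPM seeded from an *enriched data word*: a batch of
candidate K-mers (default 100) is drawn uniformly from the forward strands
and one is chosen with probability proportional to its exact occurrence
count on both strands, then smoothed with a per-cell pseudocount of 0.06
(≈ 0.85 peak probability).  The sharp, enrichment-biased seed matters: the
blocked sweep (sites → background → matrix) cannot bootstrap from a diffuse
matrix, because a seed needs to score its instances above the ≈ 9-nat
occupancy prior penalty before any sites are accepted at all — a uniformly
chosen, heavily smoothed seed word demonstrably never locks on.  Occupancy
indicators are initialised by a single prior draw; $\theta_0$ starts at the
empirical base composition.

## Post-processing

The M × (N − burn-in) kept states are sorted by likelihood (ties broken by
replica then iteration index for determinism) and greedily clustered: the
top remaining state seeds a cluster and absorbs every remaining state whose
PPM lies within $\lambda = 0.3$ of the seed.  The seed — the cluster's
likelihood maximiser — is the representative; clusters are ranked by the
normalised sum of their members' importance weights, ties by representative
likelihood.  A motif is flagged *enriched* when its representative occupies
at least 5% of the input sequences (inclusive boundary), the filter applied
at representative level.  $\lambda = 0$ yields one cluster per distinct PPM
and $\lambda \to \infty$ one cluster in total; the partition, determinism
and monotonicity properties are exercised on a thousand random matrices in
the tests.

## Evaluation

Against a table of known sites, performance is scored at nucleotide level:
every known motif $j$ is matched to the predicted output with the largest
nucleotide overlap (ties to the better rank), and
$$\mathrm{SN} = \frac{\sum_j \mathrm{overlap}_j}{\sum_j |\mathrm{known}_j|},
\qquad
\mathrm{PPV} = \frac{\sum_j \mathrm{overlap}_j}{\sum_j |p_j|},$$
where the PPV denominator counts only the matched outputs, so unmatched
extra outputs do not dilute precision.  Overlaps are computed on
forward-strand coordinates; reverse-strand sites are projected before
intersecting.  Site sets are additionally scored by the log-likelihood
ratio $\mathrm{LLR} = n' \sum_k \mathrm{KL}(f_k \,\|\, b)$ in natural-log
units ($0\log 0 := 0$), combining over-representation and information
content.

## The synthetic benchmark generator

`simulate_motif_data()` emulates the planted-motif benchmark the method is
assessed on: i.i.d. multinomial background sequences of fixed (1000 bp) or
variable (200–2000 bp) length; instances drawn column-wise from source PPMs,
strand chosen uniformly, written into non-overlapping windows at uniform
positions; a Poisson number of instances per sequence (mean 8 by default —
the per-sequence count distribution is a package choice, with a Bernoulli
at-most-one mode for ZOOPS-consistent designs); ground truth recorded in
forward coordinates.  The packaged `synthetic_motifs.meme` collection (ten
synthetic PPMs of widths 8–15, generated from invented consensus strings
with Dirichlet column jitter) stands in for a curated database collection;
it is not derived from any external database.  What the generator does *not*
emulate: Markovian or repeat-structured real backgrounds, GC heterogeneity
along sequences, overlapping or clustered sites, and motif
cross-correlations — passing benchmarks here therefore demonstrates the
machinery, not performance on real ChIP-seq data.

## Numerical choices and problem sizes

All densities are handled in log space with log-sum-exp normalisation;
categorical site draws pass probabilities normalised by their maximum.
Zero probabilities referenced by the likelihood yield $-\infty$, never an
error.  Ambiguous IUPAC letters are replaced at load time by uniformly drawn
bases (warned), keeping the multinomial model exact.  The defaults
($M = 50$, $N = 520$, burn-in 20) follow the published configuration; the
package's own test and acceptance runs use reduced sizes chosen to keep a
complete desk-scale verification cheap while leaving each check's power
intact — e.g. exactness against exhaustive enumeration on 3 × 12 bp with
$10^5$ kept draws, bias correction on a 4 × 8 bp enumerable instance at
constant $\beta = 10$, the two-motif separation experiment on 25 × 100 bp
over 20 paired seeded runs, and single-motif recovery on 100 × 500 bp with
$M = 10$, $N = 200$.  Burn-in detection is an open problem for multimodal
targets; the fixed 20-iteration default follows the published setting, and
`plot()` exposes the per-replica likelihood traces so users can judge
stationarity themselves.

## Known limitations

Higher-order Markov backgrounds and position-specific start-site priors are
out of scope, as are PPM-database annotation (TOMTOM/JASPAR) and multi-core
execution.  The interacting update uses each replica's nearest neighbour
among *all* other replicas inside the $\Theta$ conditional while $\psi$ is
defined through the ordered nearest-predecessor sum; for M > 2 the kernel is
therefore an approximation to the augmented target (exact for M ≤ 2), which
is the standard trade-off for this family of interacting samplers.  Weight
degeneracy at large $\beta$ is intrinsic; treat reported cluster weights as
a ranking signal rather than calibrated posterior mass.
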