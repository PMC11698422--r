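---
title: "Methods: transcript- versus DNA-derived clonal phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript- versus DNA-derived clonal phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotangle)
```

## The question and the measurement

Tumour subclones differ by somatic SNVs and CNVs, and the tree relating
them is conventionally built from DNA.  Expression data carry an imprint
of the same events — transcript dosage scales with copy number, and
expressed variants are visible in RNA reads — so one can build a second
tree from transcripts alone and ask how well it recapitulates the DNA
tree.  `clonotangle` operationalizes that question as a tanglegram
comparison: build a dendrogram per molecular channel, untangle the pair,
and report the entanglement statistic.

All trees are binary, height-based `stats::dendrogram` objects (leaves at
height 0), the container the comparison machinery and base-R plotting
already understand.

## Clustering engines and their conventions

The package ships its own agglomerative engines (UPGMA, average,
complete, `ward.D` via the Lance–Williams recurrences) rather than
delegating to `stats::hclust`, for one reason: determinism under ties.
When several cluster pairs attain the minimal merge criterion the engine
merges the pair whose sorted pair of representative labels
(lexicographically smallest member of each cluster) is smallest, and puts
the smaller representative on the left.  Tied merges are routine here —
noise-free replicate cells are at distance exactly 0 — and `stats::hclust`
resolves them by input order, which would make every downstream
entanglement value depend on column order.  On tie-free input the engines
agree with `stats::hclust` to 1e-9; the test suite checks this on 200
random matrices against both `stats::hclust` and a naive oracle that
recomputes cluster-pair linkage from the original matrix each round.

Height conventions are fixed and pinned by tests: UPGMA node height =
merge distance / 2 (so the tree is ultrametric), other linkages use the
raw criterion.  `cophenetic_dist()` returns 2 × the height of the lowest
common ancestor, which maps a UPGMA tree back onto its merge distances.

Newick I/O is a small recursive-descent reader/writer on this height
convention (branch length = parent height − child height; internal-node
labels read/written as bootstrap support).  Parse errors carry a 1-based
character offset.  Multifurcations are rejected unless `binarize = TRUE`
(left-leaning, zero-length edges).  Heights of foreign non-ultrametric
trees are flattened to max-path-below, the only lossy case; every tree
the package writes round-trips exactly (to formatting precision).

## Entanglement and untangling

With $r_i, s_i$ the ranks of shared label $i$ in the two restricted leaf
orders,

$$E = \frac{\sum_i |r_i - s_i|^L}{\sum_i |i - (n+1-i)|^L} \in [0, 1],$$

normalized so that identical orders give 0 and the exact reversal gives 1.
The norm exponent `L` defaults to 1.5 — the conventional choice, and the
single most consequential free constant in the comparison; it is exposed
everywhere (`L =`, `--L`).

Leaf order is only defined up to $2^{n-1}$ rotations of internal nodes,
so the statistic is reported after untangling.  The one-sided step is
*exact*, not greedy: because each subtree occupies a contiguous rank
block, the minimal rank-difference sum decomposes over (node, rank
offset) pairs and is solved by dynamic programming in $O(n^2)$;
`untangle_step1side()` therefore attains the true minimum over all
rotations of the movable tree.  The two-sided problem could in principle
get stuck if solved by alternation alone, so `untangle_step2side()`
enumerates all rotations of the smaller tree (each paired with an exact
one-sided solve) whenever that side has at most 12 internal nodes —
giving the certified global optimum for the tree sizes where the package
is typically used for verification — and otherwise alternates exact
one-sided passes from both start orders, keeping the better result.  The
test suite confirms the global optimum against brute force over all
rotation pairs on a 50-case random suite of 4–6-leaf trees, and the
never-increase invariant is asserted after every round.  Untangling is a
pure rotation: topology, heights, and support values are untouched.

## The five channels

**gSNV.** Identity by state on dosage matrices: per shared non-missing
site $(2 - |g_i - g_j|)/2$, averaged; distance $1 - \mathrm{IBS}$.
Missing data are handled pairwise-complete (no imputation); a pair with
no shared site is an error naming the pair.  Average linkage by default
(the linkage for this channel is not canonical, so it is an argument).

**iSNV.** RNA variant reads are sparse and depth-limited, so the channel
uses a deliberately simple depth-aware divergence instead of a
model-based estimator: a variant is present when depth ≥ `min_depth` (3)
and alt fraction ≥ `alt_threshold` (0.2); divergence is the fraction of
co-covered sites with discordant presence.  The interface isolates this
choice so a likelihood-based divergence can drop in later.  `ward.D`
linkage, the convention for this channel.

**gCNV (segments).**  Two consumers.  `gcnv_tree()` rasterizes per-unit
segment tables onto fixed-width bins and clusters Euclidean/Ward.  The
bin pipeline for multi-sample bulk data (`bin_segments()` →
`call_bins()` → `discordant_matrix()` → `bootstrap_tree()`) follows the
fixed-bin post-processing idiom: 1200-bp tiles from each chromosome
start, bin CN taken from the segment containing the bin midpoint
(internally half-open, zero-based: bins $[b, b+w)$, midpoint $b + w/2$,
segment $[start-1, end)$ — the only convention consistent with assigning
a 1–1800/1801–3600 segment boundary to bins 600/1800/3000 as 3/2/2),
deletion calls at CN ≤ 1.5 and amplification at CN ≥ 2.5 (inclusive;
the thresholds are CN values around the diploid baseline), bins missing
anywhere or identically called everywhere dropped, and plain bootstrap
proportions (row resampling, default n = 1000) as node support.
Correlation distance and average linkage default, Euclidean fallback for
zero-variance replicates; multiscale (AU) p-values are intentionally out
of scope.

**iCNV (expression).**  A transparent reimplementation of the
moving-average core of expression-based CNV inference, with no HMM state
caller — the smoothed residual itself is the signal.  Stage order:
mean-count cutoff (0.1), library-size normalization to the median
library, $\log_2(x+1)$, per-gene reference-mean subtraction (all samples
when no reference set is given), ±3 SD clamp, windowed moving average
along each chromosome (default 101 genes, truncated at chromosome ends
and reduced on short chromosomes), per-sample median centring, and
denoising (zero everything below 1 residual SD).  The window and
denoising defaults are configuration, not claims of equivalence to any
specific tool version.  Smoothing is linear, so profiles superpose on
noise-free input — a property the tests exploit.  Ward/Euclidean
clustering; spatial spots are pseudo-bulked per section first.

**Trinary.**  Counts reduced per sample against that sample's own global
distribution: $-1$ if strictly below $\mathrm{MED} - \mathrm{SD}$, $+1$
if strictly above $\mathrm{MED} + \mathrm{SD}$, else 0 — boundary values
map to 0 because the inequalities are strict.  SD is the sample
($n-1$) estimator by default; the choice is recorded in the output and
switchable, since either reading is defensible.  Distances use the
3-state symmetric ML correction $d = -\tfrac23 \ln(1 - \tfrac32 p)$
($p$ = discordant fraction), capped at `d_max = 5` from saturation
($p \ge 2/3$); a raw $p$-distance is available for sensitivity analysis.
The operation is scale-agnostic (raw counts, normalized intensities,
log-scale — the thresholds adapt to whatever distribution each sample
has), so upstream normalization is deliberately the caller's business.
All-zero genes are retained by default: they contribute concordant
states, which is information about similarity.  UPGMA completes the
channel.

## The simulator: what it emulates and what it does not

`simulate_clone_tree()` grows a random binary clone topology by leaf
splitting and assigns per-branch events: CNV events are contiguous
gene-span ±1-copy changes (span uniform in 15–45 genes by default), SNV
events mark unused sites heterozygous (infinite-sites until exhaustion).
States accumulate root-to-leaf from a diploid, variant-free root; CN is
floored at 0 with a logged clip count.  Genes map deterministically onto
22 autosomes at uniform 10-kb spacing so segment and annotation files can
be emitted.

Observations follow `sample_design()` (single-cell / bulk / spatial) and
`noise_config()`.  The expression model is the premise of the iCNV
channel made explicit: counts are negative binomial with mean
$\text{base}_g \cdot (\mathrm{CN}_{gu}/2) \cdot \text{libsize}_u$ — i.e.
dosage-linear.  Variant read totals are Poisson at `depth_mean` scaled by
local relative CN; alt reads binomial at allele fraction dosage/2.  DNA
single cells get heterozygote dropout (`ado_rate`), spurious variants
(`fp_rate`) and integer Gaussian CN jitter; bulk/spatial units get
purity-weighted mixture CN and an expected-dosage presence threshold
(0.1, configurable).  The all-zero `noise_config()` is fully
deterministic — counts and reads are rounded expectations — which is what
makes exact recovery checks possible.

Three presets fix the study conditions: `sidr_like` (30 cells from 3
populations of 10/7/13, 440 genes, 120 sites, 5 CNV + 25 SNV events per
branch — enough that populations are unambiguously distinct),
`bulk_a21_like` (7 regions from a 4-clone tree, each dominated by one
clone at 70% purity), and `st_12section_like` (12 sections × 20 spots; 4
tumour sections at 60% tumour fraction sharing one mildly perturbed
clonal composition — adjacent regions of a single tumour share their
clone mix — and 8 near-normal sections at 2%).  Every random stream
derives from the master seed by stable hashing (`derive_seed()`), so
adding a channel never perturbs another channel's draws.  The paper-free
noise defaults are recorded in each bundle's manifest rather than claimed
to match any real dataset.

What the simulator does *not* emulate: read-level artefacts, splicing,
allele-specific expression beyond the binomial, CN-independent
transcriptional programs (a config switch can add expression noise
uncoupled from CN to probe exactly this failure mode), or realistic
chromosome-scale event spectra.  Passing the zero-noise recovery suite
therefore demonstrates internal consistency of the pipeline — each
builder inverts the generative coupling it assumes — not performance on
real tissue.

## Numerical choices and degenerate inputs

- Comparisons of heights and entanglement improvements use 1e-12–1e-9
  absolute tolerances; convergence of two-sided untangling is zero
  improvement to 1e-12, capped at 25 rounds against rotation cycling.
- Constant samples in `trinarize()` (SD = 0) degenerate to
  sign-of-median-deviation coding with a warning.
- A discordant matrix with zero retained rows warns, and clustering
  refuses it; a correlation distance over a zero-variance column falls
  back to Euclidean with a logged message.
- `dist_matrix()` is the single validation choke point: symmetry to
  1e-8 (then exactly symmetrized), finite entries, unique labels.
- Problem sizes in the test suite are chosen to make the oracles
  affordable: 200 random matrices at n ≤ 10 for linkage equivalence,
  50 brute-forced rotation-pair problems at 4–6 leaves, 5 seeds of the
  30-cell preset for recovery, 10 seeds × 4 dispersion levels for the
  degradation property.

## Known limitations

- The iSNV divergence ignores read-count uncertainty beyond its two
  gates; a beta-binomial model would use the same interface.
- Bootstrap support is a plain proportion; it underestimates support for
  shallow nodes relative to multiscale methods.
- The exhaustive two-sided untangler certifies global optimality only up
  to 12 internal nodes on the smaller side; beyond that the alternating
  scheme is a (monotone) heuristic.
- Entanglement compares leaf orders only; two trees with very different
  branch lengths but aligned orders score 0.  Pair it with cophenetic or
  topological distances when height structure matters.
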