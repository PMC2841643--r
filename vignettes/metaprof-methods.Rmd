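---
title: "Methods: community profiling and pathway scoring in metaprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community profiling and pathway scoring in metaprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprof)
```

`metaprof` profiles a shotgun metagenome along two axes: *who is there*
(best-hit binning, fragment recruitment, word-frequency PCA) and *what can
they do* (pathway completeness/activity scoring, marker-gene screening).
This vignette explains each model, its assumptions and tunable parameters,
the numerical choices made where the design was genuinely open, and what
the synthetic-data tests do and do not demonstrate about real data.

## Taxonomic binning and recruitment

Each read is assigned to the subject of its highest-bitscore alignment
among hits with E-value strictly below `e_threshold` (default 1e-10, the
conventional cutoff for confident nucleotide homology at ~800 bp read
length). Ties on bitscore are broken by lower E-value, then lexicographic
subject id — the tie-break is arbitrary but fixed, so binning is a pure
function of its inputs and regression-testable. Each read gets exactly one
bin ("closest reference"); fractional or LCA-style assignment is out of
scope. Binned reads are banded by percent identity over half-open
intervals spanning 47–100% (default edges 47, 50, 60, 70, 80, 90, 95,
100, top band closed); the edges are configurable because no canonical
breakpoints exist.

Fold coverage is defined as total aligned length (gaps included) over
reference length. This is the natural definition when alignments, not base
pileups, are the unit of evidence; at low coverage the two differ
negligibly. Self-recruiting 400 error-free 800 bp reads against their
100 kb source genome therefore gives exactly 400 × 800 / 100000 = 3.2×,
which the tests assert as a closed form.

Summary fractions are reported over two denominators — all reads and
binned reads only — because community percentages are quoted against
either and the choice materially changes the numbers.

## Word-frequency composition analysis

Contigs strictly longer than `min_length` (default 1500 bp; shorter
contigs give noisy signatures) are profiled with the counts of every
overlapping DNA word of lengths 1..L (default L = 5, giving
4+16+64+256+1024 = 1364 features in fixed lexicographic order). Windows
containing `N` are skipped. Counts are normalized *within each word
length*, so every length contributes a probability vector; without this,
the 1-mer block would dominate the variance simply by scale. Features are
standardized to zero mean and unit variance before PCA by default for the
same reason; a covariance-mode flag exists because the choice between
correlation and covariance PCA is a legitimate analysis decision.

Words are counted on the given strand by default. An optional
reverse-complement-collapsed mode pools each word with its reverse
complement, making profiles strand-invariant; the uncollapsed profile of a
reverse-complemented contig equals the original under the
reverse-complement feature permutation (tested exactly).

PCA uses the deterministic spectral decomposition in `stats::prcomp` — no
randomized solver — and a sign convention (largest-magnitude loading
positive per axis) so coordinates are identical across runs and input
orders. Cluster separation is quantified with mean silhouette width of the
true labels and the adjusted Rand index against `kmeans` at k = number of
classes; k-means restarts are the only stochastic step and are governed by
the caller's seed.

## Gene calling

Candidate ORFs are maximal stop-free codon stretches on all six frames,
reported when at least `min_aa` codons (default 30 aa — long enough to
suppress random open stretches, short enough to keep genuine fragments; no
canonical value exists for read-length fragments). Candidates are
stop-bounded, not start-bounded: on an 800 bp read most genes are
truncated, so requiring a start codon would discard most true fragments.
A stretch truncated by a read edge rather than a stop is flagged run-on
(`partial5`/`partial3`); a 5'-edge stretch that begins with a start codon
(ATG/GTG/TTG) is treated as complete, since a start at the edge is
evidence of a genuine gene start rather than truncation. Translation uses
NCBI genetic code 11 without initiation-codon special-casing, so internal
alternative starts are not forced to methionine. A `require_start` flag
trims candidates to their first start codon for users who want
conservative calls.

Dereplication is a deliberately simple reimplementation of the greedy
longest-first clustering idea behind CD-HIT: sequences sorted longest
first, each joining the first representative whose global-alignment
identity (matches / alignment length, gaps included, via
`Biostrings::pairwiseAlignment`) meets the threshold. A shared-4-mer
prescreen (shared fraction ≥ 1 − 6(1 − t)) skips hopeless alignments; the
6× margin makes false skips vanishingly unlikely at the 0.95–0.97
thresholds the pipeline uses, and the prescreen can be disabled. This is a
correctness-first stand-in, not a performance clone.

## Pathway scoring

The scoring chain is: filter each query translation's hits → count unique
translations per reaction → score pathways.

**Hit filter.** Retain hits with bit score strictly greater than 50 and at
least 80% of the top hit's score (`bit_floor = 50`, `window = 0.20`).
Boundary semantics (strict `> 50`, inclusive `≥ 0.8 × top`) are a fixed
convention, asserted in tests at exactly 50 and exactly 0.8 × top.
Proteins associated with reactions only through partial EC numbers are
kept out of the filtered list whenever any fully-associated protein scores
above the floor, and used as a fallback otherwise — partial EC
associations are weak evidence, worth using only when nothing better
exists. Every suppression is visible in the returned table
(`partial_only` column).

**Counting.** A reaction's count in a sample is the number of distinct
query translations whose filtered list touches any of its proteins; a
query hitting three subunits of one reaction adds 1. Queries are assumed
to be post-dereplication representatives, otherwise redundant reads
inflate counts.

**Specificity weight.** Reactions shared across many pathways are weak
evidence for any one of them. The weight

\[ w_i = \frac{n_{totrxn,i} / n_{unirxn,i}}{n_{pw,i}} \]

counts, over the multiset of pathways containing reaction *i*: how many
there are (n_pw), their total reaction count with multiplicity (n_totrxn)
and their unique reaction count (n_unirxn). When the containing pathways
are identical copies, n_totrxn/n_unirxn = n_pw and w = 1 — duplicated
pathway variants carry no penalty — while overlap among genuinely
different pathways drives w below 1. Note the invariance is exactly the
printed identity: duplicating a pathway of atypical size *can* shift
weights of reactions it shares with differently-sized pathways, because
the correction ratio is a mean over containing pathways. The tests pin
the brute-force counts, the identical-copy identity at several
multiplicities, and the untouched weights of reactions outside a
duplicated pathway. Both formulas live behind single functions
(`specificity_weight`, `completeness_score`) so an alternative algebra is
a one-line change.

**Scores.** Completeness is the weighted fraction of a pathway's reactions
with at least one hit, C_j = Σ w_i I_i / Σ w_i ∈ [0, 1], monotone in the
indicators. Activity is the median unique-hit count over *all* of the
pathway's reactions — zero-count reactions included, an even count
averaging the central pair — so a pathway with one highly-hit promiscuous
reaction and nothing else scores 0, which is the point of using a median.

**Key-pathway selection.** Pathways with fewer than 5 reactions are
dropped in completeness mode (short pathways reach extreme completeness
too easily; the filter is optional in activity mode, where no statement
either way exists and both behaviors are exposed). PCA is run with
pathways as variables; each pathway's contribution is
Σ_c var_c · loading² over the top three components — variance-weighted
squared loadings, the standard "contribution" decomposition. The top 15
are kept, then near-duplicate variants (reaction-set symmetric difference
≤ 1) are collapsed to the higher-contribution member — an automated,
deterministic version of what would otherwise be manual curation.

**Clustering.** Average linkage throughout; Euclidean distance for
completeness matrices (bounded, comparable scales) and 1 − Pearson on
log(1 + x) for activity matrices (counts vary over orders of magnitude;
correlation compares shape, the log tames the tail). A zero-variance row
under the Pearson metric has no defined correlation and is assigned the
maximal distance 2, with a message. Dendrograms export as Newick via
`ape`.

## Marker screen

Candidates are (environmental sequence, gene symbol) pairs with E < 1e-10,
best E-value kept per pair, query coverage = aligned query span / query
length. Validation operationalizes three expert-judgment rejection rules
as label matching against a supplied reverse-annotation table: (i) the
reverse label is a different member of the query's protein family; (ii)
its functional process differs from the query's; (iii) it is on a
mis-annotation blacklist (shipped empty by default — blacklists are
dataset-specific); plus a coverage floor (`min_coverage = 0.3` — the
concern is named in the source material but no number is, and 30% of a
typical 400–700 aa query is the shortest fragment on which family-level
assignment is defensible). Rules are evaluated in the order i, ii, iii,
coverage; every call records the rule that fired so a human can audit the
screen decision by decision. Sequences missing from the reverse table are
`undetermined`, never silently confirmed.

## Synthetic data: what it emulates, and what it does not

The generator supplies every input with known truth: genomes from GC
setpoints or order-k Markov chains (rows of the transition matrix must sum
to 1; the first k bases draw from the chain's marginal); divergence by
independent per-site substitution to a uniformly chosen different base, so
expected identity is exactly 1 − d and band-assignment oracles stay
analytic (no indels, by design); paired reads from opposite ends of
uniformly placed inserts, mean 800 bp, with per-base substitution errors
(default 0.005 — Sanger-era post-trimming error rates are not well
characterized for this material, so this is a package default, not a
measured value); planted pathway content with signal bit scores ≥ 60
(safely above the 50-bit floor) and noise scores centered at 35 with
roughly a tenth crossing the floor, attached to non-encoded reactions so
every crossing is a true false positive; and planted marker genes with one
decoy per rejection rule. Default community scale is thousands of reads
per sample — a deliberate desk-scale stand-in for survey libraries of
~14,000 reads per site; all scales are parameters.

The fixture aligner exploits the substitution-only model: a read occupies
the same coordinates on any reference derived from its source genome, so
an ungapped comparison at the truth interval *is* the optimal alignment,
scored +2/match, −3/mismatch with an idealized E-value
m·n·2^(−bitscore). It is not an aligner for real data, and hit tables
from real BLAST runs are consumed through the same 12-column interface.

Consequently, passing tests demonstrate correctness of the *computations*
— binning, banding, coverage, profiles, PCA, scores, screens — under
clean, indel-free, chimera-free data with uniform read placement. They do
not demonstrate robustness to assembly artifacts, strain mixtures,
horizontal transfer, GC-coverage bias, or real alignment noise.

## Problem sizes and determinism

The bundled studies use four genomes of 100 kb (GC 0.30/0.45/0.60/0.70),
references at 5% divergence, 500 read pairs per genome, 200 contigs of
~3 kb, 50-pathway databases over 5 samples with paired noise-free genome
columns, and 2 planted markers × 2 genes × 5 samples with 4 decoys per
sample — sizes chosen so the full chain, tests included, runs in minutes
on a single core while keeping every statistical check comfortably away
from its threshold. One master seed fans out to per-stage seeds through a
fixed string hash (`derive_seed`), so stages are independently
reproducible and adding a stage never perturbs another's draws; every
reported number is bit-reproducible given the seed.

## Known limitations

* Substitution-only divergence: identity bands are exact but indel-driven
  length variation is unmodeled.
* The greedy clusterer is quadratic in cluster count and meant for
  thousands, not millions, of sequences.
* Rule ii/iii marker validation is only as good as the supplied reverse
  annotations and blacklist; the package ships no curated blacklist.
* The completeness/activity algebra is fixed to the forms above; scores
  are comparable within a database, not across databases with different
  overlap structure.
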