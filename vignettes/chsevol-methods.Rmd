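---
title: "Models and methods behind chsevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chsevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chsevol studies the evolution of chitin synthases (CHS) — processive
family-2 glycosyltransferases that polymerise UDP-GlcNAc into chitin — and
of their relatives (hyaluronan synthases, bacterial NodC). The package
implements the full inference chain used to classify CHS proteins and to
detect horizontal gene transfer (HGT) and recombination, together with a
gene-family evolution simulator that provides ground truth for every
inference stage. This vignette documents the models, the tunable
parameters, the numerical conventions, and what validation on simulated
data does and does not establish.

## The generative model

### Species tree

`sample_species_tree()` draws a rooted, binary, ultrametric tree by
sequential random coalescence: node heights are uniform draws rescaled so
every root-to-leaf path equals `depth` (expected substitutions per site).
With a named `groups` vector, each group becomes a basal clade joined at
the root by stems of length `depth * stem_fraction` (default 0.5). Deeply
split groups emulate the situation of interest — say, a eukaryotic donor
group and a bacterial recipient group — so cross-group transfers carry an
unambiguous phylogenetic signal.

### Duplication, loss and transfer

`evolve_family()` runs a birth–death–transfer process top-down along the
species tree. Each gene lineage experiences events as a Poisson process
with per-unit-branch-length rates: a duplication splits the lineage in
place, a loss terminates it, and a transfer sends a copy to another branch
alive at the transfer time while the donor lineage continues
(prune-and-regraft with additive acquisition, matching how bacterial
recipients gain genes without displacing a native copy). Lineage
identifiers persist through speciations; every event is logged with its
branch, time, parent lineage and created lineage, so an independent
interpreter can replay the log and must reproduce the extant gene set
exactly — this is tested.

Exact-count "planted" transfers are supported through the `planted_hgt`
argument: each planted event names a donor taxon, a recipient taxon and a
time, and is executed inside the same simulation, so the event log and
gene tree stay mutually consistent. The standard fixture plants three
transfers at times 0.55–0.9 (fraction of tree depth), i.e. recent enough
that each recipient branch belongs to a single extant genome. Donor and
recipient taxa are drawn without replacement where group sizes allow, so
transfers involve distinct lineages and leave independent incongruence
signals.

### Sequence evolution

`evolve_sequences()` uses a uniform-rate Poisson replacement process: each
site accumulates `Poisson(rate × branch length)` events, each replacing
the residue with one of the other 19 amino acids uniformly. No rate
matrix and no across-site rate variation are modelled; none of the
downstream inferences requires them, and the simple process keeps the
expected p-distance between two leaves at total path `d` in closed form,

$$p = \frac{19}{20}\left(1 - e^{-\frac{20}{19}\,\mu d}\right),$$

which the test suite checks by simulation at 2000 sites. Indels are
single-column insertions and deletions (no affine length model — a single
column suffices to exercise the trimming stage), and true homology columns
are tracked throughout, so the simulator emits the true alignment.

The root protein (`chs_root_protein()`) plants the motifs the screening
stage relies on: catalytic aspartates at positions 30, 60 and 90, `QXXRW`
at 120 and a single `QXXXY` at 160, in a 260-residue background drawn
uniformly from the 20 amino acids. Planted motif positions are immutable
by default — no substitution, deletion, or insertion inside a motif span —
so every simulated gene passes the functionality filter unless it is
explicitly degraded with `decay_motifs()` (which destroys every `QXXRW`
occurrence), giving exact ground truth for the dubious-candidate
partition.

### Coding sequences and composition

Coding sequences come from codon back-translation under the standard
genetic code. The synonymous-codon choice is the only composition knob:
codons are sampled with weight $\theta^{g}(1-\theta)^{3-g}$ (where $g$ is
the codon's G+C count) and $\theta$ is solved by bisection so the expected
G+C equals the target; targets outside the achievable range for a given
protein composition are clamped to the nearest achievable value.
`apply_composition_shift()` resamples synonymous positions towards the
amelioration mixture

$$\mathrm{GC}_{\text{target}} = \mathrm{GC}_{\text{donor}}(1-a) +
\mathrm{GC}_{\text{host}}\,a,$$

leaving the protein untouched. The fixture convention is $a = 0$ for
recent transfers (the case the composition evidence line can detect) and
$a \approx 0.8$ for ancient ones; these are conventions of the simulator,
not empirical estimates. Group targets default to 0.42 (donor group) and
0.58 (recipient group), a contrast typical of fungal versus
enterobacterial genomes; each gene also gets a simulated host genomic
context (6 kb of i.i.d. nucleotides at the host target) for the
sliding-window background.

### Chimeras and neighbourhoods

`make_recombinant()` fuses the N-terminal part of one protein through its
first `QXXXY` copy with the C-terminal part of another from its first
copy onwards, so the fusion retains both copies — the tandem duplication
the recombination scanner keys on. `simulate_chimera_set()` evolves two
deeply diverged families (CHS-like `A` and HAS-like `B`, 0.8
substitutions/site between, 0.05 within), builds chimeras with B-derived
N-termini and A-derived C-termini, and pads the references with a gap
block at the junction so homology in the combined alignment is exact.
Because the duplicated-motif diagnostic presupposes that `QXXXY` is rare,
the generator removes spurious `Q..Y` matches that arise by drift
(occasionally on a class stem, hence shared by a whole family) and draws
N-side parents whose first motif copy is the planted one; without this the
located breakpoint would not be the junction the fixture planted, and the
fixture would no longer test what it claims to.

Gene neighbourhoods are simulated as draws from group-specific family
pools (20 families per group, 6 neighbours per focal gene). Each planted
transfer carries a conserved three-gene trio — named after the
DUF1800/DUF1501/sugar-epimerase operon context familiar from bacterial
*chs* loci — shared between the recipient genome and one extant genome
descending from the donor branch, which is exactly the cross-group
gene-order conservation the synteny detector looks for.

## The inference chain

**Candidate screen.** `find_catalytic_motifs()` requires an ordered
assignment D < D < D < QXXRW with at least `min_gap = 10` residues between
consecutive aspartates (the spacing of the planted motifs; configurable,
since catalytic-motif spacing varies across the family). Proteins without
a complete motif set are dubious and excluded. The PSSM screen
(`build_pssm()`, log-odds with pseudocounts over a uniform background)
replaces an E-value cutoff with an empirically calibrated score threshold:
the 99th percentile of maximal window scores over seeded shuffles of the
reference sequences (`calibrate_pssm_threshold()`), preserving the
permissive intent of a screen that must not lose true family members.

**Trimming.** `score_columns()` offers normalised column entropy
(default) and min-max-normalised mean pairwise BLOSUM62 similarity; the
within-division versus cross-division matrix choice is a configuration
switch, and any substitution matrix can be supplied. `trim_alignment()`
keeps columns whose smoothed score (window 3) reaches `score_cutoff`
(default 0.5) and whose gap fraction is at most `gap_cutoff` (default
0.5). Filtering is iterated to a fixed point, which makes trimming
idempotent by construction. The cutoffs are this package's own defaults;
trimming exists to stabilise the trees, and tree stability is what the
validation checks.

**Trees.** `pairwise_distance()` computes p- or Poisson-corrected
distances over shared non-gap columns, raising a typed error for
undefined pairs. `nj_tree()` is standard neighbor joining with two
reproducibility conventions: Q-criterion ties (within 1e-12) are broken by
the lexicographically smallest pair of subtree representative labels, and
negative branch lengths are clamped to zero with the deficit moved to the
sister branch, preserving path lengths. `bootstrap_support()` resamples
columns, discards (and counts) replicates with undefined distances rather
than imputing them, and scores each internal edge of the reference
topology by the percentage of valid replicates containing the same
bipartition. On additive matrices NJ must recover the generating topology
exactly; on mildly non-additive matrices (tree distances with ±5%
multiplicative noise, the regime of sampling error on distances estimated
from finite alignments) it must agree with the exhaustive minimum-OLS
topology in at least 95 of 100 trials — both are acceptance checks against
independent oracles.

**Classification.** A class is accepted only when the proposed member set
is monophyletic with bootstrap support ≥ `support_min` (default 60, the
conventional "well-supported" threshold) in the trees from *both*
distance settings — the concordance logic of defining classes only where
two inference approaches agree. Class proposals come from ground truth
(simulations) or a user file; de-novo class discovery is deliberately not
implemented, because real classes embed taxonomic knowledge no clade
enumeration can recover. `assign_query()` is strictly phylogenetic: the
smallest clade containing the query and at least one reference must be
single-class and supported, otherwise the query stays unclassified.

**Transfer evidence.** Three independent lines:

1. *Incongruence* — `detect_incongruent_leaves()` calls a leaf whose
   smallest supported clade with at least `min_context = 2` other leaves
   is single-group and foreign to the leaf's own group. This
   smallest-supported-clade rule matches leaf-level transfer claims
   without implementing full DTL reconciliation.
2. *Composition* — `gc_windows()` (1000 bp windows, 30 bp step) profiles
   the host context; `gc_anomaly()` flags a region whose G+C differs from
   the background mean by at least `z_min = 2` standard deviations of the
   window values, with an absolute-difference fallback (0.05) for
   degenerate backgrounds. The z-rule is this package's operationalisation
   of "different G+C content"; it is configurable.
3. *Synteny* — `detect_cotransfer()` connects genomes of *different*
   taxon groups whose focal-gene neighbourhoods reach `jaccard_min = 0.3`
   similarity (strand-insensitive by default; orientation noise would
   otherwise dominate) and reports connected components of size ≥ 2.

`combine_evidence()` grades candidates: two or more lines → strong, one →
weak, none → none. Genomes that *donated* a conserved neighbourhood
legitimately acquire the synteny line; they are not called strong unless a
second line concurs.

**Recombination.** `locate_breakpoint()` places the breakpoint at the
alignment column of the midpoint between the first two `QXXXY` copies — a
documented convention, since nothing pins the junction to an exact offset
between the copies. `detect_chimera()` then runs NJ + bootstrap
independently on the two fragments (each at least 50 columns, to avoid
spurious placements) and declares a chimera only when the two fragments
place the query confidently in different reference groups. Every positive
verdict carries the caveat that a transient acceleration of evolutionary
rate can blur phylogenetic signal in a similar way; the package reports
the caveat rather than adjudicating it.

## Parameters at a glance

| Parameter | Default | Units / range | Rationale |
|---|---|---|---|
| `support_min` | 60 | bootstrap % | conventional "well-supported" threshold |
| `bootstrap_reps` | 100 | replicates | standard nonparametric bootstrap size |
| `window`, `step` | 1000, 30 | bp | standard composition-scan window |
| `z_min` | 2.0 | sd units | two-sigma anomaly rule |
| `jaccard_min` | 0.3 | fraction | trio of 6 neighbours shared → 3/9 ≈ 0.33 |
| `k_long_branch` | 4 | × median | long-branch flagging multiplier |
| `min_gap` | 10 | residues | planted catalytic-motif spacing |
| `score_cutoff`, `gap_cutoff` | 0.5, 0.5 | fraction | trimming defaults (ours) |
| `amelioration` | 0 (recent) | fraction | fixture convention |
| `min_fragment_columns` | 50 | columns | avoids tiny-fragment placements |

## Validation design and problem sizes

The validation suite runs entirely on simulated data: 100 random additive
trees (4–12 taxa) for NJ exactness; 100 perturbed 6-taxon matrices
against the exhaustive minimum-OLS oracle; exact window-arithmetic checks
at the standard window settings; motif-filter recovery with 0, 3 and 10
degraded genes; 20 transfer simulations (12 species in two groups, 3
planted transfers each, amelioration 0, co-transferred trios) with pooled
recall and precision ≥ 0.8; 10 chimeras and 10 controls with accuracy
≥ 0.9 and no false positives; 20 class simulations (three classes, ≥ 0.4
between / ≤ 0.1 within divergence) with full two-setting concordance; and
byte-level determinism of two full pipeline runs under one seed. These
sizes keep the whole suite within a few minutes on a single core while
leaving each stochastic check enough replicates to be meaningful.

The bootstrap-stability property (two 200-replicate runs agreeing within
5 points per edge) is checked on a balanced eight-leaf tree with uniform
0.06 internal edges and 1000 sites. Stability in that sense presumes
decisive edges: random coalescent trees contain arbitrarily short internal
edges whose supports hover near 50% and legitimately fluctuate between
runs, which would turn the check into a coin flip without saying anything
about correctness.

## What passing these tests does not show

The simulator's sequences evolve under uniform replacement without rate
heterogeneity, compositional bias, or alignment error — the pipeline
consumes the *true* alignment, so alignment-construction artefacts
(a major practical difficulty with real CHS, whose N- and C-termini are
highly variable) are out of scope by design. Real transfer detection also
contends with ancient, ameliorated transfers (the composition line fades
with $a \to 1$), incomplete lineage sorting, and taxon sampling gaps, none
of which the fixture emulates. Recovery rates on simulated data are
therefore upper bounds on what the same settings achieve on real
proteomes.

Known limitations worth naming: the strict smallest-clade assignment rule
occasionally leaves a true chimera "unclassified" on one fragment when
near-identical references compete for the query (observed as support
shortfalls in two or three cases per twenty at the standard divergences);
transfer direction is not inferred beyond recipient identification; and
codon back-translation cannot reach extreme G+C targets for every protein
composition (targets are clamped to the achievable range).
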