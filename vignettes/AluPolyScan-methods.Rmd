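---
title: "Detecting and genotyping polymorphic Alu elements from paired-end reads"
author: "AluPolyScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and genotyping polymorphic Alu elements from paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AluPolyScan)
```

## The problem

Alu elements are ~300 bp SINE retrotransposons present in more than a million
copies in primate genomes.  The young AluY subfamilies are still
polymorphic in humans: an element may be present in the reference genome but
absent from a sequenced individual ("deleted with respect to the
reference"), or present in the individual but absent from the reference
("inserted").  Both states leave a characteristic footprint in paired-end
sequencing data, because the outer distance between the two reads of a
fragment, mapped to the reference, is shifted by the element length whenever
the element separates the two reads on one genome but not the other.

AluPolyScan genotypes deletions at annotated Alu loci, discovers and
genotypes insertions at unannotated positions, and ships a diploid
population/trio simulator so the entire method can be exercised end to end
without any external data.

## The insert-size model

All evidence flows through the insert-size distribution $Y$, estimated per
individual from uniquely mapped proper pairs.  We store the *outer* distance
(rightmost end minus leftmost start; 0-based half-open coordinates
throughout).  Location and scale are estimated robustly -- median and
$1.4826\times$MAD -- so that the minority of pairs spanning true structural
events cannot inflate the scale; the window quantiles $Y_\epsilon$ and
$Y_{1-\epsilon}$ (default $\epsilon = 0.005$) delimit "proper" inserts.  The
default density is Gaussian in these robust parameters; a smoothed empirical
density is available (`form = "empirical"`) when the library is visibly
non-Gaussian.  Both densities are floored at $10^{-300}$ so that
log-likelihood products over many pairs remain finite; the floor only
matters for inserts beyond ~37 standard deviations, far outside any window
we evaluate.

A note on conventions: the spacing between the two reads of a pair (the
mate gap) equals the outer distance minus both read lengths.  Two parts of
the method are naturally expressed on the gap scale and the package converts
internally:

* the covering geometry of insertion discovery (below) uses gap quantiles
  $Y^{gap} = Y - 2L$, so that a cover interval has width
  $Y^{gap}_{1-\epsilon} - Y^{gap}_{\epsilon} + L$, about one element length
  plus insert noise -- wide enough that every mate of a true insertion is
  co-coverable at the true position;
* the length-refinement equations use start-to-start distances
  ($m_t = \bar Y - L$), which is the scale on which the per-read offset
  equations are linear.

## Scanning for Alu mates

A single pass over the coordinate-sorted alignments classifies each pair as
proper or improper (mate unmapped, interchromosomal, wrong orientation, or
insert outside $[Y_\epsilon, Y_{1-\epsilon}]$).  For improper pairs, ends
that are unmapped or multi-mapping are aligned locally (both orientations)
against the consensus library; a read is an *Alu read* when the best local
alignment reaches $\ge 90\%$ identity over $\ge 80\%$ of the read.  These
thresholds are configurable; they were chosen once as a standard "aligns
well" criterion and sit comfortably between the ~97% identity of a read
drawn from a 3%-diverged element copy and the <60% identity of random
sequence.  When an improper pair has exactly one Alu end and a uniquely
mapped mate ($b = 1$ best mappings), the mate becomes an *Alu mate*,
labelled `l` if it lies to the left of the implied element (anchor on the +
strand) and `r` otherwise, and carries the element name, family and the
offset $a_t$ of the Alu read within the consensus.  Reads with $b$ best
mappings otherwise contribute weight $1/b$.

## Genotyping deletions

At an annotated locus of length $l_{Alu}$ we collect the spanning set $T$:
pairs with both ends inside the window extending $Y_{1-\epsilon}$ beyond the
locus *whose span overlaps the element*, plus any Alu mates in the window
realigned into the locus element via their consensus offsets.  The overlap
restriction is deliberate: the genotype model treats every $t \in T$ as
drawn from $Y$ (element present on that fragment's haplotype) or from
$Z = Y + l_{Alu}$ (element absent), which is only true of fragments that
interact with the element -- window pairs wholly to one side are
$Y$-distributed under every genotype and would otherwise swamp the
homozygous-deletion likelihood.

With $g$ = number of haplotypes carrying the deletion:

$$P(D\mid 0) = \prod_{t\in T} Y(t), \qquad
  P(D\mid 1) = \prod_{t\in T}\Big(\tfrac13 Z(t) + \tfrac23 Y(t)\Big), \qquad
  P(D\mid 2) = \prod_{t\in T} Z(t).$$

The heterozygote weights reflect that a window-spanning fragment arises in
one of three equally likely ways: from the deleted haplotype, or from the
element-bearing haplotype with one read inside the element and the mate on
either side.  The call is the arg-max (ties toward smaller $g$); copies of
the element carried are $2 - g$.  Read weights $1/b$ multiply the
log-factors (configurable off); with all-unique evidence this is a no-op.

### Population test

Across $m$ individuals, under Hardy-Weinberg equilibrium with deletion
allele frequency $p$:

$$L(p) = \prod_{i=1}^m \Big((1-p)^2 P(D_i\mid 0) + 2p(1-p) P(D_i\mid 1)
  + p^2 P(D_i\mid 2)\Big),$$

maximised over $p \in [0,1]$ by golden-section/Brent search (`optimize`,
tolerance $10^{-6}$) with the boundary values checked explicitly, since the
null $p = 0$ sits on the boundary.  The statistic
$2\log L(\hat p) - 2\log \prod_i P(D_i\mid 0)$ is referred to $\chi^2_1$;
this is the default test.  Without HWE the genotype-frequency triple
$(f_0, f_1, f_2)$ is fitted on the simplex by EM and the statistic has two
degrees of freedom.  Because the null is a boundary point, the test is
conservative (roughly half the nominal size empirically), which the
calibration test asserts as type-I $\le 0.06$ at $\alpha = 0.05$.  Across
annotated loci, p-values are Bonferroni-adjusted by default (configurable
to BH or none) and flagged at $\alpha = 0.05$.

## Discovering insertions

An `l` Alu mate with right endpoint $l_r$ is *covered* by an element
position $\alpha$ when $l_r + q_{lo} \le \alpha + L$ and
$l_r + q_{hi} \ge \alpha$, with $(q_{lo}, q_{hi})$ the gap quantiles;
symmetrically for `r` mates.  Discovery chooses element positions $A$ and
error reads $E$ minimising $|E| + k|A|$ (default $k = 3$: three co-coverable
mates warrant an element rather than three error labels).  Because cover
regions are intervals on the line, the optimum is found by dynamic
programming over candidate positions restricted to interval right endpoints
(any stabbing point can slide right to the nearest covered interval's right
endpoint without losing coverage).  Ties are broken toward fewer errors,
then leftmost positions.  To keep instances small, a sweep first sums the
$1/b$-weighted `l` mates within $Y_{1-\epsilon}$ left of each position and
`r` mates within $Y_{1-\epsilon}$ right of it, evaluated only at read
endpoints where the indicator changes; maximal runs above a threshold
(default 3, mirroring $k$) become candidate windows and the solver runs per
window.

For several individuals the objective becomes
$|E| + k_1|A| + k_2\sum_j |A_j|$ (defaults $k_1 = k_2 = 2$), with $A_j$ the
individuals assigned to element $j$.  The exact complexity of this problem
is open, so the package ships the heuristic: per-individual clusters of at
least two mates within a $2Y_{1-\epsilon}$ window propose positions,
positions within $Y_{1-\epsilon}$ (the default merge distance -- "very
close" made concrete) merge across individuals, and an individual joins a
merged element when it contributes at least two covering reads, its reads
otherwise going to $E$.  A small-instance exhaustive solver in the test
suite certifies the single-individual optimum.

## Refining and genotyping insertions

The inserted element is modelled as the matched consensus of length
$l_{Alu}$ extended by signed offsets $\lambda$ (left) and $\rho$ (right).
Each supporting mate gives a per-read estimate, e.g.
$\lambda^t = m_t - d_t - a_t$ with $d_t = p_{Alu} - c_t$, combined by
inverse-variance weighting with the individual's insert standard deviation;
negative per-read estimates are allowed.  Position re-estimation isolates
$p_{Alu}$ from the same equations.  The loop alternates length and position
estimation until the position moves less than 1 bp (at most 10 iterations;
positions are integral and the two-block ascent stabilises in two or three
steps).  One numerical point deserves note: the equations only identify
$p + \lambda$ and $p - \rho$ jointly, so starting the loop by estimating
offsets at an arbitrary seed position would freeze the position there.  The
loop therefore seeds the position from the supports under
$\lambda = \rho = 0$, after which the iteration is stable and, on supports
simulated at the true length, recovers the planted position to within a few
base pairs.  Supports whose anchor sits exactly at the insertion point
count as left supports (deterministic tie-break); a side with no support
has its offset flagged undefined and treated as 0 with infinite variance.

The refined element (consensus trimmed for negative offsets, padded with
copies of its own flank for positive ones) is spliced into the reference in
silico.  The element is then *present* in the modified reference, so every
individual is genotyped with the deletion machinery: mapped pairs whose
inner gap straddles the insertion point re-enter with $t + \text{length}$
(reads crossing the point itself are junction-split and ignored; split-read
evidence is out of scope), Alu mates realign into the element via their
consensus offsets, and copies of the element carried are again $2 - g$.

## The simulator

The built-in benchmark plants 5 consensus entries (synthetic random 300-mers
by default, named after active subfamilies; a real consensus FASTA is
accepted) at 10 sites each on a 2 Mb synthetic reference: 50 sites, each
copy independently mutated at 3% per base, each family receiving the
frequency ladder {2, 4, 5, 10, 20, 80, 90, 94, 96, 98}% once.  Sites keep a
minimum separation of $2Y_{1-\epsilon}$ plus an element length, and at most
1% N in the surrounding window when a real reference is supplied.  100
haploid chromosomes draw carrier status independently per site (expected
24.95 planted elements per haploid) and are paired sequentially into 50
diploids; trios draw four fresh parental haploids and copy one uniformly
chosen haploid per parent into the child, so child haplotypes match a
parental haplotype exactly by construction.  Reads are 100 bp pairs with
Gaussian(400, 50) outer inserts at 5x coverage per haploid, with optional
uniform substitution error (0 or 2% in the benchmarks).  Read length and
insert parameters are not dictated by the benchmark design and are declared
package defaults, configurable in `simulationConfig()`.

The simulator emits truth alignments by construction instead of running an
external mapper: reads lying wholly in sequence present in the target
reference map uniquely at their projected coordinates; reads overlapping a
planted element (when mapping to the element-free reference) are emitted
unmapped with their sequence and must pass the library classifier like any
real read; reads crossing a breakpoint absent from the target are
junction-split and dropped from the mapped stream.  Best-hit counts for
Alu-derived reads are computed against the library.  Consequences worth
stating plainly: mapping ambiguity in repetitive reference context, chimeric
fragments, indel/quality error structure and reference Ns are *not*
emulated, so passing benchmarks demonstrate the statistical machinery and
its implementation, not robustness to real-data mapping artifacts.  With
substitution error the truth alignment of a mappable read is unchanged (two
errors in a 100 bp read do not defeat a unique mapping), so error stresses
only the classifier; the error-induced sensitivity drop is accordingly
smaller here than a mapper-in-the-loop experiment would show.

## Benchmarks and problem sizes

`runInsertionBenchmark()` scores per-individual discovery against the truth
table: an expected event is an (individual, site) pair with at least one
carried haplotype, found when a call lands within 150 bp (about one element
half-length plus position noise) of the true point; calls matching no
carried site are false positives.  `runDeletionBenchmark()` maps reads to
the all-element reference and scores called deletion genotypes the same
way.  `runTrioBenchmark()` checks Mendelian consistency of child calls
against called parental genotypes.  The shipped acceptance checks run the
full 50-diploid cohort (about 100,000 pairs per individual) twice for
insertions and twice for deletions plus a 10-trio experiment; property
checks use 1000 random covering instances (at most 12 reads, certified by
exhaustive enumeration), 1000 estimator-recovery replicates and 1000 null
LRT loci with 20 individuals each.  These sizes were chosen as the smallest
that make the binomial/chi-square tolerances meaningful.

## Limitations

* Deletions are only sought at annotated loci; insertions only where Alu
  mates cluster.  Split-read ("broken" read) evidence is not used.
* A single insertion event shared by all carriers is assumed; allelic
  length heterogeneity at one site is not modelled.
* Elements are planted and matched in the forward orientation of their
  consensus; classification handles reverse-complement reads, but
  orientation of the inserted element itself is not reported.
* The multi-individual cover is heuristic; only the single-individual
  solver is optimal.
* The spanning-set realignment of Alu mates uses the classifier's consensus
  offsets rather than a second banded alignment against the locus; with
  consensus-derived elements these coincide up to the local alignment's
  end-trimming.
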