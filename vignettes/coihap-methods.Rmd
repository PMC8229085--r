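---
title: "Methods: in-silico PCR-RFLP typing and haplotype population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico PCR-RFLP typing and haplotype population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coihap)
```

## Scope and model

`coihap` implements the computational chain of a molecular survey of
*Bemisia tabaci* (whitefly) populations typed at the mitochondrial COI
locus:

1. **in-silico PCR-RFLP typing** — locate primers, cut out the 866-bp
   diagnostic COI amplicon, digest it with ApoI, and read the species or
   haplogroup off the fragment pattern;
2. **population genetics** — collapse sequences into haplotypes and compute
   haplotype diversity, nucleotide diversity, segregating sites, Tajima's
   *D* and Fu's *Fs*;
3. **median-joining haplotype networks** and a TN93 + neighbor-joining
   distance summary;
4. a **synthetic-data generator** that produces COI-like populations with
   controlled haplogroup identity and diversity, so every stage can be
   validated against known truth.

## In-silico PCR-RFLP

### Primer search and amplicon extraction

Primers are matched IUPAC-aware (an ambiguity code in the primer matches
any base it denotes; the subject sequence is read literally) on both
strands, with a configurable mismatch budget (default 1). The amplicon
spans from the first base of the forward-primer hit to the last base of
the reverse-primer hit, *primers included* — the convention under which
the diagnostic COI amplicon is 866 bp. When several primer-hit pairs
exist, the pair whose product is nearest the expected length wins.

Primer sequences are **not** hardcoded: diagnostic assays publish the
primer names but the package cannot assume any particular pair. A
*pre-cut bypass* exists instead: an input that is already amplicon-length
and has no primer hit passes through unchanged, flagged `pre_cut`, so the
pipeline runs on deposited amplicon sequences with no primer
configuration at all. The test suite asserts that a primered run on
flanked constructs and a pre-cut run on bare amplicons give byte-identical
downstream results.

### Digestion conventions

A restriction enzyme is a recognition sequence plus a plus-strand cut
offset; ApoI is `R^AATTY` (offset 1). Cut positions are reported as
**prefix lengths** — the number of bases 5' of the cut on the plus
strand — because that is the arithmetic under which published diagnostic
patterns add up exactly: cuts at 252, 296, 562 and 654 on an 866-bp
amplicon give fragments 252, 44, 266, 92 and 212, summing to 866.
Double-strand nicks and sticky-end overhangs are deliberately ignored;
fragment lengths are distances between plus-strand cut points, which is
what a gel shows. Overlapping recognition matches each contribute a cut;
duplicates collapse. Ambiguity codes inside an amplicon make site status
undecidable and raise an error naming the position rather than guessing.

### Classification

The pattern library ties labels to cut-position sets; expected fragments
are *derived* from the cuts at construction, so the two can never
disagree. Three match modes:

* `cut_set_exact` (default for sequence-derived digests): identical cut
  sets;
* `fragment_multiset`: identical fragment multisets;
* `gel_visible_fragments`: fragment multisets after discarding, from both
  sides, fragments shorter than `gel_min_visible` (default 25 bp — chosen
  because an 18-bp diagnostic fragment is known not to be visible on a
  standard stained agarose gel, while ~44-bp fragments are). This mode is
  intended for classifying user-entered fragment lists read off gels.

Only a distance-0 match classifies; anything else is `unclassified` with
the nearest pattern and its distance reported. Distance-0 ties are
reported as unclassified with both candidates, never resolved silently.

The built-in library carries the three MED ApoI patterns (MEDQ1; the
Sardinian MEDQ1 variant with its extra site at position 672; MEDQ2). The
MEAM1 pattern is *not* built in: its cut positions are assay-specific and
must be supplied by the user, because inventing them would be worse than
requiring configuration.

## Population genetics

All statistics are computed from first principles on equal-length
sequences.

* **Column policy.** `complete_deletion` (default) excludes any column
  containing a gap or ambiguity code from every statistic, mirroring the
  common default of desktop popgen software; `pairwise_deletion` is
  provided as an explicit alternative. The choice matters for real,
  partially ambiguous data; published values computed under an unknown
  policy may only be reproducible under one of the two.
* **Haplotype diversity.** Nei's unbiased estimator
  `Hd = n/(n-1) (1 - sum p_i^2)` with Nei's sampling variance for the
  reported SD. `Hd` depends only on the haplotype frequency spectrum,
  which the tests exploit: a generated population's `Hd` must equal the
  value implied by its configured frequencies exactly.
* **Nucleotide diversity.** `pi = sum_{i<j} d_ij / (C(n,2) L)`; the SD is
  the square root of the total (stochastic + sampling) no-recombination
  variance `(n+1)/(3(n-1)L) pi + 2(n^2+n+3)/(9n(n-1)) pi^2`. Internally
  pairwise differences are computed between unique haplotypes and
  weighted by frequencies, so large samples stay cheap; the identity
  `pi = theta_pi / L` under complete deletion is asserted in tests.
* **Tajima's D** uses the standard constants
  (`a1, a2, b1, b2, c1, c2, e1, e2`). With no segregating sites the
  statistic is *undefined* and reported as such — never as 0, which would
  be a valid-looking but wrong value.
* **Fu's Fs** follows the original definition:
  `S' = Pr(K >= k_obs)` under the Ewens sampling formula evaluated at
  `theta = theta_pi` (mean pairwise differences per sequence, **not** per
  site, the estimator used by the common desktop implementation), and
  `Fs = ln(S'/(1-S'))`. The Ewens distribution
  `Pr(K=k) = |s(n,k)| theta^k / theta^(n)` is computed with unsigned
  Stirling numbers of the first kind by the standard recurrence, entirely
  in log space with `logaddexp` accumulation; it normalises to 1 within
  1e-12 up to at least n = 200. The tests cross-check it against an
  independent route — the sequential (Chinese-restaurant) recurrence
  `P_{n+1}(k) = theta/(theta+n) P_n(k-1) + n/(theta+n) P_n(k)` — which
  avoids Stirling numbers altogether; exact integer Stirling numbers
  overflow double precision beyond n ≈ 20 (|s(n,1)| = (n-1)!), so a
  probability-space recurrence is the sound exact oracle at n = 30.
* **No p-values** are attached to *D* or *Fs*: their null distributions
  require coalescent simulation, which is out of scope; reporting
  table-derived significance without the tables would be misleading.

## Median-joining networks

The network construction:

1. restrict haplotypes to segregating columns;
2. connect them by the **minimum-spanning network** — the union of all
   minimum spanning trees, computed as all edges whose weight is within
   `epsilon` of the bottleneck (minimax-path) distance between their
   endpoints. `epsilon = 0` is the default, matching the common default
   of network software; larger values admit more alternative links.
3. for node triples connected in the network, compute per-column
   **majority (median) vectors**; add the median that most reduces the
   total connection cost, defined as the weight of a minimum spanning
   tree over the augmented node set. Where the three states all differ at
   a column there is no majority; the candidate keeps the state of the
   first node in processing order — a deterministic rule that matches the
   binary-dominant behaviour of mtDNA SNPs.
4. iterate to a fixpoint. Each accepted median strictly decreases an
   integer-valued cost bounded below, so termination is guaranteed. When
   no *single* median reduces the cost, pairs of candidates (including
   second-level medians of triples through a candidate) are tried before
   stopping: two interior vectors can be jointly cost-reducing where
   neither helps alone, and without this the construction provably misses
   optima on some four-haplotype inputs.
5. prune obsolete medians: degree ≤ 2 median nodes lying on no shortest
   connection between observed haplotypes are removed iteratively.

Determinism everywhere: nodes in first-occurrence order, candidates in
lexicographic order, ties toward the lexicographically smallest sequence.
On all tested instances with ≤ 4 haplotypes over ≤ 5 segregating columns
(300 random instances plus canonical toys), the final cost equals the
optimum found by exhaustive Steiner search over per-column observed
states.

Trait annotations (e.g. region of origin per haplotype) attach counts to
observed nodes and never affect topology — asserted in tests. "Main
haplotype groups" drawn on published network figures are hand annotations;
the package deliberately does not infer them. An explicit
`edge_cut_groups()` convenience (components after removing edges heavier
than a threshold) is provided, clearly labelled as a computational
grouping, not a reproduction of hand-drawn figure annotation.

Exports: GraphML (lossless round trip via igraph), a PopART-style NEXUS
with a Traits block plus a private network block that makes the file
lossless too, and a TSV edge list.

## Distances and trees

`tn93_distance()` is the Tamura-Nei (1993) closed form with empirical
base frequencies pooled from each pair and separate purine/pyrimidine
transition classes (computed via `ape::dist.dna` on the pair; the test
suite checks it against an independently coded evaluation of the closed
form). Saturated pairs — where a logarithm argument goes non-positive —
are flagged `NA`, never clamped to a number. Gamma rate variation is
*not* implemented: the tree stage here is a cluster sanity check, not an
inference engine, and full likelihood tree inference (alignment,
bootstrap, model selection) is an explicit non-goal. Neighbor joining is
Saitou-Nei via `ape::nj` with negative branch lengths clamped to zero
(logged); the all-zero matrix degenerates to a star tree in label order.
Newick output quotes labels containing metacharacters; the writer is
implemented in-package because the stock serialiser rewrites labels
containing spaces instead of quoting them.

## The synthetic-data generator

The generator's defaults encode the population structure the package is
validated against:

* **MEDQ1-like**: 31 specimens, 13 haplotypes, frequency composition
  chosen as the 13-part composition of 31 whose Nei `Hd` is closest to
  0.908 (found by exhaustive partition enumeration: 8, 4, 3, six 2s, four
  1s), star-like genealogy (every derived haplotype is a direct mutant of
  the central template), and 2–3 substitutions per derived haplotype —
  chosen so the mean pairwise difference lands near 3.5 substitutions,
  i.e. a nucleotide diversity of about 0.004/site over 866 bp.
* **MEDQ2-like**: 23 specimens, 3 haplotypes at frequencies (19, 3, 1)
  (`Hd ≈ 0.312`), one substitution per derived haplotype
  (`pi ≈ 0.0004`).
* **Sardinian MEDQ1**: 5 specimens, 2 haplotypes, carrying the extra ApoI
  site at position 672.

Templates carry exactly the requested ApoI cut sites: sites are planted
as concrete realisations of `RAATTY` and spurious sites in the random
background are destroyed by single-base resampling until a clean scan,
with bounded retries. Templates for different haplogroups derive from a
common ancestor (default 25 substitutions for MEDQ2, about 3% — a
realistic within-species haplogroup divergence); independently random
templates would be ~75% divergent, far beyond anything biological and
TN93-saturated.

Mutations in derived haplotypes avoid recognition-site windows (so every
generated specimen round-trips through the classifier, asserted at 100%
in tests) and the outer 25 bp (so primer-based extraction stays exact on
every haplotype); a flag lifts the site protection for generating
deliberately aberrant patterns. Digestion of every derived haplotype is
re-verified after mutation, with redraws on the rare collision. Seeding
uses one master seed with per-haplotype streams at fixed offsets, so a
subset of haplotypes can be regenerated identically.

What the generator does **not** emulate: transition/transversion bias and
codon structure (substitutions are unconstrained — no downstream
statistic in scope depends on them), indels, recombination (absent from
animal mtDNA), within-haplotype sequencing error, and base composition
bias (templates are uniform random). Passing tests therefore validate
the *arithmetic* of the statistics and the *logic* of the typing chain,
not the realism of any particular biological parameter combination.

## Numerical and interface choices

* Undefined statistics propagate as explicit flags with reasons, never
  as silent zeros or NaNs.
* Exact integer arithmetic wherever the quantity is integral (cut
  positions, fragments, Hamming distances, Steiner costs).
* Log-space accumulation for all Ewens/Stirling computations.
* The frequency-search utility enumerates all partitions exhaustively for
  n ≤ 60 (a few hundred to a few thousand compositions) and falls back to
  deterministic hill-climbing beyond.
* Errors are classed conditions (`coihap_parse_error`,
  `coihap_config_error`, `coihap_data_error`, ...) naming the offending
  record, column or position.
* Problem sizes in the test suite: digestion is cross-checked against an
  exhaustive IUPAC-expansion scan on 1,000 random 200-bp sequences;
  Steiner optimality on 25 random small instances per run (300 during
  development); generator recovery on 100 seeds of the MEDQ1 preset and
  20 of the MEDQ2 preset. These sizes exercise every code path while
  keeping a full run to well under a minute.

## Known limitations

* Published diversity values for the deposited survey sequences can only
  be checked against a user-fetched copy of the GenBank records; the
  package ships no sequence data.
* `gel_visible_fragments` mode cannot distinguish patterns whose visible
  fragments coincide; the cut-set modes can.
* The median-joining depth-2 stall search is exact for the small-instance
  class it is tested on but is a heuristic in general, as is every
  median-joining implementation; epsilon and masking choices can change
  published network topologies, which is why network topology is treated
  as a qualitative, not exact, validation surface.
* TN93 distances without gamma rate variation underestimate divergence on
  saturated data; the package flags saturation rather than correcting it.
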