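---
title: "Methods: union-code SSP typing, its decoder, and the simulation world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: union-code SSP typing, its decoder, and the simulation world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlassp)
```

## The model

The typing platform interrogates the class I HLA-A, -B and -C loci with
arrays of 20, 46 and 15 multiplexed real-time PCR reactions. Each
reaction carries a sequence-specific primer pair whose 3' extremes (often
sharpened by locked-nucleic-acid bases) determine which alleles amplify,
plus a variation-insensitive primer pair in the converse exon that
amplifies regardless of genotype and serves as an internal standard. The
two amplifications are read out by probes with different dyes.

Formally the panel is a binary code book: allele $a$ has a pattern
$P(a) \subseteq R$, the set of reactions that address it. Because PCR on
a heterozygous template amplifies whenever either chromosome matches, a
diploid genotype renders the superimposed (union) pattern
$P(a,b) = P(a) \cup P(b)$. Typing therefore reduces to (i) scoring each
reaction positive or negative, and (ii) inverting the union map. The
inversion is exact precisely when all $n(n+1)/2$ genotype unions are
distinct; `uniqueness_audit()` verifies this property and reports it as
105/105 distinct for HLA-A, 78/78 for HLA-C, and 273/276 for HLA-B, where
three genotype pairs collide. All three collisions trace to B\*4201 and
B\*4202 differing by a single base: $P(B*4202) = P(B*4201) \setminus
\{\text{HLA-B 004}\}$, and reaction 004 also addresses B\*0702 and
B\*8101, so pairing either of those alleles (or B\*4201 itself) with
B\*4201 versus B\*4202 yields identical unions.

## Reaction calling

A reaction is scored from the paired cycle-threshold values,

$$\Delta C_t = C_t^{\text{specific}} - C_t^{\text{internal}},$$

with $C_t = 60$ encoding "threshold never crossed" (the instrument
convention of the platform). Tunable parameters:

* **`cutoffs` (default 7 cycles).** The platform's own per-reaction
  cutoffs were determined empirically and are not public, so the package
  uses a global default of 7, overridable per reaction. Under the
  simulator's noise model reactive reactions sit at
  $\Delta C_t \approx 1 \pm 0.5$ and non-reactive ones at $\ge 12$, so 7
  is more than eight standard deviations from either class.
  `calibrate_cutoffs()` supplies a data-driven alternative (midpoint
  between the extreme labeled classes, flagging non-separable reactions).
* **`internal_fail_ct` (default 40 cycles).** A reaction whose internal
  standard has not amplified by cycle 40 is considered failed
  (`invalid`) rather than negative; 40 cycles is the conventional qPCR
  detection bound, well below the 60-cycle sentinel.

## Decoding

`decode()` compares the observed positive set, restricted to reactions
with a valid read-out, against every genotype union restricted the same
way. The contract:

1. exact matches are the candidate set (`exact`, or
   `ambiguous_collision` when several genotypes share the pattern);
2. otherwise, genotypes minimizing the symmetric difference are returned
   if that minimum is at most `max_mismatch` (default 1, flagged
   `possible_nonaddressed`), ties all reported;
3. otherwise `no_call`. An all-negative pattern is a `no_call` flagged
   `all_negative` — no addressed allele has an empty pattern.

`max_mismatch = 1` reflects how near-cognate non-addressed alleles
behave on this panel: they typically differ from an addressed relative by
the addition or absence of one or two reactions. Homozygote candidates
carry `homozygote_overcall_risk`, since a rare non-addressed second
allele with an eclipsed pattern would be invisible.

How partially failed plates were handled in the original validation is
not documented; restricting both observed and expected patterns to the
valid reactions is this package's reasoned extension, and it is monotone:
shrinking the valid set can only grow the exact candidate set (tested as
a property).

**Ambiguity policy for validation.** `carrier_confusion()` counts a
sample as a called carrier of allele $a$ only when *every* candidate
genotype contains $a$. This is conservative — it never inflates
sensitivity — and makes B\*4201/B\*4202 the only alleles whose carrier
status can be genuinely undecidable; `validate_typing()` therefore scores
those two alleles on samples outside the collision groups (the default
`exclude_collisions = TRUE`), while still requiring the truth to be in
the candidate set everywhere. Ratios with empty denominators (e.g.
sensitivity with zero true carriers) are reported `NA`, never 0.

## The in-silico predictor

`find_primer_sites()` models SSP specificity with three rules, exposed in
`ssp_rules()` rather than hard-coded, because the real determinant —
relative amplification efficiency — is empirical:

* the `three_prime_exact = 3` terminal bases must match with zero
  mismatches (3'-extreme specificity);
* LNA positions must match exactly wherever they fall (LNAs are modeled
  as "higher specificity", their efficiency cost is ignored);
* at most `max_other_mismatch = 0` IUPAC-incompatible positions
  elsewhere; degenerate primer codes (Y, S, M, R, N, V, W) expand per the
  IUPAC table.

An amplicon is predicted for a forward site and a downstream
minus-strand reverse site spanning fewer than 250 bp — under the assay's
cycling conditions longer products do not amplify efficiently — and a
reaction is predicted reactive only if its probe matches IUPAC-exactly
inside such an amplicon. All coordinates are 1-based inclusive, matching
the convention of the panel tables.

The packaged fixtures contain no proprietary allele sequences; the
predictor is tested against synthetic templates engineered by
`make_fixture_alleles()` to realize a chosen target matrix (reactive
blocks embed intact primer + probe sites; non-reactive blocks mutate the
forward primer's 3'-terminal base to an incompatible base; blocks are
padded to ≥ 260 bp so no cross-reaction amplicon can sneak under the
length bound). Running the predictor on real exon 2–3 templates is a
supported user workflow, not a test dependency.

## Population genetics

* **Allele frequencies** are direct counts over $2n$ chromosomes;
  carrier frequencies are fractions of samples with at least one copy.
  `coverage()` sums addressed-allele frequencies;
  `cumulative_coverage_curve()` orders alleles by descending frequency
  (ties lexicographic).
* **Hardy–Weinberg testing** is a seeded Monte-Carlo exact test in the
  Guo–Thompson spirit: shuffle the $2n$ allele copies, re-pair, and
  compare the conditional probability of the genotype configuration
  given the allele counts. The original analysis does not state its HWE
  method; this is a substitute with the right null, not a replication,
  and its p-values are checked for null uniformity in the test suite.
  Monomorphic data return $p = 1$ by convention.
* **Chord distance.** The platform's source cites an external
  implementation without printing a formula; the package fixes the
  normalization as
  $D^2 = 4\sum_l (1 - \sum_a \sqrt{p_{1a} p_{2a}}) / \sum_l (a_l - 1)$
  with $a_l$ the alleles seen at locus $l$ in either population. This
  gives the closed form $D = 2$ for two populations fixed for different
  alleles at one biallelic locus, used as an anchor test; exact numeric
  agreement with other implementations' normalizations is not claimed.
* **Trees and ordination.** `nj_tree()` is the standard Saitou–Nei
  agglomeration with a deterministic tie-break (smallest index pair) and
  negative branch lengths clamped to zero with a warning; it recovers
  additive matrices exactly (checked against the generating tree's
  path-length matrix, and against an independent NJ implementation).
  "PCA on genetic distances" is realized as its principled equivalent,
  classical metric scaling (`pcoa()`): double-center $-D^2/2$,
  eigendecompose, scale by $\sqrt{\lambda}$; axis signs are fixed by
  making the largest-magnitude loading positive; negative eigenvalues
  are reported but yield no axes.
* **Aliasing and contingency tests.** `default_allele_aliases()` encodes
  the conventional HLA-C groupings used for cross-dataset comparison
  (Cw\*0210 synonymous with Cw\*0202, plus the Cw\*0401G-style G groups);
  aliases resolve transitively with cycle detection, conserving total
  mass. `fisher_exact_2x2()` is full hypergeometric enumeration; larger
  tables use a seeded Monte-Carlo Freeman–Halton extension (the exact
  network algorithm is out of scope).

## The synthetic-data world

The simulator emulates the platform's observed read-out: a tight
internal-standard Ct distribution and a bimodal specific signal cleanly
separating carriers from non-carriers. Defaults (all overridable in
`noise_model()`):

| parameter | default | meaning |
|---|---|---|
| `internal_ct_mean`, `internal_ct_sd` | 24, 0.7 | internal-standard Ct (cycles) |
| `reactive_delta_mean`, `reactive_delta_sd` | 1.0, 0.5 | ΔCt of reactive reactions |
| `nonreactive_undetermined_prob` | 0.8 | non-reactive reactions with Ct 60 |
| `nonreactive_delta_mean`, `nonreactive_delta_sd` | 15, 2 | ΔCt of late non-reactive amplification |
| `dropout_prob` | 0 | internal-standard failure |

No Ct distributions were published, only the qualitative class
separation; the normal-with-clipping defaults were chosen once so the
classes are separated by ≥ 8 sd at the ΔCt = 7 cutoff, and are not tuned
against test outcomes. Genotypes are drawn under Hardy–Weinberg
equilibrium by random union of gametes; the end-to-end acceptance
simulation uses **uniform frequencies over the addressed alleles**, a
deliberate choice that guarantees every allele ample carriers and
non-carriers at $n = 500$ per locus (a realistic East African frequency
profile is log-like, but would leave rare-allele metrics undefined at
this sample size).

What a green simulation test does **not** establish: the simulator draws
only addressed alleles, so homozygote overcalling by eclipsed
non-addressed alleles — the platform's main real-world failure mode — is
outside the simulated world, as are plate-position effects, probe
cross-talk, partial amplification-efficiency differences, and any
wet-lab artefact upstream of the Ct value. The 100% carrier-level
sensitivity/specificity reached in simulation is a property of the code
book plus a separable noise model, a surrogate for (not a reproduction
of) the published validation-panel figures, whose raw plates are not
available.

## Verbatim fidelity and numerical conventions

* Panel fixtures are stored exactly as printed, including bracketed LNA
  notation, the legacy allele-name dialect (`Cw*0702`, no colons), and
  two self-inconsistent printed reference spans (primers A429R02 and
  B445R03, whose spans disagree with their lengths). These are flagged
  by `audit_panel()` but never corrected and never used in computation.
  One reaction row in the HLA-B source table lists two alleles with a
  missing comma; the loader's transcription splits on whitespace, which
  the 23-allele census corroborates. The HLA-B reactivity matrix is
  reconstructed from the reaction-composition table's specificity
  column (the canonical source packaged here); for HLA-A and HLA-C the
  independently printed pattern grids are also packaged and
  cross-checked cell-for-cell against the reconstruction in the test
  suite.
* Load/serialize round-trips are byte-identical; all candidate lists,
  collision groups and curve ties are ordered lexicographically;
  written floating-point artifacts use 6 significant digits; every
  stochastic operation takes an explicit seed.

## Known limitations

Binary reactivity (no efficiency modeling), no probabilistic genotype
likelihoods, no fluorescence-curve processing, no non-addressed-allele
simulation, no haplotype or linkage-disequilibrium inference. The
platform itself is a research tool scoped to the common East African
allele repertoire; decoding assumes the sample's alleles are addressed,
and flags rather than resolves the cases where that assumption can fail.
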