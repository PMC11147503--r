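---
title: "Models and methods behind ampedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ampedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ampedit` supports amplicon-based CRISPR editing experiments in which a
Cas9 ribonucleoprotein and a single-stranded oligodeoxynucleotide (ssODN)
donor are delivered to cells, and editing outcomes are read out from
amplicon sequencing, restriction digests, or size shifts. The package
covers four connected pieces of methodology:

1. **HDR donor design** — placing silent, codon-usage-matched mutations in
   the PAM and the PAM-proximal spacer so that repaired alleles are no
   longer re-cut;
2. **outcome quantification** — per-read classification into WT /
   complete HDR / partial HDR / NHEJ, plus the two orthogonal gel-based
   assays (RFLP digest fraction, insert size shift);
3. **off-target per-site summaries** — the quality-filtered pileup and
   per-target variant percentages used to demonstrate the absence of
   off-target editing, with paired FDR-corrected comparisons;
4. **zygosity planning** — a donor-mixture sampling model linking the
   mutant:silent donor ratio to clone genotypes, and a single-hit Poisson
   limiting-dilution estimator for stem-cell frequency endpoints.

A seeded synthetic-read generator ties these together and is itself part
of the tested surface.

# Coordinates and data model

All positions are 0-based with half-open intervals `[start, end)`;
between-base indices (cut sites, insertion anchors, phosphorothioate
bonds) refer to the gap after the indexed base. Rendered TSV reports use
1-based inclusive coordinates. Donors are written in the compact vendor
notation — lowercase matches the reference, UPPERCASE marks an edited
base, `*` a phosphorothioate bond — and `parse_donor()` /
`render_donor()` round-trip that notation byte-identically.

SpCas9 conventions: 20-nt spacer by default (21-nt guides are accepted —
where a printed crRNA admits both a 20- and a 21-nt protospacer reading,
both are supported via the spacer argument and neither is assumed), NGG
PAM, blunt cut 3 nt 5′ of the PAM. `cut_site()` is invariant under
reverse-complementing the amplicon.

# Donor design

`design_ssodn()` assembles homology arms (default 45 nt each, two
phosphorothioate bonds per end, mirroring the printed `t*g*…g*t`
pattern) around the cut site and places three classes of substitutions:

- **payload** edits supplied by the user;
- a **PAM-disrupting** edit when requested: only the two G positions can
  break an NGG, and a synonymous option is preferred — ranked by codon
  usage distance — with a non-synonymous fallback only behind
  `allow_nonsilent = TRUE`;
- `n_spacer_silent` **silent spacer** edits inside the PAM-proximal
  `spacer_region` (default 10 nt, the seed region; the design target is
  "PAM-proximal", and 10 nt is the smallest window consistently
  described as seed in the Cas9 literature).

"Equivalent codon frequency" is operationalised as the minimal
`|usage(WT codon) − usage(alt codon)|` over synonymous single-nucleotide
substitutions, using a bundled human codon-usage table (relative
frequency within each amino-acid family, renormalised on load; the table
is an argument of `coding_context()` and can be swapped). Ties are broken
toward the PAM. `validate_donor()` re-scans the edited allele for any
surviving spacer+PAM match on either strand, checks translation of
silent-classed edits, and counts restriction sites gained/lost — BspEI
(`TCCGGA`) being the assay-relevant default.

The designed-donor invariant is exact: mismatches = payload count +
(1 if a PAM edit was needed) + `n_spacer_silent`; a payload that itself
destroys the PAM (as in the published P95H donor) adds no extra PAM edit.

# Synthetic reads

`simulate_reads()` draws allele identities multinomially from the
mixture, then corrupts each template with per-base independent
substitutions, geometric-length insertions and deletions, and a deletion
multiplier (default 3×) inside homopolymers of length ≥ 3 — a caricature
of nanopore R10-class behaviour that stresses left-alignment and the
quality filters. Base qualities are drawn from a clipped normal
(mean 20, sd 5) for correct bases and a lower mean (default 10) for
substituted/inserted bases: basecaller confidence correlates with error,
and without that correlation a base-quality filter would have nothing to
act on. The true allele of each read rides in the FASTQ comment, where
downstream tools ignore it.

What the generator does *not* model: signal-level artefacts, chimeras,
adapters, barcode hopping, strand bias, and PCR amplification bias.
Passing tests therefore demonstrate the statistical machinery under an
idealised, parameterically controlled error process, not performance on
real flow-cell data.

Clone genotypes (`simulate_clones()`) and limiting-dilution wells
(`simulate_ld_wells()`) implement exactly the models fitted downstream,
so parameter-recovery tests are meaningful: two alleles drawn
independently (edited with probability `h`, mutant with probability `p`
given edited), and `P(well negative | dose d) = exp(-f·d)`.

# Alignment

`align_read()` performs end-free ("glocal") alignment: reference flanks
are free, the read is fully aligned, and unaligned read ends surface as
soft clips. Scoring is match +2, mismatch −4 with a **two-piece gap
penalty**: a gap of length *k* costs `min(4 + 2k, 24 + k)`. The second
piece is the package's own addition to the classical affine scheme: with
a single affine penalty at these values, a chance 2-base match inside a
long insert pays for splitting the gap, and simulated 143-bp intron
inserts fragmented into several I operations in a sizeable minority of
reads, corrupting size-shift quantification. The long-gap piece (open
24, extend 1, crossover at 20 nt) keeps such inserts contiguous — the
same reasoning that leads minimap2 to its two-piece cost. Banding covers
`2×expected_indel + 32` diagonals around the colinear band and widens
automatically (doubling) until the optimum is stable, so banded results
equal the exhaustive full-matrix optimum; tie-breaking is deterministic
(diagonal before deletion before insertion, leftmost reference end).
Indels are left-aligned post hoc to canonical VCF-style coordinates so
pileup anchors and window overlaps are reproducible.

`assign_amplicon()` tries both strands of every amplicon and converts
the score margin between best and second-best into a mapping confidence
(`min(60, 6·margin)`); a single-amplicon pool gives 60, duplicated
amplicons force 0. The unassigned floor is applied to the *base-level
support* (score of aligned columns only, gaps excluded): a read carrying
a long legitimate insert has a negative total score but overwhelming
base support, whereas junk reads fail both. SAM text import/export
round-trips CIGAR/MAPQ so minimap2 output can substitute for the native
aligner.

# Pileup and target summaries

`pileup()` applies the calling criteria of the original pipeline: reads
below mapping quality 10 are excluded entirely, base calls below quality
16 are excluded at that site only, and depth is capped at 10,000 reads
in input order. Deletions are counted once at their left-aligned anchor
(with the span recorded) *and* tracked as per-position span coverage —
the anchor drives event counting, the span drives window-overlap logic.
Insertions anchor after the preceding reference base (VCF convention).
Adjacent mismatches are counted as independent single-nucleotide
substitutions; an upstream caller that merges MNPs would count them
once, a discrepancy documented rather than resolved.

`summarize_target()` counts substitutions and insertions whose site lies
in the target window and deletions whose span intersects it (anchors
upstream included — deletions "starting in or extending into" the
window). A variant is reported only with ≥ 3 supporting reads *and*
≥ 0.1% of total reads; the fully-reference percentage is 100 minus the
sum of passing variant percentages, under the single-variant-per-read
assumption, clipped at 0 with a warning if multi-variant reads push the
sum past 100. An uncovered window reports `NA`, never 0. The default
window is spacer ∪ PAM with configurable padding — the smallest interval
consistent with scoring variants that overlap the predicted cut site.

`compare_conditions()` runs two-sided paired t-tests per target and
metric, with Benjamini–Hochberg correction across the whole family
tested in one invocation; zero-variance zero-difference pairs give p = 1
by convention (a numerical tie is evidence of equivalence, not an
error).

# HDR quantification

Three modes mirror the three wet-lab readouts:

- **sequence**: `classify_read()` labels each read by the precedence
  NHEJ > HDR_complete > HDR_partial > WT. Any indel overlapping the NHEJ
  window (cut ± 4 nt by default; narrow, to resist nanopore indel noise)
  dominates — a read with donor bases *and* a cut-site indel is an
  imperfect repair product, counted as NHEJ and never folded into HDR.
  At donor edit positions, only calls matching the donor or the
  reference base are informative votes; other calls are sequencing noise
  and are uncounted, like sub-threshold-quality calls. Reads not
  covering the window and all edit positions are ambiguous and reported
  separately. HDR_partial is never merged into HDR_complete. Fractions
  carry Wilson 95% intervals.
- **digest** (RFLP): from molecules/reads, the fraction containing the
  intact recognition site (validated to be absent from the WT allele —
  a site in WT invalidates the assay); from gel bands, the mass-weighted
  cut fraction `Σmass(cut)/Σmass(all)`, which equals the molar fraction
  because cutting conserves mass.
- **size shift**: reads whose *total* inserted length overlapping the
  cut window lies within `expected_insert_len·(1 ± tol)` count as
  integrated. The total (rather than a single-insertion rule) is the
  read-level analogue of a gel size shift and is robust to error indels
  that fragment the insert boundary. The expected length defaults to
  143 bp; where source descriptions disagree on the insert size
  (~100 vs 143 bp) the value is a parameter, deliberately not resolved
  in code.

Known limitation: under the full indel error model, per-read
classification misattributes a few percent of reads to NHEJ (error
indels landing in the cut window); the indel-free substitution regime
recovers mixtures to binomial accuracy. Bulk comparisons across
conditions are unaffected because the bias is condition-independent.

# Zygosity and limiting dilution

`genotype_distribution(p, h)` expands the two-allele sampling model:
hom-mutant `h²p²`, het mutant/silent `2h²p(1−p)`, hom-silent
`h²(1−p)²`, mutant/WT `2h(1−h)p`, silent/WT `2h(1−h)(1−p)`, unedited
`(1−h)²`. Allele independence is the model's core assumption — no
gene-conversion coupling between the two alleles. "Heterozygous" is
modelled as mutant/silent biallelic; mutant/WT clones are a distinct
class, and both conditional views (any-edited, biallelic-edited) are
exposed rather than asserting either as the canonical one. The bulk
mutant allele frequency is `h·p`, linear in the donor ratio — the fact
that makes zygosity tunable. `fit_mixture()` is the multinomial MLE
(closed-form allele counting with the full table, numerical profile
likelihood with pooled tables) with profile-likelihood 95% intervals;
`plan_donor_ratio()` inverts the closed forms, refusing het targets
above the attainable maximum of 0.5.

`ld_frequency()` fits the single-hit Poisson model by a binomial GLM
with complementary log-log link and `log(dose)` offset — the standard
limiting-dilution regression — which reduces *exactly* to
`f̂ = −log(neg/total)/d` at a single dose. Intervals are Wald on
`log f` (common limiting-dilution practice); groups are compared by a
likelihood-ratio test. All-negative and all-positive plates return
flagged boundary results with one-sided bounds instead of failing.

# Numerical choices and test scale

Tolerances: mixture fractions must sum to 1 within 1e−9; genotype
probabilities within 1e−12; the single-dose GLM matches the closed form
to 1e−9 (IRLS epsilon 1e−12). Stochastic checks use 3σ binomial bounds
at their stated n. The test suite exercises: digest limit-of-detection
on 10,000-molecule mixtures across {0, 0.5, 1, 2, 5}% with ten seeds;
sequence-mode round-trip at n = 5,000 reads; the off-target null with 3
targets × 3 paired samples × 2 conditions over 100 seeds at 120 reads
per sample (substitution-only reads, for which the identity alignment
is exact, keeping the check focused on the statistics rather than the
DP); aligner-oracle equality on 500 random pairs up to 40 nt; and
parameter recovery for `(p, h)` over 100 seeds at 500 clones — sizes
chosen so each property is measured at the scale where its guarantee is
claimed.

# Known limitations

- The native aligner is quadratic per read and intended for amplicon
  scale (≲ 1 kb); genome-scale mapping should come in as SAM from an
  external aligner.
- Per-read phasing, MNP merging, strand-bias models, and structural
  variants beyond simple insertions/deletions are out of scope.
- The wild-type sequence at a published locus cannot always be
  reconstructed from donor strings alone (positions edited in every
  printed donor stay unknown); tests use explicitly labelled synthetic
  stand-ins in that case.
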