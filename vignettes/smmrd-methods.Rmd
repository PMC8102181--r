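---
title: "Error-corrected smMIPS MRD analysis: models, parameters and design choices"
author: "smMRD authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-corrected smMIPS MRD analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smMRD)
```

# The problem

After induction or consolidation chemotherapy, most patients with acute
myeloid leukemia (AML) are in morphological remission, yet many harbor
residual leukemic cells far below the ~5% blast threshold that
morphology can see. Measurable residual disease (MRD) assays quantify
this burden. A sequencing-based MRD assay tracks the patient's own
diagnostic mutations — typically one to six trackable variants per
patient — at variant allele fractions (VAFs) of 0.05% and below. Raw
Illumina error rates (~10^-3^ per base) sit orders of magnitude above
that, so two layers of error correction are required:

1. **Molecular consensus.** Each single-molecule molecular inversion
   probe (smMIPS) tags one captured DNA molecule with an 8 bp unique
   molecular identifier (UMI). Reads sharing a (target, UMI) key derive
   from one molecule; collapsing them to a consensus removes errors
   introduced during PCR and sequencing. A mutation present in the
   original molecule is present in *every* read of the family; an error
   is not.
2. **Statistical background modeling.** Even consensus reads retain a
   site- and substitution-specific error floor (notably C>T and G>A
   changes from oxidative guanine damage, which precede UMI attachment
   and therefore survive consensus). The caller tests each tracked
   mutation's supporting family count against a background rate fitted
   at that exact site and allele in control samples.

The package implements the full chain — simulation with ground truth,
UMI consensus, error model, tracked-mutation calling with the
DNMT3A/TET2/ASXL1 (DTA) clonal-hematopoiesis policy, an ultrasensitive
FLT3 internal-tandem-duplication (ITD) detector, and the concordance and
limit-of-detection (LoD) machinery used to characterize such assays.

# The synthetic-data generator

`simulateSample()` emulates the statistical structure of an smMIPS
capture rather than its biochemistry:

* **Molecules and family sizes.** Each target receives `nFamilies`
  molecules; the number of reads per molecule is
  `1 + Poisson(familySizeMean − 1)`. The default mean of
  14,728 / 11,363 ≈ 1.296 is the ratio of the assay's median raw to
  consensus coverage, i.e. the average sequencing redundancy per
  molecule. Under this distribution ~74% of molecules are singletons
  and are discarded; the simulator therefore uses ~43,800 molecules per
  target when a retained consensus depth of 11,363 families is required.
* **UMIs.** 8 bp by default, drawn *without replacement* within a
  target so each molecule owns a distinct (target, UMI) key. Real
  pipelines disambiguate UMI collisions with fragment coordinates from
  genome alignment; in target-local simulation that information does
  not exist, and drawing with replacement at ~44k molecules in a 65,536
  key space would merge unrelated molecules at a rate no real assay
  exhibits. The choice is configuration, not inference, and is the one
  respect in which the generator is cleaner than reality.
* **Spike-ins are molecules, not reads.** A tracked variant at VAF *v*
  is assigned per molecule by an independent Bernoulli(v) draw and
  propagated to all of that molecule's reads: MRD VAF is a molecule
  fraction. Insertions and deletions are expressed VCF-style in the
  spike table and applied to the haplotype, so mutant families carry
  length-discordant reads end to end.
* **Errors.** Substitutions are injected per base per class. The
  default spectrum puts C>T and G>A at four times the transversion
  rate (4 × 10^-4^ vs 10^-4^; A>G/T>C at 2 × 10^-4^), a total per-base
  error of ~6 × 10^-4^ consistent with Q30 base calls; quality strings
  are constant Q30 and errors are injected independently of quality.
  Indel sequencing errors, adapter/arm sequence, PCR chimeras and
  quality modeling are out of scope — which means passing tests say
  nothing about, e.g., indel-error-driven false ITDs in real data.
* **Determinism.** Every simulation is governed by one integer seed;
  identical configurations give byte-identical FASTQ and truth tables.

Every emitted read maps to exactly one truth record, and the read count
equals the sum of family sizes — both enforced by the class validity.

# Consensus and pileup

Families are formed by **exact match** on (target, UMI); no
edit-distance merging is attempted, because a merging rule would be an
unverifiable invention and exactness is conservative and oracle-testable.
Singletons are discarded. Consensus takes the modal base per position
when its fraction reaches the quorum (default 0.70 — chosen so a
2-read disagreement yields N rather than a coin flip), else N; families
with more than `maxNFraction = 0.20` N are dropped as too damaged.
Members of unequal length cannot be stacked positionally and the family
is rejected (paired-end assembly is an upstream concern; the simulator
emits pre-merged reads).

Pileups are 1-based and per target. Length-discordant consensus reads
are interpreted as one clean left-aligned insertion (counted under the
inserted sequence, consuming no base slot) or deletion (counted at each
deleted position); reads not explained by one clean indel contribute N
everywhere, so `A + C + G + T + N + del = depth` holds at every site
unconditionally. Target-local coordinates replace genome alignment
throughout: mapping to a genome build is an adapter concern
(`assignTargets()` provides probe-arm prefix matching for real reads),
not core logic.

# The background error model

For every (target, position, alternate allele), alternate and total
counts are pooled across control samples and converted to the rate
`(alt + 0.5) / (depth + 1)` — a Jeffreys-style pseudocount of 0.5, so
channels with zero observed events (virtually all indel channels) still
get finite, testable rates. The observed-variant test is the one-sided
exact binomial upper tail at the site's rate. This is the minimal model
consistent with "site- and mutation-specific" background; the published
assay does not specify a distributional form, so the choice is this
package's own. Two documented consequences:

* p-values are conservative at small expected counts (discreteness),
  which the type-I calibration test quantifies;
* between-run variability beyond binomial sampling is not captured by
  pooling. For overdispersed panels `sitePValue(..., rho = )` computes
  the same tail under a beta-binomial with matching mean and intra-class
  correlation `rho`; it reduces to the binomial as `rho → 0` and is
  strictly more conservative otherwise.

Multiple testing is corrected by Benjamini–Hochberg **within the
sample's tracked set only** (one to six prespecified hypotheses), never
across the panel: MRD tracking is confirmation of known mutations, not
discovery, and panel-wide correction would trade sensitivity for
protection against hypotheses never tested. Sites with zero pooled
control depth are *unmodeled*: the caller refuses them explicitly
(status `untestable`), never reporting a silent p-value.

# Tracked-mutation calling

A mutation is **detected** when (i) its BH-adjusted p-value is below
`qMax = 0.05`, (ii) it is supported by at least `minFamilies = 2`
consensus families, and (iii) its VAF clears the per-class `vafFloor`
(default 0). `untestable` — site absent, unmodeled, or consensus depth
below 1,000 families — is a first-class status distinct from negative,
because silent negatives at low depth are the main failure mode of MRD
reporting.

Two defaults deserve their rationale, since the assay's supplementary
calling criteria are not public and these are the package's own
choices:

* **No VAF floor by default.** The assay's validated class LoDs (0.05%
  for SNVs, 0.03% for NPM1-type insertions) are *outputs* of the LoD
  experiment, not gates inside the caller. Gating detection at the
  class LoD would be circular when measuring the LoD, and — because
  family counts are discrete — would halve sensitivity exactly at the
  limit: at 11,363 families and VAF 0.05%, E[alt] = 5.68 and
  P(alt/depth ≥ 5 × 10^-4^) ≈ 0.51. A laboratory that wants a
  reporting floor sets `vafFloor` explicitly and it is recorded in
  every output header.
* **`minFamilies = 2` for all classes.** A closed-form power analysis
  at the assay's operating point fixed this before any end-to-end runs:
  with near-zero fitted background (rate ≈ 1.5 × 10^-5^ from three
  pooled controls), two supporting families are already significant
  (p ≈ 0.013), and requiring three would cap per-replicate power at
  P(Pois(5.68) ≥ 3) ≈ 0.92 at the claimed 0.05% limit, versus ≈ 0.98
  at two. Type-I behavior at the lower floor is verified by the
  error-only false-positivity test (≤ q·m expected positives across
  seeded error-only samples).

**DTA policy.** Persistent DNMT3A/TET2/ASXL1 mutations often trace
clonal hematopoiesis, not leukemia. A sample is positive on any
detected non-DTA mutation; DTA-only positivity is never accepted at the
post-consolidation time point, and at post-induction only under the
default `"pi-permissive"` policy (for patients whose *only* trackable
mutation is a DTA clone, matching clinical precedent), never under
`"strict"`. Tissue (bone marrow vs peripheral blood) is carried as
metadata only; no numerical adjustment between sources is applied.

# FLT3-ITD detection

The FLT3 assay is a UMI-free, one-step PCR amplicon sequenced to
~1.4 million× depth, so the detector must resolve single supporting
reads among millions. The algorithm is anchor-based self-alignment:

1. distinct read sequences are tabulated once (support is the sum of
   multiplicities — duplicate stacks are scanned a single time);
2. substitutions never change read length, so only length-discordant
   sequences are candidates — this also makes the scan cheap;
3. the insertion is placed by maximal prefix/suffix matching against
   the amplicon and each valid placement is tested for tandem
   structure: the inserted block must reproduce the adjacent reference
   block (either side) within one mismatch. Graded passes keep clean
   reads on the deterministic exact path; a mismatch-tolerant pass
   (up to two substitutions across the flanks) recovers errored copies;
4. events are merged on (length, position ± 2) with the modal
   supporting sequence — substitution errors inside the duplicated
   block must not split one molecule population into several events —
   and reported at `minSupport = 5` reads, which holds false events
   below one per million reads at 0.5% per-base error in testing.

Tandem-repeat ambiguity means the same physical ITD admits several
(position, sequence) representations that reconstruct the identical
mutant read; events are therefore canonicalized by the leftmost exact
placement, and the oracle used in tests is reconstruction equality, not
string identity of the reported block. The detector assumes full-length
amplicon reads (merged pairs); truncated reads are out of scope.

# Limit-of-detection experiment

`lodExperiment()` runs the full simulate → consensus → call chain on a
VAF grid with independently seeded replicates (error model fitted once
from three spike-free controls under identical conditions), and derives
the LoD as the lowest grid VAF whose detection rate reaches 0.90.
"Reliably detectable" has no canonical definition, so the threshold is
explicit, configurable, and reported with the table. The defaults are
the assay's published operating point: grid {0.5, 0.1, 0.05, 0.01}%,
consensus depth 11,363 families, 50 replicates per point. At these
settings the derived SNV LoD is 0.05% VAF, and the expected detection
rate at the limit (~0.98 from the closed form above) leaves the
empirical 45-of-50 requirement comfortable margins. The NPM1-type
insertion channel, with effectively zero background, detects 0.03%
spikes in the majority of replicates, matching the assay's finer
insertion limit.

# Problem sizes used by the test suite

Simulations in the unit tests are scaled to what the properties need,
not to cohort scale: consensus-suppression measurements use ≥10^5^
consensus bases; type-I calibration uses >10^4^ site-tests at ~520
family depth; error-only false-positivity uses 60 seeded samples of
three tracked mutations; the acceptance checks run the published
operating points in full (11,363-family LoD grid at 50 replicates per
point; one million amplicon reads for the ITD limit). The clinical
cohort itself — survival endpoints, hazard ratios, patient-level
PPV/NPV — is out of scope: those are downstream analyses for standard
statistical software, and no desk-scale simulation can reproduce them.

# Known limitations

* Exact-match family keys overcount molecules when true UMI collisions
  occur; the simulator sidesteps collisions by construction (above), so
  collision-induced VAF bias in real data is not quantified here.
* The error model pools controls; run-to-run overdispersion must be
  handled via the beta-binomial option with an externally chosen `rho`.
* Deletion support is read from per-position deletion counts (minimum
  over the deleted range), which cannot distinguish two different
  tracked deletions sharing a footprint.
* The ITD detector keys on read-length change and will miss ITDs in
  truncated or heavily indel-errored reads.
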