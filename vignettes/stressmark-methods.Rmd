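---
title: "Methods: island calling and factorial stress classification"
author: "stressmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: island calling and factorial stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmark)
```

# Overview

`stressmark` analyses H3K4me3 ChIP-seq from a factorial stress
time-course: three conditions (unstressed control C, drought DT, and
drought followed by heat DTHT), six collection time points (0, 72, 96,
120, 144, 168 h of drought; heat is imposed after 72 h of drought), and
three biological replicates per condition and time point, with one input
(sonicated chromatin) control per condition. The pipeline has five
computational stages:

1. **Read model.** Aligned reads are reduced to their strand-aware 5'
   ends, deduplicated to at most one read per (chromosome, position,
   strand), and extended to the expected fragment size of 300 bp. All
   downstream counting operates on fragments, counted into a window when
   they overlap it by at least 1 bp.
2. **Island calling** per ChIP library against its condition's input.
3. **Differential windows** between two pooled groups at one time point.
4. **Factorial classification** of merged regions into drought-,
   combined-, and heat-responsive sets.
5. **Annotation**: genomic-feature classes, TSS distances and
   metaprofiles, peak-gene overlap, hypergeometric term enrichment,
   MapMan export, and 2^-ddCT quantification of ChIP-qPCR validation.

# The island model

Each chromosome is tiled with non-overlapping 200-bp windows. Under a
uniform background, the expected fragment count of a full window is

$$\lambda_w = \frac{N \cdot W}{L \cdot f},$$

with $N$ the library size, $W$ the window width, $L$ the total genome
length and $f = 0.7$ the effective (mappable) genome fraction. The
effective fraction raises the background rate; windows are still tiled
genome-wide. A window is *eligible* when its count reaches the smallest
integer $c_0$ whose Poisson upper tail under $\lambda_w$ falls below
$p_0 = 0.2$; eligible windows are clustered, bridging runs across at most
one ineligible window per 200-bp gap allowance. An island's score is the
sum over its eligible windows of $-\ln P(X = k; \lambda_w)$.

Each candidate island is then tested against the input control: the
island's ChIP fragment count is compared with a Poisson expectation equal
to the input count scaled by the ChIP/input library-size ratio, floored
at the genome-background expectation for the island's width (so an
island with zero input coverage is still tested against a positive
expectation). Benjamini–Hochberg correction is applied across candidate
islands and islands at FDR <= 0.05 are reported.

Numerical notes: a chromosome whose length is not a multiple of $W$ ends
in one short window whose $\lambda$ is scaled by its width; the eligibility
threshold is found by direct evaluation of the Poisson tail, never by a
normal approximation; island calling involves no randomness, so identical
inputs give identical island sets.

# The differential window test

Differential detection slides 200-bp windows every 100 bp. Replicates of
each group are pooled at the fragment level; per-replicate concordance is
not used for calling. For one window with counts $(k_A, k_B)$ and library
sizes $(N_A, N_B)$, the test conditions on $t = k_A + k_B$: under the
null of equal per-million rates, $k_A \sim \mathrm{Binomial}(t, N_A /
(N_A + N_B))$. The two-sided p-value sums the probabilities of all
outcomes at most as likely as the observed one (the minimum-likelihood
convention, identical to `binom.test`; the test suite checks agreement
with `binom.test` exhaustively for all $t \le 30$). Windows with $t = 0$
get $p = 1$. The direction is the sign of $k_A/N_A - k_B/N_B$.

No multiple-testing correction is applied at this stage: calling uses the
raw cutoff $p < 0.01$, deliberately. Significant windows of the same
direction are merged when touching or overlapping (gap 0). Where peaks of
opposite direction overlap — possible because windows overlap — the
contested interval is assigned to the peak with the smaller p-value and
trimmed from the other; exact ties split the overlap at its midpoint.

Two properties of this exact test matter for interpretation. First, at
the low counts typical of desk-scale data its discreteness makes it
conservative: the realised type-I error at $p < 0.01$ is far below 0.01
(the acceptance suite measures it on over $10^5$ null windows). Second,
the conservatism vanishes where both groups are deep (a strongly marked
domain that is truly unchanged), so raw-p calling accumulates false
windows preferentially in high-signal unchanged regions — the reason the
region universe reports, rather than hides, background regions.

# Factorial classification

All differential peaks from every contrast and time point are merged by
single-linkage overlap (>= 1 bp) into a *region universe*; each region's
membership records, for every `contrast:timepoint`, whether it overlaps a
differential peak there. The three rules are then purely set-logical:

* **DT-responsive**: not differential in DT vs C at 0 h, differential in
  DT vs C at >= 1 of 72/96/120/144/168 h.
* **DTHT-responsive**: the same template for DTHT vs C.
* **HT-responsive**: not differential in DTHT vs DT at 0 h nor at 72 h,
  and differential in DTHT vs C at >= 1 of 96/120/144/168 h. Heat effects
  are read from the combined arm because heat is imposed on top of
  drought at 72 h; there is no heat-only arm.

Design choices made where the procedure was genuinely open:

* Region identity across comparisons is single-linkage merging — the
  least-assumptive way to give "a region" a persistent coordinate
  identity across contrasts and time points.
* "Not differential at the baseline" is evaluated on the merged region:
  the region must overlap *no* differential peak of that contrast at the
  excluded time point(s).
* A region's direction (gain or loss of the mark) is taken from the
  smallest-p peak at its earliest supporting time point; that sign feeds
  the MapMan {0, 1, -1} export.
* No exclusivity is imposed between the three classes, and no extra FDR
  layer is added across regions; by their very construction the rules
  overlap (a drought effect is also visible in the combined arm, so a
  genuine DT region typically satisfies the DTHT and HT rules as well).
  The classifier is verified against an exhaustive truth-table oracle
  over all $2^{14}$ membership patterns.

# Annotation and profiling

Every peak receives exactly one genomic-feature label, decided at its
midpoint with a fixed precedence: 5'-UTR > CDS > 3'-UTR > intron >
upstream (within 2 kb of a TSS, strand-aware) > downstream (within 2 kb
past the stop codon, strand-aware) > repeat > intergenic. Midpoint
assignment with genic-first precedence is centralised in one function so
the alternative (whole-peak overlap, or repeat-first precedence) is a
one-line change. Percentages are reported at two decimals and counts are
conserved, so summaries are internally consistent by construction.

Nearest-TSS distances are signed in transcription orientation (positive
downstream into the gene body); equidistant genes tie-break to the
lexicographically smaller gene identifier for determinism. The TSS
metaprofile counts fragments in orientation-aligned 100-bp bins across
+-2 kb of every TSS, averages over genes and scales to fragments per
million. Peak-gene overlap extends gene intervals by 2 kb on both sides
and permits many-to-many links, so region and gene counts are reported
separately. Term enrichment is a hypergeometric upper tail with
Benjamini–Hochberg adjustment; a term is significant only when adjusted
p < 0.05 *and* fold enrichment > 1.3.

# ChIP-qPCR quantification

Relative expression uses the 2^-ddCT method with the constitutive
reference gene (cons7 in this assay): dCT = CT(gene) - CT(reference)
within each condition, ddCT = dCT(sample) - dCT(calibrator), fold =
2^-ddCT. Fold changes are computed per replicate, paired by replicate
index, and the displayed dispersion is the standard error of the
per-replicate fold changes (the mean +- SE convention of qPCR reporting;
the SE could equally be propagated on the ddCT scale, which is not what
is shown). Reference-gene cancellation — adding a constant to every CT of
a condition leaves the fold unchanged — is tested as an algebraic
invariant.

# The synthetic experiment

The generator emulates the full design — 54 ChIP libraries (3 conditions
x 6 time points x 3 replicates) plus one input per condition — on a toy
genome, so every stage is testable without any downloads. Genes with
5'-UTR/CDS/intron/3'-UTR structure are placed without overlap; intergenic
repeats fill a configurable fraction; enrichment islands are implanted at
the TSSs of sampled genes, extending downstream in transcription
orientation (the canonical H3K4me3 geometry). Every library draws
Poisson background fragments (uniform positions, random strand, 300 bp)
and each island multiplies the local fragment rate by 4 when its effect
is *active*: drought islands act in the DT and DTHT arms from their
onset; combined and heat islands act only in the DTHT arm (heat onsets
are constrained to >= 96 h because heat begins at 72 h of drought);
constitutive islands are always marked. Input libraries see background
only.

Default study conditions (chosen from an exact power/type-I analysis of
the window test, then fixed): 2 x 500 kb chromosomes, 100 genes of 2 kb,
background 1.25 fragments/kb per library, 2.5-kb islands at 4x with
onset 96 h, and 24 drought-, 12 combined-, 12 heat-effect islands plus 2
constitutive ones. Three of these choices deserve explanation:

* **Gain/loss pairing.** Half of the drought islands are implanted as
  *losses*: constitutively marked domains whose rate drops to background
  when the effect is active. Besides exercising the direction (-1) path,
  this balances expected library mass across conditions. Without it,
  gains alone inflate treated-library sizes and the per-million
  normalisation makes every background window look depleted in the
  treated arm — a composition bias that is a genuine hazard of
  library-size normalisation, reproduced and then removed by design.
* **Losses only in the drought class.** A loss island of the combined or
  heat class would be a deeply marked *unchanged* domain in the DT-vs-C
  contrast, exactly where the raw-p window test is least conservative;
  restricting losses to the DT class (whose gain/loss pairs balance both
  the DT and DTHT arms) keeps the other contrasts' nulls at background
  depth. For the same reason the constitutive domains are sharp (800 bp),
  which also matches the biology of constitutive promoter H3K4me3.
* **Depth.** 1.25 fragments/kb puts pooled null window totals around 4,
  where the discrete test's realised type-I error is a few parts in
  10^4, while 2.5-kb islands offer enough windows that detection at >= 1
  of 4 support time points is nearly certain.

Ground truth for end-to-end scoring is *rule-derived*: for each island,
the expected classes are computed analytically from its activity pattern
through the same factorial rules (a drought island satisfies all three
rules; a combined island with onset 72 h satisfies only the combined
rule). Precision and recall are measured over (island, class) pairs, and
spurious regions that overlap no island are counted separately as
background calls.

What the generator does *not* emulate: mappability and GC bias, read-
level errors, fragment-length variation, overdispersed (non-Poisson)
biological replication, chromatin contact artefacts, and the repeat-dense
intergenic landscape of a real plant genome. Passing the synthetic suite
therefore demonstrates the correctness and calibration of the
*computation*, not the field performance of the protocol on real
switchgrass-scale data.

# Problem sizes used by the test and acceptance suites

The test suite runs the full 57-library experiment on the 1-Mb toy
genome (about a minute), the window-test calibration on 10^5 sliding
windows of a 10-Mb null genome, the island-caller calibration on 200
null simulations of a 100-kb genome, and exhaustive truth-table checks
over all membership patterns. These sizes were chosen so the whole suite
completes in a few minutes on one CPU while every assertion retains a
comfortable statistical margin.

# Known limitations

* The exact conditional binomial assumes independent fragments; PCR
  duplicates violate this upstream of the deduplication step.
* Pooling replicates discards between-replicate dispersion; a
  negative-binomial model would be strictly more cautious for noisy
  replicates (out of scope here, as is spike-in normalisation).
* Raw-p window calling without correction reports background false
  windows at a rate the calibration quantifies; downstream consumers
  should treat isolated single-window regions accordingly.
* Feature labels depend on the midpoint convention; peaks much wider
  than genes can be assigned to a class their edges do not touch.
* With all effect onsets at 96 h the combined- and heat-responsive truth
  sets coincide on the synthetic data; the truth-table suite, not the
  end-to-end run, is what establishes that the two rules are logically
  distinct.
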