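---
title: "Detecting induced mutation frequencies from overlapping read pairs"
author: "popmutscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting induced mutation frequencies from overlapping read pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmutscan)
```

## The problem

Chemical mutagens induce base substitutions at frequencies of roughly one
per 10^4 to 10^6 bp in bacterial populations shortly after exposure — far
below the raw error rate of short-read sequencing (~10^-2 to 10^-3 per
base). Classical approaches recover the induced mutation spectrum by
cloning single cells and sequencing each clone, which is slow, expensive,
and filters the spectrum through cell selection. popmutscan implements the
alternative: sequence the heterogeneous population directly and measure
*increases in substitution frequencies* over unexposed controls, without
ever calling individual mutant sites. The output is the six-type
substitution spectrum and the 96-trinucleotide mutation pattern of the
exposure, comparable to the signature catalogues extracted from human
cancer genomes.

## The method

### Error suppression by overlap consensus

Libraries are built from ~150 bp fragments sequenced 2×150, so each pair
covers its fragment completely in both directions. Each pair is merged
over its best-scoring overlap (`mergePairs()`): within the overlap only
bases on which the two mates *agree* are kept; disagreements are masked to
N and carry no information downstream. Quality never resolves a conflict —
consistency is the filter. If each mate independently miscalls a base with
probability $e$ (uniform over the three alternatives), a wrong consensus
base requires both mates to make the *same* miscall, which happens at rate

$$ 3 \times \left(\frac{e}{3}\right)^2 = \frac{e^2}{3}, $$

so a raw error rate of $10^{-2}$ becomes a consensus error rate of
$3\times10^{-5}$. `consensusErrorStudy()` verifies this closed form by
simulation; the overlap-offset search itself is validated against a
brute-force scan in the unit tests. Offsets are restricted to the proper
fragment orientation (mate 1 never starts after reverse-complemented
mate 2); adapter read-through pairs, like gapped overlaps, do not merge.

### Counting and frequencies

Merged reads are aligned (externally in production use; the package ships
a gapless exhaustive-scan fixture aligner, `alignExact()`, so that the
whole workflow runs without external tools), optionally deduplicated by
(contig, start, end, orientation), and piled into per-position base-call
counts (`buildBaseCounts()`). A call is counted only if it lies in the
overlap span, is unmasked, and has quality ≥ `qMin` (default Q30, the
conventional HiSeq threshold). Every non-reference call increments its
pyrimidine-represented substitution type, and the type frequency is

$$ f_t = \frac{m_t}{D_c} \times 10^6, $$

where $D_c$ is the *total filtered base calls* over that type's base-pair
class (G:C or A:T reference sites), not the number of genome positions —
which makes frequencies depth-robust. Because every substitution type
carries a type-specific background error rate, the induced frequency is
estimated as the excess over unexposed controls,
$\Delta f_t = f_t - \overline{f_t(\mathrm{control})}$
(`subtractBackground()`); negative values are kept in tables (they are
sampling noise around zero) and clipped only when spectra are built.

### Statistics

Dose groups are compared to control with Dunnett's many-to-one test
(`dunnettTest()`): pooled within-group variance across all groups,
per-group statistics, and family-wise adjusted p-values from the
equicoordinate multivariate-t distribution (computed with mvtnorm's
quasi-Monte-Carlo integration under a fixed internal seed; p-values are
reproducible to ~10^-3). The test is applied to the raw per-sample
frequencies with control as reference, two-sided by default (a one-sided
mode is available). With one comparison group the test reduces exactly to
the pooled two-sample t-test, and its family-wise type-I error is
calibrated by simulation in `dunnettTypeIStudy()`.

### 96-class spectra and signature comparison

The bases 5′ and 3′ of each substitution define 96 classes (6 types × 16
contexts, pyrimidine-represented; `classifySubstitution()` is an exact
2-to-1 map from the 192 strand-resolved cases). Sites without defined
context — contig ends and N neighbours, an edge rule the upstream
protocols leave unstated, resolved here by a no-context sentinel — count
toward type totals only. 96-class frequencies use the type's whole
base-pair-class denominator, so they partition each type's frequency
across contexts. Excess 96-class frequencies are clipped at zero and
normalized to a `Spectrum96`; spectra are compared by cosine similarity
and clustered on 1 − cosine distance with average linkage
(`clusterSpectra()`; complete and single linkage are available — the
choice is a convention, and average linkage is the standard for signature
comparison). `npcyFraction()` summarises the NpCpY consensus peak
characteristic of alkylating agents, and `joinsBefore()` asks whether
sample spectra join a given catalogue signature before any other
signature.

### The strand-bias diagnostic

Oxidative damage of guanine during library preparation (8-oxo-dG) causes
spurious G>T calls that are consistent between mates — they survive the
consensus — but occur only on the strand physically carrying the damaged
G, i.e. in one read-1 orientation class. `strandBiasDiagnostic()` splits
every substitution by read-1 orientation and flags types whose orientation
ratio exceeds 3 (configurable) with at least 25 supporting calls; an
infinite ratio (zero denominator with calls on the other orientation) is
always flagged. A symmetric error process never trips the flag.

## The simulator

`simulateReads()` generates the study designs the package validates
against. Fragments are drawn uniformly from a weighted molecule pool (the
spike-in mixtures) or from an exposure model (an effectively infinite
population: each fragment derives from an independent molecule, as in a
bulk DNA extract, with per-site planting at the class-specific rates and
exact truth bookkeeping). Each fragment gets a random read-1 strand; the
oxidative artifact (fragment-level G→T on the read-1 strand) is applied
before sequencing so it is mate-consistent; then each mate receives
independent per-base miscalls.

The default error calibration places post-consensus residual backgrounds
in the 10^-6–10^-5 per-bp band, plus the strand-biased oxidative G>T
component (3×10^-5), matching the magnitude and type-dependence of
backgrounds reported for libraries of this design; per-sample lognormal
jitter (sdlog 0.02 on miscall rates, 0.05 on the artifact) models
library-to-library variability. Base qualities are flat Q37; a
quality-by-cycle model, PCR amplification bias and indel errors are
deliberately out of scope, so passing tests say nothing about
indel-containing reads or amplification artifacts in real data.

### Spike-in validation design

`spikeInDesign()` builds a ~3.66 kb construct: a seeded random 2,660 bp
backbone standing in for the cloning vector (a synthetic stand-in — only
base composition matters to frequencies) with a 1,000 bp random insert
placed centrally so that insert coverage is uniform under fragmentation.
The insert's central G:C site and the adjacent A:T site are each replaced
by the three alternative base pairs to give six single-substitution
variants; mixing the variant pool at ratio $r$ against the control gives
exactly known excess frequencies, nominally 10/100/1000 per 10^6 class bp
at $r$ = 0.01/0.1/1 ($r \ge 1$ means the pure variant mix). The designed
truth is always computed from the actual construct composition
(`designedDeltas()`), not the rounded labels: those labels are consistent
with denominators taken over the insert (~500 G:C bp), which is why the
spike-in analysis counts frequencies over the insert region
(`countSubstitutions(region = insertRegion(design))`).

## The validation studies and their problem sizes

All study sizes below are the package's defaults, chosen to resolve the
quantities of interest well above their sampling error while staying
desk-scale; each study is driven by a single seed.

* **Spike-in recovery** (`runSpikeInValidation()`): 3 controls + ratios
  0.01/0.1/1, 4×10^5 pairs each (the binomial standard error at the
  smallest spike is then ~2.7 per 10^6, so the designed 10 is resolved);
  no duplicate removal, as appropriate for a plasmid library. Recovery is
  checked within 3 binomial standard errors of the designed values.
* **Detection limit** (`detectionLimitStudy()`): a 1 Mb synthetic random
  genome, 3 controls + 3 replicates at context-uniform per-type
  frequencies 10^-4/10^-5/10^-6 per bp, 2×10^5 pairs per sample,
  duplicate removal on. The detection limit is the smallest level at
  which *every* type shows a significant positive Dunnett result; under
  the calibrated backgrounds this is 10^-5 per bp — at 10^-6 the types
  with backgrounds at or above 10^-5 cannot be resolved.
* **Sub-sampling power** (`powerStudy()`): a 2 Mb genome, 3 controls + 3
  exposed replicates at an alkylating-agent-like pattern — C>T 47.5,
  T>C 11, T>A 11, T>G 0.5 per 10^6 class bp (total 70 per 10^6), C>T
  peaked on 3′-pyrimidine contexts — with a 15% lognormal
  between-replicate biological multiplier; 1.05×10^6 simulated pairs per
  sample, subsampled to 10^5 and 10^6 merged pairs. "Detection" means
  every planted type is significant: the dominant C>T excess alone is
  statistically resolvable even at 10^5 pairs at these depths, so the
  full-pattern criterion is what makes ~10^6 pairs the practical minimum
  — the smallest planted component (T>G at 0.5 per 10^6) sits at the
  decision boundary at 10^5 pairs, which also means the outcome at that
  size is intrinsically borderline and can fluctuate between seeds. The
  recovered 96-class spectrum at 10^6 pairs is compared to the planted
  spectrum by cosine similarity (≥ 0.95 expected; the threshold is ours).

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; SAM's 1-based
  coordinates are converted at the I/O boundary.
* N reference bases join no denominator or tally; circular molecules are
  treated as linear (the two end positions lack context — negligible
  beyond plasmid scale and documented as a limitation).
* Overlap ties break toward the longest overlap, then the smallest
  offset; the merge is accepted only if the best offset's mismatch
  fraction is ≤ 0.1 (default; the merge parameters of the upstream tools
  are unpublished, so the defaults here are the package's own and are
  exposed in the configuration).
* The fixture aligner requires a unique mismatch-minimal placement;
  ambiguous reads stay unaligned. Its k-mer-index mode restricts the
  exhaustive scan to seed candidates; on repetitive references it can
  miss an equally good second site, so ambiguity detection there is
  seed-limited (irrelevant for the random references of the studies).
* Zero pooled variance in the Dunnett test is degenerate: equal means
  give p = 1, unequal means p = 0, both with a warning.
* An all-nonpositive delta vector cannot be normalized into a spectrum
  and is an error, not a zero spectrum.

## Limitations

The simulator emulates fragment sampling, mate-consistent artifacts and
independent miscalls, but not PCR duplication families, quality decay
along the read, context-dependent polymerase error, or indels; the
detection-limit and power results therefore characterise the method under
a clean, calibrated error model, not any particular instrument run. Real
analyses should map with a production aligner and pass the SAM files in
(`readSam()`), and should treat the strand-bias diagnostic as a screen:
a flagged type (typically G:C>T:A) has reduced sensitivity because part
of its background is artifactual.

```{r quick-example, eval = FALSE}
# a complete miniature run
set.seed(1)
design <- spikeInDesign()
pool <- makeSpikeInSample(design, ratio = 0.1)
pairs <- simulateReads(pool, 5e4)
merged <- mergePairs(pairs)
aligned <- alignExact(merged, designReference(design))
counts <- buildBaseCounts(aligned, designReference(design))
mft <- countSubstitutions(counts, designReference(design),
                          region = insertRegion(design))
typeFrequencies(mft)
```
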