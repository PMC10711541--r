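---
title: "Branch point prediction and constraint analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch point prediction and constraint analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpscan)
```

# Scope

`bpscan` implements three connected analyses: prediction of branch point
sequences (BPS) in introns, quantification of evolutionary constraint from a
catalogue of biallelic SNVs, and a plausibility audit of variant databases.
A synthetic-data generator produces genomes, annotations and variant
catalogues with known ground truth, so each stage can be validated by
parameter recovery rather than by fiat. This vignette records the model,
its tunable parameters, the numerical conventions, and the design decisions
taken where several reasonable choices existed.

# The prediction model

## Ingredients

The spliceosomal branch point resides in a degenerate heptamer whose
position 4 is a conserved thymine and whose position 6 is the branch-point
adenine. Two signals localize it: the motif itself, and the composition of
the sequence between the motif and the 3′ splice site (the polypyrimidine
tract). The score of a candidate heptamer $b_1..b_7$ at branch point offset
$d$ (bases between the branch point and the 3′ splice site, transcript
orientation) is

$$
S(d) \;=\; \sum_{k=1}^{7} \log_2 \frac{PWM_{k,b_k}}{q_{b_k}}
\;+\; \lambda \sum_{o \in \mathrm{ctx}(d)}
      \log_2 \frac{f_{\mathrm{bin}(e_o)}(o)}{g(o)},
$$

with $q$ the genome-wide base composition, $\mathrm{ctx}(d)$ the sliding
octanucleotides of the sequence from the base after the branch point to the
3′ splice site, $e_o$ the distance of an octamer's 3′-most base to the 3′
splice site, $f_c$ the per-distance-bin octamer frequency tables estimated
from the species' own introns, and $g$ the genome-wide intronic octamer
background. Both components are log-odds in bits; the functional form makes
every constant explicit rather than delegating to an external tool, and
bit-compatibility with any particular published implementation is a
non-goal.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `d_min`, `d_max` | 9, 150 bp | search range of branch point offsets; observed branch points in many species fall between roughly 14 and 145 bp upstream of the 3′ splice site, and the range is deliberately wider |
| `donor_guard` | 8 bp | candidates leave at least 8 intron bases at the 5′ end, keeping the heptamer clear of the donor dinucleotide |
| `L` | 150 bp | intronic window (upstream of the 3′ splice site) used to estimate the octamer background |
| `bin_width` | 10 bp | distance-bin width of the octamer background; `L` must be a multiple of it |
| `lambda` | 1.0 | weight of the octamer context component; 0 disables it |
| PWM pseudocount | 1 | per base per position: $p_{k,b} = (c_{k,b}+1)/(n+4)$ |
| octamer pseudocount | 1 | per octamer per bin: $f_c(o) = (c_o+1)/(N_c+4^8)$ |
| consensus thresholds | 0.75 / 0.75 | uppercase when one base reaches 0.75; `y`/`r` when a pyrimidine/purine pair jointly reaches 0.75 with no dominant base; `n` otherwise |

The packaged default PWM (`inst/extdata/default_bps_pwm.tsv`) is a
degenerate matrix whose consensus under these rules is `nnyTrAy`. Users can
retrain from their own heptamer sets with `train_pwm()`; whether
species-specific retraining shifts the consensus is exposed as
configuration, not resolved by the package.

## Numerical conventions

* **Coordinates.** Intervals are held in `GRanges` (1-based, closed), the
  standard container in this ecosystem; GTF is read as 1-based inclusive
  and VCF positions as 1-based points. All reported point positions are
  1-based forward-strand coordinates.
* **Distance bins.** An octamer belongs to the bin of its 3′-most base's
  distance $e$ to the 3′ splice site; bins tile $[0, L)$. Only octamers
  fully inside the last $\min(L, \text{intron length})$ bases contribute
  ($e \le L - 8$), and the same cap applies at scoring time so that
  estimation and scoring see the same window.
* **N handling.** Candidate heptamers containing N are skipped (the intron
  is still scanned at other offsets); octamers containing N contribute
  nothing to estimation or scoring; profile sites falling on N or outside
  the chromosome are removed from that offset's denominator; effective
  lengths count non-N bases of the *union* of a class's intervals.
* **Ties.** Bit-identical candidate scores resolve toward the smaller
  offset (closer to the 3′ splice site), where functional branch points
  cluster; the rule is deterministic and strand-independent.
* **Introns with no valid candidate** (shorter than `d_min + donor_guard`,
  or N-saturated) are reported as unpredicted, not as errors.
* **Fisher's exact test** is the two-sided point-probability rule as
  implemented in `stats::fisher.test`; the test suite checks it against an
  exhaustive hypergeometric enumeration. Two-sided conventions differ
  between implementations, which is why the rule is stated here.

## Behaviour of the octamer component at small corpus sizes

The context component sums one log-odds term per octamer of the candidate's
context, so its expected contribution grows with the offset $d$. Against a
large training corpus the per-bin tables are well determined and the
component encodes genuine positional composition (pyrimidine enrichment
near the acceptor). When the corpus is small relative to the $4^8$ octamer
types — as in desk-scale simulations with a few thousand introns — each
observed octamer is partly memorized by its own bin, the expected term is
positive, and maximization drifts toward the largest offsets. Parameter
recovery experiments on synthetic data therefore score with `lambda = 0`
(motif only); the component is retained, at its default weight, for
realistically sized corpora. This is a documented limitation, not a tuning
knob: the recovery tests state the conditions under which they hold.

# The synthetic-data generator

## What it emulates

`sim_config()` defaults define the study conditions: a 2 Mb genome on two
chromosomes; ~340 non-overlapping single-transcript protein-coding genes
(3–6 exons of 120–300 bp, introns of 200–2000 bp, either strand with equal
probability), yielding about 1000 introns; one heptamer per intron drawn
from the generative PWM and written into the sequence at an offset drawn
from a discretized gamma distribution on 9–150 bp with mode near 26 bp,
echoing the median branch point placement of about 26–27 bp reported
across species; 1% of the genome masked as N, in intergenic sequence only;
and a variant catalogue in which each non-N base mutates independently at
`base_mutation_rate` (0.03) times a class multiplier, with transitions at
probability 0.7 (Ti/Tv $= 0.7/0.3 \approx 2.33$, within the 2.2–2.6 range
typical of genome-wide mammalian catalogues).

The default multipliers (splice site 0.02, BPS positions 4/6 0.12, other
heptamer positions 0.85, coding 0.35, UTR 0.7, intron 0.9, intergenic 1.15)
reproduce the qualitative constraint ordering that motivates the analysis:
splice sites < BPS 4/6 < coding < genome average < intergenic. Their
magnitudes were chosen once, when the generator was designed, so that class
totals on a 2 Mb genome are large enough for the ordering to be stable at
any seed (the rarest class, splice-site variants, has an expected count
near 3); they are conditions of the simulated study, not fitted values.
Class priority at overlapping bases is splice site > BPS 4/6 > other BPS >
coding > UTR > intron > intergenic.

The generative PWM concentrates 94% probability on the canonical `TACTAAC`
motif at every position (~13 bits of information). Real BPS are far more
degenerate; the sharpness is what makes exact-recovery experiments
meaningful, because a motif near the background's information content
cannot be localized exactly by any scorer. Consequently, recovery rates on
synthetic data say that the scanner finds what was planted — they do not
estimate prediction accuracy on real, degenerate motifs.

Two contamination modes mimic documented failure modes of public
databases: `exome_batch` adds variants uniformly over exonic non-N bases
(concentrating density in exons, which depresses *relative* intergenic
variability), and `error_batch` adds variants uniformly genome-wide with
the alternate allele uniform over the three possibilities, giving the
Ti/Tv of 0.5 expected from random errors. An optional interval restriction
lets tests aim an error batch at splice-site neighbourhoods, producing a
catalogue whose overall Ti/Tv stays plausible while splice-site depletion
vanishes — the situation the audit's criterion iii exists to catch.

## What it does not emulate

Read-level sequencing, genotypes and allele frequencies, indels,
multi-allelic sites, overlapping or multi-transcript genes, alternative
splicing, non-uniform background composition (isochores, CpG), linkage,
and N-runs inside genes. Effective-length accounting and the audit criteria
do not depend on these, but passing tests on this generator does not
certify behaviour on, say, GC-biased real genomes.

## Determinism

A `sim_config(seed = s)` fixes every draw: genome bytes, GTF, truth table
and VCF are byte-identical across runs. The variant draw uses `seed + 1`
so the catalogue is reproducible given the genome; contamination takes its
own seed.

# Constraint analysis conventions

* **Relative variability** of a class is (variants per 100 non-N bp of the
  class's interval union) / (genome-wide variants per 100 non-N bp). The
  whole genome scores exactly 1 by construction. Variants may count in
  several classes; within a class each variant counts once.
* **Coding** defaults to exon ∪ start ∪ stop codons — i.e. every exonic
  base including UTRs, the literal reading of "variants overlapping exons,
  start codons and stop codons" — with a `cds` mode (CDS ∪ start ∪ stop)
  selectable where the stricter definition is wanted.
* **Profiles are site-level**: at each offset a site either overlaps ≥ 1
  SNV or not, so recurrent variation at one site cannot inflate a
  position's signal. Windows default to 3 exonic + 8 intronic bases around
  each splice junction; both flanks are configurable.
* **Introns are deduplicated** across transcripts by (chrom, start, end,
  strand) before any counting, so shared introns are not weighted by
  transcript number; only protein-coding genes contribute introns.

# The database audit

Criterion i is a density floor (≥ 1 variable site per 1000 non-N bp);
criterion ii requires intergenic relative variability strictly above 1;
criterion iii requires relative variability strictly below 1 at *each* of
the four splice-site bases (donor +1, +2; acceptor −2, −1). "Depletion" has
no canonical magnitude, so the cap is exposed in `qc_thresholds()` with a
default of 1.0, and the per-base (rather than averaged) form was chosen as
the stricter reading. Ti/Tv and the coding percentage are computed and
reported but never gate the verdict — catalogues can present plausible
values of both while failing the positional criteria, and the audit is
designed to expose exactly that. When a toy genome has no intergenic
sequence, criterion ii is not assessable and fails fail-safe.

Submission-based filtering supports two semantics, because "submitted at
least twice" is ambiguous in public archives: a minimum count over distinct
submitter labels (`min_submissions`), and removal of variants private to a
named batch (`exclude_private_to`). They are deliberately not combinable in
one call; apply them sequentially when both are wanted.

# Problem sizes used in the test suite

Unit tests run on 60–300 kb genomes (6–40 genes); oracle-equivalence
checks run on ≤ 100 kb genomes where per-base brute force is exact and
fast; end-to-end acceptance checks use the default 2 Mb configuration
(~1000 introns, ~50k SNVs), which gives the rarest classes expected counts
large enough for strict-ordering assertions while keeping a full suite run
within a few minutes. The same 2 Mb configuration backs
`scripts/acceptance.R`.

# Known limitations

* The octamer context component length-biases candidate selection when the
  training corpus is small (see above).
* Single-heptamer-per-intron output: multiple or alternative branch points
  in one intron are out of scope.
* The generator's uniform base composition means the PWM component's
  background odds are flat; on real genomes, composition heterogeneity
  will modulate scores in ways the synthetic tests do not exercise.
* Effective lengths treat any non-ACGT character as N.
* The audit is a gate, not a diagnosis: failing criteria indicate bias but
  do not identify the contaminating submission; submission-metadata
  filtering is only possible when the VCF carries submitter annotations.
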