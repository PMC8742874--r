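---
title: "Mapping RNA-binding protein motif landscapes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping RNA-binding protein motif landscapes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmotif)
library(dplyr)
```

## The problem

RNA-binding proteins (RBPs) such as Rbfox1 (which recognises the
5′-UGCAUG-3′ element) and the CELF-family protein Bruno 1 (Bru1) regulate
alternative splicing and transcript stability by binding short sequence
elements in pre-mRNAs. In systems without CLIP data — *Drosophila* muscle
being a prominent example — candidate target genes are identified
*bioinformatically*: motif instances are located genome-wide from a position
weight matrix (PWM) or consensus, assigned to genes, classified by the gene
feature they fall in (intron, exon, CDS, 5′-UTR, 3′-UTR), and then
summarised with statistics that ask whether a gene category is enriched for
motifs, whether two RBP motifs co-occur in the same genes, and whether their
instances sit closer together than chance placement would put them.
`rbmotif` implements that whole analysis as a tested, seeded, tidyverse-style
pipeline, together with the splice-junction usage and gel-densitometry
quantifications that typically accompany the molecular follow-up.

Everything operates on plain tibbles, so each stage can be inspected,
filtered, or re-entered with ordinary dplyr verbs.

## Coordinates and alphabets

All internal coordinates are **0-based half-open**, everywhere. Conversion
happens only at format boundaries: GFF3 and STAR's `SJ.out.tab` are 1-based
closed and are shifted on read (`start - 1`) and write (`start + 1`); BED
already matches the internal convention. A single convention eliminates the
usual off-by-one bug class, and the io round-trip tests assert the shift is
idempotent.

Sequences are stored as uppercase DNA; RNA `U` becomes `T` at load time, for
motifs as well as sequences (RBP motifs are usually written as RNA). `N`
bases are legal in sequences but any scan window containing one is skipped.

## Motif scanning

A PWM is a position × base probability matrix with a background composition
and a pseudocount. Windows are scored in bits:

$$s(w) = \sum_{i=1}^{L} \log_2 \frac{p_{i,w_i} + c\,b_{w_i}}{(1+c)\,b_{w_i}}$$

where $c$ is the pseudocount (default **0.01**, scaled by the background so
that zero cells in database matrices score finitely rather than $-\infty$)
and $b$ the background (default uniform). A window is a hit when
$s(w) \ge \theta$.

Because published database scans rarely state their cutoff, the default
threshold style is **fraction of the maximum attainable score**, default
0.8 — reproducible and tunable. An absolute threshold in bits is accepted
instead. **Consensus mode** gives the parameter-free reference behaviour for
(U)GCAUG-style analyses: a window is a hit iff it matches the IUPAC string
exactly (matching is boolean, never a float comparison, so exact matches can
never be lost to rounding); its reported score is the maximum score of the
equivalent uniform-over-allowed-bases PWM.

Genome-style scans examine both strands; a reverse-strand hit is a match of
the reverse complement, reported with forward coordinates and strand `-`.
Transcript scans are forward-only. Overlapping hits are all reported — no
greedy masking — because the downstream distance statistics need every
instance. Every scan is validated in the test suite against a brute-force
all-windows scorer written independently of the scan implementation.

## Gene assignment and region classification

A hit is assigned to **every** gene whose span shares at least one base with
it; overlap means ≥ 1 base, with no minimum-overlap fraction (for 6-mers a
fractional rule would silently drop boundary instances). The
**transcribed-strand filter** then keeps only hits on the strand of their
assigned gene — the matches actually present in the pre-mRNA. Unstranded
hits are kept by default (configurable) and counted in a message. The filter
is applied per (hit, gene) pair, so a hit inside two overlapping antiparallel
genes is retained for the sense gene and dropped for the other.

Region classification takes the union over the gene's transcripts of all
feature classes the hit overlaps; a hit may be `exon;3UTR`, or intronic in
one isoform and exonic in another. UTR or CDS membership implies exon
membership. Introns are never read from the annotation: they are derived per
transcript as the gaps between sorted exons, which keeps them consistent
with the exons by construction.

## Gene classes and category statistics

Per (gene, motif), hits collapse to booleans (5′-UTR / 3′-UTR / CDS /
intron) and one class: `UTR_and_CDS` when both a UTR and a CDS hit exist,
else `UTR_only` / `CDS_only`, `intron_only` when only intronic hits exist,
`none` otherwise, with an intron *flag* carried independently of class. One
extra class, `exon_only`, covers genes whose only hits fall in exonic
sequence with no CDS/UTR sub-annotation (non-coding transcripts): without it
such genes would either be mislabelled or silently dropped from "has a
motif". In the synthetic genomes every exon base is UTR or CDS, so the class
is empty there; on real annotations it is a small, honest bucket.

The observed category statistic is simply the percent of genes in a set
with class ≠ `none`. The **expectation** is Monte-Carlo: draw `n_sims`
(default **150**) random gene sets of each size from the annotated-gene
universe *without replacement* (random sets of genes are sets; replacement
would overweight duplicates) and report the mean and SD of the percent per
size. Default sizes are **100, 500, 1000, 3000**. The third size is a
judgement call: the source convention this mirrors lists set sizes with an
apparent typo (a duplicated 100 alongside a 100–3,000 range), and 1000 is
the natural reading; sizes are an argument, so any list can be used.
Sampling without replacement makes the mean unbiased for the population
fraction at every size, which the tests verify to within three standard
errors, along with the hypergeometric variance ordering (SD shrinks as set
size grows).

Both the observed statistic and the expectation accept a `scope`: `"any"`
region (default) or `"utr_cds"`. The scope of the published expectation this
emulates is unstated; defaulting both sides to the same scope keeps observed
and expected comparable, which is the property that actually matters.

Two-motif **co-occurrence** reports the percent of genes carrying instances
of both motifs. The default denominator is the genes with at least one
instance of *either* motif — the "of N genes with at least one motif"
conditioning — with `denominator = "all"` available for the unconditioned
comparison.

## Nearest-distance analysis and its null

For each A-motif instance, the distance to the nearest B-motif instance on
the same sequence. The **gap convention** is fixed: 0 for overlapping or
book-ended intervals, otherwise the count of bases strictly between
(`later.start − earlier.end` under half-open coordinates). Interval toolkits
differ by ±1 on adjacency and the exact convention used upstream of
published analyses is generally unrecoverable; what matters is that observed
and null distances use the *same* convention, so any constant offset cancels
in the comparison. A instances on sequences with no B are excluded and
counted rather than given infinite distances.

The null re-places the observed **number** of B instances (length preserved,
per-gene counts not preserved — "randomly distributed across the
transcriptome" is a global statement) uniformly over exon space: an exon is
chosen with probability proportional to its number of valid start positions
(`len − L + 1`), the start uniform within it; duplicate exon intervals
shared by transcripts are used once. Simulated intervals may overlap each
other and A — no exclusion rule is imposed, the simplest faithful reading.
Default **50 simulations**. "Averaging the results" is ambiguous between
pooling distances and averaging summaries, so both are kept: pooled
distances feed the density curves, per-simulation medians feed inference.
The comparison reports the observed median, the null median mean ± SD, and
the empirical p — the fraction of simulations whose median is at most the
observed median, labelled `< 1/n_sims` when zero. Calibration is tested: when
the "observed" B set is itself drawn from the uniform-in-exons law, the
empirical percentile is approximately uniform across repeated draws.

## Splice-junction usage

For junctions sharing a donor D (or, with roles swapped, an acceptor), the
usage of alternative $x$ is

$$100 \times \frac{\text{reads}(D\,A_x)}{\sum_{k}\text{reads}(D\,A_k)}.$$

Events are user-declared coordinate lists (hand-selected, as in practice),
not discovered; a helper lists all junctions sharing an anchor to assist
event definition. Counts default to uniquely-mapping reads (STAR column 7),
with a flag to add multi-mappers. Events whose total is zero are flagged
undefined and get `NA` percents — never 0/0 → 0, which would fabricate a
usage value. Whether replicates should be pooled or kept separate is a
reporting choice, so both per-sample and pooled rows are emitted. The strand
geometry of an event is validated (a donor sits at the intron start on `+`
and at the intron end on `-`), and a matched junction record whose strand
contradicts the declared anchor role is an error rather than a silent zero.

## Densitometry

Two quantities: percent of signal,
$100 \cdot x_i / \sum_j x_j$ over the bands of one lane/primer pair, and
normalised fold change,
$(\text{sample}_t/\text{sample}_c)\,/\,(\text{ref}_t/\text{ref}_c)$,
with the control gene (default `RpL32`, configurable) measured in the same
condition and the reference condition measured **in the same replicate**.
Replicate pairing is mandatory metadata: cross-replicate ratios refuse to
compute with an error naming the missing measurement. All-zero lanes are
flagged undefined. Identities (self-fold-change ≡ 1, invariance to within-
replicate rescaling, percent sums of 100) are asserted over randomised
tables in the tests.

## The synthetic-data generator

The generator exists so that every stage has ground truth without any
download. `make_genome()` draws non-overlapping genes (2–6 exons, both
strands, exon lengths 80–300, introns 60–200, 5′-UTRs 30–120 and 3′-UTRs
60–250 capped to leave ≥ 10 coding bases in the terminal exons, intergenic
gaps 100–400 — magnitudes chosen to resemble a compact invertebrate genome)
on a uniform 25%-per-base background. Uniform composition makes
spurious-match screening cheap and the analytic checks clean; a GC-biased
composition is available for robustness experiments.

`plant_motifs()` writes motif instances wholly inside feature intervals of
the requested type, on the transcribed strand (reverse-complemented into the
genome for `-` genes), at per-gene, per-region Bernoulli rates. A coupling
rule plants a B instance within `d_max` bases of each A instance with
probability `q`, which creates the proximity signal the distance analysis
must detect. An `antisense` fraction plants on the wrong strand on purpose,
giving the strand filter something to remove — ground truth records the
strand, so exclusion can be checked exactly. After planting, the background
is screened: any exact consensus match (either strand, any motif) outside
the planted set has its free bases re-rolled until none remain, so a
consensus-mode scan recovers exactly the truth table. Plants are kept ≥ 1
base apart so every spurious window retains a re-rollable base; motifs whose
consensus can appear inside another motif's planted instance cannot be
screened and raise an error rather than returning a dirty fixture.
Screening applies to consensus-mode truth only — PWM hits in random
background are legitimate matches, not artifacts, so PWM-mode experiments
use threshold-relative truth instead.

`make_sj()` draws junction reads multinomially at a declared depth per
event and omits zero-read lines, as an aligner would; `make_bands()` builds
band tables exactly consistent with declared fold changes under randomised
per-replicate scales (to which the statistic must be invariant), plus
optional log-normal noise.

What the generator does **not** emulate: realistic base composition, repeat
content, codon structure, overlapping genes (available but off by default),
multi-isoform genes, read-level noise, or mapping artifacts. Passing tests
on these fixtures therefore demonstrate the correctness of the *computation*
— coordinate handling, strand logic, class assignment, Monte-Carlo
machinery — not robustness to the messiness of real annotation or real
alignments.

## Problem sizes and numerical choices

The test suite runs the scanner against the brute-force oracle on 100
random problems up to 10 kb, the end-to-end recovery on a 210-gene genome,
the expectation at population fractions 0.1/0.25/0.4 on a 6,000-gene
universe, null calibration over 200 repetitions of a 50-simulation null,
and the distance oracle on 100 instances of up to 500 intervals per side.
The acceptance script regenerates a 3,200-gene transcriptome (~5.6 Mb over
four sequences) so that the full default expectation sizes, including
3,000, run against a real population. These sizes were chosen as the
smallest that exercise every code path at meaningful statistical
resolution.

Other numerical choices worth knowing: PWM row sums are validated to 1e-6;
scan thresholds are compared with `>=`; consensus matching never touches
floats; empirical p values of zero are reported with a `< 1/n_sims` label;
`percent` is `NA`, never 0, when a denominator is zero; all Monte-Carlo
functions take an explicit `seed` and are bit-reproducible under it, using
`withr::with_seed` so the caller's RNG state is untouched.

## Limitations

- PWM score calibration against a background model (p-values) is out of
  scope; the fraction-of-max threshold is a transparent substitute, not an
  equivalent.
- Gene categories are inputs; no enrichment testing (GO or otherwise) is
  provided.
- The proximity null preserves only the count and length of B instances; a
  per-gene-count-preserving placement would answer a subtly different
  question and is not implemented.
- Junction usage is exact-coordinate matching of declared events: no
  junction discovery, no PSI-style exon models, no differential testing.

## A small worked example

```{r example, message = FALSE}
g <- make_genome(genome_spec(n_seqs = 1, seq_length = 60000, n_genes = 18),
                 seed = 1)
pl <- plant_motifs(g, plant_spec(
  coupling = list(a = "Rbfox1", b = "Bru1", d_max = 50, q = 0.5)), seed = 2)

hits <- bind_rows(lapply(c(Rbfox1 = "TGCATG", Bru1 = "TGTTGT"), function(cons) {
  scan_motifs(pl$sequences,
              settings = scan_settings("consensus", iupac = cons,
                                       both_strands = TRUE))
}) |> setNames(NULL)) |>
  mutate(motif = ifelse(motif == "TGCATG", "Rbfox1", "Bru1"))

ah <- annotate_hits(hits, pl$annotation)
sm <- summarize_genes(ah, pl$annotation)
count(sm, motif, class)

category_percent(filter(sm, motif == "Rbfox1"),
                 pl$annotation$genes$gene_id)$percent_with_motif

a <- filter(ah, motif == "Rbfox1")
b <- filter(ah, motif == "Bru1")
obs <- nearest_distance(a, b)
null <- simulate_null(pl$annotation, a, n_b = nrow(b), motif_len_b = 6,
                      n_sims = 50, seed = 3)
compare_to_null(obs, null)
```
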