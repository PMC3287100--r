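---
title: "Measuring synonymous codon usage bias: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring synonymous codon usage bias: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The problem

Synonymous codons code for the same amino acid but are not used
interchangeably. In compact viral genomes — hepatitis B virus being the
motivating case, with ~3.2 kb of coding content spread over four overlapping
reading frames — the observed codon preferences reflect a tug-of-war between
**mutation pressure** (directional nucleotide-composition bias of the genome)
and **translational selection** (pressure toward codons that translate well
in the host cell). `codonbias` implements the standard descriptive toolkit
for separating these forces in a cohort of coding sequences, plus a
generator of synthetic cohorts in which the two forces can be dialed
independently, so every statistic can be validated against known truth.

## Statistics

### RSCU

For amino acid $i$ with $n_i$ synonymous codons, total count $X_i$ and codon
count $x_{ij}$, the relative synonymous codon usage is

$$\mathrm{RSCU}_{ij} = \frac{x_{ij}\, n_i}{X_i}.$$

Values within a family sum to the family degeneracy, 1.0 means unbiased
usage, and the statistic is invariant to amino-acid composition and sequence
length. RSCU vectors here cover the 59 *synonymous sense codons*: the 61
non-stop codons minus ATG and TGG, whose amino acids offer no synonymous
choice. A family absent from a sequence has *undefined* (not zero) RSCU.
Codons with RSCU above 1.6 are flagged over-represented and below 0.6
under-represented; both thresholds are strict inequalities, so a value of
exactly 1.6 is "normal". Note that applying the under-representation rule to
a published profile can flag codons that narrative summaries of the same
table omit (e.g. a serine codon at 0.58); the code follows the rule, not any
prose list.

### ENC

Wright's effective number of codons summarizes absolute bias on a 20–61
scale. Per family with $n \ge 2$ occurrences and within-family frequencies
$p_j$, the homozygosity is

$$F = \frac{n \sum_j p_j^2 - 1}{n - 1},$$

and with $\bar F_k$ the mean over usable families of degeneracy $k$,

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3}
  + \frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

capped at 61 (the finite-$n$ estimator overshoots slightly under equal
usage). Numerical policies, chosen where the estimator is classically
underdetermined:

* families with $n < 2$ have no defined $F$ and contribute nothing;
* $F \le 0$ values (possible at small $n$ under near-equal usage) are
  discarded as unusable rather than clamped;
* if the lone 3-fold family (Ile) is unusable, $\bar F_3$ is imputed as
  $(\bar F_2 + \bar F_4)/2$ — the standard practice, since Ile is often
  sparse in short sequences;
* if the 2-, 4- or 6-fold class is empty the ENC is reported missing with
  per-class diagnostics, never imputed.

### Composition and the expected-ENC curve

Composition profiles report overall nucleotide percentages over the three
positions of the counted sense codons, third-position percentages over the
59 synonymous sense codons only (the GC3s convention), GC pooled over
positions 1–2 (GC12) and GC at the synonymous third positions (GC3). Stop
codons are never counted anywhere: a terminal stop is retained in the record
for round-trip fidelity but excluded from every statistic.

When composition alone drives codon choice, the ENC expected at GC3 fraction
$s$ is

$$\mathrm{ENC}_{\exp}(s) = 2 + s + \frac{29}{s^2 + (1-s)^2},$$

so `expected_enc(0.5) == 60.5`, `expected_enc(0) == 31`,
`expected_enc(1) == 32`. Strains sitting clearly below this curve show bias
beyond mutation pressure; GC12–GC3 correlation across strains is the
complementary neutrality diagnostic.

### PCA and correlations

Strains become rows of a strains × 59 RSCU matrix (columns alphabetical in
DNA spelling; cells undefined in a strain imputed at the neutral value 1.0,
with a warning — imputing 0 would manufacture bias in absent families). PCA
is the column-centered decomposition of that matrix. The default scaling is
**covariance** — RSCU values already share a dimensionless scale, so
standardizing columns would up-weight near-constant codons; correlation
scaling remains available as a flag because published analyses do not always
state their choice, and the two can differ materially in the leading
variance fractions. Component signs are fixed by making the largest-|loading|
entry of each component positive, which makes scores reproducible across
platforms; published score tables should be compared by configuration
(distances), not raw signs. "Pearson's rank" in older methods sections is
read as the product-moment coefficient (papers report $r$); the correlation
suite pairs each overall nucleotide content with each synonymous
third-position content, plus GC12–GC3 and ENC–GC3, with two-sided $p$ from
the $t$ distribution on $n-2$ df.

### Host comparison

The bundled `"human-Table2"` reference is a published human RSCU table
frozen at its printed two-decimal values, making comparisons download-free
and stable (its underlying gene set is uncited in the source, so it is
treated as an opaque constant). A codon is *coincident* when virus and host
fall on the same side of 1 (both ≥ 1 or both ≤ 1) and *antagonistic*
otherwise — a sharp, implementable surrogate for loosely defined
"similar pattern" prose lists, which tend to be internally inconsistent at
the codon level. The report also flags, per family, whether the argmax
codon matches, and lists codons the virus uses freely (RSCU > 1) that the
host under-represents (RSCU < 0.6).

## Sequence ingestion

FASTA and GenBank flat files are supported; U is normalized to T at
ingestion and all computation runs in the DNA alphabet. For GenBank records
the default `concatenate-all-cds` mode joins every annotated CDS, each gene
read in its own frame — the right convention for genomes with overlapping
reading frames, where codon statistics are frame-dependent and a
whole-genome single-frame reading would be meaningless. Overlapping
genomic regions therefore contribute once per gene that spans them;
`per-cds` mode exposes the individual features for any other convention.
Validation is policy-driven: frame-breaking lengths error by default
(truncation available), internal stops warn and keep by default (each
upstream CDS in a concatenation ends in its own stop), and ambiguous codons
are flagged and excluded from all counts.

## The synthetic cohort generator

`simulate_cds()` draws, for every codon slot, an amino acid from a profile
(uniform over the 20 amino acids by default), then a codon within the family
from the mixture

$$(1-w)\,P_{\mathrm{mut}}(\text{codon}\mid\text{family}) +
  w\,P_{\mathrm{sel}}(\text{codon}\mid\text{family}),$$

where $P_{\mathrm{mut}}$ is the product of per-position nucleotide
probabilities renormalized within the family and $P_{\mathrm{sel}}$ is the
target RSCU divided by degeneracy. Drawing the amino-acid sequence first
decouples amino-acid composition from synonymous preference — exactly the
separation RSCU is designed around, and the property that makes its
invariances testable. Consequences worth knowing:

* positions 1–2 are dictated by the amino-acid profile, so the mutation
  model effectively controls composition at the third position; the
  composition-recovery tests therefore target GC3, not all three positions;
* with a GC-symmetric mutation model (`mutation_model_gc`) the expected GC3
  of every family equals the model's GC target, so `w = 0` cohorts land on
  the expected-ENC curve up to sampling noise, while mixing in a
  concentrated selection model pulls strains below it — the geometry the
  neutrality plot diagnoses;
* stop codons are never generated internally; one terminal stop (drawn from
  the mutation model restricted to stops) is appended per sequence, which
  also exercises the readers' stop-exclusion logic;
* cohorts are deterministic given the spec (seed included): identical specs
  produce byte-identical FASTA.

What the generator does *not* emulate: phylogenetic correlation between
strains, substitution dynamics, overlapping-ORF constraints, and real
amino-acid usage (unless a profile is supplied). Passing tests on synthetic
cohorts validate the statistics and their geometry, not any claim about a
particular real virus.

## Problem sizes and tolerances

The validation suite runs at sizes where the checked properties are
statistically sharp: ENC endpoint checks at ~3k–50k codons (the equal-usage
limit is within 0.5 of 61 from ~50k codons); curve-geometry checks at 50
strains × 10,000 codons, where mean |ENC − expected| < 1 for null cohorts
and ≥ 95% of selection-mixed strains sit below the curve; RSCU
target-recovery on a pooled 5 × 100,000-codon cohort, where the 0.05
max-deviation bound is ~3.5 sd on the noisiest (6-fold) cells; and ENC is
checked against a brute-force homozygosity oracle to 1e-9 on hundreds of
random sparse tables. The 58-strain accession panel itself is shipped as a
verbatim manifest (with its two source anomalies — a duplicated accession
and a truncated one — flagged); recomputing its published scores requires
fetching the GenBank records, which the library deliberately never does:
point `read_genbank_cds()` + `run_pipeline()` at downloaded records to
reproduce that tier, under the documented concatenate-all-cds convention.

## Known limitations

* ENC variants differ across legacy software in rare-amino-acid handling;
  second-decimal disagreement with older published per-strain values is
  expected and documented rather than tuned away.
* The concordance rule is codon-level and sharp; it will not reproduce
  amino-acid-level "similarity" narratives that mix directions within a
  family.
* No CAI, tRNA adaptation, dinucleotide bias, codon-pair bias, alignment or
  phylogenetics — deliberately out of scope.
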