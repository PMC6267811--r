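---
title: "Assessing variant benchmark representativeness with benchrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing variant benchmark representativeness with benchrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benchrep)
```

## The problem

Benchmark datasets of single amino acid substitutions (SAASs) are the
training and evaluation material for variant tolerance predictors. A
benchmark is *representative* when it covers the space of the phenomenon it
stands for — here, the structural and functional category space of the
human proteome. A predictor trained on variants concentrated in a handful
of intensively studied disease proteins cannot learn the parts of the
protein universe those proteins do not inhabit.

benchrep quantifies representativeness for one or many datasets by
projecting their variants into five category spaces and comparing each
projection with a proteome-wide background:

| space | levels | variant assignment | background |
|---|---|---|---|
| chromosome | 1 | gene of the canonical protein | gene counts and summed CDS lengths per chromosome |
| CATH | class, architecture, topology, homology | domain segment containing the mapped structure residue | one count per domain on each 95%-identity cluster representative chain |
| Pfam | family | families whose interval contains the position | one count per protein–family annotation row |
| EC | levels 1–4 | all codes of the canonical protein | one count per protein–code row, per level |
| GO | term, aspect | all terms of the canonical protein | one count per annotation row |

## The mapping funnel

Variants arrive keyed by RefSeq, Ensembl, or UniProt identifiers. The
funnel is strictly monotone — structure-mapped ⊆ protein-mapped ⊆ all
records:

1. **Canonical resolution.** UniProt records pass through when the
   accession exists. RefSeq/Ensembl records resolve through cross-reference
   tables *only when the foreign and canonical sequence lengths match
   exactly*; a position beyond the canonical length also unmaps the record.
   No alignment is attempted — identifier translation is a table lookup
   plus the length-equality guard.
2. **Structure selection.** Candidate structures are those with a chain
   whose mapped interval contains the position. They are tried from the
   best (lowest) resolution upward. A structure whose residue at the
   position is flagged Not\_Observed is discarded entirely and the next
   structure is tried; within a structure, the first chain in mapping-file
   order containing the position is taken, with no further checking.

Three choices here were genuinely open and are fixed as follows.
Structures without a resolution value (NMR-like entries) sort after all
resolved structures, and equal resolutions tie-break by structure
identifier — selection must be a total order to be deterministic. When the
first chain of a structure is unobserved at the position but another chain
of the same structure is observed, the whole structure is still discarded:
that is the closest reading of the discard rule, which operates on
structures, not chains. "First chain" means first in the residue-mapping
file, whose row order is recorded at read time.

## The statistical battery

**Chromosomes.** Expected counts are `E_c = n · w_c / Σw` under two
weighting bases, gene counts and summed coding-sequence (CDS) lengths.
Each chromosome gets a minimum-likelihood two-tailed binomial test (the
total probability of all outcomes whose mass does not exceed the mass at
the observed count, with a 1 + 1e-7 relative slack); the headline
"unbiased chromosomes" count uses the gene basis at α = 0.05. The overall
distribution gets a Pearson chi-square statistic on k − 1 degrees of
freedom (proportions are fixed, not estimated). The per-chromosome test is
exact, hence slightly conservative at finite n: its achieved size is a
little below α for small expected counts, which the calibration tests
account for by comparing the empirical false-bias rate against α with an
empirical standard error.

**Category distributions.** At each level the two Kolmogorov–Smirnov
samples are per-category *relative frequencies*: the dataset's counts
normalized by its total assignments (one value per category present) and
the background's normalized counts (one value per background category).
The p-value is the asymptotic Kolmogorov approximation evaluated at
`(e + 0.12 + 0.11/e)·D`, `e = √(nm/(n+m))` — the classical corrected form
used by the standard scientific-computing implementations this battery is
meant to agree with. It is applied at every sample size, including the
3-point aspect-level comparison; `ks_p_method = "exact"` switches to the
exact conditional distribution for honest small-sample inference, at the
price of no longer matching the conventional printed values. Bias calls
use α = 0.01: with only a handful of frequency values per side the KS test
has little resolution, and 0.01 is the threshold consistent with treating
a p of ~0.05 at EC level 3 as unbiased while all topology/homology-level
deviations remain flagged.

**Coverage.** `coverage = A(DS)/A`, the fraction of the scheme's classes
with at least one representative in the dataset; labels outside the
background are counted separately as excess rather than as coverage.

**Contamination.** A pathogenic dataset is screened against an ExAC-style
allele-frequency table: a record is "likely benign" when an entry with the
identical (accession, position, ref, alt) has minor allele frequency
strictly between 1% and 25% in at least one of the populations.

**Score.** Each of the 11 category tests (CATH ×4, EC ×4, Pfam, GO term,
GO aspect) contributes 1 when unbiased. A category that cannot be computed
— e.g. every CATH level for a dataset with zero structure-mapped variants
— scores 0 *with an explicit note*; silently omitting it would make
scores incomparable across datasets. The chromosome battery is reported
alongside but excluded from the category sum, mirroring the convention of
summarizing chromosomal bias as a count of unbiased chromosomes.

Multiplicity is configurable: by default a variant lying in two Pfam
families (or annotated with the same GO term twice) increments each
category once per variant. GO terms are weighted per-variant, not
per-protein — the alternative would discard exactly the over-study signal
the score is meant to catch.

## The synthetic universe

All reference inputs are emulated by `generate_proteome()` so the entire
pipeline runs with no external downloads. Defaults describe a miniature
human-like universe, fixed once:

* 300 genes on chromosomes 1–22, X, Y (no MT), apportioned by the human
  per-chromosome protein-coding gene counts (largest-remainder method);
* CDS lengths log-normal (meanlog 7.2, sdlog 0.55 nt ≈ median 1340 nt,
  matching the human mean of ~1.7 kb within a factor close to one);
  protein length is `floor(CDS/3) − 1` residues, floored at 30 — the
  subtraction keeps the gene-count and length weightings coupled but
  distinct;
* 40% of proteins carry 1–3 structures. The first structure of a covered
  protein spans the whole chain (so full coverage with a zero unobserved
  rate maps every residue by construction); additional structures cover
  partial runs, resolutions are uniform on 1.0–3.5 Å with 10% absent, and
  each mapped residue is Not\_Observed with probability 0.05;
* a CATH hierarchy of 4 classes / 10 architectures / 25 topologies / 40
  superfamilies — the human proteome's 4/30/508/907 scaled down while
  keeping enough categories per level for the KS tests to resolve shape
  differences; superfamily usage is Zipf-weighted because real domain
  family sizes are heavy-tailed (the exact background shapes are not
  documented anywhere, so a power law is an explicit stand-in);
* 60 Pfam families with Zipf-weighted usage; intervals lie inside the
  protein and never tile a whole sequence;
* 21% of proteins are enzymes; 20% of EC codes lack their deepest
  level(s), exercising the rule that incomplete codes drop out of deeper
  level counts;
* 150 GO terms over the aspects MF/BP/CC, every protein annotated with at
  least one term, each term in exactly one aspect;
* 2% of cross-reference rows carry a deliberately wrong foreign length,
  exercising the length-match rule.

Each component draws from its own independently seeded stream, so adding a
generator never perturbs another's output; identical configurations give
byte-identical tables.

Variant datasets come in two modes. `uniform` draws residues uniformly
over all residues of all proteins — the unbiased reference condition.
`hotspot` first draws a protein with probability ∝ rank^(−s) and then a
residue uniformly within it; the Zipf rank law is the simplest heavy-tail
stand-in for the documented extreme concentration of curated variants in
a few disease proteins (thousands of variants on one protein while most
carry a handful).

**What the generator does not emulate:** real human gene content, real
CATH/Pfam frequency spectra, linkage between variants, nucleotide-level
variation, or the DNA→protein translation step of real pipelines (only
protein-level substitutions are accepted). Passing tests therefore show
the machinery is correct and calibrated under controlled conditions, not
that any real dataset is representative.

## Numerical conventions and degenerate inputs

* All residue coordinates are 1-based inclusive; structure-vs-protein
  numbering is crossed only inside the structure registry.
* Reported percentages are rounded to 2 decimals, round-half-even.
* Residues outside the 20-letter alphabet, non-positive positions and
  ref = alt rows are dropped by the readers and counted, never silently
  repaired.
* An empty dataset reports zero percentages (not NaN), vacuous
  per-chromosome p-values of 1 (a 0-trial binomial has a single outcome),
  and an NA chi-square.
* A dataset with no assignment at some level marks that category
  not-computable; coverage for it is 0 over the background classes.

## Calibration and test problem sizes

The test suite runs the generator at its default size (300 genes) with
datasets of 10²–10⁴ variants, 50–200 replicate seeds per property, chosen
so the whole suite completes in a few minutes while keeping Monte-Carlo
standard errors well below the margins being asserted:

* uniform datasets keep the per-chromosome false-bias rate within 3
  standard errors of α over 200 replicates (CDS basis — uniform-by-residue
  sampling is length-weighted by construction, so the gene basis is the
  *intended* misfit and is indeed flagged);
* the overall chi-square on hotspot data increases with the concentration
  exponent;
* uniform datasets of 4000 variants score 8–9 of 11 — the deep EC levels
  stay biased because background EC frequencies are per-annotation-row
  while variants weight proteins by length, an intrinsic mismatch that
  real datasets share — whereas hotspot datasets (s = 2) are flagged at
  the topology, homology, Pfam and GO-term levels in ≥ 90% of seeds.

The same per-variant vs per-annotation-row mismatch puts a small floor
under the total-variation distance between a uniform dataset's annotation
profile and the background; convergence with n is therefore asserted on
the chromosome and Pfam profiles, where the floor is far below the
sampling noise at the sizes tested.

## Known limitations

* Identifier resolution is by exact length-matched lookup; isoforms or
  updated sequences that shifted numbering are unmapped rather than
  rescued by alignment.
* The corrected-asymptotic KS p-value is anticonservative at very small
  samples; the exact mode exists for real inference, the default exists
  for comparability with the conventional printed values.
* No multiple-testing correction is applied anywhere — the score counts
  marginal calls at fixed α by design.
* GO annotation is used flat: no propagation to ancestor terms, so a
  dataset annotated with specific child terms and a background annotated
  with their parents would look artificially disjoint.
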