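---
title: "tetrasnp: models, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tetrasnp: models, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical models and algorithmic rules, why each tunable threshold has
the default it has, what the synthetic allotetraploid generator does and
does not emulate, and the choices made where the design was genuinely open.

## 1. Setting and assumptions

`tetrasnp` analyses bulk RNA-seq of an allotetraploid (AABB) species whose
genes exist as homoeolog pairs at roughly 95–100% nucleotide identity, read
against a collapsed transcript reference. Two assumptions carry the whole
analysis:

* **Inbred material.** Every variety in the panel is an inbred line, so a
  heterozygous-looking genotype call reflects a mixture of the two homoeolog
  copies, not allelic heterozygosity. This is what licenses the five-way SNP
  taxonomy.
* **A-genome-like reference.** The reference used for phasing is close to
  the A subgenome, so the phased haplotype that matches the reference
  pattern can be labelled A and its complement B.

Only substitutions are modelled end to end. Alignment gaps count against a
read inside the caller's quality window but are never emitted as variants,
because the downstream taxonomy and phasing operate on SNPs.

## 2. Variant calling (`caller_params`)

Each aligned base must survive a quality window centred on it: window length
11 bp, at most 6 gaps+mismatches inside the window, central base quality
≥ 20, mean window quality ≥ 15 (window truncated at read ends). A position
is callable at ≥ 8 filtered reads. An alternative allele is *supported* when
its filtered read count is ≥ 4 **and** either its frequency is ≥ 10% or its
count reaches 1000 — the absolute-count waiver matters only at extreme
depths, where a fixed frequency cut would be too blunt; at desk scale it is
inert. Genotypes: HOM_ALT at ≥ 90% alternative frequency, HET when
reference and alternative both reach 10%, HOM_REF otherwise.

Two of these numbers are package choices rather than quoted settings:

* `hom_frequency = 0.90`: the homozygosity boundary, chosen symmetric with
  the 10% support threshold. Inbred-line hemi-SNPs sit near 50% frequency,
  far from either bound, so the classification downstream is insensitive to
  this value over a wide range.
* The interpretation of the two variant-count thresholds (floor of 4;
  frequency waived at 1000) is recorded in the configuration so an
  alternative reading can be tested by changing two numbers.

Homozygous-reference positions with coverage ≥ 8 are *kept* in the caller
output: the taxonomy needs them as "sufficient information" cells.

## 3. The SNP taxonomy (`taxonomy_params`)

Rows of the multi-variety genotype matrix are retained when at least one
variety calls a non-reference genotype and at least
`min_informative_varieties` (default 5) varieties have coverage ≥ 8. The
decision table over non-missing calls is total and single-valued:

| pattern | class |
|---|---|
| all HOM_ALT | misassembly |
| all HET | inter_homoeolog |
| homozygous only, both classes present | simple |
| HET plus exactly one homozygous class | hemi |
| HET plus both homozygous classes | multi_genotype |

Notes on the open points:

* Two informative-variety thresholds are in circulation (5 for the SNP
  table, 7 for frequency-distribution reports); they are one parameter with
  default 5, and the active value is recorded in the configuration.
* The frequency histogram uses seven half-open bins of width 0.13 starting
  at 0.05. The scheme is inferred from the single published bin
  `[0.18, 0.31)` containing the worked 25% example; origin and width are
  exposed as parameters. Frequencies beyond the last edge (a frequency of
  exactly 1.0) are clamped into the top bin.
* A "carrier" counts HET and HOM_ALT cells equally, both for rarity
  (rare = at most 1 carrier) and for the frequency numerator; carriers are
  counted over non-missing cells only.
* Array-candidate selection keeps simple and hemi SNPs with ≥ 3 carriers;
  inter-homoeolog and misassembly rows are excluded as non-varietal.

## 4. Phasing (`phasing_params`)

Read pairs become fragments over the heterozygous sites they cover
(0 = reference allele, 1 = alternative, gap otherwise; mates disagreeing at
a shared site contribute a gap — conservative evidence handling). Sites
co-covered by a fragment are connected; each connectivity component with
≥ 2 sites is a candidate block.

The block's haplotype pair minimises the **MEC score**: the sum over
fragments of the smaller mismatch count against either haplotype. Up to
`exhaustive_site_limit = 15` sites the search is exhaustive over all
2^(n−1) bipartitions (vectorised); beyond that a greedy left-to-right
extension is refined by single-site *and* suffix flips from several
deterministic starts (all-reference, the greedy solution, and the
highest-coverage fragments). Suffix flips are the move class that repairs
chain-break errors, the typical local optimum of single-flip search. The
exhaustive/heuristic switch at 15 sites keeps the exact path testable while
bounding the worst case.

Filtering and labelling implement one coherent criterion with two knobs:
a block is kept when MEC ≤ 10 and the better haplotype matches the
all-reference pattern at ≥ `min_reference_concordance` (0.90) of sites; the
A label additionally requires ≥ `min_subgenome_match` (0.90). Whether these
two 90% rules are one threshold applied once or twice cannot be settled
from their descriptions, so both default to 0.90 but are independent
parameters. When both haplotypes match equally the labels stay unassigned
and the block is excluded from expression analysis rather than fabricating
a subgenome assignment.

Sequence editing substitutes the A-labelled allele into the A copy and its
complement into the B copy at phased sites; homozygous-alternative (fixed)
variants are edited into both. Transcripts with two or more discontinuous
blocks are split at the midpoints between neighbouring blocks, so the
pieces tile the transcript without overlap.

## 5. Double-reference counting and the expression models (`de_params`)

A read pair is scored against the A and B variant of each block it overlaps
as matches − mismatches over the block region; since the two variants are
identical away from divergent sites, the score difference is twice the
difference in divergent sites matched, and the implementation inspects only
those sites. Strictly-better wins; ties (pairs covering no divergent site)
are ambiguous and dropped; a proper pair counts once. Only within-block A/B
ambiguity is modelled — multi-gene mappers are out of scope and noted in
the configuration.

Counts from the 13 varieties are merged into five pseudo-replicate groups
(Altar84+Capeiti8+Claudio; Creso+Edmore+Kofa; Meridiano+Neodur+Saragolla;
Strongfield+Svevo; Valnova+Yavaros79), compensating the scarcity of
homoeolog-specific reads in lowly expressed genes.

The testing machinery is the classic negative-binomial pipeline,
re-implemented so its rules are explicit and testable:

* **Size factors**: median over all-positive rows of the count/geometric-mean
  ratio, normalised to geometric mean 1. A matrix with no all-positive row
  falls back to positive-subset medians with a warning. The implementation
  is cross-checked in the test suite against
  `DESeq2::estimateSizeFactorsForMatrix` (proportional equality), which
  serves as the independent oracle, never the implementation.
* **Dispersions**: per unit, method-of-moments within each tissue's
  replicate columns on normalised counts, pooled across tissues by degrees
  of freedom; a trend `alpha(mu) = a0 + a1/mu` is fitted across units
  (Gamma GLM, identity link; linear fallback) and each unit takes
  max(empirical, fitted) — the conservative choice. All-zero units are
  excluded from testing.
* **GLM Wald test**: per gene-block, a log-link NB regression of the 2×15
  counts on tissue + subgenome with log size factors as offset and the
  pooled dispersion fixed; the Wald statistic of the subgenome coefficient
  (dispersion pinned at 1, since the NB variance is already in the family)
  gives the p-value, BH-adjusted across blocks, significant at ≤ 0.001.
* **Per-tissue test**: A and B counts summed over the tissue's five
  replicate columns and compared by a conditioned exact NB test under the
  pooled dispersion; above 10,000 total reads an asymptotic two-sample
  z-test substitutes for tractability. Bonferroni correction over the units
  tested within the tissue, significant at ≤ 0.01.
* **Fold changes** are computed from normalised means with a 0.5 pseudocount
  on both sides (no zero-handling rule exists for the |log2FC| > 7
  exclusion, and the pseudocount keeps the cap well-defined); units beyond
  the cap are never flagged significant.
* **Multiple-testing universes**: BH over all tested blocks for the GLM;
  Bonferroni within each tissue for the per-tissue test, matching the
  per-tissue reporting convention.

Genes with ≥ 2 tested blocks get a concordance report: a gene is concordant
when all its blocks' fold-changes share one sign.

## 6. Assembly QC (`qc_params`)

Hits (≥ 80% identity) are accepted when ≥ 60% of the contig, > 80% of the
gene, or ≥ 200 bp. Gene span is the union of accepted hit intervals over
the gene length; the contig count is a greedy minimal cover (largest
uncovered gain first, ties to the longer total hit), which the test suite
checks against exhaustive search on small cases. For homoeolog copy
estimation, a hit is assigned A at ≥ 99% identity ("close to 100%" is fixed
at 99.0 and exposed as `a_identity_floor`, symmetric with the quantified
1%-band B rule) and B within 1% of the known paired identity; overlapping
hits keep the higher-identity hit and trim the other, higher identity being
the less ambiguous evidence. The five copy categories have no published
thresholds; the rule used — full copy at coverage ≥ 0.8, presence floor at
0.2 — reproduces the category semantics (both / one / between one and two /
less than one / none) and both numbers are parameters. A paired identity at
or above the A floor makes the bands overlap and flags the estimate
indeterminate.

## 7. The synthetic allotetraploid generator (`sim_params`)

The generator is the package's ground-truth instrument: every downstream
stage is tested by recovery of what it injected.

**What it emulates.** Homoeolog pairs diverging at 2% per bp (~98%
identity, inside the observed 95–100% band); a 13-variety inbred panel with
varietal SNPs of each mechanistic class; paired-end 2×100 bp reads with
i.i.d. base errors (Q30 bases, Q10 at injected errors — constant qualities
make the caller's window filters deterministic to test); negative-binomial
counts over three tissues with a configurable homoeolog bias.

**Site mechanisms.**

* *inter_homoeolog*: the divergent sites themselves — present in every
  variety, heterozygous-looking everywhere.
* *hemi*: a substitution on one subgenome in a carrier subset (uniform
  1..12 carriers by default; the varietal allele-frequency spectrum is not
  pinned down by any published value, so `carriers_distribution` is a
  parameter).
* *multi_genotype*: a hemi mechanism plus additional carriers homozygous
  for the alternative on both subgenomes.
* *misassembly*: the reference itself mutated, so every variety is
  homozygous-alternative against it.
* *simple*: loss of the whole B homoeolog transcript in all varieties plus
  varietal substitutions on the retained A copy — the "one subgenome as the
  only allelic complement" mechanism. The deletion is modelled at
  whole-transcript scope: a partial-segment deletion creates junction
  shadows where read coverage of the deleted copy ramps down over one read
  length, making the observable class of neighbouring sites
  coverage-dependent rather than deterministic. Whole-copy loss keeps every
  injected label exactly recoverable, at the cost of not exercising
  partial-deletion geometry.

**Uniform-core site placement.** Injected polymorphic sites are confined to
the transcript core, at least one read length (`site_margin`) from each
end, and the per-bp divergence rate is rescaled over the core so the
expected divergent-site count per gene remains `homoeolog_divergence * L`.
Near transcript ends, finite-fragment coverage necessarily ramps up from
zero; positions there can reach the 8-read coverage floor while one
subgenome still sits below the 4-read allele-support floor, which would
turn a deterministic class label into a coin flip. Restricting sites to the
uniformly covered core is the generator design that makes "error-free data
⇒ exact label recovery" a theorem rather than a tendency.

**Read model.** Per gene, fragment counts are Poisson with total mean
`2 · depth · L / (2 · read_length)` split between subgenomes by the
tissue's true expression ratio, so each homoeolog's expected coverage is
`depth` in the unbiased case (`depth` is per-homoeolog coverage
throughout). Fragments are 200 ± 20 bp: with 100 bp mates this makes the
pair tile its fragment, avoiding a systematic inner coverage gap that
minimum-length (300 bp) transcripts could not average out; it is
deliberately shorter than typical wheat RNA-seq libraries, a simplification
tied to the 300 bp minimum transcript length. Reads are emitted in
reference orientation with their true alignment positions — the generator
plays the role of a perfect aligner, because alignment itself is outside
the package's scope.

**Expression model.** Per-gene base means are lognormal around `expr_mean`
with per-gene×tissue lognormal effects (so the tissue factor in the GLM is
informative); biased genes (default 20% of genes) carry a constant
two-fold A/B ratio (`bias_log2fc = 1`, the conventional magnitude for
calling a homoeolog "biased"; tests that need stronger effects set it
explicitly).

**What it does not emulate** — and hence what passing tests do *not* show
about real data: alignment and alignment bias, indels and splice isoforms,
position- and sequence-dependent error profiles, GC and 3′ coverage bias,
genotype-by-environment variation across tissues, and varietal population
structure. Recovery results on this generator validate the pipeline's
*rules*; they do not certify performance on real libraries.

## 8. Numerical and degenerate-input choices

* Allele ties in the caller break deterministically (higher count first,
  then alphabetical allele).
* The caller treats each mate as independent evidence; where mates overlap
  a position is counted twice. Phasing, by contrast, merges mates into one
  fragment, and the counter counts a pair once.
* `phase_block` fixes the first site's allele to 0, halving the search
  space; haplotype identity is defined up to complementation.
* Empty inputs return typed empty tables rather than errors wherever the
  empty case is meaningful (no reads, no hits, no blocks); true contract
  violations (unknown transcript ids, overlapping blocks, a variety missing
  from the replicate scheme) stop with an error.
* GLM fits run with up to 100 IRLS iterations; non-converged units are
  flagged and excluded from significance calls rather than reported with
  unreliable p-values.
* The exact NB test enumerates outcomes up to 10,000 total reads; beyond
  that an asymptotic z substitutes (the regime where the discrete
  enumeration is both slow and indistinguishable from its limit).

## 9. Test-suite problem sizes

The suite's simulation sizes are the package's own trade-off between
statistical resolution and a test run measured in minutes: the end-to-end
recovery run uses 200 genes × 13 varieties at per-homoeolog depth 30 with
error-free reads; MEC optimality is checked against brute force on 500
random instances of up to 10 sites; the classifier is compared with its
oracle on every genotype multiset up to panel size 13; the expression
null/power/bias checks use 2,000, 500 and 400 gene-blocks respectively.
Larger runs change nothing qualitatively; the recovery guarantees are
by-design exact at these depths.

## 10. Known limitations

* The zero-misassignment guarantee of double-reference counting holds for
  the sample whose reads built the phase blocks. Other varieties carry
  varietal alleles the blocks never saw; reads covering only such sites can
  be systematically assigned to the wrong subgenome. This is a property of
  the double-reference method itself, not of the implementation.
* Blocks in which the focal sample's varietal (hemi) alleles sit on a
  phased haplotype pass the 90% concordance filter only while they are
  ≤ 10% of sites; such blocks lower reference concordance without being
  errors.
* Splitting transcripts at block midpoints is a convention; reads spanning
  a split boundary are assigned to the block with the stronger evidence.
* The per-tissue exact test conditions on summed counts with a dispersion
  propagated from per-replicate moments; it is exact under the pooled-
  dispersion model, not under arbitrary overdispersion heterogeneity.
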