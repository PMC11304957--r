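---
title: "Methods: enrichment analysis of saturation CXXX selection screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment analysis of saturation CXXX selection screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caaxscreen)
```

## The experiment being modelled

A CaaX-type prenyltransferase recognises a C-terminal tetrapeptide — cysteine,
two aliphatic positions a1/a2, and a variable X residue — and attaches an
isoprenoid lipid to the cysteine. To map the enzyme's specificity
exhaustively, a saturation screen fuses every one of the 20³ = 8,000 possible
C-fixed tetrapeptides (the "CXXX space") to a reporter whose function depends
on being prenylated, pools the library, grows it competitively under a
selective condition, and sequences the variable region before and after
selection. Variants that support reporter function expand; variants that do
not are diluted out.

Two reporter designs are covered. In the thermotolerance design, a chaperone
reporter supports growth at elevated temperature (37 °C or 42 °C) when
prenylated but *not* proteolytically processed further, so the screen enriches
"shunted" motifs — prenylated sequences whose a2 residue is not accepted by
the downstream CaaX protease — while canonically processed motifs are
de-enriched. In the viability design, an essential GTPase reporter tolerates
either route, so any prenylatable variant survives; hits are recovered as
individual colonies and Sanger-sequenced.

## The enrichment statistic

For a library (naive or selected), the frequency of variant $v$ is

$$f(v) = \frac{\sum_{r} c_r(v)}{\sum_{v'} \sum_{r} c_r(v')}$$

where $c_r(v)$ is the validated read count in replicate $r$ — reads rejected
during extraction or translation never enter the denominator. The enrichment
score is the frequency ratio

$$E(v) = \frac{f_{\mathrm{selected}}(v)}{f_{\mathrm{naive}}(v)},$$

greater than 1 for enrichment, less than 1 for de-enrichment. Three choices
are deliberate:

- **No pseudocounts.** The observed minimum score in such screens is exactly
  0 (a variant present in the naive pool and absent after selection), which a
  pseudocount would obscure. A zero *denominator* — impossible when the naive
  pool truly contains the full library, possible on user data — yields an
  `undefined` flag and a warning, and the variant is excluded from rankings.
- **The permissive-temperature library is never a denominator.** It is
  computed and exported for inspection, but permissive-growth pools show
  idiosyncratic outliers that would propagate into every score.
- **Deterministic ordering.** Subset selections order by score and break ties
  lexicographically by variant, so the top-$n$ subset is identical across
  runs and platforms.

## Motif classification

Classification flags are computed from configurable residue sets
(`caax_ruleset()`), defaulting to the consensus the screen data themselves
support: consensus X residue L/F/I/M/V; branched-chain aliphatic (BCA) a2
V/I/L, the CaaX-protease requirement; restrictive residues a2 ∈ {D,E,K,R} or
X ∈ {K,R,P}, which block prenylation of the reporter. `canonical_cleavable`
requires BCA a2 *and* consensus X; a1 is left unconstrained because sequences
with non-aliphatic a1 (e.g. CAIL) behave canonically in this assay — the rule
is keyed on what the selection actually discriminates. When residue sets are
overridden, the restrictive flag takes precedence in the fitness-tier mapping
so no variant can occupy two tiers.

The five residue colour classes used in logos (cysteine; V/I/L; K/R/H/D/E;
S/Q/T/N; A/G/P/F/W/Y/M) partition the 20 amino acids and are exposed as data
via `residue_classes()`.

## The simulator and its calibration

The generator reproduces the statistical structure of the screen, not its
biochemistry:

1. **Naive pool.** One library-wide abundance vector is drawn from a
   symmetric Dirichlet with concentration 5 — uneven enough to reproduce the
   outlier dispersion seen in real transformation pools (frequencies spanning
   roughly an order of magnitude) while keeping all 8,000 variants present.
   Each replicate's colony counts are an independent multinomial of 150,000
   colonies from this shared vector, matching the design in which one
   transformant pool seeds every replicate culture.
2. **Growth.** Deterministic exponential growth $N' = N \cdot 2^{fD}$ with
   $D = 8$ doublings, the simplest law consistent with a fixed number of
   doubling rounds. Relative rates $f \in [0,1]$ come from a tier table.
3. **Sequencing.** Multinomial reads proportional to the grown abundances.
   In FASTQ mode each read is `left anchor + coding 9-mer + right anchor`
   with each base substituted uniformly at rate 0.001; the anchors are fixed
   20-nt synthetic sequences, standing in for an amplicon layout that is not
   part of the model.

**Fitness tiers.** The default 42 °C table is `shunted` 1.0, `canonical`
0.35, `nonconsensus` 0.25, `restrictive` 0.10. Restrictive sequences sit in
their own tier *below* generic non-consensus sequences because restrictive
residues block prenylation outright, and because a three-tier table that
lumps them together cannot reproduce the screen's observed composition: the
library holds 2,560 restrictive variants among 6,400 non-shunted,
non-canonical ones, so a merged bottom tier would put only ~40% restrictive
sequences in the bottom-500 subset, whereas the screen finds well over half.
The 37 °C table (`shunted` 1.0, `nonconsensus` 0.85, `restrictive` 0.70,
`canonical` 0.30) has a smaller spread and inverts the canonical/restrictive
order: at the milder temperature only the canonically processed cluster is
strongly de-enriched, and unmodified sequences sit near neutrality. All
magnitudes are the package's own calibration of the screen's qualitative
outcome, not measured rates. The viability-reporter table is binary: shunted
and canonical variants are viable, others are not.

**Read depth.** Selected libraries default to 100,000 reads per replicate,
the scale of a multi-million-read run divided over conditions and replicates.
The naive library defaults to 1,000,000 reads per replicate — ten-fold deeper
— because it is the shared denominator of every E-Score: the ratio estimator
$\hat f_s/\hat f_n$ carries a finite-count bias of order $1/(\text{naive
reads per variant})$, and sequencing the denominator pool deeper keeps that
bias well below the sampling noise across 8,000 variants. This mirrors
standard practice of sequencing the input pool of a selection screen more
deeply than the outputs.

**Determinism.** A single integer seed governs everything; each stochastic
stage consumes a stream derived from `(seed, stage)` and restores the
caller's RNG state afterwards, so independent stages cannot perturb one
another and two runs with one seed are byte-identical down to the FASTQ
files.

**Colony screen.** `simulate_rho1_colonies()` models the three artefacts of
colony picking: gene conversion with the resident wild-type plasmid (a pick
returns the exact parent DNA, probability 83/200 by default), double-picked
colonies (a non-parent pick repeats an earlier one, probability 5/117), and
fresh survivors, drawn uniformly from the viable variants and encoded with
random synonymous codons so that distinct DNA sequences can encode one
protein. The default fractions are calibrated so the deduplication ladder is
200 picks → 117 non-parent → 112 unique DNA *in expectation*; individual runs
vary binomially.

## Library coverage

The coverage claim behind "~150,000 colonies per replicate" is
coupon-collector mathematics under equal-abundance sampling:

- expected covered fraction $1 - (1 - 1/L)^n$, computed via `log1p`/`expm1`;
- complete-coverage probability by inclusion–exclusion,
  $\sum_{j=0}^{L} (-1)^j \binom{L}{j}(1 - j/L)^n$, with every term evaluated
  in log space, truncation once terms underflow, and a union-bound fallback.
  For $L = 8000$, $n = 150000$ the alternating series is dominated by its
  $j=1$ term ($\approx 5.7\times10^{-5}$), giving
  $P(\text{all present}) \approx 0.99994$ — both definitions exceed the
  0.999 the design aimed for.

```{r coverage}
expected_coverage(8000, 150000)
prob_complete_coverage(8000, 150000)
required_sample_size(8000, 0.999, mode = "complete")
```

An optional Monte-Carlo mode (`simulated_complete_coverage()`) quantifies how
Dirichlet-uneven abundances erode the equal-abundance guarantee; the
equal-abundance assumption is what the commonly used coverage calculators
assume, so it is the declared default.

## Logos, consensus strings, composition

Position frequency matrices are plain per-position residue frequencies
(frequency-scaled logos, not information bits — matching how such screens are
usually visualised, and making columns sum to exactly 1). The consensus
string emits, per position, the smallest residue set reaching a cumulative
frequency threshold (default 0.9), ordered by descending frequency with
alphabetical tie-breaks, rendering positions that need more than `max_set`
residues as `x`. Composition reports count the classification flags over a
subset; the flags are not mutually exclusive (canonical ⊆ consensus-X), and a
`none` row counts variants matching no flag.

## The deduplication ladder

Colony-screen inputs are 9-nt variable regions. Untranslatable picks (stop
codon, bad base, wrong length) leave the ladder first and are reported as
rejects, so the ladder identities hold exactly over what remains:
`n_remaining = n_input − n_parent_identical`,
`n_unique_dna = n_remaining − n_duplicate_dna`, and
`n_distinct_protein ≤ n_unique_dna`. "Duplicate" means exact DNA identity
(double-picked colonies); synonymous-codon collapse to proteins is a separate
subsequent step, reported with per-protein codon multiplicities. Hit lists
are cross-referenced against an E-Score table with bins above 2 (enriched),
0.5–2, and below 0.5 (de-enriched), plus explicit `undefined` and
`not_in_universe` bins so counts always sum to the list size.

## Numerical and degenerate-input choices

- Frequencies sum to 1 within 1e−9 by construction; tests assert 1e−12
  agreement against brute-force recounts.
- Anchor matching allows substitutions only (no indels), for determinism and
  speed; one mismatch per anchor is tolerated by default.
- Reads are not reverse-complement searched (the simulator emits forward
  reads); real data can be pre-oriented upstream.
- No quality filter is applied by default; an optional mean-Phred threshold
  exists for real data.
- Empty subsets, all-zero count tables, zero-length hit lists, and
  populations collapsing to zero mass all raise informative errors rather
  than propagating NaN.

## What the synthetic data do and do not show

The generator reproduces replicate structure, uneven naive abundances,
fitness-driven competitive growth, finite read depth, sequencing error, and
the colony-picking artefacts. It does **not** model PCR jackpots, quality-
score structure, chimeric reads, position-dependent error, transformation
bias between bacterial and yeast pools, or any real biochemistry of the
enzyme — the fitness tiers are a calibration, not a prediction. Passing
recovery tests therefore demonstrates that the *analysis* is correct and
well-calibrated (neutral data score neutral; planted structure is recovered),
not that the biological conclusions of any particular screen are right.

## Problem sizes used in the test suite

The suite runs the full 8,000-variant library wherever the property concerns
the whole space (classification, frequencies, E-Score recovery, subset
composition) with 10 replicates and the default depths, which takes a few
seconds per simulated condition at the count level. FASTQ-level round trips
use reduced libraries (10–50 variants, ≤ 300 reads per replicate), and the
pipeline-determinism check uses 3 replicates at reduced depth; these sizes
exercise every code path while keeping the whole suite under a minute.
Exhaustive coverage enumeration is feasible for $L \le 4$, $n \le 8$ and is
tested to 1e−12 there.
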