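---
title: "Sanger sequencing versus HTS metabarcoding for dominant-symbiont detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sanger sequencing versus HTS metabarcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Lichen thalli frequently host more than one green-algal photobiont
(*Trebouxia*) strain, which amplicon metabarcoding resolves as several ITS
OTUs with very unequal read abundances. Direct Sanger sequencing of the same
mixed DNA extract yields a single electropherogram. Two questions follow:
does the Sanger sequence identify the *most abundant* OTU, and at what
secondary-strain abundance does Sanger sequencing stop producing a readable
sequence at all? `sangermeta` implements both the data-generating model
needed to study this mechanistically and the analysis pipeline applied to
such data.

## The chromatogram mixing model

Sanger chemistry reads all templates simultaneously, so the four-channel
trace at position $i$ superimposes the templates' signals. For templates $t$
with relative abundances $f_t$ (summing to 1) and base $b$:

$$h_b(i) = \Big(\sum_t f_t\, [\,x_t(i) = b\,]\Big)\,(1 + \varepsilon_{ib}),
\qquad \varepsilon_{ib} \sim N(0, \sigma^2),$$

clipped at zero. Templates are pre-aligned by construction (substitution-only
divergence), so position $i$ is well defined across templates; positions
where all templates agree carry a single peak of height $\approx 1$, and a
two-template mixture with secondary fraction $f$ shows secondary/primary
peak ratios of $f/(1-f)$ at the sites where the templates differ.

The noise is *multiplicative* Gaussian with default $\sigma = 0.05$; no
published noise model exists for this instrument chain, and a small relative
intensity jitter is the choice that reproduces occasional borderline calls
without altering noise-free behaviour. Two consequences are worth stating
because tests rely on them: (i) noise cannot create a peak where the clean
height is zero, so single-template chromatograms never produce false
ambiguities under this model, and (ii) with $\sigma = 0.05$ a ratio of
$3/7 \approx 0.43$ (secondary strain at 30%) cannot fluctuate below the 25%
calling threshold, so category-5 samples fail deterministically in practice.

Base calling applies the secondary-peak rule with threshold $r = 0.25$: if
$h_{(2)}/h_{(1)} > r$ the position is ambiguous and is written as the IUPAC
code covering *every* base whose peak exceeds $r\,h_{(1)}$ (two-, three- or
four-fold codes, since a thallus can rarely carry three abundant strains).
The rule's boundary is strict — a ratio of exactly 0.25 is a clean call.

Quality control is zero-tolerance by default: any ambiguous call fails the
sequence (`"ambiguous_calls"`), as does truncation below 90% of the expected
marker length (`"truncated"`). In the simulated world every inter-OTU
variable site is diagnostic for OTU membership, so any ambiguity is an
assignment-relevant ambiguity; `qc_mode = "variable_sites_only"` exists for
sensitivity analysis on real data, where ambiguities can fall on
non-diagnostic sites. How many ambiguities a human curator would tolerate is
genuinely unknown; zero is the reproducible reading of "exclude sequences
with unresolved ambiguous calls", and it is a parameter, not a constant.

## The synthetic world

`sim_config()` states the emulated study design once; the generator does not
re-tune any of it.

| parameter | default | why |
|---|---|---|
| `n_samples` | 240 | 2 lichen species × 6 sites × 20 individuals |
| `n_otus` | 6 | the six *Trebouxia* OTUs of the metabarcoding study |
| `n_variable_sites` | 3 | "a handful" of diagnostic sites per subregion per OTU pair |
| `seq_length` | 600 nt | typical full ITS1–5.8S–ITS2 amplicon length (~450–700 nt) |
| `hts_depth` | 10,000 | typical per-sample MiSeq amplicon depth after filtering |
| `category_design` | (61, 163/3, 163/3, 163/3, 16)/240 | cat. 1 and cat. 5 anchored at the published category counts (61 of 240 single-photobiont samples; 16 of 240 above 30%); the unpublished middle mass split equally |
| `p_tertiary` | 0.10 | "maximally two, or very rarely three" abundant strains |
| `chromatogram_noise_sd` | 0.05 | see above |
| `hts_error_rate` | 10⁻³ | order of magnitude of Illumina per-base error |
| `rng_seed` | 1 | all stages derive private substreams from it |

Panel generation gives every OTU `m = max(n_variable_sites, …)` *private*
substitution positions inside ITS1 and inside ITS2 relative to one ancestral
sequence, positions disjoint across OTUs. Every pair then differs at $2m$
sites per subregion, full-length identity is exactly $(L-4m)/L$, and the
`max(…)` term guarantees it lands strictly below 99% while the feasibility
check keeps it at or above 95% — mutually comparable under the 95% search
floor, discriminable under the 99% acceptance rule. The 5.8S, the flanks and
the four anchor motifs are untouched by mutation, and the generator resamples
the ancestor until each motif occurs exactly once per reference.

Secondary fractions are drawn uniformly within the category's bin; category
5 uses (30%, 50%) because the secondary strain cannot exceed the dominant
one. A tertiary strain (probability `p_tertiary`, fraction below both the
secondary fraction and the dominance constraint) completes the community.
Dominant ties are excluded by construction, so "most abundant OTU" is always
well defined. The first `n_otus` samples cycle the dominant role through the
panel so every OTU is predominant somewhere (the rare-but-dominant situation
the rescue filter addresses).

HTS counts are a multinomial draw of `hts_depth` reads over the true
fractions. Sequencing error is applied at the count level as a symmetric
cross-assignment probability *derived* from the per-base rate: a read only
changes OTU when errors flip at least half of the $d$ diagnostic sites
separating the two closest panel members, so
$p_\times = \binom{d}{\lceil d/2\rceil}\,e^{\lceil d/2\rceil}$ — about
$10^{-15}$ at the defaults, i.e. effectively zero. This is deliberate: it
keeps single-photobiont samples at exactly 100% dominant reads (category-1
thalli do exist in real, filtered data), while `cross_assignment_prob`
can force large leakage for sensitivity tests.

**What the generator does not emulate** — and what a green test therefore
does not establish: no indel variation between haplotypes (no frame shifts
in mixed traces), no chimeras, no PCR amplification bias (HTS fractions are
treated as unbiased estimates of template fractions), no Phred-style quality
scores, no forward/reverse chromatogram assembly (one full-length trace per
sample per marker), and no taxonomic contaminants. Real-data mode reads
FASTA/TSV inputs, and users should pre-extract ITS regions with ITSx rather
than rely on the anchor motifs, which are a property of the synthetic panel.

## The analysis pipeline

**OTU-table filtering.** The abundance floor removes, per sample, counts
strictly below `floor ×` that sample's total (the per-sample reading of
"0.005% of the total read count in each sample"; a per-dataset alternative
would be a different filter, and the per-sample reading is what the wording
supports — the choice is a config value, not a constant). The prevalence
filter drops OTUs present in fewer than $\lceil 0.05\,n\rceil$ samples
("present" = nonzero after the abundance filter; with $n = 240$ the cutoff
is 12, matching the published filter). Both filters are idempotent and
applied in this order. The predominant rescue restores removed OTUs that are
the strictly most abundant taxon of at least one sample, judged on
post-abundance-filter, pre-prevalence-filter counts; ties confer nothing.
Rescue is off by default (mirroring the original metabarcoding filtering,
which is what created the rare-but-dominant OTU problem) and on when the
recommendation to retain predominant taxa is wanted.

**Assignment.** `pairwise_identity()` is a Needleman–Wunsch/Gotoh global
alignment replacing a local BLAST: query and references are the same
near-full-length marker region, where the two coincide. Scoring is match +1,
mismatch −1, and affine gaps with open −2 and extend −1 under the convention
that a gap of length $g$ costs $2 + (g-1)$ — the stated penalties leave the
convention open, so it is fixed and documented here, and the test suite's
brute-force enumeration oracle scores alignments the same way. Identity is
matched columns over all aligned columns including gap columns (the BLAST
convention; matches over the shorter length is a common alternative and
would differ on gapped alignments). Traceback ties break deterministically
diagonal → up → left. A query IUPAC code matches any reference base in its
set. Assignment requires best identity ≥ 99%, a strictly unique best hit,
and a best-minus-second margin (default 0.5 percentage points ≈ one
diagnostic mismatch on a ~200-nt ITS2) — the margin operationalises
"second-best hit not significantly lower", for which no number was
published. Both the 99% criterion and the clear-best criterion must hold;
the published exclusion of a 98.27% best hit conflates the two, and
requiring both is the conservative reading.

**Categories and concordance.** Bins on the secondary OTU's read fraction
are upper-inclusive — {0} → 1, (0,10] → 2, (10,20] → 3, (20,30] → 4,
(30,100] → 5 — because legend-style "10–20%" ranges overlap at the
boundaries; the convention is fixed once here. Categorisation uses the
*filtered* (and, when rescue is on, rescued) relative abundances, so a
rare-but-dominant OTU restored by rescue is the sample's dominant OTU for
concordance purposes. `concordance_table()` counts a sample as a success
when it passes QC *and* is assigned; the concordant fraction is computed
among assigned sequences. Greedy clustering (`greedy_cluster()`) replaces
vsearch's abundance-sorted `cluster_size`: decreasing abundance, ties by
input order, first centroid at ≥ 99% wins.

## Degenerate inputs and numerical edges

All-zero chromatogram positions are malformed input (error), all-zero OTU
table rows are flagged and excluded with a warning (never silently dropped),
dominant-OTU ties make the category undefined (error per sample, flagged and
excluded upstream), anchor motifs found zero or multiple times flag the
region as failed, and an empty ITS1/ITS2 overlap makes the resolution
comparison `NA` ("undefined"), not 0. Fraction sums are checked to 1e-9;
identity ties use a 1e-9 comparison; dominance ties 1e-12. Config
serialisation uses JSON (no YAML parser is assumed on the host), and every
stage derives its own RNG substream from the single seed so stages can be
re-run in isolation bit-identically.

## What the tests establish

The acceptance suite checks: the success-rate, prevalence-cutoff and
category-1 arithmetic against published counts (76.25%, 82.5%, 12, 88.52%);
that 500 simulated category-5 samples fail QC without exception and 500
single-template samples pass without exception at the default noise; that
over 1,200 simulated samples spanning all five categories, *every*
QC-passing assigned sequence names the dominant HTS OTU (zero exceptions)
and per-category success is monotonically non-increasing; that ITS1- and
ITS2-based assignments agree three-way with the dominant OTU; and the oracle
suites (alignment DP vs exhaustive enumeration on short pairs — lengths ≤ 5
exercise every traceback state, with score spot-checks at length 8, since
full enumeration at 8×8 is ~2.7·10⁵ alignments per pair in interpreted R —
filter idempotence, the rescue subset sandwich, and bit-identical pipeline
re-runs under a fixed seed). These are statements about the stated synthetic
world; they demonstrate the *mechanism* (peak-ratio arithmetic plus a 25%
threshold) and the internal consistency of the pipeline, not the behaviour
of any particular sequencer.

## Known limitations

Secondary-peak detection in commercial software involves windowing and
normalisation heuristics that are proprietary; only the published 25% ratio
rule is implemented. The simulation treats HTS read fractions as unbiased
template-fraction estimates; PCR bias in real data is unknowable from the
sources used here. Indel-divergent photobiont mixtures — which in reality
produce frame-shifted, unreadable traces downstream of the indel — are out
of scope, as are chimera formation and paired-end trace assembly.
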