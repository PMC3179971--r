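---
title: "Haplotype-sharing linkage analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-sharing linkage analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplolink)
```

## The problem and the model

Two-point linkage analysis with individual SNPs is weak because a biallelic
marker is often homozygous in the informative parent, so many meioses carry
no signal. `haplolink` instead uses *haplotype fragments* as markers: a run
of many SNPs is practically always heterozygous in a founder, so every
meiosis across it is informative, and a single co-segregating fragment can
concentrate the whole family's linkage information.

The procedure has four stages.

1. **Trio phasing.** The family is decomposed into nuclear trios
   (father, mother, one child); a child with only one genotyped parent
   forms a duo. At each SNP the transmitted and untransmitted parental
   alleles are deduced by Mendelian rules whenever the assignment is
   unique. The only ambiguous complete-data configuration — all three
   members heterozygous — is recorded as *uninformative*; an impossible
   configuration is a *Mendelian error*, and any SNP showing one in any
   nuclear unit is removed genome-wide so that all trios stay on a single
   marker grid. In a duo, a site is phased only where the present parent's
   transmission is forced (parent homozygous, or child homozygous).

2. **Affected-haploid (aHap) selection.** Under a dominant model, each
   trio with an affected parent contributes: an affected child fixes that
   parent's *transmitted* haploid as a disease co-segregating haploid
   (aHap); an unaffected child, under complete penetrance, fixes the
   *untransmitted* haploid. When the child's status is unknown — or the
   child is unaffected but penetrance is incomplete — both haploids enter
   as a *paired* set of which at least one is the disease haploid. Under a
   recessive model both haploids received by every affected child are
   aHaps. Both parents contribute independently when both are affected;
   parents of unknown status contribute nothing, because every selection
   rule starts from an affected parent.

3. **Sharing scan.** The disease mutation lies on the one founder haplotype
   that all assured aHaps must share, so the candidate region is where the
   aHaps are mutually identical ("homozygous" across the aHap set). A
   window slides along each chromosome in physical coordinates; a window is
   homozygous when it has enough evaluable SNPs and the fraction of
   inconsistent ones is *strictly below* the tolerance. Homozygous windows
   merge into segments, which paired aHaps may then trim or split: a SNP
   supports the segment only if, for every pair, at least one member
   matches the assured consensus.

4. **LOD scoring.** Each surviving segment behaves as a single fully
   informative marker. With $k$ informative meioses, $r$ of them
   recombinant, the two-point LOD is
   $$\mathrm{LOD}(\theta) \;=\; \log_{10}
   \frac{\theta^{\,r}\,(1-\theta)^{\,k-r}}{0.5^{\,k}},$$
   maximized at $\hat\theta = r/k$ (clipped to $[0, 0.5]$), with the
   convention $0^0 = 1$. A fully co-segregating haplotype over ten
   informative meioses therefore attains $10\log_{10}2 = 3.0103$, the
   classical genome-wide significance anchor. Every assured aHap with at
   least one resolved allele inside the segment counts one meiosis with no
   recombinant (inside a homozygous segment its segregation matches the
   affection-predicted pattern by construction); a *resolved* pair (exactly
   one member matching the consensus) adds one more. An unaffected
   resolved carrier under incomplete penetrance is explained by penetrance,
   not recombination, and is deliberately not counted in $r$ — counting it
   would produce a spurious $-\infty$ at $\theta = 0$.

```{r lod}
lod(10, 0, 0)      # the 3.010 genome-wide ceiling for k = 10
max_lod(10, 1)     # one recombinant: theta-hat = 0.1
```

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `window_kb` | 500 | kb | sliding-window length; sets boundary resolution and the maximum bound inflation |
| `step_kb` | 50 | kb | window step; must not exceed the window so consecutive windows overlap |
| `tolerance` | 0.05 | fraction | strict upper bound on inconsistent SNPs per window; absorbs genotyping error |
| `min_snps` | 20 | count | evaluable SNPs a window needs to carry evidence; sparser windows are uninformative |
| `loh min_kb` | 500 | kb | LOH runs must exceed this span strictly |
| `loh min_snps` | 25 | count | minimum SNPs in an LOH run |

The 5% tolerance is deliberately conservative: it is far above realistic
array error rates, so genotyping noise cannot introduce false breakpoints,
at the price of candidate regions slightly larger than the true shared
interval. The comparison is strict (a window with exactly 5% inconsistent
SNPs is rejected), and a window with zero inconsistent SNPs is accepted at
any tolerance, including 0. The scan assumes a marker density of roughly
one SNP per 20 kb or better; below that, 500-kb windows fall under
`min_snps` and stop carrying evidence.

## Numerical and design choices

* **Windows are bp-based, not SNP-count-based**, because all reported
  coordinates are physical; the `min_snps` floor guards sparse regions.
* **Segment bounds snap to the outermost consistent SNPs.** The merged
  window span is extended outward — at most one window length past each
  edge — until the first inconsistent evaluable SNP. This caps bound
  inflation at one window length on dense data and makes the
  tolerance-0 scan coincide with the exhaustive maximal-consistent-run
  enumeration.
* **Uninformative windows break window merging** (absence of evidence must
  not bridge two distinct blocks), but two snapped segments that end up
  overlapping or abutting — with no inconsistent SNP between them — are
  re-joined: they are one area of homozygosity split only by a locally
  sparse window.
* **Mendelian-error removal is genome-wide** (the whole SNP column), the
  conservative reading that keeps every trio on one marker grid; the
  removed ids are logged.
* **The LOH deletion test reads the raw genotypes**, not the cleaned
  matrix: a hemizygous deletion manufactures Mendelian errors, so its SNPs
  would otherwise have been removed before the test could see them. The
  test itself is a run rule — a span in which every affected individual is
  homozygous or missing, longer than 500 kb and at least 25 SNPs — because
  a deletion destroys heterozygous calls; intensity-based CNV evidence is
  out of scope.
* **Ties in the region table sort by chromosome then start**, making
  reports deterministic; maximum-LOD regions are flagged.
* **Degenerate inputs**: no affected parent with a usable child raises
  `E_NO_AHAP`; an affected child of two unaffected parents under
  dominant/complete is a model violation and an instructive error (use
  incomplete penetrance); a single assured aHap is trivially homozygous
  everywhere and yields a warning and no regions unless explicitly allowed;
  a family whose aHaps share nothing anywhere triggers a
  locus-heterogeneity warning, since two disease founders produce two
  disease haplotypes and no genome-wide consensus.

## What the simulator emulates — and what it does not

The gene-dropping simulator generates founder haplotypes with independent
per-SNP allele frequencies drawn from a configurable minor-allele-frequency
range (default 0.1–0.5), drops them through the pedigree with Haldane
recombination (Poisson crossover counts, uniform positions, no
interference) or an exact fixed-crossover list, forces the declared
carrier pattern by choosing each gamete's starting phase (never by bending
the crossover process), and records complete truth: chromatid mosaics,
crossovers, carrier status, and the realized shared disease-haplotype
interval per locus. Truth intervals are kept half-open in continuous
coordinates, so a crossover placed exactly mid-interval halves the
realized length exactly.

```{r fixture}
fix <- build_validation_fixture(snps_per_chromosome = 2000, seed = 11)
fix$truth$realized[, c("chrom", "designed_start", "designed_end",
                       "realized_length_mb")]
```

The bundled validation design is a three-generation, fully penetrant
autosomal-dominant pedigree with exactly ten assured meioses on six
synthetic 24-Mb chromosomes whose disease intervals are initialized at 1,
3, 4, 5, 8 and 10 Mb; mid-interval crossovers on the last two leave
realized shared lengths of 1, 3, 4, 5, 4 and 5 Mb. Running the full
pipeline on it recovers six regions at LOD 3.010 — and nothing else:

```{r pipeline}
res <- run_linkage(fix$pedigree, fix$genotypes, fix$map)
res$regions[, c("chrom", "start_bp", "end_bp", "k_meioses", "lod", "is_max")]
```

The simulator does *not* model linkage disequilibrium between founder
SNPs, sex-specific genetic maps, crossover interference, or chip-specific
clustering artifacts. Passing tests on simulated data therefore
demonstrate the correctness of phasing, selection, scanning and scoring
under realistic density, error and recombination regimes — not robustness
to background LD structure, which in real data mostly makes founder
haplotypes *more* distinguishable, nor to systematically clustered
genotyping failures.

A note on truth comparisons: realized truth bounds are continuous crossover
positions that fall between markers, while reported regions are bounded by
SNPs. Containment of the truth interval is therefore asserted at marker
resolution (every evaluable SNP inside the truth interval lies in the
reported region), with each reported bound within one window length of the
truth bound.

## Problem sizes used by the test-suite

The suite works at 2,000 SNPs per 24-Mb chromosome over six chromosomes —
about one SNP per 12 kb, a faithful scaled stand-in for a 370K genome-wide
array at roughly one-third density — and validates the scan against an
exhaustive per-SNP oracle on 50 random chromosomes of 1,000–2,000 SNPs.
The false-positive study uses thirty structurally varied pedigrees (sibship
sizes 3–5, two gen-III branches, 5–9 assured meioses each) with one causal
mutation each on a rotating chromosome; the published thirty-pedigree
cohort's exact structures are not public, so the generator documents its
own.

## Known limitations

* Single disease founder only: locus heterogeneity (two founders) breaks
  the consensus and is detected, not resolved.
* Autosomal models only; X-linked, mitochondrial and imprinting models are
  out of scope.
* The LOD treats the shared segment as one fully informative marker; it is
  not a multipoint Lander-Green/Elston-Stewart likelihood and does not
  model liability classes.
* Paired aHaps enter the LOD only when resolved, and their accounting can
  be disabled (`include_pairs = FALSE`) for a strictly assured-only score.
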