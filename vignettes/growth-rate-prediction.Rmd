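---
title: "Predicting prokaryotic maximal growth rates from codon usage bias"
author: "codongrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting prokaryotic maximal growth rates from codon usage bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codongrowth)
library(dplyr)
```

## The model

Fast-growing bacteria and archaea carry a genomic imprint of their growth
potential: selection for rapid, accurate translation concentrates the
synonymous-codon usage of highly expressed genes (HEG) — above all the
ribosomal proteins — onto a small set of translationally optimal codons,
while the rest of the genome stays close to the mutational background. The
strength of that differential bias can therefore be read off a genome, or
even a handful of genes, and converted into an estimate of the species'
minimal generation time `d` (the shortest doubling time it achieves under
optimal conditions, in hours). `codongrowth` implements that pipeline:

1. **ENC′** — the effective number of codons corrected for background
   nucleotide composition. For each synonymous family the codon frequencies
   expected from the background A/C/G/T composition are compared with the
   observed counts by a chi-square statistic; the resulting corrected
   homozygosity per family, `F̂ = (X² + n − k) / (k(n − 1))`, is averaged
   within degeneracy classes and combined by Wright's formula,

   `ENC′ = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`.

   ENC′ runs from 20 (one codon per amino acid, maximal bias) to 61 (usage
   indistinguishable from the background expectation). The background
   correction matters because compositional bias (G+C pressure) restricts
   codon usage without implying selection.

2. **ΔENC′** — the relative reduction of ENC′ in highly expressed genes:
   `ΔENC′ = (ENC′_all − ENC′_heg) / ENC′_all`. Larger values mean stronger
   translation-associated selection.

3. **S** — a selection-strength index over the four two-codon amino acids
   whose optimal codon is the same in essentially all species (Phe
   TTC/TTT, Ile ATC/ATT, Tyr TAC/TAT, Asn AAC/AAT; the C-ending codon
   pairs with its tRNA by Watson–Crick rules and is translationally
   favoured). With `P = C1/(C1+C2)` the frequency of the optimal codon,
   each amino acid contributes the log odds ratio
   `S_i = ln[(P_heg/(1−P_heg)) / (P_all/(1−P_all))]`, and `S` is their mean
   weighted by the number of C1+C2 codons observed in the HEG set.

4. **F** — the first principal component of z-scored (ΔENC′, S), oriented
   so larger F means stronger selection. The two indices measure the same
   selective pressure through different statistics, so their first
   component carries more predictive power than either alone.

5. **The predictor** — ordinary least squares of the Box-Cox-transformed
   doubling time on F. With the published coefficients, in the log limit
   of the transform:

   `Φ(d) = 0.8741 − 0.6496 F`, i.e. `d = exp(0.8741 − 0.6496 F)` hours.

   `F = 0` (a genome of average bias) corresponds to `d ≈ 2.40` h, and
   every unit of F divides the predicted doubling time by `e^0.6496 ≈
   1.91`. An optional linear optimal-growth-temperature (OGT) term can be
   refit, because the residuals of the temperature-free model are
   systematically positive for psychrophiles and negative for
   thermophiles; the temperature-free model should be trusted only for
   mesophiles (OGT between 15 and 60 °C).

For community data (metagenomes), concatenating sequences from organisms
with different preferred codons would make the pooled set look less biased
than its members, inflating ENC′. The gene-averaged variants therefore
compute ENC′ and P gene by gene — each gene against its own nucleotide
composition — and average within the HEG and all-gene sets before applying
the same ΔENC′ and S formulas to the set means. Because genes enter
unweighted, species contribute in proportion to their sequence abundance.

## A worked run

```{r worked}
genome <- synth_genome(n_genes = 120, n_heg = 20, s_strength = 1, seed = 1)
bias_indices(genome) |> select(enc_all, enc_heg, delta_enc, s)

composite <- fit_composite(synth_training_table(n_species = 200, seed = 7))
model <- published_growth_model(composite = composite)
predict(model, bias_indices(genome)[, c("delta_enc", "s")]) |>
  select(delta_enc, s, f, d_hours, class)
```

```{r bootstrap}
boot <- bootstrap_community(genome, model, B = 200, seed = 1,
                            name = "demo genome")
glance(boot)
```

## Parameters that matter

* **Minimum ORF length, 450 nt.** ORFs shorter than ~150 codons carry too
  few synonymous families for a stable per-gene ENC′; 450 nt is the
  default throughout the metagenome workflow ([extract_orfs()]).
* **Genetic code, table 11.** The bacterial/archaeal code; configurable
  everywhere a code is consumed.
* **ORF definition.** Stop-bounded maximal regions trimmed to the first
  ATG/GTG/TTG start codon, because downstream codon counting assumes
  in-frame coding sequence; `mode = "stop-to-stop"` keeps untrimmed
  regions for users who prefer the permissive convention. Regions
  truncated by a contig end (no terminal stop codon) are discarded.
* **HEG detection.** Ribosomal proteins by id list, annotation keyword, or
  protein-level local alignment (BLOSUM62) against a reference set with a
  best-score-per-gene rule; the default score threshold of 100 sits well
  above chance-level scores for typical gene lengths while genuine
  ribosomal-protein homologues score several-fold higher.
* **Bootstrap replicates, B = 1000.** Background genes and HEG are
  resampled with replacement, independently, each to its original
  cardinality, inside every joint replicate; the replicate spread then
  reflects the sampling uncertainty of both sets. Comparisons between
  communities pair replicates by iteration index and report the fraction
  of iterations contradicting the sign of the observed mean difference
  (`<1/B` when none does).
* **Growth classes.** very fast `d < 1` h, fast `1 ≤ d < 2`, intermediate
  `2 ≤ d < 5`, slow `d ≥ 5`; interval boundaries are right-open except the
  slow class, which includes 5 h.

## Numerical conventions and edge cases

Several choices are needed where the mathematics runs out of data:

* **Degeneracy classes.** Wright's original composition is used: nine
  twofold families, Ile as the single threefold, five fourfold, and the
  three sixfold families (Leu, Ser, Arg) kept whole, with Met/Trp
  contributing the constant 2. This keeps the index on its familiar
  20–61 scale with the floor exactly attained at one-codon-per-family
  usage. A missing threefold or sixfold class mean is estimated as the
  average of the twofold and fourfold means; if two or more classes are
  missing the per-gene index is undefined and the gene is dropped from
  set means.
* **Capping.** Sampling noise can push the estimator above 61; values are
  capped to [20, 61]. Families with fewer than two observed codons, or a
  non-positive homozygosity estimate, are excluded.
* **Ambiguous bases.** Codons containing N are skipped individually; the
  rest of the gene is kept (metagenome contigs contain Ns).
* **Pseudocounts for P.** When exactly one of C1/C2 is zero, 0.5 is added
  to both, keeping the log odds finite; when both are zero the amino acid
  is flagged absent and dropped from the relevant mean. This matters only
  for per-gene counts — genome-scale concatenated counts essentially never
  need it.
* **The "all-gene" set.** ΔENC′ and S contrast the HEG set against the
  non-HEG rows of the input. In metagenome practice the ORF set *is* the
  all-gene set; when reproducing whole-genome concatenated indices in
  which ribosomal proteins are part of the all-gene concatenation, set
  `include_heg_in_all = TRUE`. With HEG a few percent of genes the
  difference is negligible.
* **PCA.** On the correlation (z-scored) matrix, never covariance — ΔENC′
  and S live on different scales. The component is sign-flipped if needed
  so the ΔENC′ loading is positive.
* **Box-Cox λ.** The published-coefficient model uses the λ → 0 log limit,
  corroborated by reproducing the ~3 h worked predictions at F ≈ −0.2;
  refitting estimates λ by profile likelihood on a grid (−2, 2, step
  0.01) and snaps |λ| < 0.02 to the exact log limit.
* **Published-mode F.** The published fit does not include the loadings
  and standardisation constants of the original composite, so
  published-mode predictions either take F directly or map raw (ΔENC′, S)
  through a composite the user fits on their own training table (the
  command-line tool calibrates one on a synthetic training table and says
  so in its log).

## What the synthetic generator emulates — and what it does not

[synth_genome()] draws background genes codon-by-codon from a G+C-driven
mutational background and reweights the optimal codon of each family by
`exp(s_strength)` in the designated HEG subset, renormalising within
families so that amino-acid content is identical in distribution between
the two sets. Selection therefore acts on synonymous choice only, and the
injected log odds `s_strength` is recovered by the S index in expectation —
a sharp internal calibration. [synth_training_table()] inverts sampled F
values to index pairs through fixed equal loadings and generates doubling
times from known regression coefficients plus Gaussian noise on the
transformed scale, enabling exact and noisy parameter-recovery tests.

Real genomes differ in ways the generator deliberately ignores: amino-acid
composition varies between HEG and other genes, codon usage is
autocorrelated along genes and between neighbours in operons, expression
level varies continuously rather than as a two-class label, G+C varies
within a genome, and the true relation between selection strength and
growth rate is noisy and temperature-dependent. Passing tests on synthetic
data therefore demonstrate that the indices measure what they are defined
to measure and that the pipeline is self-consistent — not that the
published regression generalises to any particular new clade.

## Problem sizes used by the test-suite

The packaged tests run on deliberately small instances chosen to keep the
whole suite under a minute while leaving every quantitative check with
comfortable statistical margin: genomes of 40–240 genes (12–20% HEG) at
600–900 nt mean gene length, bootstraps of 200–500 replicates, 40–100
subsampling iterations per size, and 200-row training tables for
parameter recovery. The corresponding analyses in production use would
run on full genomes (thousands of genes) and B = 1000 bootstraps; all
sizes are arguments.

## Known limitations

* The temperature-free predictor is calibrated for mesophiles; predictions
  for psychrophiles and thermophiles are biased in opposite directions,
  and the OGT term only linearly corrects this.
* Genomes undergoing rapid reduction (high pseudogene load) retain
  ancestral codon bias long after their growth rate has collapsed; the
  method over-predicts their speed.
* Whole-metagenome averages weight species by sequence abundance, which is
  a feature for community-level questions but confounds comparisons when
  assembly or extraction bias differs between samples.
* ORF calling is a naive six-frame scan with no coding-potential model;
  on real contigs it returns spurious short ORFs that the 450 nt filter
  only partially removes.
* The packaged ribosomal-protein reference and ubi-tRNA anticodon list are
  synthetic stand-ins for demonstration and testing; real analyses should
  supply curated references.
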