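---
title: "Models and methods behind pqtlpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pqtlpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pqtlpipe` implements the computational chain of a genome-wide protein
quantitative trait locus (pQTL) study in a human tissue cohort: absolute
protein quantification from data-independent-acquisition (DIA) mass
spectrometry, genotype quality control, an additive-model association scan,
hotspot discovery over correlated proteins, regulatory-region mapping with
enrichment testing, and variant–trait/colocalization integration. This
vignette explains each model, its assumptions, the tunable parameters, and
the design choices made where the underlying procedure was genuinely open.

## Absolute quantification: the total protein approach (TPA)

The TPA assumes that a protein's share of the summed MS2 fragment-ion signal
equals its share of the total injected protein mass. For protein $i$ in one
sample,

$$
\mathrm{Protein}(i) \;=\;
\frac{\mathrm{MS2\,signal}(i)}
     {\mathrm{Total\,MS2\,signal} \times M_i} \times 10^{9}
\quad \text{[pmol per mg total protein]},
$$

with $M_i$ the molecular mass in g/mol. `MS2 signal(i)` sums the peak areas
of peptides assigned to protein $i$; the $10^9$ converts mg/g to pmol.
Because the equation is a ratio, concentrations are invariant under any
per-sample rescaling of the instrument response — the package tests this
invariance explicitly.

Peptides shared between proteins are redistributed in proportion to the
carriers' unique-peptide totals:

$$
\mathrm{MS2\,signal}(i) = U_i + \sum_{\text{shared peptides } s \ni i}
\frac{U_i}{\sum_{j \in s} U_j}\, A_s ,
$$

where $U_i$ is the unique total of protein $i$ and $A_s$ the area of shared
peptide $s$. Three deliberate choices:

* **Peptide-wise splitting.** Each shared peptide is divided among exactly
  its own carriers, not among a whole connected component of the
  peptide–protein graph. This keeps redistribution exact and auditable.
* **Denominator.** `Total MS2 signal` defaults to *all* detected peptides in
  the sample (including peptides of proteins that end up unquantifiable),
  with a `total_signal = "quantified"` switch.
* **Per-sample unique totals.** Redistribution weights are computed per
  sample, not from study-wide totals; a missing peptide contributes nothing
  (it is *not detected*, not zero).

A shared peptide whose carriers all lack unique signal is unassignable; its
area is excluded and logged per sample. Proteins with no detected peptide in
a sample are missing (`NA`), never zero.

## Genotype quality control

Variant-level QC drops variants with call rate < 0.99, minor allele
frequency < 0.01, or exact Hardy–Weinberg p < $10^{-4}$ (all comparisons
strict, so a variant at exactly the threshold is kept). The HWE test is the
classical exact conditional test: given the allele counts, the p-value sums
the probabilities of all heterozygote counts whose conditional probability
does not exceed that of the observed table. No mid-p correction is applied;
a chi-square variant sits behind `method = "chisq"`. The implementation is
validated against a full enumeration oracle for every genotype table with
up to 30 samples.

LD pruning slides a window of 50 variants by steps of 5 per chromosome;
while any retained pair in the window has $r^2 > 0.8$ (squared Pearson
correlation of dosages on pairwise-complete samples), one member is removed.
The external tools usually used for this step do not document their
tie-break, so ours is explicit: remove the lower-MAF member; on ties, the
later position. Violating pairs are visited in left-to-right index order,
making the procedure deterministic and reproducible.

Genotype PCA operates on the column-standardised dosage matrix (monomorphic
variants skipped, missing dosages mean-imputed for the decomposition only).
The top three PCs become scan covariates. The outlier rule — no criterion is
standard — is |score| > 6 SD on any of the top PCs, configurable.

## The additive association scan

For each (variant, protein) pair the model is ordinary least squares:

$$ y_p = \alpha + \beta\, g_v + \gamma^\top c + \varepsilon, $$

with $y_p$ the protein concentration (untransformed by default; `--log10`
flag available, since the source procedure does not state a transformation),
$g_v$ the additive dosage, and $c$ the covariates: gender, ethnicity
(dummy-coded with the largest group as reference) and three genotype PCs.
Two-sided p-values come from the t distribution with $n - p$ degrees of
freedom after listwise deletion. Complete dosage matrices are scanned with a
vectorised Frisch–Waugh solver (residualise $y$ and all dosage columns on
the covariate design once per protein, then the slope is a ratio of cross
products); it is tested to agree with `lm()` to $10^{-10}$. Constant-dosage
columns are skipped and logged, never raised as errors.

Multiple testing uses a single genome-wide threshold $\alpha/\#\text{SNPs}$
across all SNPs, not per protein — with the study-scale SNP count of
1,671,387 this reproduces the printed threshold $2.99 \times 10^{-8}$.
Proteins enter the scan only if quantified in strictly more than 90% of
samples. A significant variant is **local** when it lies on the chromosome
of the regulated gene within 1 Mb of the gene *body* (inclusive at exactly
1 Mb; distance 0 inside the gene), **distant** otherwise; measuring to the
gene body rather than the TSS is a documented choice, as is the inclusive
boundary.

## Hotspots of pQTLs over correlated proteins

Protein co-expression uses Spearman correlation with average ranks on
pairwise-complete samples; p-values use the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$.

Hotspot discovery scans position-sorted significant variants per
chromosome. A **seed** is an adjacent variant pair that (1) lies strictly
less than 1 Mb apart and (2) has some cross-pair combination of *different*
proteins with $|\rho| > 0.5$ — "associated with different proteins" is read
as the existence of such a pair, so two variants regulating the identical
multi-protein cluster (the typical signature of co-regulation) can still
seed, while variants sharing only one single protein cannot. The hotspot then
**extends** to the next variant while it is within 1 Mb (inclusive) of the
nearest member and correlates with a protein of that member. Decisions made
where the rule text is ambiguous:

* extension is bidirectional (`direction = "downstream"` to restrict);
* for variants associated with several proteins, *any* cross-variant pair
  above the threshold qualifies;
* same-protein pairs never qualify for seeding (a protein trivially
  correlates with itself) but do during extension, so two nearby QTLs of
  one protein can chain into an existing hotspot;
* hotspots never span chromosomes, and members are disjoint across hotspots.

Note the construction only constrains *adjacent* members, so the median
correlation among all within-hotspot protein pairs is not guaranteed to
exceed the threshold — the tests assert the adjacency rule itself.

Hotspot annotation keeps terms shared by at least half of the member
proteins (ceiling), with a floor of two carriers so a term private to one
protein never annotates a two-protein hotspot. Shared-hotspot enrichment is
a two-sided Fisher exact test of high correlation ($|\rho| > 0.5$) against
sharing a hotspot over all protein pairs. The same hotspot algorithm is
applied unchanged to external QTL summary tables (eQTL hotspots) after
restricting to variants and proteins observed in this study.

## Regulatory regions, gene features and regulator enrichment

All internal coordinates are 1-based inclusive; BED input (0-based
half-open) is converted on ingest, GTF stays 1-based. Variants map to
regulatory intervals (CTCF binding site, enhancer, open chromatin, promoter,
promoter flanking, TF binding site) by position, end-inclusive. Gene-feature
labels (UTR, CDS, exon, intron — introns derived as gene span minus exon
union at the gene level) are assigned per overlapped gene, so one variant
can be exonic for one gene and intronic for another; intergenic means no
gene overlap. Interval mapping is validated against a quadratic stabbing
oracle.

Regulator enrichment builds, per (gene, feature) and protein, the 2×2 table
{variant is a pQTL for this protein} × {variant in this feature} over the
post-QC tested-SNP universe (the most conservative self-contained
background; configurable). Two-sided Fisher p-values are
Bonferroni-corrected across *all* tests performed; a predicted regulator
needs adjusted p < 0.05 *and* odds ratio > 1, since enrichment rather than
depletion is the claim.

The local/distant region distribution replicates a per-association counting
convention: each (variant, protein) association contributes one count for
the variant's region with respect to that association's own regulated gene
when such a label exists, and one count per distinct label otherwise — so a
variant regulating two proteins from the CDS of one gene and the promoter
region of the other is counted twice, not four times.

## Trait integration and colocalization

Variant–trait catalogs (GWAS Catalog / ClinVar / PharmGKB exports unified
to `rsid, trait, source`) join to significant pQTLs by rsID; triples are
deduplicated. For colocalization, each protein's **lead** variant (smallest
p; ties by position then rsID) is compared with every external eQTL/GWAS
variant: a pair is a candidate when LD $r^2 > 0.8$ (computed from this
study's genotypes; no external panel), and **colocalizes** when the lead's p
is no longer significant after the candidate's dosage is added to the model.
"No longer significant" defaults to the discovery threshold (flag for
nominal 0.05). Covariates are retained in the conditional model, matching
discovery. A candidate column-identical to the lead — including the lead
itself appearing in the external table — is reported collinear with
conditional p = 1, i.e. colocalized: a variant trivially explains its own
signal.

## The synthetic cohort: what it emulates, and what it does not

The generator states a world modelled on the study design: 287 donors, a
desk-scaled panel of thousands of autosomal SNPs (the real study's ~1.7M is
scaled to keep runs in minutes), 1344 quantifiable proteins, gender and
3-level ethnicity covariates, ~2% missing protein values.

* **Genotypes** use a Gaussian-copula haplotype model: within an LD block
  the latent normals are AR(1) with correlation `ld_decay^|i-j|`,
  thresholded at the allele-frequency quantile; two haplotypes per donor
  give Hardy–Weinberg dosages with tunable block LD. Thresholding
  attenuates correlation, so dosage $r^2$ sits well below the latent
  $\rho^2$ (e.g. latent 0.9 gives adjacent $r^2 \approx 0.5$ at
  intermediate MAF); colocalization demonstrations therefore use a tight
  block (`ld_decay = 0.998`, MAF 0.4–0.5) to emulate a causal variant with
  a close tag SNP.
* **Protein levels** are log-normal baselines (median ≈ 7.4 pmol/mg) plus
  additive planted dosage effects, covariate mean shifts and Gaussian noise
  (default SD 1 protein unit), floored at 0.001 pmol/mg — with default
  baselines the floor is essentially never reached, preserving exact
  additivity for noiseless checks. Abundance variability across livers is
  not characterised in the source material; the log-normal marginal is an
  assumption, exposed in the configuration.
* **Missingness** is completely at random in position but with a fixed
  per-protein count capped at the 90%-quantifiability bound: a raw
  Bernoulli rate would occasionally push single proteins below the
  eligibility rule purely by binomial noise, contradicting the stated
  invariant that all generated proteins remain scannable.
* **Peptide tables** are the exact inverse of the TPA equations: per-protein
  target signals are split over 2–4 peptides; a configurable fraction of
  proteins carries one peptide shared with a partner, with unique areas
  shrunk and the shared area set so proportional redistribution recovers
  the targets exactly. A background filler protein (`BGFILL01`, excluded
  from the ground truth and labelled synthetic) absorbs the remaining
  signal so the TPA denominator corresponds to exactly 1 mg of protein —
  making the round trip exact rather than approximate. Ethnicity affects
  protein means only; genotype population structure is deliberately not
  simulated.

A green test on this world therefore establishes correctness of the
*computational chain* — quantification algebra, test statistics, filtering
rules, interval logic, the hotspot and colocalization procedures — not the
biological realism of DIA acquisition, imputation uncertainty, peptide
detectability or population stratification, all of which are out of scope.

## Numerical choices and degenerate inputs

* HWE ties between outcome probabilities are resolved with a relative
  tolerance of $10^{-12}$ so enumeration and log-space computation agree.
* OLS refuses (returns `NULL`, logged) rather than errors on constant
  dosage or too few complete cases; conditional tests report collinear
  candidates (sample $r^2 = 1$) with conditional p = 1.
* The planted-beta recovery rate of the generator is governed by the exact
  OLS standard error ($\sigma/\sqrt{2n\,f(1-f)}$); at $n = 287$, noise 1
  and MAF 0.3 this is 0.091, so ±0.15 recovery holds in ≈90% of
  replicates — the property tests assert the binomial band around this
  analytic rate.
* End-to-end runs are bit-reproducible: all randomness flows from the
  configured seed, and the run manifest records package version, seed and
  every parameter.

## Known limitations

No mixed models or kinship correction; no dominance or interaction terms;
no stepwise conditional discovery of secondary signals; no Bayesian
colocalization posteriors; biallelic autosomal SNPs only; GO-style
annotations enter as plain two-column term maps rather than ontology files.
The empirical permutation FDR facility is a labelled approximation — the
source study's FDR estimates have an unstated method and are not
reproduced.
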