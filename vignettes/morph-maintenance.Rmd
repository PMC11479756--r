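---
title: "Modelling the maintenance of male reproductive morphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the maintenance of male reproductive morphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphsim)
```

## The biological scenario

`morphsim` models a population in which males express two heritable binary
traits: *courting* (displaying to attract females) and *parenting*
(obligate male-only care). Their combinations define four morphs —
courter/parent (CP), courter/non-parent (CN), non-courter/parent (NP) and
non-courter/non-parent (NN). Females always prefer courting males but cannot
tell whether a male will care; males that do not court can only reproduce by
sneak-fertilizing eggs in another male's clutch; clutches die unless the
male tending them provides care. Viability selection penalizes the
expression of courting and of care in male offspring. Negative
frequency-dependence emerges from the interplay of these stages: sneaking
pays only while courters are common, and care pays only while clutches
exist.

The package asks how the *genetic architecture* of the two traits — one
Mendelian locus per trait, many additive quantitative trait loci (QTLs)
scattered genome-wide, or the same QTLs clustered in a non-recombining
supergene — changes which morphs persist.

## The analytical recurrence

The deterministic core iterates the morph-frequency vector
$f = (f_{CP}, f_{CN}, f_{NP}, f_{NN})$ through five stages per generation:

1. **Mate choice.** The number of clutches is
   $n = w_s N_m (f_{CP} + f_{CN}) + (1 - w_s) N_m (f_{NP} + f_{NN})$, with
   $w_s = 1$ under the baseline assumption that every female accepts a
   courting male.
2. **Fertilization.** Chosen males fertilize
   $e_{oM} = f_M N_m r_M w_{sM}$ eggs, where $r_M$ is the morph's
   reproductive allocation. Each non-courting morph independently realizes
   sneak fertilizations $e_{sM} = \min(N_s,\, f_M N_m r_M)$ against the
   population-level sneak capacity $N_s = n\, c\, n_{sneak}\, r_{NN}$
   ($c$ is the sperm-competition coefficient). The printed description of
   the truncation is self-contradictory; the `min` reading is the only one
   consistent with both of its branches, and the literal
   difference-truncated-at-zero rule is available as
   `analytic_params(sneak_rule = "literal")` for sensitivity analysis.
3. **Care.** $o_{oM} = e_{oM} w_{nM}$ with baseline
   $w_n = (1, 0, 1, 0)$; sneak-sired offspring survive in proportion to the
   survival of the clutches they sit in,
   $o_{sM} = e_{sM} \sum o_{oM} / \sum e_{oM}$ (taken as 0 when no
   chosen-male eggs exist — with no surviving clutches there is nowhere for
   a sneak-sired egg to be raised).
4. **Viability.** $j_M = o_M w_{vM}$, with
   $w_v = (v_c v_p,\, v_c,\, v_p,\, 1)$ multiplying per-trait retentions;
   the baseline uses $v_c = v_p = 1$.
5. **Maturation.** $f' = j / \sum_M j_M$. If $\sum_M j_M = 0$ the
   trajectory is truncated and flagged instead of emitting NaNs.

Useful structural consequences, all covered by tests: CN is lost after one
generation under baseline care; $N_m$ cancels (every stage is linear in it);
without sneaking ($c = 0$ or $n_{sneak} = 0$) CP fixes from any interior
start; and with baseline viability the interior equilibrium satisfies
$f_{CP}^* = r/(r + 2 c\, n_{sneak})$ (in units of the courter:non-courter
allocation ratio $r$), which the long-run sweep tests check directly.

### The parameter sweep and its aggregation

`run_sweep()` crosses $c \in \{0, 0.25, 0.5, 0.75, 1\}$, the allocation
ratio $r \in \{0, 0.1, \dots, 2\}$ (applied as $r_{CP} = r \cdot 8$ against
a fixed non-courter allocation of 8 — only the ratio matters) and
$n_{sneak} \in \{1, 2, 3\}$ from an equal start, 10,000 generations. Two
retention classifiers are provided. The default for reporting aggregates is
the Shannon-diversity filter $H \ge 1$, which is the criterion used to
delimit the multi-morph region of parameter space in the study this package
reproduces; a per-morph frequency threshold (> 0.01) is the alternative.
The two disagree materially: the frequency filter admits many combinations
where one non-courting pair of morphs sits just above threshold, which
drags the mean retained proportions apart. Combinations that collapse
reproductively (e.g. $r = 0$ with $c > 0$, where no clutch survives) are
flagged and never counted as retaining polymorphism.

Under the recurrence, the NP and NN morphs are exactly symmetric from an
equal start, so their mean retained proportions are identical; a small
asymmetry between them in the published numbers cannot be produced by these
equations and presumably reflects details of the original code.

## The individual-based simulator

The stochastic model follows diploid individuals with explicit genomes:
`n_chrom` chromosomes of `loci_per_chrom = 1000` multi-state loci, two
allele states (0/1) segregating initially with probability 1/2 each. Each
trait is the sum of the allelic effects carried by the individual's copies
at that trait's QTLs; a male expresses courting (parenting) when his trait
value strictly exceeds a threshold frozen at the generation-0 mean
phenotype. Ties at the threshold express the non-courting/non-parenting
state; with continuous effects the tie set has measure zero.

Per generation: every female samples `mate_search_n` males without
replacement and mates with the first courter she encounters; the chosen
male sires `min(r_chosen, E)` of her `E` eggs and up to `n_sneak`
non-courting males then sire `min(round(c * r_sneaker), remaining)` each,
in draw order; the whole clutch survives only if the chosen male is a
parent; male offspring survive viability selection with probability
$e^{-(I_c-\theta)^2/\omega_v} e^{-(I_p-\theta)^2/\omega_v}$ (trait
indicators $I \in \{0,1\}$, optimum $\theta = 0$); survivors are culled
uniformly to the carrying capacity `K`.

Gametes recombine with a Poisson(0.2) number of crossovers per chromosome
at uniformly drawn breakpoints; in supergene architectures a breakpoint
strictly inside the region renders the zygote inviable (it is discarded,
not redrawn, so supergene heterokaryotypes pay a fecundity cost — and every
surviving offspring carries an intact copy of one parental supergene
haplotype, which the tests assert). Mutation counts per offspring are
Poisson with mean $2 \mu\, n_{SNPs}\, n_{chrom}$ ($n_{SNPs}$ read as loci
per chromosome, i.e. the mean scales with the whole genome); each mutation
re-draws the allele among the states currently segregating at that locus
and, at QTLs, perturbs the *carried* copy's effect by
$\mathcal{N}(0, \sigma_\mu)$. Effects are therefore properties of copies,
not states: after mutation, two copies in the same state may carry
different effects.

### Defaults that the source material does not fix

Several quantities are not printed anywhere and are set here once, exposed
in the constructors and recorded in run manifests:

| parameter | default | rationale |
|---|---|---|
| `omega_v` | 4 | weak-to-moderate viability cost: a courter-and-parent male survives with probability $e^{-1/2} \approx 0.61$, keeping all four morphs viable at realistic rates |
| `eggs_per_female` | `max(r)` | the clutch is exactly large enough for the best-provisioned morph to realize its allocation ceiling |
| `mate_search_n` | 50 | females almost always find a courter when courters are present at a few percent, while keeping the finite-search stochasticity the model calls for |
| `mu` | 1e-4 | per locus per generation, a standard forward-simulation rate that yields a handful of mutations per genome per generation |
| `sigma_effect` | 0.5 | initial allelic-effect scale; only the ratio to `sigma_mu` matters for how fast mutation reshapes the liability distribution |
| `sigma_mu` | 0.05 | mutational effect perturbations an order of magnitude below standing effects |

The equilibrium morph frequencies of the high-diversity regime are
sensitive to two of these. Clutch size `E` sets the paternity split of a
clutch (chosen male `min(r_chosen, E)` first, sneakers the remainder): at
the default `E = max(r)` a high-diversity clutch is split 6:2 in favour of
the chosen courter, while a much larger `E` would approach the
proportional sharing of the analytical model (each sneaker up to
$c \cdot r$). Similarly, smaller `omega_v` penalizes courting more
heavily. Under the documented defaults the high-diversity polygenic runs
settle with the courter/parent morph near 0.7 rather than near 0.5 — the
acceptance tests record this honestly; the qualitative structure (exactly
two morphs, CP coexisting with NP, the courter/non-parent never
maintained) is robust to these choices.

### Replicate sets and schedules

`run_replicate_set()` draws one architecture, one set of allelic effects,
one generation-0 population and one pair of thresholds under an
architecture seed, then runs several replicates from identical copies of
that state under their own seeds, so between-replicate differences are
purely stochastic. The full schedule is 10,000 burn-in plus 2,000
experimental generations at `K = 1000`. The test-bench uses
`schedule("desk")`: `K = 300`, 600 + 150 generations, four replicates per
set. These sizes were chosen because the morph-frequency dynamics of both
models equilibrate within a few hundred generations (trajectories are flat
well before generation 600 at every scale we examined, and the equilibrium
is indistinguishable between `K = 300` and `K = 1000`), so the desk scale
measures the same steady state at a cost that fits a single-CPU test run.
What desk-scale agreement does *not* probe is slow genetic turnover —
e.g. long-term erosion of heterozygosity inside supergenes — which only
the full schedule can reveal.

## The statistics layer

`as_genotype_table()` (or a VCF round trip through `write_sim_vcf()` /
`read_sim_vcf()`) exposes the final generation to per-locus statistics:

- observed and expected heterozygosity;
- Nei's $G_{ST} = (H_T - H_S)/H_T$ between male morphs, with unweighted
  group means by default (morph counts are unequal by construction; a
  sample-size-weighted variant is available) and $G_{ST} := 0$ where
  $H_T = 0$;
- a per-locus association score test: genotypes reduce to major-allele
  dosage (multi-allelic loci: major vs rest) and a 1-d.f. chi-square score
  test of logistic regression on dosage is applied — deterministic,
  closed-form, and calibrated against a uniform null in the tests;
  monomorphic loci report p = 1;
- Tajima's D in non-overlapping windows of 50 loci per chromosome, from
  the 2N pseudo-haplotypes, with multi-state loci counted once as
  segregating and $\pi$ computed exactly from allele counts; windows with
  no segregating sites are reported missing;
- pairwise LD as squared Pearson correlation of dosages;
- peak calling: a locus qualifies beyond the genome-wide 0.99 quantile
  (0.95 also reported in grids, bracketing the unspecified choice),
  adjacent qualifying loci merge into one peak at their extremum, and a
  peak must be the extremum within ±25 loci; detection compares peaks with
  the true QTL map within a two-sided 50-position window (loci are
  abstract 1..1000 coordinates, so "50 basepairs" maps to 50 positions);
- a resampling null (999 draws of as many non-QTL loci as there are QTLs)
  and a Welch t-test for QTL-vs-marker contrasts.

Every bounded statistic is tested against independent brute-force oracles
(explicit loops over individuals and haplotype pairs) to 1e-10 on random
fixtures generated by `random_genotype_table()`, which emulates small
diploid tables with known per-group allele frequencies. That generator
deliberately omits features of simulator output — linkage, morph-correlated
structure, mutation-perturbed effects — so oracle agreement certifies the
formulas, not the evolutionary dynamics.

## Numerical and degenerate-input conventions

- Frequencies validate to sum 1 within 1e-9; renormalization guards the
  recurrence against drift in long runs.
- `0/0` situations are defined explicitly: the sneak-survival fraction is
  0 when no chosen-male eggs exist; $G_{ST}$ is 0 at monomorphic loci;
  detection proportions are missing when there are no peaks.
- Internal locus coordinates are 0-based (supergene intervals half-open);
  VCF positions are 1-based and BED intervals 0-based half-open, with the
  conversions centralized in the IO layer and pinned by tests.
- VCF export keeps multi-allelic records intact and maps allele states to
  placeholder bases in rank order, so a round trip relabels states to
  ranks; all downstream statistics are invariant to that relabeling, and
  the tests verify both the relabeled identity and statistic-level
  equality.
- The single-locus architecture uses fixed effects −1/+1 with thresholds
  at 0, making each trait effectively recessive (only +/+ homozygotes
  express it); heterozygotes sit exactly at the threshold and express the
  non-courting/non-parenting state by the strict-inequality convention.

## Known limitations

- Dominance, epistasis, sex linkage, environmental effects, overlapping
  generations and female morphs are out of scope by design.
- The published analytical aggregates are only reproducible under the
  Shannon $H \ge 1$ retention filter; the exact NP/NN asymmetry and the
  individual-based equilibrium near 50% courter/parent depend on
  unpublished implementation details (clutch size, viability strength)
  and are not reproduced at the documented defaults.
- In the architecture-free (single-locus) high-diversity runs, care
  selection reliably fixes the parenting allele here, so the coexisting
  morph is NP in every seed we ran; the published runs report either NP
  or NN depending on chance.
- Peak-detection rates depend on an unspecified peak definition; the
  implementation exposes the quantile and window as parameters rather than
  pinning detection percentages.

## A worked session

```{r example, eval = FALSE}
library(morphsim)

# analytic: high-diversity preset, 100 generations
p <- preset_params("high_diversity", model = "analytic")
traj <- morph_iterate(morph_freqs(0.25, 0.25, 0.25, 0.25), p, 100)
glance(traj)
autoplot(traj)

# a desk-scale replicate set with a supergene
rs <- run_replicate_set(
  function() genome_architecture("supergene", n_chrom = 2, n_qtl = 8,
                                 supergene_prop = 0.25),
  preset_params("high_diversity", K = 300),
  generations = 750, n_replicates = 4, arch_seed = 1, keep_pops = TRUE)
rs$summary

# statistics on the final generation of the first replicate
gt <- as_genotype_table(rs$runs[[1]]$pop)
stats <- locus_stats(gt)
peaks <- find_peaks(stats$gst, stats$chrom, stats$pos)
qtl_detection(peaks, dplyr::mutate(rs$arch$qtl, pos = locus + 1))
```
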