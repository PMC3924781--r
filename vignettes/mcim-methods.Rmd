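---
title: "Mixed-model composite interval mapping in double backcross populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model composite interval mapping in double backcross populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design and the genetic model

An *immortal double backcross population* is built by crossing a panel of
doubled-haploid (DH) or selfed recombinant-inbred (RI) lines to both
homozygous parents P1 and P2.  Because line genotypes are fixed, only
phenotyping has to be repeated across environments, and the pooled
population segregates all three genotypes at every locus (the P1-side
backcross segregates QQ:Qq, the P2-side Qq:qq), so dominance and
additive-additive epistasis become estimable — unlike in a single
backcross or in a DH/RI panel alone.

The phenotype of individual $k$ in environment $h$ is modelled as

$$y_{hk} = \mu + \sum_i a_i x_{A_{ki}} + \sum_i d_i x_{D_{ki}}
         + \sum_{ij} aa_{ij} x_{AA_{kij}} + e_h
         + \sum_i ae_{hi} x_{A_{ki}} + \sum_i de_{hi} x_{D_{ki}}
         + \sum_{ij} aae_{hij} x_{AA_{kij}} + \varepsilon_{hk},$$

with fixed additive $a_i$, dominance $d_i$ and additive-additive
epistatic $aa_{ij}$ effects, random environment main effects and random
environment-interaction (QE) deviations, and
$\varepsilon_{hk} \sim N(0, \sigma^2_\varepsilon)$.  Coefficients are
coded $x_A \in \{1, 0, -1\}$ and $x_D \in \{-0.5, 0.5, -0.5\}$ for QQ,
Qq, qq, and $x_{AA} = x_A^{(i)} x_A^{(j)}$.  At a scanned position the
genotype is unobserved and the coefficients are replaced by their
conditional expectations given the flanking markers:
$x_A = p_1 - p_3$, $x_D = (p_2 - p_1 - p_3)/2$, where $(p_1,p_2,p_3)$
are the conditional QTL-genotype probabilities implemented in
`conditional_probs()`.

## The probability kernel

Distances are converted to recombination fractions with the Haldane map
function (no interference), which is the unique choice consistent with
the kernel's own bookkeeping $r = r_1 + r_2 - 2 r_1 r_2$ for a split
interval.  For DH lines the conditional probabilities follow from
enumerating the F1 gamete classes; for selfed RI lines the kernel uses
the classical map expansion, i.e. it treats the fixed-line genome as a
Markov chain with effective recombination $R = 2r/(1+2r)$ per interval.
Both backcross sides reduce to the same gamete-level computation: the
side only relabels which marker genotype signals a P1-carrying line
gamete, which is how `conditional_probs()` implements the mirror
symmetry $(p_1,p_2,p_3) \mapsto (p_3,p_2,p_1)$.

Two numerical rules: recombination fractions below $10^{-8}$ are treated
as exact zero (a position at a marker becomes a point mass on the marker
genotype), and a recombinant flank class observed at $r = 0$ raises an
inconsistency error rather than producing 0/0.

**A limitation found while testing.**  An exact three-locus
selfing-to-fixation enumeration (used as the test oracle) shows that the
selfed-RI genome is *not* exactly Markov at three loci: the kernel's RI
conditionals agree with the enumeration's pairwise margins exactly but
differ in the three-locus conditionals by up to about 0.01 at
$r_1 = r_2 = 0.1$.  The kernel deliberately implements the standard
closed forms; the RI simulator uses the matching Markov chain, so
simulated data and kernel are mutually consistent, but users analysing
real selfed-RI material should know the conditionals are approximate at
this magnitude.

## The simulator as a stated world

`default_linkage_map()` builds 5 chromosomes x 11 markers at 10 cM;
`default_qtl_scenario()` encodes the built-in architecture: five
main-effect QTLs (Q1-Q5, one per chromosome), two pure-epistatic QTLs
(Q6, Q7), three additive-additive pairs EQ1 (Q1-Q6), EQ2 (Q3-Q5), EQ3
(Q6-Q7, epistasis only), three environments, total broad-sense
heritability 60%.  Choices the generator fixes, and why:

* **QE deviations are fixed per-environment constants** (they all sum to
  zero across the three environments).  This is the only reading under
  which tabulated per-environment "expected" QE values are meaningful;
  the *inference* model still treats QE as random vectors with variance
  components.
* **Environment main effects default to zero variance** (`sigma2_env =
  0`, configurable); no target quantity depends on them.
* **Residual calibration**: $\sigma^2_\varepsilon = V_G (1 - h^2)/h^2$,
  where $V_G$ is the empirical variance of the summed genetic terms over
  the realized individuals and environments.  This makes the realized
  heritability land on the target on average (checked at 60% +/- 3%).
* **One progeny per sampled line**, lines sampled with replacement only
  if the panel is smaller than the progeny count; population sizes count
  progeny.
* **Seeding**: a master seed plus a fixed counter scheme
  (`.child_seed`) gives bit-reproducible replicates below $2^{31}$.

A structural property of this design worth knowing: conditional on the
backcross side, $E[x_A] = \pm 1/2$ at *every* locus, so the additive
coefficients of any two loci — linked or not — correlate 0.5 in the
pooled population, and $E[x_{AA}] = 1/4$.  The simulator reproduces this
faithfully; it is not an artifact.  Real data add features the generator
does not emulate (missing genotypes beyond the reader's nearest-flank
handling, segregation distortion, genotyping error, non-identity
kinship), so a green simulation suite does not establish performance
under those conditions.

## Testing and estimation machinery

**Henderson III F.**  Each scan test is the extra-sum-of-squares ratio
$F = \frac{SSR(b_Q \mid b_B)/(r_W - r_{W_B})}{SSE/(n - r_W)}$ computed
by pivoted QR with a relative rank tolerance of $10^{-10}$; aliased
tested blocks return an explicit `inestimable` status, never a silent 0.
The scan engines evaluate the same quadratic forms through shared
orthonormal bases of the background block, which lets one background
factorization serve a whole grid of tested positions and all permuted
phenotype vectors at once (this is what makes 200-permutation
genome-wide thresholds affordable); the engines are tested to agree with
the direct per-position fits to $10^{-8}$.  During scanning the QE
random terms are absorbed into the residual (ordinary least squares
projections); the full random structure is honoured at the estimation
stage.

**Gibbs estimation.**  The final model is fitted by a block Gibbs
sampler run entirely in coefficient space on precomputed crossproducts:
flat priors on fixed effects, limiting-vague scaled-inverse-chi-square
priors on variance components with a positivity floor of $10^{-10}$ and
a divergence guard at $10^6 \times \mathrm{var}(y)$, defaults 2,000
burn-in + 10,000 kept draws (the Monte Carlo harness uses 400 + 1,200;
posterior-mean noise from the shorter chain is an order of magnitude
below replicate-to-replicate variation).  One identification choice
matters: the fixed main effects and the means of their QE random vectors
are confounded in the model as written, so the environment and QE blocks
are parameterized on the orthonormal **sum-to-zero subspace** across
environments.  This matches the generative world (all the built-in QE
vectors sum to zero) and, without it, the sampler demonstrably lets $a$
and the mean of $ae$ drift against each other.  A deterministic EM
fallback (`method = "em"`) on the mixed model equations is provided for
fast tests; it reduces exactly to OLS when no random blocks are present.

## The scan workflow and its tunables

`map_qtls()` runs: stepwise marker-interval cofactor selection (entry
p < 0.01, at most 10 intervals) — 1D permutation threshold (200
permutations, genome-wide $\alpha = 0.05$, phenotypes shuffled within
environment-by-origin cells) — 1D scan on a 1 cM grid testing the
per-environment additive and dominance block, with cofactors within
10 cM of the tested interval excluded — peak calling (local maxima above
threshold, merged within 20 cM keeping the larger F, ties leftmost) —
pair-cofactor selection (pairs formed from the selected intervals and
the declared QTLs' intervals, at most 5) — 2D threshold and scan on a
5 cM pair grid over distinct non-adjacent intervals, testing the
per-environment additive-additive block given the declared QTLs' main
terms — pair calling with 1 cM refinement in a +/-4 cM box and
re-application of the separation rule (refinement can pull two peaks
together) — backward elimination of candidate blocks at $\alpha = 0.05$
— Gibbs estimation of the survivors.  Monte Carlo matching: a declared
QTL within 10 cM of a true QTL counts as detected; declared QTLs with no
true QTL within 20 cM count as false positives; pairs must match both
members within 10 cM.

## Known limitations

* **Epistasis conditioning in this design.**  Because any two loci's
  additive coefficients correlate 0.5 through the origin structure, a
  pure-epistatic QTL leaks a marginal main-effect signal, gets declared
  as a 1D candidate, and its per-environment main terms then absorb much
  of the epistatic F at the true pair position (measured: the EQ1
  partial F drops about four-fold).  The 2D surface can peak 10-25 cM
  away from the truth, which displaces some pair declarations beyond the
  10 cM matching window and inflates the pair false discovery rate
  (~0.15 at the balanced n = 300 design over 50 replicates, ~0.32 at
  n = 180) even while the pair detection powers stay in their expected
  ranges.  Dropping the declared mains from the 2D background instead
  lets main effects leak *into* the product terms, which is worse.  The
  harness reports what the stated procedure actually achieves.
* Only additive-additive epistasis is estimable in this design; sib-mated
  RILs, interference models, kinship structures and dominant markers are
  out of scope.
* Permutation thresholds are cached from a reference replicate in Monte
  Carlo mode (flag `cache_thresholds`); per-replicate recomputation is
  available but ~5x slower.
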