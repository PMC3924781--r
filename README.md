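# dbxqtl

QTL mapping for **immortal double backcross populations**: progeny panels
obtained by crossing doubled-haploid (DH) or selfed recombinant-inbred (RI)
lines to *both* homozygous parents.  Pooling the two backcrosses segregates
all three genotypes at every locus, so — unlike a single backcross or a
DH/RI panel — the design supports estimation of additive (*a*), dominance
(*d*) and additive×additive epistatic (*aa*) QTL effects together with
their environment interactions (*ae*, *de*, *aae*), from one genotyping of
the immortal lines and repeated phenotyping across environments.

## The method

Phenotypes follow a mixed linear model

y<sub>hk</sub> = μ + Σ a·x<sub>A</sub> + Σ d·x<sub>D</sub> + Σ aa·x<sub>AA</sub> +
e<sub>h</sub> + Σ ae<sub>h</sub>·x<sub>A</sub> + Σ de<sub>h</sub>·x<sub>D</sub> +
Σ aae<sub>h</sub>·x<sub>AA</sub> + ε<sub>hk</sub>,

with coefficients x<sub>A</sub> ∈ {1, 0, −1}, x<sub>D</sub> ∈ {−½, ½, −½}
for genotypes QQ, Qq, qq and x<sub>AA</sub> = x<sub>A</sub>x<sub>A</sub>.
At scanned positions the coefficients are replaced by conditional
expectations given the flanking markers (x<sub>A</sub> = p₁ − p₃,
x<sub>D</sub> = (p₂ − p₁ − p₃)/2), computed from closed-form conditional
probability tables for both backcross sides and both line types (Haldane
map function; selfed-RI via the 2r/(1+2r) map expansion).

Mapping is composite interval mapping under this model: stepwise
marker-interval cofactor pre-selection, a 1 cM 1D scan testing the
per-environment (a, d) block with the Henderson III extra-sum-of-squares
F-statistic, permutation-based genome-wide thresholds, a 2D scan for
additive×additive pairs given the declared QTLs, backward model selection,
and Gibbs-sampling estimation of effects and variance components.

A gamete-level simulator and a Monte Carlo harness reproduce the standard
validation studies (power, bias, false discovery rate) for a 5-chromosome,
55-marker genome with 7 QTLs, 3 epistatic pairs, 3 environments and 60%
heritability.

## Worked example

```r
library(dbxqtl)

scenario <- default_qtl_scenario()          # 7 QTLs, 3 pairs, 3 environments
data <- simulate_cross(scenario, seed = 1)  # 150:150 double backcross
res <- map_qtls(data, dbx_config(gibbs_burn = 500, gibbs_keep = 1500),
                seed = 99)
res
```

```
Mapping result: 6 QTL(s), 1 epistatic pair(s)

Main-effect QTLs:
  chrom pos_cM      a     d    ae1    de1     ae2    de2     ae3    de3
1     1     45 -2.543 -1.44  0.167 -1.844  0.1382  0.239 -0.3053  1.605
2     2     74  0.443  2.04 -1.899  0.618 -0.9564 -0.177  2.8552 -0.441
3     3     50  2.078  2.30  2.889  0.895 -1.3052  0.165 -1.5836 -1.060
4     4     23  0.308  2.17 -0.072 -1.811 -0.0572  0.742  0.1292  1.070
5     4     73 -3.330 -2.32 -0.198 -2.496  0.1461  2.985  0.0520 -0.489
6     5      8  0.994 -1.08  0.432  0.793 -0.4452 -0.127  0.0132 -0.666

Epistatic pairs:
  chrom_i pos_i chrom_j pos_j    aa   aae1  aae2    aae3
1       4    24       5    80 -2.34 -0.867 0.944 -0.0774
```

Reading the output: the five generative main-effect QTLs sit at 44, 75,
50, 73 and 15 cM on chromosomes 1–5; the scan recovers them within a few
cM and the posterior means track the generative effects (e.g. chromosome 4
at 73 cM: a = −3.33 vs. truth −3.30; chromosome 2: the ae pattern
(−1.9, −0.96, 2.86) tracks the generative (−2.0, −0.7, 2.7)).  The pair on
chromosomes 4×5 is the pure-epistatic pair (truth aa = −2.60 at 24/79 cM).
The extra declaration at chromosome 4, 23 cM is the pure-epistatic locus
Q6 picked up through its marginal signal — in this design the additive
coefficients of any two loci correlate 0.5 through the backcross-origin
structure, so epistasis leaks a main-effect signal (see the methods
vignette).  In this replicate the chromosome-1×4 pair fell below the
genome-wide threshold, and the chromosome-1 dominance estimate is
correspondingly attenuated (−1.44 vs. truth −3.08) — exactly the
misspecification bias the Monte Carlo harness quantifies.

Replicate-level studies:

```r
tab <- run_experiment(default_qtl_scenario(), n1 = 150, n2 = 150,
                      n_reps = 50, seed = 1,
                      config = dbx_config(gibbs_burn = 400, gibbs_keep = 1200))
tab          # per-QTL power, mean(SD) estimates, epistasis FDR
```

A command-line interface covers the same workflows
(`simulate`, `scan1d`, `scan2d`, `permute`, `map`, `montecarlo`):

```sh
Rscript inst/cli/dbxqtl.R simulate --out d/ --seed 1
Rscript inst/cli/dbxqtl.R map --data d/ --out result.json --n-perm 200 --seed 1
```

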