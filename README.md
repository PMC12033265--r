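# ystrmatch

Pedigree-based Y-STR haplotype match probabilities by importance sampling.

## The problem

Y-chromosomal short tandem repeats (Y-STRs) are inherited intact down male
lineages and change only by mutation, so a suspect typically shares his
Y-STR haplotype with close patrilineal relatives. When a crime-scene trace
matches the suspect's haplotype, the evidentially relevant quantity is the
probability that some *other* plausible donor — above all an untyped male
relative — carries the same haplotype. Estimating that probability from
population databases of unrelated males is known to be anti-conservative;
`ystrmatch` instead computes it from the suspect's own pedigree.

Given

* the pedigree of `n` patrilineally related males (a rooted tree of
  father–son edges, read from a TGF file),
* haplotypes for `k` typed members including the suspect (`h^v`, a CSV of
  integer repeat counts per marker), and
* per-marker single-step mutation rates `mu_i` (CSV or JSON),

the package estimates

* `P(h^v)` — the probability of the observed typed haplotypes given the
  suspect's haplotype, and
* `p_x = P(m(H^u) = x | h^v)` — the conditional probability that exactly `x`
  of the `n - k` untyped members carry the suspect's haplotype, for
  `x = 0, ..., n - k`.

## The method

Mutation follows the symmetric single-step model: per meiosis and marker an
allele moves by −1, 0, +1 with probabilities `mu/2`, `1 − mu`, `mu/2`
(`z = mu/2` is the unidirectional rate). Because the model is symmetric, the
pedigree can be re-rooted so the suspect becomes the most recent common
ancestor; members are renumbered by generation and untyped members are
simulated in level order, each from his (then known) father.

Direct Monte Carlo is hopeless when `p_x` is small, so `p_x` is estimated by
importance sampling: each simulation first pins a uniformly random size-`x`
subset of the untyped members to the suspect haplotype, then simulates the
rest, and accumulates the proposal weight

```
bin(n-k, x) * prod(edge transition probabilities not simulated) / P(h^v)
```

over simulations in which exactly `x` untyped members match. `P(h^v)` itself
is estimated once per pedigree by the same machinery with `x = 0`, averaging
the product of transition probabilities over edges ending in typed members.
`p_0` is obtained by subtracting the `p_x` estimates from unity.

For small pedigrees the package also computes the exact answer two
independent ways — bounded exhaustive enumeration and a sum-product dynamic
program over the tree — and ships a catalogue of 33 elementary validation
scenarios (pedigrees A–I with all sensible allele assignments) whose
closed-form results in `z` are checked against the oracle at build- and
test-time.

## Worked example

Example inputs for validation pedigree I (suspect `1`, an untyped son `4`
with a typed son `2` and an untyped son `5`, whose son `3` is typed; all
typed members carry the suspect allele 14; one marker with `mu = 0.1`) are
shipped under `inst/extdata/`:

```r
library(ystrmatch)

ped   <- read_tgf(system.file("extdata", "I01_pedigree.tgf", package = "ystrmatch"))
model <- read_mutation_rates(system.file("extdata", "I01_rates.csv", package = "ystrmatch"))
typed <- read_haplotypes_csv(system.file("extdata", "I01_haplotypes.csv", package = "ystrmatch"),
                             panel = model$markers)
case  <- case_configuration(ped, suspect = "1", typed = typed)

exact_distribution_dp(case, model)
#> $pv
#> [1] 0.6606
#> $dist  (exact)
#>           0           1           2
#> 0.000340599 0.006471390 0.993188011

est <- estimate_distribution(case, model, n_sims = 1e5, seed = 1)
est$pv$estimate   # 0.6611107  (exact 0.6606)
est$dist$probs    # 0: 0.00119  1: 0.00639  2: 0.99242
```

Reading: the observed haplotypes have probability `P(h^v) ≈ 0.66`, and
given them it is almost certain (`p_2 ≈ 0.99`) that *both* untyped
relatives share the suspect's haplotype — with one marker and two typed
relatives carrying the suspect allele, the match probability inside this
pedigree is overwhelming, and the haplotype match has little power to
single out the suspect.

The same computation from the shell:

```sh
ystrmatch estimate --pedigree I01_pedigree.tgf --haplotypes I01_haplotypes.csv \
  --rates I01_rates.csv --suspect 1 --sims 100000 --seed 1
ystrmatch exact    --pedigree I01_pedigree.tgf --haplotypes I01_haplotypes.csv \
  --rates I01_rates.csv --suspect 1
ystrmatch validate --scenario A01,D02 --mu 0.1 --sims 100000 --repeats 10 --seed 1
```

For a relative *outside* the pedigree, at most `m` meioses from the suspect,
an exact upper bound on the match probability is

```r
meiosis_match_prob(2, mutation_model(c(M1 = 0.1)))  # 0.815
```

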