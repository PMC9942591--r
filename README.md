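# evograde

Per-site evolutionary rate estimation and nine-grade conservation mapping
for proteins and nucleic acids.

## The problem

Functionally important sites in macromolecules — catalytic residues,
ligand-binding pockets, oligomerization interfaces — tend to evolve slowly
because purifying selection removes variants that break them. Mapping the
per-site evolutionary rate of a query protein or nucleic acid, estimated
from its homologues, therefore highlights candidate functional regions,
especially when the rates are painted onto a 3-D structure. Consensus- or
entropy-based conservation scores ignore both the phylogenetic
relationships among the homologues (a taxonomically biased sample looks
artificially conserved) and the exchangeability between residues; `evograde`
instead estimates rates under an explicit probabilistic model of sequence
evolution on a phylogenetic tree.

It is aimed at structural biologists, protein engineers, and variant
analysts who have (or can generate) a set of homologues for their query and
want a reproducible, scriptable conservation analysis.

## The model

For an alignment column \(x_i\) and a tree \(T\) with branch lengths, the
likelihood \(L_i(r) = P(x_i \mid T, r)\) under a reversible substitution
model (JTT for proteins, Jukes–Cantor for nucleotides) is computed by
Felsenstein's pruning algorithm, with the rate multiplier \(r\) scaling all
branch lengths. Rate variation across sites follows a gamma prior with
mean 1 and shape \(\alpha\), discretized into \(K = 16\) equal-probability
categories with rates \(r_1 < \dots < r_K\). The shape is fitted by maximum
likelihood over all sites,

\[ \hat\alpha = \arg\max_\alpha \sum_i \log \tfrac1K \sum_k L_i(r_k(\alpha)), \]

and each site's rate is the empirical Bayes posterior mean

\[ \hat r_i = \sum_k w_{ik} r_k, \qquad
   w_{ik} \propto \tfrac1K L_i(r_k), \]

with a central 95% credible interval on the discrete category grid.
Rates over the query's ungapped positions are standardized to z-scores and
binned into nine equal-width bins symmetric around zero: grade 1 = most
variable, 5 = average, 9 = most conserved. A grade is flagged unreliable
when its credible interval spans more than 3 grades or fewer than 6
sequences are informative at the site.

Upstream, homologue hit tables are reduced deterministically: hits are
sorted by E-value (ties by id), filtered by identity/coverage bounds,
de-redundified by greedy clustering at 95% identity, and thinned to 150
evenly spaced representatives. Downstream, grades can be written into the
temperature-factor column of a PDB or mmCIF structure, propagated across
identical chains of a homo-oligomer, and exported as PyMOL/ChimeraX
coloring scripts.

## Worked example

Simulate a 40-sequence, 200-site protein family with known site rates
(gamma shape 0.6), then run the full pipeline on the alignment:

```r
library(evograde)

sim <- simulate_dataset(n_leaves = 40, n_sites = 200, alphabet = "protein",
                        alpha = 0.6, seed = 2024)
paths <- write_simulation(sim, "demo")
cfg <- run_config(msa = paths[["alignment"]], query_id = "t1",
                  out_dir = "demo_run", seed = 1)
res <- run_pipeline(cfg)
#> [..] alignment: 40 sequences x 200 sites (protein)
#> [..] tree: neighbor joining on corrected distances
#> [..] rates: fitted gamma shape alpha = 0.6976 (K = 16)
#> [..] grading: 200 query positions, 29 flagged unreliable

head(res$grades[, c("query_position", "residue", "score", "grade",
                    "ci_grade_low", "ci_grade_high", "reliable")], 8)
#>   query_position residue      score grade ci_grade_low ci_grade_high reliable
#> 1              1       G  0.7021770     4            1             6    FALSE
#> 2              2       M  1.1991735     3            1             5    FALSE
#> 3              3       A -0.3777072     6            5             7     TRUE
#> 4              4       S -1.0252586     7            7             7     TRUE
#> 5              5       F  0.9692682     3            1             5    FALSE
#> 6              6       L  0.1678273     5            3             6     TRUE
#> 7              7       N  0.1315126     5            3             6     TRUE
#> 8              8       Y  0.1460422     5            3             6     TRUE

cor(sim$true_rates, res$rates$rate_hat, method = "spearman")
#> [1] 0.9465
```

The fitted shape (0.70 against a generating value of 0.6) and the rank
correlation of 0.95 between true and estimated site rates show the
estimator recovering the simulated signal. Position 4 is a conserved site
(negative score, grade 7) whose tight credible interval (7–7) makes it
reliable; positions with wide intervals are reported but starred as
unreliable in `demo_run/grades.tsv`. The run directory also contains the
processed alignment, the Newick tree, per-site rates, and a JSON mirror of
the grades. Supplying `structure =` (PDB or mmCIF) additionally writes a
copy of the structure with grades in the B-factor column plus
`coloring.pml` / `coloring.cxc` scripts.

A command-line front end with `run`, `subtree`, and `simulate` verbs is
installed at `inst/cli/evograde.R`:

```sh
Rscript inst/cli/evograde.R run --msa demo/alignment.fasta --query t1 --out demo_run
```

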