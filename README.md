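# critres

Classification of critical residues for protein function from
structure-derived descriptors.

## The problem

A residue is *critical* when mutating it degrades the protein's function —
through stability, folding, binding or catalysis.  Mapping critical residues
onto protein structure is a way to probe the structure–function
relationship, but it needs (i) a quantitative, mutation-based definition of
criticality and (ii) structure descriptors informative enough to learn that
definition.  `critres` implements both sides:

* **Structure descriptors.**  From a PDB chain it builds the residue
  contact graph (edge between residues whose heavy atoms lie within a
  cutoff, default 5 Å) and computes 11 per-residue centralities:
  eccentricity and its inverse, degree, sphere degree and its accumulated
  variant (SNN), mean hop distance, closeness, clustering coefficient and
  its inverse, and two deterministic single-shortest-path traversity
  variants.  From a multiple sequence alignment it adds the
  correlated-mutation index *CM*<sub>j</sub> = Σ<sub>i∈contacts(j)</sub>
  *S*<sub>i</sub>, where *S*<sub>i</sub> is the fraction of homologs whose
  residue differs from the reference at the contacting column.

* **Criticality index.**  Every substitution *a*→*b* between distinct
  amino acids is scored by the Euclidean distance between the residues'
  five physicochemical factor scores (polarity, secondary structure,
  molecular volume, codon diversity, charge; Atchley et al. 2005) and
  ranked 1…380, rank 380 being the most dissimilar.  For a position with
  *m* reported deleterious mutations of ranks *R*<sub>i</sub>,

      CI = Σ R_i / Σ_{i=381−m}^{380} i ,

  the observed rank sum over the largest rank sum *m* mutations can attain,
  so CI ∈ (0, 1].  When both tolerated (wild-type phenotype, ranks *RW*)
  and deleterious (mutant phenotype, ranks *RM*) substitutions are reported,

      CI = ½ [ (1 − Σ RW_i / D_w) + Σ RM_i / D_m ] ,

  with *D*<sub>w</sub>, *D*<sub>m</sub> the corresponding top-rank sums.
  A residue is labeled critical exactly when CI > 0.5.

* **Model building.**  Descriptor tables (CSV or ARFF, e.g. external
  physicochemical descriptor exports) are filtered — constant columns,
  Spearman-redundant columns (|ρ| ≥ 0.95), zero-information-gain columns
  under MDL discretization — and a genetic algorithm (SSOCF crossover,
  binary tournament, toggle mutation, elitism) searches descriptor subsets
  maximizing the 10-fold cross-validated Matthews correlation coefficient
  of a class-weighted linear SVM.  Evaluation harnesses provide
  leave-one-out, swapped-dataset tests and asymmetric model-overlap
  comparison.

Synthetic generators (toy structures, alignments, mutagenesis tables,
feature tables with planted signal) make the entire pipeline testable
without external data.

## Worked example

```r
library(critres)

ch <- makeStructure(30, geometry = "spiral", seed = 1)   # helix-like CA trace
g  <- buildContactGraph(ch, cutoff = 5)
g
#> ResidueContactGraph: 30 residues, 29 contacts (cutoff 5.00 A, mode heavy, min. separation 1)

prof <- centralityProfile(g)
round(head(prof[, c("degree", "closeness", "clustering_coefficient",
                    "traversity_A")], 4), 4)
#>   degree closeness clustering_coefficient traversity_A
#> 1      1    0.0023                      0            0
#> 2      2    0.0025                      0           28
#> 3      2    0.0026                      0           54
#> 4      2    0.0028                      0           78

rk <- buildSubstitutionRanking()
rk
#> SubstitutionRanking: 380 ordered substitutions
#>  least dissimilar: F->I (rank 1, d = 0.949)
#>  most dissimilar:  Y->S (rank 380, d = 9.048)

muts <- data.frame(position  = c(12, 12, 17),
                   wt        = c("A", "A", "L"),
                   mut       = c("W", "D", "I"),
                   phenotype = c("mutant", "mutant", "wild-type"))
annotateCriticality(muts, rk)
#>   position m        CI        label
#> 1       12 2 0.6772069     critical
#> 2       17 1 0.4421053 non-critical
```

Position 12 accumulated two fairly dissimilar deleterious substitutions
(A→W, A→D), so its rank sum approaches the top-2 bound and CI exceeds the
0.5 threshold; position 17 tolerated the conservative L→I exchange, which
pulls its index below it.  `runPipeline()` chains these stages with
filtering, GA selection and leave-one-out evaluation; `gaSelect()` and
`leaveOneOut()` expose the individual steps.

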