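# codonbias

Codon usage bias analysis for collections of protein-coding sequences
(CDSs), in R.

Synonymous codons are not used at random: GC-biased mutation pressure,
selection for translational efficiency and local sequence structure all
leave signatures in which codon a gene uses for a given amino acid.
`codonbias` implements a complete per-genome analysis of these
signatures, of the kind routinely applied to plant nuclear genomes
(e.g. sets of *Brachypodium distachyon* inbred lines): it filters a CDS
FASTA down to clean sequences, computes the standard usage indices,
separates mutational from selective signal with ENC–GC3 and parity-rule-2
diagnostics, ordinates genes by correspondence analysis of their RSCU
profiles, calls optimal codons from the axis extremes, and profiles the
5′-to-3′ decline of hydrogen bonding and CG-skew along the CDSs. A
synthetic CDS generator with exact positional expectations makes every
stage testable without genome downloads.

## The quantities computed

For a gene with codon counts $g_{ij}$ (codon $i$ of amino acid $j$,
synonymous family size $n_j$):

- **RSCU** (relative synonymous codon usage):
  $\mathrm{RSCU}_{ij} = g_{ij} \big/ \bigl(\tfrac{1}{n_j}\sum_i g_{ij}\bigr)$ —
  1 means no bias within the family.
- **ENC** (effective number of codons, Wright-style): per family
  $\hat F = (n\sum_i \hat p_i^2 - 1)/(n-1)$, then
  $\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
  capped at 61; 20 means one codon per amino acid, 61 equal usage of all
  61 sense codons.
- **Expected ENC** under mutation pressure alone, as a function of GC3s
  ($S$): $\mathrm{ENC}_{exp} = 2 + S + 29/(S^2 + (1-S)^2)$.
- **A3s/T3s/G3s/C3s, GC3s, GC** — third-position base frequencies over
  synonymous codons, and overall G+C.
- **PR2 coordinates** $G_{3s}/(G_{3s}+C_{3s})$ vs $A_{3s}/(A_{3s}+T_{3s})$;
  (0.5, 0.5) is the parity point.
- **Correspondence analysis** of the genes × 59-codon RSCU matrix (SVD
  of standardized residuals), with per-axis inertia fractions.
- **Optimal codons**: 2×2 Pearson chi-square (codon vs other synonyms ×
  high- vs low-bias gene set, the sets being the 5% axis-1 extremes),
  called at p < 0.01 with higher usage in the high-bias set.
- **Positional profiles**: mean Watson–Crick hydrogen bonds per codon
  position (A:T = 2, G:C = 3; codons with 6–7 bonds are "cheap", 8–9
  "expensive") with bootstrap confidence bands, and sliding-window
  CG-skew $(C-G)/(C+G)$ and AT-skew $(A-T)/(A+T)$ trends with OLS
  slopes.

## Worked example

```r
library(codonbias)

spec   <- synthetic_genome_spec(n_genes = 300, seed = 8)
genome <- generate_genome(spec)     # or read_cds_fasta("my_cds.fasta")

f <- filter_cds(genome)
f$report
#> CDS filter report: 300 input, 300 passed
#>   no rejections

prof <- gene_profiles(f$cds)
c(gc3s = mean(prof$gc3s), gc = mean(prof$gc), enc = mean(prof$enc))
#> mean GC3s 0.603 | mean GC 0.505 | mean ENC 53.4

coa <- run_coa(build_rscu_matrix(prof))
coa
#> Correspondence analysis: 300 rows x 59 cols, 4 axis(es)
#>   inertia fractions: 40.59%, 3.76%, 3.28%, 3.14%

axis_correlations(coa, prof)
#>   index          r        r2   n
#> 1    gc -0.9694883 0.9399075 300
#> 2  gc3s -0.9958497 0.9917166 300
#> 3   enc  0.9207284 0.8477407 300

opt <- call_optimal_codons(select_extreme_genes(coa, attr(prof, "counts")))
opt
#> Optimal codons (p < 0.01, higher usage in high-bias set): 29
#>   AAC AAG ACC ACG AGC AGG ATC CAC CAG CCC CCG CGC CGG CTC CTG GAC GAG
#>   GCC GCG GGC GGG GTC GTG TAC TCC TCG TGC TTC TTG

aggregate_skew_profile(genome, max_len = 600, n_boot = 100, seed = 1)
#> Skew profile: 600 positions (window 100 bp, step 1 bp)
#>   CG-skew slope: -2.49e-05 per bp (bootstrap SE 1.99e-05)
#>   AT-skew slope: 7.94e-06 per bp (bootstrap SE 2.18e-05)
```

Reading the output: the gene ordination is dominated by one axis (about
41% of the inertia) that is almost perfectly aligned with GC3s
(r² = 0.99) — nucleotide composition, not selection, orders the genes.
All called optimal codons end in C or G, and the CG-skew trends downward
from the 5′ end: C is preferred early in the CDS and the preference
decays. `positional_profile()` gives the matching hydrogen-bond profile
with bootstrap bands, and `run_pipeline()` executes all stages at once,
writing per-stage TSV tables and a JSON summary.

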