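# acylsite

Downstream analysis of lysine **succinylation** (SuccK, +100.016 Da) and
**malonylation** (MalK, +86.000 Da) in label-free quantitative proteomics.
The package is aimed at PTM proteomics analysts who have a peptide-level
quantitation export (one row per identified peptide ion with per-sample
normalized abundances) and want, without commercial software:

* quality filtering — `|mass error| < 20 ppm`, ≤ 1 tryptic missed cleavage
  with acyl-modified lysines excluded from the count;
* PTM site annotation in protein coordinates from a FASTA;
* Hi-N (top-3) protein-level relative quantitation;
* per-modified-peptide one-way ANOVA (significance at raw `p ≤ 0.05`, BH
  q-values reported) with per-protein Up/Down/Both direction summaries;
* a graded **attenuation classifier** for insult/rescue designs;
* hypergeometric over-representation analysis against GMT gene sets with
  BH FDR (reported at FDR ≤ 1 %, p ≤ 0.01, ≥ 5 gene names found);
* a synthetic-data generator with planted ground truth for benchmarking.

## The attenuation classifier

For a design with two vehicle controls, an insult group (e.g. the NMDA
antagonist MK-801) and a co-treatment group (insult + antipsychotic), and
for each acyl-modified peptide whose vehicle means agree within 10 %
(symmetric relative difference), let `b` be the mean of the two vehicle
means and

```
d_model   = (mean_model   − b) / b
d_treated = (mean_treated − b) / b
```

Severity follows `|d_model|`: none (≤ 0.10), mild (0.10–0.25], moderate
(0.25–0.50], severe (> 0.50), in either direction.  The site is
*attenuated* when `|d_treated|` returns back under the threshold its
severity crossed and `|d_treated| < |d_model|`.  Attenuated sites land in
a residual band (< 10 %, 10–25 %, 25–50 %) and earn one asterisk per extra
threshold passed on the way back — so `**` marks exactly the sites
disturbed by more than ±50 % that return to within ±10 % of control.

## Worked example

```r
library(acylsite)

sim <- simulate_acyl_experiment(seed = 42)   # 500 proteins, 4 groups x 3
sim
#> Simulated acylation experiment: 3421 peptides / 500 proteins / 12 samples
#>   modified peptides : 246 (218 concordant, 66 dysregulated, 27 attenuated)

at <- attenuation_table(sim$peptides, sim$design, proteome = sim$proteome)
head(format_attenuation_table(at), 5)
#>       ptm band    gene position asterisks multi_peptide
#> 1 malonyl lt10 SYN0026       30                   FALSE
#> 2 malonyl lt10 SYN0086       10        **         FALSE
#> 3 malonyl lt10 SYN0120       40         *         FALSE
#> 4 malonyl lt10 SYN0217       51                   FALSE
#> 5 malonyl lt10 SYN0225        8                    TRUE

dd <- call_differential(sim$peptides, sim$design)
frequency_summary(sim$peptides, dd)
#> Quantified peptides: 3421
#>   overall   modified: 246 (7.19%), dysregulated: 84 (34.15% of modified)
#>   succinyl  modified: 121 (3.54%), dysregulated: 47 (38.84% of modified)
#>   malonyl   modified: 125 (3.65%), dysregulated: 37 (29.60% of modified)
#> Protein direction (significant sites): Up=40, Down=35, Both=4

evaluate_recovery(at, dd, sim$truth)
#> Recovery vs planted truth (246 sites, 203 matched):
#>   severity band accuracy : 0.951
#>   residual band accuracy : 0.951
#>   asterisk accuracy      : 0.990
#>   attenuated             : P=0.759 R=0.815 F1=0.786
#>   double_asterisk        : P=1.000 R=1.000 F1=1.000
#>   differential           : P=0.917 R=0.819 F1=0.865
```

Reading the output: 7.2 % of the simulated peptides carry an acyl mark
(the generator plants 7 %); of the modified peptides 34 % are called
dysregulated at `p ≤ 0.05`; `SYN0086**` is a malonylation site pushed
> 50 % off baseline by the insult and pulled back to within 10 % by the
co-treatment; `SYN0225` contributed more than one attenuated peptide.  At
noise σ = 0.1 (log2) the pipeline recovers the planted severity band for
95 % of matched sites and every `**` call is a planted `**` site.

`run_pipeline()` chains all stages and writes TSV outputs plus a JSON
manifest into a run directory; `inst/cli/acylsite.R` is a thin Rscript
wrapper (`simulate` / `run` subcommands).  A full account of the model,
parameter choices and simulator assumptions is in
`vignettes/acylsite-methods.Rmd`.

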