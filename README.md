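# cckit — peak calling and differential analysis for transposon Calling Cards

Calling Cards (CC) is a method for recording transcription-factor (TF)
binding: a piggyBac transposase (PBase), optionally fused to a TF, deposits
transposons into the genome near where the TF binds — exclusively at TTAA
tetranucleotides — and the insertions are read out later by sequencing.
Unfused PBase tracks Brd4 and so maps enhancer activity; a TF–PBase fusion
maps that TF's binding, with the unfused data serving as the background
(null) insertion distribution. Single-cell CC additionally tags every
insertion with a cell barcode so TF binding and mRNA expression can be
compared across cell types.

`cckit` is an R toolkit for everything downstream of the insertion file:

* **I/O** — qbed insertion files (5 or 6 columns, gzip OK), TTAA indexes
  from genome FASTA, BED/bedGraph/gene tables (`read_qbed()`,
  `build_ttaa_index()`, `read_genes()`, ...).
* **Peak calling** — three callers sharing one significance engine:
  `call_cccaller()` (greedy: extend a block while the next insertion is
  within `maxbetween` bp), `call_maccs()` (sliding window, merge enriched
  windows, re-center, re-test), and `call_blockify()` (Bayesian-Blocks
  event segmentation).
* **Differential binding** — cells/groups-by-peaks sparse matrices
  (`assign_insertions()`), two-sided Fisher and one-sided binomial tests
  (`fisher_diff()`, `binomial_diff()`, `rank_peak_groups()`), and the two
  comparison strategies `diff_strategy_joint()` / `diff_strategy_separate()`.
* **Interpretation** — two-nearest-gene annotation (`annotate_peaks()`),
  pairing differentially bound peaks with differentially expressed genes
  (`pair_peak_gene()`), GWAS-catalog intersection (`gwas_intersect()`),
  signal-around-peak profiles (`signal_matrix()`), and Gaussian-mixture
  footprint refinement for yeast-style data (`fit_footprint()`).
* **Simulation** — a seeded generator with ground truth
  (`simulate_insertions()`, `score_caller()`) so every stage is testable
  without external downloads.

## The model

All statistics count **insertions** (read counts are carried for plotting
only). A candidate interval with `n` experiment insertions is tested with a
one-sided Poisson upper tail `P(X ≥ n)`, `X ~ Poisson(λ)`, where λ is the
expected count under the null, corrected for TTAA availability. With a
background set of insertions,

    λ = max( max(n_bkg, c) · (N_exp / N_bkg) · T_peak / max(T_local, 1) )

taken over the peak itself and every flanking "lambda window" larger than
the peak (the most conservative estimate wins, MACS2-style); `n_bkg` is the
background count in the interval considered, `N_exp`/`N_bkg` are library
sizes, `T` are TTAA counts, and `c` is a pseudocount. Background-free, the
local rate comes from the experiment itself:

    λ = max over lambda windows of (n_win − n_peak) · T_peak / max(T_win − T_peak, 1)

floored at the pseudocount. Candidates with at least `min_insertions`
insertions are tested and filtered on Benjamini–Hochberg adjusted p-values.

## Worked example

Simulate a 1 Mb chromosome with 10 planted binding sites (≈50 directed
insertions each over a sparse uniform TTAA background), call peaks with the
greedy caller, and score against ground truth:

```r
library(cckit)
sim   <- simulate_insertions(sim_config(seed = 11))
sim$exp
#> InsertionSet with 696 insertions on 1 chromosome(s)

peaks <- call_cccaller(sim$exp, sim$bkg, sim$ttaa)
as.data.frame(peaks)[1:4, c("chrom","start","end","n_exp","n_bkg","n_ttaa","lam","pvalue","qvalue")]
#>     chrom  start    end n_exp n_bkg n_ttaa  lam   pvalue   qvalue
#> 1 chrSim1  22075  22781    54     0      5 1.93 1.88e-57 7.50e-57
#> 2 chrSim1  88189  88282    44     0      2 1.99 7.37e-43 1.26e-42
#> 3 chrSim1 231449 235302    51     1     19 3.48 8.88e-41 1.33e-40
#> 4 chrSim1 276472 278686    53     1      7 3.48 3.89e-43 7.79e-43

unlist(score_caller(peaks, sim$truth, sim$exp)[c("recall","precision","insertion_fraction")])
#>     recall  precision insertion_fraction
#>      1.000      1.000              0.737
```

Each row is one called peak: `n_exp` insertions observed against an
expected `lam` under the TTAA-corrected null, giving the Poisson `pvalue`
and BH-adjusted `qvalue`. Here all 10 planted sites are recovered with no
false positives, and 74% of all insertions (directed + background) fall
under called peaks.

A command-line interface is installed with the package
(`<library>/cckit/exec/cckit`), with subcommands `simulate`, `callpeaks`,
`diff`, `annotate`, `footprint`, `gwas`, `signal` and `pipeline`.

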