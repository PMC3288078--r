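# chromintegrate

Integrated analysis of two-condition ChIP-seq peak tracks and replicated
expression profiles, built around the question of how stimulus-responsive
genes are wired at the chromatin level. The motivating system is the
macrophage early inflammatory response: THP-1 macrophages with and without
2 h of LPS stimulation, profiled for histone H3 acetylation (H3Ac, open
chromatin), serine-5-phosphorylated RNA polymerase II (S5P RNAPII,
transcription initiation), the transcription factor Sp1, and genome-wide
expression.

## What it computes

Given per-mark, per-condition peak calls (BED), gene models with one or
more annotated TSSs per gene, CpG-island intervals, a genome FASTA and a
replicated log2 expression matrix, the package provides:

- **Peak comparison** (`compare_conditions`): peaks overlapping (≥1 bp) a
  peak of the other condition are grouped into connected components of the
  bipartite overlap graph ("common" peaks); the rest are condition-unique.
  Because overlap can be many-to-many, per-condition common counts and the
  component count are reported side by side — they are not additive.
- **Widening calls** (`extension_call`): per component, the growth of the
  stimulated envelope beyond the unstimulated one is read strand-aware as
  upstream-only, downstream-only, both, or none (growth < 200 bp, about
  one peak-caller window, is ignored; shrinkage never calls a direction).
- **Annotation** (`classify_peaks`, `cpg_split`, `genome_composition`):
  promoter > exon > intron > intergenic precedence with any-overlap
  semantics, high/low CpG splits, and the per-base expected genome
  composition baseline.
- **TATA-box scanning** (`scan_tata`): matrix-similarity scanning of the
  −150/+50 core promoter,
  `sim(s) = Σ_j C_j f_j(s_j) / Σ_j C_j max_b f_j(b)` with conservation
  weights `C_j = (1/ln4) Σ_b f_j(b) ln(4 f_j(b))`, cutoff 0.9. Default
  matrices are built from the classical consensus strings `gTATAAAa`
  (VTATA.01) and `ctATAAAA` (VTATA.02); user matrices can replace them.
- **Differential expression** (`differential_expression`): per-gene
  two-sided t-test on log2 replicates with the signed fold-change
  convention (`+2^Δ` / `−2^(−Δ)`), called at |FC| ≥ 2 and p < 0.05.
- **Integration** (`build_profiles`, `classify_group`): one feature
  profile per annotated TSS (promoter H3Ac, extension direction, S5P/Sp1
  occupancy per condition, CpG, TATA, DE result). Regulated genes are
  classified into **group 1** (no promoter H3Ac; typically CpG-poor,
  TATA-containing sharp promoters — interleukin/CC-chemokine style) or
  **group 2** (common promoter H3Ac; typically CpG-rich, TATA-less broad
  promoters — TNF style). The one hard decider is promoter H3Ac; CpG,
  TATA and Sp1 are reported as a consistency score.
- **Synthetic data** (`sim_config`, `simulate_chromatin`): a generator
  that plants all of the above (widened common peaks, unique peaks,
  group-1/2 promoter architectures, TATA motifs, CpG islands, fold
  changes) with exact ground truth, used by the test suite.
- **Pipeline** (`run_pipeline`, `chromintegrate_cli`): simulate or load →
  compare per mark → annotate → scan → DE → integrate, writing summary
  tables, a co-localization table, the per-TSS feature table and a run
  log; byte-reproducible under a fixed seed.

## Worked example

```r
library(chromintegrate)

sim <- simulate_chromatin(sim_config(seed = 42, n_genes = 60,
                                     n_up = 20, n_down = 5,
                                     replicate_sd = 0.1))
cmp <- compare_conditions(sim$peaks$h3ac$minus, sim$peaks$h3ac$plus)
length_summary(cmp)$table
#>          class  n mean_length
#> 1  minus_total 39       982.6
#> 2   plus_total 43      1477.7
#> 3 common_minus 33       983.2
#> 4  common_plus 33      1804.3
#> 5 unique_minus  6       978.8
#> 6  unique_plus 10       400.0
```

Most H3Ac peaks are preserved across stimulation (33 common components vs
6 + 10 unique peaks) and the common islands roughly double
(`widening_ratio` 1.84 here; 10% of planted peaks do not expand).

```r
de <- differential_expression(sim$expr)
summarize_de(de)[c("n_up", "n_down")]    # $n_up 20, $n_down 5
tata <- scan_tata(sim$tss, sim$genome)
pr <- build_profiles(sim$tss, cmp, s5p = sim$peaks$s5p, sp1 = sim$peaks$sp1,
                     cpg_islands = sim$cpg, tata = tata, de = de)
table(pr$group)
#>          1          2 unassigned
#>         12         13         35
head(pr[pr$group != "unassigned",
        c("gene_id", "fold_change", "h3ac_common", "extension",
          "s5p_status", "cpg", "tata", "group")])
#>   gene_id fold_change h3ac_common extension s5p_status   cpg  tata group
#> 1 gene001        3.89        TRUE      both       both  TRUE FALSE     2
#> 2 gene002        3.80       FALSE      none       none FALSE  TRUE     1
#> 3 gene003        3.94        TRUE      both       both  TRUE FALSE     2
#> 4 gene004        3.93       FALSE      none  plus_only FALSE  TRUE     1
#> 5 gene005        3.96        TRUE      none       both  TRUE FALSE     2
#> 6 gene006        4.02       FALSE      none       none FALSE  TRUE     1
```

Every regulated gene lands in the group its promoter architecture was
planted with: H3Ac-marked, CpG-island promoters are group 2 even when
widened in either direction; H3Ac-free, TATA-containing promoters are
group 1 even when S5P RNAPII appears upon stimulation.

The same run end-to-end, with reports on disk:

```sh
./exec/chromintegrate run --config demo.json
# demo.json: {"simulate": {"seed": 42, "n_genes": 60, "n_up": 20, "n_down": 5},
#             "outdir": "demo_out"}
```

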