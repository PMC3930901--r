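# ssrforge

Genome-wide development of SSR (microsatellite) markers from genome
assemblies, for crop and plant geneticists who need locus-specific,
polymorphic, PCR-ready markers plus the statistics to characterize them.

Simple sequence repeats are tandem repetitions of 1–6 bp motifs whose
allele length varies by repeat-count mutation. ssrforge implements the
complete marker-development chain:

1. **Scan** — detect all maximal perfect tandem tracts whose repeat count
   reaches a per-class threshold (defaults Mono ≥ 20, Di/Tri/Tetra ≥ 8,
   Penta/Hexa ≥ 6, with per-sequence overrides), canonicalizing motifs
   into cyclic-rotation families (AG ≡ GA, kept distinct from CT ≡ TC).
2. **Single-copy filter** — keep a locus when its top genome-alignment
   score is at least 5× the second-best (inclusive boundary); hit tables
   in standard 12-column tabular format, or a built-in desk-scale
   seed-and-extend search.
3. **Polymorphism calls** — anchor each locus's 50 bp flanks in alternate
   assemblies (≤ 2 mismatches, uniqueness required) and re-measure the
   tract; any length difference ≥ `min_diff` (default 1 bp) is
   polymorphic.
4. **Primer design** — deterministic enumeration under explicit
   constraints (length 18–24, Wallace Tm 55–62 °C, GC 0.40–0.60, product
   100–300 bp), minimizing
   `|tm_f−60| + |tm_r−60| + |tm_f−tm_r| + 0.01·|product−200|`.
5. **Statistics** — Botstein PIC
   `1 − Σp_i² − Σ_{i<j} 2p_i²p_j²`, cross-species transferability, Nei
   (1983) D_A distance `1 − (1/L) Σ_loci Σ_alleles √(x_a y_a)`,
   neighbor-joining trees (Newick), and a physical map with inter-marker
   gaps in Kb.

A seeded synthetic-data module (genomes with planted SSRs, mutated
alternate genotypes, group-structured genotype matrices) makes every
stage testable with known truth and no downloads. See the vignette
(`vignettes/ssr-marker-development.Rmd`) for the model conventions and
their rationale.

## Worked example

Simulate a 10 kb genome with five planted SSRs, derive a diverged
accession in which three tracts changed length, and run the pipeline:

```r
library(ssrforge)

plants <- rbind(plant_spec("seq1", 1000L, "AT",    10L),
                plant_spec("seq1", 2500L, "AAG",    9L),
                plant_spec("seq1", 4000L, "AC",    12L),
                plant_spec("seq1", 5500L, "AAAT",   8L),
                plant_spec("seq1", 7000L, "AGATC",  7L))
gen <- generate_genome(1, 10000, plants, seed = 42)
alt <- derive_genotype(gen$genome, gen$truth, c(2L, 0L, 3L, 1L, 0L),
                       snp_rate = 0.002, seed = 43)
write_fasta(gen$genome, "ref.fa"); write_fasta(alt$genome, "alt.fa")

cfg <- run_config(reference = "ref.fa", alternates = c(DQJ = "alt.fa"),
                  out_dir = "demo_out", seed = 42)
res <- run_all(cfg)
#> scan: 5 loci
#> unique: 5 of 5 single-copy
#> compare: 3 of 5 polymorphic (either)
#> design: 3 primer pairs
res$summary
#>   seq_id n_ssr DQJ_polymorphic DQJ_pct designed
#> 1   seq1     5               3      60        3
#> 2  Total     5               3      60        3
```

All five planted tracts are found and confirmed single-copy; exactly the
three mutated loci are called polymorphic against the simulated "DQJ"
accession (60.0% of loci), and each gets a primer pair, e.g.:

```r
res$primers[1, c("fwd_seq", "rev_seq", "tm_f", "tm_r", "product_size")]
#>               fwd_seq               rev_seq tm_f tm_r product_size
#> 1 GGAGCGAGGGTACTGATAG CGGTAGAATTTGTGCAAAGCA   60   60          200
```

Both primers sit at the Tm target of 60 °C and bracket a 200 bp product
(the penalty optimum). The physical map orders the designed markers with
gaps in Kb:

```r
res$map$map
#>   seq_id position       marker gap_kb
#> 1   seq1     1000 seq1_SSR0001     NA
#> 2   seq1     4000 seq1_SSR0003    3.0
#> 3   seq1     5500 seq1_SSR0004    1.5
```

Every stage writes its TSV artifacts (plus the resolved configuration)
under `demo_out/`. The same workflow is scriptable via the CLI launcher:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ssrforge.R", package="ssrforge"))')
Rscript "$CLI" scan --fasta ref.fa --out loci.tsv
Rscript "$CLI" all  --config run.cfg
```

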