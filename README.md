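# spongetag

Analysis of short hypervariable-region 16S rRNA sequence tags ("V6 tags",
50–60 nt) from host-associated microbial communities — built for the
question of where sponge symbionts come from, usable for any deeply
sequenced amplicon-tag census with replicated host and environmental
samples.

Deep tag pyrosequencing turns two classical questions into computable
ones:

* **How rich is the community?** Tags are dereplicated, pairwise
  gap-aware Jukes–Cantor distances are computed
  (d = −(3/4)·ln(1 − (4/3)·p), terminal gaps ignored, each internal gap
  run a single evolutionary event), and OTUs are formed by
  furthest-neighbour (complete-linkage) clustering at a stated similarity
  level. Richness is estimated by exact rarefaction
  (E[Sₙ] = Σᵢ (1 − C(N−Nᵢ, n)/C(N, n))), Chao1 (S_obs + F₁²/2F₂) and ACE.
* **Who is there, and where else?** Each tag is assigned a taxonomy by a
  nearest-set majority rule: all references within 0.1% divergence of the
  best hit vote, a rank label needs a 60% majority and rank-specific
  similarity floors (genus 95%, family 90%, order 85%, class 80%, phylum
  75%). The same rule assigns "sponge-specific" (SC/SCC) sequence-cluster
  labels at 75%. Communities are compared by Bray–Curtis similarity
  (100·(1 − Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ))) on per-rank percent profiles, and each
  cluster is classified **sponge_exclusive** (found in adults/larvae,
  never in seawater — implying vertical transmission) or
  **also_in_seawater** (trace detection in the rare seawater biosphere —
  compatible with environmental acquisition).

A synthetic-data generator (`scenario_spec()` / `build_scenario()`)
produces a full replicated study design — 3 sponge species × 3 adult
replicates, 3 larval samples, 4 seawater replicates, lognormal rank
abundance, host-enriched cluster taxa seeded into seawater at 1e-4, flat
per-base sequencing error — with complete ground truth, so every stage is
testable end to end without external data.

## Worked example

```r
library(spongetag)

scn <- build_scenario(scenario_spec(seed = 1L))   # 16 samples, 80,000 tags
write_scenario(scn, "scn")
res <- run_pipeline(run_config(manifest = "scn/manifest.tsv",
                               refdb = "scn/refdb.tsv", out_dir = "run"))

res$richness
#>            pool level n_reads s_obs    chao1      ace
#>   adult_sponge1    95   14998   722 1638.782 1730.581
#>   adult_sponge2    95   14908   964 2175.066 2373.205
#>   adult_sponge3    95   14965   548 1007.043 1105.944
#>  larvae_sponge1    95   14984   891 2264.885 2597.537
#>        seawater    95   19939   944 1975.902 2220.052

attr(res$transmission, "summary")
#> clusters detected: 24; also in seawater: 12; %exclusive: 50.0 (designed 50.0)
```

Reading the output: `s_obs` is the number of 95%-similarity OTUs observed
per pooled sample type; Chao1/ACE exceed it substantially because
sequencing error inflates the singleton tail — the known behaviour of
richness estimators on unpolished pyrosequencing reads. The transmission
summary recovers the scenario's designed split exactly: 12 of the 24
sponge-specific clusters were seeded into seawater at 1e-4 relative
abundance and all 12 were detected there (often in a single replicate);
the other 12 are called sponge-exclusive. Replicate structure is also
recovered: within-species Bray–Curtis at class level is ≈97 versus ≈47
for sponge-vs-seawater (`res$bray_curtis[["class"]]`).

The pipeline writes every table as TSV into `out_dir` (`qc_report.tsv`,
`assignments.tsv`, `otu_table_*.tsv`, `richness.tsv`, `rarefaction.tsv`,
`rank_abundance.tsv`, `braycurtis_<rank>.tsv`, `cluster_occurrence.tsv`,
`transmission.tsv`, `stage_counts.tsv`, plus the effective `config.txt`)
and is byte-for-byte deterministic given the configuration.

A command-line front end lives at `inst/cli/spongetag.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","spongetag.R",package="spongetag"))')" \
    simulate --out-dir scn --seed 1
Rscript ... pipeline --manifest scn/manifest.tsv --refdb scn/refdb.tsv --out-dir run
Rscript ... assign --tags scn/sp1_ad1.fasta --sample sp1_ad1 \
    --refdb scn/refdb.tsv --out assignments.tsv
```

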