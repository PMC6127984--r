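# adratio

Coverage-based assignment of nuclear genome scaffolds to autosomes, the Z
chromosome, or the W chromosome in ZW sex-determination systems (moths,
birds: males ZZ, females ZW).

## The idea

A shotgun library samples each genomic fragment in proportion to its copy
number in the sequenced individual. For scaffold *s* with mean depth *d*ₛₗ in
library *ℓ* and library mapped-read count *N*ₗ, define the standardized depth
*d̃*ₛₗ = 10⁶ *d*ₛₗ / *N*ₗ and, for a male/female pair (*m*, *f*), the
**AD-ratio**

&nbsp;&nbsp;&nbsp;&nbsp;*R*ₛ = *d̃*ₛₘ / *d̃*ₛf

with expectation **1** for autosomal scaffolds (2 copies in both sexes),
**2** for Z-linked scaffolds (ZZ vs. ZW), and **0** for W-linked scaffolds
(absent in males). The package computes the ratio per scaffold and per
male/female replicate pair, bands it into a provisional label
(log2-symmetric bands, configurable), and combines pairs into a final 5-way
annotation:

* `autosomal`, `Z`, `W` — all replicate pairs agree;
* `ambiguous` ("putatively Z-heterosomal") — pairs disagree: the ratio is
  not reproducible between biological replicates;
* `unannotated` — mean depth below 4X (raw coverage units, configurable) in
  one or several libraries.

Inputs are Popoolation2-style synchronized allele-count files (scaffold,
1-based position, reference base, per-library `A:T:C:G:N:del` counts), a
`.fai`-style scaffold length table, and a library metadata table with sexes,
mapped-read counts and replicate pairing. A synthetic ZW depth simulator
with negative-binomial noise generates all of these with a known truth
table, so the whole pipeline runs end to end with no external data. An
a-posteriori validation stage compares the blinded annotation against genes
of known autosomal/Z location.

## Worked example

```r
library(adratio)

spec <- sim_spec(n_autosomal = 50, n_z = 10, n_w = 5, length_bp = 10000,
                 coverage = 20, overdispersion = 0.2, seed = 1)
sim   <- simulate_depth(spec = spec)
depth <- sync_scaffold_depth(sim$sync, sim$index, sim$libraries)
ann   <- annotate_genome(depth)
summarize_partition(ann)
```

```
Assembly partition by depth-based annotation
                          final_label n_scaffolds total_mb
                            autosomal          47     0.47
                                    Z          10     0.10
 ambiguous (putatively Z-heterosomal)           0     0.00
                                    W           0     0.00
                          unannotated           8     0.08
total: 65 scaffolds, 0.65 Mb
```

All 10 true-Z scaffolds are recovered as `Z`; the 8 `unannotated` scaffolds
are the 5 W scaffolds (zero male coverage always fails the 4X filter — a
male-derived reference would contain no W sequence anyway) plus 3 scaffolds
the simulator placed in its low-coverage fraction. Per-scaffold ratios,
per-pair labels and depths are in `ann`; `write_annotation_table(ann, f)`
serializes them, `write_z_bed(ann, f)` exports the Z scaffolds as BED.

Validation against genes of known location:

```r
genes <- read_gene_table("genes.tsv")   # gene_id, scaffold_id, known_class
concordance_report(ann, genes)
#> strict concordance: 8/8 = 1.000
```

A command-line wrapper exposes the three stages:

```sh
Rscript inst/cli/adratio.R simulate --out fixture/ --seed 42
Rscript inst/cli/adratio.R annotate --sync fixture/depth.sync \
    --index fixture/scaffolds.fai --libraries fixture/libraries.tsv --out run
Rscript inst/cli/adratio.R validate --annotation run.annotation.tsv --genes genes.tsv
```

See `vignettes/adratio-methods.Rmd` for the model, the banding rules, the
simulator's assumptions, and known limitations.

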