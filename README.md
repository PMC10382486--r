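# petprofiler

Backbone torsion divergence and assay analytics for PET hydrolases.

Engineering a plastic-degrading enzyme typically changes its backbone very
little in Cartesian terms — homologs superpose to well under 1 Å — while
the functionally decisive changes concentrate in a handful of active-site
loops. `petprofiler` makes that signal visible by comparing homologous
structures **per residue in Ramachandran (φ/ψ) space**, where a remodeled
loop stands out sharply against an otherwise identical fold, and by
reducing the standard characterisation assays (thermal shift, DSC, HPLC,
pH-stat depolymerization) to reproducible numbers.

What it does:

* **Structure I/O** — PDB reading with altloc resolution, chain-break
  detection and MSE handling; writing per-residue values into the B-factor
  column for putty-style rendering.
* **Geometry** — φ/ψ/ω profiles; backbone reconstruction from internal
  coordinates (the inverse operation, used as a correctness oracle and
  synthetic-data generator).
* **Alignment** — global affine-gap alignment (BLOSUM62, 11/1) with a
  deterministic tie-break; percent-identity matrices.
* **Superposition** — Kabsch fitting with iterative outlier trimming and
  optional geometric re-pairing.
* **Divergence** — wrapped per-residue Ramachandran distance, region
  summaries, ensemble RMSF.
* **Assays** — Tm from melt-curve derivatives, DSC crystallinity, HPLC
  calibration, depolymerization extent, pH-stat titrant accounting.
* **Pipelines** — one-call runners writing TSV/CSV/PDB/JSON bundles with
  manifests; byte-identical reruns.

## Worked example

```r
library(petprofiler)

# a 30-residue helix and a variant with residues 10-14 remodeled
ref <- make_ideal_structure(30, "helix")
mut <- perturb_torsions(ref, residues = 10:14, sigma = 20, seed = 7)

aln <- global_align(extract_sequence(ref, "A"), extract_sequence(mut, "A"))
percent_identity(aln)
#> [1] 100

superpose_structures(mut, ref, aln)
#> <superposition: rmsd 1.3459 A over 30/30 pair(s)>

d <- divergence_profile(backbone_torsions(ref, "A"),
                        backbone_torsions(mut, "A"), aln)
round(d$distance[d$resno %in% 9:15], 2)
#> [1]  0.00 49.51 28.23 14.08  8.79 47.91  0.00

region_summary(d, data.frame(name = "loop", chain = "A",
                             start = 10, end = 14))
#>   name chain start end n    mean      max
#> 1 loop     A    10  14 5 29.7048 49.51298
```

Identical sequence, sub-1.5 Å RMSD — yet the divergence profile pinpoints
exactly the five remodeled residues. The assay side:

```r
fit_tm(simulate_melt_curve(tm = 66.8, seed = 1))
#> <tm_estimate: Tm 66.73 degC (derivative peak 164, window 5)>

crystallinity(50, 20)
#> [1] 21.41328

tc <- simulate_depolymerization()   # 3.75 g PET, 0.150 L, 94.1% plateau
tail(depolymerization_extent(tc), 1)
#>   time   extent
#>      12  94.07
```

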