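#!/usr/bin/env Rscript
# Optional, network-enabled benchmark: superposes the engineered hydrolase
# structure 7YM9 onto the homologs 5XJH, 4EB0 and 4CG1 and compares the
# resulting global CA RMSDs with the published values 0.69, 0.65 and 0.53 A
# (tolerance +/- 0.15 A; the source tool's exact correspondence and trimming
# settings are unspecified, so only agreement to that tolerance is expected).
#
# Requires internet access to fetch the PDB entries; it is NOT part of the
# offline test suite.
#
# Usage: Rscript scripts/accession_benchmark.R [download_dir]

suppressPackageStartupMessages(library(petprofiler))

args <- commandArgs(trailingOnly = TRUE)
dl_dir <- if (length(args) >= 1L) args[1L] else tempdir()

published <- c(`5xjh` = 0.69, `4eb0` = 0.65, `4cg1` = 0.53)
ids <- c("7ym9", names(published))

paths <- tryCatch(
  bio3d::get.pdb(ids, path = dl_dir, verbose = FALSE),
  error = function(e) stop("download failed (network required): ",
                           conditionMessage(e))
)
names(paths) <- ids

ref <- read_pdb(paths[["7ym9"]])
ch_ref <- structure_chains(ref)[1L]
seq_ref <- extract_sequence(ref, ch_ref)

for (id in names(published)) {
  cmp <- read_pdb(paths[[id]])
  ch_cmp <- structure_chains(cmp)[1L]
  aln <- global_align(extract_sequence(cmp, ch_cmp), seq_ref)
  fit <- superpose_structures(cmp, ref, aln, chain_a = ch_cmp,
                              chain_b = ch_ref, repair = TRUE)
  status <- if (abs(fit$rmsd - published[[id]]) <= 0.15) "OK" else "DEVIATES"
  cat(sprintf("7ym9 vs %s: rmsd %.2f A (published %.2f, %d/%d pairs) %s\n",
              id, fit$rmsd, published[[id]], fit$n_used, fit$n_initial,
              status))
}
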