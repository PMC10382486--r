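# End-to-end report runners: structure-comparison bundles (alignment,
# superposition, torsion divergence, region summary, annotated PDB) and
# assay report bundles. Outputs are deterministic for a fixed
# configuration (including the seed) and every run writes a JSON manifest
# sufficient to reproduce it.

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(path, stage, cfg, outputs) {
  manifest <- list(
    stage = stage,
    package = "petprofiler",
    version = as.character(utils::packageVersion("petprofiler")),
    config = cfg,
    config_hash = .config_hash(cfg),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

.as_structure <- function(x) {
  if (inherits(x, "pet_structure")) x else read_pdb(x)
}

#' Run a reference-vs-comparators structure comparison
#'
#' For each comparator: aligns the chain sequences globally, superposes the
#' comparator onto the reference on aligned CA atoms with outlier trimming,
#' computes both torsion profiles and the per-residue Ramachandran
#' divergence, optionally aggregates it over named regions, and writes a
#' TSV per pair plus a reference PDB with the divergence in the B-factor
#' column (for putty-style rendering). A JSON manifest records the
#' configuration and its hash. On error the partial outputs of the run are
#' removed.
#'
#' @param reference reference structure (path or `pet_structure`).
#' @param comparators named list/vector of comparator structures (paths or
#'   `pet_structure`s).
#' @param out_dir output directory (created if needed).
#' @param chain_ref,chain_cmp chain selections (defaults: first chain).
#' @param mode divergence mode, `"wrapped"` or `"unwrapped"`.
#' @param regions optional region table for [region_summary()].
#' @param trim_factor,max_iter superposition trimming controls.
#' @param seed recorded in the manifest (the comparison itself is
#'   deterministic).
#' @return Invisibly, a list per comparator with `alignment`,
#'   `superposition`, `divergence`, `regions`.
#' @export
run_structure_comparison <- function(reference, comparators, out_dir,
                                     chain_ref = NULL, chain_cmp = NULL,
                                     mode = "wrapped", regions = NULL,
                                     trim_factor = 2, max_iter = 5L,
                                     seed = 1L) {
  if (length(comparators) < 1L) stop("configuration error: no comparators")
  if (is.null(names(comparators)) || any(!nzchar(names(comparators)))) {
    names(comparators) <- paste0("comparator", seq_along(comparators))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  cfg <- list(reference = if (is.character(reference)) reference else "<object>",
              comparators = vapply(comparators, function(x) {
                if (is.character(x)) x else "<object>"
              }, character(1L)),
              chain_ref = chain_ref, chain_cmp = chain_cmp, mode = mode,
              trim_factor = trim_factor, max_iter = max_iter, seed = seed)

  run <- function() {
    ref <- .as_structure(reference)
    ch_ref <- chain_ref %||% structure_chains(ref)[1L]
    seq_ref <- extract_sequence(ref, ch_ref)
    tor_ref <- backbone_torsions(ref, ch_ref)
    results <- list()
    for (nm in names(comparators)) {
      cmp <- .as_structure(comparators[[nm]])
      ch_cmp <- chain_cmp %||% structure_chains(cmp)[1L]
      aln <- global_align(seq_ref, extract_sequence(cmp, ch_cmp))
      # mobile = comparator, target = reference
      sup <- superpose_structures(cmp, ref,
                                  .swap_map(aln), chain_a = ch_cmp,
                                  chain_b = ch_ref,
                                  trim_factor = trim_factor,
                                  max_iter = max_iter)
      tor_cmp <- backbone_torsions(cmp, ch_cmp)
      div <- divergence_profile(tor_ref, tor_cmp, aln, mode = mode)
      reg <- if (!is.null(regions)) region_summary(div, regions) else NULL

      div_path <- file.path(out_dir, paste0("divergence_", nm, ".tsv"))
      write_divergence_tsv(div, div_path)
      written <<- c(written, div_path)
      pdb_path <- file.path(out_dir, paste0("divergence_", nm, ".pdb"))
      write_annotated_pdb(ref, divergence_values(div), pdb_path)
      written <<- c(written, pdb_path)
      sup_path <- file.path(out_dir, paste0("superposition_", nm, ".json"))
      jsonlite::write_json(list(rotation = sup$rotation,
                                translation = sup$translation,
                                rmsd = sup$rmsd, n_used = sup$n_used,
                                n_initial = sup$n_initial),
                           sup_path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      written <<- c(written, sup_path)
      if (!is.null(reg)) {
        reg_path <- file.path(out_dir, paste0("regions_", nm, ".tsv"))
        utils::write.table(reg, reg_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <<- c(written, reg_path)
      }
      results[[nm]] <- list(alignment = aln, superposition = sup,
                            divergence = div, regions = reg)
    }
    man <- .write_manifest(file.path(out_dir, "manifest.json"),
                           "structure_comparison", cfg, basename(written))
    written <<- c(written, man)
    results
  }

  results <- tryCatch(run(), error = function(e) {
    unlink(written)
    stop("structure comparison failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(results)
}

# transpose an alignment map (A<->B)
.swap_map <- function(m) {
  structure(list(pairs = cbind(A = m$pairs[, 2L], B = m$pairs[, 1L]),
                 score = m$score, identity_fraction = m$identity_fraction,
                 seqA = m$seqB, seqB = m$seqA),
            class = "alignment_map")
}

#' Run an assay report
#'
#' Reduces any combination of assay inputs to result tables and writes them
#' as CSV plus a JSON manifest. At least one input must be configured.
#'
#' @param out_dir output directory.
#' @param melt_curves named list of melt-curve data frames
#'   (temperature/signal) for [fit_tm()].
#' @param dsc data frame with columns `sample`, `dHm`, `dHc` and optional
#'   `dHf` for [crystallinity()].
#' @param hplc list with elements `standards` and `samples` (and optional
#'   `dilution_factor`) for [calibrate_and_quantify()].
#' @param depoly named list of [product_time_course()] objects for
#'   [depolymerization_extent()].
#' @param titration list with `times`, `cumulative_volume`, `molarity` for
#'   [base_to_acid_equivalents()].
#' @param include_bhet passed to [depolymerization_extent()].
#' @param tm_window passed to [fit_tm()].
#' @param seed recorded in the manifest.
#' @return Invisibly, a list of result tables.
#' @export
run_assay_report <- function(out_dir, melt_curves = NULL, dsc = NULL,
                             hplc = NULL, depoly = NULL, titration = NULL,
                             include_bhet = FALSE, tm_window = 5L,
                             seed = 1L) {
  if (is.null(melt_curves) && is.null(dsc) && is.null(hplc) &&
      is.null(depoly) && is.null(titration)) {
    stop("configuration error: no assay inputs supplied")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  cfg <- list(melt_curves = names(melt_curves), dsc = !is.null(dsc),
              hplc = !is.null(hplc), depoly = names(depoly),
              titration = !is.null(titration), include_bhet = include_bhet,
              tm_window = tm_window, seed = seed)
  out <- list()

  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
    df
  }

  run <- function() {
    if (!is.null(melt_curves)) {
      tm_tab <- do.call(rbind, lapply(names(melt_curves), function(nm) {
        est <- fit_tm(melt_curves[[nm]], window = tm_window)
        data.frame(sample = nm, tm = est$tm,
                   derivative_peak = est$derivative_peak_value)
      }))
      out$tm <<- emit(tm_tab, "tm")
    }
    if (!is.null(dsc)) {
      dHf <- if ("dHf" %in% names(dsc)) dsc$dHf else 140.1
      dsc_tab <- data.frame(sample = dsc$sample,
                            crystallinity = mapply(crystallinity, dsc$dHm,
                                                   dsc$dHc, dHf))
      out$crystallinity <<- emit(dsc_tab, "crystallinity")
    }
    if (!is.null(hplc)) {
      quant <- calibrate_and_quantify(hplc$standards, hplc$samples,
                                      hplc$dilution_factor %||% 1)
      out$concentrations <<- emit(quant, "concentrations")
    }
    if (!is.null(depoly)) {
      dep_tab <- do.call(rbind, lapply(names(depoly), function(nm) {
        e <- depolymerization_extent(depoly[[nm]], include_bhet = include_bhet)
        cbind(sample = nm, e)
      }))
      out$extent <<- emit(dep_tab, "extent")
    }
    if (!is.null(titration)) {
      eq <- base_to_acid_equivalents(titration$times,
                                     titration$cumulative_volume,
                                     titration$molarity)
      out$equivalents <<- emit(eq, "equivalents")
    }
    man <- .write_manifest(file.path(out_dir, "manifest.json"),
                           "assay_report", cfg, basename(written))
    written <<- c(written, man)
    out
  }

  out <- tryCatch(run(), error = function(e) {
    unlink(written)
    stop("assay report failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(out)
}
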