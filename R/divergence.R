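# Backbone-torsion divergence between homologous structures and ensemble
# fluctuation (RMSF) profiles.
#
# The per-residue statistic is the Euclidean distance between the two
# Ramachandran points (phi, psi) of each aligned residue pair. Because phi
# and psi are periodic, the default "wrapped" mode takes each angle
# difference as its minimal image in [-180, 180]; the "unwrapped" mode
# takes plain differences (which inflates divergence across the +/-180
# seam and is retained only for literal reproduction of naive pipelines).
# omega is profiled by the geometry module but excluded from the distance.

#' Minimal-image angle difference
#'
#' Signed difference `a - b` modulo 360, mapped into \[-180, 180\].
#'
#' @param a,b angles in degrees (vectorised).
#' @return Difference in degrees.
#' @examples
#' wrapped_delta(170, -170)  # -20
#' @export
wrapped_delta <- function(a, b) {
  d <- (a - b) %% 360
  d[!is.na(d) & d > 180] <- d[!is.na(d) & d > 180] - 360
  d
}

#' Per-residue Ramachandran divergence between two torsion profiles
#'
#' For each aligned residue pair with phi and psi defined on both sides,
#' computes `distance = sqrt(dphi^2 + dpsi^2)` with the angle differences
#' taken per `mode`. Pairs with any undefined angle are retained with
#' `defined = FALSE`; unaligned residues are absent.
#'
#' @param tA,tB `torsion_profile` objects (see [backbone_torsions()]); the
#'   row order defines the sequence positions the alignment refers to.
#' @param map `alignment_map` between the two sequences, or `NULL` for the
#'   identity correspondence (requires equal lengths).
#' @param mode `"wrapped"` (default) or `"unwrapped"`.
#' @return Data frame of class `divergence_profile`: `chain`, `resno`,
#'   `insert`, `key` (reference residue), `key_b` (partner), `dphi`,
#'   `dpsi`, `distance` (degrees), `defined`.
#' @export
divergence_profile <- function(tA, tB, map = NULL,
                               mode = c("wrapped", "unwrapped")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tA, "torsion_profile"), inherits(tB, "torsion_profile"))
  if (is.null(map)) {
    if (nrow(tA) != nrow(tB)) {
      stop("identity correspondence requires equal-length profiles")
    }
    pairs <- cbind(A = seq_len(nrow(tA)), B = seq_len(nrow(tB)))
  } else {
    stopifnot(inherits(map, "alignment_map"))
    pairs <- map$pairs
    if (nrow(pairs) > 0L &&
        (max(pairs[, 1L]) > nrow(tA) || max(pairs[, 2L]) > nrow(tB))) {
      stop("alignment map indices exceed profile lengths")
    }
  }
  ia <- pairs[, 1L]; ib <- pairs[, 2L]
  delta <- function(x, y) {
    if (mode == "wrapped") wrapped_delta(x, y) else x - y
  }
  dphi <- delta(tA$phi[ia], tB$phi[ib])
  dpsi <- delta(tA$psi[ia], tB$psi[ib])
  defined <- !is.na(dphi) & !is.na(dpsi)
  dist <- ifelse(defined, sqrt(dphi^2 + dpsi^2), NA_real_)
  out <- data.frame(chain = tA$chain[ia], resno = tA$resno[ia],
                    insert = tA$insert[ia], key = tA$key[ia],
                    key_b = tB$key[ib],
                    dphi = dphi, dpsi = dpsi, distance = dist,
                    defined = defined, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("divergence_profile", "data.frame")
  out
}

#' Summarise divergence over named residue regions
#'
#' Aggregates a divergence profile over user-defined residue ranges (e.g.
#' the connecting loops that form a hydrolase active site). Statistics use
#' defined entries only; an empty region reports `n = 0` with `NA`
#' statistics.
#'
#' @param d a `divergence_profile`.
#' @param regions data frame with columns `name`, `chain`, `start`, `end`
#'   (author residue numbers, inclusive).
#' @return Data frame: `name`, `chain`, `start`, `end`, `n`, `mean`, `max`.
#' @export
region_summary <- function(d, regions) {
  stopifnot(inherits(d, "divergence_profile"))
  req <- c("name", "chain", "start", "end")
  if (!all(req %in% names(regions))) {
    stop("regions must have columns: ", paste(req, collapse = ", "))
  }
  if (any(regions$start > regions$end)) stop("region start exceeds end")
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    sel <- d$chain == r$chain & d$resno >= r$start & d$resno <= r$end &
      d$defined
    v <- d$distance[sel]
    data.frame(name = r$name, chain = r$chain, start = r$start, end = r$end,
               n = length(v),
               mean = if (length(v) > 0L) mean(v) else NA_real_,
               max = if (length(v) > 0L) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Divergence profile as a named per-residue value vector
#'
#' Convenience for [write_annotated_pdb()]: defined distances keyed by the
#' reference residue key (undefined residues omitted, hence written 0.00).
#'
#' @param d a `divergence_profile`.
#' @return Named numeric vector.
#' @export
divergence_values <- function(d) {
  stopifnot(inherits(d, "divergence_profile"))
  stats::setNames(d$distance[d$defined], d$key[d$defined])
}

#' Write a divergence profile as TSV
#' @param d a `divergence_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_divergence_tsv <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE)
  invisible(path)
}

#' Per-residue root-mean-square fluctuation over an ensemble
#'
#' `rmsf_i = sqrt(mean_f |r_i(f) - rbar_i|^2)` where `rbar_i` is the mean
#' position of atom i over frames (after optional rigid-body fitting of
#' each frame to the reference on the full selection).
#'
#' @param frames list of n x 3 coordinate matrices (one per frame, same
#'   atom selection and order), or a 3-dimensional array n x 3 x n_frames.
#' @param reference n x 3 reference coordinates (default: first frame).
#' @param presuperpose Kabsch-fit each frame to the reference before
#'   averaging (default `TRUE`, the common practice for trajectory
#'   analysis).
#' @return Data frame of class `fluctuation_profile`: `index`, `rmsf`
#'   (Angstrom), with attribute `n_frames`.
#' @export
rmsf <- function(frames, reference = NULL, presuperpose = TRUE) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(k) frames[, , k])
  }
  if (!is.list(frames) || length(frames) < 2L) stop("need at least 2 frames")
  n <- nrow(frames[[1L]])
  if (n < 3L) stop("selection must contain at least 3 atoms")
  if (!all(vapply(frames, function(f) nrow(f) == n && ncol(f) == 3L,
                  logical(1L)))) {
    stop("all frames must share the same n x 3 selection")
  }
  reference <- reference %||% frames[[1L]]
  if (nrow(reference) != n) stop("reference selection length mismatch")

  keys <- rownames(frames[[1L]])
  if (presuperpose) {
    frames <- lapply(frames, function(f) {
      fit <- kabsch(f, reference)
      f %*% t(fit$rotation) + matrix(fit$translation, n, 3L, byrow = TRUE)
    })
  }
  nf <- length(frames)
  mean_pos <- Reduce(`+`, frames) / nf
  ss <- Reduce(`+`, lapply(frames, function(f) rowSums((f - mean_pos)^2)))
  out <- data.frame(index = seq_len(n), rmsf = sqrt(ss / nf))
  if (!is.null(keys)) out$key <- keys
  attr(out, "n_frames") <- nf
  class(out) <- c("fluctuation_profile", "data.frame")
  out
}

#' Read a CA coordinate ensemble from a multi-model PDB file
#'
#' @param path multi-model PDB file.
#' @param chain_id chain to select (default: first).
#' @return List of n x 3 CA coordinate matrices, one per model, with
#'   residue keys as rownames.
#' @export
read_ensemble <- function(path, chain_id = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  lapply(seq_len(n_models), function(k) {
    s <- read_pdb(path, model_index = k)
    ch <- chain_id %||% structure_chains(s)[1L]
    ca_coords(s, ch)
  })
}
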