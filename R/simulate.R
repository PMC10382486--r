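# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: ideal backbones, loop-torsion perturbed homologs,
# Gaussian coordinate ensembles, two-state melt curves and logistic
# depolymerization time courses. Every generator is a deterministic
# function of its arguments including the seed; the caller's RNG state is
# never disturbed.

.IDEAL_TORSIONS <- list(helix = c(phi = -57, psi = -47),
                        strand = c(phi = -139, psi = 135))

#' Ideal secondary-structure backbone
#'
#' Builds an n-residue backbone with canonical torsions (helix:
#' phi = -57, psi = -47; strand: phi = -139, psi = 135; omega = 180)
#' through [build_backbone()].
#'
#' @param n residue count, >= 2.
#' @param kind `"helix"` or `"strand"`.
#' @return A `pet_structure`.
#' @export
make_ideal_structure <- function(n, kind = c("helix", "strand")) {
  kind <- match.arg(kind)
  if (n < 2L) stop("need at least 2 residues")
  t0 <- .IDEAL_TORSIONS[[kind]]
  build_backbone(data.frame(phi = rep(t0[["phi"]], n),
                            psi = rep(t0[["psi"]], n),
                            omega = rep(180, n)))
}

#' Perturb backbone torsions at selected residues
#'
#' Measures the torsion profile of (the first chain of) `s`, adds
#' independent Gaussian offsets with standard deviation `sigma` to the phi
#' and psi of the named residues, and rebuilds the backbone with idealised
#' geometry. Intended for synthetic backbones built by [build_backbone()]
#' (for which a zero perturbation reproduces the input coordinates
#' exactly); torsion perturbations are strictly local in torsion space, so
#' the Ramachandran divergence against the unperturbed structure is nonzero
#' only at the perturbed residues.
#'
#' @param s a `pet_structure` with a single fully defined chain.
#' @param residues author residue numbers to perturb.
#' @param sigma torsion offset standard deviation, degrees, >= 0.
#' @param seed RNG seed.
#' @return The rebuilt `pet_structure`.
#' @export
perturb_torsions <- function(s, residues, sigma, seed = 1L) {
  stopifnot(inherits(s, "pet_structure"), sigma >= 0)
  chain <- structure_chains(s)[1L]
  tor <- backbone_torsions(s, chain)
  idx <- match(residues, tor$resno)
  if (anyNA(idx)) {
    stop("residues not in structure: ",
         paste(residues[is.na(idx)], collapse = ", "))
  }
  offsets <- with_seed(seed, matrix(stats::rnorm(2L * length(idx), 0, sigma),
                                    ncol = 2L))
  tor$phi[idx] <- wrap_angle(tor$phi[idx] + offsets[, 1L])
  tor$psi[idx] <- wrap_angle(tor$psi[idx] + offsets[, 2L])
  build_backbone(tor[, c("phi", "psi", "omega")], chain = chain)
}

#' Gaussian coordinate ensemble around a reference backbone
#'
#' Each frame is the reference CA coordinates plus independent Gaussian
#' noise with per-residue standard deviation `sigma_profile` applied to
#' each coordinate. The noise is isotropic and frame-independent (no
#' autocorrelation) -- sufficient to exercise RMSF analysis, deliberately
#' simpler than real trajectory dynamics.
#'
#' @param s a `pet_structure` (its first chain's CA atoms are the
#'   selection) or an n x 3 coordinate matrix.
#' @param sigma_profile per-residue noise SD in Angstrom (scalar or length
#'   n), >= 0.
#' @param n_frames number of frames, >= 2.
#' @param seed RNG seed.
#' @return List of n x 3 frame matrices with attribute `reference`.
#' @export
make_ensemble <- function(s, sigma_profile, n_frames, seed = 1L) {
  ref <- if (inherits(s, "pet_structure")) {
    ca_coords(s, structure_chains(s)[1L])
  } else {
    as.matrix(s)
  }
  if (anyNA(ref)) stop("reference CA selection contains missing atoms")
  n <- nrow(ref)
  if (n_frames < 2L) stop("need at least 2 frames")
  if (length(sigma_profile) == 1L) sigma_profile <- rep(sigma_profile, n)
  if (length(sigma_profile) != n || any(sigma_profile < 0)) {
    stop("sigma_profile must be nonnegative, scalar or length n")
  }
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(k) {
    ref + matrix(stats::rnorm(3L * n, 0, sigma_profile), n, 3L)
  }))
  attr(frames, "reference") <- ref
  frames
}

#' Write an ensemble as a multi-model PDB file
#'
#' Frames are written as CA-only MODEL/ENDMDL records readable by
#' [read_ensemble()].
#'
#' @param frames list of n x 3 coordinate matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(frames, path) {
  n <- nrow(frames[[1L]])
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    f <- frames[[k]]
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), seq_len(n), f[, 1L], f[, 2L], f[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Simulate a two-state thermal-shift melt curve
#'
#' Fluorescence model: linear pre- and post-transition baselines mixed by a
#' logistic unfolded fraction centred at `tm` with width `slope`, plus
#' Gaussian noise. The derivative maximum of the noiseless curve (flat
#' baselines) lies at `tm`.
#'
#' @param tm transition midpoint, deg C.
#' @param slope logistic width parameter, deg C, > 0. Default 1.5 deg C
#'   gives a 10-90% transition of about 6.6 deg C, typical of dye-based
#'   protein unfolding curves.
#' @param pre_level,pre_drift folded baseline intercept and slope (signal
#'   units, units/deg C).
#' @param post_level,post_drift unfolded baseline intercept and slope.
#' @param noise_sd Gaussian noise SD in signal units; the default is 2% of
#'   the baseline separation.
#' @param grid temperature grid, deg C (default 25-99 in 0.5 steps, the
#'   usual real-time-PCR scan range).
#' @param seed RNG seed.
#' @return Data frame `temperature`, `signal` of class `melt_curve`.
#' @export
simulate_melt_curve <- function(tm = 66.8, slope = 1.5,
                                pre_level = 1000, pre_drift = 0,
                                post_level = 2000, post_drift = 0,
                                noise_sd = 0.02 * abs(post_level - pre_level),
                                grid = seq(25, 99, by = 0.5), seed = 1L) {
  if (slope <= 0) stop("slope must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  f <- 1 / (1 + exp(-(grid - tm) / slope))
  pre <- pre_level + pre_drift * (grid - grid[1L])
  post <- post_level + post_drift * (grid - grid[1L])
  signal <- pre * (1 - f) + post * f
  if (noise_sd > 0) {
    signal <- signal + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  }
  out <- data.frame(temperature = grid, signal = signal)
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Simulate a logistic PET depolymerization time course
#'
#' The total depolymerized fraction follows a logistic in time scaled to
#' `plateau`; product moles are allocated to TPA/MHET/BHET by `split`.
#' Defaults reproduce the bench-scale pH-stat bioreactor conditions used to
#' characterise engineered PET hydrolases: 3.75 g PET in 0.150 L, half of
#' the final conversion reached at 4 h, and a 94.1% plateau approached by
#' 12 h.
#'
#' @param pet_load PET charge, grams.
#' @param volume reaction volume, litres.
#' @param plateau final depolymerized fraction in \[0, 1\].
#' @param rate logistic rate constant, 1/h.
#' @param midpoint time of half-plateau conversion, hours.
#' @param split fractions of product moles as c(tpa, mhet, bhet), summing
#'   to 1.
#' @param times sampling times, hours.
#' @param noise_sd relative Gaussian noise on product amounts (0 = exact).
#' @param seed RNG seed.
#' @return A [product_time_course()].
#' @export
simulate_depolymerization <- function(pet_load = 3.75, volume = 0.150,
                                      plateau = 0.941, rate = 1.0,
                                      midpoint = 4,
                                      split = c(tpa = 0.55, mhet = 0.45,
                                                bhet = 0),
                                      times = seq(0, 12, by = 0.5),
                                      noise_sd = 0, seed = 1L) {
  if (plateau < 0 || plateau > 1) stop("plateau must lie in [0, 1]")
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (any(split < 0)) stop("split fractions must be nonnegative")
  frac <- plateau / (1 + exp(-rate * (times - midpoint)))
  total_mol <- frac * pet_load / PET_REPEAT_UNIT_MASS
  amounts <- outer(total_mol, split)
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(length(amounts), 1, noise_sd),
                                    nrow = nrow(amounts)))
    amounts <- pmax(amounts * noise, 0)
  }
  product_time_course(times, tpa = amounts[, 1L], mhet = amounts[, 2L],
                      bhet = amounts[, 3L], pet_load = pet_load,
                      volume = volume)
}
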