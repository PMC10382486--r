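# Backbone dihedral geometry: torsion measurement from coordinates and
# reconstruction of coordinates from torsions (internal-coordinate
# extension, a.k.a. NeRF). The measure/build pair is exactly inverse on
# torsion space, which the test suite exploits as its main oracle.

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: the angle by which the p1-p2 bond must be rotated
#' about the p2-p3 axis to eclipse p3-p4, clockwise positive when viewed
#' from p2 towards p3. Result in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @param tol collinearity tolerance: the dihedral is undefined when either
#'   plane normal has squared norm below `tol` times the product of the
#'   segment norms.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4, tol = 1e-9) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) == 0 || vnorm(b2) == 0 || vnorm(b3) == 0) {
    stop("undefined dihedral: consecutive points coincide")
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < tol * vnorm(b1) * vnorm(b2) ||
      vnorm(n2) < tol * vnorm(b2) * vnorm(b3)) {
    stop("undefined dihedral: collinear points")
  }
  b2h <- b2 / vnorm(b2)
  ang <- atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Default idealised backbone geometry
#'
#' Standard bond lengths and angles (Engh–Huber-like values) used when
#' rebuilding backbones from torsions.
#'
#' @return List with bond lengths `b_nca`, `b_cac`, `b_cn` (Angstrom) and
#'   bond angles `a_ncac`, `a_cacn`, `a_cnca` (degrees).
#' @export
backbone_geometry_params <- function() {
  list(b_nca = 1.458, b_cac = 1.525, b_cn = 1.329,
       a_ncac = 111.2, a_cacn = 116.2, a_cnca = 121.7)
}

.check_geometry_params <- function(p) {
  len <- c(p$b_nca, p$b_cac, p$b_cn)
  ang <- c(p$a_ncac, p$a_cacn, p$a_cnca)
  if (any(!is.finite(len)) || any(len <= 1) || any(len >= 2)) {
    stop("degenerate geometry: bond lengths must lie in (1, 2) Angstrom")
  }
  if (any(!is.finite(ang)) || any(ang <= 90) || any(ang >= 150)) {
    stop("degenerate geometry: bond angles must lie in (90, 150) degrees")
  }
  invisible(p)
}

#' Phi/psi/omega torsion profile of a chain
#'
#' phi(i) = dihedral(C(i-1), N(i), CA(i), C(i));
#' psi(i) = dihedral(N(i), CA(i), C(i), N(i+1));
#' omega(i) = dihedral(CA(i), C(i), N(i+1), CA(i+1)).
#' An angle is `NA` (undefined) at chain termini, across flagged chain
#' breaks, or where a required atom is missing.
#'
#' @param s a `pet_structure`.
#' @param chain_id chain identifier.
#' @return Data frame of class `torsion_profile` with columns `chain`,
#'   `resno`, `insert`, `resid`, `key`, `phi`, `psi`, `omega` (degrees).
#' @export
backbone_torsions <- function(s, chain_id) {
  stopifnot(inherits(s, "pet_structure"))
  res <- s$residues[s$residues$chain == chain_id, , drop = FALSE]
  if (nrow(res) == 0L) stop("no such chain: '", chain_id, "'")
  n <- nrow(res)
  N <- t(vapply(res$key, function(k) .atom_xyz(s$atoms, k, "N"), numeric(3L)))
  CA <- t(vapply(res$key, function(k) .atom_xyz(s$atoms, k, "CA"), numeric(3L)))
  C <- t(vapply(res$key, function(k) .atom_xyz(s$atoms, k, "C"), numeric(3L)))
  brk <- res$chain_break_after

  safe_dihedral <- function(a, b, c_, d) {
    if (anyNA(a) || anyNA(b) || anyNA(c_) || anyNA(d)) return(NA_real_)
    tryCatch(dihedral(a, b, c_, d), error = function(e) NA_real_)
  }

  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L && !brk[i - 1L]) {
      phi[i] <- safe_dihedral(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    }
    if (i < n && !brk[i]) {
      psi[i] <- safe_dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
      omega[i] <- safe_dihedral(CA[i, ], C[i, ], N[i + 1L, ], CA[i + 1L, ])
    }
  }
  out <- data.frame(chain = res$chain, resno = res$resno, insert = res$insert,
                    resid = res$resid, key = res$key,
                    phi = phi, psi = psi, omega = omega,
                    stringsAsFactors = FALSE)
  class(out) <- c("torsion_profile", "data.frame")
  out
}

# Place atom D given the three previous atoms A, B, C, the C-D bond length,
# the B-C-D bond angle (degrees) and the A-B-C-D torsion (degrees), such
# that dihedral(A, B, C, D) == torsion exactly.
place_atom <- function(A, B, C, length, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(ph),
          length * sin(th) * sin(ph))
  bc <- (C - B) / vnorm(C - B)
  ab <- (B - A) / vnorm(B - A)
  n <- cross3(ab, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  C + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Build an idealised backbone from a torsion list
#'
#' Places N/CA/C atoms by sequential internal-coordinate extension from a
#' canonical frame (N1 at the origin, CA1 on +x, C1 in the xy-plane) using
#' idealised bond lengths and angles. `phi[1]`, `psi[n]` and `omega[n]` are
#' not used (they are undefined at the termini).
#'
#' @param torsions data frame or matrix with columns/names `phi`, `psi`,
#'   `omega` (degrees), one row per residue; `n >= 2`.
#' @param params geometry parameters, see [backbone_geometry_params()].
#' @param chain chain identifier to assign.
#' @param resid three-letter residue name to assign (sequence content is
#'   irrelevant to the geometry).
#' @return A `pet_structure` with residues numbered 1..n.
#' @export
build_backbone <- function(torsions, params = backbone_geometry_params(),
                           chain = "A", resid = "ALA") {
  .check_geometry_params(params)
  tor <- as.data.frame(torsions)
  if (!all(c("phi", "psi", "omega") %in% names(tor))) {
    stop("torsions must have columns phi, psi, omega")
  }
  n <- nrow(tor)
  if (n < 2L) stop("need at least 2 residues")
  used <- c(tor$phi[-1L], tor$psi[-n], tor$omega[-n])
  if (anyNA(used) || any(!is.finite(used))) {
    stop("interior torsions must be finite")
  }
  if (any(used <= -180 | used > 180)) {
    stop("torsions must lie in (-180, 180] degrees")
  }

  N <- CA <- C <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(params$b_nca, 0, 0)
  a <- (180 - params$a_ncac) * pi / 180
  C[1L, ] <- CA[1L, ] + params$b_cac * c(cos(a), sin(a), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                              params$b_cn, params$a_cacn, tor$psi[i])
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                               params$b_nca, params$a_cnca, tor$omega[i])
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                              params$b_cac, params$a_ncac, tor$phi[i + 1L])
  }

  atoms <- data.frame(
    chain = chain,
    resno = rep(seq_len(n), each = 3L),
    insert = "",
    resid = resid,
    elety = rep(c("N", "CA", "C"), n),
    x = as.vector(rbind(N[, 1L], CA[, 1L], C[, 1L])),
    y = as.vector(rbind(N[, 2L], CA[, 2L], C[, 2L])),
    z = as.vector(rbind(N[, 3L], CA[, 3L], C[, 3L])),
    o = 1, b = 0, stringsAsFactors = FALSE
  )
  new_structure(atoms, id = sprintf("built backbone (%d residues)", n))
}

#' Export a torsion profile as TSV
#'
#' Columns: chain, resno, insert, resid, phi, psi, omega; undefined angles
#' are written as empty fields.
#'
#' @param profile a `torsion_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_torsion_tsv <- function(profile, path) {
  out <- profile[, c("chain", "resno", "insert", "resid",
                     "phi", "psi", "omega")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
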