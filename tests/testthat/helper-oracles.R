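# Independent oracles and fixture builders used across the suite.

# Quaternion-characteristic (Horn) RMSD: computes the optimal-superposition
# RMSD from the largest eigenvalue of the 4x4 key matrix, without ever
# constructing a rotation. Independent of the SVD route used by kabsch().
quaternion_rmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  S <- t(Pc) %*% Qc
  K <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]
  ), 4L, 4L, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * lambda) / n))
}

# Exhaustive enumeration of all global alignments under affine gap costs
# (gap of length L costs open + L * extend); returns the maximum score.
# Exponential-time by construction -- usable only for short sequences.
enum_align_score <- function(a, b, mat = petprofiler::blosum62(),
                             open = 11, extend = 1) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  na <- length(a); nb <- length(b)
  ps <- function(x, y) {
    if (!(x %in% rownames(mat)) || !(y %in% colnames(mat))) return(0)
    mat[x, y]
  }
  rec <- function(i, j, prev) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      best <- max(best, ps(a[i], b[j]) + rec(i + 1L, j + 1L, 1L))
    }
    if (i <= na) {
      cost <- if (prev == 2L) extend else open + extend
      best <- max(best, -cost + rec(i + 1L, j, 2L))
    }
    if (j <= nb) {
      cost <- if (prev == 3L) extend else open + extend
      best <- max(best, -cost + rec(i, j + 1L, 3L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Random proper rotation matrix (QR of a Gaussian matrix, det forced +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

apply_rigid <- function(X, R, t) X %*% t(R) + matrix(t, nrow(X), 3L, byrow = TRUE)

# Fixed-column PDB ATOM/HETATM line (wwPDB v3.3 layout).
pdb_line <- function(record, eleno, elety, alt, resid, chain, resno, icode,
                     x, y, z, occ = 1, b = 0) {
  name_field <- if (nchar(elety) < 4L) sprintf(" %-3s", elety) else elety
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, eleno, name_field, alt, resid, chain, resno, icode,
          x, y, z, occ, b)
}

# Three-residue backbone fixture written as PDB text. Coordinates come from
# an ideal helix build, so bond lengths and the C-N linkage are realistic.
# Options inject an altloc pair on residue 2's N, a chain break before the
# last residue, or a selenomethionine (MSE) HETATM residue.
write_fixture_pdb <- function(path, resids = c("ALA", "CYS", "ASP"),
                              altloc = FALSE, break_gap = FALSE,
                              mse = FALSE, shuffle_altloc = FALSE) {
  s <- make_ideal_structure(length(resids), "helix")
  at <- s$atoms
  at$resid <- resids[at$resno]
  if (mse) at$resid[at$resno == 2L] <- "MSE"
  if (break_gap) {
    at[at$resno == length(resids), c("x", "y", "z")] <-
      at[at$resno == length(resids), c("x", "y", "z")] + 50
  }
  lines <- character(0)
  eleno <- 0L
  for (i in seq_len(nrow(at))) {
    eleno <- eleno + 1L
    record <- if (at$resid[i] == "MSE") "HETATM" else "ATOM"
    if (altloc && at$resno[i] == 2L && at$elety[i] == "N") {
      l1 <- pdb_line(record, eleno, "N", "A", at$resid[i], "A", at$resno[i],
                     " ", at$x[i], at$y[i], at$z[i], occ = 0.6)
      l2 <- pdb_line(record, eleno + 1L, "N", "B", at$resid[i], "A",
                     at$resno[i], " ", at$x[i] + 0.4, at$y[i], at$z[i],
                     occ = 0.4)
      eleno <- eleno + 1L
      lines <- c(lines, if (shuffle_altloc) c(l2, l1) else c(l1, l2))
    } else {
      lines <- c(lines, pdb_line(record, eleno, at$elety[i], " ",
                                 at$resid[i], "A", at$resno[i], " ",
                                 at$x[i], at$y[i], at$z[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
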