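# Rigid-body superposition: Kabsch least-squares fitting, alignment-guided
# CA correspondence with iterative outlier trimming, and coordinate
# transforms.

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation R (det +1; reflections excluded) and
#' translation t minimising the (optionally weighted) least-squares
#' deviation of `R p + t` from `q` over paired points.
#'
#' @param P,Q n x 3 matrices of paired coordinates (P is mobile, Q is the
#'   target); n >= 3 and not collinear.
#' @param weights optional nonnegative weights (default uniform). Weights
#'   affect the fit; the reported RMSD is the unweighted root mean square
#'   of the residual pair distances.
#' @return Object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom), `n_used`, `n_initial`.
#' @export
kabsch <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L) {
    stop("P and Q must be equal-size n x 3 matrices")
  }
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 point pairs")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be nonnegative with positive sum")
  }
  w <- weights / sum(weights)
  pbar <- colSums(P * w)
  qbar <- colSums(Q * w)
  Pc <- sweep(P, 2L, pbar)
  Qc <- sweep(Q, 2L, qbar)
  if (qr(Pc)$rank < 2L || qr(Qc)$rank < 2L) {
    stop("degenerate (collinear) point configuration")
  }
  H <- t(Pc * w) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- qbar - as.vector(R %*% pbar)
  resid <- Q - (P %*% t(R) + matrix(tr, n, 3L, byrow = TRUE))
  rmsd <- sqrt(mean(rowSums(resid^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_used = n, n_initial = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.4f A over %d/%d pair(s)>\n",
              x$rmsd, x$n_used, x$n_initial))
  invisible(x)
}

# longest strictly-increasing subsequence (indices), O(n log n)
.lis <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- integer(0); tails_idx <- integer(0); prev <- integer(n)
  for (i in seq_len(n)) {
    pos <- findInterval(x[i] - 1L, x[tails_idx]) + 1L
    prev[i] <- if (pos > 1L) tails_idx[pos - 1L] else 0L
    tails_idx[pos] <- i
    if (pos > length(tails)) tails <- c(tails, x[i]) else tails[pos] <- x[i]
    length(tails_idx) <- length(tails)
  }
  out <- integer(0); k <- tails_idx[length(tails_idx)]
  while (k > 0L) { out <- c(k, out); k <- prev[k] }
  out
}

#' Superpose two structures on aligned CA atoms with outlier trimming
#'
#' Seeds the CA correspondence from a sequence alignment, fits by
#' [kabsch()], then iteratively drops pairs whose post-fit distance exceeds
#' `trim_factor` times the current RMSD and refits, until no pair is
#' dropped or `max_iter` is reached. With `repair = TRUE` the
#' correspondence is additionally re-derived after each fit by pairing each
#' mobile CA with its nearest target CA within `repair_cutoff` Angstrom
#' (order-preserving), which makes the final fit effectively independent of
#' the initial sequence alignment.
#'
#' @param A mobile `pet_structure`.
#' @param B target `pet_structure`.
#' @param map `alignment_map` between the chain sequences (from
#'   [global_align()] on [extract_sequence()] output).
#' @param chain_a,chain_b chains to fit (defaults: first chain of each).
#' @param trim_factor trimming multiplier (default 2; `Inf` disables
#'   trimming).
#' @param max_iter maximum refit iterations.
#' @param repair logical; re-derive the correspondence geometrically after
#'   each fit.
#' @param repair_cutoff distance cutoff (Angstrom) for geometric
#'   re-pairing.
#' @return A `superposition` (rotation/translation map A onto B) with
#'   `n_initial` the seeded pair count and `n_used` the pairs in the final
#'   fit.
#' @export
superpose_structures <- function(A, B, map, chain_a = NULL, chain_b = NULL,
                                 trim_factor = 2, max_iter = 5L,
                                 repair = FALSE, repair_cutoff = 5) {
  stopifnot(inherits(A, "pet_structure"), inherits(B, "pet_structure"),
            inherits(map, "alignment_map"))
  if (trim_factor <= 0) stop("trim_factor must be positive")
  chain_a <- chain_a %||% structure_chains(A)[1L]
  chain_b <- chain_b %||% structure_chains(B)[1L]
  caA <- ca_coords(A, chain_a)
  caB <- ca_coords(B, chain_b)
  pairs <- map$pairs
  ok <- pairs[, 1L] <= nrow(caA) & pairs[, 2L] <= nrow(caB)
  pairs <- pairs[ok, , drop = FALSE]
  keep <- stats::complete.cases(caA[pairs[, 1L], , drop = FALSE]) &
    stats::complete.cases(caB[pairs[, 2L], , drop = FALSE])
  pairs <- pairs[keep, , drop = FALSE]
  n_initial <- nrow(pairs)
  if (n_initial < 3L) stop("fewer than 3 usable CA pairs")

  cur <- pairs
  fit <- NULL
  for (iter in seq_len(max(1L, max_iter))) {
    fit <- kabsch(caA[cur[, 1L], , drop = FALSE],
                  caB[cur[, 2L], , drop = FALSE])
    if (repair) {
      moved <- caA %*% t(fit$rotation) +
        matrix(fit$translation, nrow(caA), 3L, byrow = TRUE)
      cand <- t(vapply(seq_len(nrow(moved)), function(i) {
        if (anyNA(moved[i, ])) return(c(NA_real_, NA_real_))
        d2 <- rowSums(sweep(caB, 2L, moved[i, ])^2)
        j <- which.min(d2)
        c(j, sqrt(d2[j]))
      }, numeric(2L)))
      sel <- which(!is.na(cand[, 2L]) & cand[, 2L] <= repair_cutoff)
      if (length(sel) >= 3L) {
        mono <- sel[.lis(as.integer(cand[sel, 1L]))]
        if (length(mono) >= 3L) {
          cur2 <- cbind(A = mono, B = as.integer(cand[mono, 1L]))
          fit2 <- kabsch(caA[cur2[, 1L], , drop = FALSE],
                         caB[cur2[, 2L], , drop = FALSE])
          cur <- cur2
          fit <- fit2
        }
      }
    }
    if (!is.finite(trim_factor)) break
    moved <- caA[cur[, 1L], , drop = FALSE] %*% t(fit$rotation) +
      matrix(fit$translation, nrow(cur), 3L, byrow = TRUE)
    d <- sqrt(rowSums((caB[cur[, 2L], , drop = FALSE] - moved)^2))
    keep <- d <= trim_factor * fit$rmsd
    if (all(keep)) break
    if (sum(keep) < 3L) break
    cur <- cur[keep, , drop = FALSE]
  }
  fit$n_initial <- n_initial
  fit$n_used <- nrow(cur)
  fit$pairs <- cur
  fit
}

#' Apply a superposition transform to a structure
#' @param s a `pet_structure`.
#' @param r a `superposition`.
#' @return The transformed `pet_structure`.
#' @export
apply_transform <- function(s, r) {
  stopifnot(inherits(s, "pet_structure"), inherits(r, "superposition"))
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  moved <- xyz %*% t(r$rotation) +
    matrix(r$translation, nrow(xyz), 3L, byrow = TRUE)
  s$atoms$x <- moved[, 1L]
  s$atoms$y <- moved[, 2L]
  s$atoms$z <- moved[, 3L]
  s
}

#' Invert a superposition transform
#' @param r a `superposition`.
#' @return The inverse `superposition` (same rmsd and counts).
#' @export
invert_transform <- function(r) {
  stopifnot(inherits(r, "superposition"))
  Rt <- t(r$rotation)
  structure(list(rotation = Rt, translation = as.vector(-Rt %*% r$translation),
                 rmsd = r$rmsd, n_used = r$n_used, n_initial = r$n_initial),
            class = "superposition")
}
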