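test_that("kabsch recovers an exact rigid transform", {
  set.seed(61)
  P <- matrix(rnorm(30), 10L, 3L)
  R <- random_rotation()
  t0 <- c(3, -2, 7)
  Q <- apply_rigid(P, R, t0)
  fit <- kabsch(P, Q)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, t0, tolerance = 1e-9)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch RMSD matches the quaternion eigenvalue oracle", {
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    P <- matrix(rnorm(3 * n), n, 3L)
    Q <- apply_rigid(P, random_rotation(), rnorm(3)) +
      matrix(rnorm(3 * n, 0, 0.3), n, 3L)
    fit <- kabsch(P, Q)
    expect_equal(fit$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-9)
    # symmetry: fitting Q onto P gives the same minimum
    expect_equal(kabsch(Q, P)$rmsd, fit$rmsd, tolerance = 1e-9)
  }
})

test_that("kabsch never returns a reflection for mirrored data", {
  set.seed(63)
  P <- matrix(rnorm(24), 8L, 3L)
  Q <- P %*% diag(c(1, 1, -1))  # improper transform
  fit <- kabsch(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0)
})

test_that("degenerate and undersized inputs are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line + 1), "collinear")
  P <- matrix(rnorm(6), 2L, 3L)
  expect_error(kabsch(P, P), "at least 3")
  expect_error(kabsch(matrix(0, 4, 3), matrix(0, 4, 2)), "equal-size")
  P4 <- matrix(rnorm(12), 4L, 3L)
  expect_error(kabsch(P4, P4, weights = c(-1, 1, 1, 1)), "nonnegative")
})

test_that("trimming excludes a displaced loop and lowers the RMSD", {
  set.seed(64)
  s <- make_ideal_structure(30, "helix")
  caA <- ca_coords(s, "A")
  caB <- caA
  caB[13:17, ] <- caB[13:17, ] + 8  # displaced segment
  sA <- s
  sB <- s
  sB$atoms[sB$atoms$elety == "CA", c("x", "y", "z")] <- caB
  map <- global_align(extract_sequence(sA, "A"), extract_sequence(sB, "A"))

  untrimmed <- superpose_structures(sA, sB, map, trim_factor = Inf)
  trimmed <- superpose_structures(sA, sB, map, trim_factor = 2)
  expect_equal(untrimmed$n_used, 30L)
  expect_equal(trimmed$n_initial, 30L)
  expect_equal(trimmed$n_used, 25L)
  expect_false(any(trimmed$pairs[, 1L] %in% 13:17))
  expect_lt(trimmed$rmsd, untrimmed$rmsd)
  expect_equal(trimmed$rmsd, 0, tolerance = 1e-9)
})

test_that("apply and invert compose to the identity", {
  set.seed(65)
  s <- make_ideal_structure(10, "strand")
  r <- structure(list(rotation = random_rotation(),
                      translation = rnorm(3), rmsd = 0,
                      n_used = 10L, n_initial = 10L),
                 class = "superposition")
  s2 <- apply_transform(apply_transform(s, r), invert_transform(r))
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("superposing a structure onto a rigidly moved copy is exact", {
  s <- make_ideal_structure(20, "helix")
  set.seed(66)
  r <- structure(list(rotation = random_rotation(),
                      translation = c(10, 0, -5), rmsd = 0,
                      n_used = 1L, n_initial = 1L),
                 class = "superposition")
  moved <- apply_transform(s, r)
  map <- global_align(extract_sequence(s, "A"), extract_sequence(moved, "A"))
  fit <- superpose_structures(s, moved, map)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$n_used, 20L)
  expect_equal(fit$rotation, r$rotation, tolerance = 1e-9)
})

test_that("geometric repair recovers pairs after a corrupted alignment", {
  s <- make_ideal_structure(20, "helix")
  set.seed(67)
  r <- structure(list(rotation = diag(3), translation = c(1, 2, 3),
                      rmsd = 0, n_used = 1L, n_initial = 1L),
                 class = "superposition")
  moved <- apply_transform(s, r)
  # misaligned map: offset correspondence for the last five residues
  pairs <- cbind(A = 1:15, B = 1:15)
  map <- structure(list(pairs = pairs, score = 0, identity_fraction = 1,
                        seqA = extract_sequence(s, "A"),
                        seqB = extract_sequence(moved, "A")),
                   class = "alignment_map")
  fit <- superpose_structures(s, moved, map, repair = TRUE)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_gte(fit$n_used, 15L)
})

test_that("superpose_structures validates its inputs", {
  s <- make_ideal_structure(5, "helix")
  map <- global_align(extract_sequence(s, "A"), extract_sequence(s, "A"))
  expect_error(superpose_structures(s, s, map, trim_factor = 0), "positive")
  tiny_map <- structure(list(pairs = cbind(A = 1:2, B = 1:2), score = 0,
                             identity_fraction = 1, seqA = "AA", seqB = "AA"),
                        class = "alignment_map")
  expect_error(superpose_structures(s, s, tiny_map), "fewer than 3")
})
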