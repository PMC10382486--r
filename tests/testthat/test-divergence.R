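test_that("wrapped_delta takes the minimal image", {
  expect_equal(wrapped_delta(170, -170), -20)
  expect_equal(wrapped_delta(-170, 170), 20)
  expect_equal(wrapped_delta(10, 350), 20)
  expect_equal(wrapped_delta(90, 30), 60)
  expect_equal(wrapped_delta(0, 180), 180)
  expect_true(is.na(wrapped_delta(NA, 10)))
  set.seed(71)
  a <- runif(1000, -720, 720)
  b <- runif(1000, -720, 720)
  d <- wrapped_delta(a, b)
  expect_true(all(d >= -180 & d <= 180))
  # wrapped difference never exceeds the plain difference in magnitude
  expect_true(all(abs(d) <= abs(a - b) + 1e-9))
})

test_that("divergence distance follows the 3-4-5 construction", {
  s1 <- make_ideal_structure(6, "helix")
  tor1 <- backbone_torsions(s1, "A")
  tor2 <- tor1
  tor2$phi[3L] <- tor2$phi[3L] + 3
  tor2$psi[3L] <- tor2$psi[3L] - 4
  d <- divergence_profile(tor1, tor2)
  expect_equal(d$distance[3L], 5)
  expect_equal(d$dphi[3L], -3)
  expect_equal(d$dpsi[3L], 4)
  expect_equal(d$distance[c(2L, 4L, 5L)], rep(0, 3))
  expect_false(d$defined[1L])  # terminal phi undefined
})

test_that("wrapped mode is seam-invariant where unwrapped is not", {
  s <- make_ideal_structure(6, "helix")
  tor1 <- backbone_torsions(s, "A")
  tor2 <- tor1
  tor1$phi[3L] <- 179
  tor2$phi[3L] <- -179  # 2 degrees apart across the seam
  w <- divergence_profile(tor1, tor2, mode = "wrapped")
  u <- divergence_profile(tor1, tor2, mode = "unwrapped")
  expect_equal(w$dphi[3L], -2)
  expect_equal(u$dphi[3L], 358)
  expect_true(all(w$distance <= u$distance + 1e-9, na.rm = TRUE))
})

test_that("the wrapped per-residue distance is a torus metric", {
  set.seed(72)
  torus_dist <- function(p, q) {
    sqrt(wrapped_delta(p[1L], q[1L])^2 + wrapped_delta(p[2L], q[2L])^2)
  }
  for (rep in 1:200) {
    p <- runif(2, -180, 180); q <- runif(2, -180, 180); r <- runif(2, -180, 180)
    expect_equal(torus_dist(p, p), 0)
    expect_equal(torus_dist(p, q), torus_dist(q, p), tolerance = 1e-9)
    expect_lte(torus_dist(p, r), torus_dist(p, q) + torus_dist(q, r) + 1e-9)
  }
})

test_that("divergence localises to perturbed residues", {
  s <- make_ideal_structure(25, "helix")
  p <- perturb_torsions(s, residues = 10:14, sigma = 20, seed = 7)
  d <- divergence_profile(backbone_torsions(s, "A"),
                          backbone_torsions(p, "A"))
  hit <- d$resno %in% 10:14
  expect_true(all(d$distance[hit & d$defined] > 1e-6))
  expect_true(all(d$distance[!hit & d$defined] < 1e-6))
})

test_that("identity correspondence demands equal lengths; maps are checked", {
  t1 <- backbone_torsions(make_ideal_structure(5, "helix"), "A")
  t2 <- backbone_torsions(make_ideal_structure(6, "helix"), "A")
  expect_error(divergence_profile(t1, t2), "equal-length")
  bad_map <- structure(list(pairs = cbind(A = 1:9, B = 1:9), score = 0,
                            identity_fraction = 1, seqA = "", seqB = ""),
                       class = "alignment_map")
  expect_error(divergence_profile(t1, t2, bad_map), "exceed")
})

test_that("region summaries aggregate only defined entries and add up", {
  s <- make_ideal_structure(20, "helix")
  p <- perturb_torsions(s, residues = 5:8, sigma = 15, seed = 3)
  d <- divergence_profile(backbone_torsions(s, "A"),
                          backbone_torsions(p, "A"))
  regions <- data.frame(name = c("loopA", "loopB", "empty"),
                        chain = "A",
                        start = c(5L, 9L, 100L), end = c(8L, 12L, 110L))
  rs <- region_summary(d, regions)
  expect_equal(rs$n, c(4L, 4L, 0L))
  expect_true(is.na(rs$mean[3L]))
  expect_equal(rs$mean[1L], mean(d$distance[d$resno %in% 5:8 & d$defined]))
  expect_equal(rs$max[2L], max(d$distance[d$resno %in% 9:12 & d$defined]))
  # additivity of counts/sums when a region is split
  halves <- data.frame(name = c("h1", "h2"), chain = "A",
                       start = c(5L, 7L), end = c(6L, 8L))
  rh <- region_summary(d, halves)
  expect_equal(sum(rh$n), rs$n[1L])
  expect_equal(sum(rh$mean * rh$n), rs$mean[1L] * rs$n[1L], tolerance = 1e-9)
  expect_error(region_summary(d, data.frame(name = "x", chain = "A",
                                            start = 9, end = 5)),
               "start exceeds end")
})

test_that("divergence values and TSV round-trip", {
  s <- make_ideal_structure(8, "helix")
  p <- perturb_torsions(s, residues = 4, sigma = 10, seed = 5)
  d <- divergence_profile(backbone_torsions(s, "A"),
                          backbone_torsions(p, "A"))
  v <- divergence_values(d)
  expect_true(all(names(v) %in% d$key))
  expect_equal(unname(v[d$key[4L]]), d$distance[4L])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_divergence_tsv(d, f)
  back <- utils::read.delim(f)
  expect_equal(back$distance, d$distance, tolerance = 1e-9)
})

test_that("rmsf is zero for a rigidly moving ensemble", {
  s <- make_ideal_structure(10, "helix")
  ca <- ca_coords(s, "A")
  set.seed(73)
  frames <- lapply(1:6, function(k) apply_rigid(ca, random_rotation(), rnorm(3)))
  r <- rmsf(frames)
  expect_true(all(r$rmsf < 1e-9))
  # without pre-superposition the rigid motion shows up as fluctuation
  r2 <- rmsf(frames, presuperpose = FALSE)
  expect_true(mean(r2$rmsf) > 1)
})

test_that("rmsf matches the isotropic analytic value and scales with sigma", {
  s <- make_ideal_structure(12, "helix")
  f1 <- make_ensemble(s, 0.3, n_frames = 4000, seed = 11)
  f2 <- make_ensemble(s, 0.6, n_frames = 4000, seed = 11)
  r1 <- rmsf(f1, presuperpose = FALSE)
  r2 <- rmsf(f2, presuperpose = FALSE)
  expect_equal(mean(r1$rmsf), 0.3 * sqrt(3), tolerance = 0.02)
  expect_equal(mean(r2$rmsf) / mean(r1$rmsf), 2, tolerance = 0.02)
  expect_equal(attr(r1, "n_frames"), 4000L)
})

test_that("rmsf resolves a stepped mobility profile", {
  s <- make_ideal_structure(20, "helix")
  sig <- rep(c(0.1, 0.4), each = 10L)
  fr <- make_ensemble(s, sig, n_frames = 2000, seed = 13)
  r <- rmsf(fr, presuperpose = FALSE)
  ratio <- mean(r$rmsf[11:20]) / mean(r$rmsf[1:10])
  expect_equal(ratio, 4, tolerance = 0.15)
})

test_that("rmsf validates frame shape", {
  m <- matrix(0, 5L, 3L)
  expect_error(rmsf(list(m)), "at least 2 frames")
  expect_error(rmsf(list(m, m[1:4, ])), "same n x 3")
  expect_error(rmsf(list(m, m), reference = m[1:4, ]), "mismatch")
})
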