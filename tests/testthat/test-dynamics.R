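test_that("kabsch_superpose recovers rigid transforms and matches the quaternion oracle", {
  set.seed(17)
  ref <- matrix(rnorm(30, sd = 5), ncol = 3)
  R <- random_rotation()
  mobile <- sweep(ref %*% t(R), 2, c(4, -2, 9), "+")
  fit <- kabsch_superpose(mobile, ref)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$transform(mobile) - ref)), 1e-8)

  # one atom displaced by 1 A among n = 100 -> rmsd <= sqrt(1/100)
  set.seed(18)
  ref100 <- matrix(rnorm(300, sd = 10), ncol = 3)
  mob100 <- ref100
  mob100[7, 1] <- mob100[7, 1] + 1
  expect_lte(kabsch_superpose(mob100, ref100)$rmsd, sqrt(1 / 100))

  # independent quaternion oracle on random pairs
  for (seed in 1:20) {
    set.seed(200 + seed)
    a <- matrix(rnorm(30, sd = 3), ncol = 3)
    b <- matrix(rnorm(30, sd = 3), ncol = 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-8)
  }

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 atoms")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd_series reports per-frame deviation and a plateau summary", {
  s <- random_structure(n = 30, seed = 19)
  static <- md_ensemble(s, replicate(20, coords(s), simplify = FALSE))
  r0 <- rmsd_series(static, s)
  expect_true(all(r0$rmsd < 1e-10))
  expect_equal(r0$plateau$mean, 0, tolerance = 1e-10)
  expect_equal(r0$plateau$n_frames, 5)

  # isotropic jitter sd sigma -> plateau ~ sigma * sqrt(3) within 5%
  sigma <- 0.5
  set.seed(23)
  jit <- md_ensemble(s, lapply(1:5000, function(i) {
    coords(s) + matrix(rnorm(3 * n_atoms(s), sd = sigma), ncol = 3)
  }))
  rj <- rmsd_series(jit, s, superpose = FALSE)
  expect_equal(rj$plateau$mean, sigma * sqrt(3), tolerance = 0.05)

  # rigid global rotation: superposed rmsd 0, raw rmsd > 0
  set.seed(29)
  rot_frames <- lapply(1:10, function(i) {
    sweep(coords(s) %*% t(random_rotation()), 2, rnorm(3, sd = 5), "+")
  })
  rot <- md_ensemble(s, rot_frames)
  expect_true(all(rmsd_series(rot, s, superpose = TRUE)$rmsd < 1e-8))
  expect_true(all(rmsd_series(rot, s, superpose = FALSE)$rmsd > 0.1))

  expect_error(rmsd_series(static, coords(s)[1:5, ]), "mismatch")
})

test_that("rmsf matches closed forms and planted mobility ratios", {
  s <- random_structure(n = 40, seed = 20)
  static <- md_ensemble(s, replicate(5, coords(s), simplify = FALSE))
  expect_true(all(rmsf(static) < 1e-12))
  expect_error(rmsf(md_ensemble(s, list(coords(s)))), "insufficient")

  sigma <- 0.4
  set.seed(37)
  jit <- md_ensemble(s, lapply(1:5000, function(i) {
    coords(s) + matrix(rnorm(3 * n_atoms(s), sd = sigma), ncol = 3)
  }))
  vals <- rmsf(jit)
  expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.05)
  expect_lt(max(abs(vals - sigma * sqrt(3)) / (sigma * sqrt(3))), 0.12)

  # planted high-mobility block (tail mimic): RMSF ratio ~ planted ratio
  ratio <- 4
  set.seed(41)
  two <- md_ensemble(s, lapply(1:3000, function(i) {
    sd_vec <- rep(c(sigma, ratio * sigma), times = c(30, 10))
    coords(s) + matrix(rnorm(3 * 40, sd = rep(sd_vec, 3)), ncol = 3)
  }))
  v2 <- rmsf(two)
  expect_equal(mean(v2[31:40]) / mean(v2[1:30]), ratio, tolerance = 0.05)
})

test_that("dccm recovers planted block structure with exact diagonal and symmetry", {
  ref <- random_structure(n = 60, seed = 22)
  blocks <- rep(1:2, each = 30)
  traj <- gen_correlated_trajectory(correlated_trajectory_spec(
    ref, blocks, intra_block_correlation = 0.8, inter_block_correlation = 0,
    n_frames = 5000, seed = 31))
  cm <- dccm(traj, superpose = FALSE)
  C <- cm$matrix
  expect_equal(diag(C), rep(1, 60))
  expect_equal(C, t(C), tolerance = 1e-12)
  expect_true(all(abs(C) <= 1))
  same <- outer(blocks, blocks, "==") & upper.tri(C)
  diff_b <- outer(blocks, blocks, "!=") & upper.tri(C)
  expect_lt(max(abs(C[same] - 0.8)), 0.05)
  expect_lt(max(abs(C[diff_b] - 0)), 0.05)

  # perfectly anticorrelated pair
  s2 <- random_structure(n = 3, seed = 1)
  set.seed(3)
  z <- rnorm(2000)
  anti <- md_ensemble(s2, lapply(seq_along(z), function(i) {
    coords(s2) + rbind(c(z[i], 0, 0), c(-z[i], 0, 0), c(0.3 * z[i], 0, 0))
  }))
  Ca <- dccm(anti, superpose = FALSE)$matrix
  expect_equal(Ca[1, 2], -1, tolerance = 1e-9)

  # zero-variance atom handled with a warning
  s3 <- random_structure(n = 4, seed = 2)
  set.seed(9)
  zz <- rnorm(100)
  frames <- lapply(seq_along(zz), function(i) {
    f <- coords(s3)
    f[1:3, 1] <- f[1:3, 1] + c(zz[i], -zz[i], zz[i])
    f
  })
  expect_warning(cm3 <- dccm(md_ensemble(s3, frames), superpose = FALSE),
                 "zero-variance")
  expect_equal(cm3$matrix[4, 4], 1)
  expect_true(all(cm3$matrix[4, -4] == 0))
})

test_that("dccm is invariant under joint rigid-body motion once superposed", {
  ref <- random_structure(n = 30, seed = 25)
  blocks <- rep(1:2, each = 15)
  traj <- gen_correlated_trajectory(correlated_trajectory_spec(
    ref, blocks, n_frames = 800, seed = 5))
  C_plain <- dccm(traj, superpose = TRUE)$matrix
  set.seed(55)
  moved <- md_ensemble(ref, lapply(traj$frames, function(f) {
    sweep(f %*% t(random_rotation()), 2, rnorm(3, sd = 20), "+")
  }), traj$times)
  C_moved <- dccm(moved, superpose = TRUE)$matrix
  expect_equal(C_moved, C_plain, tolerance = 1e-6)
})

test_that("correlation_change classifies weakened couplings and is antisymmetric", {
  ref <- random_structure(n = 40, seed = 26)
  blocks <- rep(1:2, each = 20)
  apo_t <- gen_correlated_trajectory(correlated_trajectory_spec(
    ref, blocks, intra_block_correlation = 0.8, n_frames = 4000, seed = 61))
  holo_t <- gen_correlated_trajectory(correlated_trajectory_spec(
    ref, blocks, intra_block_correlation = 0.3, n_frames = 4000, seed = 62))
  A <- dccm(apo_t, superpose = FALSE)
  H <- dccm(holo_t, superpose = FALSE)

  expect_equal(nrow(correlation_change(A, A)), 0)    # apo = apo -> no edges

  edges <- correlation_change(A, H, threshold = 0.2)
  within <- outer(blocks, blocks, "==")
  n_within_pairs <- sum(within & upper.tri(within))
  expect_equal(nrow(edges), n_within_pairs)          # all within-block pairs move
  expect_true(all(edges$classification == "weakened"))
  expect_true(all(diff(abs(edges$delta)) <= 1e-12))  # sorted by |delta| desc

  # raising the threshold never adds edges
  expect_lte(nrow(correlation_change(A, H, threshold = 0.4)), nrow(edges))

  # swapping conditions flips the classification
  rev_edges <- correlation_change(H, A, threshold = 0.2)
  expect_true(all(rev_edges$classification == "enhanced"))
  expect_equal(nrow(rev_edges), nrow(edges))

  A2 <- dccm(apo_t, superpose = FALSE)
  A2$atom_ids <- A2$atom_ids + 1L
  expect_error(correlation_change(A2, H), "match")
})
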