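test_that("pose_distance is the in-frame ligand RMSD", {
  a <- matrix(rnorm(15), ncol = 3)
  expect_equal(pose_distance(a, a), 0)
  expect_equal(pose_distance(a, sweep(a, 2, c(3, 0, 0), "+")), 3.0)

  set.seed(31)
  b <- matrix(rnorm(15), ncol = 3)
  brute <- sqrt(sum(rowSums((a - b)^2)) / 5)
  expect_equal(pose_distance(a, b), brute)
  expect_equal(pose_distance(a, b), pose_distance(b, a))

  expect_error(pose_distance(a, matrix(0, 4, 3)), "mismatch")
})

test_that("cluster_poses recovers planted clusters and obeys limit cases", {
  for (seed in c(1, 7)) {
    ps <- gen_pose_cloud(pose_cloud_spec(
      site_centers = default_site_centers(20, 15), per_site_count = 6,
      spread_sd = 1, seed = seed))
    cl <- cluster_poses(ps, cutoff = 5)
    expect_length(cl, 20)
    truth <- ground_truth(ps)$site
    for (c1 in cl) {
      expect_length(unique(truth[c1$member_pose_ids]), 1)   # pure clusters
      expect_equal(c1$size, 6)
    }
  }

  # all poses identical -> 1 cluster
  one <- matrix(0, 5, 3)
  ps1 <- pose_set(rep(list(one), 8), score = rep(-5, 8))
  expect_length(cluster_poses(ps1, cutoff = 1), 1)

  # cutoff below the minimum pairwise distance -> singletons
  ps2 <- gen_pose_cloud(pose_cloud_spec(per_site_count = 3, seed = 2))
  dmin <- min(pose_dist_matrix(ps2))
  cl2 <- cluster_poses(ps2, cutoff = dmin * 0.5)
  expect_length(cl2, n_poses(ps2))

  # cluster count is monotonically non-increasing in the cutoff
  counts <- vapply(c(0.5, 2, 5, 20, 100),
                   function(h) length(cluster_poses(ps2, cutoff = h)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering output is deterministic under pose relabeling", {
  ps <- gen_pose_cloud(pose_cloud_spec(per_site_count = 5, seed = 9))
  n <- n_poses(ps)
  set.seed(1)
  perm <- sample(n)
  ps_perm <- pose_set(ps$coords[perm], ps$score[perm], ps$snapshot[perm],
                      atoms = ps$atoms)
  cl <- cluster_poses(ps, cutoff = 5)
  cl_perm <- cluster_poses(ps_perm, cutoff = 5)
  # same partition: compare member sets mapped back through the permutation
  sets <- lapply(cl, function(x) sort(x$member_pose_ids))
  sets_perm <- lapply(cl_perm, function(x) sort(perm[x$member_pose_ids]))
  expect_setequal(lapply(sets_perm, paste, collapse = ","),
                  lapply(sets, paste, collapse = ","))
})

test_that("select_representative picks the best score with lowest-id ties", {
  one <- matrix(0, 2, 3)
  ps <- pose_set(rep(list(one), 3), score = c(-5.1, -6.2, -4.0))
  cl <- list(member_pose_ids = 1:3)
  expect_equal(select_representative(cl, ps)$pose_id, 2)
  expect_equal(select_representative(cl, ps)$score, -6.2)

  ps_tie <- pose_set(rep(list(one), 3), score = c(-6.2, -4.0, -6.2))
  expect_equal(select_representative(cl, ps_tie)$pose_id, 1)

  expect_equal(select_representative(list(member_pose_ids = 3L), ps)$pose_id, 3)
})

test_that("contact_residues finds planted landmark contacts and matches brute force", {
  s <- gen_pseudo_nucleosome(pseudo_nucleosome_spec(seed = 1))
  tail_sel <- select_atoms(s, chain = "H4", resid = 18:23)
  # ligand laid along the tail landmark, 0.3 A off each bead: with a 2 A
  # cutoff exactly the planted residues are contacts (neighbours are >= 3.5 A)
  pose <- coords(s)[tail_sel, , drop = FALSE] + 0.3 / sqrt(3)
  hits <- contact_residues(pose, s, cutoff = 2)
  expect_equal(paste(hits$chain, hits$resid), paste("H4", 18:23))

  far <- sweep(ligand_template()$coords, 2, c(500, 500, 500), "+")
  expect_equal(nrow(contact_residues(far, s)), 0)

  # O(n^2) brute-force oracle on a 30-residue toy, several random poses
  toy <- random_structure(n = 30, seed = 12)
  for (seed in 1:5) {
    set.seed(seed)
    pose_r <- matrix(rnorm(12, sd = 20), ncol = 3)
    expect_equal(contact_residues(pose_r, toy, cutoff = 8),
                 brute_contacts(pose_r, toy, cutoff = 8))
  }
})

test_that("partition_sites reproduces the forced two-system split", {
  mk_site <- function(id, center) {
    binding_site_model(id, list(pose_id = 1L,
                                coords = matrix(center, 1, 3, byrow = TRUE),
                                score = -5, snapshot = 1L),
                       data.frame(chain = "H4", resid = 18, resname = "HIS"))
  }
  centers <- list(s1 = c(0, 0, 0), s2 = c(30, 0, 0), s3 = c(-30, 0, 0),
                  s4 = c(100, 0, 0), s5 = c(0, -30, 0), s6 = c(0, 100, 0))
  sites <- Map(mk_site, names(centers), centers)
  groups <- partition_sites(unname(sites), min_separation = 40)
  expect_length(groups, 2)
  expect_setequal(groups[[1]], c("s1", "s4", "s6"))
  expect_setequal(groups[[2]], c("s2", "s3", "s5"))
  # every within-group pair separated by >= min_separation
  for (g in groups) {
    cc <- do.call(rbind, centers[g])
    if (nrow(cc) > 1) expect_gte(min(dist(cc)), 40)
  }

  # mutually distant -> one group; coincident -> singletons
  far_sites <- Map(mk_site, c("s1", "s2", "s3"),
                   list(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0)))
  expect_length(partition_sites(unname(far_sites), 40), 1)
  same_sites <- Map(mk_site, c("s1", "s2", "s3"),
                    rep(list(c(1, 1, 1)), 3))
  expect_length(partition_sites(unname(same_sites), 40), 3)
})

test_that("pose sets round-trip through multi-model PDB with scores", {
  ps <- gen_pose_cloud(pose_cloud_spec(per_site_count = 3, seed = 4))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pose_pdb(ps, f)
  back <- read_pose_pdb(f)
  expect_equal(n_poses(back), n_poses(ps))
  expect_equal(back$score, ps$score, tolerance = 1e-4)  # scores stored %.4f
  expect_lt(max(abs(back$coords[[5]] - ps$coords[[5]])), 1e-3 + 1e-12)
})
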