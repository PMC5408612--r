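#!/usr/bin/env Rscript
# Stage 2 — cluster docking poses into binding sites.
#
# Reads the stage-1 pose cloud, clusters by average-linkage ligand RMSD at
# the 5 A default cut, models the six largest clusters as binding sites
# (representative = best-scored pose; contacts at 4 A heavy-atom cutoff),
# and partitions sites into co-simulable groups (21 A minimum separation).

suppressPackageStartupMessages(library(nucbind))
dir.create("results", showWarnings = FALSE)

poses <- read_pose_pdb("results/sim/poses.pdb")
receptor <- read_pdb("results/sim/receptor.pdb")[[1]]

clusters <- cluster_poses(poses, cutoff = 5)
cat(sprintf("found %d clusters (sizes: %s)\n", length(clusters),
            paste(vapply(clusters, `[[`, numeric(1), "size"), collapse = ", ")))

sites <- build_binding_sites(clusters, poses, receptor, n_sites = 6,
                             contact_cutoff = 4)
groups <- partition_sites(sites, min_separation = 21)
cat("co-simulation groups:",
    paste(vapply(groups, paste, character(1), collapse = ","), collapse = " | "),
    "\n")

site_tab <- do.call(rbind, lapply(sites, function(s) {
  data.frame(site_id = s$site_id, pose_id = s$representative$pose_id,
             score = s$representative$score,
             x = s$center[1], y = s$center[2], z = s$center[3],
             n_contacts = nrow(s$contact_residues))
}))
write.csv(site_tab, "results/binding_sites.csv", row.names = FALSE)
cat("site table -> results/binding_sites.csv\n")
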