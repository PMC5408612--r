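#' A set of docked ligand poses over a receptor ensemble
#'
#' All poses share one ligand topology (same atom count and order) and are
#' expressed in the common receptor frame of the pre-aligned ensemble, so
#' pose-pose distances are plain RMSDs without re-superposition.
#'
#' @param coords list of `m x 3` ligand coordinate matrices (Angstrom).
#' @param score numeric docking scores in kcal/mol (lower = better).
#' @param snapshot integer receptor snapshot index per pose.
#' @param atoms data.frame with `name` and `element` for the ligand atoms.
#' @return An object of class `pose_set`.
#' @export
pose_set <- function(coords, score, snapshot = seq_along(coords),
                     atoms = NULL) {
  if (!is.list(coords) || length(coords) == 0) stop("at least one pose required")
  m <- nrow(as.matrix(coords[[1]]))
  coords <- lapply(coords, function(p) {
    p <- as.matrix(p)
    if (nrow(p) != m || ncol(p) != 3) {
      stop("ligand atom count must be constant across a pose set")
    }
    if (!all(is.finite(p))) stop("pose coordinates must be finite")
    p
  })
  if (length(score) != length(coords)) stop("one score per pose required")
  if (is.null(atoms)) {
    atoms <- data.frame(name = paste0("C", seq_len(m)),
                        element = rep("C", m), stringsAsFactors = FALSE)
  }
  out <- list(coords = coords, score = as.numeric(score),
              snapshot = as.integer(snapshot), atoms = atoms)
  class(out) <- "pose_set"
  out
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("pose_set: %d poses x %d ligand atoms, best score %.2f kcal/mol\n",
              length(x$coords), nrow(x$atoms), min(x$score)))
  invisible(x)
}

#' Number of poses in a set
#' @param poses a `pose_set`.
#' @return Integer count.
#' @export
n_poses <- function(poses) length(poses$coords)

#' RMSD between two poses in the common receptor frame
#'
#' Root-mean-square deviation over matched ligand atoms with no
#' re-superposition: poses from ensemble docking already share the receptor
#' frame, and superposing would erase exactly the binding-site geometry the
#' clustering is meant to distinguish.
#'
#' @param a,b `m x 3` coordinate matrices (or single-pose extracts).
#' @return RMSD in Angstrom.
#' @export
pose_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("atom-count mismatch between poses")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Pairwise pose RMSD matrix as a `dist`
#' @param poses a `pose_set`.
#' @return A `stats::dist` object of pose RMSDs.
#' @export
pose_dist_matrix <- function(poses) {
  m <- nrow(poses$atoms)
  flat <- t(vapply(poses$coords, function(p) as.numeric(p), numeric(3 * m)))
  stats::dist(flat) / sqrt(m)
}

#' Cluster docked poses into candidate binding sites
#'
#' Average-linkage agglomerative clustering on the pose RMSD matrix, cut at
#' `cutoff` Angstrom. No cluster count is fixed a priori: the number of
#' groups emerges from the cut, as in distance-based clustering of ensemble
#' docking solutions. Clusters are ordered by size (descending), then by the
#' best (lowest) member score, then by lowest member pose id; this makes the
#' output deterministic under pose relabeling up to those tie rules.
#'
#' @param poses a `pose_set`.
#' @param cutoff clustering cutoff in Angstrom (default 5).
#' @return List of `pose_cluster` records: `member_pose_ids`, `centroid`
#'   (mean ligand centroid, 3-vector), `representative_id` (lowest-score
#'   member, ties to lowest id), `size`, `best_score`.
#' @export
cluster_poses <- function(poses, cutoff = 5) {
  stopifnot(inherits(poses, "pose_set"))
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- n_poses(poses)
  memb <- if (n == 1L) 1L else {
    hc <- stats::hclust(pose_dist_matrix(poses), method = "average")
    stats::cutree(hc, h = cutoff)
  }
  ids <- split(seq_len(n), memb)
  clusters <- lapply(ids, function(ii) {
    ii <- sort(ii)
    cents <- t(vapply(poses$coords[ii], colMeans, numeric(3)))
    rep_id <- ii[order(poses$score[ii], ii)][1]
    structure(list(member_pose_ids = ii, centroid = colMeans(cents),
                   representative_id = rep_id, size = length(ii),
                   best_score = min(poses$score[ii])),
              class = "pose_cluster")
  })
  ord <- order(-vapply(clusters, `[[`, numeric(1), "size"),
               vapply(clusters, `[[`, numeric(1), "best_score"),
               vapply(clusters, function(cl) min(cl$member_pose_ids), numeric(1)))
  unname(clusters[ord])
}

#' Most favorable pose of a cluster
#'
#' The member with the lowest (most favorable) docking score; ties resolved
#' to the lowest pose id.
#'
#' @param cluster a `pose_cluster`.
#' @param poses the `pose_set` the cluster indexes into.
#' @return List with `pose_id`, `coords`, `score`, `snapshot`.
#' @export
select_representative <- function(cluster, poses) {
  ii <- cluster$member_pose_ids
  if (length(ii) == 0) stop("cluster has no members")
  id <- ii[order(poses$score[ii], ii)][1]
  list(pose_id = id, coords = poses$coords[[id]],
       score = poses$score[id], snapshot = poses$snapshot[id])
}

#' Receptor residues in contact with a ligand pose
#'
#' A residue is a contact when at least one of its heavy atoms lies within
#' `cutoff` (inclusive) of any ligand heavy atom. Hydrogens are excluded on
#' both sides; results are sorted by chain then resid with duplicates
#' collapsed.
#'
#' @param pose_coords `m x 3` ligand coordinates.
#' @param receptor an `md_structure`.
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @param ligand_elements element symbols of the ligand atoms (default: all
#'   heavy; pass to drop ligand hydrogens).
#' @return data.frame with columns `chain`, `resid`, `resname` (possibly
#'   zero rows).
#' @export
contact_residues <- function(pose_coords, receptor, cutoff = 4.0,
                             ligand_elements = NULL) {
  stopifnot(inherits(receptor, "md_structure"))
  if (cutoff <= 0) stop("cutoff must be positive")
  lig <- as.matrix(pose_coords)
  if (!is.null(ligand_elements)) {
    lig <- lig[toupper(ligand_elements) != "H", , drop = FALSE]
  }
  at <- receptor$atoms
  heavy <- toupper(at$element) != "H"
  rec <- receptor$xyz[heavy, , drop = FALSE]
  at <- at[heavy, , drop = FALSE]
  # min distance from each receptor heavy atom to any ligand atom
  d2 <- outer(rowSums(rec^2), rowSums(lig^2), "+") - 2 * rec %*% t(lig)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  hit <- mind <= cutoff + 1e-12
  if (!any(hit)) {
    return(data.frame(chain = character(0), resid = integer(0),
                      resname = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(at[hit, c("chain", "resid", "resname")])
  res <- res[order(res$chain, res$resid), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Binding-site model: representative pose plus contacts
#'
#' @param site_id label, "s1" style.
#' @param representative result of [select_representative()].
#' @param contacts data.frame from [contact_residues()].
#' @return A `binding_site_model` with `center` = representative ligand
#'   centroid.
#' @export
binding_site_model <- function(site_id, representative, contacts) {
  structure(list(site_id = site_id, representative = representative,
                 contact_residues = contacts,
                 center = colMeans(representative$coords)),
            class = "binding_site_model")
}

#' Build site models from the largest pose clusters
#'
#' Takes the first `n_sites` clusters in the deterministic cluster order and
#' labels them s1, s2, ... Site selection beyond cluster rank (e.g. keeping
#' only sites near regions of biological interest) is the caller's judgment:
#' pass `keep` to subset/annotate explicitly.
#'
#' @param clusters result of [cluster_poses()].
#' @param poses the `pose_set`.
#' @param receptor `md_structure` used for contact mapping.
#' @param n_sites number of sites to model (default: all clusters).
#' @param contact_cutoff Angstrom (default 4.0).
#' @param keep optional integer vector of cluster indices to keep, in order.
#' @return List of `binding_site_model`.
#' @export
build_binding_sites <- function(clusters, poses, receptor,
                                n_sites = length(clusters),
                                contact_cutoff = 4.0, keep = NULL) {
  idx <- if (is.null(keep)) seq_len(min(n_sites, length(clusters))) else keep
  lapply(seq_along(idx), function(i) {
    rep_pose <- select_representative(clusters[[idx[i]]], poses)
    binding_site_model(paste0("s", i), rep_pose,
                       contact_residues(rep_pose$coords, receptor,
                                        cutoff = contact_cutoff))
  })
}

#' Partition binding sites into co-simulable groups
#'
#' Greedy coloring of the conflict graph whose edges join sites closer than
#' `min_separation`: sites are visited in `site_id` order and each goes into
#' the first existing group it does not conflict with, opening a new group
#' when every group conflicts. Within any returned group all pairwise center
#' distances are >= `min_separation`, so the grouped ligands can share one
#' simulation box without crowding one another.
#'
#' @param sites list of `binding_site_model`.
#' @param min_separation Angstrom.
#' @return List of character vectors of site ids.
#' @export
partition_sites <- function(sites, min_separation) {
  if (length(sites) == 0) stop("at least one site required")
  ids <- vapply(sites, `[[`, character(1), "site_id")
  centers <- t(vapply(sites, `[[`, numeric(3), "center"))
  ord <- order(ids)
  groups <- list()        # integer indices into sites
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      dists <- sqrt(rowSums((centers[groups[[g]], , drop = FALSE] -
                               matrix(centers[i, ], nrow = length(groups[[g]]),
                                      ncol = 3, byrow = TRUE))^2))
      if (all(dists >= min_separation)) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  lapply(groups, function(ii) ids[ii])
}
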