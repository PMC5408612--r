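#' Evaluate code with a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive an independent child seed from a global seed
#'
#' One global seed expands to per-generator seeds by fixed offsets, keeping
#' results reproducible while decoupling the generators' streams.
#'
#' @param seed global integer seed.
#' @param k child index (0, 1, 2, ...).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483629)
}

#' Ground truth sidecar of a synthetic object
#' @param x an object produced by one of the `gen_*` generators.
#' @return The generator's ground-truth record (a list), or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

# ---------------------------------------------------------------------------
# pseudo-nucleosome structure

#' Specification for the pseudo-nucleosome test structure
#'
#' A coarse stand-in for the nucleosome core particle: eight histone-like
#' chains (H3, H4, H2A, H2B and primed copies) plus two DNA-like strands,
#' one C-alpha (or phosphate) bead per residue, laid out on concentric
#' helical arcs. Landmark residues mimic the particle's functional surface:
#' the H4 N-terminal tail (resids 18-23: H18, R19, K20, G21, L22, R23) and
#' the H2A' acidic patch glutamates (E91, E92 when the chain is long enough,
#' otherwise the chain's last two residues).
#'
#' @param residues_per_chain beads per chain; must be >= 24 so the tail
#'   landmark fits (default 100, so canonical acidic-patch numbering holds).
#' @param bead_spacing along-chain bead spacing in Angstrom (default 3.8, the
#'   C-alpha virtual bond length).
#' @param seed integer seed.
#' @return A `pseudo_nucleosome_spec` list.
#' @export
pseudo_nucleosome_spec <- function(residues_per_chain = 100,
                                   bead_spacing = 3.8, seed = 1) {
  if (residues_per_chain < 24) {
    stop("residues_per_chain must be >= 24 (landmarks would not fit)")
  }
  if (bead_spacing <= 0) stop("bead_spacing must be positive")
  structure(list(residues_per_chain = as.integer(residues_per_chain),
                 bead_spacing = bead_spacing, seed = as.integer(seed)),
            class = "pseudo_nucleosome_spec")
}

#' Generate the pseudo-nucleosome structure
#'
#' Deterministic for a given spec (the seed only perturbs bead positions by a
#' small reproducible jitter so chains are non-collinear). The ground-truth
#' sidecar records the chain roles and the landmark residue locations.
#'
#' @param spec a [pseudo_nucleosome_spec()].
#' @return An `md_structure` with `ground_truth()` attached.
#' @export
gen_pseudo_nucleosome <- function(spec = pseudo_nucleosome_spec()) {
  stopifnot(inherits(spec, "pseudo_nucleosome_spec"))
  rpc <- spec$residues_per_chain
  protein_chains <- c("H3", "H4", "H2A", "H2B", "H3'", "H4'", "H2A'", "H2B'")
  dna_chains <- c("DI", "DJ")
  chains <- c(protein_chains, dna_chains)

  acidic_resids <- if (rpc >= 92) c(91L, 92L) else c(rpc - 1L, rpc)
  tail_names <- c("HIS", "ARG", "LYS", "GLY", "LEU", "ARG")  # 18..23

  with_seed(spec$seed, {
    rows <- list(); xyz <- list(); serial <- 0L
    for (ci in seq_along(chains)) {
      ch <- chains[ci]
      is_dna <- ch %in% dna_chains
      # each chain: helical arc on its own cylinder shell
      radius <- if (is_dna) 41.8 else 10 + 3 * ci
      t <- seq_len(rpc)
      dtheta <- spec$bead_spacing / radius
      theta <- (ci - 1) * (2 * pi / length(chains)) + t * dtheta
      z <- (ci - (length(chains) + 1) / 2) * 6 + 0.15 * t
      pos <- cbind(radius * cos(theta), radius * sin(theta), z)
      pos <- pos + matrix(stats::rnorm(3 * rpc, sd = 0.05), ncol = 3)
      resname <- rep(if (is_dna) "DA" else "ALA", rpc)
      if (ch == "H4") resname[18:23] <- tail_names
      if (ch == "H2A'") resname[acidic_resids] <- "GLU"
      rows[[ci]] <- data.frame(
        serial = serial + t, name = if (is_dna) "P" else "CA",
        element = if (is_dna) "P" else "C",
        resname = resname, resid = t, chain = ch,
        stringsAsFactors = FALSE)
      xyz[[ci]] <- pos
      serial <- serial + rpc
    }
    s <- md_structure(do.call(rbind, rows), do.call(rbind, xyz),
                      title = "synthetic pseudo-nucleosome")
    attr(s, "ground_truth") <- list(
      chains = chains, protein_chains = protein_chains,
      dna_chains = dna_chains,
      h4_tail = list(chain = "H4", resid = 18:23, resname = tail_names),
      acidic_patch = list(chain = "H2A'", resid = acidic_resids,
                          resname = c("GLU", "GLU")),
      spec = spec)
    s
  })
}

# ---------------------------------------------------------------------------
# energy series

#' Specification for synthetic bound/free interaction-energy series
#'
#' Each component (vdW and electrostatic, bound and free) is a stationary
#' AR(1) process `x_t = mu + phi (x_{t-1} - mu) + eps_t` with stationary
#' standard deviation `sd`, the simplest process with a tunable correlation
#' time, which is what block-error estimators must handle. The true binding
#' free energy under a given LIE parameter set is computable from the means.
#'
#' @param n_frames frames per series (default 2000, i.e. 200 ns at one sample
#'   per 100 ps).
#' @param mean_vdw,mean_el named numeric vectors with entries `bound` and
#'   `free`: stationary means in kcal/mol.
#' @param sd stationary standard deviation in kcal/mol (same for all four
#'   components; default 2.5).
#' @param ar1_coefficient AR(1) coefficient in [0, 1) (default 0.8).
#' @param dt frame spacing in ns.
#' @param seed integer seed.
#' @return An `energy_series_spec` list.
#' @export
energy_series_spec <- function(n_frames = 2000,
                               mean_vdw = c(bound = -20, free = -15),
                               mean_el = c(bound = -10, free = -6),
                               sd = 2.5, ar1_coefficient = 0.8,
                               dt = 0.1, seed = 1) {
  if (sd < 0) stop("sd must be >= 0")
  if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
    stop("ar1_coefficient must lie in [0, 1) for a stationary process")
  }
  for (v in list(mean_vdw, mean_el)) {
    if (!all(c("bound", "free") %in% names(v))) {
      stop("mean_vdw and mean_el need named entries 'bound' and 'free'")
    }
  }
  structure(list(n_frames = as.integer(n_frames), mean_vdw = mean_vdw,
                 mean_el = mean_el, sd = sd,
                 ar1_coefficient = ar1_coefficient, dt = dt,
                 seed = as.integer(seed)),
            class = "energy_series_spec")
}

#' True LIE free energy implied by an energy-series spec
#' @param spec an [energy_series_spec()].
#' @param params a [lie_params()].
#' @return The planted binding free energy in kcal/mol.
#' @export
true_delta_g <- function(spec, params = lie_params()) {
  params$alpha * (spec$mean_vdw[["bound"]] - spec$mean_vdw[["free"]]) +
    params$beta * (spec$mean_el[["bound"]] - spec$mean_el[["free"]]) +
    params$gamma
}

#' Generate a bound/free pair of AR(1) energy series
#'
#' @param spec an [energy_series_spec()].
#' @return List with elements `bound` and `free` ([energy_series()] objects);
#'   `ground_truth()` holds the spec and the component means.
#' @export
gen_energy_series <- function(spec = energy_series_spec()) {
  stopifnot(inherits(spec, "energy_series_spec"))
  phi <- spec$ar1_coefficient
  n <- spec$n_frames
  ar1 <- function(mu) {
    if (spec$sd == 0) return(rep(mu, n))
    innov_sd <- spec$sd * sqrt(1 - phi^2)
    dev1 <- stats::rnorm(1, 0, spec$sd)  # stationary start
    innov <- if (n > 1) stats::rnorm(n - 1, 0, innov_sd) else numeric(0)
    dev <- as.numeric(stats::filter(c(dev1, innov), phi, method = "recursive"))
    mu + dev
  }
  out <- with_seed(spec$seed, {
    list(bound = energy_series(ar1(spec$mean_vdw[["bound"]]),
                               ar1(spec$mean_el[["bound"]]),
                               state = "bound", dt = spec$dt),
         free = energy_series(ar1(spec$mean_vdw[["free"]]),
                              ar1(spec$mean_el[["free"]]),
                              state = "free", dt = spec$dt))
  })
  attr(out, "ground_truth") <- list(spec = spec,
                                    mean_vdw = spec$mean_vdw,
                                    mean_el = spec$mean_el)
  out
}

# ---------------------------------------------------------------------------
# pose clouds

#' Default widely separated site centers
#' @param n number of centers.
#' @param separation minimum pairwise distance in Angstrom.
#' @return An `n x 3` matrix of centers.
#' @export
default_site_centers <- function(n = 6, separation = 15) {
  # points on a coarse 3D grid, spacing = separation
  k <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(x = 0:(k), y = 0:(k), z = 0:(k))) * separation
  g[seq_len(n), , drop = FALSE]
}

#' Specification for planted docking-pose clouds
#'
#' Emulates ensemble-docking output with known cluster structure: around each
#' site center, `per_site_count` rigid ligand copies are displaced by an
#' isotropic Gaussian of standard deviation `spread_sd`; docking scores are
#' Gaussian. Poses carry receptor snapshot indices round-robin over the
#' ensemble, and true site labels are kept for testing.
#'
#' @param site_centers matrix (k x 3) of site centers in Angstrom, pairwise
#'   distinct (default: 6 centers 15 Angstrom apart).
#' @param per_site_count poses per site (default 20, so 6 sites give 120
#'   poses, one per receptor snapshot of a 120-frame ensemble).
#' @param spread_sd isotropic positional spread in Angstrom (default 1).
#' @param score_mean,score_sd docking score distribution in kcal/mol
#'   (default -5 and 1; lower is better).
#' @param seed integer seed.
#' @return A `pose_cloud_spec` list.
#' @export
pose_cloud_spec <- function(site_centers = default_site_centers(),
                            per_site_count = 20, spread_sd = 1,
                            score_mean = -5, score_sd = 1, seed = 1) {
  site_centers <- as.matrix(site_centers)
  if (nrow(site_centers) < 1 || ncol(site_centers) != 3) {
    stop("site_centers must be a k x 3 matrix with k >= 1")
  }
  if (per_site_count < 1) stop("per_site_count must be >= 1")
  if (nrow(site_centers) > 1) {
    dmin <- min(stats::dist(site_centers))
    if (anyDuplicated(site_centers)) stop("site centers must be pairwise distinct")
    if (spread_sd >= dmin / 2) {
      warning("spread_sd >= half the minimum inter-center distance; clusters may merge")
    }
  }
  structure(list(site_centers = site_centers,
                 per_site_count = as.integer(per_site_count),
                 spread_sd = spread_sd, score_mean = score_mean,
                 score_sd = score_sd, seed = as.integer(seed)),
            class = "pose_cloud_spec")
}

#' Rigid ligand template used for synthetic poses
#'
#' A compact 8-heavy-atom rigid body (centroid at the origin) standing in for
#' a small sterol-like ligand; clustering operates on positions only, so no
#' internal torsions are modelled.
#' @return List with `atoms` (name/element data.frame) and `coords`
#'   (8 x 3 matrix).
#' @export
ligand_template <- function() {
  coords <- matrix(c(
     0.0,  0.0,  0.0,
     1.5,  0.0,  0.0,
     2.3,  1.2,  0.2,
     1.6,  2.5,  0.1,
     0.1,  2.5, -0.2,
    -0.7,  1.2, -0.1,
    -2.2,  1.2,  0.0,
     3.8,  1.2,  0.3), ncol = 3, byrow = TRUE)
  coords <- sweep(coords, 2, colMeans(coords))
  list(atoms = data.frame(name = c(paste0("C", 1:7), "O1"),
                          element = c(rep("C", 7), "O"),
                          stringsAsFactors = FALSE),
       coords = coords)
}

#' Generate a planted pose cloud
#'
#' @param spec a [pose_cloud_spec()].
#' @param ensemble optional `md_ensemble`; pose snapshot indices cycle
#'   round-robin over its frames (without it, over `1:n_poses`).
#' @return A `pose_set`; `ground_truth()` holds the true site labels and
#'   centers.
#' @export
gen_pose_cloud <- function(spec = pose_cloud_spec(), ensemble = NULL) {
  stopifnot(inherits(spec, "pose_cloud_spec"))
  tmpl <- ligand_template()
  k <- nrow(spec$site_centers)
  n <- k * spec$per_site_count
  n_snap <- if (is.null(ensemble)) n else n_frames(ensemble)
  with_seed(spec$seed, {
    site <- rep(seq_len(k), each = spec$per_site_count)
    disp <- matrix(stats::rnorm(3 * n, sd = spec$spread_sd), ncol = 3)
    centers <- spec$site_centers[site, , drop = FALSE] + disp
    coords_list <- lapply(seq_len(n), function(i) {
      sweep(tmpl$coords, 2, centers[i, ], "+")
    })
    scores <- stats::rnorm(n, spec$score_mean, spec$score_sd)
    ps <- pose_set(coords_list, scores,
                   snapshot = ((seq_len(n) - 1L) %% n_snap) + 1L,
                   atoms = tmpl$atoms)
    attr(ps, "ground_truth") <- list(site = site,
                                     centers = spec$site_centers,
                                     spec = spec)
    ps
  })
}

# ---------------------------------------------------------------------------
# water configurations

#' Generate a water-oxygen configuration with a known shell count
#'
#' Places exactly `n_inside` oxygens strictly inside the cutoff sphere around
#' `site_center` and `n_outside` strictly outside, with a guard margin of at
#' least 0.1 Angstrom on both sides of the boundary so counting is unambiguous.
#'
#' @param site_center 3-vector in Angstrom.
#' @param n_inside,n_outside water counts inside/outside the sphere.
#' @param cutoff sphere radius in Angstrom.
#' @param seed integer seed.
#' @param frame frame index attached to the set.
#' @return A `water_set` (list with `coords` n x 3 and `frame`);
#'   `ground_truth()` records the planted counts.
#' @export
gen_water_configuration <- function(site_center = c(0, 0, 0), n_inside = 17,
                                    n_outside = 50, cutoff = 10, seed = 1,
                                    frame = 1L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (n_inside < 0 || n_outside < 0) stop("counts must be non-negative")
  margin <- 0.1
  if (cutoff <= 2 * margin && n_inside > 0) {
    stop("cutoff too small to place interior waters with the guard margin")
  }
  with_seed(seed, {
    n <- n_inside + n_outside
    dirs <- matrix(stats::rnorm(3 * max(n, 1)), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    r_in <- if (n_inside > 0) stats::runif(n_inside, margin, cutoff - margin) else numeric(0)
    r_out <- if (n_outside > 0) stats::runif(n_outside, cutoff + margin, cutoff + 15) else numeric(0)
    r <- c(r_in, r_out)
    coords <- dirs[seq_len(n), , drop = FALSE] * r +
      matrix(site_center, nrow = n, ncol = 3, byrow = TRUE)
    ws <- water_set(coords, frame = frame)
    attr(ws, "ground_truth") <- list(n_inside = n_inside, n_outside = n_outside,
                                     cutoff = cutoff, site_center = site_center)
    ws
  })
}

# ---------------------------------------------------------------------------
# block-correlated trajectories

#' Specification for a trajectory with planted positional correlations
#'
#' Per-frame displacements about the reference are drawn from a zero-mean
#' Gaussian whose atom-atom correlation matrix is `intra_block_correlation`
#' within blocks and `inter_block_correlation` between blocks (applied
#' identically and independently to x, y and z, so the expected dynamic
#' cross-correlation map equals that matrix).
#'
#' @param reference an `md_structure` giving mean positions.
#' @param block_assignment integer vector, one block id per atom.
#' @param intra_block_correlation,inter_block_correlation correlations in
#'   [-1, 1] (defaults 0.8 and 0).
#' @param fluctuation_sd per-axis displacement standard deviation in
#'   Angstrom (default 0.5).
#' @param n_frames frames to draw (default 1000).
#' @param dt frame spacing in ns.
#' @param seed integer seed.
#' @return A `correlated_trajectory_spec` list.
#' @export
correlated_trajectory_spec <- function(reference, block_assignment,
                                       intra_block_correlation = 0.8,
                                       inter_block_correlation = 0,
                                       fluctuation_sd = 0.5,
                                       n_frames = 1000, dt = 0.1, seed = 1) {
  stopifnot(inherits(reference, "md_structure"))
  block_assignment <- as.integer(block_assignment)
  if (length(block_assignment) != n_atoms(reference)) {
    stop("block_assignment must give one block per atom")
  }
  for (v in c(intra_block_correlation, inter_block_correlation)) {
    if (abs(v) > 1) stop("correlations must lie in [-1, 1]")
  }
  if (fluctuation_sd < 0) stop("fluctuation_sd must be >= 0")
  structure(list(reference = reference, block_assignment = block_assignment,
                 intra = intra_block_correlation,
                 inter = inter_block_correlation,
                 fluctuation_sd = fluctuation_sd,
                 n_frames = as.integer(n_frames), dt = dt,
                 seed = as.integer(seed)),
            class = "correlated_trajectory_spec")
}

#' Correlation matrix implied by a correlated-trajectory spec
#' @param spec a [correlated_trajectory_spec()].
#' @return The n_atoms x n_atoms planted correlation matrix.
#' @export
planted_correlation <- function(spec) {
  b <- spec$block_assignment
  same <- outer(b, b, "==")
  C <- ifelse(same, spec$intra, spec$inter)
  diag(C) <- 1
  C
}

#' Generate a trajectory with planted block correlations
#'
#' @param spec a [correlated_trajectory_spec()].
#' @return An `md_ensemble`; `ground_truth()` holds the planted correlation
#'   matrix and the spec.
#' @export
gen_correlated_trajectory <- function(spec) {
  stopifnot(inherits(spec, "correlated_trajectory_spec"))
  C <- planted_correlation(spec)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("implied covariance is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  }
  n <- nrow(C)
  L <- t(chol(C + diag(1e-10, n)))
  ref <- coords(spec$reference)
  out <- with_seed(spec$seed, {
    per_axis <- lapply(1:3, function(d) {
      Z <- matrix(stats::rnorm(n * spec$n_frames), nrow = n)
      spec$fluctuation_sd * (L %*% Z)   # n x F
    })
    frames <- lapply(seq_len(spec$n_frames), function(f) {
      ref + cbind(per_axis[[1]][, f], per_axis[[2]][, f], per_axis[[3]][, f])
    })
    md_ensemble(spec$reference, frames, times = spec$dt * (seq_len(spec$n_frames) - 1))
  })
  attr(out, "ground_truth") <- list(correlation = C, spec = spec)
  out
}
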