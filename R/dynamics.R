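#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1, reflections corrected via the SVD
#' sign fix) and translation minimising the RMSD between the selected atoms
#' of `mobile` and `reference`, and reports that minimised RMSD.
#'
#' @param mobile,reference `n x 3` coordinate matrices.
#' @param selection optional atom indices used for the fit (default: all);
#'   at least 3 non-collinear atoms required.
#' @return List with `rotation` (3 x 3), `translation` (3-vector), `rmsd`
#'   (Angstrom over the selection after transform), and `transform(x)`, a
#'   function applying the fit to any `n x 3` matrix.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) stop("coordinate dimension mismatch")
  sel <- if (is.null(selection)) seq_len(nrow(mobile)) else as.integer(selection)
  if (length(sel) < 3) stop("degenerate geometry: need >= 3 atoms to superpose")
  M <- mobile[sel, , drop = FALSE]
  Rf <- reference[sel, , drop = FALSE]
  mc <- colMeans(M); rc <- colMeans(Rf)
  Mc <- sweep(M, 2, mc); Rc <- sweep(Rf, 2, rc)
  sv_m <- svd(Mc)$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1)) {
    stop("degenerate geometry: selected atoms are collinear")
  }
  H <- crossprod(Mc, Rc)                     # 3 x 3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  Rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transform <- function(x) {
    sweep(sweep(as.matrix(x), 2, mc) %*% t(Rot), 2, rc, "+")
  }
  fitted <- transform(M)
  rmsd <- sqrt(sum((fitted - Rf)^2) / length(sel))
  list(rotation = Rot, translation = rc - as.numeric(Rot %*% mc),
       rmsd = rmsd, transform = transform)
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' With `superpose = TRUE` each frame is first optimally superposed onto the
#' reference over the selection; the RMSD is then computed over the same
#' selection. The plateau summary is the mean and sd over the final
#' `plateau_fraction` of frames, the usual way a converged equilibration
#' RMSD level is reported.
#'
#' @param traj an `md_ensemble`.
#' @param reference an `md_structure` (or `n x 3` matrix) with matching atoms.
#' @param selection optional atom indices (default: all atoms).
#' @param superpose remove global rotation/translation first (default TRUE).
#' @param plateau_fraction final fraction summarised (default 0.25).
#' @return List with `rmsd` (per-frame vector, Angstrom), `times`,
#'   `plateau` (list mean, sd, n_frames).
#' @export
rmsd_series <- function(traj, reference, selection = NULL, superpose = TRUE,
                        plateau_fraction = 0.25) {
  stopifnot(inherits(traj, "md_ensemble"))
  ref <- if (inherits(reference, "md_structure")) coords(reference) else as.matrix(reference)
  if (nrow(ref) != n_atoms(traj)) stop("topology mismatch with reference")
  sel <- if (is.null(selection)) seq_len(nrow(ref)) else as.integer(selection)
  vals <- vapply(traj$frames, function(f) {
    if (superpose) {
      kabsch_superpose(f, ref, sel)$rmsd
    } else {
      sqrt(sum((f[sel, , drop = FALSE] - ref[sel, , drop = FALSE])^2) / length(sel))
    }
  }, numeric(1))
  n <- length(vals)
  tail_n <- max(1L, floor(plateau_fraction * n))
  tail_vals <- vals[(n - tail_n + 1L):n]
  list(rmsd = vals, times = traj$times,
       plateau = list(mean = mean(tail_vals), sd = stats::sd(tail_vals),
                      n_frames = tail_n))
}

#' Superpose all frames onto their mean structure
#'
#' Two-pass iterative scheme: frames are superposed onto a running reference
#' (frame 1, then the mean of the superposed frames), which removes global
#' rigid-body motion deterministically before RMSF/DCCM analysis.
#'
#' @param traj an `md_ensemble`.
#' @param selection atoms used for the fit (default: all).
#' @param iterations mean-refinement passes (default 2).
#' @return An `md_ensemble` of superposed frames.
#' @export
superpose_ensemble <- function(traj, selection = NULL, iterations = 2) {
  stopifnot(inherits(traj, "md_ensemble"))
  frames <- traj$frames
  ref <- frames[[1]]
  for (it in seq_len(iterations)) {
    frames <- lapply(frames, function(f) {
      kabsch_superpose(f, ref, selection)$transform(f)
    })
    ref <- Reduce(`+`, frames) / length(frames)
  }
  md_ensemble(traj$topology, frames, traj$times)
}

#' Frames of an ensemble as a frames x atoms x 3 array
#' @noRd
frame_array <- function(traj, sel) {
  n <- length(sel)
  arr <- vapply(traj$frames, function(f) f[sel, , drop = FALSE],
                matrix(0, n, 3))
  aperm(arr, c(3, 1, 2))   # F x n x 3
}

#' Root-mean-square fluctuation per atom
#'
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` over frames, after optional removal of
#' global motion. For isotropic Gaussian jitter of per-axis sd sigma the
#' expected RMSF is `sigma * sqrt(3)`.
#'
#' @param traj an `md_ensemble` with >= 2 frames.
#' @param selection optional atom indices (default: all).
#' @param superpose superpose frames onto the mean structure first
#'   (default FALSE: frames are assumed pre-aligned).
#' @return Numeric vector of per-atom RMSF in Angstrom.
#' @export
rmsf <- function(traj, selection = NULL, superpose = FALSE) {
  stopifnot(inherits(traj, "md_ensemble"))
  if (n_frames(traj) < 2) stop("insufficient data: need >= 2 frames")
  if (superpose) traj <- superpose_ensemble(traj, selection)
  sel <- if (is.null(selection)) seq_len(n_atoms(traj)) else as.integer(selection)
  arr <- frame_array(traj, sel)                       # F x n x 3
  mu <- apply(arr, c(2, 3), mean)
  dev <- sweep(arr, c(2, 3), mu)
  sqrt(apply(dev^2, 2, sum) / dim(arr)[1])
}

#' Dynamic cross-correlation map of positional fluctuations
#'
#' Scalar (dot-product) normalized covariance of atomic displacements about
#' their trajectory means:
#' \deqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#'   \sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}}
#' Frames should be free of global rigid-body motion; by default the
#' trajectory is superposed onto its mean structure first (2 passes). An
#' atom with zero positional variance gets a zero row/column (diagonal 1)
#' and a warning.
#'
#' @param traj an `md_ensemble` with >= 2 frames.
#' @param selection atom indices of the map (default: all; typically the
#'   C-alpha selection).
#' @param superpose remove global motion first (default TRUE; set FALSE for
#'   trajectories generated in a common frame).
#' @return A `correlation_map`: list with `matrix` (symmetric, unit
#'   diagonal) and `atom_ids` (the selection indices).
#' @export
dccm <- function(traj, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(traj, "md_ensemble"))
  if (n_frames(traj) < 2) stop("insufficient data: need >= 2 frames")
  sel <- if (is.null(selection)) seq_len(n_atoms(traj)) else as.integer(selection)
  if (superpose) traj <- superpose_ensemble(traj, sel)
  arr <- frame_array(traj, sel)                       # F x n x 3
  nf <- dim(arr)[1]
  mu <- apply(arr, c(2, 3), mean)
  num <- matrix(0, length(sel), length(sel))
  for (d in 1:3) {
    Dd <- arr[, , d] - matrix(mu[, d], nf, length(sel), byrow = TRUE)
    num <- num + crossprod(Dd)
  }
  v <- diag(num)
  zero <- v <= 1e-300
  if (any(zero)) {
    warning(sum(zero), " zero-variance atom(s): rows/columns set to 0")
    v[zero] <- 1
  }
  C <- num / sqrt(outer(v, v))
  C[zero, ] <- 0; C[, zero] <- 0
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  structure(list(matrix = C, atom_ids = sel), class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("correlation_map: %d x %d atoms\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Classified apo-to-holo correlation changes
#'
#' Reports atom pairs whose correlation changes by at least `threshold` in
#' magnitude between conditions, classified `enhanced` when the holo
#' correlation magnitude exceeds the apo one and `weakened` otherwise —
#' i.e. whether ligand binding strengthens or loosens that dynamic coupling.
#' Edges are sorted by `|delta|` descending.
#'
#' @param apo,holo `correlation_map` objects over identical atom ids.
#' @param threshold minimum `|c_holo - c_apo|` to report (default 0.2).
#' @return data.frame with `i`, `j` (atom ids, i < j position-wise),
#'   `c_apo`, `c_holo`, `delta`, `classification`.
#' @export
correlation_change <- function(apo, holo, threshold = 0.2) {
  stopifnot(inherits(apo, "correlation_map"), inherits(holo, "correlation_map"))
  if (!identical(apo$atom_ids, holo$atom_ids)) {
    stop("atom ids of the two maps must match")
  }
  A <- apo$matrix; H <- holo$matrix
  n <- nrow(A)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  delta <- H[ut] - A[ut]
  keep <- abs(delta) >= threshold
  out <- data.frame(
    i = apo$atom_ids[ut[keep, 1]],
    j = apo$atom_ids[ut[keep, 2]],
    c_apo = A[ut][keep], c_holo = H[ut][keep], delta = delta[keep],
    stringsAsFactors = FALSE)
  out$classification <- ifelse(abs(out$c_holo) > abs(out$c_apo),
                               "enhanced", "weakened")
  out <- out[order(-abs(out$delta), out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a correlation map as a CSV matrix
#' @param map a `correlation_map`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_correlation_csv <- function(map, path) {
  m <- as.data.frame(map$matrix)
  names(m) <- paste0("a", map$atom_ids)
  utils::write.csv(cbind(atom_id = map$atom_ids, m), path, row.names = FALSE)
  invisible(path)
}
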