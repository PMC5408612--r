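#' @title Structure and ensemble containers
#' @name structure-containers
#' @description
#' `md_structure` holds one conformation: an atom table (serial, name, element,
#' resname, resid, chain) plus an `n x 3` coordinate matrix in Angstrom.
#' `md_ensemble` holds a shared topology (`md_structure`) and a list of
#' per-frame coordinate matrices with strictly increasing frame times in ns.
NULL

#' Create a structure object
#'
#' @param atoms data.frame with columns `serial` (integer), `name`, `element`,
#'   `resname` (character), `resid` (integer), `chain` (character).
#' @param xyz numeric matrix, `nrow(atoms)` x 3, coordinates in Angstrom.
#' @param title optional title string.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz, title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  required <- c("serial", "name", "element", "resname", "resid", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L) {
    stop("xyz must be an n_atoms x 3 matrix")
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(chain, resid, name) must be unique within a structure")
  }
  # chain labels must partition atoms contiguously
  r <- rle(atoms$chain)$values
  if (anyDuplicated(r)) stop("chain labels must be contiguous blocks")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  out <- list(atoms = atoms, xyz = xyz, title = as.character(title)[1])
  class(out) <- "md_structure"
  out
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, %d chains%s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              if (nzchar(x$title)) paste0(" (", x$title, ")") else ""))
  invisible(x)
}

#' Number of atoms in a structure or ensemble
#' @param x an `md_structure` or `md_ensemble`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_ensemble")) x <- x$topology
  nrow(x$atoms)
}

#' Coordinates of a structure
#' @param x an `md_structure`.
#' @return Numeric `n x 3` matrix (Angstrom).
#' @export
coords <- function(x) x$xyz

#' Create a structure ensemble (shared topology, many frames)
#'
#' @param topology an `md_structure` giving the atom identities; its own
#'   coordinates are frame 1's unless `frames` is supplied.
#' @param frames list of `n_atoms x 3` coordinate matrices.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @return An object of class `md_ensemble`.
#' @export
md_ensemble <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "md_structure"))
  if (!is.list(frames) || length(frames) == 0L) {
    stop("frames must be a non-empty list of coordinate matrices")
  }
  n <- n_atoms(topology)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    storage.mode(f) <- "double"
    if (nrow(f) != n || ncol(f) != 3L) {
      stop("every frame must be an n_atoms x 3 matrix matching the topology")
    }
    if (!all(is.finite(f))) stop("frame coordinates must be finite")
    f
  })
  if (is.null(times)) times <- seq_along(frames) - 1
  times <- as.numeric(times)
  if (length(times) != length(frames)) stop("one time per frame required")
  if (any(diff(times) <= 0)) stop("frame_times must be strictly increasing")
  out <- list(topology = topology, frames = frames, times = times)
  class(out) <- "md_ensemble"
  out
}

#' @export
print.md_ensemble <- function(x, ...) {
  cat(sprintf("md_ensemble: %d frames x %d atoms, t = [%g, %g] ns\n",
              length(x$frames), n_atoms(x), min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an `md_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Select atoms by chain, residue range, atom name and element
#'
#' Conjunction over the supplied fields; within a field, a vector means "any
#' of". Residues are matched by identity so ranges are expressed as e.g.
#' `resid = 18:23`. An empty result is a valid (empty) selection. Selection
#' is order-preserving and idempotent: re-selecting an already selected subset
#' with the same query returns the same indices.
#'
#' @param structure an `md_structure` (or `md_ensemble`, whose topology is used).
#' @param chain,resid,name,element optional filters; `NULL` means "any".
#' @param ... must be empty; an unknown filter name is an error.
#' @return Integer vector of 1-based atom indices, class `atom_selection`.
#' @examples
#' s <- gen_pseudo_nucleosome(pseudo_nucleosome_spec(seed = 1))
#' sel <- select_atoms(s, chain = "H4", resid = 18:23)
#' @export
select_atoms <- function(structure, chain = NULL, resid = NULL,
                         name = NULL, element = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown selection field(s): ", paste(names(extra), collapse = ", "))
  }
  if (inherits(structure, "md_ensemble")) structure <- structure$topology
  stopifnot(inherits(structure, "md_structure"))
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain))   keep <- keep & at$chain   %in% chain
  if (!is.null(resid))   keep <- keep & at$resid   %in% resid
  if (!is.null(name))    keep <- keep & at$name    %in% name
  if (!is.null(element)) keep <- keep & at$element %in% element
  idx <- which(keep)
  structure(as.integer(idx), class = "atom_selection")
}

#' Subset a structure to a selection
#' @param structure an `md_structure`.
#' @param selection integer atom indices (e.g. from [select_atoms()]).
#' @return A new `md_structure` with only the selected atoms.
#' @export
subset_structure <- function(structure, selection) {
  stopifnot(inherits(structure, "md_structure"))
  idx <- as.integer(selection)
  if (length(idx) == 0L) stop("cannot build a structure from an empty selection")
  md_structure(structure$atoms[idx, , drop = FALSE],
               structure$xyz[idx, , drop = FALSE],
               structure$title)
}

#' Extract an evenly spaced snapshot ensemble from a trajectory window
#'
#' Target times are `window_start + k * (window length)/n_snapshots` for
#' `k = 0 .. n_snapshots - 1`; each target is snapped to the nearest stored
#' frame inside the window (ties resolved to the earlier frame). This mirrors
#' the common practice of harvesting a receptor ensemble (e.g. 120 snapshots
#' from the last 6 ns of an equilibration run) for ensemble docking.
#'
#' @param traj an `md_ensemble`.
#' @param window_start,window_end window in ns.
#' @param n_snapshots number of snapshots to extract.
#' @return An `md_ensemble` with `n_snapshots` frames, times strictly
#'   increasing and inside the window.
#' @export
extract_ensemble <- function(traj, window_start, window_end, n_snapshots) {
  stopifnot(inherits(traj, "md_ensemble"))
  if (window_end <= window_start) stop("window_end must exceed window_start")
  n_snapshots <- as.integer(n_snapshots)
  if (n_snapshots < 1L) stop("n_snapshots must be >= 1")
  in_win <- which(traj$times >= window_start - 1e-9 &
                  traj$times <= window_end + 1e-9)
  if (length(in_win) < n_snapshots) {
    stop(sprintf("insufficient frames: window holds %d, %d requested",
                 length(in_win), n_snapshots))
  }
  spacing <- (window_end - window_start) / n_snapshots
  targets <- window_start + (seq_len(n_snapshots) - 1L) * spacing
  tw <- traj$times[in_win]
  pick <- vapply(targets, function(tt) {
    d <- abs(tw - tt)
    # tie -> earlier frame: which.min returns the first minimum, and tw is sorted
    in_win[which.min(round(d, 9))]
  }, integer(1))
  if (anyDuplicated(pick)) {
    stop("snapshot times collide on stored frames; request fewer snapshots")
  }
  md_ensemble(traj$topology, traj$frames[pick], traj$times[pick])
}
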