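#' Water-oxygen coordinate set for one frame
#'
#' Waters are represented by their oxygen positions only: captions counting
#' "water molecules" are conventionally realised by the oxygen position, and
#' hydrogens add nothing to a distance count.
#'
#' @param coords `n x 3` matrix of oxygen coordinates in Angstrom (0 rows
#'   allowed).
#' @param frame integer frame index.
#' @return An object of class `water_set`.
#' @export
water_set <- function(coords, frame = 1L) {
  coords <- as.matrix(coords)
  if (length(coords) == 0) coords <- matrix(numeric(0), ncol = 3)
  if (ncol(coords) != 3) stop("water coordinates must be n x 3")
  if (!all(is.finite(coords))) stop("water coordinates must be finite")
  structure(list(coords = coords, frame = as.integer(frame)),
            class = "water_set")
}

#' @export
print.water_set <- function(x, ...) {
  cat(sprintf("water_set: %d oxygens (frame %d)\n", nrow(x$coords), x$frame))
  invisible(x)
}

#' Read water oxygens from a PDB file
#'
#' Accepts resnames HOH, WAT and TIP3; keeps atoms whose name starts with O.
#' @param path PDB path (multi-model gives one `water_set` per model).
#' @return List of `water_set`.
#' @export
read_waters_pdb <- function(path) {
  structs <- read_pdb(path)
  lapply(seq_along(structs), function(i) {
    s <- structs[[i]]
    keep <- s$atoms$resname %in% c("HOH", "WAT", "TIP3") &
      startsWith(s$atoms$name, "O")
    water_set(s$xyz[keep, , drop = FALSE], frame = i)
  })
}

#' Squared-distance matrix helper
#' @noRd
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' First-hydration-shell water counts around selected residues
#'
#' A water counts for a residue when its oxygen lies within `cutoff`
#' (inclusive) of any heavy atom of that residue. Waters shared between
#' residues appear in each residue's count; the net count deduplicates them
#' (each water counted once if within the shell of any selected residue).
#'
#' @param waters a `water_set`.
#' @param structure an `md_structure`.
#' @param selection atom indices (e.g. [select_atoms()]) defining the target
#'   residues; must be non-empty.
#' @param cutoff shell cutoff in Angstrom (default 3.5).
#' @return List with `per_residue` (data.frame chain, resid, count) and `net`
#'   (deduplicated water count).
#' @export
count_first_shell <- function(waters, structure, selection, cutoff = 3.5) {
  stopifnot(inherits(waters, "water_set"), inherits(structure, "md_structure"))
  if (cutoff <= 0) stop("cutoff must be positive")
  idx <- as.integer(selection)
  if (length(idx) == 0) stop("empty target selection")
  at <- structure$atoms[idx, , drop = FALSE]
  xyz <- structure$xyz[idx, , drop = FALSE]
  heavy <- toupper(at$element) != "H"
  at <- at[heavy, , drop = FALSE]
  xyz <- xyz[heavy, , drop = FALSE]
  if (nrow(at) == 0) stop("target selection contains no heavy atoms")
  res_key <- paste(at$chain, at$resid, sep = "\r")
  res_tab <- unique(data.frame(chain = at$chain, resid = at$resid,
                               stringsAsFactors = FALSE))
  res_tab <- res_tab[order(res_tab$chain, res_tab$resid), , drop = FALSE]
  rownames(res_tab) <- NULL
  if (nrow(waters$coords) == 0) {
    res_tab$count <- 0L
    return(list(per_residue = res_tab, net = 0L))
  }
  d <- cross_dist(waters$coords, xyz)          # n_wat x n_atoms
  within <- d <= cutoff + 1e-12
  keys <- paste(res_tab$chain, res_tab$resid, sep = "\r")
  res_tab$count <- vapply(keys, function(k) {
    sum(apply(within[, res_key == k, drop = FALSE], 1, any))
  }, integer(1), USE.NAMES = FALSE)
  list(per_residue = res_tab, net = sum(apply(within, 1, any)))
}

#' Mean water occupancy of a binding-site sphere
#'
#' Counts oxygens within `cutoff` (inclusive) of the site center in each
#' frame and returns the mean with a block-averaged standard error (10
#' blocks when the trajectory is long enough, otherwise as many length-2+
#' blocks as fit), mirroring how long-simulation occupancy averages carry
#' their errors.
#'
#' @param water_frames list of `water_set`, one per frame (>= 2 frames).
#' @param site_center 3-vector, Angstrom.
#' @param cutoff sphere radius in Angstrom (default 10).
#' @param n_blocks blocks for the SE (default 10).
#' @return List with `mean`, `se`, and the per-frame `counts`.
#' @export
site_occupancy <- function(water_frames, site_center, cutoff = 10,
                           n_blocks = 10) {
  if (length(water_frames) < 2) stop("insufficient data: need >= 2 frames")
  if (cutoff <= 0) stop("cutoff must be positive")
  ctr <- as.numeric(site_center)
  counts <- vapply(water_frames, function(w) {
    stopifnot(inherits(w, "water_set"))
    if (nrow(w$coords) == 0) return(0L)
    d2 <- rowSums(sweep(w$coords, 2, ctr)^2)
    sum(d2 <= cutoff^2 + 1e-9)
  }, integer(1))
  nb <- min(n_blocks, length(counts) %/% 2L)
  se <- if (stats::sd(counts) == 0) 0 else block_standard_error(counts, nb)
  list(mean = mean(counts), se = se, counts = counts)
}

#' Apo-to-holo dewetting per binding site
#'
#' The dewetting of a site is the drop in its water occupancy upon ligand
#' binding: `delta = apo - holo`, with standard errors propagated in
#' quadrature.
#'
#' @param apo,holo named lists mapping site id -> occupancy (as returned by
#'   [site_occupancy()]); site ids must match.
#' @return data.frame with `site_id`, `apo`, `holo`, `delta`, `se`.
#' @export
dewetting_delta <- function(apo, holo) {
  if (!setequal(names(apo), names(holo)) || is.null(names(apo))) {
    stop("apo and holo site ids must match")
  }
  ids <- sort(names(apo))
  out <- data.frame(
    site_id = ids,
    apo = vapply(apo[ids], `[[`, numeric(1), "mean"),
    holo = vapply(holo[ids], `[[`, numeric(1), "mean"),
    stringsAsFactors = FALSE)
  out$delta <- out$apo - out$holo
  out$se <- sqrt(vapply(apo[ids], `[[`, numeric(1), "se")^2 +
                   vapply(holo[ids], `[[`, numeric(1), "se")^2)
  rownames(out) <- NULL
  out
}
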