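# Independent oracles used to cross-check the package's implementations.

# Horn's quaternion method for optimal rigid superposition: an independent
# route to the least-squares RMSD that never touches the SVD-based code path.
quaternion_rmsd <- function(mobile, reference) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(M, R)   # Sxy = sum m_x r_y
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(M^2) + sum(R^2) - 2 * lam) / nrow(M)
  sqrt(max(msd, 0))
}

# Brute-force all-pairs contact-residue finder.
brute_contacts <- function(pose_coords, receptor, cutoff = 4.0) {
  at <- receptor$atoms
  hits <- list()
  for (k in seq_len(nrow(at))) {
    if (toupper(at$element[k]) == "H") next
    for (l in seq_len(nrow(pose_coords))) {
      if (sqrt(sum((receptor$xyz[k, ] - pose_coords[l, ])^2)) <= cutoff) {
        hits[[length(hits) + 1L]] <- at[k, c("chain", "resid", "resname")]
        break
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(chain = character(0), resid = integer(0),
                      resname = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, hits))
  res <- res[order(res$chain, res$resid), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Brute-force shell count: each water once if within cutoff of any heavy
# atom of the selection; plus per-residue loop counts.
brute_shell <- function(waters, structure, selection, cutoff = 3.5) {
  at <- structure$atoms[selection, , drop = FALSE]
  xyz <- structure$xyz[selection, , drop = FALSE]
  keep <- toupper(at$element) != "H"
  at <- at[keep, , drop = FALSE]; xyz <- xyz[keep, , drop = FALSE]
  n_wat <- nrow(waters$coords)
  net <- 0L
  if (n_wat > 0) {
    for (w in seq_len(n_wat)) {
      for (k in seq_len(nrow(xyz))) {
        if (sqrt(sum((waters$coords[w, ] - xyz[k, ])^2)) <= cutoff) {
          net <- net + 1L
          break
        }
      }
    }
  }
  net
}

# Small random structure for I/O and geometry tests.
random_structure <- function(n = 50, seed = 1, chains = c("A", "B")) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    ch <- sort(rep_len(chains, n))
    at <- data.frame(serial = seq_len(n), name = paste0("C", seq_len(n)),
                     element = "C", resname = "ALA",
                     resid = ave(seq_len(n), ch, FUN = seq_along),
                     chain = ch, stringsAsFactors = FALSE)
    md_structure(at, matrix(round(stats::runif(3 * n, -50, 50), 3), ncol = 3),
                 title = "random test structure")
  })
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
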