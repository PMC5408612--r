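#' Gas constant in kcal mol^-1 K^-1
#' @keywords internal
.R_KCAL <- 1.9872e-3

#' Per-frame ligand-environment interaction energy series
#'
#' Holds van der Waals and electrostatic ligand-environment interaction
#' energies for one simulation of the ligand either bound to the receptor or
#' free in solution. These are the inputs of the linear interaction energy
#' (LIE) estimator; the package never computes them from coordinates.
#'
#' @param e_vdw,e_el numeric vectors of per-frame energies (kcal/mol).
#' @param state "bound" or "free".
#' @param dt frame spacing in ns.
#' @return An object of class `energy_series`.
#' @export
energy_series <- function(e_vdw, e_el, state = c("bound", "free"), dt = 0.1) {
  state <- match.arg(state)
  e_vdw <- as.numeric(e_vdw); e_el <- as.numeric(e_el)
  if (length(e_vdw) != length(e_el)) stop("e_vdw and e_el must have equal length")
  if (length(e_vdw) < 1L) stop("energy series must be non-empty")
  if (!all(is.finite(e_vdw)) || !all(is.finite(e_el))) stop("energies must be finite")
  out <- list(frames = data.frame(e_vdw = e_vdw, e_el = e_el),
              state = state, dt = as.numeric(dt))
  class(out) <- "energy_series"
  out
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("energy_series (%s): %d frames, <e_vdw> = %.2f, <e_el> = %.2f kcal/mol\n",
              x$state, nrow(x$frames), mean(x$frames$e_vdw), mean(x$frames$e_el)))
  invisible(x)
}

#' LIE parameter set
#'
#' The canonical empirical coefficients of the linear interaction energy
#' method: `alpha` scales the van der Waals average difference, `beta` the
#' electrostatic one, and `gamma` is a constant offset in kcal/mol. Defaults
#' are the method's standard alpha = 0.18, beta = 0.5, gamma = 0.
#'
#' @param alpha,beta dimensionless non-negative coefficients.
#' @param gamma offset in kcal/mol.
#' @return A `lie_params` list.
#' @export
lie_params <- function(alpha = 0.18, beta = 0.5, gamma = 0) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma), class = "lie_params")
}

#' Block-averaged standard error of an autocorrelated series
#'
#' Splits the series into `n_blocks` contiguous blocks of equal length
#' (truncating any remainder), and returns `sd(block means)/sqrt(n_blocks)`.
#' For series whose autocorrelation time is short relative to the block
#' length this is an approximately unbiased standard error of the overall
#' mean, unlike the naive `sd/sqrt(n)` which underestimates it for positively
#' autocorrelated data.
#'
#' @param x numeric vector of per-frame values.
#' @param n_blocks number of blocks (default 10).
#' @return Standard error of the mean of `x`.
#' @export
block_standard_error <- function(x, n_blocks = 10) {
  x <- as.numeric(x)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("n_blocks must be >= 2")
  if (length(x) < 2L * n_blocks) {
    stop(sprintf("insufficient data: need >= %d points for %d blocks",
                 2L * n_blocks, n_blocks))
  }
  blen <- length(x) %/% n_blocks
  xm <- matrix(x[seq_len(blen * n_blocks)], nrow = blen)
  stats::sd(colMeans(xm)) / sqrt(n_blocks)
}

#' Linear interaction energy binding free energy
#'
#' Computes
#' \deqn{\Delta G = \alpha(\langle E_{vdW}\rangle_{bound} -
#'   \langle E_{vdW}\rangle_{free}) + \beta(\langle E_{el}\rangle_{bound} -
#'   \langle E_{el}\rangle_{free}) + \gamma}
#' from bound- and free-state interaction-energy series. The standard error
#' propagates the per-series block standard errors (see
#' [block_standard_error()]) of each of the four component means through the
#' linear formula:
#' `se^2 = alpha^2 (se_vdw,b^2 + se_vdw,f^2) + beta^2 (se_el,b^2 + se_el,f^2)`.
#'
#' @param bound,free `energy_series` objects with matching state labels.
#' @param params a [lie_params()] object.
#' @param n_blocks blocks for the standard error (default 10).
#' @param temperature temperature in K used for the derived constant.
#' @return A `binding_estimate`: list with `delta_g`, `se` (kcal/mol),
#'   `K` (mM^-1), `temperature`, `params`.
#' @examples
#' b <- energy_series(c(-20, -20), c(-10, -10), "bound")
#' f <- energy_series(c(-15, -15), c(-6, -6), "free")
#' lie_delta_g(b, f, lie_params(0.18, 0.5, 0))$delta_g  # -2.9
#' @export
lie_delta_g <- function(bound, free, params = lie_params(), n_blocks = 10,
                        temperature = 300) {
  stopifnot(inherits(bound, "energy_series"), inherits(free, "energy_series"))
  if (bound$state != "bound" || free$state != "free") {
    stop("state mislabel: expected one 'bound' and one 'free' series")
  }
  a <- params$alpha; b <- params$beta
  dvdw <- mean(bound$frames$e_vdw) - mean(free$frames$e_vdw)
  del <- mean(bound$frames$e_el) - mean(free$frames$e_el)
  dg <- a * dvdw + b * del + params$gamma
  se_one <- function(w) {
    if (length(w) < 2L * n_blocks || stats::sd(w) == 0) {
      if (length(w) < 2L) return(NA_real_)
      # short series: fall back to the naive SE
      return(stats::sd(w) / sqrt(length(w)))
    }
    block_standard_error(w, n_blocks)
  }
  se <- sqrt(a^2 * (se_one(bound$frames$e_vdw)^2 + se_one(free$frames$e_vdw)^2) +
             b^2 * (se_one(bound$frames$e_el)^2 + se_one(free$frames$e_el)^2))
  structure(list(delta_g = dg, se = se,
                 K = delta_g_to_K(dg, temperature),
                 temperature = temperature, params = params),
            class = "binding_estimate")
}

#' @export
print.binding_estimate <- function(x, ...) {
  cat(sprintf("binding estimate: dG = %.2f +/- %.2f kcal/mol, K = %.4f mM^-1 (T = %g K)\n",
              x$delta_g, x$se, x$K, x$temperature))
  invisible(x)
}

#' Convert a standard binding free energy to an equilibrium constant
#'
#' `K = exp(-dG / (R T))` in M^-1 under the 1 M standard state, reported in
#' mM^-1 (divided by 1000). `R = 1.9872e-3` kcal mol^-1 K^-1. The value is
#' returned unrounded; use `round(K, 4)` for 4-decimal table formatting
#' (R rounds half-even).
#'
#' @param delta_g standard binding free energy in kcal/mol.
#' @param temperature temperature in K (default 300).
#' @return Equilibrium constant in mM^-1.
#' @examples
#' round(delta_g_to_K(-1.75), 4)  # 0.0188
#' @export
delta_g_to_K <- function(delta_g, temperature = 300) {
  if (temperature <= 0) stop("temperature must be positive")
  exp(-delta_g / (.R_KCAL * temperature)) / 1000
}

#' Convert an equilibrium constant (mM^-1) back to a free energy
#'
#' Exact inverse of [delta_g_to_K()].
#'
#' @param K equilibrium constant in mM^-1, must be positive.
#' @param temperature temperature in K (default 300).
#' @return Standard binding free energy in kcal/mol.
#' @export
K_to_delta_g <- function(K, temperature = 300) {
  if (any(K <= 0)) stop("K must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  -.R_KCAL * temperature * log(K * 1000)
}

#' Ligand-per-particle stoichiometry report
#'
#' Exact concentration ratios for an in vitro binding experiment: how many
#' ligand molecules are present per particle (e.g. per reconstituted
#' chromatin fiber) and per subunit (e.g. per nucleosome). No rounding is
#' applied; the caller formats.
#'
#' @param ligand_conc ligand concentration in M.
#' @param particle_conc particle concentration in M.
#' @param subunits subunits per particle (e.g. nucleosomes per fiber).
#' @return A `stoichiometry_report` list with the inputs and the exact
#'   `ligands_per_particle` and `ligands_per_subunit` ratios.
#' @examples
#' r <- ligand_stoichiometry(100e-6, 60e-9, 36)
#' round(r$ligands_per_particle, 2)  # 1666.67
#' round(r$ligands_per_subunit, 2)   # 46.30
#' @export
ligand_stoichiometry <- function(ligand_conc, particle_conc, subunits) {
  if (ligand_conc <= 0 || particle_conc <= 0 || subunits <= 0) {
    stop("concentrations and subunit count must be positive")
  }
  per_particle <- ligand_conc / particle_conc
  structure(list(ligand_conc = ligand_conc, particle_conc = particle_conc,
                 subunits_per_particle = subunits,
                 ligands_per_particle = per_particle,
                 ligands_per_subunit = per_particle / subunits),
            class = "stoichiometry_report")
}

#' @export
print.stoichiometry_report <- function(x, ...) {
  cat(sprintf("stoichiometry: %.2f ligands/particle, %.2f ligands/subunit (%d subunits)\n",
              x$ligands_per_particle, x$ligands_per_subunit,
              as.integer(x$subunits_per_particle)))
  invisible(x)
}
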