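# Synthetic inputs with planted ground truth.
#
# Conventions: lipid MS intensities are log-normal; SEC elution peaks are
# Gaussian in fraction index. All randomness flows from one explicit seed
# (restored on exit; no hidden global state left behind).

.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Ground truth for a synthetic SEC co-elution run
#'
#' @param ltp_id Protein identifier.
#' @param planted_ligands Lipid ids that truly co-elute with the protein.
#' @param background_lipids Lipid ids eluting elsewhere; disjoint from
#'   \code{planted_ligands}.
#' @param noise_sd Gaussian noise standard deviation as a fraction of each
#'   profile's peak intensity (default 0.05).
#' @param n_fractions Number of SEC fractions (>= 5; default 40).
#' @return Object of class \code{"sec_sim_truth"}.
#' @export
sec_sim_truth <- function(ltp_id, planted_ligands, background_lipids,
                          noise_sd = 0.05, n_fractions = 40) {
  if (length(intersect(planted_ligands, background_lipids)) > 0)
    stop("planted_ligands and background_lipids overlap", call. = FALSE)
  if (n_fractions < 5) stop("n_fractions must be >= 5", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(ltp_id = ltp_id,
                 planted_ligands = unique(as.character(planted_ligands)),
                 background_lipids = unique(as.character(background_lipids)),
                 noise_sd = noise_sd, n_fractions = as.integer(n_fractions)),
            class = "sec_sim_truth")
}

.gauss_peak <- function(n, center, width, height) {
  height * exp(-0.5 * ((seq_len(n) - center) / width) ^ 2)
}

#' Generate a synthetic SEC co-elution run
#'
#' The protein elutes as a Gaussian peak. Planted ligands are the protein
#' profile times a positive scale plus Gaussian noise of sd
#' \code{noise_sd} x their own peak; background lipids get Gaussian peaks
#' whose apex is displaced by at least 2 fractions from the protein's, so
#' planted vs background is unambiguous at test time. Bit-identical output
#' for a fixed seed.
#'
#' @param truth A \code{\link{sec_sim_truth}}.
#' @param seed Integer seed.
#' @param peak_width Chromatographic peak width in fractions (default 1.5).
#' @return list with \code{protein} (an \code{\link{elution_profile}}),
#'   \code{lipids} (data.frame \code{lipid_id} + fraction columns
#'   \code{F1..Fn}) and \code{truth}.
#' @export
gen_sec_run <- function(truth, seed, peak_width = 1.5) {
  stopifnot(inherits(truth, "sec_sim_truth"))
  .with_seed(seed, {
    n <- truth$n_fractions
    center <- floor(n / 2)
    prot <- .gauss_peak(n, center, peak_width, 1e6)

    ids <- c(truth$planted_ligands, truth$background_lipids)
    prof <- matrix(0, nrow = length(ids), ncol = n,
                   dimnames = list(ids, paste0("F", seq_len(n))))
    for (id in truth$planted_ligands) {
      scale <- stats::rlnorm(1, meanlog = log(0.1), sdlog = 0.5)
      base <- prot * scale
      prof[id, ] <- pmax(0, base + stats::rnorm(n, 0, truth$noise_sd * max(base)))
    }
    # background apex displaced >= 2 fractions from the protein peak
    allowed <- setdiff(seq_len(n), (center - 1L):(center + 1L))
    for (id in truth$background_lipids) {
      pk <- sample(allowed, 1)
      height <- stats::rlnorm(1, meanlog = log(1e5), sdlog = 0.7)
      base <- .gauss_peak(n, pk, peak_width, height)
      prof[id, ] <- pmax(0, base + stats::rnorm(n, 0, truth$noise_sd * height))
    }
    lipids <- data.frame(lipid_id = ids, prof, stringsAsFactors = FALSE,
                         row.names = NULL, check.names = FALSE)
    list(protein = elution_profile(truth$ltp_id, prot, seq_len(n)),
         lipids = lipids, truth = truth)
  })
}

#' Ground truth for a synthetic overexpression panel
#'
#' @param ltp_id Panel (LTP) identifier.
#' @param species_ids Lipid species measured in the panel.
#' @param affected_species Named numeric vector of signed planted log2
#'   effect sizes (names in \code{species_ids}; finite and nonzero).
#' @param n_replicates Biological replicates per arm (>= 2; default 3).
#' @param baseline_log_mean Per-species mean of log2 intensity (scalar or
#'   named vector; default 20).
#' @param baseline_log_sd Per-species sd of log2 intensity (scalar or named
#'   vector; default 0.25).
#' @return Object of class \code{"oe_panel_truth"}.
#' @export
oe_panel_truth <- function(ltp_id, species_ids, affected_species = numeric(0),
                           n_replicates = 3, baseline_log_mean = 20,
                           baseline_log_sd = 0.25) {
  if (n_replicates < 2)
    stop("n_replicates must be >= 2 (tests undefined otherwise)", call. = FALSE)
  if (length(affected_species)) {
    if (is.null(names(affected_species)) ||
        !all(names(affected_species) %in% species_ids))
      stop("affected_species must be named by species in species_ids",
           call. = FALSE)
    if (any(!is.finite(affected_species) | affected_species == 0))
      stop("planted effects must be finite and nonzero", call. = FALSE)
  }
  expand <- function(x) {
    if (length(x) == 1) x <- stats::setNames(rep(x, length(species_ids)),
                                             species_ids)
    stopifnot(all(species_ids %in% names(x)))
    x[species_ids]
  }
  structure(list(ltp_id = ltp_id, species_ids = as.character(species_ids),
                 affected_species = affected_species,
                 n_replicates = as.integer(n_replicates),
                 baseline_log_mean = expand(baseline_log_mean),
                 baseline_log_sd = expand(baseline_log_sd)),
            class = "oe_panel_truth")
}

#' Generate a synthetic overexpression (gain-of-function) panel
#'
#' Control replicates are drawn log-normal (normal in log2 intensity at the
#' baseline parameters); induced replicates are shifted by the planted log2
#' effects. Reproducible for a fixed seed.
#'
#' @param truth An \code{\link{oe_panel_truth}}.
#' @param seed Integer seed.
#' @return A \code{\link{perturbation_panel}}; the truth is attached as
#'   attribute \code{"truth"}.
#' @export
gen_oe_panel <- function(truth, seed) {
  stopifnot(inherits(truth, "oe_panel_truth"))
  .with_seed(seed, {
    ns <- length(truth$species_ids)
    nr <- truth$n_replicates
    eff <- stats::setNames(rep(0, ns), truth$species_ids)
    eff[names(truth$affected_species)] <- truth$affected_species
    draw <- function(shift) {
      lg <- matrix(stats::rnorm(ns * nr,
                                mean = truth$baseline_log_mean + shift,
                                sd = truth$baseline_log_sd),
                   nrow = ns, ncol = nr)
      rownames(lg) <- truth$species_ids
      2 ^ lg
    }
    control <- draw(0)
    induced <- draw(eff)
    panel <- perturbation_panel(truth$ltp_id, truth$species_ids,
                                induced, control, paired = FALSE)
    attr(panel, "truth") <- truth
    panel
  })
}

#' Ground truth for synthetic co-localization maps
#'
#' @param pixel_count Number of pixels (>= 10).
#' @param coloc_pairs Two-column matrix (or list of length-2 vectors) of
#'   lipid-id pairs that share spatial support.
#' @param independent_lipids Lipid ids with independent spatial patterns.
#' @return Object of class \code{"coloc_truth"}.
#' @export
coloc_truth <- function(pixel_count, coloc_pairs, independent_lipids = character(0)) {
  if (pixel_count < 10) stop("pixel_count must be >= 10", call. = FALSE)
  if (is.list(coloc_pairs)) coloc_pairs <- do.call(rbind, coloc_pairs)
  coloc_pairs <- matrix(as.character(coloc_pairs), ncol = 2)
  structure(list(pixel_count = as.integer(pixel_count),
                 coloc_pairs = coloc_pairs,
                 independent_lipids = as.character(independent_lipids)),
            class = "coloc_truth")
}

#' Generate synthetic pixel-level co-localization maps
#'
#' Each co-localized pair shares one latent spatial pattern (a random
#' support of pixels with log-normal intensities); the two members observe
#' it under independent multiplicative log-normal noise. Independent lipids
#' get their own independent patterns. Every lipid is positive in at least
#' one pixel.
#'
#' @param truth A \code{\link{coloc_truth}}.
#' @param seed Integer seed.
#' @param noise_sd sd of the multiplicative log-noise (default 0.2; 0 gives
#'   members identical to the latent pattern).
#' @param support_frac Fraction of pixels in each latent support
#'   (default 0.3).
#' @return Matrix lipids x pixels of non-negative intensities.
#' @export
gen_coloc_maps <- function(truth, seed, noise_sd = 0.2, support_frac = 0.3) {
  stopifnot(inherits(truth, "coloc_truth"))
  .with_seed(seed, {
    np <- truth$pixel_count
    ids <- unique(c(as.vector(t(truth$coloc_pairs)), truth$independent_lipids))
    out <- matrix(0, nrow = length(ids), ncol = np,
                  dimnames = list(ids, paste0("px", seq_len(np))))
    latent <- function() {
      k <- max(1L, round(support_frac * np))
      sup <- sample.int(np, k)
      z <- numeric(np)
      z[sup] <- stats::rlnorm(k, meanlog = log(100), sdlog = 0.5)
      z
    }
    observe <- function(z) z * exp(stats::rnorm(np, 0, noise_sd))
    for (i in seq_len(nrow(truth$coloc_pairs))) {
      z <- latent()
      out[truth$coloc_pairs[i, 1], ] <- observe(z)
      out[truth$coloc_pairs[i, 2], ] <- observe(z)
    }
    for (id in truth$independent_lipids) out[id, ] <- observe(latent())
    out
  })
}

#' Write a hollow-sphere cavity fixture as a PDB file
#'
#' Places pseudo-atoms (carbon) on a sphere of radius \code{shell_radius} so
#' that neighbouring atom spheres overlap and enclose an empty central
#' cavity. For a zero-radius probe the enclosed cavity volume is close to
#' the closed form \eqn{(4/3)\pi(shell\_radius - atom\_radius)^3}, which
#' makes the fixture an analytic oracle for grid cavity-volume estimation.
#' Atom placement uses a Fibonacci spherical lattice under a seeded random
#' rotation; output files are byte-identical for a fixed seed.
#'
#' If \code{n_atoms} is too small for neighbouring atom spheres to overlap
#' (estimated lattice spacing >= 1.9 x \code{atom_radius}) the shell cannot
#' contain a probe and the fixture is flagged \code{leaky = TRUE} in its
#' metadata (and in a \code{REMARK} line).
#'
#' @param path Output PDB path.
#' @param shell_radius Sphere radius in Angstrom (default 10).
#' @param atom_radius Nominal atom radius used to choose the default lattice
#'   density (default 1.5).
#' @param n_atoms Number of shell atoms; default chooses a lattice spacing
#'   of about \code{0.6 * atom_radius} so the shell is watertight.
#' @param seed Integer seed for the lattice rotation.
#' @return (invisibly) list with \code{path}, \code{n_atoms},
#'   \code{shell_radius}, \code{atom_radius}, \code{spacing_estimate},
#'   \code{leaky}, \code{expected_cavity_volume} and the coordinate matrix.
#' @export
gen_cavity_fixture <- function(path, shell_radius = 10, atom_radius = 1.5,
                               n_atoms = NULL, seed = 1) {
  stopifnot(shell_radius > 0, atom_radius > 0)
  if (is.null(n_atoms))
    n_atoms <- ceiling(4 * pi * shell_radius ^ 2 / (0.6 * atom_radius) ^ 2)
  n_atoms <- as.integer(n_atoms)
  stopifnot(n_atoms >= 4)
  spacing_est <- sqrt(4 * pi * shell_radius ^ 2 / n_atoms)
  leaky <- spacing_est >= 1.9 * atom_radius

  .with_seed(seed, {
    # Fibonacci lattice on the unit sphere
    i <- seq_len(n_atoms) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / n_atoms
    r <- sqrt(pmax(0, 1 - z ^ 2))
    pts <- cbind(r * cos(phi), r * sin(phi), z)
    # seeded random rotation (QR of a Gaussian matrix)
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    rot <- qr.Q(qr_)
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    coords <- shell_radius * (pts %*% rot)
  })

  rec <- sprintf(
    "ATOM  %5d  C   SPH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n_atoms), rep(1L, n_atoms),
    coords[, 1], coords[, 2], coords[, 3])
  hdr <- c(
    "HEADER    SYNTHETIC CAVITY FIXTURE",
    sprintf("REMARK 900 SYNTHETIC HOLLOW SPHERE SHELL_RADIUS=%.3f ATOM_RADIUS=%.3f",
            shell_radius, atom_radius),
    sprintf("REMARK 900 N_ATOMS=%d SPACING_EST=%.3f LEAKY=%s SEED=%d",
            n_atoms, spacing_est, if (leaky) "YES" else "NO", as.integer(seed)))
  .write_lines_atomic(c(hdr, rec, "END"), path)

  invisible(list(path = path, n_atoms = n_atoms, shell_radius = shell_radius,
                 atom_radius = atom_radius, spacing_estimate = spacing_est,
                 leaky = leaky,
                 expected_cavity_volume =
                   4 / 3 * pi * (shell_radius - atom_radius) ^ 3,
                 coords = coords))
}

#' Generate a reference/mobilized lipidome pair with a planted
#' chain-length preference
#'
#' Builds a glycerophospholipid species pool on a grid of total chain
#' lengths and unsaturations; reference intensities follow a Gaussian
#' profile over total carbons, and the mobilized lipidome follows the same
#' profile shifted by \code{carbon_shift} (negative = preference for
#' shorter chains). Species-level multiplicative log-normal noise is
#' applied independently to both lipidomes.
#'
#' @param seed Integer seed.
#' @param carbon_shift Planted shift of the mean total chain length
#'   (default -2).
#' @param carbons Grid of total carbon numbers (default even 28-44).
#' @param double_bonds Grid of unsaturations (default 0-5).
#' @param center Reference mean chain length (default 36) and
#' @param width its Gaussian width (default 3).
#' @param noise_sd Species-level log-normal noise sd (default 0.3).
#' @return list with \code{reference} and \code{mobilized} (data.frames
#'   \code{lipid_id}, \code{intensity}) and \code{truth}
#'   (list with \code{carbon_shift}).
#' @export
gen_lipidome_pair <- function(seed, carbon_shift = -2,
                              carbons = seq(28, 44, by = 2),
                              double_bonds = 0:5, center = 36, width = 3,
                              noise_sd = 0.3) {
  .with_seed(seed, {
    grid <- expand.grid(c = carbons, d = double_bonds)
    ids <- sprintf("PC(%d:%d)", grid$c, grid$d)
    base <- function(mu) stats::dnorm(grid$c, mean = mu, sd = width) *
      stats::dnorm(grid$d, mean = 2, sd = 1.5)
    noisy <- function(w) 1e6 * w * exp(stats::rnorm(length(w), 0, noise_sd))
    list(reference = data.frame(lipid_id = ids,
                                intensity = noisy(base(center)),
                                stringsAsFactors = FALSE),
         mobilized = data.frame(lipid_id = ids,
                                intensity = noisy(base(center + carbon_shift)),
                                stringsAsFactors = FALSE),
         truth = list(carbon_shift = carbon_shift))
  })
}
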