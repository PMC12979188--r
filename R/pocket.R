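# Binding-pocket volumes by grid flood fill, volume-ratio benchmark.

#' Van der Waals radii by element
#'
#' Fixed element table (Angstrom) used to inflate atoms when rasterizing a
#' structure onto the cavity grid. Unknown elements fall back to carbon.
#'
#' @return Named numeric vector.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, FE = 1.80,
    ZN = 1.39, MG = 1.73, CA = 1.74, `NA` = 2.27, K = 2.75)
}

#' Read atoms from a PDB structure
#'
#' Reads the first model of a PDB file via \pkg{bio3d} and returns the atom
#' list used by \code{\link{pocket_volume}}. Waters and HETATM ligands are
#' excluded by default.
#'
#' @param path PDB file path.
#' @param include_het Keep non-water HETATM records (default FALSE; the
#'   synthetic cavity fixtures use ATOM records and are unaffected).
#' @param include_waters Keep waters (default FALSE).
#' @param include_hydrogens Keep hydrogens (default TRUE).
#' @return data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (Angstrom).
#' @export
read_structure_atoms <- function(path, include_het = FALSE,
                                 include_waters = FALSE,
                                 include_hydrogens = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop(sprintf("cannot read structure '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop(sprintf("empty structure: no atoms in '%s'", path), call. = FALSE)
  keep <- rep(TRUE, nrow(at))
  if (!include_waters) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!include_het) keep <- keep & (at$type == "ATOM" |
                                      at$resid %in% c("HOH", "WAT", "DOD"))
  el <- toupper(trimws(at$elesy))
  miss <- is.na(el) | !nzchar(el)
  el[miss] <- toupper(substr(trimws(at$elety[miss]), 1, 1))
  if (!include_hydrogens) keep <- keep & el != "H"
  at <- at[keep, , drop = FALSE]
  el <- el[keep]
  if (nrow(at) == 0)
    stop(sprintf("empty structure after filtering: '%s'", path), call. = FALSE)
  data.frame(element = el, x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

#' Interior cavity (pocket) volume of a structure
#'
#' Estimates the total volume of interior cavities by voxelizing space at
#' \code{grid_spacing}: a voxel counts toward the cavity volume when its
#' centre is outside every probe-inflated atom sphere AND cannot be reached
#' by a 6-connected flood fill from outside the structure's bounding box.
#' Open grooves reachable from the exterior are not counted. Deterministic
#' for fixed inputs, and exactly invariant to rigid translation and axis
#' permutation of the structure (the grid is anchored to the structure's
#' own bounding box).
#'
#' @param structure A PDB path or a data.frame as returned by
#'   \code{\link{read_structure_atoms}}.
#' @param probe_radius Probe radius in Angstrom added to every atom radius
#'   (default 1.4, a water-sized probe; 0 gives the van-der-Waals cavity).
#' @param grid_spacing Voxel edge in Angstrom (default 0.5).
#' @param radii Named van der Waals radius table (default
#'   \code{\link{vdw_radii}}).
#' @param ltp_id Optional identifier stored on the result.
#' @param ... Passed to \code{\link{read_structure_atoms}} when
#'   \code{structure} is a path.
#' @return Object of class \code{"pocket_model"}: list with
#'   \code{ltp_id}, \code{pocket_volume} (cubic Angstrom), \code{source =
#'   "computed_grid"}, \code{grid_spacing}, \code{probe_radius},
#'   \code{n_cavity_voxels}.
#' @export
pocket_volume <- function(structure, probe_radius = 1.4, grid_spacing = 0.5,
                          radii = vdw_radii(), ltp_id = NA_character_, ...) {
  if (is.character(structure) && length(structure) == 1)
    structure <- read_structure_atoms(structure, ...)
  stopifnot(is.data.frame(structure),
            all(c("element", "x", "y", "z") %in% names(structure)))
  if (nrow(structure) < 1) stop("empty structure: no atoms", call. = FALSE)
  if (grid_spacing <= 0) stop("grid_spacing must be > 0", call. = FALSE)
  if (probe_radius < 0) stop("probe_radius must be >= 0", call. = FALSE)
  el <- toupper(structure$element)
  r <- unname(radii[el])
  r[is.na(r)] <- radii[["C"]]
  res <- cpp_cavity_volume(as.matrix(structure[, c("x", "y", "z")]),
                           r, probe_radius, grid_spacing)
  out <- list(ltp_id = ltp_id, pocket_volume = res$volume,
              source = "computed_grid", grid_spacing = grid_spacing,
              probe_radius = probe_radius,
              n_cavity_voxels = res$n_cavity_voxels)
  class(out) <- "pocket_model"
  out
}

#' Pocket model from a published volume table
#'
#' Wraps an externally provided pocket volume (e.g. from a deposited
#' supplementary table) in the same container as \code{\link{pocket_volume}}
#' so downstream benchmarking is agnostic to the volume's origin.
#'
#' @param ltp_id Protein identifier.
#' @param volume Pocket volume in cubic Angstrom (> 0).
#' @return Object of class \code{"pocket_model"} with
#'   \code{source = "provided_table"}.
#' @export
pocket_model_from_table <- function(ltp_id, volume) {
  stopifnot(is.numeric(volume), length(volume) == 1, volume > 0)
  structure(list(ltp_id = ltp_id, pocket_volume = as.numeric(volume),
                 source = "provided_table", grid_spacing = NA_real_,
                 probe_radius = NA_real_, n_cavity_voxels = NA_real_),
            class = "pocket_model")
}

#' @export
print.pocket_model <- function(x, ...) {
  cat(sprintf("<pocket_model> %s: %.1f A^3 (%s%s)\n",
              if (is.na(x$ltp_id)) "?" else x$ltp_id, x$pocket_volume,
              x$source,
              if (x$source == "computed_grid")
                sprintf(", grid %.2g A, probe %.2g A",
                        x$grid_spacing, x$probe_radius) else ""))
  invisible(x)
}

#' Lipid/pocket volume-ratio record
#'
#' @param lipid_volume Lipid molecular volume in cubic Angstrom (> 0), or a
#'   \code{lipid_volume} object.
#' @param pocket A \code{pocket_model}.
#' @param lipid_id Lipid name (taken from the \code{lipid_volume} object if
#'   given).
#' @param known_pair Is this a previously known LTP-ligand pair?
#' @param assay Assay label.
#' @return One-row data.frame of class \code{"fit_record"}: \code{ltp_id},
#'   \code{lipid_id}, \code{lipid_volume}, \code{pocket_volume},
#'   \code{ratio}, \code{known_pair}, \code{assay}, \code{in_buffer_zone}
#'   (NA until a threshold is applied by \code{\link{fit_benchmark}}).
#' @export
fit_ratio <- function(lipid_volume, pocket, lipid_id = NA_character_,
                      known_pair = FALSE, assay = NA_character_) {
  if (inherits(lipid_volume, "lipid_volume")) {
    if (is.na(lipid_id)) lipid_id <- canonical_lipid_name(lipid_volume$species)
    lipid_volume <- lipid_volume$volume
  }
  stopifnot(inherits(pocket, "pocket_model"),
            is.numeric(lipid_volume), lipid_volume > 0,
            pocket$pocket_volume > 0)
  out <- data.frame(ltp_id = pocket$ltp_id, lipid_id = lipid_id,
                    lipid_volume = lipid_volume,
                    pocket_volume = pocket$pocket_volume,
                    ratio = lipid_volume / pocket$pocket_volume,
                    known_pair = known_pair, assay = assay,
                    pocket_source = pocket$source,
                    in_buffer_zone = NA,
                    stringsAsFactors = FALSE)
  class(out) <- c("fit_record", "data.frame")
  out
}

#' Buffer-zone threshold from known pairs
#'
#' The maximal lipid/pocket volume ratio observed among known LTP-ligand
#' pairs. Ratios above it lie in the pocket's "buffer zone" (region of
#' unfilled space never used by a known ligand). Being a maximum, adding a
#' known record can only raise it.
#'
#' @param records data.frame of fit records (rows with
#'   \code{known_pair == TRUE} are used).
#' @param exclude_ltps Optional LTP ids excluded before taking the maximum
#'   (config-listed outliers, e.g. unusually small pockets).
#' @return The threshold ratio (numeric scalar).
#' @export
buffer_zone_threshold <- function(records, exclude_ltps = character(0)) {
  stopifnot(is.data.frame(records), "ratio" %in% names(records))
  known <- records[records$known_pair & !(records$ltp_id %in% exclude_ltps), ]
  if (nrow(known) == 0)
    stop("no known pairs: buffer-zone threshold undefined", call. = FALSE)
  max(known$ratio)
}

#' Structural benchmark: flag pairs in the buffer zone
#'
#' Derives the buffer-zone threshold from the known pairs and flags every
#' record whose ratio exceeds it.
#'
#' @inheritParams buffer_zone_threshold
#' @return list with \code{threshold} and \code{records} (the input with
#'   \code{in_buffer_zone} filled in), plus counts \code{n_known},
#'   \code{n_novel}, \code{n_in_buffer_zone}.
#' @export
fit_benchmark <- function(records, exclude_ltps = character(0)) {
  thr <- buffer_zone_threshold(records, exclude_ltps)
  records$in_buffer_zone <- records$ratio > thr
  list(threshold = thr, records = records,
       n_known = sum(records$known_pair),
       n_novel = sum(!records$known_pair),
       n_in_buffer_zone = sum(records$in_buffer_zone))
}

#' Welch comparison of two groups of volume ratios
#'
#' Welch's two-sided t-test (Satterthwaite degrees of freedom), e.g. known
#' vs novel ligand ratios or in cellulo vs in vitro.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2 and nonzero
#'   variance.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
compare_ratio_groups <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b))))
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    stop("degenerate: both groups have zero variance with unequal means",
         call. = FALSE)
  }
  if (stats::var(group_a) == 0 || stats::var(group_b) == 0)
    stop("degenerate: a group has zero variance", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
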