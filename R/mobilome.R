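# Chain-length / unsaturation profiling of the mobilized lipidome.

.profile_obj <- function(bins, values, axis, source = NA_character_) {
  out <- data.frame(bin = as.integer(bins), value = as.numeric(values))
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "axis") <- axis
  attr(out, "source") <- source
  class(out) <- c("lipidome_profile", "data.frame")
  out
}

#' Chain-length or unsaturation profile of a lipidome
#'
#' Sums intensities per bin of total chain length (carbons) or total double
#' bonds, then min-max scales the bin values. Glycerophospholipids and
#' sphingolipids are profiled separately by default (for sphingolipids the
#' total chain length is sphingoid base plus fatty-acid carbons, which is
#' what the parser's \code{total_carbons} already sums).
#'
#' @param lipidome data.frame with \code{lipid_id} (parseable names) and
#'   \code{intensity} (non-negative).
#' @param axis \code{"total_carbons"} (default) or \code{"double_bonds"}.
#' @param split_by_class Profile each lipid class separately (default TRUE).
#' @param source Optional label stored on the profiles.
#' @return If \code{split_by_class}, a named list of
#'   \code{"lipidome_profile"} data.frames (one per class present);
#'   otherwise a single profile.
#' @export
chain_profile <- function(lipidome, axis = c("total_carbons", "double_bonds"),
                          split_by_class = TRUE, source = NA_character_) {
  axis <- match.arg(axis)
  stopifnot(all(c("lipid_id", "intensity") %in% names(lipidome)))
  if (any(lipidome$intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  parsed <- parse_lipid_names(lipidome$lipid_id)
  if (nrow(attr(parsed, "warnings")) > 0)
    stop(sprintf("unparseable lipid names: %s",
                 paste(attr(parsed, "warnings")$name, collapse = ", ")),
         call. = FALSE)
  val <- if (axis == "total_carbons") parsed$total_carbons else
    parsed$total_double_bonds
  one <- function(idx) {
    s <- tapply(lipidome$intensity[idx], val[idx], sum)
    .profile_obj(as.integer(names(s)), normalize_minmax(as.numeric(s)),
                 axis, source)
  }
  if (!split_by_class) return(one(seq_len(nrow(lipidome))))
  idx_by <- split(seq_len(nrow(lipidome)), parsed$lipid_class)
  lapply(idx_by, one)
}

#' @export
print.lipidome_profile <- function(x, ...) {
  cat(sprintf("<lipidome_profile> axis=%s%s, %d bins\n", attr(x, "axis"),
              if (is.na(attr(x, "source"))) "" else
                paste0(", source=", attr(x, "source")), nrow(x)))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Compare a mobilized profile against a reference profile
#'
#' Outer-joins the two profiles on their bins (absent bins count 0), takes
#' the signed per-bin difference (mobilized - reference) and summarizes it
#' as the difference of intensity-weighted mean bin positions. A negative
#' chain-length shift means the mobilized lipidome prefers shorter chains.
#'
#' @param mobilized,reference \code{"lipidome_profile"} data.frames on the
#'   same axis.
#' @return list with \code{diff} (data.frame \code{bin}, \code{mobilized},
#'   \code{reference}, \code{difference}) and \code{shift}.
#' @export
compare_profiles <- function(mobilized, reference) {
  if (!identical(attr(mobilized, "axis"), attr(reference, "axis")))
    stop("profiles are on different axes", call. = FALSE)
  bins <- sort(union(mobilized$bin, reference$bin))
  get <- function(p) {
    v <- stats::setNames(rep(0, length(bins)), bins)
    v[as.character(p$bin)] <- p$value
    v
  }
  vm <- get(mobilized); vr <- get(reference)
  shift <- stats::weighted.mean(bins, vm) - stats::weighted.mean(bins, vr)
  list(diff = data.frame(bin = bins, mobilized = unname(vm),
                         reference = unname(vr),
                         difference = unname(vm - vr)),
       shift = shift)
}

#' Profile of the affected-species fraction by chain property
#'
#' For gain-of-function results, computes per bin (total chain length or
#' unsaturation) the fraction of measured species that were significantly
#' affected, min-max scaled.
#'
#' @param results A \code{"perturbation_results"} data.frame (species
#'   parseable).
#' @param axis \code{"total_carbons"} or \code{"double_bonds"}.
#' @return A \code{"lipidome_profile"} data.frame (source
#'   \code{"oe_affected_fraction"}).
#' @export
affected_fraction_profile <- function(results,
                                      axis = c("total_carbons", "double_bonds")) {
  axis <- match.arg(axis)
  stopifnot(all(c("species", "affected") %in% names(results)))
  parsed <- parse_lipid_names(results$species)
  val <- if (axis == "total_carbons") parsed$total_carbons else
    parsed$total_double_bonds
  frac <- tapply(results$affected, val, mean)
  .profile_obj(as.integer(names(frac)), normalize_minmax(as.numeric(frac)),
               axis, "oe_affected_fraction")
}

#' Normalize ligand intensities to the subclass maximum
#'
#' Within each (LTP, subclass) group, divides intensities by the group's
#' maximum, so the most abundant species of each subclass maps to 1.0.
#' Idempotent. An optional merge map pools subclasses before grouping
#' (e.g. all hexosyl-containing sphingolipids as \code{"xHexCer"}).
#'
#' @param ligand_table data.frame with \code{ltp_id}, \code{lipid_id}
#'   (parseable) and \code{intensity}.
#' @param merge_map Optional named character vector mapping subclass ->
#'   merged label, e.g. \code{c(HexCer = "xHexCer", Hex2Cer = "xHexCer",
#'   SHexCer = "xHexCer")}.
#' @return The table with columns \code{subclass} (post-merge) and
#'   \code{normalized_intensity} appended.
#' @export
subclass_max_normalize <- function(ligand_table, merge_map = NULL) {
  stopifnot(all(c("ltp_id", "lipid_id", "intensity") %in% names(ligand_table)))
  sub <- subclass_of(ligand_table$lipid_id)
  if (!is.null(merge_map)) {
    hit <- sub %in% names(merge_map)
    sub[hit] <- merge_map[sub[hit]]
  }
  grp <- paste(ligand_table$ltp_id, sub, sep = "\r")
  mx <- tapply(ligand_table$intensity, grp, max)
  ligand_table$subclass <- sub
  ligand_table$normalized_intensity <-
    ligand_table$intensity / as.numeric(mx[grp])
  rownames(ligand_table) <- NULL
  ligand_table
}
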