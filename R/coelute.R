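# Co-elution ligand calling from SEC fraction profiles.

#' Min-max scaling
#'
#' \code{(x - min) / (max - min)}. Constant vectors map to all zeros, the
#' convention used for intensities not observed above floor.
#'
#' @param values Non-empty numeric vector (NA not allowed).
#' @return Vector rescaled into [0, 1].
#' @examples
#' normalize_minmax(c(2, 4, 6))  # 0.0 0.5 1.0
#' @export
normalize_minmax <- function(values) {
  if (length(values) == 0) stop("'values' must be non-empty", call. = FALSE)
  if (anyNA(values)) stop("'values' contains NA", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Elution profile over SEC fractions
#'
#' @param entity_id Identifier of the protein or lipid.
#' @param intensities Non-negative intensity vector, one per fraction, with
#'   at least one positive value.
#' @param fraction_ids Fraction labels (1-based by convention).
#' @return Object of class \code{"elution_profile"}.
#' @export
elution_profile <- function(entity_id, intensities,
                            fraction_ids = seq_along(intensities)) {
  stopifnot(is.character(entity_id), length(entity_id) == 1)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(fraction_ids))
    stop("'intensities' and 'fraction_ids' lengths differ", call. = FALSE)
  if (anyNA(intensities) || any(intensities < 0))
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  if (!any(intensities > 0))
    stop(sprintf("profile '%s' has no positive intensity", entity_id),
         call. = FALSE)
  structure(list(entity_id = entity_id, intensities = intensities,
                 fraction_ids = fraction_ids),
            class = "elution_profile")
}

#' @export
print.elution_profile <- function(x, ...) {
  cat(sprintf("<elution_profile> %s over %d fractions (peak at %s)\n",
              x$entity_id, length(x$intensities),
              x$fraction_ids[which.max(x$intensities)]))
  invisible(x)
}

# lipid table (data.frame: lipid_id + fraction columns) -> matrix
.lipid_matrix <- function(lipids) {
  if (is.matrix(lipids)) return(lipids)
  stopifnot(is.data.frame(lipids), "lipid_id" %in% names(lipids))
  m <- as.matrix(lipids[, setdiff(names(lipids), "lipid_id"), drop = FALSE])
  rownames(m) <- lipids$lipid_id
  storage.mode(m) <- "double"
  m
}

#' Call LTP-lipid ligand pairs from co-elution
#'
#' A lipid is accepted as a candidate ligand of the protein iff
#' \itemize{
#'   \item \emph{presence}: at least \code{min_presence} of its total SEC
#'     intensity lies in fractions where the protein is detected (protein
#'     intensity at least \code{detection_floor} of its own peak), and
#'   \item \emph{similarity}: its Pearson correlation with the protein
#'     elution profile is at least \code{min_similarity}.
#' }
#' Similarity is invariant to positive affine rescaling of either profile,
#' and acceptance is monotone in both thresholds.
#'
#' @param protein An \code{\link{elution_profile}} for the LTP.
#' @param lipids Lipid profile table: data.frame with a \code{lipid_id}
#'   column followed by one numeric column per fraction (same fraction axis
#'   as \code{protein}), or an equivalent matrix with lipid ids as rownames.
#' @param min_similarity Pearson correlation threshold (default 0.8).
#' @param min_presence Minimum fraction of lipid signal inside
#'   protein-containing fractions (default 0.5).
#' @param detection_floor Protein detection floor as a fraction of its peak
#'   intensity (default 0.05).
#' @param assay Assay label stored on the calls
#'   (\code{"in_cellulo"}, \code{"in_vitro"} or \code{"hptlc"}).
#' @return A data.frame of class \code{"ligand_calls"}, one row per lipid,
#'   sorted by decreasing similarity (ties broken by \code{lipid_id}):
#'   columns \code{ltp_id}, \code{lipid_id}, \code{assay}, \code{similarity},
#'   \code{presence}, \code{normalized_intensity} (min-max scaled total
#'   intensity across the run's lipids) and \code{accepted}.
#' @export
call_ligands <- function(protein, lipids, min_similarity = 0.8,
                         min_presence = 0.5, detection_floor = 0.05,
                         assay = c("in_cellulo", "in_vitro", "hptlc")) {
  assay <- match.arg(assay)
  stopifnot(inherits(protein, "elution_profile"))
  m <- .lipid_matrix(lipids)
  if (ncol(m) != length(protein$intensities))
    stop("lipid profiles and protein profile have mismatched fraction axes",
         call. = FALSE)
  if (is.data.frame(lipids) || !is.null(colnames(m))) {
    lab <- colnames(m)
    if (!is.null(lab) && !identical(sub("^[FfVv]", "", lab),
                                    as.character(protein$fraction_ids)) &&
        !identical(lab, as.character(protein$fraction_ids)) &&
        !identical(lab, paste0("F", protein$fraction_ids)))
      stop("lipid profiles and protein profile have mismatched fraction axes",
           call. = FALSE)
  }
  p <- protein$intensities
  if (!any(p > 0)) stop("LTP not detected: all-zero protein profile",
                        call. = FALSE)

  detected <- p >= detection_floor * max(p)
  total <- rowSums(m)
  presence <- ifelse(total > 0, rowSums(m[, detected, drop = FALSE]) / total, 0)
  similarity <- suppressWarnings(
    as.numeric(stats::cor(t(m), p, method = "pearson")))
  accepted <- !is.na(similarity) & similarity >= min_similarity &
    presence >= min_presence

  out <- data.frame(
    ltp_id = protein$entity_id,
    lipid_id = rownames(m),
    assay = assay,
    similarity = similarity,
    presence = presence,
    normalized_intensity = normalize_minmax(total),
    accepted = accepted,
    stringsAsFactors = FALSE)
  out <- out[order(-out$similarity, out$lipid_id, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("ligand_calls", "data.frame")
  out
}

#' @export
print.ligand_calls <- function(x, ...) {
  cat(sprintf("<ligand_calls> %s (%s): %d/%d lipids accepted\n",
              x$ltp_id[1], x$assay[1], sum(x$accepted), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x)[x$accepted, ], 10),
                   digits = 3)
  invisible(x)
}

#' Merge ligand calls across assays
#'
#' Combines accepted calls from the in cellulo, in vitro and HPTLC assays
#' into one row per (LTP, lipid) pair with per-assay evidence flags. HPTLC
#' evidence is retained only where no mass-spectrometry evidence exists for
#' that pair.
#'
#' @param calls_cellulo,calls_vitro,calls_hptlc \code{ligand_calls} tables
#'   (or NULL); only rows with \code{accepted == TRUE} contribute.
#' @return data.frame with columns \code{ltp_id}, \code{lipid_id},
#'   \code{in_cellulo}, \code{in_vitro}, \code{hptlc}, \code{assay} (the
#'   evidence summary label: \code{"ms"} or \code{"hptlc"}).
#' @export
merge_assays <- function(calls_cellulo = NULL, calls_vitro = NULL,
                         calls_hptlc = NULL) {
  acc <- function(x) if (is.null(x)) x[0] else {
    d <- as.data.frame(x)
    d[d$accepted, c("ltp_id", "lipid_id"), drop = FALSE]
  }
  cc <- acc(calls_cellulo); cv <- acc(calls_vitro); ch <- acc(calls_hptlc)
  key <- function(d) if (is.null(d) || nrow(d) == 0) character(0) else
    paste(d$ltp_id, d$lipid_id, sep = "\r")
  all_keys <- sort(unique(c(key(cc), key(cv), key(ch))))
  if (length(all_keys) == 0)
    return(data.frame(ltp_id = character(0), lipid_id = character(0),
                      in_cellulo = logical(0), in_vitro = logical(0),
                      hptlc = logical(0), assay = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  in_cellulo <- all_keys %in% key(cc)
  in_vitro <- all_keys %in% key(cv)
  ms <- in_cellulo | in_vitro
  hptlc <- (all_keys %in% key(ch)) & !ms   # HPTLC only without MS evidence
  out <- data.frame(
    ltp_id = vapply(parts, `[`, "", 1),
    lipid_id = vapply(parts, `[`, "", 2),
    in_cellulo = in_cellulo, in_vitro = in_vitro, hptlc = hptlc,
    assay = ifelse(ms, "ms", "hptlc"),
    stringsAsFactors = FALSE)
  out <- out[ms | hptlc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-LTP count of distinct bound lipid classes
#'
#' Counts, for each LTP in a merged ligand table, how many distinct lipid
#' classes its ligands span (ether subclasses merge with their ester class),
#' and tabulates the multi-class binding distribution.
#'
#' @param ligand_table data.frame with \code{ltp_id} and \code{lipid_id}
#'   (lipid names parseable by \code{\link{parse_lipid_name}}).
#' @return list with \code{per_ltp} (data.frame \code{ltp_id},
#'   \code{n_classes}), \code{histogram} (table of class counts), and
#'   \code{n_multiclass} (number of LTPs binding more than one class).
#' @export
multiclass_summary <- function(ligand_table) {
  stopifnot(all(c("ltp_id", "lipid_id") %in% names(ligand_table)))
  cls <- class_of(ligand_table$lipid_id)
  n_by <- tapply(cls, ligand_table$ltp_id, function(z) length(unique(z)))
  per <- data.frame(ltp_id = names(n_by), n_classes = as.integer(n_by),
                    stringsAsFactors = FALSE)
  per <- per[order(per$ltp_id), , drop = FALSE]
  rownames(per) <- NULL
  list(per_ltp = per, histogram = table(per$n_classes),
       n_multiclass = sum(per$n_classes > 1))
}
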