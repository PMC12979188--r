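# Gain-of-function lipidomics statistics: per-species Welch / paired tests,
# Bonferroni correction, multiplicity weights, subclass calls, Fisher
# enrichment.

#' Overexpression perturbation panel
#'
#' Induced and control replicate intensity matrices for one LTP
#' overexpression experiment, species in rows.
#'
#' @param ltp_id Panel identifier.
#' @param species_ids Species (row) identifiers.
#' @param induced,control Numeric matrices species x replicates (>= 2
#'   replicates per arm).
#' @param paired Are replicates matched column-for-column across arms?
#' @return Object of class \code{"perturbation_panel"}.
#' @export
perturbation_panel <- function(ltp_id, species_ids, induced, control,
                               paired = FALSE) {
  induced <- as.matrix(induced); control <- as.matrix(control)
  if (nrow(induced) != length(species_ids) ||
      nrow(control) != length(species_ids))
    stop("matrices must share the species axis", call. = FALSE)
  if (ncol(induced) < 2 || ncol(control) < 2)
    stop("need >= 2 replicates per arm", call. = FALSE)
  if (paired && ncol(induced) != ncol(control))
    stop("paired panels need equal replicate counts", call. = FALSE)
  rownames(induced) <- rownames(control) <- species_ids
  structure(list(ltp_id = ltp_id, species_ids = as.character(species_ids),
                 induced = induced, control = control, paired = paired),
            class = "perturbation_panel")
}

#' @export
print.perturbation_panel <- function(x, ...) {
  cat(sprintf("<perturbation_panel> %s: %d species, %d induced / %d control replicates%s\n",
              x$ltp_id, length(x$species_ids), ncol(x$induced),
              ncol(x$control), if (x$paired) " (paired)" else ""))
  invisible(x)
}

# row-wise means and variances of a matrix
.row_mv <- function(m) {
  mu <- rowMeans(m)
  v <- rowSums((m - mu) ^ 2) / (ncol(m) - 1)
  list(mean = mu, var = v)
}

.log2_matrix <- function(m, arm) {
  if (any(m <= 0))
    stop(sprintf("non-positive intensities in %s arm; log transform undefined",
                 arm), call. = FALSE)
  log2(m)
}

.finish_results <- function(ltp_id, species, log2_fc, p_raw, degenerate,
                            alpha, family_size) {
  m <- if (is.null(family_size)) sum(!degenerate) else family_size
  p_adj <- pmin(1, m * p_raw)
  p_adj[degenerate] <- NA_real_
  out <- data.frame(
    ltp_id = ltp_id, species = species,
    log2_fc = log2_fc, weight = 1, weighted_fc = log2_fc,
    p_raw = p_raw, p_adj = p_adj,
    affected = !degenerate & !is.na(p_adj) & p_adj <= alpha,
    direction = sign(log2_fc),
    degenerate = degenerate,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "family_size") <- m
  class(out) <- c("perturbation_results", "data.frame")
  out
}

#' Per-species Welch tests for one overexpression panel
#'
#' Welch's two-sided t-test per lipid species on log2-transformed
#' intensities, Bonferroni-adjusted. The Bonferroni family defaults to the
#' panel's own non-degenerate tests; pass \code{family_size} to adjust
#' within a larger family (all species x all panels analysed together, as
#' \code{\link{perturb_screen}} does).
#'
#' Degenerate species (zero variance in both arms): equal means give
#' p = 1 by convention; unequal means are flagged \code{degenerate} and
#' excluded from the family (p set to NA, never silently dropped).
#'
#' @param panel A \code{\link{perturbation_panel}}.
#' @param alpha Significance level on adjusted p (default 0.05).
#' @param log_transform Log2-transform intensities first (default TRUE;
#'   requires positive values).
#' @param family_size Bonferroni family size m; default = number of
#'   non-degenerate tests in this panel.
#' @return data.frame of class \code{"perturbation_results"}: one row per
#'   species with \code{log2_fc} (log2 ratio of arm means), \code{weight},
#'   \code{weighted_fc}, \code{p_raw}, \code{p_adj}, \code{affected},
#'   \code{direction}, \code{degenerate}.
#' @export
welch_species_tests <- function(panel, alpha = 0.05, log_transform = TRUE,
                                family_size = NULL) {
  stopifnot(inherits(panel, "perturbation_panel"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  xi <- if (log_transform) .log2_matrix(panel$induced, "induced") else panel$induced
  xc <- if (log_transform) .log2_matrix(panel$control, "control") else panel$control
  ni <- ncol(xi); nc <- ncol(xc)
  i <- .row_mv(xi); c_ <- .row_mv(xc)

  se2 <- i$var / ni + c_$var / nc
  tstat <- (i$mean - c_$mean) / sqrt(se2)
  df <- se2 ^ 2 / ((i$var / ni) ^ 2 / (ni - 1) + (c_$var / nc) ^ 2 / (nc - 1))
  p_raw <- 2 * stats::pt(-abs(tstat), df)

  both_zero <- i$var == 0 & c_$var == 0
  eq_mean <- abs(i$mean - c_$mean) < 1e-12
  p_raw[both_zero & eq_mean] <- 1
  degenerate <- both_zero & !eq_mean
  p_raw[degenerate] <- NA_real_

  log2_fc <- log2(rowMeans(panel$induced) / rowMeans(panel$control))
  .finish_results(panel$ltp_id, panel$species_ids, log2_fc, p_raw,
                  degenerate, alpha, family_size)
}

#' Per-species paired t-tests for a matched panel
#'
#' Paired two-sided t-test of induced versus non-induced replicates per
#' species on log2 differences; same adjustment and degeneracy contract as
#' \code{\link{welch_species_tests}}. All-zero differences give p = 1;
#' constant nonzero differences have zero variance and are flagged
#' degenerate.
#'
#' @inheritParams welch_species_tests
#' @return A \code{"perturbation_results"} data.frame.
#' @export
paired_species_tests <- function(panel, alpha = 0.05, log_transform = TRUE,
                                 family_size = NULL) {
  stopifnot(inherits(panel, "perturbation_panel"))
  if (!panel$paired) stop("panel is not paired", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  xi <- if (log_transform) .log2_matrix(panel$induced, "induced") else panel$induced
  xc <- if (log_transform) .log2_matrix(panel$control, "control") else panel$control
  d <- xi - xc
  n <- ncol(d)
  mv <- .row_mv(d)
  tstat <- mv$mean / sqrt(mv$var / n)
  p_raw <- 2 * stats::pt(-abs(tstat), n - 1)

  zero_var <- mv$var == 0
  all_zero <- zero_var & abs(mv$mean) < 1e-12
  p_raw[all_zero] <- 1
  degenerate <- zero_var & !all_zero
  p_raw[degenerate] <- NA_real_

  log2_fc <- log2(rowMeans(panel$induced) / rowMeans(panel$control))
  .finish_results(panel$ltp_id, panel$species_ids, log2_fc, p_raw,
                  degenerate, alpha, family_size)
}

#' Run the gain-of-function screen across panels
#'
#' Tests every panel and adjusts with a shared Bonferroni family (m = total
#' non-degenerate tests across all panels, the default) or per panel, then
#' applies the multiplicity weights of \code{\link{weight_multiplicity}}.
#'
#' @param panels list of \code{\link{perturbation_panel}}s.
#' @param alpha Significance level (default 0.05).
#' @param family \code{"global"} (default) or \code{"per_panel"}.
#' @param test \code{"welch"} (default) or \code{"paired"}.
#' @return Combined \code{"perturbation_results"} data.frame.
#' @export
perturb_screen <- function(panels, alpha = 0.05,
                           family = c("global", "per_panel"),
                           test = c("welch", "paired")) {
  family <- match.arg(family); test <- match.arg(test)
  fun <- if (test == "welch") welch_species_tests else paired_species_tests
  raw <- lapply(panels, fun, alpha = alpha)   # per-panel families, pass 1
  if (family == "global") {
    m <- sum(vapply(raw, function(r) sum(!r$degenerate), 0L))
    raw <- lapply(panels, fun, alpha = alpha, family_size = m)
  } else {
    m <- NA_integer_
  }
  res <- do.call(rbind, lapply(raw, as.data.frame))
  class(res) <- c("perturbation_results", "data.frame")
  attr(res, "alpha") <- alpha
  attr(res, "family_size") <- m
  weight_multiplicity(res)
}

#' Multiplicity weights across panels
#'
#' A species affected in k LTP panels gets weight 1/k (weight 1 where
#' affected nowhere), downweighting species whose abundance responds to
#' many LTPs; \code{weighted_fc = weight * log2_fc}.
#'
#' @param results A \code{"perturbation_results"} data.frame covering one or
#'   more panels.
#' @return The results with \code{weight} and \code{weighted_fc} updated.
#' @export
weight_multiplicity <- function(results) {
  stopifnot(all(c("species", "ltp_id", "affected", "log2_fc") %in% names(results)))
  aff <- results[results$affected, c("species", "ltp_id")]
  k <- tapply(aff$ltp_id, aff$species, function(z) length(unique(z)))
  kk <- rep(1, nrow(results))
  hit <- results$species %in% names(k)
  kk[hit] <- k[results$species[hit]]
  results$weight <- 1 / pmax(kk, 1)
  results$weighted_fc <- results$weight * results$log2_fc
  results
}

#' Subclass-level "affected" calls
#'
#' A lipid subclass is affected under an LTP if at least one of its member
#' species is affected. Returns the full LTP x subclass flag matrix over
#' all subclasses seen in the results.
#'
#' @param results A \code{"perturbation_results"} data.frame (species names
#'   parseable by \code{\link{parse_lipid_name}}).
#' @return list with \code{matrix} (logical, LTPs x subclasses),
#'   \code{flags} (long data.frame \code{ltp_id}, \code{subclass},
#'   \code{affected}) and \code{n_pairs} (matrix size).
#' @export
subclass_affected <- function(results) {
  sub <- subclass_of(results$species)
  ltps <- sort(unique(results$ltp_id))
  subs <- sort(unique(sub))
  m <- matrix(FALSE, length(ltps), length(subs), dimnames = list(ltps, subs))
  aff <- results$affected
  for (i in which(aff)) m[results$ltp_id[i], sub[i]] <- TRUE
  flags <- data.frame(ltp_id = rep(ltps, times = length(subs)),
                      subclass = rep(subs, each = length(ltps)),
                      affected = as.vector(m), stringsAsFactors = FALSE)
  list(matrix = m, flags = flags, n_pairs = length(m))
}

#' Fisher exact enrichment of affected pairs in a subset
#'
#' Tests whether (LTP, lipid) pairs in a subset (e.g. ligand pairs found in
#' both screens) are affected by overexpression more often than the
#' remaining pairs, via the two-sided Fisher exact test on the 2x2 table
#' {subset, complement} x {affected, not}.
#'
#' @param subset_pairs Character ids of the subset (must be a non-empty
#'   proper subset of \code{all_pairs}).
#' @param all_pairs Character ids of all pairs.
#' @param affected Logical vector named by \code{all_pairs} (or in their
#'   order).
#' @return list with \code{table} (2x2), \code{odds_ratio} (conditional MLE
#'   from the exact test), \code{p_value}, and the subset/complement
#'   affected fractions.
#' @export
fisher_enrichment <- function(subset_pairs, all_pairs, affected) {
  subset_pairs <- unique(as.character(subset_pairs))
  all_pairs <- as.character(all_pairs)
  if (length(subset_pairs) == 0) stop("empty subset", call. = FALSE)
  if (!all(subset_pairs %in% all_pairs))
    stop("subset_pairs must be a subset of all_pairs", call. = FALSE)
  if (length(subset_pairs) == length(unique(all_pairs)))
    stop("subset equals all_pairs: degenerate 2x2 table", call. = FALSE)
  if (is.null(names(affected))) {
    stopifnot(length(affected) == length(all_pairs))
    names(affected) <- all_pairs
  }
  in_sub <- all_pairs %in% subset_pairs
  aff <- as.logical(affected[all_pairs])
  tab <- matrix(c(sum(in_sub & aff), sum(in_sub & !aff),
                  sum(!in_sub & aff), sum(!in_sub & !aff)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("subset", "complement"),
                                c("affected", "not_affected")))
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab,
       odds_ratio = unname(ht$estimate),
       p_value = ht$p.value,
       frac_subset = mean(aff[in_sub]),
       frac_complement = mean(aff[!in_sub]))
}
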