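# Lipid-pair co-regulation and co-localization scoring, with random-pair
# null enrichment tests.

# canonical unordered pair key
.pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

#' Co-regulation score of a lipid pair
#'
#' Over a matrix of perturbation response directions (entries +1 / -1 for a
#' significant increase / decrease, 0 for not significant), the score of a
#' pair is the mean over perturbations where BOTH lipids respond of +1 when
#' they move in the same direction and -1 when they move oppositely.
#' +1.0 therefore denotes perfect co-regulation (the lipids always change
#' abundance the same way) and -1.0 mutual exclusion.
#'
#' @param lipid_a,lipid_b Row names in \code{directions}.
#' @param directions Matrix lipids x perturbations with entries in
#'   \{-1, 0, +1\}.
#' @return Score in [-1, 1], or NA when the pair is never jointly
#'   significant (reported missing, never silently 0).
#' @export
coregulation_score <- function(lipid_a, lipid_b, directions) {
  stopifnot(is.matrix(directions),
            lipid_a %in% rownames(directions),
            lipid_b %in% rownames(directions))
  if (!all(directions %in% c(-1, 0, 1)))
    stop("directions entries must be -1, 0 or +1", call. = FALSE)
  a <- directions[lipid_a, ]
  b <- directions[lipid_b, ]
  both <- a != 0 & b != 0
  if (!any(both)) return(NA_real_)
  mean(ifelse(a[both] == b[both], 1, -1))
}

#' Co-regulation scores for a table of pairs
#'
#' @param pairs data.frame with columns \code{lipid_a}, \code{lipid_b}.
#' @param directions Direction matrix as in
#'   \code{\link{coregulation_score}}.
#' @return The pairs with a \code{coregulation} column appended.
#' @export
coregulation_scores <- function(pairs, directions) {
  stopifnot(all(c("lipid_a", "lipid_b") %in% names(pairs)))
  pairs$coregulation <- mapply(coregulation_score, pairs$lipid_a,
                               pairs$lipid_b,
                               MoreArgs = list(directions = directions))
  pairs
}

#' Manders overlap coefficient
#'
#' \eqn{\sum a_i b_i / \sqrt{\sum a_i^2 \sum b_i^2}} for two non-negative
#' intensity vectors (pixels or organelle fractions). 1.0 means the pair
#' always co-localizes, 0.0 never; Cauchy-Schwarz bounds it in [0, 1] for
#' non-negative inputs. Symmetric, and invariant to positive rescaling of
#' either vector.
#'
#' @param intensity_a,intensity_b Equal-length non-negative vectors.
#' @return The coefficient, or NA when either vector is all zero
#'   (undefined; reported missing).
#' @examples
#' manders_overlap(c(1, 1, 0), c(0, 1, 1))  # 0.5
#' @export
manders_overlap <- function(intensity_a, intensity_b) {
  if (length(intensity_a) != length(intensity_b) || length(intensity_a) == 0)
    stop("vectors must have equal positive length", call. = FALSE)
  if (anyNA(intensity_a) || anyNA(intensity_b) ||
      any(intensity_a < 0) || any(intensity_b < 0))
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  na2 <- sum(intensity_a ^ 2)
  nb2 <- sum(intensity_b ^ 2)
  if (na2 == 0 || nb2 == 0) return(NA_real_)
  sum(intensity_a * intensity_b) / sqrt(na2 * nb2)
}

#' Manders coefficients for a table of pairs
#'
#' @param pairs data.frame with \code{lipid_a}, \code{lipid_b}.
#' @param intensities Matrix lipids x pixels (non-negative).
#' @return The pairs with a \code{manders} column appended.
#' @export
manders_scores <- function(pairs, intensities) {
  stopifnot(is.matrix(intensities),
            all(c("lipid_a", "lipid_b") %in% names(pairs)))
  pairs$manders <- mapply(
    function(a, b) manders_overlap(intensities[a, ], intensities[b, ]),
    pairs$lipid_a, pairs$lipid_b)
  pairs
}

#' Enrichment of co-mobilized pairs in high pair scores
#'
#' Tests whether lipid pairs co-mobilized by the same LTP score higher
#' (co-regulation or Manders co-localization) than random lipid pairs:
#' \itemize{
#'   \item Fisher exact test on \{co-mobilized, random sample\} x
#'     \{high, low\} where "high" means at or above the
#'     \code{high_quantile} (default 75th percentile) of the pooled score
#'     distribution;
#'   \item permutation p = fraction of \code{n_random} random pair sets
#'     (same size, sampled without replacement from the non-co-mobilized
#'     pairs) whose mean score is at least the observed co-mobilized mean
#'     (computed with the add-one rule so p is in (0, 1]).
#' }
#'
#' @param comobilized_pairs Character keys of co-mobilized pairs (subset of
#'   \code{names(scores)}).
#' @param scores Named numeric vector of pair scores over all measurable
#'   pairs (NA scores are dropped).
#' @param n_random Number of random sets (>= 100).
#' @param seed Integer seed for the sampling.
#' @param high_quantile Quantile defining "high" scores (default 0.75).
#' @return list with \code{observed_mean}, \code{perm_p}, \code{fisher_p},
#'   \code{fisher_odds}, \code{high_cut}, \code{table}, \code{null_means}.
#' @export
pair_enrichment <- function(comobilized_pairs, scores, n_random = 1000,
                            seed = 1, high_quantile = 0.75) {
  if (n_random < 100)
    stop("n_random must be >= 100", call. = FALSE)
  scores <- scores[!is.na(scores)]
  comobilized_pairs <- unique(as.character(comobilized_pairs))
  comobilized_pairs <- comobilized_pairs[comobilized_pairs %in% names(scores)]
  if (length(comobilized_pairs) == 0)
    stop("no co-mobilized pair has a score", call. = FALSE)
  pool <- setdiff(names(scores), comobilized_pairs)
  k <- length(comobilized_pairs)
  if (length(pool) < k)
    stop("not enough non-co-mobilized pairs to sample from", call. = FALSE)

  obs <- mean(scores[comobilized_pairs])
  .with_seed(seed, {
    null_means <- vapply(seq_len(n_random), function(i)
      mean(scores[sample(pool, k)]), 0)
  })
  perm_p <- (1 + sum(null_means >= obs)) / (n_random + 1)

  high_cut <- stats::quantile(scores, high_quantile, names = FALSE)
  .with_seed(seed + 1L, rand_set <- sample(pool, k))
  tab <- matrix(c(sum(scores[comobilized_pairs] >= high_cut),
                  sum(scores[comobilized_pairs] < high_cut),
                  sum(scores[rand_set] >= high_cut),
                  sum(scores[rand_set] < high_cut)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("comobilized", "random"),
                                c("high", "low")))
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  list(observed_mean = obs, perm_p = perm_p,
       fisher_p = ht$p.value, fisher_odds = unname(ht$estimate),
       high_cut = high_cut, table = tab, null_means = null_means)
}

#' Pairs co-mobilized by the same LTP
#'
#' Builds the set of unordered lipid pairs sharing at least one LTP in a
#' merged ligand table.
#'
#' @param ligand_table data.frame with \code{ltp_id}, \code{lipid_id}.
#' @return data.frame \code{lipid_a}, \code{lipid_b} (canonically ordered,
#'   deduplicated).
#' @export
comobilized_pairs <- function(ligand_table) {
  stopifnot(all(c("ltp_id", "lipid_id") %in% names(ligand_table)))
  by_ltp <- split(unique(ligand_table[, c("ltp_id", "lipid_id")])$lipid_id,
                  unique(ligand_table[, c("ltp_id", "lipid_id")])$ltp_id)
  out <- do.call(rbind, lapply(by_ltp, function(ls) {
    ls <- sort(unique(ls))
    if (length(ls) < 2) return(NULL)
    cmb <- utils::combn(ls, 2)
    data.frame(lipid_a = cmb[1, ], lipid_b = cmb[2, ],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(lipid_a = character(0), lipid_b = character(0),
                      stringsAsFactors = FALSE))
  out <- out[!duplicated(.pair_key(out$lipid_a, out$lipid_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse a pair table to subclass or class level
#'
#' At \code{level = "class"}, pairs whose members share a lipid class are
#' excluded (likewise subclass at \code{level = "subclass"}), so that
#' enrichment re-run on the survivors cannot be driven by closely related
#' species. Species level returns the pairs unchanged. Collapsing is
#' idempotent.
#'
#' @param pairs data.frame with \code{lipid_a}, \code{lipid_b} (parseable
#'   lipid names).
#' @param level \code{"species"}, \code{"subclass"} or \code{"class"}.
#' @return The filtered pairs, with the grouping labels attached as
#'   columns \code{group_a}, \code{group_b} for the chosen level.
#' @export
collapse_level <- function(pairs, level = c("species", "subclass", "class")) {
  level <- match.arg(level)
  stopifnot(all(c("lipid_a", "lipid_b") %in% names(pairs)))
  if (level == "species") return(pairs)
  fun <- if (level == "subclass") subclass_of else class_of
  ga <- fun(pairs$lipid_a)
  gb <- fun(pairs$lipid_b)
  keep <- ga != gb
  out <- pairs[keep, , drop = FALSE]
  out$group_a <- ga[keep]
  out$group_b <- gb[keep]
  rownames(out) <- NULL
  out
}
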