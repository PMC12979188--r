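# Shared I/O, configuration and the end-to-end pipeline driver.
#
# All file writes are atomic (write to a temporary sibling, then rename);
# tables are TSV, UTF-8, '.' decimal separator, lipid names never quoted.

.write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  if (!file.rename(tmp, path))
    stop(sprintf("cannot write '%s'", path), call. = FALSE)
  invisible(path)
}

#' Write a table as TSV (atomically)
#'
#' @param x data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!file.rename(tmp, path))
    stop(sprintf("cannot write '%s'", path), call. = FALSE)
  invisible(path)
}

#' Write an object as JSON (atomically)
#'
#' @param x Object serializable by \pkg{jsonlite}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_json <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!file.rename(tmp, path))
    stop(sprintf("cannot write '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read a lipidomics intensity table
#'
#' Reads a TSV whose first column holds lipid names and the remaining
#' columns sample (or SEC fraction) intensities. Names are validated with
#' the shorthand parser; rows with unparseable names are removed from the
#' table and collected into a warnings report attached as attribute
#' \code{"warnings"} (a data.frame of \code{name}, \code{message}), never
#' silently dropped.
#'
#' @param path TSV path with a header row.
#' @return data.frame with \code{lipid_id} plus numeric sample columns.
#' @export
read_lipidome_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("lipidome table needs a name column plus samples",
                        call. = FALSE)
  names(d)[1] <- "lipid_id"
  parsed <- parse_lipid_names(d$lipid_id)
  warn <- attr(parsed, "warnings")
  if (nrow(warn) > 0) {
    warning(sprintf("%d unparseable lipid name(s): %s", nrow(warn),
                    paste(warn$name, collapse = ", ")), call. = FALSE)
    d <- d[!(d$lipid_id %in% warn$name), , drop = FALSE]
  }
  for (j in seq(2, ncol(d))) d[[j]] <- as.numeric(d[[j]])
  rownames(d) <- NULL
  attr(d, "warnings") <- warn
  d
}

#' Default pipeline configuration
#'
#' Thresholds and settings used by \code{\link{run_pipeline}}; every
#' analysis records the configuration (and its hash) it ran with.
#'
#' @param seed Master seed for all synthetic stages.
#' @return Named list of settings.
#' @export
default_config <- function(seed = 42) {
  list(
    seed = as.integer(seed),
    sec = list(n_planted = 5, n_background = 100, noise_sd = 0.05,
               n_fractions = 40),
    coelute = list(min_similarity = 0.8, min_presence = 0.5,
                   detection_floor = 0.05),
    pocket = list(probe_radius = 0, grid_spacing = 0.5,
                  shell_radius = 10, atom_radius = 1.5,
                  exclude_ltps = character(0)),
    perturb = list(alpha = 0.05, n_replicates = 3, effect_log2 = 2,
                   baseline_log_sd = 0.25, family = "global"),
    copairs = list(n_random = 1000, high_quantile = 0.75,
                   coloc_pixels = 400, coloc_noise_sd = 0.2),
    mobilome = list(carbon_shift = -2)
  )
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Demo species pool over the consistently measured subclasses
#'
#' Deterministic pool of parseable lipid species spanning the first
#' \code{n_subclasses} chain-bearing subclasses of the vocabulary, used by
#' the synthetic pipeline and the acceptance checks (24 subclasses mirrors
#' the set of subclasses a lipidomics screen measures consistently).
#'
#' @param n_subclasses Number of subclasses to span (default 24).
#' @param per_subclass Species per subclass (default 2).
#' @return Character vector of species names.
#' @export
demo_species_pool <- function(n_subclasses = 24, per_subclass = 2) {
  vocab <- lipid_vocabulary()
  subs <- vocab$subclass[is.na(vocab$fixed_volume)]
  if (n_subclasses > length(subs))
    stop("not enough chain-bearing subclasses in the vocabulary", call. = FALSE)
  subs <- utils::head(subs, n_subclasses)
  unlist(lapply(subs, function(s) {
    row <- vocab[vocab$subclass == s, ]
    carb <- seq(32, by = 2, length.out = per_subclass)
    if (row$expected_chains == 1) carb <- carb - 16
    if (row$sphingo == 1)
      sprintf("%s(d%d:1)", s, carb)
    else
      sprintf("%s(%d:%d)", s, carb, seq(0, per_subclass - 1))
  }))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the whole chain on synthetic data with planted truth:
#' simulate -> call-ligands -> pocket/fit benchmark -> perturbation tests ->
#' co-pair enrichment -> mobilome profiling, writing one results directory
#' with TSV/JSON outputs, a log and a configuration snapshot (with hash).
#' Rerunning with the same configuration reproduces identical result files.
#'
#' @param config Configuration list from \code{\link{default_config}}.
#' @param out_dir Output directory (created if missing).
#' @return (invisibly) list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[ltpmob] ", msg)
  }
  seed <- config$seed
  say("config hash %s, seed %d", hash, seed)

  # --- stage: SEC simulation + ligand calling -------------------------------
  pool <- demo_species_pool(24, 6)
  planted <- pool[seq_len(config$sec$n_planted)]
  background <- setdiff(pool, planted)[seq_len(config$sec$n_background)]
  truth <- sec_sim_truth("LTP1", planted, background,
                         noise_sd = config$sec$noise_sd,
                         n_fractions = config$sec$n_fractions)
  run <- gen_sec_run(truth, seed = seed)
  calls <- call_ligands(run$protein, run$lipids,
                        min_similarity = config$coelute$min_similarity,
                        min_presence = config$coelute$min_presence,
                        detection_floor = config$coelute$detection_floor)
  hits <- calls$lipid_id[calls$accepted]
  recall <- mean(planted %in% hits)
  fdp <- if (length(hits)) mean(!(hits %in% planted)) else 0
  say("call-ligands: %d accepted of %d lipids (recall %.3f, FDP %.3f)",
      length(hits), nrow(calls), recall, fdp)
  write_tsv(as.data.frame(calls), file.path(out_dir, "ligand_calls.tsv"))

  # --- stage: structural benchmark ------------------------------------------
  pdb_path <- file.path(out_dir, "cavity_fixture.pdb")
  fx <- gen_cavity_fixture(pdb_path, shell_radius = config$pocket$shell_radius,
                           atom_radius = config$pocket$atom_radius,
                           seed = seed)
  # fixture pseudo-atoms carry the configured radius, not carbon's vdW value
  pm <- pocket_volume(pdb_path, probe_radius = config$pocket$probe_radius,
                      grid_spacing = config$pocket$grid_spacing,
                      radii = c(C = config$pocket$atom_radius),
                      ltp_id = "LTP1")
  vol_err <- abs(pm$pocket_volume - fx$expected_cavity_volume) /
    fx$expected_cavity_volume
  say("pocket-volume: %.0f A^3 vs analytic %.0f A^3 (rel err %.3f)",
      pm$pocket_volume, fx$expected_cavity_volume, vol_err)
  fits <- do.call(rbind, lapply(seq_along(hits), function(i) {
    as.data.frame(fit_ratio(lipid_volume(hits[i]), pm, lipid_id = hits[i],
                            known_pair = i <= ceiling(length(hits) / 2),
                            assay = "in_cellulo"))
  }))
  bench <- fit_benchmark(fits, exclude_ltps = config$pocket$exclude_ltps)
  say("fit-benchmark: threshold %.3f, %d of %d pairs in buffer zone",
      bench$threshold, bench$n_in_buffer_zone, nrow(bench$records))
  write_tsv(bench$records, file.path(out_dir, "fit_records.tsv"))

  # --- stage: gain-of-function panels ---------------------------------------
  species <- pool
  panels <- lapply(1:4, function(i) {
    eff <- stats::setNames(
      rep(config$perturb$effect_log2, 3),
      species[seq(3 * (i - 1) + 1, 3 * i)])
    gen_oe_panel(oe_panel_truth(paste0("LTP", i), species, eff,
                                n_replicates = config$perturb$n_replicates,
                                baseline_log_sd = config$perturb$baseline_log_sd),
                 seed = seed + i)
  })
  res <- perturb_screen(panels, alpha = config$perturb$alpha,
                        family = config$perturb$family)
  sub_aff <- subclass_affected(res)
  say("perturb-test: %d/%d species tests affected; %d LTP x subclass pairs",
      sum(res$affected), nrow(res), sub_aff$n_pairs)
  write_tsv(as.data.frame(res), file.path(out_dir, "perturbation_results.tsv"))

  # --- stage: co-pair enrichment --------------------------------------------
  ligands <- data.frame(
    ltp_id = rep(paste0("LTP", 1:4), each = 3),
    lipid_id = species[1:12], stringsAsFactors = FALSE)
  cpairs <- comobilized_pairs(ligands)
  n_coloc <- nrow(cpairs)
  others <- setdiff(species, unique(c(cpairs$lipid_a, cpairs$lipid_b)))
  ct <- coloc_truth(config$copairs$coloc_pixels,
                    as.matrix(cpairs[, c("lipid_a", "lipid_b")]),
                    independent_lipids = others)
  maps <- gen_coloc_maps(ct, seed = seed + 10,
                         noise_sd = config$copairs$coloc_noise_sd)
  all_pairs <- t(utils::combn(rownames(maps), 2))
  pair_tab <- data.frame(lipid_a = all_pairs[, 1], lipid_b = all_pairs[, 2],
                         stringsAsFactors = FALSE)
  pair_tab <- manders_scores(pair_tab, maps)
  scores <- stats::setNames(pair_tab$manders,
                            .pair_key(pair_tab$lipid_a, pair_tab$lipid_b))
  enr <- pair_enrichment(.pair_key(cpairs$lipid_a, cpairs$lipid_b), scores,
                         n_random = config$copairs$n_random,
                         seed = seed + 11,
                         high_quantile = config$copairs$high_quantile)
  say("copairs: %d co-mobilized pairs, permutation p %.4g, Fisher p %.4g",
      n_coloc, enr$perm_p, enr$fisher_p)
  write_json(enr[c("observed_mean", "perm_p", "fisher_p", "fisher_odds",
                   "high_cut")],
             file.path(out_dir, "copair_enrichment.json"))

  # --- stage: mobilome profile ----------------------------------------------
  lp <- gen_lipidome_pair(seed = seed + 20,
                          carbon_shift = config$mobilome$carbon_shift)
  prof_m <- chain_profile(lp$mobilized, "total_carbons",
                          split_by_class = FALSE, source = "mobilized_cellulo")
  prof_r <- chain_profile(lp$reference, "total_carbons",
                          split_by_class = FALSE, source = "reference_hek293")
  cmp <- compare_profiles(prof_m, prof_r)
  say("profile: chain-length shift %.2f (planted %.2f)", cmp$shift,
      config$mobilome$carbon_shift)
  write_tsv(cmp$diff, file.path(out_dir, "chain_profile_diff.tsv"))

  snapshot <- c(config, list(config_hash = hash))
  write_json(snapshot, file.path(out_dir, "config.json"))
  .write_lines_atomic(log_lines, file.path(out_dir, "pipeline.log"))

  invisible(list(config = snapshot, calls = calls, recall = recall, fdp = fdp,
                 pocket = pm, cavity_rel_err = vol_err, benchmark = bench,
                 perturbation = res, subclass = sub_aff, enrichment = enr,
                 chain_shift = cmp$shift))
}
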