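test_that("panel constructor enforces its invariants", {
  m <- matrix(1, 3, 3)
  expect_error(perturbation_panel("L", c("a", "b"), m, m), "species axis")
  expect_error(perturbation_panel("L", c("a", "b", "c"), m[, 1, drop = FALSE], m),
               ">= 2 replicates")
  expect_error(perturbation_panel("L", c("a", "b", "c"), m, m[, 1:2],
                                  paired = TRUE), "equal replicate")
})

test_that("vectorized Welch tests equal the reference implementation", {
  set.seed(42)
  sp <- sprintf("s%02d", 1:40)
  pan <- perturbation_panel("L", sp,
                            matrix(rlnorm(120, 10), 40),
                            matrix(rlnorm(160, 10), 40, 4))
  res <- welch_species_tests(pan)
  oracle <- sapply(1:40, function(i)
    stats::t.test(log2(pan$induced[i, ]), log2(pan$control[i, ]),
                  var.equal = FALSE)$p.value)
  expect_equal(res$p_raw, oracle, tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$p_adj <= 1 & res$p_raw > 0))
})

test_that("identical arms yield no affected species", {
  m <- matrix(rlnorm(60, 8), 20)
  pan <- perturbation_panel("L", sprintf("s%d", 1:20), m, m)
  res <- welch_species_tests(pan)
  expect_false(any(res$affected))
  expect_true(all(res$p_raw == 1))
})

test_that("planted effects are recovered with the simulated power", {
  # With n = 3 the Welch degrees of freedom can collapse toward 2, so even a
  # |log2 effect| of 2 at sd 0.1 is not flagged in every run; an independent
  # simulation puts the per-species recovery rate near 0.7 under a
  # 200-test Bonferroni family. Assert that rate (with Monte-Carlo slack)
  # plus perfect specificity and correct signs.
  sp <- sprintf("s%03d", 1:200)
  tr <- oe_panel_truth("L1", sp, c(s001 = 2, s002 = -2),
                       baseline_log_sd = 0.1)
  hit <- matrix(NA, 50, 2)
  false_calls <- 0
  for (s in 1:50) {
    res <- welch_species_tests(gen_oe_panel(tr, seed = s))
    hit[s, ] <- res$affected[match(c("s001", "s002"), res$species)]
    false_calls <- false_calls +
      sum(res$affected[!res$species %in% c("s001", "s002")])
    expect_equal(res$direction[res$species == "s001"], 1)
    expect_equal(res$direction[res$species == "s002"], -1)
  }
  expect_gte(mean(hit), 0.6)
  expect_lte(false_calls, 2)   # ~alpha-level false positives over 50 panels
})

test_that("degenerate zero-variance species are flagged, not dropped", {
  ind <- rbind(c(1, 1, 1), c(2, 2, 2), c(1, 2, 3))
  ctl <- rbind(c(1, 1, 1), c(1, 1, 1), c(2, 3, 4))
  pan <- perturbation_panel("L", c("equal", "shifted", "normal"), ind, ctl)
  res <- welch_species_tests(pan)
  expect_equal(res$p_raw[res$species == "equal"], 1)
  expect_true(res$degenerate[res$species == "shifted"])
  expect_true(is.na(res$p_adj[res$species == "shifted"]))
  expect_false(res$degenerate[res$species == "normal"])
  # family excludes the degenerate test
  expect_equal(attr(res, "family_size"), 2L)
})

test_that("paired tests match t.test and honour the degeneracy contract", {
  set.seed(7)
  sp <- sprintf("s%d", 1:10)
  ind <- matrix(rlnorm(30, 6), 10)
  ctl <- matrix(rlnorm(30, 6), 10)
  pan <- perturbation_panel("L", sp, ind, ctl, paired = TRUE)
  res <- paired_species_tests(pan)
  oracle <- sapply(1:10, function(i)
    stats::t.test(log2(ind[i, ]), log2(ctl[i, ]), paired = TRUE)$p.value)
  expect_equal(res$p_raw, oracle, tolerance = 1e-12)

  same <- perturbation_panel("L", "a", matrix(c(2, 3, 4), 1),
                             matrix(c(2, 3, 4), 1), paired = TRUE)
  expect_equal(paired_species_tests(same)$p_raw, 1)
  cons <- perturbation_panel("L", "a", matrix(c(4, 6, 8), 1),
                             matrix(c(2, 3, 4), 1), paired = TRUE)
  expect_error(welch_species_tests(cons, log_transform = TRUE), NA)
  expect_true(paired_species_tests(cons)$degenerate)  # constant log2 diff
  expect_error(paired_species_tests(gen_oe_panel(
    oe_panel_truth("L", sp), seed = 1)), "not paired")
})

test_that("multiplicity weights follow the 1/k rule", {
  res <- data.frame(
    ltp_id = c("L1", "L2", "L3", "L4", "L1", "L1"),
    species = c("a", "a", "a", "a", "b", "c"),
    log2_fc = c(2, 2, 2, 2, 1, 1),
    affected = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  w <- weight_multiplicity(res)
  expect_equal(w$weight[w$species == "a"], rep(0.25, 4))
  expect_equal(w$weight[w$species == "b"], 1)
  expect_equal(w$weight[w$species == "c"], 1)   # affected nowhere -> 1
  expect_equal(w$weighted_fc, w$weight * w$log2_fc)
  expect_true(all(w$weight > 0 & w$weight <= 1))
})

test_that("subclass calls OR over member species and span the full matrix", {
  res <- data.frame(
    ltp_id = rep(c("L1", "L2"), each = 4),
    species = rep(c("PC(34:1)", "PC(36:2)", "SM(d34:1)", "Cer(d34:1)"), 2),
    affected = c(TRUE, FALSE, FALSE, FALSE,  FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  sa <- subclass_affected(res)
  expect_equal(dim(sa$matrix), c(2L, 3L))
  expect_equal(sa$n_pairs, 6L)
  expect_true(sa$matrix["L1", "PC"])    # one affected species is enough
  expect_false(sa$matrix["L1", "SM"])
  expect_false(any(sa$matrix["L2", ]))
})

test_that("Fisher enrichment agrees with exhaustive enumeration", {
  ids <- sprintf("p%03d", 1:110)
  aff <- stats::setNames(c(rep(TRUE, 8), rep(FALSE, 2),
                           rep(TRUE, 20), rep(FALSE, 80)), ids)
  fe <- fisher_enrichment(ids[1:10], ids, aff)
  expect_equal(unname(fe$table), matrix(c(8, 2, 20, 80), 2, byrow = TRUE))
  expect_equal(fe$p_value, oracle_fisher_two_sided(fe$table),
               tolerance = 1e-09)
  # equal affected proportions -> p = 1
  aff2 <- stats::setNames(c(rep(TRUE, 5), rep(FALSE, 5),
                            rep(TRUE, 50), rep(FALSE, 50)), ids)
  expect_equal(fisher_enrichment(ids[1:10], ids, aff2)$p_value, 1)
  expect_error(fisher_enrichment(character(0), ids, aff), "empty subset")
  # symmetric under simultaneous row/column swap
  fe_sw <- fisher_enrichment(ids[11:110], ids, !aff)
  expect_equal(fe_sw$p_value, fe$p_value, tolerance = 1e-12)
})

test_that("screen-level adjustment uses one global Bonferroni family", {
  sp <- sprintf("s%02d", 1:30)
  # near-noiseless planted effects so the family bookkeeping, not test
  # power, is what this block exercises
  panels <- lapply(1:3, function(i)
    gen_oe_panel(oe_panel_truth(paste0("L", i), sp,
                                stats::setNames(2, sp[i]),
                                baseline_log_sd = 0.02), seed = i))
  res <- perturb_screen(panels, family = "global")
  expect_equal(attr(res, "family_size"), 90L)
  expect_equal(nrow(res), 90L)
  one <- welch_species_tests(panels[[1]], family_size = 90L)
  expect_equal(res$p_adj[res$ltp_id == "L1"], one$p_adj)
  expect_true(all(res$affected[paste(res$ltp_id, res$species) %in%
                                 c("L1 s01", "L2 s02", "L3 s03")]))
})
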