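test_that("chain profiles sum and scale as a hand count says", {
  tab <- data.frame(
    lipid_id = c("PC(32:1)", "PC(34:1)", "PC(34:2)", "PC(36:2)",
                 "SM(d34:1)", "Cer(d36:1)"),
    intensity = c(1, 3, 2, 4, 5, 2), stringsAsFactors = FALSE)
  pr <- chain_profile(tab, "total_carbons")
  expect_named(pr, c("glycerophospholipid", "sphingolipid"), ignore.order = TRUE)
  gp <- pr$glycerophospholipid
  # raw sums: 32 -> 1, 34 -> 5, 36 -> 4; min-max: 0, 1, 0.75
  expect_equal(gp$bin, c(32L, 34L, 36L))
  expect_equal(gp$value, c(0, 1, 0.75))
  sl <- pr$sphingolipid
  expect_equal(sl$bin, c(34L, 36L))
  expect_equal(sl$value, c(1, 0))

  du <- chain_profile(tab, "double_bonds")$glycerophospholipid
  # db sums: 1 -> 4, 2 -> 6 ; scaled 0, 1
  expect_equal(du$value, c(0, 1))

  single <- chain_profile(tab[1, ], split_by_class = FALSE)
  expect_equal(single$value, 0)  # constant-vector convention of min-max
  two <- chain_profile(tab[c(1, 4), ], split_by_class = FALSE)
  expect_equal(two$value, c(0, 1))
})

test_that("profile comparison is zero on identity and signed as declared", {
  tab <- data.frame(lipid_id = c("PC(32:0)", "PC(36:0)", "PC(40:0)"),
                    intensity = c(1, 2, 1), stringsAsFactors = FALSE)
  p <- chain_profile(tab, split_by_class = FALSE)
  cmp <- compare_profiles(p, p)
  expect_true(all(cmp$diff$difference == 0))
  expect_equal(cmp$shift, 0)

  shorter <- data.frame(lipid_id = c("PC(32:0)", "PC(36:0)", "PC(40:0)"),
                        intensity = c(2, 2, 0.5), stringsAsFactors = FALSE)
  cmp2 <- compare_profiles(chain_profile(shorter, split_by_class = FALSE), p)
  expect_lt(cmp2$shift, 0)       # mass moved to shorter chains
  expect_error(compare_profiles(p, chain_profile(tab, "double_bonds",
                                                 split_by_class = FALSE)),
               "different axes")
})

test_that("planted chain-length preference is recovered across seeds", {
  shifts <- sapply(1:20, function(s) {
    lp <- gen_lipidome_pair(seed = s, carbon_shift = -2)
    compare_profiles(chain_profile(lp$mobilized, split_by_class = FALSE),
                     chain_profile(lp$reference, split_by_class = FALSE))$shift
  })
  expect_true(all(shifts < 0))                  # sign in every seed
  expect_equal(mean(shifts), -2, tolerance = 0.25)
})

test_that("affected-fraction profiles count and scale correctly", {
  res <- data.frame(
    species = c("PC(32:1)", "PC(32:2)", "PC(36:1)", "PC(36:2)"),
    affected = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  pr <- affected_fraction_profile(res, "total_carbons")
  # fractions: 32 -> 1.0, 36 -> 0.5; scaled: 1, 0
  expect_equal(pr$value, c(1, 0))
  none <- affected_fraction_profile(transform(res, affected = FALSE))
  expect_true(all(none$value == 0))
  all_one_bin <- affected_fraction_profile(res[1:2, ])
  expect_equal(all_one_bin$value, 0)  # single constant bin scales to zero
})

test_that("subclass-max normalization maps each group max to 1", {
  tab <- data.frame(
    ltp_id = c("L1", "L1", "L1", "L2"),
    lipid_id = c("PC(34:1)", "PC(36:2)", "SM(d34:1)", "PC(34:1)"),
    intensity = c(2, 4, 5, 7), stringsAsFactors = FALSE)
  out <- subclass_max_normalize(tab)
  expect_equal(out$normalized_intensity, c(0.5, 1, 1, 1))
  # idempotent
  tab2 <- out; tab2$intensity <- out$normalized_intensity
  expect_equal(subclass_max_normalize(tab2)$normalized_intensity,
               out$normalized_intensity)
  # hexosyl merge map pools the subclasses before grouping
  hx <- data.frame(ltp_id = "L1",
                   lipid_id = c("HexCer(d34:1)", "Hex2Cer(d34:1)"),
                   intensity = c(1, 4), stringsAsFactors = FALSE)
  merged <- subclass_max_normalize(
    hx, merge_map = c(HexCer = "xHexCer", Hex2Cer = "xHexCer",
                      SHexCer = "xHexCer"))
  expect_equal(merged$subclass, c("xHexCer", "xHexCer"))
  expect_equal(merged$normalized_intensity, c(0.25, 1))
})
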