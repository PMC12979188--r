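test_that("a solid atom cluster has zero cavity volume", {
  g <- expand.grid(x = 0:2, y = 0:2, z = 0:2)
  solid <- data.frame(element = "C", g)
  expect_equal(pocket_volume(solid, probe_radius = 0)$pocket_volume, 0)
  expect_error(pocket_volume(solid[0, ], 0), "empty structure")
  expect_error(pocket_volume(solid, grid_spacing = 0), "> 0")
})

test_that("hollow-sphere cavity volume matches the analytic oracle", {
  path <- file.path(tempdir(), "sphere.pdb")
  fx <- gen_cavity_fixture(path, shell_radius = 10, atom_radius = 1.5,
                           seed = 1)
  pm <- pocket_volume(path, probe_radius = 0, grid_spacing = 0.5,
                      radii = c(C = 1.5))
  expect_equal(pm$pocket_volume, fx$expected_cavity_volume, tolerance = 0.05)
  expect_equal(pm$source, "computed_grid")
})

test_that("disjoint cavities are additive", {
  a1 <- read_structure_atoms(
    gen_cavity_fixture(file.path(tempdir(), "s1.pdb"), 10, 1.5, seed = 1)$path)
  a2 <- read_structure_atoms(
    gen_cavity_fixture(file.path(tempdir(), "s2.pdb"), 6, 1.5, seed = 2)$path)
  a2$x <- a2$x + 40
  vol <- function(at) pocket_volume(at, 0, 0.5, radii = c(C = 1.5))$pocket_volume
  expect_equal(vol(rbind(a1, a2)), vol(a1) + vol(a2), tolerance = 0.01)
})

test_that("volume is exactly invariant to translation and axis permutation", {
  at <- read_structure_atoms(
    gen_cavity_fixture(file.path(tempdir(), "s3.pdb"), 8, 1.5, seed = 4)$path)
  vol <- function(a) pocket_volume(a, 0, 0.5, radii = c(C = 1.5))$pocket_volume
  v0 <- vol(at)
  tr <- at; tr$x <- tr$x + 17.3; tr$y <- tr$y - 5.8; tr$z <- tr$z + 0.41
  expect_identical(vol(tr), v0)
  pm <- data.frame(element = at$element, x = at$z, y = at$x, z = at$y)
  expect_identical(vol(pm), v0)
})

test_that("grid refinement converges on the hollow-sphere fixture", {
  path <- file.path(tempdir(), "s4.pdb")
  gen_cavity_fixture(path, shell_radius = 10, atom_radius = 1.5, seed = 1)
  at <- read_structure_atoms(path)
  v <- sapply(c(1.0, 0.5, 0.25), function(h)
    pocket_volume(at, 0, h, radii = c(C = 1.5))$pocket_volume)
  expect_lt(abs(v[3] - v[2]), abs(v[2] - v[1]))
})

test_that("fit records carry the ratio with its exact algebra", {
  pm <- pocket_model_from_table("LTPX", 1000)
  expect_equal(fit_ratio(425, pm, "lip")$ratio, 0.425)
  expect_equal(fit_ratio(1000, pm, "lip")$ratio, 1.0)
  half <- pocket_model_from_table("LTPX", 500)
  expect_equal(fit_ratio(425, half, "lip")$ratio, 2 * 0.425)
  expect_error(pocket_model_from_table("L", -1))
})

test_that("buffer-zone threshold is the max over known pairs", {
  pm <- pocket_model_from_table("L1", 1000)
  rec <- function(v, known, ltp = "L1")
    fit_ratio(v, pocket_model_from_table(ltp, 1000), known_pair = known)
  records <- rbind(rec(100, TRUE), rec(200, TRUE), rec(425, TRUE),
                   rec(500, FALSE))
  expect_equal(buffer_zone_threshold(records), 0.425)
  bench <- fit_benchmark(records)
  expect_equal(bench$records$in_buffer_zone, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(bench$n_in_buffer_zone, 1L)

  single <- rec(300, TRUE)
  expect_equal(buffer_zone_threshold(single), 0.3)
  expect_error(buffer_zone_threshold(rec(300, FALSE)), "no known pairs")
  # adding a known record can only raise the threshold
  expect_gte(buffer_zone_threshold(rbind(records, rec(600, TRUE))),
             buffer_zone_threshold(records))
  # config-listed outlier exclusion
  records2 <- rbind(records, rec(900, TRUE, ltp = "SMALLPOCKET"))
  expect_equal(buffer_zone_threshold(records2, exclude_ltps = "SMALLPOCKET"),
               0.425)
})

test_that("Welch group comparison agrees with the hand-written oracle", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  res <- compare_ratio_groups(a, b)
  expect_equal(res$p_value, oracle_welch_p(a, b), tolerance = 1e-12)
  ident <- compare_ratio_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(compare_ratio_groups(c(1, 1), c(2, 2)), "degenerate")
  expect_error(compare_ratio_groups(1, c(1, 2)), "n >= 2")
})
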