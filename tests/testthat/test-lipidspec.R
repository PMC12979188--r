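test_that("shorthand names parse to fully populated species records", {
  sp <- parse_lipid_name("PC(16:0/18:1)")
  expect_s3_class(sp, "lipid_species")
  expect_equal(sp$subclass, "PC")
  expect_equal(sp$lipid_class, "glycerophospholipid")
  expect_equal(sp$resolution, "chain_resolved")
  expect_equal(sp$chains$carbons, c(16L, 18L))
  expect_equal(sp$chains$double_bonds, c(0L, 1L))
  expect_equal(sp$total_carbons, 34L)
  expect_equal(sp$total_double_bonds, 1L)

  cer <- parse_lipid_name("Cer(DH24:0/24:0)")
  expect_equal(cer$subclass, "Cer")
  expect_equal(cer$sphingoid_prefix, "DH")
  expect_equal(cer$total_carbons, 48L)
  expect_equal(cer$total_double_bonds, 0L)

  pi38 <- parse_lipid_name("PI(38:4)")
  expect_equal(pi38$resolution, "species_total")
  expect_equal(pi38$total_carbons, 38L)
  expect_equal(pi38$total_double_bonds, 4L)
  # synonym dialect
  expect_equal(canonical_lipid_name(parse_lipid_name("PtdIns(38:4)")),
               "PI(38:4)")

  sm <- parse_lipid_name("SM(d18:1/16:0)")
  expect_equal(sm$subclass, "SM")
  expect_equal(sm$lipid_class, "sphingolipid")
  expect_equal(sm$sphingoid_prefix, "d")

  pco <- parse_lipid_name("PC-O(34:1)")
  expect_true(pco$ether)
  expect_equal(pco$subclass, "PC-O")
  expect_equal(pco$lipid_class, "glycerophospholipid")
})

test_that("malformed or unknown names give errors naming the token", {
  expect_error(parse_lipid_name("PC(16:0"), "malformed")
  expect_error(parse_lipid_name("QQ(34:1)"), "unknown subclass.*'QQ'")
  expect_error(parse_lipid_name("PC(16:x/18:1)"), "malformed chain")
  expect_error(parse_lipid_name("PC()"), "empty chain")
  expect_error(parse_lipid_name("PC(d16:0/18:1)"), "sphingoid prefix")
  expect_error(parse_lipid_name(""), "non-empty")
})

test_that("every figure-legend abbreviation parses", {
  abbr <- c("PC", "SM", "Cer", "CerP", "HexCer", "Hex2Cer", "SHexCer",
            "TAG", "DAG", "PI", "PE", "PE-O", "PC-O", "LPC", "LPE",
            "LPE-O", "LPG", "PA", "PG", "PGP", "PS", "BMP", "CL",
            "FA", "FAL", "VA")
  for (a in abbr)
    expect_s3_class(parse_lipid_name(a), "lipid_species")
  # and with chain bodies where chains apply
  withchain <- c("PC(34:1)", "SM(d34:1)", "Cer(d18:1/16:0)", "CerP(d34:1)",
                 "HexCer(d34:1)", "Hex2Cer(d40:1)", "SHexCer(d42:2)",
                 "TAG(52:2)", "DAG(36:2)", "PE-O(36:2)", "LPE-O(18:1)",
                 "LPC(16:0)", "PGP(34:1)", "BMP(36:2)", "CL(72:8)",
                 "FA(16:0)", "FAL(18:0)")
  for (a in withchain)
    expect_s3_class(parse_lipid_name(a), "lipid_species")
})

test_that("parse -> canonicalize -> parse is idempotent", {
  names <- c("PC(16:0/18:1)", "SM(d18:1/16:0)", "Cer(DH24:0/24:0)",
             "PI(38:4)", "PC-O(34:1)", "PC(16:0_18:1)", "VA", "TAG(52:2)")
  for (n in names) {
    c1 <- canonical_lipid_name(parse_lipid_name(n))
    c2 <- canonical_lipid_name(parse_lipid_name(c1))
    expect_identical(c1, c2)
  }
  # '_' records unknown sn-position but canonical form uses '/'
  expect_identical(canonical_lipid_name(parse_lipid_name("PC(16:0_18:1)")),
                   "PC(16:0/18:1)")
})

test_that("subclass and class maps are deterministic and permutation-safe", {
  expect_identical(subclass_of("PC(18:1/16:0)"), subclass_of("PC(16:0/18:1)"))
  expect_identical(subclass_of(c("PC-O(34:1)", "SM(d18:1/16:0)")),
                   c("PC-O", "SM"))
  expect_identical(class_of(c("PC-O(34:1)", "PC(34:1)", "SM(d18:1/16:0)")),
                   c("glycerophospholipid", "glycerophospholipid",
                     "sphingolipid"))
})

test_that("group-contribution volume matches the brute-force oracle", {
  for (n in c("PC(16:0/18:1)", "SM(d18:1/16:0)", "Cer(DH24:0/24:0)",
              "PI(38:4)", "PC-O(34:1)", "LPC(16:0)", "TAG(52:2)", "VA")) {
    expect_equal(lipid_volume(n)$volume, oracle_group_volume(n),
                 tolerance = 1e-12, label = n)
  }
})

test_that("volume obeys the configured group increments exactly", {
  grp <- volume_groups()
  expect_equal(lipid_volume("PC(35:1)")$volume - lipid_volume("PC(34:1)")$volume,
               unname(grp["ch2_increment"]))
  expect_equal(lipid_volume("PC(34:1)")$volume - lipid_volume("PC(34:2)")$volume,
               unname(grp["double_bond_decrement"]))
})

test_that("volume is monotone within a subclass", {
  for (sub in c("PC", "PE", "SM", "TAG", "LPC")) {
    body <- function(c, d) if (sub == "SM") sprintf("%s(d%d:%d)", sub, c, d)
      else sprintf("%s(%d:%d)", sub, c, d)
    vols_c <- sapply(seq(30, 44, 2), function(c) lipid_volume(body(c, 2))$volume)
    expect_true(all(diff(vols_c) > 0), label = paste(sub, "carbons"))
    vols_d <- sapply(0:6, function(d) lipid_volume(body(36, d))$volume)
    expect_true(all(diff(vols_d) < 0), label = paste(sub, "double bonds"))
  }
})

test_that("species without a volume model error loudly, never zero", {
  sp <- parse_lipid_name("PC(34:1)")
  sp$subclass <- "ZZZ"
  expect_error(lipid_volume(sp), "no volume model")
})

test_that("parse_lipid_names collects unparseable names as warnings", {
  out <- parse_lipid_names(c("PC(34:1)", "nonsense(1", "SM(d34:1)"))
  expect_equal(nrow(out), 2L)
  w <- attr(out, "warnings")
  expect_equal(w$name, "nonsense(1")
  expect_match(w$message, "parse")
})
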