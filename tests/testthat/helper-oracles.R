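# Independent oracles, written before (and kept independent of) the code
# paths they check.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# tables with the observed margins: sum of probabilities of tables at most
# as probable as the observed one.
oracle_fisher_two_sided <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k)
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)), 0)
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

# Welch two-sided p from first principles (formula transcribed by hand, not
# shared with the package's vectorized implementation or with t.test).
oracle_welch_p <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  2 * stats::pt(-abs(tt), df)
}

# Brute-force group-contribution volume: re-reads the shipped tables and sums
# term by term, chain by chain.
oracle_group_volume <- function(name) {
  vocab <- read.delim(system.file("extdata", "lipid_subclasses.tsv",
                                  package = "ltpmob"))
  grp <- read.delim(system.file("extdata", "volume_groups.tsv",
                                package = "ltpmob"))
  g <- function(p) grp$value[grp$parameter == p]
  core <- sub("\\(.*$", "", name)
  ether <- grepl("-O$", core)
  base <- sub("-O$", "", core)
  row <- vocab[vocab$subclass == base, ]
  if (!is.na(row$fixed_volume)) return(row$fixed_volume)
  body <- sub("\\)$", "", sub("^.*\\(", "", name))
  toks <- strsplit(body, "[/_]")[[1]]
  vol <- row$headgroup_volume
  n_chain <- if (length(toks) == row$expected_chains) length(toks) else
    row$expected_chains
  tprefix <- FALSE
  for (tok in toks) {
    pre <- regmatches(tok, regexpr("^(DH|d|t)", tok))
    if (length(pre) && pre == "t") tprefix <- TRUE
    tok <- sub("^(DH|d|t)", "", tok)
    cd <- as.integer(strsplit(tok, ":")[[1]])
    vol <- vol + cd[1] * g("ch2_increment") - cd[2] * g("double_bond_decrement")
  }
  vol <- vol + n_chain * g("chain_terminal")
  if (ether) vol <- vol + g("ether_delta")
  if (tprefix) vol <- vol + g("sphingoid_t_extra")
  vol
}

# canonical unordered pair key (mirrors the package convention)
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

# small SEC run used by several tests
make_sec_run <- function(n_planted = 5, n_background = 100, noise_sd = 0.05,
                         seed = 1) {
  truth <- sec_sim_truth("LTP1", sprintf("lig%02d", seq_len(n_planted)),
                         sprintf("bg%03d", seq_len(n_background)),
                         noise_sd = noise_sd)
  list(truth = truth, run = gen_sec_run(truth, seed = seed))
}
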