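# Lipid shorthand nomenclature: parsing, class hierarchy, molecular volumes.
#
# Grammar:  SUBCLASS[-O] '(' chain (('/'|'_') chain)* ')'
# with chain = [d|t|DH] carbons ':' double_bonds, the sphingoid prefix
# allowed on the first chain of sphingolipid subclasses. Bare subclass
# tokens ("VA", "FA") are accepted as class-level mentions without chains.

.ltpmob_env <- new.env(parent = emptyenv())

#' Lipid subclass vocabulary
#'
#' The closed vocabulary of lipid subclasses known to the parser, with their
#' lipid class, expected acyl-chain count and the head-group volume used by
#' the group-contribution volume model. Shipped as an editable TSV in
#' \code{inst/extdata/lipid_subclasses.tsv}.
#'
#' @param path Optional path to an alternative vocabulary TSV with the same
#'   columns; the default is the table shipped with the package.
#' @return A data.frame with columns \code{subclass}, \code{lipid_class},
#'   \code{expected_chains}, \code{headgroup_volume}, \code{sphingo},
#'   \code{fixed_volume}, \code{description}.
#' @export
lipid_vocabulary <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    if (!is.null(.ltpmob_env$vocab)) return(.ltpmob_env$vocab)
    path <- system.file("extdata", "lipid_subclasses.tsv", package = "ltpmob",
                        mustWork = TRUE)
  }
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subclass", "lipid_class", "expected_chains",
                  "headgroup_volume", "sphingo", "fixed_volume") %in% names(v)))
  if (default) .ltpmob_env$vocab <- v
  v
}

#' Group-contribution volume parameters
#'
#' Named vector of the chain group-contribution terms (CH2 increment,
#' terminal methyl, double-bond decrement, ether and phytosphingoid
#' adjustments), in cubic Angstrom. A declared constant table, swappable via
#' \code{path}: the volume-ratio benchmark depends on relative ordering of
#' lipid volumes, not on any particular absolute scale.
#'
#' @param path Optional path to an alternative parameter TSV
#'   (columns \code{parameter}, \code{value}).
#' @return Named numeric vector.
#' @export
volume_groups <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    if (!is.null(.ltpmob_env$volgrp)) return(.ltpmob_env$volgrp)
    path <- system.file("extdata", "volume_groups.tsv", package = "ltpmob",
                        mustWork = TRUE)
  }
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- stats::setNames(as.numeric(g$value), g$parameter)
  if (default) .ltpmob_env$volgrp <- out
  out
}

# name synonyms accepted before vocabulary lookup
.lipid_synonyms <- c(PtdIns = "PI", Chol = "ST", Cholesterol = "ST")

.parse_error <- function(name, token, what, pos = NA) {
  stop(sprintf("cannot parse lipid name '%s': %s token '%s'%s",
               name, what, token,
               if (is.na(pos)) "" else sprintf(" at position %d", pos)),
       call. = FALSE)
}

.parse_chain <- function(tok, name) {
  m <- regmatches(tok, regexec("^(DH|d|t)?([0-9]+):([0-9]+)$", tok))[[1]]
  if (length(m) == 0)
    .parse_error(name, tok, "malformed chain")
  list(prefix = if (nzchar(m[2])) m[2] else "none",
       carbons = as.integer(m[3]), double_bonds = as.integer(m[4]))
}

#' Parse a lipid shorthand name
#'
#' Parses names such as \code{"PC(16:0/18:1)"}, \code{"SM(d18:1/16:0)"},
#' \code{"Cer(DH24:0/24:0)"}, \code{"PI(38:4)"} or \code{"PC-O(34:1)"} into a
#' structured species record. Both \code{'/'} (known sn-position) and
#' \code{'_'} (unknown) chain separators are accepted and recorded; species
#' comparison ignores the distinction. \code{"PtdIns"} is accepted as a
#' synonym of \code{"PI"}.
#'
#' @param name A single non-empty lipid name.
#' @return An object of class \code{"lipid_species"}: a list with fields
#'   \code{raw_name}, \code{lipid_class}, \code{subclass} (ether subclasses
#'   carry the \code{-O} suffix), \code{ether}, \code{sphingoid_prefix},
#'   \code{chains} (data.frame of \code{carbons}, \code{double_bonds}),
#'   \code{total_carbons}, \code{total_double_bonds}, \code{resolution}
#'   (\code{"chain_resolved"} or \code{"species_total"}).
#' @examples
#' sp <- parse_lipid_name("PC(16:0/18:1)")
#' sp$total_carbons        # 34
#' sp$total_double_bonds   # 1
#' @export
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1 || is.na(name) || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  vocab <- lipid_vocabulary()

  m <- regmatches(name, regexec("^([A-Za-z0-9]+)(-O)?(\\((.*)\\))?$", name))[[1]]
  if (length(m) == 0 || (grepl("(", name, fixed = TRUE) && !grepl("\\)$", name)))
    .parse_error(name, name, "malformed species name")
  head_tok <- m[2]
  ether <- identical(m[3], "-O")
  body <- m[5]

  base <- if (head_tok %in% names(.lipid_synonyms)) {
    unname(.lipid_synonyms[head_tok])
  } else head_tok
  row <- vocab[vocab$subclass == base, , drop = FALSE]
  if (nrow(row) == 0)
    .parse_error(name, head_tok, "unknown subclass", pos = 1L)
  if (ether && row$lipid_class != "glycerophospholipid")
    .parse_error(name, paste0(head_tok, "-O"), "ether suffix on non-glycerophospholipid")

  chains <- data.frame(carbons = integer(0), double_bonds = integer(0))
  separator <- NA_character_
  prefix <- "none"
  if (!is.na(body) && nzchar(body)) {
    separator <- if (grepl("_", body, fixed = TRUE)) "_" else "/"
    toks <- strsplit(body, "[/_]")[[1]]
    if (any(!nzchar(toks))) .parse_error(name, body, "malformed chain list")
    parsed <- lapply(toks, .parse_chain, name = name)
    pref <- vapply(parsed, `[[`, "", "prefix")
    if (any(pref[-1] != "none"))
      .parse_error(name, toks[which(pref != "none")[2]],
                   "sphingoid prefix allowed only on the first chain")
    prefix <- pref[1]
    if (prefix != "none" && row$sphingo != 1)
      .parse_error(name, toks[1], "sphingoid prefix on non-sphingolipid")
    chains <- data.frame(
      carbons = vapply(parsed, `[[`, 0L, "carbons"),
      double_bonds = vapply(parsed, `[[`, 0L, "double_bonds"))
  } else if (!is.na(m[4]) && identical(m[4], "()")) {
    .parse_error(name, "()", "empty chain list")
  }

  n_chain <- nrow(chains)
  resolution <- if (n_chain == 0) {
    "species_total"
  } else if (n_chain == row$expected_chains || row$expected_chains == 0) {
    "chain_resolved"
  } else if (n_chain == 1) {
    "species_total"
  } else {
    .parse_error(name, body, sprintf(
      "chain count %d incompatible with subclass (expects %d)",
      n_chain, row$expected_chains))
  }

  structure(list(
    raw_name = name,
    lipid_class = row$lipid_class,
    subclass = paste0(base, if (ether) "-O" else ""),
    ether = ether,
    sphingoid_prefix = prefix,
    chains = chains,
    total_carbons = sum(chains$carbons),
    total_double_bonds = sum(chains$double_bonds),
    resolution = resolution,
    separator = separator
  ), class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  [%s / %s, %d:%d, %s]\n",
              canonical_lipid_name(x), x$lipid_class, x$subclass,
              x$total_carbons, x$total_double_bonds, x$resolution))
  invisible(x)
}

#' Canonical shorthand name of a parsed species
#'
#' @param species A \code{lipid_species} (or a name, parsed first).
#' @return Canonical name using \code{'/'} chain separators.
#' @export
canonical_lipid_name <- function(species) {
  species <- as_lipid_species(species)
  base <- sub("-O$", "", species$subclass)
  if (nrow(species$chains) == 0) return(base)
  ch <- sprintf("%d:%d", species$chains$carbons, species$chains$double_bonds)
  if (species$sphingoid_prefix != "none")
    ch[1] <- paste0(species$sphingoid_prefix, ch[1])
  paste0(base, if (species$ether) "-O" else "", "(", paste(ch, collapse = "/"), ")")
}

#' @rdname parse_lipid_name
#' @param x A \code{lipid_species} object or a character name.
#' @export
as_lipid_species <- function(x) {
  if (inherits(x, "lipid_species")) x else parse_lipid_name(x)
}

#' Subclass and class of a lipid name
#'
#' Deterministic species -> subclass -> class mapping. Ether subclasses
#' (\code{"PC-O"}) are distinct from their ester counterparts at subclass
#' level but merge with them at class level (both glycerophospholipid).
#' Vectorized over names.
#'
#' @param name Character vector of lipid names (or a single
#'   \code{lipid_species}).
#' @return Character vector of subclass (or class) labels.
#' @export
subclass_of <- function(name) {
  if (inherits(name, "lipid_species")) return(name$subclass)
  vapply(name, function(n) parse_lipid_name(n)$subclass, "", USE.NAMES = FALSE)
}

#' @rdname subclass_of
#' @export
class_of <- function(name) {
  if (inherits(name, "lipid_species")) return(name$lipid_class)
  vapply(name, function(n) parse_lipid_name(n)$lipid_class, "", USE.NAMES = FALSE)
}

#' Group-contribution molecular volume of a lipid species
#'
#' Volume = head-group volume + per-chain (carbons x CH2 increment +
#' terminal methyl - double bonds x unsaturation decrement), plus small
#' configured adjustments for ether linkages and phytosphingoid backbones.
#' For species-total records the expected chain count of the subclass
#' supplies the number of terminal methyls. Whole-molecule species (vitamin
#' A, sterols) use fixed volumes from the vocabulary. Within a subclass the
#' volume is strictly increasing in total carbons and strictly decreasing in
#' double bonds.
#'
#' @param species A \code{lipid_species} or a lipid name.
#' @return An object of class \code{"lipid_volume"}: list with \code{species}
#'   and \code{volume} (cubic Angstrom).
#' @examples
#' lipid_volume("PC(16:0/18:1)")$volume
#' @export
lipid_volume <- function(species) {
  species <- as_lipid_species(species)
  vocab <- lipid_vocabulary()
  grp <- volume_groups()
  base <- sub("-O$", "", species$subclass)
  row <- vocab[vocab$subclass == base, , drop = FALSE]
  if (nrow(row) == 0)
    stop(sprintf("no volume model for subclass '%s'", species$subclass),
         call. = FALSE)

  if (!is.na(row$fixed_volume)) {
    vol <- as.numeric(row$fixed_volume)
  } else {
    if (is.na(row$headgroup_volume))
      stop(sprintf("no volume model for subclass '%s'", species$subclass),
           call. = FALSE)
    n_chain <- if (species$resolution == "chain_resolved") {
      nrow(species$chains)
    } else {
      row$expected_chains
    }
    vol <- as.numeric(row$headgroup_volume) +
      species$total_carbons * grp[["ch2_increment"]] +
      n_chain * grp[["chain_terminal"]] -
      species$total_double_bonds * grp[["double_bond_decrement"]]
    if (species$ether) vol <- vol + grp[["ether_delta"]]
    if (species$sphingoid_prefix == "t") vol <- vol + grp[["sphingoid_t_extra"]]
  }
  if (!is.finite(vol) || vol <= 0)
    stop(sprintf("volume model yields non-positive volume for '%s'",
                 species$raw_name), call. = FALSE)
  structure(list(species = species, volume = vol), class = "lipid_volume")
}

#' @export
print.lipid_volume <- function(x, ...) {
  cat(sprintf("<lipid_volume> %s: %.1f A^3\n",
              canonical_lipid_name(x$species), x$volume))
  invisible(x)
}

#' Parse many lipid names, collecting failures
#'
#' @param names Character vector of lipid names.
#' @return A data.frame (one row per parseable name) with columns
#'   \code{lipid_id}, \code{canonical}, \code{lipid_class}, \code{subclass},
#'   \code{ether}, \code{sphingoid_prefix}, \code{total_carbons},
#'   \code{total_double_bonds}, \code{resolution}; unparseable names and
#'   their error messages are attached as attribute \code{"warnings"}
#'   (a data.frame with \code{name} and \code{message}).
#' @export
parse_lipid_names <- function(names) {
  recs <- lapply(names, function(n) tryCatch(parse_lipid_name(n),
                                             error = function(e) e))
  bad <- vapply(recs, inherits, TRUE, "error")
  ok <- recs[!bad]
  out <- data.frame(
    lipid_id = vapply(ok, `[[`, "", "raw_name"),
    canonical = vapply(ok, canonical_lipid_name, ""),
    lipid_class = vapply(ok, `[[`, "", "lipid_class"),
    subclass = vapply(ok, `[[`, "", "subclass"),
    ether = vapply(ok, `[[`, TRUE, "ether"),
    sphingoid_prefix = vapply(ok, `[[`, "", "sphingoid_prefix"),
    total_carbons = vapply(ok, `[[`, 0L, "total_carbons"),
    total_double_bonds = vapply(ok, `[[`, 0L, "total_double_bonds"),
    resolution = vapply(ok, `[[`, "", "resolution"),
    stringsAsFactors = FALSE)
  attr(out, "warnings") <- data.frame(
    name = as.character(names[bad]),
    message = vapply(recs[bad], conditionMessage, ""),
    stringsAsFactors = FALSE)
  out
}
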