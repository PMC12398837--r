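#' Query templates: four atypical hDAT inhibitors
#'
#' The four benztropine-like atypical inhibitors of the human dopamine
#' transporter used as similarity-search queries: benztropine, JHW007
#' (its N-butyl bis(4-fluorophenyl) congener), and the R and S enantiomers
#' of modafinil (which differ only in the sulfoxide stereo descriptor).
#' Structures are shipped as canonical SMILES fixtures.
#'
#' @return A [molecule_records] data frame with 4 rows, source
#'   `"template"`.
#' @export
default_templates <- function() {
  molecule_records(
    id = c("benztropine", "JHW007", "R-modafinil", "S-modafinil"),
    smiles = c(
      "CN1C2CCC1CC(C2)OC(c1ccccc1)c1ccccc1",
      "CCCCN1C2CCC1CC(C2)OC(c1ccc(F)cc1)c1ccc(F)cc1",
      "NC(=O)C[S@](=O)C(c1ccccc1)c1ccccc1",
      "NC(=O)C[S@@](=O)C(c1ccccc1)c1ccccc1"
    ),
    source = "template"
  )
}

#' Repurposed active compounds (fixtures)
#'
#' The three N-(2,6-dimethylphenyl)piperidine-2-carboxamide local
#' anesthetics identified as dopamine-reuptake inhibitors: mepivacaine
#' (N-methyl), ropivacaine (N-propyl) and bupivacaine (N-butyl).
#'
#' @return A [molecule_records] data frame with 3 rows, source
#'   `"fixture"`.
#' @export
active_compounds <- function() {
  molecule_records(
    id = c("mepivacaine", "ropivacaine", "bupivacaine"),
    smiles = c(
      "CN1CCCCC1C(=O)Nc1c(C)cccc1C",
      "CCCN1CCCCC1C(=O)Nc1c(C)cccc1C",
      "CCCCN1CCCCC1C(=O)Nc1c(C)cccc1C"
    ),
    source = "fixture"
  )
}

# Seeded graph edits, expressed as pattern -> replacement rewrites on the
# SMILES string; every candidate is validated by OpenBabel
# canonicalization, so rewrites that would break valence or ring closure
# are discarded rather than emitted.
perturbation_rules <- function(level) {
  light <- list(
    list(p = "c1ccccc1",
         r = c("c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(C)cc1",
               "c1cccc(F)c1", "c1cccc(C)c1")),
    list(p = "c1ccc\\(F\\)cc1",
         r = c("c1ccc(Cl)cc1", "c1ccc(C)cc1", "c1ccccc1")),
    list(p = "F", r = c("Cl", "Br")),
    list(p = "Cl", r = c("F", "Br")),
    list(p = "Br", r = c("F", "Cl"))
  )
  medium <- list(
    list(p = "^CC", r = "CCC"),
    list(p = "^C(?=N)", r = "CC"),
    list(p = "^N(?=C)", r = "NC"),
    list(p = "OC\\(", r = c("OCC(", "OC(C)("))
  )
  heavy <- list(
    list(p = "CCC1", r = "CC1"),
    list(p = "CC1", r = "CCC1"),
    list(p = "CCC2", r = "CC2"),
    list(p = "CC2", r = "CCC2")
  )
  switch(match.arg(level, c("light", "medium", "heavy")),
         light = light,
         medium = c(light, medium),
         heavy = c(light, medium, heavy))
}

# All single-rewrite products of one SMILES under a rule set.
enumerate_edits <- function(smiles, rules) {
  out <- character(0)
  for (rule in rules) {
    m <- gregexpr(rule$p, smiles, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      start <- m[k]
      len <- attr(m, "match.length")[k]
      for (rep in rule$r) {
        out <- c(out, paste0(substr(smiles, 1, start - 1), rep,
                             substr(smiles, start + len, nchar(smiles))))
      }
    }
  }
  unique(out)
}

#' Generate structural analogs of a template molecule
#'
#' Produces `k` distinct, valid analogs by seeded structural rewrites of
#' the template SMILES. At `"light"` perturbation the edits are
#' substituent swaps (halogen exchange, aromatic F/Cl/methyl
#' substitution); `"medium"` adds single-atom chain homologation;
#' `"heavy"` adds aliphatic ring contraction/expansion by one atom. Single
#' edits are enumerated first; if fewer than `k` distinct valid analogs
#' exist, second-round edits of the first-round products are added. The
#' analog set is sampled deterministically from the valid pool under the
#' seed.
#'
#' @param template One-row [molecule_records] (or list with `id`,
#'   `smiles`).
#' @param k Number of analogs (>= 1).
#' @param level `"light"`, `"medium"` or `"heavy"`.
#' @param seed Integer seed.
#' @return A [molecule_records] data frame of `k` analogs with ids
#'   `<template>_an<k>`, source `"library"`.
#' @export
generate_analogs <- function(template, k, level = "light", seed = 1L) {
  if (k < 1) stop_ws("k must be >= 1", class = "whalescreen_contract_error")
  rules <- perturbation_rules(level)
  tid <- template$id[1]
  tsmi <- template$smiles[1]
  pool <- valid_distinct_edits(enumerate_edits(tsmi, rules), tsmi)
  if (length(pool) < k) {
    second <- unique(unlist(lapply(pool, enumerate_edits, rules = rules)))
    pool <- unique(c(pool, valid_distinct_edits(second, tsmi)))
  }
  if (length(pool) < k) {
    stop_ws("edit budget exhausted for template '%s': only %d distinct analogs achievable (requested %d)",
            tid, length(pool), k,
            class = "whalescreen_generation_error")
  }
  chosen <- with_seed(seed, sample(sort(pool), k))
  molecule_records(sprintf("%s_an%02d", tid, seq_len(k)), chosen, "library")
}

# Canonicalize candidate SMILES, drop invalid/multi-fragment ones and any
# that collapse onto the template itself; returns canonical SMILES.
valid_distinct_edits <- function(cands, template_smiles) {
  cands <- unique(cands[!grepl(".", cands, fixed = TRUE)])
  if (!length(cands)) return(character(0))
  ids <- sprintf("e%05d", seq_along(cands))
  can <- ob_canonical_smiles(cands, ids)
  tcan <- ob_canonical_smiles(template_smiles, "t")$cansmi
  pool <- unique(can$cansmi[!can$cansmi %in% tcan])
  pool[backend_parseable(pool)]
}

# Fragment sets for decoy assembly: scaffold strings with {A}/{B} slots.
# Every slot sits in a branch (or after a closed ring atom), so the FIRST
# atom of the substituent makes the attachment bond; substituents are
# written with a free valence on their first atom. Ring-bearing
# substituents use ring-closure digit 3, which is never open at a slot.
decoy_scaffolds <- function() {
  c("c1cc({A})ccc1{B}", "c1cc({A})cc({B})c1", "c1ccc({A})cc1",
    "c1cc({A})ccn1", "c1cc({A})cnc1{B}", "c1cc({A})cs1",
    "c1cc({A})co1", "c1sc({A})nc1", "c1ccc2cc({A})ccc2c1",
    "C1CCC({A})CC1", "C1CCN({A})CC1", "O1CCN({A})CC1",
    "C({A})(=O)Nc1ccc({B})cc1", "C({A})(=O)N(C)c1ccc({B})cc1",
    "C({A})(=O)Oc1ccc({B})cc1", "O=S(=O)({A})Nc1ccc({B})cc1",
    "c1cc({A})ccc1OC{B}", "c1ccc(-c2ccc({A})cc2)cc1",
    "c1cc({A})ccc1N(C)C{B}", "C({A})N1CCC({B})CC1")
}

decoy_substituents <- function() {
  c("C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C",
    "CCO", "CCN", "CCOC", "OC", "OCC", "N(C)C", "NC(C)=O",
    "F", "Cl", "Br", "C(F)(F)F", "C#N", "S(C)(=O)=O",
    "OC(F)F", "CN3CCCCC3", "N3CCOCC3", "c3ccccc3", "C3CCCCC3")
}

generate_decoys <- function(n, seed, exclude = character(0)) {
  if (n == 0) {
    return(molecule_records(character(0), character(0), "library"))
  }
  scaffolds <- decoy_scaffolds()
  subs <- decoy_substituents()
  accepted <- character(0)
  round <- 0L
  while (length(accepted) < n && round < 12L) {
    round <- round + 1L
    need <- n - length(accepted)
    m <- max(50L, ceiling(need * 1.6))
    cand <- with_seed(derive_seed(seed, paste0("decoys", round)), {
      sc <- sample(scaffolds, m, replace = TRUE)
      a <- sample(subs, m, replace = TRUE)
      b <- sample(subs, m, replace = TRUE)
      mapply(function(s1, a1, b1) {
        sub("{B}", b1, sub("{A}", a1, s1, fixed = TRUE), fixed = TRUE)
      }, sc, a, b, USE.NAMES = FALSE)
    })
    cand <- setdiff(unique(cand), accepted)
    if (!length(cand)) next
    props <- ob_smiles_properties(cand, sprintf("d%06d", seq_along(cand)))
    ok <- is.finite(props$mw) & props$mw >= 100 & props$mw <= 500 &
      !grepl(".", props$cansmi, fixed = TRUE) &
      !props$cansmi %in% c(accepted, exclude) &
      !duplicated(props$cansmi)
    ok[ok] <- backend_parseable(props$cansmi[ok])
    accepted <- c(accepted, props$cansmi[ok])
  }
  if (length(accepted) < n) {
    stop_ws("decoy assembly produced only %d of %d requested molecules",
            length(accepted), n, class = "whalescreen_generation_error")
  }
  accepted <- accepted[seq_len(n)]
  molecule_records(sprintf("DEC%05d", seq_len(n)), accepted, "library")
}

#' Specify a synthetic screening library
#'
#' Defaults define the benchmark conditions used throughout the package:
#' 2,000 fragment-assembled decoys plus 5 light analogs of each of the
#' four query templates, seed 11.
#'
#' @param n_decoys Number of decoy molecules (>= 0).
#' @param n_analogs_per_template Analogs planted per template (>= 0).
#' @param perturbation_level `"light"`, `"medium"` or `"heavy"`.
#' @param seed Integer seed; the same spec and seed always regenerate an
#'   identical library.
#' @param templates [molecule_records] of the query templates.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_decoys = 2000L, n_analogs_per_template = 5L,
                         perturbation_level = "light", seed = 11L,
                         templates = default_templates()) {
  if (n_decoys < 0 || n_analogs_per_template < 0) {
    stop_ws("n_decoys and n_analogs_per_template must be >= 0",
            class = "whalescreen_contract_error")
  }
  structure(list(n_decoys = as.integer(n_decoys),
                 n_analogs_per_template = as.integer(n_analogs_per_template),
                 perturbation_level = match.arg(perturbation_level,
                                                c("light", "medium", "heavy")),
                 seed = as.integer(seed),
                 templates = templates),
            class = "library_spec")
}

#' Generate a synthetic screening library
#'
#' Emulates a drug-repurposing screening collection: a background of
#' valence-legal, drug-like decoys (MW 100-500, mixed aromatic,
#' heteroaromatic, alicyclic and linker scaffolds assembled from a shipped
#' fragment set) with a controlled number of planted structural analogs of
#' the query templates. Rows are shuffled deterministically by the seed;
#' the `provenance` column partitions the library into `"decoy"` and
#' `"analog"` (with `template_id` naming the parent template of each
#' analog).
#'
#' @param spec A [library_spec()].
#' @return A [molecule_records] data frame with extra columns `provenance`
#'   and `template_id`.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  analogs <- NULL
  if (spec$n_analogs_per_template > 0) {
    analogs <- do.call(rbind, lapply(seq_len(nrow(spec$templates)), function(t) {
      tmpl <- spec$templates[t, ]
      rec <- generate_analogs(tmpl, spec$n_analogs_per_template,
                              level = spec$perturbation_level,
                              seed = derive_seed(spec$seed, tmpl$id))
      rec$provenance <- "analog"
      rec$template_id <- tmpl$id
      rec
    }))
  }
  exclude <- ob_canonical_smiles(spec$templates$smiles,
                                 spec$templates$id)$cansmi
  if (!is.null(analogs)) exclude <- c(exclude, analogs$smiles)
  decoys <- generate_decoys(spec$n_decoys, spec$seed, exclude = exclude)
  decoys$provenance <- rep("decoy", nrow(decoys))
  decoys$template_id <- rep(NA_character_, nrow(decoys))
  lib <- rbind(decoys, analogs)
  if (!nrow(lib)) {
    stop_ws("library spec produced no molecules",
            class = "whalescreen_generation_error")
  }
  lib <- lib[with_seed(spec$seed, sample(nrow(lib))), , drop = FALSE]
  rownames(lib) <- NULL
  class(lib) <- c("molecule_records", "data.frame")
  lib
}
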