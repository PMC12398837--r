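#' Prepared 3D molecule
#'
#' A `molecule3d` holds the per-atom data the WHALES descriptor consumes:
#' element symbols, 3D coordinates in Angstrom, and Gasteiger-Marsili
#' partial charges in elementary-charge units, with explicit hydrogens.
#'
#' @param id Molecule identifier.
#' @param elements Character vector of element symbols, length `n`.
#' @param coords Numeric `n x 3` matrix of coordinates (Angstrom).
#' @param charges Numeric vector of per-atom partial charges (e).
#' @param smiles Canonical SMILES the molecule was built from (optional).
#' @param bonds Integer two-column matrix of 1-based atom index pairs
#'   (optional; used for hydrogen-bond donor counting).
#' @return An object of class `molecule3d`.
#' @export
molecule3d <- function(id, elements, coords, charges, smiles = NA_character_,
                       bonds = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (nrow(coords) != n || ncol(coords) != 3 || length(charges) != n) {
    stop_ws("molecule3d '%s': elements, coords and charges sizes disagree",
            id, class = "whalescreen_contract_error")
  }
  if (!all(is.finite(coords)) || !all(is.finite(charges))) {
    stop_ws("molecule3d '%s': non-finite coordinates or charges", id,
            class = "whalescreen_contract_error")
  }
  if (is.null(bonds)) bonds <- cbind(from = integer(0), to = integer(0))
  structure(
    list(id = as.character(id), elements = as.character(elements),
         coords = coords, charges = as.numeric(charges),
         n_atoms = n, smiles = smiles, bonds = bonds),
    class = "molecule3d"
  )
}

#' @export
print.molecule3d <- function(x, ...) {
  cat(sprintf("<molecule3d> %s: %d atoms, net charge %+.3f e\n",
              x$id, x$n_atoms, sum(x$charges)))
  invisible(x)
}

#' Prepare a collection of molecules for descriptor computation
#'
#' Adds explicit hydrogens, embeds one 3D conformation per molecule with
#' the ETKDG distance-geometry algorithm, minimizes it under the MMFF94
#' force field (falling back to UFF when MMFF94 lacks parameters for an
#' atom type), and assigns Gasteiger-Marsili partial charges. The whole
#' collection is processed in a single batched call to the RDKit backend.
#' The embedding is stochastic but seeded: each molecule's seed is derived
#' deterministically from the master seed and its id, so the same records
#' and seed give bitwise-identical coordinates, and adding molecules to a
#' collection never changes the conformers of the others.
#'
#' Failures (embedding or charging) are collected per molecule in the
#' `"failures"` attribute rather than aborting, unless every molecule
#' fails.
#'
#' @param records A [molecule_records] data frame.
#' @param seed Integer master seed; per-molecule seeds are derived from it
#'   and the molecule id.
#' @param minimize_steps Number of MMFF94 minimization steps (default 500).
#' @param num_confs Conformations embedded per molecule; the lowest-energy
#'   minimized one is kept (default 1).
#' @return A list of [molecule3d] objects, in input order, with attribute
#'   `failures` (data frame of id + reason for molecules that could not be
#'   prepared).
#' @export
prepare_collection <- function(records, seed = 7L, minimize_steps = 500L,
                               num_confs = 1L) {
  if (!nrow(records)) {
    stop_ws("cannot prepare an empty record collection",
            class = "whalescreen_contract_error")
  }
  seeds <- vapply(records$id, derive_seed, integer(1), seed = seed)
  mols <- run_prepare_backend(records$smiles, records$id, seeds,
                              minimize_steps, num_confs)
  out <- vector("list", nrow(records))
  fail_id <- character(0); fail_why <- character(0)
  formal <- smiles_formal_charge(records$smiles)
  for (k in seq_len(nrow(records))) {
    id <- records$id[k]
    m <- mols[[id]]
    reason <- NULL
    if (is.null(m)) {
      reason <- "3D embedding/minimization failed"
    } else if (!is.null(m$error)) {
      reason <- m$error
    } else if (!all(is.finite(m$coords)) || !all(is.finite(m$charges))) {
      reason <- "non-finite coordinates or charges"
    } else if (abs(sum(m$charges) - formal[k]) > 0.01) {
      reason <- sprintf("charge not conserved (sum %.4f, formal %d)",
                        sum(m$charges), formal[k])
    }
    if (is.null(reason)) {
      out[[k]] <- molecule3d(id, m$elements, m$coords, m$charges,
                             smiles = records$smiles[k], bonds = m$bonds)
    } else {
      fail_id <- c(fail_id, id); fail_why <- c(fail_why, reason)
    }
  }
  ok <- !vapply(out, is.null, logical(1))
  if (!any(ok)) {
    stop_ws("preparation failed for all %d molecules (first: %s - %s)",
            nrow(records), fail_id[1], fail_why[1],
            class = "whalescreen_preparation_error")
  }
  res <- out[ok]
  names(res) <- records$id[ok]
  attr(res, "failures") <- data.frame(id = fail_id, reason = fail_why,
                                      stringsAsFactors = FALSE)
  res
}

#' Prepare a single molecule
#'
#' Single-record convenience wrapper around [prepare_collection()]; unlike
#' the collection version it raises an error naming the molecule when
#' preparation fails.
#'
#' @param record One-row [molecule_records] data frame (or a list with
#'   `id` and `smiles`).
#' @inheritParams prepare_collection
#' @return A [molecule3d].
#' @export
prepare_molecule <- function(record, seed = 7L, minimize_steps = 500L,
                             num_confs = 1L) {
  rec <- molecule_records(record$id[1], record$smiles[1],
                          if (!is.null(record$source)) record$source[1]
                          else "library")
  res <- tryCatch(prepare_collection(rec, seed = seed,
                                     minimize_steps = minimize_steps,
                                     num_confs = num_confs),
                  error = function(e) {
                    stop_ws("preparation failed for molecule '%s': %s",
                            rec$id, conditionMessage(e),
                            class = "whalescreen_preparation_error")
                  })
  res[[1]]
}

#' Write prepared molecules to SDF with partial charges
#'
#' Serializes prepared molecules as SDF V2000 with the per-atom
#' Gasteiger-Marsili charges stored in a `PARTIAL_CHARGES` data field (one
#' value per atom, space-separated), since the V2000 atom block itself has
#' no partial-charge column.
#'
#' @param mols List of [molecule3d] objects.
#' @param path Output SDF path.
#' @return `path`, invisibly.
#' @seealso [read_prepared_sdf()]
#' @export
write_prepared_sdf <- function(mols, path) {
  blocks <- vapply(mols, function(m) {
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      m$n_atoms, nrow(m$bonds))
    atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     m$coords[, 1], m$coords[, 2], m$coords[, 3], m$elements)
    bonds <- if (nrow(m$bonds)) {
      sprintf("%3d%3d  1  0  0  0  0", m$bonds[, 1], m$bonds[, 2])
    } else character(0)
    paste(c(m$id, " whalescreen", "", counts, atoms, bonds, "M  END",
            "> <PARTIAL_CHARGES>",
            paste(sprintf("%.6f", m$charges), collapse = " "), "",
            "> <SMILES>", as.character(m$smiles), "", "$$$$"),
          collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Read prepared molecules back from SDF
#'
#' Inverse of [write_prepared_sdf()]: restores id, elements, coordinates,
#' bonds and the `PARTIAL_CHARGES` data field.
#'
#' @param path SDF file written by [write_prepared_sdf()].
#' @return List of [molecule3d] objects.
#' @export
read_prepared_sdf <- function(path) {
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  out <- lapply(seq_len(length(sdf)), function(k) {
    rec <- sdf[[k]]
    ab <- ChemmineR::atomblock(rec)
    elements <- gsub("_[0-9]+$", "", rownames(ab))
    coords <- ab[, 1:3, drop = FALSE]
    db <- ChemmineR::datablock(rec)
    charges <- as.numeric(strsplit(trimws(db[["PARTIAL_CHARGES"]]),
                                   "[ \t]+")[[1]])
    bb <- ChemmineR::bondblock(rec)
    bonds <- cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]))
    smiles <- if ("SMILES" %in% names(db)) db[["SMILES"]] else NA_character_
    id <- trimws(ChemmineR::header(rec)[["Molecule_Name"]])
    molecule3d(id, elements, coords, charges, smiles = smiles, bonds = bonds)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}
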