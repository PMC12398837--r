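# RDKit preparation backend: seeded ETKDG 3D embedding, MMFF94 (or UFF
# fallback) minimization, Gasteiger-Marsili charges. One Python process per
# collection; the helper script ships with the package.

python_path <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop_ws("no 'python' interpreter found on the PATH (required for 3D preparation)",
          class = "whalescreen_missing_python")
}

prepare_script <- function() {
  system.file("python", "prepare_molecules.py", package = "whalescreen",
              mustWork = TRUE)
}

# Returns a named list keyed by molecule id; each element has either
# elements/coords/charges/bonds/forcefield, or an `error` message.
run_prepare_backend <- function(smiles, ids, seeds, minimize_steps,
                                num_confs = 1L) {
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(smiles, ids, seeds, as.integer(minimize_steps),
                   as.integer(num_confs), sep = "\t"), infile)
  log <- suppressWarnings(
    system2(python_path(), c(prepare_script(), infile, outfile),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(log, "status")
  if (!is.null(status) && status != 0) {
    stop_ws("preparation backend failed (status %d): %s", status,
            paste(utils::tail(log, 3), collapse = "; "),
            class = "whalescreen_preparation_error")
  }
  parse_prepared_blocks(readLines(outfile, warn = FALSE))
}

# Logical vector: does each SMILES parse and sanitize (valence check
# included) as a single connected molecule in the preparation backend?
backend_parseable <- function(smiles) {
  if (!length(smiles)) return(logical(0))
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  ids <- sprintf("s%07d", seq_along(smiles))
  writeLines(paste(smiles, ids, sep = "\t"), infile)
  script <- system.file("python", "validate_smiles.py",
                        package = "whalescreen", mustWork = TRUE)
  log <- suppressWarnings(
    system2(python_path(), c(script, infile, outfile),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(log, "status")
  if (!is.null(status) && status != 0) {
    stop_ws("SMILES validation backend failed: %s",
            paste(utils::tail(log, 2), collapse = "; "),
            class = "whalescreen_preparation_error")
  }
  ok <- readLines(outfile, warn = FALSE)
  ids %in% ok
}

parse_prepared_blocks <- function(lines) {
  out <- list()
  k <- 1L
  n_lines <- length(lines)
  while (k <= n_lines) {
    toks <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (toks[1] == "ERR") {
      out[[toks[2]]] <- list(error = paste(toks[-(1:2)], collapse = " "))
      k <- k + 1L
    } else if (toks[1] == "MOL") {
      id <- toks[2]
      n_atoms <- as.integer(toks[3])
      n_bonds <- as.integer(toks[4])
      atom_rows <- lines[(k + 1L):(k + n_atoms)]
      af <- do.call(rbind, strsplit(atom_rows, "\t", fixed = TRUE))
      coords <- matrix(as.numeric(af[, 3:5]), ncol = 3,
                       dimnames = list(NULL, c("x", "y", "z")))
      bonds <- cbind(from = integer(0), to = integer(0))
      if (n_bonds > 0) {
        bond_rows <- lines[(k + n_atoms + 1L):(k + n_atoms + n_bonds)]
        bf <- do.call(rbind, strsplit(bond_rows, "\t", fixed = TRUE))
        bonds <- cbind(from = as.integer(bf[, 2]), to = as.integer(bf[, 3]))
      }
      out[[id]] <- list(elements = af[, 2], coords = coords,
                        charges = as.numeric(af[, 6]), bonds = bonds,
                        forcefield = toks[5])
      k <- k + 1L + n_atoms + n_bonds
    } else {
      k <- k + 1L
    }
  }
  out
}
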