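# Thin wrapper around the OpenBabel command-line tool, which performs the
# standard cheminformatics steps of the pipeline: SMILES parsing and
# canonicalization, 3D embedding, MMFF94 minimization, Gasteiger-Marsili
# charge assignment, and the classical logP/TPSA/MW descriptors.
#
# All conversions run as single batched invocations: one process per
# collection, never one per molecule. The deterministic embedding path
# (`--gen3d fast` + `--minimize --ff MMFF94`) is rule-based, so identical
# inputs give bitwise-identical coordinates across runs and machines.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop_ws("OpenBabel executable 'obabel' not found on the PATH",
            class = "whalescreen_missing_obabel")
  }
  p
}

run_obabel <- function(args, input_lines = NULL) {
  infile <- NULL
  if (!is.null(input_lines)) {
    infile <- tempfile(fileext = ".smi")
    on.exit(unlink(infile), add = TRUE)
    writeLines(input_lines, infile)
    args <- c(infile, args)
  }
  args <- c(args, "-e")  # continue with the next entry after parse errors
  out <- suppressWarnings(
    system2(obabel_path(), args, stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0 && !any(grepl("molecule", out))) {
    stop_ws("obabel failed (status %d): %s", status,
            paste(utils::tail(out, 3), collapse = "; "),
            class = "whalescreen_obabel_error")
  }
  out
}

# Run obabel writing to an output file and return its lines; stderr noise
# (per-molecule parse errors) is captured, not printed.
run_obabel_file <- function(args, input_lines = NULL) {
  outfile <- tempfile()
  on.exit(unlink(outfile), add = TRUE)
  run_obabel(c(args, "-O", outfile), input_lines = input_lines)
  if (!file.exists(outfile)) return(character(0))
  readLines(outfile, warn = FALSE)
}

# Canonicalize SMILES in batch. Returns a data.frame(id, cansmi) containing
# only the inputs OpenBabel could parse; invalid entries are simply absent.
ob_canonical_smiles <- function(smiles, ids, largest_fragment = FALSE) {
  stopifnot(length(smiles) == length(ids), !anyDuplicated(ids))
  args <- c("-osmi", if (largest_fragment) "-r")
  out <- run_obabel_file(args, input_lines = paste(smiles, ids))
  parse_title_lines(out, ids)
}

# Canonical SMILES plus OpenBabel MW/logP/TPSA descriptors in one pass.
ob_smiles_properties <- function(smiles, ids) {
  stopifnot(length(smiles) == length(ids), !anyDuplicated(ids))
  out <- run_obabel_file(c("-osmi", "--append", "MW logP TPSA"),
                         input_lines = paste(smiles, ids))
  parsed <- parse_title_lines(out, ids, n_trailing = 3)
  names(parsed) <- c("id", "cansmi", "mw", "logp", "tpsa")
  parsed
}

parse_title_lines <- function(lines, ids, n_trailing = 0) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(id = character(0), cansmi = character(0))
    for (k in seq_len(n_trailing)) out[[paste0("v", k)]] <- numeric(0)
    return(out)
  }
  toks <- strsplit(lines, "[ \t]+")
  smi <- vapply(toks, `[[`, character(1), 1)
  rest <- lapply(toks, function(tk) tk[-1])
  # title may itself contain no spaces (we control the ids), so the layout is
  # <smiles> <id> [<desc1> ... <descN>]
  id <- vapply(rest, `[[`, character(1), 1)
  keep <- id %in% ids
  out <- data.frame(id = id[keep], cansmi = smi[keep],
                    stringsAsFactors = FALSE)
  if (n_trailing > 0) {
    for (k in seq_len(n_trailing)) {
      out[[paste0("v", k)]] <- vapply(rest[keep], function(tk) {
        v <- suppressWarnings(as.numeric(tk[1 + k]))
        if (length(v) != 1 || is.na(v)) NA_real_ else v
      }, numeric(1))
    }
  }
  out
}

# Parse the atom and bond blocks of a (multi-molecule) mol2 string into a
# list of raw molecule entries. No installed R package reads mol2, hence
# this small dedicated reader for OpenBabel's output.
parse_mol2 <- function(lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    chunk <- lines[starts[k]:ends[k]]
    name <- trimws(chunk[2])
    atom_at <- grep("^@<TRIPOS>ATOM", chunk)[1]
    bond_at <- grep("^@<TRIPOS>BOND", chunk)[1]
    sec_at <- grep("^@<TRIPOS>", chunk)
    atom_end <- min(c(sec_at[sec_at > atom_at], length(chunk) + 1L)) - 1L
    atom_lines <- chunk[(atom_at + 1L):atom_end]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    af <- utils::read.table(text = atom_lines, stringsAsFactors = FALSE)
    elements <- sub("\\..*$", "", af[[6]])
    coords <- as.matrix(af[, 3:5])
    dimnames(coords) <- list(NULL, c("x", "y", "z"))
    charges <- if (ncol(af) >= 9) as.numeric(af[[9]]) else rep(NA_real_, nrow(af))
    bonds <- NULL
    if (!is.na(bond_at)) {
      bond_end <- min(c(sec_at[sec_at > bond_at], length(chunk) + 1L)) - 1L
      if (bond_end > bond_at) {
        bl <- chunk[(bond_at + 1L):bond_end]
        bl <- bl[nzchar(trimws(bl))]
        if (length(bl)) {
          bf <- utils::read.table(text = bl, stringsAsFactors = FALSE)
          bonds <- cbind(from = as.integer(bf[[2]]), to = as.integer(bf[[3]]))
        }
      }
    }
    if (is.null(bonds)) bonds <- cbind(from = integer(0), to = integer(0))
    list(name = name, elements = elements, coords = coords,
         charges = charges, bonds = bonds)
  })
}
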