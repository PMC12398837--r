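#' Create a table of molecule records
#'
#' A molecule record collection is the entry point of the screening
#' pipeline: a data frame with one row per molecule holding a unique `id`,
#' a SMILES string, and a `source` label (`"template"`, `"library"` or
#' `"fixture"`).
#'
#' @param id Character vector of unique identifiers.
#' @param smiles Character vector of SMILES strings, same length as `id`.
#' @param source Source label(s), recycled; one of `"template"`,
#'   `"library"`, `"fixture"`.
#' @return A data frame of class `molecule_records` with columns `id`,
#'   `smiles`, `source`.
#' @examples
#' molecule_records("etoh", "CCO", "fixture")
#' @export
molecule_records <- function(id, smiles, source = "library") {
  id <- as.character(id)
  smiles <- as.character(smiles)
  if (length(id) != length(smiles)) {
    stop_ws("id and smiles must have the same length",
            class = "whalescreen_contract_error")
  }
  if (anyDuplicated(id)) {
    stop_ws("molecule ids must be unique within a collection (duplicated: %s)",
            paste(unique(id[duplicated(id)]), collapse = ", "),
            class = "whalescreen_contract_error")
  }
  source <- rep_len(as.character(source), length(id))
  bad <- setdiff(unique(source), c("template", "library", "fixture"))
  if (length(bad)) {
    stop_ws("unknown source label(s): %s", paste(bad, collapse = ", "),
            class = "whalescreen_contract_error")
  }
  out <- data.frame(id = id, smiles = smiles, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("molecule_records", "data.frame")
  out
}

#' Read a molecule library from disk
#'
#' Reads either a multi-record SDF (V2000) file or a plain-text SMILES file
#' (one molecule per line, optionally followed by a whitespace-separated
#' id). Every entry is validated by parsing it with OpenBabel; entries that
#' fail to parse are skipped with a warning and counted in the
#' `"n_skipped"` attribute of the result. Multi-fragment inputs (salts,
#' mixtures) are reduced to their largest connected fragment, with a
#' message reporting how many were stripped.
#'
#' @param path Path to the input file.
#' @param format `"sdf"`, `"smiles"`, or `"auto"` (by file extension).
#' @param source Source label stored on the records.
#' @return A [molecule_records] data frame with attribute `n_skipped`.
#' @export
read_library <- function(path, format = c("auto", "sdf", "smiles"),
                         source = "library") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_ws("cannot read library: no such file '%s'", path,
            class = "whalescreen_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "mol")) "sdf" else "smiles"
  }
  raw <- switch(format,
    smiles = read_smiles_entries(path),
    sdf = read_sdf_entries(path)
  )
  if (!nrow(raw)) {
    stop_ws("no molecule entries found in '%s'", path,
            class = "whalescreen_empty_library")
  }
  can <- ob_canonical_smiles(raw$smiles, raw$id, largest_fragment = TRUE)
  ok <- raw$id %in% can$id
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(sprintf("skipped %d unparseable entr%s in '%s' (%s)",
                    n_skipped, if (n_skipped == 1) "y" else "ies", path,
                    paste(utils::head(raw$id[!ok], 5), collapse = ", ")),
            call. = FALSE)
  }
  if (!any(ok)) {
    stop_ws("no valid molecules in '%s' (%d entries, all unparseable)",
            path, nrow(raw), class = "whalescreen_empty_library")
  }
  kept <- raw[ok, , drop = FALSE]
  stripped <- grepl("\\.", kept$smiles, fixed = FALSE)
  cansmi <- can$cansmi[match(kept$id, can$id)]
  if (any(stripped)) {
    message(sprintf("kept largest fragment for %d multi-fragment entr%s",
                    sum(stripped), if (sum(stripped) == 1) "y" else "ies"))
    kept$smiles[stripped] <- cansmi[stripped]
  }
  out <- molecule_records(kept$id, kept$smiles, source)
  attr(out, "n_skipped") <- n_skipped
  out
}

read_smiles_entries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(id = character(0), smiles = character(0)))
  }
  toks <- strsplit(lines, "[ \t]+")
  smiles <- vapply(toks, `[[`, character(1), 1)
  id <- vapply(seq_along(toks), function(k) {
    if (length(toks[[k]]) >= 2) toks[[k]][2] else sprintf("M%04d", k)
  }, character(1))
  if (anyDuplicated(id)) id <- make.unique(id, sep = "_")
  data.frame(id = id, smiles = smiles, stringsAsFactors = FALSE)
}

read_sdf_entries <- function(path) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) {
                    stop_ws("unreadable SDF file '%s': %s", path,
                            conditionMessage(e),
                            class = "whalescreen_io_error")
                  })
  n <- length(sdf)
  if (!n) return(data.frame(id = character(0), smiles = character(0)))
  ids <- vapply(seq_len(n), function(k) {
    h <- ChemmineR::header(sdf[[k]])
    nm <- trimws(h[["Molecule_Name"]])
    if (nzchar(nm)) gsub("[ \t]+", "_", nm) else sprintf("M%04d", k)
  }, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  # convert each SDF record to SMILES in one obabel pass, keyed by position
  txt <- readLines(path, warn = FALSE)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(txt, tmp)
  out <- run_obabel_file(c(tmp, "-osmi", "-xn"))  # -xn: no titles
  out <- out[nzchar(out)]
  smi <- vapply(strsplit(out, "[ \t]+"), `[[`, character(1), 1)
  if (length(smi) != n) {
    # fall back to per-record conversion alignment via titles
    out2 <- run_obabel_file(c(tmp, "-osmi"))
    parsed <- parse_title_lines(out2, ids)
    keep <- ids %in% parsed$id
    return(data.frame(id = ids[keep],
                      smiles = parsed$cansmi[match(ids[keep], parsed$id)],
                      stringsAsFactors = FALSE))
  }
  data.frame(id = ids, smiles = smi, stringsAsFactors = FALSE)
}

#' Write records to a SMILES file
#'
#' One line per molecule: `SMILES<TAB>id`.
#'
#' @param records A [molecule_records] data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(records, path) {
  writeLines(paste(records$smiles, records$id, sep = "\t"), path)
  invisible(path)
}
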