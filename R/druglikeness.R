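#' Physicochemical property profile
#'
#' Computes the five classical drug-likeness descriptors used by the
#' screening filter:
#' * `mw` - molecular weight in Da (average atomic masses, hydrogens
#'   included);
#' * `logp` - Wildman-Crippen atom-contribution octanol/water logP
#'   (OpenBabel implementation), unitless;
#' * `hba` - hydrogen-bond acceptors, Lipinski-style N + O atom count;
#' * `hbd` - hydrogen-bond donors, count of N/O atoms bearing at least one
#'   hydrogen;
#' * `tpsa` - Ertl fragment-contribution topological polar surface area in
#'   Angstrom^2.
#'
#' All values are 2D/topological and deterministic: conformers play no
#' role.
#'
#' @param x A list of [molecule3d] objects, a single [molecule3d], or a
#'   [molecule_records] data frame.
#' @return Data frame with columns `molecule_id`, `mw`, `logp`, `hba`,
#'   `hbd`, `tpsa`.
#' @export
property_profile <- function(x) {
  if (inherits(x, "molecule3d")) x <- list(x)
  if (is.list(x) && !is.data.frame(x)) {
    ids <- vapply(x, `[[`, character(1), "id")
    smiles <- vapply(x, `[[`, character(1), "smiles")
    if (anyNA(smiles)) {
      stop_ws("molecule3d objects without a SMILES cannot be profiled",
              class = "whalescreen_contract_error")
    }
  } else {
    ids <- x$id; smiles <- x$smiles
  }
  props <- ob_smiles_properties(smiles, ids)
  if (nrow(props) < length(ids)) {
    stop_ws("property computation failed for: %s",
            paste(setdiff(ids, props$id), collapse = ", "),
            class = "whalescreen_preparation_error")
  }
  counts <- hbond_counts(smiles, ids)
  m <- match(ids, props$id)
  cm <- match(ids, counts$id)
  data.frame(molecule_id = ids,
             mw = props$mw[m],
             logp = props$logp[m],
             hba = counts$hba[cm],
             hbd = counts$hbd[cm],
             tpsa = props$tpsa[m],
             stringsAsFactors = FALSE)
}

# N+O acceptor and N/O-H donor counts from the hydrogen-complete molecular
# graph (one batched OpenBabel conversion to mol2 with explicit hydrogens).
hbond_counts <- function(smiles, ids) {
  lines <- run_obabel_file(c("-omol2", "-h"),
                           input_lines = paste(smiles, ids))
  mols <- parse_mol2(lines)
  res <- lapply(mols, function(m) {
    no <- which(m$elements %in% c("N", "O"))
    hba <- length(no)
    h <- which(m$elements == "H")
    donors <- unique(c(m$bonds[m$bonds[, "to"] %in% h, "from"],
                       m$bonds[m$bonds[, "from"] %in% h, "to"]))
    hbd <- length(intersect(donors, no))
    data.frame(id = m$name, hba = hba, hbd = hbd, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Default drug-likeness property windows
#'
#' The screening filter's ranges: MW 100-400 Da, logP 1-5, HBA 2-5,
#' HBD 0-2, TPSA 20-90 Angstrom^2, all bounds inclusive.
#'
#' @return Named list of `c(lo, hi)` windows.
#' @export
default_windows <- function() {
  list(mw = c(100, 400), logp = c(1, 5), hba = c(2, 5),
       hbd = c(0, 2), tpsa = c(20, 90))
}

#' Apply drug-likeness windows to property profiles
#'
#' Checks each profile against each configured window with inclusive
#' bounds; `pass_all` is the conjunction of the per-window flags. Widening
#' any window can only turn failures into passes, never the reverse.
#'
#' @param profile Data frame from [property_profile()].
#' @param windows Named list of `c(lo, hi)` ranges over profile columns
#'   (default [default_windows()]).
#' @return Data frame with `molecule_id`, one `pass_<window>` logical
#'   column per window, and `pass_all`.
#' @export
apply_windows <- function(profile, windows = default_windows()) {
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (length(w) != 2 || !is.numeric(w) || is.na(w[1]) || is.na(w[2]) ||
        w[1] > w[2]) {
      stop_ws("malformed window '%s': need numeric c(lo, hi) with lo <= hi",
              nm, class = "whalescreen_config_error")
    }
    if (!nm %in% names(profile)) {
      stop_ws("window '%s' has no matching profile column", nm,
              class = "whalescreen_config_error")
    }
  }
  out <- data.frame(molecule_id = profile$molecule_id,
                    stringsAsFactors = FALSE)
  pass_all <- rep(TRUE, nrow(profile))
  for (nm in names(windows)) {
    w <- windows[[nm]]
    p <- profile[[nm]] >= w[1] & profile[[nm]] <= w[2]
    out[[paste0("pass_", nm)]] <- p
    pass_all <- pass_all & p
  }
  out$pass_all <- pass_all
  out
}
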