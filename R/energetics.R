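#' MM/GBSA component bookkeeping
#'
#' End-point MM/GBSA binding free energies decompose into a gas-phase
#' electrostatic term, a gas-phase van der Waals term, and polar plus
#' nonpolar solvation terms:
#' \deqn{\Delta G_{calc} = \Delta E_{ele} + \Delta E_{vdW} +
#'       \Delta G_{pol} + \Delta G_{nonpol}}
#' This module combines and validates exported component tables; it does
#' not run simulations or solvation models.
#'
#' @param components Data frame with columns `system_id`, `e_ele`,
#'   `e_vdw`, `g_pol`, `g_nonpol` (kcal/mol); optional `sd`.
#' @return The input with a `g_total` column set to the exact component
#'   sum (kcal/mol), no re-scaling.
#' @export
combine_binding_energy <- function(components) {
  need <- c("e_ele", "e_vdw", "g_pol", "g_nonpol")
  missing <- setdiff(need, names(components))
  if (length(missing)) {
    stop_ws("missing MM/GBSA component column(s): %s",
            paste(missing, collapse = ", "),
            class = "whalescreen_contract_error")
  }
  vals <- as.matrix(components[, need])
  if (!all(is.finite(vals))) {
    stop_ws("non-finite MM/GBSA component values",
            class = "whalescreen_contract_error")
  }
  components$g_total <- components$e_ele + components$e_vdw +
    components$g_pol + components$g_nonpol
  components
}

#' Validate a claimed-total MM/GBSA component table
#'
#' Recomputes the component sum for every row of a CSV (or data frame)
#' that carries a `claimed_total` column and flags rows whose recomputed
#' total deviates from the claim by more than `tolerance` (default 0.02
#' kcal/mol, which absorbs rounding of components printed to two
#' decimals).
#'
#' @param x Path to a CSV with columns `system_id`, `e_ele`, `e_vdw`,
#'   `g_pol`, `g_nonpol`, `claimed_total` (optional `sd`), or an
#'   equivalent data frame.
#' @param tolerance Allowed absolute deviation in kcal/mol.
#' @return Data frame with `system_id`, recomputed `g_total`,
#'   `claimed_total`, `residual` (g_total - claimed) and logical `ok`;
#'   attribute `n_failed`.
#' @export
validate_component_table <- function(x, tolerance = 0.02) {
  if (is.character(x)) {
    if (!file.exists(x)) {
      stop_ws("no such component table: '%s'", x,
              class = "whalescreen_io_error")
    }
    x <- tryCatch(utils::read.csv(x, stringsAsFactors = FALSE),
                  error = function(e) {
                    stop_ws("malformed component CSV: %s",
                            conditionMessage(e),
                            class = "whalescreen_io_error")
                  })
  }
  if (!nrow(x)) {
    warning("empty component table; nothing to validate", call. = FALSE)
    out <- data.frame(system_id = character(0), g_total = numeric(0),
                      claimed_total = numeric(0), residual = numeric(0),
                      ok = logical(0))
    attr(out, "n_failed") <- 0L
    return(out)
  }
  bad <- which(!vapply(c("e_ele", "e_vdw", "g_pol", "g_nonpol"), function(cn) {
    cn %in% names(x) && all(is.finite(suppressWarnings(as.numeric(x[[cn]]))))
  }, logical(1)))
  if (length(bad)) {
    stop_ws("component table parse error: bad or missing column(s) %s",
            paste(c("e_ele", "e_vdw", "g_pol", "g_nonpol")[bad],
                  collapse = ", "),
            class = "whalescreen_io_error")
  }
  combined <- combine_binding_energy(x)
  claimed <- if ("claimed_total" %in% names(x)) as.numeric(x$claimed_total)
             else rep(NA_real_, nrow(x))
  residual <- combined$g_total - claimed
  out <- data.frame(system_id = as.character(x$system_id),
                    g_total = combined$g_total,
                    claimed_total = claimed,
                    residual = residual,
                    ok = is.na(residual) | abs(residual) <= tolerance,
                    stringsAsFactors = FALSE)
  attr(out, "n_failed") <- sum(!out$ok)
  out
}

#' Built-in MM/GBSA component table for six hDAT complexes
#'
#' Returns the path of the packaged component table for six
#' ligand-transporter complexes (three reference atypical inhibitors of
#' the human dopamine transporter and three repurposed local-anesthetic
#' actives), with per-system electrostatic, van der Waals, polar and
#' nonpolar terms, the published totals and their standard deviations, and
#' dopamine-uptake IC50 values in nM.
#'
#' @return File path of the CSV.
#' @export
hdat_gbsa_table <- function() {
  system.file("extdata", "hdat_mmgbsa_components.csv",
              package = "whalescreen", mustWork = TRUE)
}
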