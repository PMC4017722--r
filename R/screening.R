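#' Triage a virtual-screening table
#'
#' Applies the post-docking triage criteria to a screening table: an
#' estimated-activity ceiling (keep compounds predicted more potent than a
#' cutoff) and/or a docking-energy floor (keep compounds whose interaction
#' energy with the receptor exceeds a reference, typically the redocked
#' energy of a known inhibitor). Both inequalities are strict, matching the
#' study convention; a record on the boundary is excluded. At least one
#' criterion must be set. Input row order is preserved.
#'
#' @param records Screening tibble with columns `est_ic50_nM` and/or
#'   `energy_kcal_mol` as needed by the criteria set.
#' @param max_est_ic50_nM Keep records with `est_ic50_nM` strictly below this
#'   (nM), or `NULL` to skip.
#' @param min_energy_kcal_mol Keep records with `energy_kcal_mol` strictly
#'   above this (kcal/mol), or `NULL` to skip. The reference energy is an
#'   input, not a constant: it comes from an external redocking run.
#' @return The retained records, a tibble; empty is a valid result.
#' @examples
#' screen <- load_fixture("table3")
#' nrow(filter_screening(screen, min_energy_kcal_mol = 37.786))   # 21
#' nrow(filter_screening(screen, min_energy_kcal_mol = 50))       # 11
#' @export
filter_screening <- function(records, max_est_ic50_nM = NULL,
                             min_energy_kcal_mol = NULL) {
  if (is.null(max_est_ic50_nM) && is.null(min_energy_kcal_mol)) {
    abort("at least one filter criterion must be set",
          class = "qsarfuse_argument_error")
  }
  keep <- rep(TRUE, nrow(records))
  if (!is.null(max_est_ic50_nM)) {
    keep <- keep & records$est_ic50_nM < max_est_ic50_nM
  }
  if (!is.null(min_energy_kcal_mol)) {
    keep <- keep & records$energy_kcal_mol > min_energy_kcal_mol
  }
  records[keep, , drop = FALSE]
}

#' Top candidates of a screening table
#'
#' Ranks screening records by docking energy (descending: stronger predicted
#' binding first) or by estimated IC50 (ascending: more potent first) and
#' returns the best `k`. Ties break by compound id; `k` larger than the
#' table returns everything.
#'
#' @param records Screening tibble.
#' @param k Number of records to return (`k >= 0`).
#' @param key `"energy"` (default) or `"est_ic50"`.
#' @return A tibble of at most `k` rows.
#' @examples
#' top_hits(load_fixture("table3"), 2)   # NSC 136954, NSC 70804
#' @export
top_hits <- function(records, k, key = c("energy", "est_ic50")) {
  key <- match.arg(key)
  if (k < 0) abort("k must be non-negative", class = "qsarfuse_argument_error")
  ord <- if (key == "energy") {
    order(-records$energy_kcal_mol, records$id, method = "radix")
  } else {
    order(records$est_ic50_nM, records$id, method = "radix")
  }
  records[head(ord, k), , drop = FALSE]
}
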