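#' Run the full fusion-and-triage pipeline
#'
#' Executes, in order: training/testing split validation; per-system
#' evaluation on the training set; selection of the well-performing systems;
#' per-system evaluation on the testing set; all pairwise diversity
#' profiles; the exhaustive score-combination leaderboard; and, when a
#' screening table and thresholds are given, the virtual-screening triage
#' filters with top-k reporting.
#'
#' Because the two convention-silent choices that change every number are the
#' activity scale and the combination rule, both are logged prominently in
#' the run log.
#'
#' @param train,test Wide activity tables (tibbles), packaged fixture names
#'   (`"table1"`, `"table2"`), or CSV paths.
#' @param screening Optional screening table, `"table3"`, or a CSV path.
#' @param system_parent Optional named character vector mapping each testing
#'   system label to the training system it derives from (e.g.
#'   `c(BB = "Best_train", ...)`). Testing systems whose parent is dropped
#'   by the selection rule are excluded from fusion; without a mapping,
#'   selection is reported for the training stage only and all testing
#'   systems are fused.
#' @param scale Activity scale for all correlations, `"log10"` or `"raw"`.
#' @param rule Score-combination rule, see [combine_scores()].
#' @param drop_fraction Selection threshold, see [select_systems()].
#' @param max_est_ic50_nM,min_energy_kcal_mol Triage thresholds, see
#'   [filter_screening()]; both `NULL` skips the screening stage's filter.
#' @param top_k How many top screening hits to report (by energy).
#' @param out_dir Optional directory; when given, every stage's result is
#'   written as CSV alongside a plain-text run log.
#' @return A `fusion_report` list with elements `split`, `performance_train`,
#'   `selected`, `performance_test`, `profiles`, `leaderboard`, `screening`
#'   (filtered records and `top` hits, or `NULL`), and `log` (character).
#' @examples
#' rep <- run_pipeline("table1", "table2", screening = "table3",
#'                     min_energy_kcal_mol = 37.786)
#' glance(rep$leaderboard)
#' @export
run_pipeline <- function(train, test, screening = NULL,
                         system_parent = NULL,
                         scale = c("log10", "raw"),
                         rule = c("mean_log", "mean_raw"),
                         drop_fraction = 0.5,
                         max_est_ic50_nM = NULL,
                         min_energy_kcal_mol = NULL,
                         top_k = 2,
                         out_dir = NULL) {
  scale <- match.arg(scale)
  rule <- match.arg(rule)
  logline <- character(0)
  note <- function(...) logline <<- c(logline, sprintf(...))

  train <- resolve_table(train, "activity", note)
  test <- resolve_table(test, "activity", note)
  if (!is.null(screening)) {
    screening <- resolve_table(screening, "screening", note)
  }
  note("activity scale: %s | combination rule: %s", scale, rule)
  note("drop_fraction: %g | top_k: %d", drop_fraction, top_k)

  split <- validate_training_split(train, test)
  note("split: n_train=%d n_test=%d span=%.3f orders, %d rule(s) failed",
       split$n_train, split$n_test, split$span_orders,
       sum(!split$rule_flags))

  perf_train <- evaluate_systems(train, scale = scale)
  selected <- select_systems(perf_train, drop_fraction)
  note("training systems retained: %s (of %d)",
       paste(selected, collapse = ", "), nrow(perf_train))

  test_systems <- system_labels(test)
  if (!is.null(system_parent)) {
    known <- intersect(test_systems, names(system_parent))
    test_systems <- known[system_parent[known] %in% selected]
    note("testing systems after parent selection: %s",
         paste(test_systems, collapse = ", "))
  }
  perf_test <- evaluate_systems(test, systems = test_systems, scale = scale)

  profiles <- if (length(test_systems) >= 2) {
    all_pair_profiles(test, test_systems, scale = scale)
  } else NULL
  lb <- fusion_leaderboard(test, test_systems, rule = rule, scale = scale)
  note("leaderboard: %d combinations, best %s (r = %.3f)",
       nrow(lb), lb$label[1], lb$r_test[1])

  screen_out <- NULL
  if (!is.null(screening)) {
    filtered <- if (is.null(max_est_ic50_nM) && is.null(min_energy_kcal_mol)) {
      screening
    } else {
      filter_screening(screening, max_est_ic50_nM = max_est_ic50_nM,
                       min_energy_kcal_mol = min_energy_kcal_mol)
    }
    top <- top_hits(filtered, top_k, key = "energy")
    note("screening: %d of %d records retained; top hit %s (%.3f kcal/mol)",
         nrow(filtered), nrow(screening),
         if (nrow(top)) top$id[1] else "<none>",
         if (nrow(top)) top$energy_kcal_mol[1] else NA_real_)
    screen_out <- list(filtered = filtered, top = top)
  }

  report <- structure(
    list(split = split, performance_train = perf_train, selected = selected,
         performance_test = perf_test, profiles = profiles, leaderboard = lb,
         screening = screen_out, log = logline),
    class = "fusion_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# accept a tibble, a packaged fixture name, or a CSV path
resolve_table <- function(x, kind, note) {
  if (is.data.frame(x)) return(x)
  if (!is.character(x) || length(x) != 1) {
    abort("table must be a data frame, fixture name, or path",
          class = "qsarfuse_argument_error")
  }
  if (x %in% names(.fixture_md5)) {
    note("input %s: packaged fixture (md5 %s)", x, .fixture_md5[[x]])
    return(load_fixture(x))
  }
  if (!file.exists(x)) {
    abort(paste0("input path does not exist: ", x),
          class = "qsarfuse_io_error")
  }
  note("input %s (md5 %s)", x, unname(tools::md5sum(x)))
  if (kind == "screening") read_screening_table(x) else read_activity_table(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(report$split), file.path(out_dir, "split_report.csv"))
  readr::write_csv(report$performance_train,
                   file.path(out_dir, "performance_train.csv"))
  readr::write_csv(report$performance_test,
                   file.path(out_dir, "performance_test.csv"))
  readr::write_csv(tidy(report$leaderboard),
                   file.path(out_dir, "leaderboard.csv"))
  if (!is.null(report$profiles)) {
    readr::write_csv(report$profiles %>% select(!"profile"),
                     file.path(out_dir, "pair_diversity.csv"))
    gdir <- file.path(out_dir, "divgraphs")
    dir.create(gdir, showWarnings = FALSE)
    purrr::walk(report$profiles$profile, function(p) {
      pair <- attr(p, "pair")
      export_divgraph(p, file.path(gdir, paste0(pair[1], "_", pair[2], ".csv")))
    })
  }
  if (!is.null(report$screening)) {
    readr::write_csv(report$screening$filtered,
                     file.path(out_dir, "screening_filtered.csv"))
    readr::write_csv(report$screening$top,
                     file.path(out_dir, "screening_top.csv"))
  }
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.fusion_report <- function(x, ...) {
  cat("Combinatorial fusion pipeline report\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}

#' Export a diversity rank/score graph as CSV
#'
#' Writes the machine-readable form of a diversity rank/score graph: a
#' two-column CSV of rank (1..t) and the non-increasing diversity score.
#'
#' @param profile A [diversity_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_divgraph()] for the inverse.
#' @export
export_divgraph <- function(profile, path) {
  readr::write_csv(tibble(rank = profile$rank, score = profile$score), path)
  invisible(path)
}

#' @rdname export_divgraph
#' @export
read_divgraph <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE))
}
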