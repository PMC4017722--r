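#' Per-compound diversity score of a pair of prediction systems
#'
#' For a compound i and two scoring systems A and B, the diversity score
#' d_i(A, B) is the absolute difference between the two systems' estimated
#' activities for that compound, on the chosen scale. It measures how
#' distinctively the two systems score that compound; it is symmetric in
#' (A, B), non-negative, and zero exactly when the scores agree.
#'
#' @param data Wide activity table holding both system columns.
#' @param a,b System column names.
#' @param id Compound identifier(s); default all compounds in `data`.
#' @param scale `"log10"` (default) or `"raw"`.
#' @return Named numeric vector of diversity scores, one per id.
#' @examples
#' test <- load_fixture("table2")
#' diversity_score(test, "BB", "FF", id = "CHEMBL195177")
#' @export
diversity_score <- function(data, a, b, id = NULL,
                            scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  m <- eval_scale(data, c(a, b), scale)
  d <- setNames(abs(m[, 1] - m[, 2]), data$id)
  if (!is.null(id)) {
    missing_ids <- setdiff(id, data$id)
    if (length(missing_ids)) {
      abort(paste0("id(s) not present: ", paste(missing_ids, collapse = ", ")),
            class = "qsarfuse_coverage_error")
    }
    d <- d[id]
  }
  d
}

#' Diversity rank/score profile of a system pair
#'
#' Computes every compound's diversity score for the pair (A, B), then sorts
#' the scores into descending order. Re-indexing the sorted scores by rank
#' j = 1..t gives the diversity rank/score function f_(A,B)(j), whose plot is
#' the diversity rank/score graph; pairs whose curve lies higher are more
#' diverse, and hence better fusion candidates among similarly accurate
#' systems. The area under the curve (the sum of all diversity scores) is
#' kept as the scalar `aggregate` used to rank pairs.
#'
#' @inheritParams diversity_score
#' @return A `diversity_profile` tibble with columns `rank`, `id`, `score`
#'   (non-increasing in `rank`), and attributes `pair`, `scale`, `aggregate`.
#'   Ties in score are broken by id, lexicographically, so the profile is
#'   reproducible.
#' @examples
#' prof <- diversity_profile(load_fixture("table2"), "BB", "FF")
#' head(prof)
#' attr(prof, "aggregate")
#' @export
diversity_profile <- function(data, a, b, scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  d <- diversity_score(data, a, b, scale = scale)
  ord <- order(-d, names(d), method = "radix")
  out <- tibble(
    rank = seq_along(d),
    id = names(d)[ord],
    score = unname(d[ord])
  )
  structure(out,
            class = c("diversity_profile", class(out)),
            pair = c(a, b), scale = scale, aggregate = sum(d))
}

#' All pairwise diversity profiles
#'
#' Builds the diversity rank/score profile of every unordered pair among `q`
#' systems — q(q-1)/2 profiles — and returns them in one nested tibble
#' ordered lexicographically by pair labels, ready for pair ranking with
#' [recommend_pairs()] or plotting with [plot_divgraphs()].
#'
#' @param data Wide activity table.
#' @param systems Systems to pair; default all system columns.
#' @param scale `"log10"` (default) or `"raw"`.
#' @return A tibble with columns `system_a`, `system_b`, `aggregate` (sum of
#'   the pair's diversity scores) and list-column `profile` holding each
#'   [diversity_profile()].
#' @examples
#' profs <- all_pair_profiles(load_fixture("table2"))
#' nrow(profs)   # choose(6, 2) = 15
#' @export
all_pair_profiles <- function(data, systems = NULL,
                              scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  if (is.null(systems)) systems <- system_labels(data)
  if (length(systems) < 2) {
    abort("need at least 2 systems to form pairs",
          class = "qsarfuse_argument_error")
  }
  systems <- sort(systems)
  pairs <- utils::combn(systems, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    prof <- diversity_profile(data, pairs[1, k], pairs[2, k], scale = scale)
    tibble(system_a = pairs[1, k], system_b = pairs[2, k],
           aggregate = attr(prof, "aggregate"), profile = list(prof))
  })
}

#' Recommend the most diverse system pairs
#'
#' Ranks pairs by aggregate diversity (the area under the diversity
#' rank/score graph), descending; ties break lexicographically by pair
#' labels. Among systems of comparable individual accuracy, the most diverse
#' pairs are the preferred fusion candidates.
#'
#' @param profiles Output of [all_pair_profiles()].
#' @param k How many pairs to return.
#' @return The top `k` rows of `profiles`, ordered by `aggregate` descending.
#' @export
recommend_pairs <- function(profiles, k) {
  if (k > nrow(profiles)) {
    abort(paste0("k = ", k, " exceeds the ", nrow(profiles),
                 " available pairs"),
          class = "qsarfuse_argument_error")
  }
  profiles %>%
    arrange(desc(.data$aggregate), .data$system_a, .data$system_b) %>%
    head(k)
}

#' Enumerate all non-empty system combinations
#'
#' With m systems there are 2^m - 1 non-empty subsets, each a candidate
#' score combination. Enumeration order is deterministic: by subset size,
#' then lexicographically within a size.
#'
#' @param labels Distinct system labels.
#' @return A tibble with list-column `members`, `size`, and a `+`-joined
#'   `label`.
#' @examples
#' nrow(enumerate_combinations(c("BB", "FF", "FC")))   # 7
#' @export
enumerate_combinations <- function(labels) {
  if (length(labels) < 1) {
    abort("need at least one label", class = "qsarfuse_argument_error")
  }
  if (anyDuplicated(labels)) {
    abort("labels must be distinct", class = "qsarfuse_argument_error")
  }
  labels <- sort(labels)
  subsets <- purrr::map(seq_along(labels), function(k) {
    cmb <- utils::combn(labels, k, simplify = FALSE)
    cmb[order(vapply(cmb, paste, character(1), collapse = "+"))]
  })
  subsets <- purrr::flatten(subsets)
  tibble(
    members = subsets,
    size = lengths(subsets),
    label = vapply(subsets, paste, character(1), collapse = "+")
  )
}

#' Combine the scores of a subset of systems
#'
#' Forms a single consensus prediction from a subset of scoring systems.
#' The default rule, `"mean_log"`, averages the systems' log10 activities
#' and re-expresses the result as an activity in nM — i.e. the geometric
#' mean of the estimated IC50 values, the natural average for scores living
#' in log-activity space. `"mean_raw"` is the plain arithmetic mean of the
#' nM values. Combining a singleton returns that system's scores unchanged
#' under either rule.
#'
#' @param data Wide activity table holding the member columns.
#' @param members Character vector of system labels to combine.
#' @param rule `"mean_log"` (default) or `"mean_raw"`.
#' @return A tibble `id`, `combined_nM`, in the row order of `data`.
#' @examples
#' test <- load_fixture("table2")
#' combine_scores(test, c("BB", "FF"))   # geometric means
#' @export
combine_scores <- function(data, members, rule = c("mean_log", "mean_raw")) {
  rule <- match.arg(rule)
  missing_cols <- setdiff(members, names(data))
  if (length(missing_cols)) {
    abort(paste0("unknown system(s): ", paste(missing_cols, collapse = ", ")),
          class = "qsarfuse_lookup_error")
  }
  if (rule == "mean_log") {
    m <- eval_scale(data, members, "log10")
    combined <- 10^rowMeans(m)
  } else {
    m <- eval_scale(data, members, "raw")
    combined <- rowMeans(m)
  }
  tibble(id = data$id, combined_nM = unname(combined))
}

#' Evaluate every score combination: the fusion leaderboard
#'
#' Enumerates all 2^m - 1 non-empty subsets of the systems, combines each
#' subset's scores with [combine_scores()], and evaluates every combined
#' prediction against the experimental activities. Entries are sorted by
#' correlation descending (ties: smaller subset first, then
#' lexicographically); singleton entries equal the [evaluate_systems()]
#' results.
#'
#' @inheritParams evaluate_systems
#' @param rule Combination rule, see [combine_scores()].
#' @return A `fusion_leaderboard` tibble: `label`, `members` (list-column),
#'   `size`, `r_test`, `n`. `tidy()` returns the plain table, `glance()` a
#'   one-row summary with the winning combination.
#' @examples
#' lb <- fusion_leaderboard(load_fixture("table2"))
#' head(tidy(lb), 3)
#' glance(lb)
#' @export
fusion_leaderboard <- function(data, systems = NULL,
                               rule = c("mean_log", "mean_raw"),
                               scale = c("log10", "raw"),
                               truth = "ic50_nM") {
  rule <- match.arg(rule)
  scale <- match.arg(scale)
  if (is.null(systems)) systems <- system_labels(data, truth)
  combos <- enumerate_combinations(systems)
  y <- if (scale == "log10") to_log_activity(data[[truth]]) else data[[truth]]
  entries <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    members <- combos$members[[i]]
    pred <- combine_scores(data, members, rule = rule)$combined_nM
    x <- if (scale == "log10") to_log_activity(pred) else pred
    tibble(label = combos$label[i], members = list(members),
           size = combos$size[i], r_test = pearson_r(x, y), n = length(y))
  })
  out <- entries %>% arrange(desc(.data$r_test), .data$size, .data$label)
  structure(out,
            class = c("fusion_leaderboard", class(out)),
            rule = rule, scale = scale, m = length(systems))
}

#' @rdname fusion_leaderboard
#' @param x A `fusion_leaderboard`.
#' @param ... Unused.
#' @method tidy fusion_leaderboard
#' @export
tidy.fusion_leaderboard <- function(x, ...) {
  as_tibble(x) %>% select(!"members")
}

#' @rdname fusion_leaderboard
#' @method glance fusion_leaderboard
#' @export
glance.fusion_leaderboard <- function(x, ...) {
  singles <- x[x$size == 1, ]
  tibble(
    m = attr(x, "m"),
    n_combinations = nrow(x),
    rule = attr(x, "rule"),
    scale = attr(x, "scale"),
    best_label = x$label[1],
    best_r = x$r_test[1],
    best_single_r = max(singles$r_test),
    mean_combined_r = mean(x$r_test[x$size > 1])
  )
}

#' Select systems worth combining
#'
#' The first guiding rule of combinatorial fusion: only combine systems that
#' each perform relatively well. A system is retained when its correlation is
#' at least `drop_fraction` times the best system's correlation; systems far
#' below the best (e.g. a training correlation of 0.238 next to 0.955 and
#' 0.840) are dropped before any combination is formed.
#'
#' @param perfs Performance tibble from [evaluate_systems()] (columns
#'   `label`, `r`).
#' @param drop_fraction Retention threshold as a fraction of the maximum
#'   correlation, in (0, 1]; default 0.5.
#' @return Character vector of retained labels, in input order.
#' @examples
#' perf <- evaluate_systems(load_fixture("table1"))
#' select_systems(perf)   # drops Caesar_train
#' @export
select_systems <- function(perfs, drop_fraction = 0.5) {
  if (nrow(perfs) < 1) {
    abort("no performance entries", class = "qsarfuse_argument_error")
  }
  if (drop_fraction <= 0 || drop_fraction > 1) {
    abort("drop_fraction must be in (0, 1]", class = "qsarfuse_argument_error")
  }
  perfs$label[perfs$r >= drop_fraction * max(perfs$r)]
}
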