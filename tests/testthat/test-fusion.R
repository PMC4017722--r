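test_that("diversity score is the per-compound gap between two systems", {
  t2 <- load_fixture("table2")
  expect_equal(unname(diversity_score(t2, "BB", "FF", id = "CHEMBL195177")),
               abs(log10(3.9) - log10(6.2)), tolerance = 1e-12)
  expect_equal(unname(diversity_score(t2, "BB", "FF", id = "CHEMBL195177",
                                      scale = "raw")),
               2.3, tolerance = 1e-12)
  expect_equal(unname(diversity_score(t2, "BB", "BB", id = "CHEMBL195177")), 0)
  expect_error(diversity_score(t2, "BB", "FF", id = "NOPE"),
               class = "qsarfuse_coverage_error")
  expect_error(diversity_score(t2, "BB", "XX"),
               class = "qsarfuse_coverage_error")
})

test_that("diversity scores are symmetric, non-negative, zero on self-pairs", {
  set.seed(21)
  for (rep in 1:10) {
    tbl <- toy_study(n = 8, m = 3, seed = 300 + rep, noise = runif(1, 0.1, 1))
    for (scale in c("log10", "raw")) {
      dab <- diversity_score(tbl, "S1", "S2", scale = scale)
      dba <- diversity_score(tbl, "S2", "S1", scale = scale)
      expect_equal(dab, dba, tolerance = 1e-14)
      expect_true(all(dab >= 0))
      expect_equal(unname(diversity_score(tbl, "S3", "S3", scale = scale)),
                   rep(0, 8))
    }
  }
})

test_that("the rank/score function is the descending rearrangement", {
  t2 <- load_fixture("table2")
  prof <- diversity_profile(t2, "BB", "FF")
  expect_equal(nrow(prof), 133)
  expect_equal(prof$rank, 1:133)
  expect_true(all(diff(prof$score) <= 0))
  expect_equal(attr(prof, "aggregate"), sum(prof$score), tolerance = 1e-12)
  expect_setequal(prof$id, t2$id)

  # profile is a rearrangement of the unsorted scores
  d <- diversity_score(t2, "BB", "FF")
  expect_equal(sort(prof$score), sort(unname(d)), tolerance = 0)

  # two systems differing on exactly one compound
  tbl <- toy_study(n = 6, m = 1, seed = 31)
  tbl$S2 <- tbl$S1
  tbl$S2[4] <- tbl$S2[4] * 10
  p <- diversity_profile(tbl, "S1", "S2")
  expect_equal(p$score, c(1, rep(0, 5)), tolerance = 1e-12)
  expect_equal(p$id[1], tbl$id[4])

  # self-pair: all zero
  p0 <- diversity_profile(tbl, "S1", "S1")
  expect_equal(p0$score, rep(0, 6))
  expect_equal(attr(p0, "aggregate"), 0)
})

test_that("pair and combination counts match brute-force enumeration", {
  for (q in 2:10) {
    tbl <- toy_study(n = 4, m = q, seed = 40 + q)
    profs <- all_pair_profiles(tbl)
    # brute-force pair count by nested loops
    cnt <- 0
    for (i in 1:(q - 1)) for (j in (i + 1):q) cnt <- cnt + 1
    expect_equal(nrow(profs), cnt)
    expect_equal(cnt, q * (q - 1) / 2)
  }
  for (m in 1:10) {
    labels <- paste0("S", 1:m)
    combos <- enumerate_combinations(labels)
    brute <- brute_subsets(labels)
    expect_equal(nrow(combos), length(brute))
    expect_setequal(combos$label,
                    vapply(brute, function(s) paste(sort(s), collapse = "+"),
                           character(1)))
  }
  expect_equal(nrow(enumerate_combinations("A")), 1)
  expect_error(enumerate_combinations(c("A", "A")),
               class = "qsarfuse_argument_error")
  expect_error(all_pair_profiles(toy_study(m = 1)),
               class = "qsarfuse_argument_error")
})

test_that("score combination averages in log space by default", {
  t2 <- load_fixture("table2")
  comb <- combine_scores(t2, c("BB", "FF"))
  i <- match("CHEMBL195177", comb$id)
  expect_equal(comb$combined_nM[i], sqrt(3.9 * 6.2), tolerance = 1e-12)

  raw <- combine_scores(t2, c("BB", "FF"), rule = "mean_raw")
  expect_equal(raw$combined_nM[i], (3.9 + 6.2) / 2, tolerance = 1e-12)

  single <- combine_scores(t2, "BB")
  expect_equal(single$combined_nM, t2$BB, tolerance = 1e-12)

  expect_error(combine_scores(t2, c("BB", "ZZ")),
               class = "qsarfuse_lookup_error")
})

test_that("leaderboard agrees with an independent brute-force oracle", {
  for (m in 2:4) {
    tbl <- toy_study(n = 15, m = m, seed = 50 + m)
    lb <- fusion_leaderboard(tbl)
    oracle <- brute_leaderboard(tbl, paste0("S", 1:m))
    expect_equal(nrow(lb), 2^m - 1)
    expect_equal(unname(oracle[lb$label]), lb$r_test, tolerance = 1e-12)
  }
})

test_that("leaderboard ranks the study's six systems as published", {
  lb <- fusion_leaderboard(load_fixture("table2"))
  expect_equal(nrow(lb), 63)

  pairs <- lb[lb$size == 2, ]
  expect_equal(pairs$label[1], "BB+FF")
  expect_equal(pairs$r_test[1], 0.816, tolerance = 0.005)

  # singleton entries equal the per-system evaluation
  perf <- evaluate_systems(load_fixture("table2"))
  singles <- lb[lb$size == 1, ]
  expect_equal(singles$r_test[match(perf$label, singles$label)], perf$r,
               tolerance = 1e-12)

  # combinations beat the individual systems on average
  g <- glance(lb)
  expect_true(g$mean_combined_r > mean(perf$r))
})

test_that("combining two identical systems changes nothing", {
  tbl <- toy_study(n = 10, m = 1, seed = 61)
  tbl$S2 <- tbl$S1
  lb <- fusion_leaderboard(tbl)
  r_single <- lb$r_test[lb$label == "S1"]
  expect_equal(lb$r_test[lb$label == "S1+S2"], r_single, tolerance = 1e-14)
})

test_that("system selection keeps the relatively accurate systems", {
  perfs <- tibble::tibble(label = c("Best", "Fast", "Caesar"),
                          r = c(0.955, 0.840, 0.238))
  expect_equal(select_systems(perfs), c("Best", "Fast"))
  expect_equal(select_systems(perfs, drop_fraction = 1), "Best")

  equal <- tibble::tibble(label = c("A", "B"), r = c(0.5, 0.5))
  expect_equal(select_systems(equal), c("A", "B"))
  expect_equal(select_systems(equal, drop_fraction = 1), c("A", "B"))
  expect_error(select_systems(perfs[0, ]), class = "qsarfuse_argument_error")
  expect_error(select_systems(perfs, drop_fraction = 0),
               class = "qsarfuse_argument_error")
})

test_that("pair recommendation follows aggregate diversity", {
  t2 <- load_fixture("table2")
  profs <- all_pair_profiles(t2)
  top <- recommend_pairs(profs, nrow(profs))
  expect_true(all(diff(top$aggregate) <= 0))
  expect_equal(recommend_pairs(profs, 1)$aggregate, max(profs$aggregate))
  expect_error(recommend_pairs(profs, 16), class = "qsarfuse_argument_error")

  # the low-diversity pairs called out in the study rank below the
  # high-diversity ones
  agg <- function(a, b) {
    profs$aggregate[profs$system_a == a & profs$system_b == b]
  }
  low <- c(agg("BB", "BC"), agg("BB", "BF"))
  high <- c(agg("BB", "FF"), agg("BB", "FC"), agg("BF", "FF"))
  expect_true(max(low) < min(high))
})
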