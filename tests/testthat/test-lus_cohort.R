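test_that("total score is the linear map of zone grades onto 0-100", {
  expect_equal(total_score(rep(0, 12)), 0)
  expect_equal(total_score(rep(3, 12)), 100)
  expect_equal(total_score(c(3, rep(0, 11))), 100 / 12)
  # monotone in every zone
  base <- rep(1, 12)
  for (z in 1:12) {
    up <- base; up[z] <- 2
    expect_gt(total_score(up), total_score(base))
  }
  expect_error(lus_exam(rep(1, 11)), "12")
  expect_error(lus_exam(c(rep(1, 11), 5)), "grades")
})

test_that("simulated cohorts honor group sizes, labels and the score scale", {
  cohort <- simulate_cohort(lus_group_specs("s"), seed = 1)
  expect_s3_class(cohort, "lus_cohort")
  expect_equal(nrow(cohort), 132)
  expect_equal(sum(cohort$group_s == "S1"), 74)
  expect_equal(sum(cohort$group_s == "S2"), 58)
  expect_true(all(is.na(cohort$group_w)))
  expect_true(all(cohort$total_score >= 0 & cohort$total_score <= 100))
  # stored total is exactly the aggregate of the stored zone grades
  zones <- as.matrix(cohort[paste0("zone_", 1:12)])
  expect_equal(cohort$total_score, 100 * rowSums(zones) / 36, tolerance = 1e-9)
  expect_true(all(zones >= 0 & zones <= 3))
  # reproducibility
  expect_identical(cohort, simulate_cohort(lus_group_specs("s"), seed = 1))
})

test_that("degenerate spread collapses scores onto the group mean", {
  spec <- data.frame(stratum = "w", label = "W1", n = 20L, mean = 50, sd = 1e-6)
  cohort <- simulate_cohort(spec, seed = 2)
  expect_true(all(abs(cohort$total_score - 50) < 1e-3))
})

test_that("cohort simulation rejects invalid specifications", {
  expect_error(simulate_cohort(data.frame(), 1), "nonempty")
  bad_n <- data.frame(stratum = "s", label = "S1", n = 1L, mean = 40, sd = 7)
  expect_error(simulate_cohort(bad_n), "n >= 2")
  bad_sd <- data.frame(stratum = "s", label = "S1", n = 5L, mean = 40, sd = 0)
  expect_error(simulate_cohort(bad_sd), "sd > 0")
})

test_that("group proportions reproduce two-decimal table arithmetic", {
  cohort <- simulate_cohort(lus_group_specs("s"), seed = 3)
  expect_equal(unname(group_proportions(cohort, "s")), c(56.06, 43.94))
  one <- data.frame(group_s = rep("S1", 7), total_score = runif(7, 10, 90))
  expect_equal(unname(group_proportions(one, "s")), 100)
  four <- data.frame(group_p = rep(c("P1", "P2"), c(1, 3)),
                     total_score = c(10, 20, 30, 40))
  expect_equal(unname(group_proportions(four, "p")), c(25, 75))
  expect_error(group_proportions(cohort, "w"), "stratum")
})

test_that("proportion audit flags internally inconsistent printed rows", {
  ref <- ipn_reference_counts()
  gender <- audit_proportions(ref$n[ref$variable == "sex"],
                              ref$printed_pct[ref$variable == "sex"])
  expect_true(all(gender$consistent))
  mat_age <- audit_proportions(ref$n[ref$variable == "maternal_age"],
                               ref$printed_pct[ref$variable == "maternal_age"])
  expect_false(all(mat_age$consistent))  # 57/132 is not 46.28%
  age <- audit_proportions(ref$n[ref$variable == "age_days"],
                           ref$printed_pct[ref$variable == "age_days"])
  expect_false(all(age$consistent))  # 70/132 is not 53.22%
})

test_that("two-group comparison is a two-sided Welch test", {
  # permutations of the same multiset: t = 0, p = 1
  x <- c(3, 1, 4, 1, 5); y <- rev(x)
  cohort <- data.frame(group_s = rep(c("S1", "S2"), each = 5),
                       total_score = c(x, y))
  cmp <- compare_groups(cohort, "s")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  # hand-computed Welch example: means 3 vs 4, se = 1
  cohort2 <- data.frame(group_s = rep(c("S1", "S2"), each = 5),
                        total_score = c(1:5, 2:6))
  cmp2 <- compare_groups(cohort2, "s")
  expect_equal(cmp2$statistic, -1)
  expect_equal(cmp2$p_value, 0.3466, tolerance = 1e-3)
  expect_equal(cmp2$groups$mean, c(3, 4))
  # degenerate: zero variance in every group
  flat <- data.frame(group_s = rep(c("S1", "S2"), each = 3),
                     total_score = rep(c(1, 2), each = 3))
  expect_error(compare_groups(flat, "s"), "degenerate")
})

test_that("three-group comparison runs ANOVA plus Bonferroni pairwise Welch", {
  cohort <- simulate_cohort(lus_group_specs("w"), seed = 4)
  cmp <- compare_groups(cohort, "w")
  expect_match(cmp$test_name, "ANOVA")
  expect_true(is.finite(cmp$statistic))
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_equal(nrow(cmp$pairwise), 3)
  # the pairwise table agrees with a direct Bonferroni-adjusted Welch test
  w2 <- cohort$total_score[cohort$group_w == "W2"]
  w3 <- cohort$total_score[cohort$group_w == "W3"]
  direct <- min(1, 3 * t.test(w2, w3)$p.value)
  got <- cmp$pairwise$p_adj[cmp$pairwise$group1 == "W3" &
                            cmp$pairwise$group2 == "W2"]
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("group summaries partition the cohort and report table-style rounding", {
  cohort <- simulate_cohort(lus_group_specs("p"), seed = 5)
  tab <- summarize_groups(cohort)
  expect_equal(tab$label, c("P1", "P2"))
  expect_equal(sum(tab$n), nrow(cohort))
  expect_equal(tab$proportion, c(62.88, 37.12))
  # singleton group: SD is a not-available marker
  tiny <- data.frame(group_s = c("S1", "S2", "S2"),
                     total_score = c(10, 20, 30))
  tt <- summarize_groups(tiny)
  expect_true(is.na(tt$sd[tt$label == "S1"]))
  expect_false(is.na(tt$sd[tt$label == "S2"]))
})

test_that("cohorts round-trip through the CSV schema", {
  cohort <- simulate_cohort(lus_group_specs("w"), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$total_score, cohort$total_score, tolerance = 1e-12)
  expect_equal(back$group_w, cohort$group_w)
  expect_equal(names(back), names(as.data.frame(cohort)))
})
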