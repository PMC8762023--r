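test_that("the control cut-off reproduces mean + 3 SD with truncation to 0.1%", {
  res <- cutoff_from_summary(0.010, 0.0058, n = 163)
  expect_equal(res$cutoff_raw, 0.0274)
  expect_equal(res$cutoff_applied, 0.027)
  raw <- cutoff_from_summary(0.010, 0.0058, n = 163, round_cutoff = FALSE)
  expect_equal(raw$cutoff_applied, 0.0274)
  # zero-variance controls
  const <- westgard_cutoff(rep(0.01, 100))
  expect_equal(const$control_sd, 0)
  expect_equal(const$cutoff_applied, 0.01)
  expect_error(westgard_cutoff(0.01),
               class = "vafscreen_insufficient_data_error")
})

test_that("cut-off moments match an independent two-pass oracle", {
  withr::with_seed(12, {
    x <- runif(1000, 0, 0.05)
    res <- westgard_cutoff(x, round_cutoff = FALSE)
    oracle <- mean_sd_oracle(x)
    expect_equal(res$control_mean, unname(oracle["mean"]), tolerance = 1e-12)
    expect_equal(res$control_sd, unname(oracle["sd"]), tolerance = 1e-12)
    expect_equal(res$cutoff_raw,
                 unname(oracle["mean"] + 3 * oracle["sd"]), tolerance = 1e-12)
  })
})

test_that("the cut-off is weakly monotone in every control value", {
  withr::with_seed(13, {
    x <- runif(50, 0, 0.03)
    base <- westgard_cutoff(x, round_cutoff = FALSE)$cutoff_raw
    for (i in sample(50, 10)) {
      y <- x
      y[i] <- min(y[i] + 0.02, 1)
      expect_gte(westgard_cutoff(y, round_cutoff = FALSE)$cutoff_raw, base)
    }
  })
})

test_that("boundary semantics: strict above-cutoff by default, inclusive on request", {
  cut <- cutoff_from_summary(0.010, 0.0058)
  expect_true(classify_above_cutoff(0.053, cut))
  expect_false(classify_above_cutoff(0.027, cut, strict = TRUE))
  expect_true(classify_above_cutoff(0.027, cut, strict = FALSE))
  expect_equal(classify_above_cutoff(c(0.02, 0.03), 0.027), c(FALSE, TRUE))
})

test_that("contingency tables count carriers by case status", {
  groups <- c(rep("SLE", 101), rep("HC", 6), rep("family_non_SLE", 157))
  above <- c(rep(TRUE, 17), rep(FALSE, 84), rep(FALSE, 163))
  tab <- build_contingency(groups, above)
  expect_equal(unname(tab), matrix(c(17, 84, 0, 163), 2, byrow = TRUE))
  expect_equal(sum(tab), 264)
  empty <- build_contingency(character(), logical())
  expect_equal(unname(empty), matrix(0L, 2, 2))
  expect_error(build_contingency("SLE", c(TRUE, FALSE)),
               class = "vafscreen_input_error")
})

test_that("the exact test reproduces frozen enumeration values", {
  expect_equal(fisher_exact_2x2(c(1, 9, 11, 3)), 0.002759456,
               tolerance = 1e-6)
  expect_lt(fisher_exact_2x2(c(17, 84, 0, 163)), 1e-4)
  expect_lt(fisher_exact_2x2(c(37, 43, 14, 73)), 1e-4)
  expect_equal(fisher_exact_2x2(c(0, 5, 0, 7)), 1)
  expect_warning(p0 <- fisher_exact_2x2(c(0, 0, 0, 0)))
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)),
               class = "vafscreen_input_error")
})

test_that("the exact test equals the literal enumeration oracle and R's reference", {
  withr::with_seed(17, {
    for (i in 1:200) {
      x <- as.integer(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
      p <- fisher_exact_2x2(x)
      expect_equal(p, fisher_oracle(x[1], x[2], x[3], x[4]),
                   tolerance = 1e-10)
      expect_equal(p, fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-7)
      # invariance under simultaneous row and column swaps; p <= 1
      expect_equal(p, fisher_exact_2x2(c(x[4], x[3], x[2], x[1])),
                   tolerance = 1e-12)
      expect_lte(p, 1)
      expect_gt(p, 0)
    }
  })
})

test_that("family de-duplication keeps one member per group per family", {
  roster <- simulate_cohort(sim_config_cohort1(seed = 4))
  unrelated <- dedup_unrelated(roster)
  expect_equal(sum(unrelated$group == "SLE"), 86)       # 24 sporadic + 62 indices
  expect_equal(sum(unrelated$group != "SLE"), 68)       # 6 HC + 62 relatives
  expect_equal(2 * sum(unrelated$group == "SLE"), 172)  # allele denominator
  expect_equal(2 * sum(unrelated$group != "SLE"), 136)
  # one SLE and one non-SLE member per family, smallest ID kept
  fam <- unrelated[!is.na(unrelated$family_id), ]
  per <- dplyr::count(fam, family_id, group)
  expect_true(all(per$n == 1))
  f1 <- roster[which(roster$family_id == "F1" & roster$group == "SLE"), ]
  expect_true(min(f1$individual_id) %in% unrelated$individual_id)
  expect_setequal(c(unrelated$individual_id, attr(unrelated, "excluded")),
                  roster$individual_id)
})

test_that("de-duplication is the identity on an all-sporadic cohort", {
  roster <- simulate_cohort(sim_config_cohort2(seed = 4))
  unrelated <- dedup_unrelated(roster)
  expect_equal(nrow(unrelated), nrow(roster))
  expect_length(attr(unrelated, "excluded"), 0)
})

test_that("the unrelated denominator depends only on sporadic and family counts", {
  base <- sim_config_cohort1(seed = 5)
  fams <- cohort1_families()
  fams$n_unaffected <- rev(fams$n_unaffected)   # different sizes, same counts
  alt <- sim_config(n_sporadic = 24, n_hc = 6, families = fams,
                    n_somatic_carriers = 17L, seed = 5)
  n1 <- table(dedup_unrelated(simulate_cohort(base))$group == "SLE")
  n2 <- table(dedup_unrelated(simulate_cohort(alt))$group == "SLE")
  expect_equal(n1, n2)
})

test_that("family-deduplicated allele frequencies match the published ratios", {
  roster <- simulate_cohort(sim_config_cohort1(seed = 6))
  unrelated <- dedup_unrelated(roster)
  f7 <- sort(roster$individual_id[roster$family_id == "F7" &
                                    roster$group == "SLE"])
  # three heterozygous patient carriers, two from the same family
  carriers <- tibble::tibble(individual_id = c("S10", f7[1], f7[2]),
                             zygosity = "germline_het")
  res <- allele_frequency(carriers, unrelated, "SLE", "A410T")
  expect_equal(res$unrelated_carriers, 2)
  expect_equal(res$allele_count, 2)
  expect_equal(res$denominator, 172)
  expect_equal(res$frequency, 2 / 172)
  expect_equal(res$excluded_duplicates[[1]], f7[2])
  # single carrier
  res2 <- allele_frequency(
    tibble::tibble(individual_id = "S3", zygosity = "germline_het"),
    unrelated, "SLE", "A644C")
  expect_equal(res2$frequency, 1 / 172)
  # no carriers; homozygote counts two alleles; unknown carrier errors
  res3 <- allele_frequency(
    tibble::tibble(individual_id = character(), zygosity = character()),
    unrelated, "SLE")
  expect_equal(res3$frequency, 0)
  res4 <- allele_frequency(
    tibble::tibble(individual_id = "S3", zygosity = "germline_hom"),
    unrelated, "SLE")
  expect_equal(res4$allele_count, 2)
  expect_error(allele_frequency(
    tibble::tibble(individual_id = "GHOST", zygosity = "germline_het"),
    unrelated, "SLE"), class = "vafscreen_input_error")
})

test_that("screen_locus chains frequency, cut-off, classification and exact test", {
  cfg <- sim_config_cohort1(seed = 9)
  roster <- simulate_cohort(cfg)
  counts <- simulate_read_counts(roster, glk_loci(), cfg)
  res <- screen_locus(counts, roster, "T635C")
  expect_s3_class(res, "screen_result")
  expect_gte(res$table[1, 1], 17)        # all designated carriers detected
  expect_lt(res$p_value, 1e-4)
  expect_equal(sum(res$table), nrow(roster))
  g <- glance(res)
  expect_equal(g$cases_above, res$table[1, 1])
  expect_equal(nrow(tidy(res)), nrow(roster))
  expect_error(screen_locus(counts, roster, "NOPE"),
               class = "vafscreen_input_error")
})
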