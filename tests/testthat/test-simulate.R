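test_that("cohort generator reproduces the two study compositions", {
  roster1 <- simulate_cohort(sim_config_cohort1(seed = 11))
  counts1 <- table(roster1$group)
  expect_equal(unname(counts1["SLE"]), 101)
  expect_equal(unname(counts1["HC"]) + unname(counts1["family_non_SLE"]), 163)
  expect_equal(sum(!is.na(roster1$family_id)), 77 + 157)
  expect_equal(dplyr::n_distinct(roster1$family_id, na.rm = TRUE), 62)
  expect_false(anyDuplicated(roster1$individual_id) > 0)

  roster2 <- simulate_cohort(sim_config_cohort2(seed = 11))
  expect_equal(sum(roster2$group == "SLE"), 80)
  expect_equal(sum(roster2$group == "HC"), 87)
  expect_true(all(is.na(roster2$family_id)))
})

test_that("an all-zero configuration yields an empty roster with full schema", {
  cfg <- sim_config(n_sporadic = 0, n_hc = 0, families = 0,
                    n_somatic_carriers = 0L)
  roster <- simulate_cohort(cfg)
  expect_equal(nrow(roster), 0)
  expect_named(roster, c("individual_id", "group", "family_id", "sex", "age"))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_sporadic = -1), "n_sporadic",
               class = "vafscreen_config_error")
  expect_error(sim_config(depth_range = c(0, 10)), "depth_range",
               class = "vafscreen_config_error")
  expect_error(sim_config(control_error_mean = 1.5), "control_error_mean",
               class = "vafscreen_config_error")
  expect_error(sim_config(somatic_fraction_range = c(0.005, 0.05)),
               "somatic_fraction_range", class = "vafscreen_config_error")
  expect_error(
    sim_config(families = tibble::tibble(family_id = "F1", n_affected = 1,
                                         n_unaffected = 0)),
    "at least 2 members", class = "vafscreen_config_error")
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- quick_config(seed = 42)
  r1 <- simulate_cohort(cfg); r2 <- simulate_cohort(cfg)
  expect_identical(r1, r2)
  c1 <- simulate_read_counts(r1, glk_loci(), cfg)
  c2 <- simulate_read_counts(r2, glk_loci(), cfg)
  expect_identical(c1, c2)
  flags <- rep(FALSE, nrow(r1))
  expect_identical(simulate_clinical(r1, flags, cfg),
                   simulate_clinical(r1, flags, cfg))
})

test_that("read counts conserve the cohort and respect depth bounds", {
  cfg <- quick_config(seed = 3)
  roster <- simulate_cohort(cfg)
  counts <- simulate_read_counts(roster, glk_loci(), cfg)
  expect_equal(nrow(counts), nrow(roster) * nrow(glk_loci()))
  per_locus <- dplyr::count(counts, locus_id)
  expect_true(all(per_locus$n == nrow(roster)))
  expect_true(all(counts$alt_reads <= counts$depth))
  expect_true(all(counts$alt_reads >= 0))
  expect_true(all(counts$depth >= cfg$depth_range[1] &
                    counts$depth <= cfg$depth_range[2]))
})

test_that("control background calibration recovers the configured moments", {
  # many control individuals at one locus; empirical mean/SD of frequencies
  # must recover (0.010, 0.0058) within 3 standard errors
  n <- 12000
  cfg <- sim_config(n_sporadic = 0, n_hc = n, families = 0,
                    n_somatic_carriers = 0L, seed = 99)
  roster <- simulate_cohort(cfg)
  counts <- simulate_read_counts(roster, "T635C", cfg)
  freq <- counts$alt_reads / counts$depth
  se_mean <- 0.0058 / sqrt(n)
  se_sd <- 0.0058 / sqrt(2 * n)
  expect_lt(abs(mean(freq) - 0.010), 3 * se_mean)
  expect_lt(abs(sd(freq) - 0.0058), 3 * se_sd)
  # ~99.7% of control frequencies fall below the mean + 3 SD threshold
  below <- mean(freq < 0.0274)
  expect_gt(below, 0.99)
  expect_lt(below, 0.9999)
})

test_that("germline heterozygotes concentrate tightly around 50% frequency", {
  cfg <- sim_config(
    n_sporadic = 200, n_hc = 0, families = 0, n_somatic_carriers = 0L,
    germline_carriers = tibble::tibble(
      individual_id = sprintf("S%d", 1:200), locus_id = "A410T",
      zygosity = "het"),
    depth_range = c(100000L, 100000L), seed = 5)
  roster <- simulate_cohort(cfg)
  counts <- simulate_read_counts(roster, c("T635C", "A410T"), cfg)
  het <- counts[counts$locus_id == "A410T", ]
  freq <- het$alt_reads / het$depth
  expect_true(all(freq > 0.49 & freq < 0.51))
  # homozygote sits near 1
  cfg$germline_carriers$zygosity <- "hom"
  counts2 <- simulate_read_counts(roster, c("T635C", "A410T"), cfg)
  hom <- counts2[counts2$locus_id == "A410T", ]
  expect_true(all(hom$alt_reads / hom$depth > 0.95))
})

test_that("a zero background error rate with no carriers gives all-zero alt counts", {
  cfg <- sim_config(n_sporadic = 5, n_hc = 5, families = 0,
                    control_error_mean = 0, control_error_sd = 0,
                    n_somatic_carriers = 0L, seed = 2)
  roster <- simulate_cohort(cfg)
  counts <- simulate_read_counts(roster, glk_loci(), cfg)
  expect_true(all(counts$alt_reads == 0))
})

test_that("carrier designations referencing unknown individuals or loci error", {
  cfg <- quick_config(seed = 1)
  roster <- simulate_cohort(cfg)
  cfg$germline_carriers <- tibble::tibble(
    individual_id = "GHOST", locus_id = "T635C", zygosity = "het")
  expect_error(simulate_read_counts(roster, glk_loci(), cfg),
               "GHOST", class = "vafscreen_input_error")
  cfg$germline_carriers <- tibble::tibble(
    individual_id = roster$individual_id[1], locus_id = "NOPE",
    zygosity = "het")
  expect_error(simulate_read_counts(roster, glk_loci(), cfg),
               "NOPE", class = "vafscreen_input_error")
  expect_error(simulate_read_counts(roster[0, ], glk_loci(), cfg),
               class = "vafscreen_input_error")
})

test_that("clinical simulation shifts means in the configured directions", {
  cfg <- sim_config(n_sporadic = 2000, n_hc = 0, families = 0,
                    n_somatic_carriers = 0L, seed = 7)
  roster <- simulate_cohort(cfg)
  flags <- rep(c(TRUE, FALSE), length.out = nrow(roster))
  clin <- simulate_clinical(roster, flags, cfg)
  eff <- default_clinical_effects()
  for (i in seq_len(nrow(eff))) {
    p <- eff$parameter[i]
    diff <- mean(clin[[p]][clin$carrier]) - mean(clin[[p]][!clin$carrier])
    expect_equal(sign(diff), sign(eff$carrier_shift[i]),
                 info = paste("direction of", p))
  }
  # reported default signs: (+, -, -, -, -, -, +)
  expect_equal(sign(eff$carrier_shift), c(1, -1, -1, -1, -1, -1, 1))
})

test_that("zero clinical shift draws both groups from the same distribution", {
  eff <- default_clinical_effects()
  eff$carrier_shift <- 0
  cfg <- sim_config(n_sporadic = 3000, n_hc = 0, families = 0,
                    n_somatic_carriers = 0L, clinical_effects = eff, seed = 8)
  roster <- simulate_cohort(cfg)
  flags <- rep(c(TRUE, FALSE), length.out = nrow(roster))
  clin <- simulate_clinical(roster, flags, cfg)
  res <- two_sample_t(clin$anti_dsDNA[clin$carrier],
                      clin$anti_dsDNA[!clin$carrier])
  expect_gt(res$p_value, 0.001)
})
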