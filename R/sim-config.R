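#' Simulation configuration for synthetic screening cohorts
#'
#' Bundles every tunable of the synthetic-cohort generator: cohort composition
#' (sporadic patients, families, healthy controls), the sequencing depth range,
#' the control background-error distribution, somatic clone fractions, germline
#' carrier designations, and clinical covariate effects. The defaults emulate
#' the screening study's first cohort: 24 sporadic patients plus 62 families
#' (77 familial patients, 157 unaffected relatives) and 6 unrelated healthy
#' controls, sequenced to roughly 100,000-300,000 reads per locus, with a
#' control background read-error distribution of mean 1.0% and SD 0.58% at the
#' index 3'-UTR locus and somatic clone fractions of 2.7%-5.3%.
#'
#' @param n_sporadic Number of sporadic (non-familial) patients.
#' @param n_hc Number of unrelated healthy controls.
#' @param families Either a single count of families (sizes then drawn from
#'   `family_sizes`, one affected member each) or a data frame with columns
#'   `family_id`, `n_affected`, `n_unaffected` fixing the composition exactly.
#' @param family_sizes Named numeric vector: a probability distribution over
#'   total family sizes (names are sizes, all >= 2). Used only when `families`
#'   is a count.
#' @param depth_range Integer length-2 vector, inclusive range of per-locus
#'   sequencing depth in reads.
#' @param control_error_mean,control_error_sd Mean and SD (as fractions) of the
#'   realized background variant-read frequency in non-carriers. The generator
#'   moment-matches a zero-truncated normal so the simulated background
#'   reproduces these moments.
#' @param somatic_carrier_fraction Fraction of patients carrying a somatic
#'   clone at the index locus; ignored when `n_somatic_carriers` is given.
#' @param n_somatic_carriers Exact number of somatic-carrier patients at the
#'   index locus (`NULL` to draw by `somatic_carrier_fraction`).
#' @param somatic_fraction_range Length-2 fraction vector: uniform range of the
#'   somatic clone fraction added on top of background in carriers. Must lie
#'   strictly above `control_error_mean` and below 1.
#' @param germline_carriers Data frame (`individual_id`, `locus_id`,
#'   `zygosity`) designating germline carriers; zygosity is `"het"` or
#'   `"hom"`. May be empty.
#' @param clinical_effects Data frame (`parameter`, `baseline_mean`,
#'   `baseline_sd`, `carrier_shift`) controlling [simulate_clinical()]. The
#'   default shifts follow the reported directions: anti-dsDNA and SLEDAI up
#'   in high-fraction carriers; C3, C4, white cells, lymphocytes and platelets
#'   down.
#' @param age_median_sle,age_median_other Median ages (years) for patients and
#'   non-patients; ages are reporting-only.
#' @param female_fraction_sle Probability a patient is female (lupus is
#'   strongly female-biased).
#' @param seed Integer seed; all generator draws flow from it in documented
#'   order (cohort, then read counts at `seed + 1`, then clinical at
#'   `seed + 2`).
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()], [simulate_read_counts()], [simulate_clinical()]
#' @export
#' @examples
#' cfg <- sim_config(n_sporadic = 10, families = 5, n_hc = 10, seed = 1)
#' simulate_cohort(cfg)
sim_config <- function(n_sporadic = 24,
                       n_hc = 6,
                       families = cohort1_families(),
                       family_sizes = c(`3` = 0.3, `4` = 0.4, `5` = 0.3),
                       depth_range = c(100000L, 300000L),
                       control_error_mean = 0.010,
                       control_error_sd = 0.0058,
                       somatic_carrier_fraction = 17 / 101,
                       n_somatic_carriers = 17L,
                       somatic_fraction_range = c(0.027, 0.053),
                       germline_carriers = empty_germline_carriers(),
                       clinical_effects = default_clinical_effects(),
                       age_median_sle = 31,
                       age_median_other = 40,
                       female_fraction_sle = 0.9,
                       seed = 20260924L) {
  cfg <- structure(
    list(
      n_sporadic = as.integer(n_sporadic),
      n_hc = as.integer(n_hc),
      families = families,
      family_sizes = family_sizes,
      depth_range = as.integer(depth_range),
      control_error_mean = control_error_mean,
      control_error_sd = control_error_sd,
      somatic_carrier_fraction = somatic_carrier_fraction,
      n_somatic_carriers = if (is.null(n_somatic_carriers)) NULL else as.integer(n_somatic_carriers),
      somatic_fraction_range = somatic_fraction_range,
      germline_carriers = as_tibble(germline_carriers),
      clinical_effects = as_tibble(clinical_effects),
      age_median_sle = age_median_sle,
      age_median_other = age_median_other,
      female_fraction_sle = female_fraction_sle,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) vs_abort(sprintf("invalid sim_config field `%s`: %s", field, why),
                      "vafscreen_config_error")
  }
  chk(length(cfg$n_sporadic) == 1 && !is.na(cfg$n_sporadic) && cfg$n_sporadic >= 0,
      "n_sporadic", "must be a single non-negative count")
  chk(length(cfg$n_hc) == 1 && !is.na(cfg$n_hc) && cfg$n_hc >= 0,
      "n_hc", "must be a single non-negative count")
  if (is.data.frame(cfg$families)) {
    need <- c("family_id", "n_affected", "n_unaffected")
    chk(all(need %in% names(cfg$families)), "families",
        "data frame needs columns family_id, n_affected, n_unaffected")
    if (nrow(cfg$families)) {
      chk(all(cfg$families$n_affected + cfg$families$n_unaffected >= 2),
          "families", "every family must have at least 2 members")
      chk(!anyDuplicated(cfg$families$family_id), "families",
          "family_id must be unique")
    }
  } else {
    chk(length(cfg$families) == 1 && cfg$families >= 0, "families",
        "must be a count or a composition data frame")
    sizes <- as.integer(names(cfg$family_sizes))
    chk(length(cfg$family_sizes) > 0 && !anyNA(sizes) && all(sizes >= 2),
        "family_sizes", "names must be integer sizes >= 2")
    chk(all(cfg$family_sizes >= 0) && sum(cfg$family_sizes) > 0,
        "family_sizes", "probabilities must be non-negative and sum > 0")
  }
  chk(length(cfg$depth_range) == 2 && cfg$depth_range[1] >= 1 &&
        cfg$depth_range[2] >= cfg$depth_range[1],
      "depth_range", "lower bound must be >= 1 and range ordered")
  for (f in c("control_error_mean", "control_error_sd",
              "somatic_carrier_fraction")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
          cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be a fraction in [0, 1]")
  }
  chk(length(cfg$somatic_fraction_range) == 2 &&
        all(cfg$somatic_fraction_range <= 1) &&
        cfg$somatic_fraction_range[1] <= cfg$somatic_fraction_range[2] &&
        cfg$somatic_fraction_range[1] > cfg$control_error_mean,
      "somatic_fraction_range",
      "must lie within (control_error_mean, 1] and be ordered")
  need <- c("individual_id", "locus_id", "zygosity")
  chk(all(need %in% names(cfg$germline_carriers)), "germline_carriers",
      "needs columns individual_id, locus_id, zygosity")
  chk(all(cfg$germline_carriers$zygosity %in% c("het", "hom")),
      "germline_carriers", "zygosity must be 'het' or 'hom'")
  need <- c("parameter", "baseline_mean", "baseline_sd", "carrier_shift")
  chk(all(need %in% names(cfg$clinical_effects)), "clinical_effects",
      "needs columns parameter, baseline_mean, baseline_sd, carrier_shift")
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed",
      "must be a single integer")
  cfg
}

#' Family composition of the first screening cohort
#'
#' 62 families holding 77 affected members and 157 unaffected relatives in
#' total. Two families (F7 and F26, plus 13 others) carry two affected members
#' each, emulating the study's multi-case families; unaffected counts of 3 or
#' 2 per family are assigned deterministically to sum to 157.
#'
#' @return A tibble with columns `family_id`, `n_affected`, `n_unaffected`.
#' @export
cohort1_families <- function() {
  n_aff <- rep(1L, 62)
  n_aff[c(7L, 26L, 48:60)] <- 2L          # 15 two-case families -> 77 affected
  n_unaff <- c(rep(3L, 33), rep(2L, 29))  # -> 157 unaffected relatives
  tibble(
    family_id = sprintf("F%d", seq_len(62)),
    n_affected = n_aff,
    n_unaffected = n_unaff
  )
}

#' Configuration presets for the two screening cohorts
#'
#' `sim_config_cohort1()` is the family-based discovery cohort (101 patients =
#' 24 sporadic + 77 familial across 62 families; 163 non-patients = 6 healthy
#' controls + 157 relatives; 17 somatic carriers at the index locus).
#' `sim_config_cohort2()` is the all-sporadic replication cohort (80 patients,
#' 87 healthy controls, 37 patient carriers) where a fraction of controls also
#' carries low-level somatic clones, as seen in the older replication
#' population.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_cohort1 <- function(seed = 20260924L, ...) {
  sim_config(n_sporadic = 24, n_hc = 6, families = cohort1_families(),
             n_somatic_carriers = 17L, age_median_sle = 31,
             age_median_other = 40, seed = seed, ...)
}

#' @rdname sim_config_cohort1
#' @param n_somatic_carriers_hc Number of healthy-control somatic carriers.
#' @export
sim_config_cohort2 <- function(seed = 20260924L, n_somatic_carriers_hc = 14L, ...) {
  cfg <- sim_config(n_sporadic = 80, n_hc = 87, families = 0L,
                    n_somatic_carriers = 37L, age_median_sle = 43.5,
                    age_median_other = 42, seed = seed, ...)
  cfg$n_somatic_carriers_hc <- as.integer(n_somatic_carriers_hc)
  cfg
}

empty_germline_carriers <- function() {
  tibble(individual_id = character(), locus_id = character(),
         zygosity = character())
}

#' Default clinical covariate effects
#'
#' Baselines are typical lupus-clinic laboratory values; carrier shifts follow
#' the reported directions between low- and high-fraction carrier groups:
#' anti-dsDNA and SLEDAI higher in carriers, complement C3/C4, white blood
#' cells, lymphocytes and platelets lower. Shifts are 0.8 baseline SDs where
#' the comparison is reported significant, 0.5 SD for SLEDAI (reported as a
#' non-significant trend).
#'
#' @return A tibble with columns `parameter`, `baseline_mean`, `baseline_sd`,
#'   `carrier_shift`.
#' @export
default_clinical_effects <- function() {
  tibble(
    parameter = c("anti_dsDNA", "C3", "C4", "WBC", "lymphocytes",
                  "platelets", "SLEDAI"),
    baseline_mean = c(100, 90, 20, 6000, 1500, 240000, 6),
    baseline_sd = c(100, 25, 8, 1800, 550, 60000, 4),
    carrier_shift = c(80, -20, -6.4, -1440, -440, -48000, 2)
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Every [sim_config()] field is addressable by its argument name; `families`
#' and `germline_carriers`/`clinical_effects` may be given as lists of records.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    vs_abort(sprintf("config file not found: %s", path), "vafscreen_io_error")
  }
  raw <- yaml::read_yaml(path)
  for (f in c("families", "germline_carriers", "clinical_effects")) {
    if (!is.null(raw[[f]]) && is.list(raw[[f]]) && !is.data.frame(raw[[f]])) {
      raw[[f]] <- dplyr::bind_rows(lapply(raw[[f]], as_tibble))
    }
  }
  if (!is.null(raw$family_sizes)) raw$family_sizes <- unlist(raw$family_sizes)
  do.call(sim_config, raw)
}
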