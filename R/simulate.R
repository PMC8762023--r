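# All generator randomness is scoped: the caller's RNG state is saved and
# restored, so simulation is reproducible from the config seed alone.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Underlying normal parameters whose zero-truncated distribution has the
# requested mean and SD. Naive truncation of Normal(mean, sd) at zero inflates
# the realized mean (by ~5% of an SD for the default background), so the
# generator moment-matches instead: the requested moments are the moments of
# the background actually simulated.
truncnorm_params <- function(mean, sd) {
  if (sd <= 0) return(list(mu = mean, sigma = 0))
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    a <- -mu / sigma
    lam <- dnorm(a) / (1 - pnorm(a))
    m_t <- mu + sigma * lam
    v_t <- sigma^2 * (1 + a * lam - lam^2)
    (m_t - mean)^2 / mean^2 + (sqrt(v_t) - sd)^2 / sd^2
  }
  fit <- optim(c(mean, log(sd)), obj)
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Zero-truncated normal draws by rejection (acceptance > 90% for the
# background regimes of interest).
rtruncnorm0 <- function(n, mu, sigma) {
  if (sigma <= 0) return(rep(max(mu, 0), n))
  out <- rnorm(n, mu, sigma)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mu, sigma)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Generate a synthetic cohort roster
#'
#' Builds the roster of sporadic patients, families (affected members plus
#' unaffected relatives) and unrelated healthy controls described by the
#' configuration. IDs follow the study's convention: `S<k>` for sporadic
#' patients, `F<j>-<m>` for family members (affected members numbered first)
#' and `H<k>` for healthy controls.
#'
#' @param config A [sim_config()].
#' @param seed Seed override; defaults to `config$seed`.
#' @return A tibble with columns `individual_id`, `group` (`"SLE"`, `"HC"` or
#'   `"family_non_SLE"`), `family_id` (`NA` for non-familial individuals),
#'   `sex` (`"F"`/`"M"`) and `age` (years). Deterministic for a fixed seed.
#' @export
#' @examples
#' roster <- simulate_cohort(sim_config_cohort1(seed = 1))
#' dplyr::count(roster, group)
simulate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, {
    fams <- config$families
    if (!is.data.frame(fams)) {
      n_fam <- as.integer(fams)
      if (n_fam > 0) {
        sizes <- as.integer(names(config$family_sizes))
        drawn <- sizes[sample.int(length(sizes), n_fam, replace = TRUE,
                                  prob = config$family_sizes)]
        fams <- tibble(family_id = sprintf("F%d", seq_len(n_fam)),
                       n_affected = 1L, n_unaffected = drawn - 1L)
      } else {
        fams <- tibble(family_id = character(), n_affected = integer(),
                       n_unaffected = integer())
      }
    }
    sporadic <- tibble(
      individual_id = sprintf("S%d", seq_len(config$n_sporadic)),
      group = rep("SLE", config$n_sporadic),
      family_id = rep(NA_character_, config$n_sporadic)
    )
    familial <- purrr::pmap_dfr(fams, function(family_id, n_affected,
                                               n_unaffected) {
      n <- n_affected + n_unaffected
      tibble(
        individual_id = sprintf("%s-%02d", family_id, seq_len(n)),
        group = c(rep("SLE", n_affected), rep("family_non_SLE", n_unaffected)),
        family_id = family_id
      )
    })
    hc <- tibble(
      individual_id = sprintf("H%d", seq_len(config$n_hc)),
      group = rep("HC", config$n_hc),
      family_id = rep(NA_character_, config$n_hc)
    )
    roster <- bind_rows(sporadic, familial, hc)
    if (nrow(roster) == 0) {
      return(tibble(individual_id = character(), group = character(),
                    family_id = character(), sex = character(),
                    age = integer()))
    }
    p_f <- ifelse(roster$group == "SLE", config$female_fraction_sle, 0.5)
    med <- ifelse(roster$group == "SLE", config$age_median_sle,
                  config$age_median_other)
    roster$sex <- ifelse(runif(nrow(roster)) < p_f, "F", "M")
    roster$age <- as.integer(pmin(pmax(round(rnorm(nrow(roster), med, 12)),
                                       18), 85))
    roster
  })
}

#' Simulate a per-individual, per-locus read-count table
#'
#' For every individual x locus cell, depth is drawn uniformly from the
#' configured range and the alternate-read count binomially from the
#' individual's total alternate-read probability: a per-individual background
#' error rate (zero-truncated normal, moment-matched to the configured control
#' mean/SD), plus a somatic clone fraction for designated somatic carriers at
#' the index locus, or 0.5 for germline heterozygotes (1 minus background for
#' homozygotes). A zero background mean yields an error-free background.
#'
#' Somatic carriers at the index locus are chosen here: `n_somatic_carriers`
#' patients (or a `somatic_carrier_fraction` binomial draw), plus
#' `n_somatic_carriers_hc` healthy controls when the config sets it. The
#' designation and clone fractions are attached as the `"truth"` attribute.
#'
#' @param roster A roster from [simulate_cohort()] (non-empty).
#' @param loci Locus table with at least a `locus_id` column (see
#'   [glk_loci()]), or a character vector of locus IDs. The first locus is the
#'   index somatic locus.
#' @param config A [sim_config()].
#' @param seed Seed override; defaults to `config$seed + 1`.
#' @return A tibble with columns `individual_id`, `locus_id`, `depth`,
#'   `alt_reads`; every roster individual appears exactly once per locus and
#'   `alt_reads <= depth` always. Attribute `"truth"` holds the designated
#'   carriers (`individual_id`, `locus_id`, `type`, `fraction`).
#' @export
simulate_read_counts <- function(roster, loci, config,
                                 seed = config$seed + 1L) {
  validate_sim_config(config)
  if (nrow(roster) == 0) {
    vs_abort("roster is empty", "vafscreen_input_error")
  }
  locus_ids <- if (is.data.frame(loci)) loci$locus_id else as.character(loci)
  if (length(locus_ids) == 0) {
    vs_abort("no loci supplied", "vafscreen_input_error")
  }
  gl <- config$germline_carriers
  unknown_id <- setdiff(gl$individual_id, roster$individual_id)
  unknown_locus <- setdiff(gl$locus_id, locus_ids)
  if (length(unknown_id) || length(unknown_locus)) {
    vs_abort(sprintf(
      "germline carrier references unknown %s: %s",
      if (length(unknown_id)) "individual(s)" else "locus/loci",
      paste(c(unknown_id, unknown_locus), collapse = ", ")),
      "vafscreen_input_error")
  }

  with_seed(seed, {
    index_locus <- locus_ids[1]
    sle_ids <- roster$individual_id[roster$group == "SLE"]
    n_som <- if (!is.null(config$n_somatic_carriers)) {
      min(config$n_somatic_carriers, length(sle_ids))
    } else {
      rbinom(1, length(sle_ids), config$somatic_carrier_fraction)
    }
    som_ids <- if (n_som > 0) sample(sle_ids, n_som) else character()
    hc_ids <- roster$individual_id[roster$group == "HC"]
    n_som_hc <- min(config$n_somatic_carriers_hc %||% 0L, length(hc_ids))
    som_ids <- c(som_ids, if (n_som_hc > 0) sample(hc_ids, n_som_hc))
    somatic <- tibble(
      individual_id = som_ids,
      locus_id = rep(index_locus, length(som_ids)),
      type = rep("somatic", length(som_ids)),
      fraction = runif(length(som_ids), config$somatic_fraction_range[1],
                       config$somatic_fraction_range[2])
    )
    truth <- bind_rows(
      somatic,
      if (nrow(gl)) tibble(individual_id = gl$individual_id,
                           locus_id = gl$locus_id,
                           type = paste0("germline_", gl$zygosity),
                           fraction = NA_real_)
    )

    # per-individual background rate, shared across loci
    tp <- truncnorm_params(config$control_error_mean, config$control_error_sd)
    bg <- if (config$control_error_mean <= 0) {
      rep(0, nrow(roster))
    } else {
      rtruncnorm0(nrow(roster), tp$mu, tp$sigma)
    }
    names(bg) <- roster$individual_id

    cells <- tidyr::expand_grid(individual_id = roster$individual_id,
                                locus_id = locus_ids)
    p <- unname(bg[cells$individual_id])
    if (nrow(somatic)) {
      key <- paste(cells$individual_id, cells$locus_id)
      skey <- paste(somatic$individual_id, somatic$locus_id)
      idx <- match(key, skey)
      hit <- !is.na(idx)
      p[hit] <- p[hit] + somatic$fraction[idx[hit]]
    }
    if (nrow(gl)) {
      key <- paste(cells$individual_id, cells$locus_id)
      gkey <- paste(gl$individual_id, gl$locus_id)
      idx <- match(key, gkey)
      hit <- !is.na(idx)
      p[hit] <- ifelse(gl$zygosity[idx[hit]] == "het", 0.5, 1 - p[hit])
    }
    p <- pmin(pmax(p, 0), 1)
    depth <- as.integer(floor(runif(nrow(cells), config$depth_range[1],
                                    config$depth_range[2] + 1)))
    out <- cells
    out$depth <- depth
    out$alt_reads <- rbinom(nrow(cells), depth, p)
    attr(out, "truth") <- truth
    out
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Simulate per-patient clinical covariates
#'
#' Draws anti-dsDNA, complement C3/C4, white-cell, lymphocyte and platelet
#' counts and the SLEDAI activity score for every patient in the roster, from
#' normal distributions with the configured baselines, shifted by
#' `carrier_shift` in carriers. Default shift signs follow the reported
#' directions (anti-dsDNA and SLEDAI up; the others down in carriers). Values
#' are clamped non-negative; SLEDAI is rounded to a non-negative integer.
#'
#' @param roster A roster from [simulate_cohort()].
#' @param carrier_flags Logical vector aligned with `roster` rows (or a data
#'   frame with `individual_id` and `carrier` columns) marking high-fraction
#'   carriers.
#' @param config A [sim_config()].
#' @param seed Seed override; defaults to `config$seed + 2`.
#' @param missing_rate Fraction of patient values blanked at random per
#'   parameter (default 0), emulating per-parameter laboratory missingness.
#' @return A tibble with one row per patient: `individual_id`, `carrier`, then
#'   one column per clinical parameter.
#' @export
simulate_clinical <- function(roster, carrier_flags, config,
                              seed = config$seed + 2L, missing_rate = 0) {
  validate_sim_config(config)
  if (is.data.frame(carrier_flags)) {
    idx <- match(roster$individual_id, carrier_flags$individual_id)
    flags <- carrier_flags$carrier[idx]
    flags[is.na(flags)] <- FALSE
  } else {
    if (length(carrier_flags) != nrow(roster)) {
      vs_abort("carrier_flags must align with roster rows",
               "vafscreen_input_error")
    }
    flags <- as.logical(carrier_flags)
  }
  patients <- roster$group == "SLE"
  ids <- roster$individual_id[patients]
  flags <- flags[patients]
  eff <- config$clinical_effects
  with_seed(seed, {
    out <- tibble(individual_id = ids, carrier = flags)
    for (i in seq_len(nrow(eff))) {
      mu <- eff$baseline_mean[i] + ifelse(flags, eff$carrier_shift[i], 0)
      v <- pmax(rnorm(length(ids), mu, eff$baseline_sd[i]), 0)
      if (eff$parameter[i] == "SLEDAI") v <- as.integer(round(v))
      if (missing_rate > 0) v[runif(length(v)) < missing_rate] <- NA
      out[[eff$parameter[i]]] <- v
    }
    out
  })
}
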