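#' Run the full screening pipeline
#'
#' Orchestrates the workflow end to end: simulate a cohort (or load tables
#' from disk), quantify read frequencies, derive the control cut-off and test
#' carrier-status association at the index locus, compute family-deduplicated
#' allele frequencies for designated germline carriers, compare clinical
#' parameters between carrier groups, and write the report bundle
#' (association report, allele-frequency report, clinical comparison report,
#' VCF of above-cutoff and germline calls, and a run log). Any stage error
#' aborts the run and removes partial outputs. Inputs are never mutated.
#'
#' @param config A [sim_config()] (simulation mode), or a list with elements
#'   `roster`, `counts` and optionally `clinical` giving TSV paths
#'   (file mode).
#' @param out_dir Output directory (created if needed).
#' @param locus_id Index locus to screen (default the first locus in `loci`).
#' @param loci Locus table (default [glk_loci()]).
#' @param strict,round_cutoff Cut-off semantics, see [screen_locus()].
#' @param tails Tails for the clinical comparisons.
#' @param seed Seed recorded in outputs; defaults to the config seed (or 1).
#' @return Invisibly, a list with `screen` (the `screen_result`),
#'   `allele_freqs`, `clinical` (a `clinical_comparison` or `NULL`) and
#'   `files` (paths written).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config_cohort1(seed = 1), out_dir = tempfile())
#' res$screen$table
#' }
run_pipeline <- function(config, out_dir, locus_id = NULL, loci = glk_loci(),
                         strict = TRUE, round_cutoff = TRUE, tails = 2,
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(files), add = TRUE)

  if (inherits(config, "sim_config")) {
    seed <- seed %||% config$seed
    roster <- simulate_cohort(config)
    counts <- simulate_read_counts(roster, loci, config)
    clinical <- NULL  # generated after carrier flags are known
  } else {
    seed <- seed %||% 1L
    if (is.null(config$counts) || is.null(config$roster)) {
      vs_abort("file-mode config needs `roster` and `counts` paths",
               "vafscreen_config_error")
    }
    roster <- read_roster(config$roster)
    counts <- read_counts(config$counts)
    clinical <- if (!is.null(config$clinical)) read_clinical(config$clinical)
  }

  locus_id <- locus_id %||% loci$locus_id[1]
  scr <- screen_locus(counts, roster, locus_id, strict = strict,
                      round_cutoff = round_cutoff)

  # association report (one row per screened locus-style summary)
  assoc <- tibble(
    locus_id = locus_id,
    cutoff_raw = scr$cutoff$cutoff_raw,
    cutoff_applied = scr$cutoff$cutoff_applied,
    cases_above = scr$table[1, 1], cases_below = scr$table[1, 2],
    controls_above = scr$table[2, 1], controls_below = scr$table[2, 2],
    fisher_p = scr$p_value
  )
  f_assoc <- file.path(out_dir, "association_report.tsv")
  write_report_tsv(assoc, f_assoc, seed = seed)
  files <- c(files, f_assoc)

  # allele-frequency report for germline calls, family-deduplicated
  calls <- call_variants(counts)
  unrelated <- dedup_unrelated(roster)
  germline <- calls |>
    filter(.data$zygosity %in% c("germline_het", "germline_hom"))
  afr <- purrr::map_dfr(unique(germline$locus_id), function(l) {
    carriers <- germline |>
      filter(.data$locus_id == l) |>
      select("individual_id", "zygosity")
    bind_rows(
      allele_frequency(carriers, unrelated, "SLE", variant_label = l),
      allele_frequency(carriers, unrelated, "non_SLE", variant_label = l)
    )
  })
  f_af <- file.path(out_dir, "allele_frequency_report.tsv")
  write_report_tsv(afr, f_af, seed = seed)
  files <- c(files, f_af)

  # clinical comparisons between carrier groups (patients only)
  flags <- scr$data$above[match(roster$individual_id,
                                scr$data$individual_id)]
  if (is.null(clinical) && inherits(config, "sim_config")) {
    clinical <- simulate_clinical(roster, flags, config)
  }
  cmp <- NULL
  if (!is.null(clinical)) {
    pat <- roster$individual_id[roster$group == "SLE"]
    clin_pat <- clinical[clinical$individual_id %in% pat, , drop = FALSE]
    pat_flags <- flags[match(clin_pat$individual_id, roster$individual_id)]
    cmp <- compare_clinical(clin_pat, pat_flags, tails = tails)
    f_cmp <- file.path(out_dir, "clinical_comparison.tsv")
    write_report_tsv(cmp, f_cmp, seed = seed)
    files <- c(files, f_cmp)
  }

  # VCF of above-cutoff somatic candidates and germline calls
  vcf_calls <- calls |>
    mutate(above = classify_above_cutoff(.data$frequency, scr$cutoff,
                                         strict = strict)) |>
    filter(.data$above | .data$zygosity %in% c("germline_het", "germline_hom")) |>
    annotate_calls(loci = loci)
  f_vcf <- file.path(out_dir, "calls.vcf")
  write_vcf(vcf_calls, f_vcf)
  files <- c(files, f_vcf)

  # run log
  f_log <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("vafscreen %s", as.character(utils::packageVersion("vafscreen"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("locus: %s", locus_id),
    sprintf("cutoff: raw %.6g applied %.6g (strict=%s, rounded=%s)",
            scr$cutoff$cutoff_raw, scr$cutoff$cutoff_applied, strict,
            round_cutoff),
    sprintf("fisher_p: %.6g", scr$p_value)
  ), f_log)
  files <- c(files, f_log)

  ok <- TRUE
  invisible(list(screen = scr, allele_freqs = afr, clinical = cmp,
                 files = files))
}
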