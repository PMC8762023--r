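# Shared TSV reading with schema validation. Tables are tab-separated with a
# one-line header; lines starting with '#' are run-metadata comments.
read_vs_tsv <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) {
    vs_abort(sprintf("input file not found: %s", path), "vafscreen_io_error")
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    vs_abort(sprintf("%s: missing column(s): %s", basename(path),
                     paste(miss, collapse = ", ")), "vafscreen_schema_error")
  }
  for (col in numeric_cols) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      vs_abort(sprintf("%s: non-numeric value in column %s (line %s)",
                       basename(path), col,
                       paste(bad + 1L, collapse = ", ")),
               "vafscreen_parse_error")
    }
  }
  tab
}

#' Read and validate the pipeline's tab-separated input tables
#'
#' `read_roster()` expects columns `individual_id`, `group`, `family_id`,
#' `sex`, `age`; `read_counts()` expects `individual_id`, `locus_id`, `depth`,
#' `alt_reads`; `read_clinical()` expects `individual_id` plus numeric
#' parameter columns. Duplicate individual IDs (roster/clinical) and rows with
#' `alt_reads > depth` (counts) are rejected with the offending ID or line.
#'
#' @param path Path to a TSV file with a one-line header; `#`-prefixed lines
#'   are treated as comments.
#' @return A validated tibble.
#' @export
read_roster <- function(path) {
  tab <- read_vs_tsv(path, c("individual_id", "group", "family_id"),
                     character())
  dup <- tab$individual_id[duplicated(tab$individual_id)]
  if (length(dup)) {
    vs_abort(sprintf("duplicated individual_id in roster: %s",
                     paste(unique(dup), collapse = ", ")),
             "vafscreen_schema_error")
  }
  bad <- setdiff(unique(tab$group), c("SLE", "HC", "family_non_SLE"))
  if (length(bad)) {
    vs_abort(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
             "vafscreen_schema_error")
  }
  tab
}

#' @rdname read_roster
#' @export
read_counts <- function(path) {
  tab <- read_vs_tsv(path, c("individual_id", "locus_id", "depth", "alt_reads"),
                     c("depth", "alt_reads"))
  bad <- which(tab$alt_reads > tab$depth | tab$alt_reads < 0 | tab$depth < 1)
  if (length(bad)) {
    vs_abort(sprintf(
      "counts violate 0 <= alt_reads <= depth (data line %s)",
      paste(bad + 1L, collapse = ", ")), "vafscreen_schema_error")
  }
  tab
}

#' @rdname read_roster
#' @export
read_clinical <- function(path) {
  tab <- read_vs_tsv(path, "individual_id", character())
  dup <- tab$individual_id[duplicated(tab$individual_id)]
  if (length(dup)) {
    vs_abort(sprintf("duplicated individual_id in clinical table: %s",
                     paste(unique(dup), collapse = ", ")),
             "vafscreen_schema_error")
  }
  tab
}

#' Write a report table as TSV with a run-metadata header
#'
#' Every output starts with `#`-prefixed comment lines recording the package
#' version and, when given, the seed — so a finished run is reproducible from
#' its own outputs.
#'
#' @param tab A data frame.
#' @param path Output path.
#' @param seed Optional integer seed to record.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(tab, path, seed = NULL) {
  tab <- as_tibble(tab)
  tab <- tab[, !vapply(tab, is.list, logical(1)), drop = FALSE]
  hdr <- c(
    sprintf("# vafscreen %s", as.character(utils::packageVersion("vafscreen"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))
  )
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(tab, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Write annotated variant calls as a minimal VCF 4.2 file
#'
#' Emits forward-strand REF/ALT alleles with INFO keys `VF` (variant read
#' frequency), `ZYG` (zygosity class), `CDNA` (HGVS-style cDNA label) and
#' `PLAB` (protein or 3'-UTR label, apostrophe-free), one record per call,
#' sorted by position. The header documents the 1-based coordinate convention
#' and that cDNA labels refer to the minus strand.
#'
#' @param calls Annotated calls from [annotate_calls()]; needs columns
#'   `individual_id`, `chrom`, `pos`, `ref_fwd`, `alt_fwd`, `frequency`,
#'   `zygosity`, `hgvs_cdna`, `protein_or_utr_label`.
#' @param path Output path.
#' @param model A [gene_model()] used to sanity-check REF consistency against
#'   the locus table orientation.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, model = glk_gene_model()) {
  need <- c("individual_id", "chrom", "pos", "ref_fwd", "alt_fwd",
            "frequency", "zygosity", "hgvs_cdna", "protein_or_utr_label")
  miss <- setdiff(need, names(calls))
  if (length(miss) && nrow(calls) > 0) {
    vs_abort(sprintf("calls missing column(s): %s",
                     paste(miss, collapse = ", ")), "vafscreen_schema_error")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=vafscreen_%s",
            as.character(utils::packageVersion("vafscreen"))),
    "##reference=hg19",
    sprintf("##note=coordinates are 1-based; gene is on the %s strand; cDNA labels are transcript-strand",
            model$strand),
    '##INFO=<ID=VF,Number=1,Type=Float,Description="Variant read frequency (alt/depth)">',
    '##INFO=<ID=ZYG,Number=1,Type=String,Description="Zygosity class">',
    '##INFO=<ID=CDNA,Number=1,Type=String,Description="cDNA change, HGVS-style">',
    '##INFO=<ID=PLAB,Number=1,Type=String,Description="Protein or 3-UTR label">',
    '##INFO=<ID=IND,Number=1,Type=String,Description="Individual ID">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  calls <- calls[order(calls$pos), , drop = FALSE]
  plab <- gsub("'", "", calls$protein_or_utr_label)
  recs <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\tPASS\tVF=%.6g;ZYG=%s;CDNA=%s;PLAB=%s;IND=%s",
    calls$chrom, calls$pos,
    if ("locus_id" %in% names(calls)) calls$locus_id else ".",
    calls$ref_fwd, calls$alt_fwd, calls$frequency, calls$zygosity,
    calls$hgvs_cdna, plab, calls$individual_id)
  writeLines(c(header, recs), path)
  invisible(path)
}
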