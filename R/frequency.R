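#' Variant read frequency
#'
#' The fraction of reads supporting the alternate allele: `alt / depth`.
#' Vectorised.
#'
#' @param alt Alternate-supporting read count(s), `0 <= alt <= depth`.
#' @param depth Total read depth(s), `>= 1`.
#' @return Fraction(s) in \[0, 1\].
#' @export
#' @examples
#' variant_frequency(2700, 100000)   # 0.027, the screening cut-off scale
#' variant_frequency(50600, 100000)  # 0.506, a germline heterozygote
variant_frequency <- function(alt, depth) {
  if (any(depth == 0)) {
    vs_abort("depth is zero: frequency undefined",
             "vafscreen_undefined_frequency_error")
  }
  if (any(depth < 1) || any(alt < 0) || any(alt > depth)) {
    vs_abort("need depth >= 1 and 0 <= alt <= depth",
             "vafscreen_input_error")
  }
  alt / depth
}

#' Zygosity classification bands
#'
#' Read-frequency bands separating background noise, candidate somatic
#' clones, germline heterozygotes and homozygotes. Defaults: heterozygous
#' band \[0.35, 0.65\], homozygous floor 0.90, candidate-somatic floor 0.001.
#' At depths of 100,000 reads binomial noise around 0.5 stays within
#' \[0.49, 0.51\], so the default het band is generous.
#'
#' @param het Length-2 vector, the heterozygous frequency band.
#' @param hom_floor Minimum frequency called homozygous.
#' @param background_floor Frequencies at or below this are background.
#' @return A list of class `zygosity_bands`.
#' @export
zygosity_bands <- function(het = c(0.35, 0.65), hom_floor = 0.90,
                           background_floor = 0.001) {
  if (het[1] >= het[2] || background_floor >= het[1] || het[2] > hom_floor) {
    vs_abort("zygosity bands overlap or are inverted",
             "vafscreen_config_error")
  }
  structure(list(het = het, hom_floor = hom_floor,
                 background_floor = background_floor),
            class = "zygosity_bands")
}

#' Classify a read frequency into a zygosity band
#'
#' @param frequency Read frequency/frequencies in \[0, 1\].
#' @param bands A [zygosity_bands()].
#' @return Character vector: `"germline_hom"`, `"germline_het"`,
#'   `"candidate_somatic"` or `"background"`.
#' @export
#' @examples
#' classify_zygosity(c(0.506, 0.053, 1.0, 0.0005))
classify_zygosity <- function(frequency, bands = zygosity_bands()) {
  if (any(frequency < 0 | frequency > 1)) {
    vs_abort("frequency must be in [0, 1]", "vafscreen_input_error")
  }
  dplyr::case_when(
    frequency >= bands$hom_floor ~ "germline_hom",
    frequency >= bands$het[1] & frequency <= bands$het[2] ~ "germline_het",
    frequency > bands$background_floor ~ "candidate_somatic",
    TRUE ~ "background"
  )
}

#' Turn a read-count table into variant calls
#'
#' Adds the read frequency and zygosity class to each (individual, locus) row.
#'
#' @param counts Data frame with columns `individual_id`, `locus_id`, `depth`,
#'   `alt_reads` (as produced by [simulate_read_counts()] or [read_counts()]).
#' @param bands A [zygosity_bands()].
#' @return The input tibble with `frequency` and `zygosity` columns appended.
#' @export
call_variants <- function(counts, bands = zygosity_bands()) {
  need <- c("individual_id", "locus_id", "depth", "alt_reads")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    vs_abort(sprintf("counts table missing column(s): %s",
                     paste(miss, collapse = ", ")), "vafscreen_schema_error")
  }
  counts |>
    as_tibble() |>
    mutate(frequency = variant_frequency(.data$alt_reads, .data$depth),
           zygosity = classify_zygosity(.data$frequency, bands))
}

#' Annotate variant calls with cDNA and protein/UTR labels
#'
#' Joins calls to the locus table, maps each locus through the gene model
#' (minus-strand complementation), and emits both the study-style label
#' (continuation-numbered `3'-UTR U635C` for UTR variants, `p.Ala410Thr` for
#' coding ones) and the HGVS-style cDNA name (`c.3320T>C`, starred `c.*635T>C`
#' for UTR positions).
#'
#' @param calls Output of [call_variants()].
#' @param loci Locus table (see [glk_loci()]).
#' @param model A [gene_model()].
#' @param cds CDS sequence used for codon context (default the packaged
#'   fixture).
#' @return `calls` with columns `chrom`, `pos`, `ref_fwd`, `alt_fwd`,
#'   `region`, `cdna_label`, `hgvs_cdna`, `protein_or_utr_label` appended.
#' @export
annotate_calls <- function(calls, loci = glk_loci(), model = glk_gene_model(),
                           cds = glk_cds_fixture()) {
  ann <- loci |>
    mutate(purrr::pmap_dfr(
      list(.data$pos, .data$ref_fwd, .data$alt_fwd, .data$region),
      function(pos, ref_fwd, alt_fwd, region) {
        m <- genomic_to_cdna(pos, ref_fwd, alt_fwd, model)
        cdna_label <- sprintf("c.%d%s>%s", m$cdna_pos, m$cdna_ref, m$cdna_alt)
        if (region == "UTR3") {
          u <- cdna_to_utr3(m$cdna_pos, model)
          lab <- sprintf("3'-UTR %s%d%s",
                         sub("T", "U", m$cdna_ref), u,
                         sub("T", "U", m$cdna_alt))
          hgvs <- sprintf("c.*%d%s>%s", u, m$cdna_ref, m$cdna_alt)
        } else {
          lab <- annotate_codon_change(m$cdna_pos, m$cdna_ref, m$cdna_alt,
                                       cds, model)
          hgvs <- cdna_label
        }
        tibble(cdna_label = cdna_label, hgvs_cdna = hgvs,
               protein_or_utr_label = lab)
      }))
  dplyr::left_join(calls, ann, by = "locus_id")
}
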