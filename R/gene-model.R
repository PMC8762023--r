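#' Minus-strand gene coordinate model
#'
#' A gene model maps between genomic and cDNA coordinates through a list of
#' anchored blocks. For a minus-strand gene, cDNA position increases as
#' genomic position decreases within a block: block row
#' `(genomic_anchor, cdna_anchor, length)` maps cDNA position
#' `cdna_anchor + k` to genomic position `genomic_anchor - k` for
#' `k = 0 .. length - 1`. cDNA positions beyond `cds_length` are 3'-UTR;
#' [cdna_to_utr3()] converts to the UTR continuation numbering.
#'
#' @param strand `"+"` or `"-"` (only `"-"` is exercised by the default model).
#' @param cds_length CDS length in nucleotides; must be divisible by 3.
#' @param blocks Data frame with columns `genomic_anchor`, `cdna_anchor`,
#'   `length`; blocks must not overlap in either coordinate system.
#' @param chrom Chromosome name.
#' @return A list of class `gene_model`.
#' @seealso [glk_gene_model()] for the packaged default.
#' @export
gene_model <- function(strand, cds_length, blocks, chrom = "chr2") {
  stopifnot(strand %in% c("+", "-"))
  if (cds_length %% 3 != 0) {
    vs_abort("cds_length must be divisible by 3", "vafscreen_config_error")
  }
  blocks <- as_tibble(blocks)
  need <- c("genomic_anchor", "cdna_anchor", "length")
  if (!all(need %in% names(blocks))) {
    vs_abort("blocks need columns genomic_anchor, cdna_anchor, length",
             "vafscreen_config_error")
  }
  # overlap check in both coordinate systems
  civ <- cbind(blocks$cdna_anchor, blocks$cdna_anchor + blocks$length - 1)
  giv <- if (strand == "-") {
    cbind(blocks$genomic_anchor - blocks$length + 1, blocks$genomic_anchor)
  } else {
    cbind(blocks$genomic_anchor, blocks$genomic_anchor + blocks$length - 1)
  }
  overlaps <- function(iv) {
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])
  }
  if (overlaps(civ) || overlaps(giv)) {
    vs_abort("gene model blocks overlap", "vafscreen_config_error")
  }
  structure(list(strand = strand, cds_length = as.integer(cds_length),
                 blocks = blocks, chrom = chrom),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> strand %s, CDS %d nt, %d block(s) on %s\n",
              x$strand, x$cds_length, nrow(x$blocks), x$chrom))
  print(x$blocks)
  invisible(x)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A")

#' Complement a nucleotide base
#'
#' @param base Character vector of single bases (`A`, `C`, `G`, `T`/`U`).
#' @return The complementary base(s) in DNA alphabet.
#' @export
complement_base <- function(base) {
  base <- toupper(base)
  if (!all(base %in% names(COMPLEMENT))) {
    vs_abort("non-nucleotide base", "vafscreen_input_error")
  }
  unname(COMPLEMENT[base])
}

#' Map a genomic substitution to cDNA coordinates
#'
#' Looks the genomic position up in the model blocks; on the minus strand both
#' alleles are complemented. Vectorised over positions/alleles.
#'
#' @param pos 1-based genomic position(s).
#' @param ref_fwd,alt_fwd Forward-strand reference and alternate bases.
#' @param model A [gene_model()].
#' @return A tibble with columns `cdna_pos`, `cdna_ref`, `cdna_alt`.
#' @export
#' @examples
#' genomic_to_cdna(39477124, "A", "G", glk_gene_model())  # c.3320 T>C
genomic_to_cdna <- function(pos, ref_fwd, alt_fwd, model) {
  b <- model$blocks
  out_pos <- integer(length(pos))
  for (i in seq_along(pos)) {
    if (model$strand == "-") {
      hit <- which(pos[i] <= b$genomic_anchor &
                     pos[i] > b$genomic_anchor - b$length)
      if (!length(hit)) {
        vs_abort(sprintf("genomic position %d outside all model blocks",
                         pos[i]), "vafscreen_out_of_model_error")
      }
      out_pos[i] <- b$cdna_anchor[hit] + (b$genomic_anchor[hit] - pos[i])
    } else {
      hit <- which(pos[i] >= b$genomic_anchor &
                     pos[i] < b$genomic_anchor + b$length)
      if (!length(hit)) {
        vs_abort(sprintf("genomic position %d outside all model blocks",
                         pos[i]), "vafscreen_out_of_model_error")
      }
      out_pos[i] <- b$cdna_anchor[hit] + (pos[i] - b$genomic_anchor[hit])
    }
  }
  if (model$strand == "-") {
    tibble(cdna_pos = out_pos, cdna_ref = complement_base(ref_fwd),
           cdna_alt = complement_base(alt_fwd))
  } else {
    tibble(cdna_pos = out_pos, cdna_ref = toupper(ref_fwd),
           cdna_alt = toupper(alt_fwd))
  }
}

#' Map a cDNA position back to genomic coordinates
#'
#' Inverse of [genomic_to_cdna()]; the two round-trip to the identity on every
#' in-model position.
#'
#' @param cdna_pos 1-based cDNA position(s).
#' @param model A [gene_model()].
#' @return Integer genomic position(s).
#' @export
cdna_to_genomic <- function(cdna_pos, model) {
  b <- model$blocks
  vapply(cdna_pos, function(p) {
    hit <- which(p >= b$cdna_anchor & p < b$cdna_anchor + b$length)
    if (!length(hit)) {
      vs_abort(sprintf("cDNA position %d outside all model blocks", p),
               "vafscreen_out_of_model_error")
    }
    if (model$strand == "-") {
      as.integer(b$genomic_anchor[hit] - (p - b$cdna_anchor[hit]))
    } else {
      as.integer(b$genomic_anchor[hit] + (p - b$cdna_anchor[hit]))
    }
  }, integer(1))
}

#' Convert a cDNA position to 3'-UTR continuation numbering
#'
#' The study labels 3'-UTR variants by continuation numbering (UTR position =
#' cDNA position minus CDS length), e.g. c.3320 -> UTR 635 for a 2685-nt CDS.
#'
#' @param cdna_pos cDNA position(s), each `> cds_length`.
#' @param model A [gene_model()].
#' @return Integer UTR position(s), 1-based from the first base after the stop
#'   codon.
#' @export
cdna_to_utr3 <- function(cdna_pos, model) {
  if (any(cdna_pos <= model$cds_length)) {
    vs_abort("cDNA position is within the CDS, not the 3'-UTR",
             "vafscreen_not_in_utr_error")
  }
  as.integer(cdna_pos - model$cds_length)
}

# one- to three-letter amino-acid names, HGVS style
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

# standard genetic code (DNA codons)
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
}

#' Annotate a coding substitution as a protein change
#'
#' Rebuilds the affected codon from the supplied CDS context, substitutes the
#' alternate base, translates both codons and emits an HGVS-style protein
#' label `p.<RefAA><codon><AltAA>` (`Ter` for stop gains, `p.(=)` for
#' synonymous changes).
#'
#' @param cdna_pos cDNA position of the substitution (1..cds_length).
#' @param ref,alt cDNA-strand reference and alternate bases.
#' @param cds Either the full CDS sequence (a single string) or the 3-base
#'   codon containing `cdna_pos`.
#' @param model A [gene_model()].
#' @return The protein change label, e.g. `"p.Ala410Thr"`.
#' @export
#' @examples
#' annotate_codon_change(1228, "G", "A", "GCA", glk_gene_model())
annotate_codon_change <- function(cdna_pos, ref, alt, cds, model) {
  if (cdna_pos < 1 || cdna_pos > model$cds_length) {
    vs_abort("cdna_pos outside the CDS", "vafscreen_input_error")
  }
  codon_idx <- ceiling(cdna_pos / 3)
  offset <- (cdna_pos - 1L) %% 3L            # 0-based position within codon
  cds <- toupper(cds)
  codon <- if (nchar(cds) == 3) {
    cds
  } else {
    substr(cds, 3 * (codon_idx - 1) + 1, 3 * codon_idx)
  }
  if (nchar(codon) != 3) {
    vs_abort("CDS context does not cover the affected codon",
             "vafscreen_input_error")
  }
  if (substr(codon, offset + 1, offset + 1) != toupper(ref)) {
    vs_abort(sprintf(
      "reference mismatch at c.%d: context has %s, call says %s",
      cdna_pos, substr(codon, offset + 1, offset + 1), ref),
      "vafscreen_ref_mismatch_error")
  }
  mutated <- codon
  substr(mutated, offset + 1, offset + 1) <- toupper(alt)
  tab <- codon_table()
  aa_ref <- tab[[codon]]
  aa_alt <- tab[[mutated]]
  if (aa_ref == aa_alt) return("p.(=)")
  sprintf("p.%s%d%s", AA3[[aa_ref]], codon_idx, AA3[[aa_alt]])
}

#' Annotate an out-of-frame coding insertion as a frameshift
#'
#' Frameshift labels name the first affected codon: an insertion between cDNA
#' positions `(left, right)` shifts the frame from the codon containing
#' `right`, giving `p.<AA><codon>fs`. In-frame insertions are not consequence-
#' predicted and raise an unsupported-annotation condition.
#'
#' @param cdna_interval Length-2 vector, the flanking cDNA positions
#'   `(left, right)` of the insertion point, e.g. `c(1942, 1943)`.
#' @param inserted Inserted sequence (its length decides in/out of frame).
#' @param cds Full CDS sequence or the codon containing the first affected
#'   position.
#' @param model A [gene_model()].
#' @return The frameshift label, e.g. `"p.Ala648fs"`.
#' @export
annotate_insertion <- function(cdna_interval, inserted, cds, model) {
  if (length(cdna_interval) != 2 ||
      cdna_interval[2] != cdna_interval[1] + 1) {
    vs_abort("cdna_interval must be the flanking pair (left, right)",
             "vafscreen_input_error")
  }
  if (nchar(inserted) %% 3 == 0) {
    vs_abort("in-frame insertions are not consequence-annotated",
             "vafscreen_unsupported_annotation")
  }
  first_affected <- cdna_interval[2]
  codon_idx <- ceiling(first_affected / 3)
  cds <- toupper(cds)
  codon <- if (nchar(cds) == 3) {
    cds
  } else {
    substr(cds, 3 * (codon_idx - 1) + 1, 3 * codon_idx)
  }
  if (nchar(codon) != 3) {
    vs_abort("CDS context does not cover the affected codon",
             "vafscreen_input_error")
  }
  aa <- codon_table()[[codon]]
  sprintf("p.%s%dfs", AA3[[aa]], codon_idx)
}

#' Default minus-strand gene model fixture
#'
#' A packaged coordinate model for the screened kinase gene (MAP4K3/GLK, minus
#' strand of chromosome 2, hg19 numbering) with a 2685-nt CDS. Four blocks are
#' anchored on the published coordinate/label pairs (c.800 at chr2:39,552,878;
#' c.1228 at chr2:39,519,957; c.1943 at chr2:39,499,454; c.2624 at
#' chr2:39,477,820 running through the 3'-UTR, so that UTR position 635 falls
#' at chr2:39,477,124). Block extents beyond those anchors are synthetic: the
#' model reproduces every published pair but is not the gene's full exon
#' structure.
#'
#' @return A `gene_model`.
#' @export
glk_gene_model <- function() {
  gene_model(
    strand = "-",
    cds_length = 2685L,
    chrom = "chr2",
    blocks = tibble(
      genomic_anchor = c(39552898L, 39519985L, 39499477L, 39477844L),
      cdna_anchor    = c(780L,      1200L,     1920L,     2600L),
      length         = c(41L,       61L,       41L,       754L)
    )
  )
}

#' Candidate locus table for the screened gene
#'
#' The published substitution loci: the index somatic 3'-UTR locus (T635C)
#' first, then the germline/somatic coding and UTR loci. Forward-strand
#' reference and alternate alleles as printed; `region` separates CDS from
#' 3'-UTR.
#'
#' @return A tibble with columns `locus_id`, `chrom`, `pos`, `ref_fwd`,
#'   `alt_fwd`, `region`.
#' @export
glk_loci <- function() {
  tibble(
    locus_id = c("T635C", "A644C", "A410T", "K650R", "L267X", "T875S"),
    chrom = "chr2",
    pos = c(39477124L, 39477115L, 39519957L, 39499448L, 39552878L, 39477820L),
    ref_fwd = c("A", "T", "C", "T", "A", "G"),
    alt_fwd = c("G", "G", "T", "C", "T", "C"),
    region = c("UTR3", "UTR3", "CDS", "CDS", "CDS", "CDS")
  )
}

#' Synthetic CDS fixture for the default gene model
#'
#' A 2685-nt synthetic coding sequence carrying the published codons at the
#' published positions (codon 267 TTA, 410 GCA, 579 GCC, 648 GCT, 650 AAA,
#' 875 ACC; ATG start, TAA stop); every other codon is GCT filler. Synthetic:
#' only the planted codons reflect the real transcript.
#'
#' @return A single character string of length 2685.
#' @export
glk_cds_fixture <- function() {
  codons <- rep("GCT", 895)
  codons[1] <- "ATG"
  codons[267] <- "TTA"
  codons[410] <- "GCA"
  codons[579] <- "GCC"
  codons[650] <- "AAA"
  codons[875] <- "ACC"
  codons[895] <- "TAA"
  paste(codons, collapse = "")
}

#' Synthetic 3'-UTR fixture with an embedded AU-rich element
#'
#' A 700-nt synthetic 3'-UTR whose positions 603-664 hold a 62-nt AU-rich
#' element with 43 A/U bases (69.4% AU), a U at UTR position 635 and an A at
#' position 644 — the two variant positions the screen targets. The flanks are
#' GC-only so the ARE is the sequence's only AU-rich segment. Synthetic: the
#' composition, not the base order, mirrors the real element.
#'
#' @return A single character string of length 700.
#' @export
glk_utr3_fixture <- function() {
  are <- "AGTTCAATGTACATGTACATTGAACTTGAATCTAGATCTAGATTCAAGTTCAAGTTACATGT"
  flank5 <- paste(rep("GC", 301), collapse = "")  # 602 nt
  flank3 <- paste(rep("GC", 18), collapse = "")   # 36 nt
  paste0(flank5, are, flank3)
}
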