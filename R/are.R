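#' Scan a 3'-UTR sequence for AU-rich elements
#'
#' AU-rich elements (AREs) are A/U-dense 3'-UTR segments that destabilise
#' mRNA; variants inside them can stabilise the transcript. There is no
#' universal ARE-calling rule, so this scanner uses an explicit, documented
#' definition: every window of `min_length` bases whose A+U fraction is at
#' least `min_au` qualifies; overlapping qualifying windows are merged; each
#' merged segment is trimmed to its outermost A/U bases and re-checked against
#' both thresholds. Reported segments therefore never overlap, always start
#' and end on an A/U base, and each individually satisfies both thresholds.
#'
#' @param utr_seq A single string over `A`, `C`, `G`, `T`/`U` (case
#'   insensitive; `U` is treated as `T`).
#' @param min_length Minimum segment length in nucleotides (default 60).
#' @param min_au Minimum A+U fraction in (0, 1\] (default 0.65).
#' @return A tibble with columns `start`, `end` (1-based inclusive), `length`,
#'   `au_fraction`; zero rows when nothing qualifies.
#' @export
#' @examples
#' scan_are(glk_utr3_fixture())  # the packaged UTR's single ARE
scan_are <- function(utr_seq, min_length = 60L, min_au = 0.65) {
  if (min_au <= 0 || min_au > 1) {
    vs_abort("min_au must be in (0, 1]", "vafscreen_config_error")
  }
  bases <- strsplit(toupper(utr_seq), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T", "U"))) {
    vs_abort("sequence contains a non-nucleotide character",
             "vafscreen_input_error")
  }
  n <- length(bases)
  empty <- tibble(start = integer(), end = integer(), length = integer(),
                  au_fraction = double())
  if (n < min_length) return(empty)

  is_au <- bases %in% c("A", "T", "U")
  cum <- c(0L, cumsum(is_au))
  starts <- seq_len(n - min_length + 1L)
  au_in_window <- cum[starts + min_length] - cum[starts]
  ok <- au_in_window / min_length >= min_au
  if (!any(ok)) return(empty)

  # merge overlapping qualifying windows into candidate segments
  qs <- starts[ok]
  qe <- qs + min_length - 1L
  brk <- which(qs[-1] > head(qe, -1) + 1L)
  seg_start <- qs[c(1L, brk + 1L)]
  seg_end <- qe[c(brk, length(qe))]

  out <- purrr::map2_dfr(seg_start, seg_end, function(s, e) {
    # trim to the outermost A/U base
    while (s <= e && !is_au[s]) s <- s + 1L
    while (e >= s && !is_au[e]) e <- e - 1L
    len <- e - s + 1L
    if (len < min_length) return(empty)
    frac <- (cum[e + 1L] - cum[s]) / len
    if (frac < min_au) return(empty)
    tibble(start = s, end = e, length = len, au_fraction = frac)
  })
  out
}
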