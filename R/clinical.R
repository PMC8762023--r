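#' Pooled-variance two-sample Student's t-test
#'
#' Computes the equal-variance Student statistic and its p-value from the t
#' distribution with `n1 + n2 - 2` degrees of freedom. The one-tailed p-value
#' is half the two-tailed p when the observed difference lies on the tested
#' side, and `1 - p/2` otherwise. Welch's unequal-variance statistic is
#' available behind a flag for robustness comparisons.
#'
#' @param x,y Numeric samples (the "high"/carrier and "low"/non-carrier
#'   groups); missing values are dropped; each group needs >= 2 values.
#' @param tails 1 or 2.
#' @param direction For one-tailed tests, the tested sign of `mean(x) -
#'   mean(y)`: `"greater"` or `"less"`.
#' @param welch Use Welch's statistic and Satterthwaite degrees of freedom.
#' @return A one-row tibble: `n_x`, `n_y`, `mean_x`, `mean_y`, `statistic`,
#'   `df`, `tails`, `p_value`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
two_sample_t <- function(x, y, tails = 2, direction = c("greater", "less"),
                         welch = FALSE) {
  direction <- match.arg(direction)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    vs_abort("each group needs at least 2 non-missing values",
             "vafscreen_insufficient_data_error")
  }
  n1 <- length(x); n2 <- length(y)
  d <- mean(x) - mean(y)
  if (welch) {
    se2 <- var(x) / n1 + var(y) / n2
    df <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
    se <- sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0) {
    t_stat <- 0
    p2 <- 1
  } else {
    t_stat <- d / se
    p2 <- 2 * pt(-abs(t_stat), df)
  }
  p <- if (tails == 2) {
    p2
  } else {
    on_side <- if (direction == "greater") t_stat >= 0 else t_stat <= 0
    if (on_side) p2 / 2 else 1 - p2 / 2
  }
  tibble(n_x = n1, n_y = n2, mean_x = mean(x), mean_y = mean(y),
         statistic = t_stat, df = df, tails = as.integer(tails),
         p_value = min(max(p, 0), 1))
}

# default one-tailed directions, following the reported arrows: anti-dsDNA
# and SLEDAI higher in carriers, the rest lower
default_directions <- function() {
  c(anti_dsDNA = "greater", C3 = "less", C4 = "less", WBC = "less",
    lymphocytes = "less", platelets = "less", SLEDAI = "greater")
}

#' Compare clinical parameters between carrier groups
#'
#' Runs one two-sample t-test per clinical parameter between high-fraction
#' carriers and non-carriers, with per-parameter (pairwise) deletion of
#' missing values — the per-parameter `n` is reported, mirroring the unequal
#' group sizes of laboratory panels. No multiplicity adjustment is applied
#' across parameters (the comparisons are reported as-is; interpret jointly
#' with care).
#'
#' @param clinical Clinical table with `individual_id` and one numeric column
#'   per parameter (see [simulate_clinical()] / [read_clinical()]).
#' @param carrier_flags Logical vector aligned with `clinical` rows, or a data
#'   frame with `individual_id` and `carrier`.
#' @param tails 1 or 2 (scalar, or named per-parameter vector).
#' @param directions Named character vector of one-tailed directions per
#'   parameter (defaults follow the reported effect directions).
#' @param parameters Which columns to compare (default: every numeric column
#'   except `carrier`).
#' @param welch Use Welch's test instead of pooled Student.
#' @return A tibble of class `clinical_comparison`, one row per parameter:
#'   `parameter`, `n_low`, `n_high`, `mean_low`, `mean_high`, `statistic`,
#'   `df`, `tails`, `p_value`, `significance` (`*` < 0.05, `**` < 0.01,
#'   `***` < 0.001 two-tailed; `§` < 0.05 one-tailed). Parameters with an
#'   entirely missing group are skipped with a warning.
#' @export
compare_clinical <- function(clinical, carrier_flags, tails = 2,
                             directions = default_directions(),
                             parameters = NULL, welch = FALSE) {
  clinical <- as_tibble(clinical)
  if (is.data.frame(carrier_flags)) {
    idx <- match(clinical$individual_id, carrier_flags$individual_id)
    flags <- as.logical(carrier_flags$carrier[idx])
  } else {
    if (length(carrier_flags) != nrow(clinical)) {
      vs_abort("carrier_flags must align with clinical rows",
               "vafscreen_input_error")
    }
    flags <- as.logical(carrier_flags)
  }
  if (is.null(parameters)) {
    parameters <- setdiff(
      names(clinical)[vapply(clinical, is.numeric, logical(1))], "carrier")
  }
  rows <- purrr::map_dfr(parameters, function(p) {
    hi <- clinical[[p]][flags %in% TRUE]
    lo <- clinical[[p]][flags %in% FALSE]
    if (sum(!is.na(hi)) < 2 || sum(!is.na(lo)) < 2) {
      warn(sprintf("parameter %s skipped: a group has < 2 non-missing values", p))
      return(tibble())
    }
    tl <- if (length(tails) > 1) unname(tails[p]) else tails
    dir <- directions[p] %||% "greater"
    if (is.na(dir)) dir <- "greater"
    res <- two_sample_t(hi, lo, tails = tl, direction = dir, welch = welch)
    tibble(parameter = p,
           n_low = res$n_y, n_high = res$n_x,
           mean_low = res$mean_y, mean_high = res$mean_x,
           statistic = res$statistic, df = res$df, tails = res$tails,
           p_value = res$p_value,
           significance = sig_marker(res$p_value, res$tails))
  })
  class(rows) <- c("clinical_comparison", class(rows))
  rows
}

sig_marker <- function(p, tails) {
  if (tails == 1) return(if (p < 0.05) "§" else "")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Exact association between a binary outcome and carrier status
#'
#' Cross-tabulates two aligned boolean vectors (e.g. organ involvement or a
#' treatment vs high-fraction carrier status) and applies the two-tailed
#' Fisher exact test.
#'
#' @param outcome,carrier Logical vectors of equal length; `NA` pairs are
#'   dropped.
#' @return The two-tailed exact p-value.
#' @export
categorical_assoc <- function(outcome, carrier) {
  if (length(outcome) != length(carrier)) {
    vs_abort("outcome and carrier flags are not aligned",
             "vafscreen_input_error")
  }
  ok <- !is.na(outcome) & !is.na(carrier)
  outcome <- as.logical(outcome)[ok]
  carrier <- as.logical(carrier)[ok]
  tab <- matrix(c(sum(carrier & outcome), sum(carrier & !outcome),
                  sum(!carrier & outcome), sum(!carrier & !outcome)),
                nrow = 2, byrow = TRUE)
  fisher_exact_2x2(tab)
}
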