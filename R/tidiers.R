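#' Tidy and glance methods for screening results
#'
#' `tidy.cutoff_result()` returns the threshold components as a one-row
#' tibble; `tidy.screen_result()` returns the per-individual frequencies and
#' carrier flags; `glance.screen_result()` condenses the whole screen (cut-off,
#' carrier counts per group, exact p) into one row.
#'
#' @param x A `cutoff_result` or `screen_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name vafscreen-tidiers
NULL

#' @rdname vafscreen-tidiers
#' @method tidy cutoff_result
#' @export
tidy.cutoff_result <- function(x, ...) {
  tibble(control_mean = x$control_mean, control_sd = x$control_sd,
         cutoff_raw = x$cutoff_raw, cutoff_applied = x$cutoff_applied,
         n_controls = x$n_controls)
}

#' @rdname vafscreen-tidiers
#' @method glance cutoff_result
#' @export
glance.cutoff_result <- function(x, ...) tidy.cutoff_result(x, ...)

#' @rdname vafscreen-tidiers
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  x$data |>
    select("individual_id", "group", "depth", "alt_reads", "frequency",
           "above")
}

#' @rdname vafscreen-tidiers
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    locus_id = x$locus_id,
    n = nrow(x$data),
    n_cases = sum(x$data$group == "SLE"),
    n_controls = sum(x$data$group != "SLE"),
    cutoff_raw = x$cutoff$cutoff_raw,
    cutoff_applied = x$cutoff$cutoff_applied,
    cases_above = x$table[1, 1],
    controls_above = x$table[2, 1],
    carrier_rate_cases = x$table[1, 1] / max(sum(x$table[1, ]), 1),
    carrier_rate_controls = x$table[2, 1] / max(sum(x$table[2, ]), 1),
    p_value = x$p_value
  )
}
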