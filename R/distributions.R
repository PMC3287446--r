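#' Rank distribution of a value over units
#'
#' Orders units by a value (stored, searched or downloaded records) and
#' attaches 1-based ranks and cumulative shares. Occurrence-data holdings
#' are strongly long-tailed — a few datasets hold most records while many
#' hold few — and rank tables are the standard way to inspect that shape.
#' Ties are broken by `unit_id` (lexicographic) so the table is reproducible
#' regardless of input order.
#'
#' @param units Data frame with columns `unit_id` and `value` (non-negative).
#' @param value_kind One of `"records"`, `"searched"`, `"downloaded"`;
#'   recorded as an attribute on the result.
#' @return Tibble `rank`, `unit_id`, `value`, `cumulative_share`, sorted by
#'   descending value. `cumulative_share` is `NA` when all values are zero.
#' @export
rank_distribution <- function(units, value_kind = c("records", "searched", "downloaded")) {
  value_kind <- match.arg(value_kind)
  units <- tibble::as_tibble(units)
  if (!all(c("unit_id", "value") %in% names(units))) {
    abort("units needs columns unit_id and value")
  }
  if (nrow(units) == 0) abort("at least one unit is required")
  if (any(units$value < 0)) abort("values must be non-negative")
  ord <- order(-units$value, units$unit_id)
  total <- sum(units$value)
  out <- tibble::tibble(
    rank = seq_len(nrow(units)),
    unit_id = units$unit_id[ord],
    value = units$value[ord],
    cumulative_share = if (total > 0) cumsum(units$value[ord]) / total else NA_real_)
  attr(out, "value_kind") <- value_kind
  out
}

#' Long-tail summary of a rank table
#'
#' Quantifies concentration with the top-k share (fraction of the total held
#' by the k highest-ranked units) and the Gini coefficient computed by the
#' standard sorted-sum formula.
#'
#' @param table A [rank_distribution()] table (or any data frame with a
#'   `value` column).
#' @param k Number of top units for the share (default: top decile, at
#'   least 1).
#' @return List with `top_k_share`, `k` and `gini`; both statistics are `NA`
#'   when all values are zero.
#' @export
tail_summary <- function(table, k = NULL) {
  values <- table$value
  n <- length(values)
  if (is.null(k)) k <- max(1L, floor(n / 10))
  if (k < 1 || k > n) abort("k must be between 1 and the number of units")
  total <- sum(values)
  if (total == 0) {
    warn("all values are zero; long-tail summary undefined")
    return(list(top_k_share = NA_real_, k = as.integer(k), gini = NA_real_))
  }
  desc <- sort(values, decreasing = TRUE)
  asc <- sort(values)
  gini <- sum((2 * seq_len(n) - n - 1) * asc) / (n * total)
  list(top_k_share = sum(desc[seq_len(k)]) / total, k = as.integer(k), gini = gini)
}

#' Rank-vs-value figure
#'
#' Log-log rank plot of a rank table; the signature long tail appears as a
#' steeply falling curve.
#'
#' @param table A [rank_distribution()] table.
#' @return A ggplot object.
#' @export
plot_rank_distribution <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(table[table$value > 0, ],
                  ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = attr(table, "value_kind") %||% "value") +
    ggplot2::theme_minimal()
}
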