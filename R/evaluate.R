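# Top-k accuracy reporting over per-case causal-gene ranks.

#' Top-k accuracy report
#'
#' Counts, for each cutoff `k`, the cases whose causal gene ranked at or
#' above `k`. Unranked cases (`NA`) count toward the total but toward no
#' cutoff; fractions are reported to 0.1%.
#'
#' @param causal_ranks Integer vector of per-case causal ranks (`NA` =
#'   unranked).
#' @param k_values Integer cutoffs, default `c(1, 5, 20, 50)`.
#' @return A `topk_report` list: `k_values`, `counts`, `n_cases`,
#'   `fractions`.
#' @export
top_k_accuracy <- function(causal_ranks, k_values = c(1L, 5L, 20L, 50L)) {
  k_values <- sort(unique(as.integer(k_values)))
  counts <- vapply(k_values, function(k)
    sum(!is.na(causal_ranks) & causal_ranks <= k), integer(1))
  n <- length(causal_ranks)
  structure(list(k_values = k_values,
                 counts = stats::setNames(counts, k_values),
                 n_cases = n,
                 fractions = stats::setNames(
                   if (n) round(counts / n, 3) else rep(NA_real_, length(counts)),
                   k_values)),
            class = "topk_report")
}

#' @export
print.topk_report <- function(x, ...) {
  cat("top-k accuracy over", x$n_cases, "cases\n")
  for (i in seq_along(x$k_values))
    cat(sprintf("  top-%-3d %4d/%d (%.1f%%)\n", x$k_values[i], x$counts[i],
                x$n_cases, 100 * x$fractions[i]))
  invisible(x)
}

#' Export a top-k report as JSON
#' @param report A [top_k_accuracy()] report.
#' @param path Output path.
#' @export
write_topk_json <- function(report, path) {
  jsonlite::write_json(list(k_values = report$k_values,
                            counts = as.list(report$counts),
                            n_cases = report$n_cases,
                            fractions = as.list(report$fractions)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
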