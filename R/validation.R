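# Accuracy analysis: automated counts against ground truth.

#' Compare automated and reference cell counts
#'
#' Per-section agreement between the automated cell finder and a reference
#' count (ground truth here; an expert annotator in the original protocol):
#' squared Pearson correlation, the least-squares line, and per-section
#' signed errors (automated minus reference).
#'
#' @param true_counts,auto_counts Equal-length numeric vectors, one entry per
#'   section.
#' @return Object of class `count_comparison`: `data` (`true`, `auto`,
#'   `error`), `r_squared`, `slope`, `intercept`, `degenerate`.
#' @export
compare_counts <- function(true_counts, auto_counts) {
  if (length(true_counts) != length(auto_counts) || length(true_counts) == 0L) {
    stop_sectionmap("count vectors must be non-empty and equal length",
                    "value_error")
  }
  degenerate <- stats::var(true_counts) == 0 || stats::var(auto_counts) == 0
  r2 <- if (degenerate) NA_real_ else
    stats::cor(true_counts, auto_counts)^2
  fit <- if (degenerate) c(NA_real_, NA_real_) else
    stats::coef(stats::lm(auto_counts ~ true_counts))
  structure(list(
    data = data.frame(true = true_counts, auto = auto_counts,
                      error = auto_counts - true_counts),
    r_squared = r2, intercept = unname(fit[1L]), slope = unname(fit[2L]),
    degenerate = degenerate), class = "count_comparison")
}

#' @export
print.count_comparison <- function(x, ...) {
  cat(sprintf("<count_comparison> n = %d, R^2 = %.3f, fit auto = %.2f + %.2f * true\n",
              nrow(x$data), x$r_squared, x$intercept, x$slope))
  invisible(x)
}

#' Count error as a function of label density
#'
#' Bins sections by reference count (deciles by default) and reports the mean
#' signed error per bin, plus the Spearman correlation of error with density.
#' Merged, unresolvable clumps at densely labeled injection sites make the
#' error increasingly negative at high density.
#'
#' @param comparison A [compare_counts()] result.
#' @param n_bins Number of density bins (quantile-based).
#' @return List: `bins` (`data.frame`: `bin`, `mean_true`, `mean_error`,
#'   `n`), `spearman` (cor of error with true count).
#' @export
error_vs_density <- function(comparison, n_bins = 10L) {
  d <- comparison$data
  qs <- unique(stats::quantile(d$true, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(qs) < 3L) {
    stop_sectionmap("need at least 2 populated density bins", "value_error")
  }
  bin <- cut(d$true, qs, include.lowest = TRUE, labels = FALSE)
  agg <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    data.frame(bin = b, mean_true = mean(d$true[bin == b]),
               mean_error = mean(d$error[bin == b]), n = sum(bin == b))
  }))
  sp <- suppressWarnings(stats::cor(d$true, d$error, method = "spearman"))
  list(bins = agg, spearman = sp)
}
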