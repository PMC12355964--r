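# Large-scale agreement analysis between two sources of kinetic constants:
# paired log10 statistics (Spearman rho, Pearson R, R^2, MAD, RMSD) and
# detection of fixed-log-offset clusters diagnostic of systematic unit
# errors (s^-1 vs min^-1 shifts by log10 60; micro vs milli shifts by 3).

#' Paired log10 concordance statistics
#'
#' Pearson correlation on the paired log10 values, Spearman as the Pearson
#' correlation of mid-rank vectors, `R^2` as the squared Pearson
#' correlation, mean absolute deviation and root-mean-square deviation of
#' the log10 differences. With fewer than two pairs or a constant vector the
#' correlations are `NA`; the deviations are still computed.
#'
#' @param pairs a data frame with numeric columns `log10_a` and `log10_b`
#'   (finite).
#' @return a list of class `concordance_report` with `n`, `pearson_r`,
#'   `spearman_rho`, `r_squared`, `mad`, `rmsd`.
#' @export
paired_stats <- function(pairs) {
  a <- pairs$log10_a; b <- pairs$log10_b
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("paired_stats requires finite log10 values")
  }
  n <- length(a)
  d <- a - b
  degenerate <- n < 2L || stats::sd(a) == 0 || stats::sd(b) == 0
  pearson <- if (degenerate) NA_real_ else stats::cor(a, b)
  spearman <- if (degenerate) NA_real_ else
    stats::cor(a, b, method = "spearman")
  structure(list(
    n = n,
    pearson_r = pearson,
    spearman_rho = spearman,
    r_squared = if (is.na(pearson)) NA_real_ else pearson^2,
    mad = if (n) mean(abs(d)) else NA_real_,
    rmsd = if (n) sqrt(mean(d^2)) else NA_real_
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "Concordance (n=%d): Spearman rho %.3f, Pearson R %.3f (R^2 %.3f), MAD %.3f, RMSD %.3f\n",
    x$n, x$spearman_rho, x$pearson_r, x$r_squared, x$mad, x$rmsd))
  invisible(x)
}

offset_diagnosis <- function(delta) {
  if (abs(abs(delta) - log10(60)) < 1e-6) return("minute_vs_second")
  if (abs(abs(delta) - 3) < 1e-6) return("micro_vs_milli")
  "unknown_offset"
}

#' Detect fixed-log-offset clusters
#'
#' For each candidate offset delta, the members are pairs whose log10
#' difference lies within `tol` of delta; clusters reaching `min_members`
#' are reported with a diagnosis tag: `minute_vs_second` for |delta| near
#' log10(60) = 1.778 and `micro_vs_milli` for |delta| near 3.
#'
#' @param pairs data frame with `log10_a`, `log10_b`.
#' @param candidate_offsets offsets to test (default +/- log10(60), +/- 3).
#' @param tol membership half-width in log10 units (default 0.15).
#' @param min_members minimum cluster size to report (default 5).
#' @return a tibble with columns `offset`, `n_members`, `diagnosis`,
#'   `members` (list of row indices).
#' @export
detect_offset_clusters <- function(pairs,
                                   candidate_offsets = c(log10(60), -log10(60), 3, -3),
                                   tol = 0.15, min_members = 5L) {
  d <- pairs$log10_a - pairs$log10_b
  out <- list()
  for (delta in candidate_offsets) {
    members <- which(abs(d - delta) <= tol)
    if (length(members) >= min_members) {
      out[[length(out) + 1L]] <- tibble::tibble(
        offset = delta, n_members = length(members),
        diagnosis = offset_diagnosis(delta), members = list(members)
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(offset = double(), n_members = integer(),
                   diagnosis = character(), members = list())
}

#' Read a matched-pairs CSV and compute log10 pairs
#'
#' Input columns: key columns (free), `value_a`, `unit_a`, `value_b`,
#' `unit_b`, and `parameter` (kcat / km) selecting the canonical kind.
#'
#' @param path CSV file.
#' @return the input tibble with `log10_a` and `log10_b` appended.
#' @export
read_concordance_pairs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("value_a", "unit_a", "value_b", "unit_b", "parameter")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("pairs file missing columns: ",
                            paste(missing, collapse = ", "))
  canon <- function(v, u, p) {
    kind <- ifelse(p == "kcat", "rate", "concentration")
    vapply(seq_along(v), function(i) {
      parse_quantity(paste(v[i], u[i]), kind[i])$canonical_value
    }, numeric(1))
  }
  df$log10_a <- log10_value(canon(df$value_a, df$unit_a, df$parameter))
  df$log10_b <- log10_value(canon(df$value_b, df$unit_b, df$parameter))
  df
}

#' Export flagged cluster members for manual review
#'
#' @param pairs the pairs table handed to [detect_offset_clusters()].
#' @param clusters the cluster tibble it returned.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_cluster_members <- function(pairs, clusters, path) {
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    idx <- clusters$members[[i]]
    sub <- tibble::as_tibble(pairs[idx, , drop = FALSE])
    sub$offset <- clusters$offset[i]
    sub$diagnosis <- clusters$diagnosis[i]
    rows[[length(rows) + 1L]] <- sub
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  out <- dplyr::select(out, -dplyr::any_of("members"))
  readr::write_csv(out, path)
  invisible(path)
}
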