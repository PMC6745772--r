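#' Qualitative rating of a coefficient of variation
#'
#' Bands used for observer agreement of normalized circumferential strain:
#' good (<= 0.20), fair (0.21-0.30], poor (> 0.30).
#'
#' @param cov non-negative coefficient of variation.
#' @return `"good"`, `"fair"` or `"poor"`.
#' @export
rate_cov <- function(cov) {
  if (!is.numeric(cov) || any(!is.finite(cov)) || any(cov < 0))
    .stopf("invalid 'cov': must be non-negative")
  ifelse(cov <= 0.20, "good", ifelse(cov <= 0.30, "fair", "poor"))
}

# Local extrema of a circular vector under strict inequality; plateaus (runs
# of equal values) count once at their lowest sector index and must strictly
# exceed/undercut both adjacent runs.
.circular_extrema <- function(v) {
  n <- length(v)
  # collapse circular runs of equal values
  run_id <- cumsum(c(TRUE, v[-1L] != v[-n]))
  if (n > 1L && v[1L] == v[n]) run_id[run_id == run_id[n]] <- 1L
  runs <- sort(unique(run_id))
  rv <- vapply(runs, function(k) v[which(run_id == k)[1L]], numeric(1L))
  rs <- vapply(runs, function(k) min(which(run_id == k)), integer(1L))
  m <- length(runs)
  if (m < 2L) return(list(maxima = integer(0L), minima = integer(0L)))
  prev <- rv[c(m, seq_len(m - 1L))]
  nxt <- rv[c(seq_len(m)[-1L], 1L)]
  list(maxima = rs[rv > prev & rv > nxt], minima = rs[rv < prev & rv < nxt])
}

# pick the k most extreme of the candidate sectors by value
.top_extrema <- function(v, idx, k, decreasing) {
  if (!length(idx)) return(integer(0L))
  idx[order(v[idx], decreasing = decreasing)][seq_len(min(k, length(idx)))]
}

#' Observer-agreement metrics between two NCS sector maps
#'
#' Compares two normalized circumferential strain maps of the same scan
#' (e.g. two readers, or one reader twice). Sector-wise differences
#' \eqn{\Delta_s = b_s - a_s} yield the mean absolute difference and the
#' coefficient of variation, defined as the sample standard deviation of the
#' non-absolute differences divided by the mean NCS, which is 1 by
#' construction. The same metrics are recomputed on the local extrema only:
#' the two largest local maxima and two smallest local minima of each map on
#' the circular 16-vector (strict inequality against both neighbors), each
#' extremum of map `a` paired with the nearest same-type extremum of map `b`
#' by circular sector distance.
#'
#' @param ncs_a,ncs_b length-16 NCS vectors, each with mean 1 (tolerance
#'   1e-9).
#' @return An object of class `reproducibility_report`: `abs_mean_diff`,
#'   `cov_mean`, `abs_extrema_diff`, `cov_extrema`, `extrema_sector_diff`,
#'   `n_extrema_pairs`, `rating` (from `cov_mean`) and `rating_extrema`.
#' @export
compare_maps <- function(ncs_a, ncs_b) {
  ncs_a <- as.numeric(ncs_a); ncs_b <- as.numeric(ncs_b)
  if (length(ncs_a) != length(ncs_b))
    .stopf("maps must have the same number of sectors")
  n <- length(ncs_a)
  if (anyNA(ncs_a) || anyNA(ncs_b))
    .stopf("maps must be complete (no missing sectors)")
  for (nm in c("ncs_a", "ncs_b")) {
    m <- mean(get(nm))
    if (abs(m - 1) > 1e-9)
      .stopf("'%s' is not normalized: mean = %.6f (expected 1)", nm, m)
  }
  delta <- ncs_b - ncs_a
  abs_mean_diff <- mean(abs(delta))
  cov_mean <- stats::sd(delta) / 1        # mean NCS is 1 by construction

  ex_a <- .circular_extrema(ncs_a)
  ex_b <- .circular_extrema(ncs_b)
  pairs <- list(
    list(a = .top_extrema(ncs_a, ex_a$maxima, 2L, TRUE),
         b = .top_extrema(ncs_b, ex_b$maxima, 2L, TRUE)),
    list(a = .top_extrema(ncs_a, ex_a$minima, 2L, FALSE),
         b = .top_extrema(ncs_b, ex_b$minima, 2L, FALSE)))
  d_val <- d_sec <- numeric(0L)
  for (p in pairs) {
    if (!length(p$a) || !length(p$b)) next
    for (sa in p$a) {
      dist <- .circ_sector_dist(sa, p$b, n)
      sb <- p$b[which.min(dist)]
      d_sec <- c(d_sec, min(dist))
      d_val <- c(d_val, ncs_b[sb] - ncs_a[sa])
    }
  }
  n_pairs <- length(d_val)
  abs_extrema_diff <- if (n_pairs) mean(abs(d_val)) else NA_real_
  cov_extrema <- if (n_pairs >= 2L) stats::sd(d_val) / 1 else NA_real_
  extrema_sector_diff <- if (n_pairs) mean(d_sec) else NA_real_

  structure(list(abs_mean_diff = abs_mean_diff, cov_mean = cov_mean,
                 abs_extrema_diff = abs_extrema_diff, cov_extrema = cov_extrema,
                 extrema_sector_diff = extrema_sector_diff,
                 n_extrema_pairs = n_pairs,
                 rating = rate_cov(cov_mean),
                 rating_extrema = if (is.na(cov_extrema)) NA_character_
                                  else rate_cov(cov_extrema)),
            class = "reproducibility_report")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat("NCS reproducibility:\n")
  cat(sprintf("  all sectors : abs mean diff %.3f, CoV %.3f (%s)\n",
              x$abs_mean_diff, x$cov_mean, x$rating))
  if (!is.na(x$abs_extrema_diff))
    cat(sprintf("  extrema     : abs diff %.3f, CoV %s (%s), sector diff %.2f over %d pairs\n",
                x$abs_extrema_diff,
                ifelse(is.na(x$cov_extrema), "NA", sprintf("%.3f", x$cov_extrema)),
                ifelse(is.na(x$rating_extrema), "NA", x$rating_extrema),
                x$extrema_sector_diff, x$n_extrema_pairs))
  invisible(x)
}

#' Three-way observer comparison
#'
#' Inter-observer agreement when one reader analysed the scan twice: the
#' second reader's map is compared against each of the first reader's two
#' analyses and the two pairwise reports are averaged metric-by-metric.
#'
#' @param ncs_reader2 the second reader's NCS map.
#' @param ncs_reader1_a,ncs_reader1_b the first reader's two NCS maps.
#' @return A `reproducibility_report` with averaged metrics.
#' @export
compare_three_way <- function(ncs_reader2, ncs_reader1_a, ncs_reader1_b) {
  r1 <- compare_maps(ncs_reader1_a, ncs_reader2)
  r2 <- compare_maps(ncs_reader1_b, ncs_reader2)
  avg <- function(f) mean(c(r1[[f]], r2[[f]]), na.rm = TRUE)
  cov_mean <- avg("cov_mean")
  cov_ex <- avg("cov_extrema")
  structure(list(abs_mean_diff = avg("abs_mean_diff"), cov_mean = cov_mean,
                 abs_extrema_diff = avg("abs_extrema_diff"),
                 cov_extrema = cov_ex,
                 extrema_sector_diff = avg("extrema_sector_diff"),
                 n_extrema_pairs = r1$n_extrema_pairs + r2$n_extrema_pairs,
                 rating = rate_cov(cov_mean),
                 rating_extrema = if (is.na(cov_ex)) NA_character_ else rate_cov(cov_ex)),
            class = "reproducibility_report")
}
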