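#' @include morphometry.R
NULL

# Null distribution of the Mann-Whitney U statistic for tie-free samples:
# counts[u + 1] = number of the choose(n1+n2, n1) rank arrangements with
# U = u. U counts partitions fitting an n1 x n2 box; DP over the box
# recurrence P(i, j, u) = P(i-1, j, u - j) + P(i, j-1, u).
.u_null_counts <- function(n1, n2) {
  umax <- n1 * n2
  prev <- matrix(0, nrow = n2 + 1L, ncol = umax + 1L)  # i = 0
  prev[, 1L] <- 1
  for (i in seq_len(n1)) {
    cur <- matrix(0, nrow = n2 + 1L, ncol = umax + 1L)
    cur[1L, 1L] <- 1                                    # j = 0
    for (j in seq_len(n2)) {
      shifted <- c(rep(0, j), prev[j + 1L, seq_len(umax + 1L - j)])
      cur[j + 1L, ] <- shifted + cur[j, ]
    }
    prev <- cur
  }
  prev[n2 + 1L, ]
}

#' Mann-Whitney U test for two independent samples
#'
#' The U statistic is computed from midranks (so ties contribute half
#' units). The two-sided p-value is exact -- by enumeration of the null
#' distribution of U -- when the combined sample size is at most
#' \code{exactLimit} and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' The statistic reported is U of \code{group1}; swapping the groups maps
#' U to n1*n2 - U and leaves p unchanged.
#'
#' @param group1,group2 numeric vectors (each non-empty).
#' @param exactLimit combined-size bound for the exact branch (default 12).
#' @return A list: \code{u} (U of group1), \code{p} (two-sided),
#'   \code{n1}, \code{n2}, \code{exact} (logical).
#' @export
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mannWhitneyU <- function(group1, group2, exactLimit = 12L) {
  g1 <- as.numeric(group1); g2 <- as.numeric(group2)
  if (!length(g1) || !length(g2) || anyNA(g1) || anyNA(g2))
    stop("both groups must be non-empty and free of NA", call. = FALSE)
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  r <- rank(c(g1, g2))                      # midranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(g1, g2)) > 0L
  exact <- !ties && n <= exactLimit
  if (exact) {
    counts <- .u_null_counts(n1, n2)
    u_min <- min(u1, n1 * n2 - u1)
    p <- min(1, 2 * sum(counts[seq_len(u_min + 1L)]) / sum(counts))
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(g1, g2))
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u1 - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
  }
  list(u = u1, p = p, n1 = n1, n2 = n2, exact = exact)
}

#' Tukey box-and-whisker summary
#'
#' Quartiles by linear interpolation of order statistics (the "type 7"
#' quantile convention); whiskers at the most extreme data points within
#' 1.5 x IQR of the quartiles; points beyond the whiskers are outliers.
#'
#' @param values numeric vector (non-empty).
#' @return A list: \code{median}, \code{q1}, \code{q3}, \code{iqr},
#'   \code{whiskerLow}, \code{whiskerHigh}, \code{outliers}, \code{n}.
#' @export
#' @examples
#' tukeyBoxStats(c(1:7, 100))  # 100 is flagged as an outlier
tukeyBoxStats <- function(values) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  if (!length(x)) stop("no values to summarize", call. = FALSE)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whiskerLow = min(x[inside]), whiskerHigh = max(x[inside]),
       outliers = sort(x[!inside]), n = length(x))
}

.compare_params <- c("media_area_um2", "lumen_area_um2", "plaque_area_um2",
                     "collagen_area_um2", "lipid_area_um2",
                     "total_vessel_area_um2", "relative_lumen_pct",
                     "relative_plaque_pct", "relative_collagen_pct",
                     "relative_lipid_pct")

#' Compare morphometric parameters between two groups of sections
#'
#' For each of the six absolute areas (media, lumen, plaque, collagen,
#' lipid, total vessel) and four relative parameters (relative lumen,
#' plaque, collagen, lipid), runs \code{\link{mannWhitneyU}} between the
#' two segment groups and computes Tukey box statistics per group. Each
#' parameter is tested marginally at \code{alpha} (no multiple-testing
#' correction by default, a Holm adjustment can be enabled).
#'
#' @param records list of \code{\linkS4class{MorphometryRecord}}s or a
#'   data.frame from \code{\link{morphometryTable}} /
#'   \code{\link{readMorphometryCSV}}.
#' @param group1,group2 the two \code{segment_label} values to compare
#'   (defaults \code{"proximal"} vs \code{"distal"}).
#' @param alpha significance level (default 0.05).
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @return A data.frame with one row per parameter: \code{parameter},
#'   \code{n1}, \code{n2}, \code{u_statistic}, \code{p_value},
#'   \code{significant}, and per-group box statistics
#'   (\code{median/q1/q3/whisker_low/whisker_high/n_outliers} suffixed
#'   \code{_1}/\code{_2}).
#' @export
compareSegments <- function(records, group1 = "proximal", group2 = "distal",
                            alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  tab <- if (is.data.frame(records)) records else morphometryTable(records)
  g1 <- tab[tab$segment_label == group1, , drop = FALSE]
  g2 <- tab[tab$segment_label == group2, , drop = FALSE]
  if (!nrow(g1) || !nrow(g2))
    stop("both groups must be non-empty (labels '", group1, "' and '",
         group2, "')", call. = FALSE)
  rows <- lapply(.compare_params, function(p) {
    x1 <- g1[[p]]; x1 <- x1[!is.na(x1)]
    x2 <- g2[[p]]; x2 <- x2[!is.na(x2)]
    if (!length(x1) || !length(x2))
      return(data.frame(parameter = p, n1 = length(x1), n2 = length(x2),
                        u_statistic = NA_real_, p_value = NA_real_))
    mw <- mannWhitneyU(x1, x2)
    b1 <- tukeyBoxStats(x1); b2 <- tukeyBoxStats(x2)
    data.frame(parameter = p, n1 = mw$n1, n2 = mw$n2,
               u_statistic = mw$u, p_value = mw$p,
               median_1 = b1$median, q1_1 = b1$q1, q3_1 = b1$q3,
               whisker_low_1 = b1$whiskerLow, whisker_high_1 = b1$whiskerHigh,
               n_outliers_1 = length(b1$outliers),
               median_2 = b2$median, q1_2 = b2$q1, q3_2 = b2$q3,
               whisker_low_2 = b2$whiskerLow, whisker_high_2 = b2$whiskerHigh,
               n_outliers_2 = length(b2$outliers))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    # pad rows that lack box columns (all-NA parameter in one group)
    miss <- setdiff(names(rows[[which.max(vapply(rows, ncol, 1L))]]), names(r))
    for (m in miss) r[[m]] <- NA_real_
    r
  }))
  p_used <- if (adjust == "holm") stats::p.adjust(out$p_value, "holm")
            else out$p_value
  out$p_adjusted <- if (adjust == "holm") p_used else out$p_value
  out$significant <- !is.na(p_used) & p_used < alpha
  rownames(out) <- NULL
  out
}

#' Write a group-comparison table as CSV or JSON
#'
#' @param comparison data.frame from \code{\link{compareSegments}}.
#' @param path output path (.csv or .json by extension).
#' @return \code{path}, invisibly.
#' @export
writeComparison <- function(comparison, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    writeLines(jsonlite::toJSON(comparison, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA, na = "null"),
               path)
  } else {
    write.csv(comparison, path, row.names = FALSE)
  }
  invisible(path)
}
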