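# Statistical core: the three-correlation suite, Fisher-z comparison of two
# correlations, top-k fold-change lists, the permutation test for top-k list
# overlap with an exact hypergeometric oracle, threshold concordance, and
# pairwise reproducibility reports.

#' Three-measure correlation suite
#'
#' Pearson correlation of the untransformed values, Pearson correlation of
#' the log2-transformed values, and the Spearman rank correlation (average
#' ranks for ties), all on the identical pair set. Values must be strictly
#' positive so the log transform applies.
#'
#' @param x,y Equal-length numeric vectors of positive values (n >= 3).
#' @return Object of class `correlation_triple`: list with `pearson`,
#'   `pearson_log2`, `spearman`, `n`.
#' @export
#' @examples
#' correlation_suite(c(1, 2, 3, 4), c(1, 3, 2, 4))  # pearson = spearman = 0.8
correlation_suite <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  bad <- sum(!is.finite(x) | x <= 0 | !is.finite(y) | y <= 0)
  if (bad > 0)
    stop(bad, " non-positive or non-finite value(s); log transform undefined",
         call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  structure(list(pearson = cor(x, y),
                 pearson_log2 = cor(log2(x), log2(y)),
                 spearman = cor(x, y, method = "spearman"),
                 n = length(x)),
            class = "correlation_triple")
}

#' @export
print.correlation_triple <- function(x, ...) {
  cat(sprintf("Pearson %.3f | Pearson(log2) %.3f | Spearman %.3f (n = %d)\n",
              x$pearson, x$pearson_log2, x$spearman, x$n))
  invisible(x)
}

#' Compare two correlation coefficients via Fisher's z-transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value from the standard normal. This is the independent-samples
#' form; it does not account for the two correlations sharing a variable.
#'
#' @param r1,r2 Correlation coefficients with `|r| < 1`.
#' @param n1,n2 Pair counts (> 3).
#' @return List with `z` and `p_value`.
#' @export
#' @examples
#' compare_correlations_fisher_z(0.56, 76, 0.48, 76)  # z ~ 0.66, p > 0.05
compare_correlations_fisher_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 (Fisher transform infinite at 1)", call. = FALSE)
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Top-k probes by fold change
#'
#' Probes sorted by fold change (descending for `"highest"`, ascending for
#' `"lowest"`), ties broken by ascending probe id in C-locale (lexicographic)
#' order; the first `k` ids are returned.
#'
#' @param fc_table A [fold_change_table()].
#' @param k List size, `k <= nrow(fc_table)`.
#' @param direction `"highest"` or `"lowest"`.
#' @return Character vector of `k` probe ids.
#' @export
top_k_list <- function(fc_table, k, direction = c("highest", "lowest")) {
  direction <- match.arg(direction)
  if (k > nrow(fc_table))
    stop("k exceeds the number of probes", call. = FALSE)
  ord <- if (direction == "highest")
    order(-fc_table$fc, fc_table$probe_id, method = "radix")
  else
    order(fc_table$fc, fc_table$probe_id, method = "radix")
  fc_table$probe_id[ord][seq_len(k)]
}

#' Permutation test for the overlap of two top-k lists
#'
#' Observes `n = |list_a intersect list_b|` and compares it with the null in
#' which both lists are independent uniform k-subsets of a universe of
#' `universe_size` probes: each of `n_trials` trials draws two such subsets
#' without replacement and records their overlap. The p-value is the
#' proportion of trials with overlap greater than or equal to the observed
#' one (so `n = 0` always gives p = 1).
#'
#' @param list_a,list_b Character vectors of equal length `k`, no duplicates
#'   within a list.
#' @param universe_size Size of the probe universe the lists were drawn from.
#' @param n_trials Number of random trials (default 10000).
#' @param seed Seed for the trial draws.
#' @return Object of class `overlap_test_result`: `k`, `n_observed`,
#'   `n_trials`, `n_trials_ge` (count of trials at or above the observed
#'   overlap), `p_value`, `seed`, `universe_size`, and the raw
#'   `trial_overlaps` vector.
#' @seealso [overlap_exact_pvalue()] for the closed-form null.
#' @export
overlap_permutation_test <- function(list_a, list_b, universe_size,
                                     n_trials = 10000L, seed = 1L) {
  if (anyDuplicated(list_a) || anyDuplicated(list_b))
    stop("duplicate ids within a list", call. = FALSE)
  k <- length(list_a)
  if (length(list_b) != k) stop("lists differ in length", call. = FALSE)
  if (k > universe_size) stop("k exceeds the universe size", call. = FALSE)
  n_observed <- length(intersect(list_a, list_b))
  overlaps <- withr::with_seed(seed, {
    member <- logical(universe_size)
    vapply(seq_len(n_trials), function(i) {
      a <- sample.int(universe_size, k)
      b <- sample.int(universe_size, k)
      member[a] <- TRUE
      o <- sum(member[b])
      member[a] <- FALSE
      o
    }, integer(1))
  })
  n_ge <- sum(overlaps >= n_observed)
  structure(list(k = k, n_observed = n_observed, n_trials = n_trials,
                 n_trials_ge = n_ge, p_value = n_ge / n_trials,
                 seed = seed, universe_size = universe_size,
                 trial_overlaps = overlaps),
            class = "overlap_test_result")
}

#' @export
print.overlap_test_result <- function(x, ...) {
  cat(sprintf("Top-%d overlap: n = %d of universe %d, p = %.4f (%d/%d trials)\n",
              x$k, x$n_observed, x$universe_size, x$p_value, x$n_trials_ge,
              x$n_trials))
  invisible(x)
}

#' Exact tail probability of the top-k overlap null
#'
#' `P(X >= n_observed)` where `X ~ Hypergeometric(universe_size, k, k)` is
#' the overlap of two independent uniform k-subsets of the universe.
#' Computed by summing log-binomial terms, serving as the closed-form oracle
#' for [overlap_permutation_test()].
#'
#' @param k List size.
#' @param n_observed Observed overlap, `0 <= n_observed <= k`.
#' @param universe_size Universe size, `>= k`.
#' @return The tail probability.
#' @export
#' @examples
#' overlap_exact_pvalue(5, 2, 20)  # 0.366099
overlap_exact_pvalue <- function(k, n_observed, universe_size) {
  if (k < 0 || k > universe_size)
    stop("need 0 <= k <= universe_size", call. = FALSE)
  if (n_observed < 0 || n_observed > k)
    stop("need 0 <= n_observed <= k", call. = FALSE)
  if (n_observed == 0) return(1)
  i <- seq(n_observed, k)
  sum(exp(lchoose(k, i) + lchoose(universe_size - k, k - i) -
            lchoose(universe_size, k)))
}

#' Percent of threshold-exceeding probes confirmed on a second platform
#'
#' @param n_both Probes above threshold on both platforms.
#' @param n_above Probes above threshold on the reference platform.
#' @return `100 * n_both / n_above` rounded to one decimal; `NA` when
#'   `n_above` is 0.
#' @export
#' @examples
#' percent_concordant(31, 225)  # 13.8
percent_concordant <- function(n_both, n_above) {
  if (n_above == 0) return(NA_real_)
  round(100 * n_both / n_above, 1)
}

#' Fold-change threshold concordance between two platforms
#'
#' Counts probes whose fold change exceeds `threshold` in `fc_a`, and among
#' those, how many also exceed it in `fc_b`, over the common probe set.
#'
#' @param fc_a,fc_b [fold_change_table()]s sharing probes.
#' @param threshold Positive fold-change threshold (default 5).
#' @return List with `n_a_above`, `n_both_above` and `percent`
#'   (one decimal; `NA` when no probe passes in `fc_a`).
#' @export
threshold_concordance <- function(fc_a, fc_b, threshold = 5) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  common <- intersect(fc_a$probe_id, fc_b$probe_id)
  if (!length(common)) stop("no probes in common", call. = FALSE)
  a <- fc_a$fc[match(common, fc_a$probe_id)]
  b <- fc_b$fc[match(common, fc_b$probe_id)]
  above <- a > threshold
  both <- above & b > threshold
  list(n_a_above = sum(above), n_both_above = sum(both),
       percent = percent_concordant(sum(both), sum(above)))
}

# Which channel carries which state, given the scan's orientation.
state_intensities <- function(scan, state) {
  z <- scan$intensities[!scan$intensities$excluded, ]
  qui_is_cy5 <- scan$orientation == "qui-cy5"
  v <- if (state == "qui") {
    if (qui_is_cy5) z$cy5 else z$cy3
  } else {
    if (qui_is_cy5) z$cy3 else z$cy5
  }
  setNames(v, z$probe_id)
}

#' Pairwise reproducibility report
#'
#' Applies [correlation_suite()] to every unordered pair of sources. Two
#' input modes:
#' * a named list of [fold_change_table()]s — one row per pair comparing FC
#'   values (measure `"fc"`);
#' * a named list of [array_scan()]s — two rows per pair comparing per-state
#'   intensities (measures `"intensity_pro"`, `"intensity_qui"`).
#'
#' Each pair is evaluated on the probes the two sources share.
#'
#' @param sources Named list (>= 2 elements) of fold-change tables or array
#'   scans.
#' @return Data frame with `source_a`, `source_b`, `measure`, `pearson`,
#'   `pearson_log2`, `spearman`, `n`.
#' @export
reproducibility_report <- function(sources) {
  if (length(sources) < 2L) stop("need at least 2 sources", call. = FALSE)
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    stop("sources must be named", call. = FALSE)
  is_scan <- vapply(sources, inherits, logical(1), "array_scan")
  rows <- list()
  nm <- names(sources)
  add_row <- function(a, b, measure, x, y) {
    if (length(x) < 3L)
      stop("fewer than 3 shared probes for pair ", a, "/", b, call. = FALSE)
    ct <- correlation_suite(x, y)
    rows[[length(rows) + 1L]] <<- data.frame(
      source_a = a, source_b = b, measure = measure,
      pearson = ct$pearson, pearson_log2 = ct$pearson_log2,
      spearman = ct$spearman, n = ct$n, stringsAsFactors = FALSE)
  }
  for (i in seq_len(length(sources) - 1L)) {
    for (j in seq((i + 1L), length(sources))) {
      if (all(is_scan)) {
        for (state in c("pro", "qui")) {
          xi <- state_intensities(sources[[i]], state)
          yj <- state_intensities(sources[[j]], state)
          common <- intersect(names(xi), names(yj))
          add_row(nm[i], nm[j], paste0("intensity_", state),
                  xi[common], yj[common])
        }
      } else {
        a <- sources[[i]]; b <- sources[[j]]
        common <- intersect(a$probe_id, b$probe_id)
        add_row(nm[i], nm[j], "fc",
                a$fc[match(common, a$probe_id)],
                b$fc[match(common, b$probe_id)])
      }
    }
  }
  do.call(rbind, rows)
}
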