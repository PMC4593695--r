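# Two-channel microarray processing: crosstalk unmixing, MA-LOWESS
# within-array normalization, fold changes under a dye orientation,
# dye swapping and geometric-mean combination.

#' Construct a two-channel array scan
#'
#' @param array_id Scan label, e.g. `"QP1"`.
#' @param orientation `"qui-cy5"` if the quiescent sample was labelled with
#'   Cy5, `"qui-cy3"` otherwise (a dye swap). The orientation is metadata:
#'   dye swapping never relabels intensities.
#' @param intensities Data frame with columns `probe_id`, `cy3`, `cy5` and
#'   logical `excluded` (spots removed for insufficient signal).
#' @return An object of class `array_scan`.
#' @export
array_scan <- function(array_id, orientation, intensities) {
  orientation <- match.arg(orientation, c("qui-cy5", "qui-cy3"))
  stopifnot(is.data.frame(intensities),
            all(c("probe_id", "cy3", "cy5") %in% names(intensities)))
  if (is.null(intensities$excluded)) intensities$excluded <- FALSE
  if (anyDuplicated(intensities$probe_id))
    stop("duplicate probe_id in array scan", call. = FALSE)
  if (any(intensities$cy3 < 0 | intensities$cy5 < 0, na.rm = TRUE))
    stop("negative intensities", call. = FALSE)
  structure(list(array_id = array_id, orientation = orientation,
                 intensities = intensities),
            class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("Array scan %s (%s): %d probes, %d excluded\n", x$array_id,
              x$orientation, nrow(x$intensities), sum(x$intensities$excluded)))
  invisible(x)
}

#' Correct fluorophore cross-talk between the two channels
#'
#' Inverts the symmetric linear mixing model
#' `observed_A = clean_A + alpha * clean_B` (both directions) exactly:
#' `clean_A = (obs_A - alpha * obs_B) / (1 - alpha^2)`. Results that come out
#' negative are floored at a small positive epsilon and flagged in a
#' `floored` column.
#'
#' @param scan An [array_scan()].
#' @param alpha Crosstalk proportion in `[0, 0.5)`; `alpha >= 0.5` is
#'   rejected as non-invertible by policy.
#' @param eps Floor applied to negative unmixed intensities.
#' @return The corrected [array_scan()].
#' @export
#' @examples
#' sc <- array_scan("QP1", "qui-cy5",
#'                  data.frame(probe_id = "p1", cy3 = 105, cy5 = 60))
#' cross_channel_correct(sc, 0.1)$intensities[, c("cy3", "cy5")]  # 100, 50
cross_channel_correct <- function(scan, alpha, eps = 1e-6) {
  stopifnot(inherits(scan, "array_scan"))
  if (alpha < 0 || alpha >= 0.5)
    stop("alpha must lie in [0, 0.5)", call. = FALSE)
  z <- scan$intensities
  denom <- 1 - alpha^2
  cy3 <- (z$cy3 - alpha * z$cy5) / denom
  cy5 <- (z$cy5 - alpha * z$cy3) / denom
  floored <- cy3 < 0 | cy5 < 0
  z$cy3 <- pmax(cy3, eps)
  z$cy5 <- pmax(cy5, eps)
  z$floored <- floored
  scan$intensities <- z
  scan
}

#' Within-array MA-LOWESS normalization
#'
#' Computes `M = log2(cy5 / cy3)` and `A = 0.5 * log2(cy5 * cy3)` over
#' retained probes, fits a LOWESS curve of M on A (tricube weights,
#' `iter` robustness iterations), subtracts the fitted trend from M, and
#' reconstructs channels preserving A. This removes intensity-dependent dye
#' bias within one array.
#'
#' @param scan An [array_scan()] whose retained probes have strictly positive
#'   intensities in both channels.
#' @param span LOWESS smoother span (proportion of points), default 0.3.
#' @param iter Robustness iterations, default 3.
#' @return The normalized [array_scan()].
#' @export
lowess_normalize <- function(scan, span = 0.3, iter = 3L) {
  stopifnot(inherits(scan, "array_scan"))
  z <- scan$intensities
  keep <- !z$excluded
  if (sum(keep) < 10L)
    stop("fewer than 10 retained probes: LOWESS curve underdetermined",
         call. = FALSE)
  if (any(z$cy3[keep] <= 0 | z$cy5[keep] <= 0))
    stop("retained probes must have positive intensities in both channels",
         call. = FALSE)
  M <- log2(z$cy5[keep]) - log2(z$cy3[keep])
  A <- 0.5 * (log2(z$cy5[keep]) + log2(z$cy3[keep]))
  fit <- lowess(A, M, f = span, iter = iter)
  Mhat <- approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  Mn <- M - Mhat
  z$cy5[keep] <- 2^(A + Mn / 2)
  z$cy3[keep] <- 2^(A - Mn / 2)
  scan$intensities <- z
  scan
}

#' Construct a fold-change table
#'
#' @param probe_id Probe identifiers.
#' @param fc Positive fold changes (QUI over PRO).
#' @param source Label of the producing platform/array.
#' @return Data frame of class `fold_change_table` with columns `probe_id`,
#'   `fc` and `log2_fc` and a `source` attribute.
#' @export
fold_change_table <- function(probe_id, fc, source = "unknown") {
  if (any(!is.finite(fc) | fc <= 0))
    stop("fold changes must be finite and > 0", call. = FALSE)
  if (anyDuplicated(probe_id)) stop("duplicate probe_id", call. = FALSE)
  out <- data.frame(probe_id = as.character(probe_id), fc = fc,
                    log2_fc = log2(fc), stringsAsFactors = FALSE)
  attr(out, "source") <- source
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Per-probe fold changes from one array scan
#'
#' `fc = intensity(QUI channel) / intensity(PRO channel)` for each retained
#' probe, where the QUI channel is given by the scan's dye orientation.
#' Probes with a zero PRO-channel intensity are excluded (with a message
#' naming how many).
#'
#' @param scan An [array_scan()].
#' @return A [fold_change_table()] labelled with the scan's `array_id`.
#' @export
array_fold_changes <- function(scan) {
  stopifnot(inherits(scan, "array_scan"))
  z <- scan$intensities[!scan$intensities$excluded, ]
  qui <- if (scan$orientation == "qui-cy5") z$cy5 else z$cy3
  pro <- if (scan$orientation == "qui-cy5") z$cy3 else z$cy5
  drop <- pro == 0
  if (any(drop))
    message(sum(drop), " probe(s) dropped: zero PRO-channel intensity")
  fold_change_table(z$probe_id[!drop], qui[!drop] / pro[!drop],
                    source = scan$array_id)
}

#' Artificially swap the dye orientation of a scan
#'
#' Flips the orientation metadata; intensities are untouched. Downstream
#' fold changes become per-probe reciprocals. Applying the swap twice
#' restores the original analysis.
#'
#' @param scan An [array_scan()].
#' @return The scan with flipped orientation.
#' @export
swap_orientation <- function(scan) {
  stopifnot(inherits(scan, "array_scan"))
  scan$orientation <- if (scan$orientation == "qui-cy5") "qui-cy3" else "qui-cy5"
  scan
}

#' Combine fold-change tables by the geometric mean
#'
#' Over probes present in every table, computes
#' `fc = (prod fc_i)^(1/n)`, i.e. the arithmetic mean on the log2 scale.
#'
#' @param tables A list of [fold_change_table()]s (at least one).
#' @param source Label for the combined table (default `"all"`).
#' @return A [fold_change_table()] over the common probes.
#' @export
#' @examples
#' a <- fold_change_table("p1", 2); b <- fold_change_table("p1", 8)
#' combine_arrays_geometric_mean(list(a, b))$fc  # 4
combine_arrays_geometric_mean <- function(tables, source = "all") {
  if (!length(tables)) stop("need at least one fold-change table", call. = FALSE)
  common <- Reduce(intersect, lapply(tables, `[[`, "probe_id"))
  if (!length(common)) stop("no probes common to all tables", call. = FALSE)
  common <- sort(common)
  logs <- vapply(tables, function(tb) tb$log2_fc[match(common, tb$probe_id)],
                 numeric(length(common)))
  logs <- matrix(logs, nrow = length(common))
  fold_change_table(common, 2^rowMeans(logs), source = source)
}
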