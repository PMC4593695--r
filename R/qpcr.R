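# qRT-PCR relative quantification (delta-delta-CT against multiple
# normalizer genes) and gene-by-gene platform adjudication.

#' Average replicate CT values into one value per gene and state
#'
#' Technical replicates are averaged at the CT stage, before any
#' delta-delta-CT arithmetic.
#'
#' @param ct_table Long-format data frame with `gene`, `state`
#'   (`"pro"`/`"qui"`), `ct` (and optionally `replicate`).
#' @return Data frame with one row per gene: `gene`, `ct_pro`, `ct_qui`.
#' @export
average_ct <- function(ct_table) {
  stopifnot(all(c("gene", "state", "ct") %in% names(ct_table)))
  if (any(!is.finite(ct_table$ct) | ct_table$ct <= 0))
    stop("CT values must be finite and > 0", call. = FALSE)
  m <- aggregate(ct ~ gene + state, data = ct_table, FUN = mean)
  pro <- m[m$state == "pro", ]
  qui <- m[m$state == "qui", ]
  genes <- sort(unique(ct_table$gene))
  if (!all(genes %in% pro$gene) || !all(genes %in% qui$gene))
    stop("every gene needs CT values in both states", call. = FALSE)
  data.frame(gene = genes,
             ct_pro = pro$ct[match(genes, pro$gene)],
             ct_qui = qui$ct[match(genes, qui$gene)],
             stringsAsFactors = FALSE)
}

#' Delta-delta-CT fold change of a target gene against one normalizer
#'
#' `ddCT = (CT_target,QUI - CT_norm,QUI) - (CT_target,PRO - CT_norm,PRO)`;
#' `fc = 2^(-ddCT)`, the classical relative-quantification formula assuming
#' 100% amplification efficiency.
#'
#' @param target,normalizer Lists or one-row data frames with `ct_pro` and
#'   `ct_qui`.
#' @return The positive fold change (QUI over PRO).
#' @export
#' @examples
#' ddct_fold_change(list(ct_pro = 20, ct_qui = 18),
#'                  list(ct_pro = 15, ct_qui = 15))  # 4
ddct_fold_change <- function(target, normalizer) {
  need <- function(m, nm) {
    v <- m[[nm]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("missing CT value: ", nm, call. = FALSE)
    v
  }
  ddct <- (need(target, "ct_qui") - need(normalizer, "ct_qui")) -
    (need(target, "ct_pro") - need(normalizer, "ct_pro"))
  2^(-ddct)
}

#' Average per-normalizer fold changes into one value
#'
#' The arithmetic mean of the fold changes computed against each normalizer
#' gene; a geometric mean (mean on the log scale) is available as the
#' standard alternative.
#'
#' @param fcs Positive fold changes, one per normalizer.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return The averaged fold change.
#' @export
average_over_normalizers <- function(fcs, method = c("arithmetic",
                                                     "geometric")) {
  method <- match.arg(method)
  if (!length(fcs)) stop("need at least one fold change", call. = FALSE)
  if (any(fcs <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (method == "arithmetic") mean(fcs) else 2^mean(log2(fcs))
}

#' Gene-level microarray fold change from multiple probes
#'
#' When several array probes interrogate one gene, the gene's fold change is
#' the geometric mean of the probe fold changes.
#'
#' @param probe_fcs Positive per-probe fold changes (>= 1 value).
#' @return The geometric-mean fold change.
#' @export
#' @examples
#' gene_level_array_fc(c(1, 4, 16))  # 4
gene_level_array_fc <- function(probe_fcs) {
  if (!length(probe_fcs)) stop("need at least one probe", call. = FALSE)
  if (any(probe_fcs <= 0)) stop("fold changes must be > 0", call. = FALSE)
  2^mean(log2(probe_fcs))
}

#' Per-gene qPCR fold changes against a panel of normalizers
#'
#' Replicate CTs are averaged per gene and state; each target gene's fold
#' change is computed by [ddct_fold_change()] against every normalizer and
#' the per-normalizer values are averaged with
#' [average_over_normalizers()].
#'
#' @param ct_table Long-format CT table (see [average_ct()]).
#' @param normalizers Character vector of normalizer gene names present in
#'   `ct_table`.
#' @param method Averaging method across normalizers.
#' @return A [fold_change_table()] over the target (non-normalizer) genes,
#'   labelled `"qpcr"`; `probe_id` holds the gene names.
#' @export
qpcr_fold_changes <- function(ct_table, normalizers,
                              method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  wide <- average_ct(ct_table)
  miss <- setdiff(normalizers, wide$gene)
  if (length(miss))
    stop("normalizer(s) absent from CT table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  targets <- setdiff(wide$gene, normalizers)
  norm_rows <- wide[match(normalizers, wide$gene), ]
  fc <- vapply(targets, function(g) {
    trow <- wide[wide$gene == g, ]
    per_norm <- vapply(seq_len(nrow(norm_rows)), function(i)
      ddct_fold_change(trow, norm_rows[i, ]), numeric(1))
    average_over_normalizers(per_norm, method)
  }, numeric(1))
  fold_change_table(targets, fc, source = "qpcr")
}

#' Gene-by-gene platform agreement against qPCR
#'
#' Correlates each platform's fold changes with the qPCR fold changes
#' ([correlation_suite()]) and, per gene, decides which platform's log2 fold
#' change lies closer to the qPCR value. Ties are declared when the two
#' log-distances differ by less than `tie_tol`.
#'
#' @param genes Data frame with `gene`, `fc_qpcr`, `fc_rnaseq`, `fc_array`
#'   (all positive).
#' @param threshold Optional fold-change threshold: restrict to genes with
#'   `fc_qpcr > threshold` or `< 1/threshold` (differential genes).
#' @param tie_tol Tolerance on the difference of log-distances.
#' @return List with `cor_qpcr_rnaseq`, `cor_qpcr_array` (correlation
#'   triples), `n_rnaseq_closer`, `n_array_closer`, `n_ties`, `n_genes`,
#'   and the per-gene data frame (`closer_platform` column added).
#' @export
platform_agreement <- function(genes, threshold = NULL, tie_tol = 1e-12) {
  stopifnot(all(c("gene", "fc_qpcr", "fc_rnaseq", "fc_array") %in%
                  names(genes)))
  if (!is.null(threshold)) {
    stopifnot(threshold > 0)
    genes <- genes[genes$fc_qpcr > threshold | genes$fc_qpcr < 1 / threshold, ]
  }
  if (nrow(genes) < 3L) stop("need at least 3 genes", call. = FALSE)
  d_seq <- abs(log2(genes$fc_rnaseq) - log2(genes$fc_qpcr))
  d_arr <- abs(log2(genes$fc_array) - log2(genes$fc_qpcr))
  closer <- ifelse(abs(d_seq - d_arr) < tie_tol, "tie",
                   ifelse(d_seq < d_arr, "rnaseq", "array"))
  genes$closer_platform <- closer
  list(cor_qpcr_rnaseq = correlation_suite(genes$fc_qpcr, genes$fc_rnaseq),
       cor_qpcr_array = correlation_suite(genes$fc_qpcr, genes$fc_array),
       n_rnaseq_closer = sum(closer == "rnaseq"),
       n_array_closer = sum(closer == "array"),
       n_ties = sum(closer == "tie"),
       n_genes = nrow(genes),
       genes = genes)
}
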