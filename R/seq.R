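# RNA-seq feature-probe quantification: probe generation from annotation,
# RPKM normalization with pseudocount, replicate pooling, fold changes.

#' Generate feature probes from a transcript annotation
#'
#' One probe per annotated mRNA transcript, spanning its full annotated
#' extent; the probe sequence is extracted from the forward strand of the
#' reference genome. Coordinates are 1-based inclusive.
#'
#' @param annotations Data frame with `transcript_id`, `chromosome`,
#'   `start`, `end` (and optionally `strand`).
#' @param genome Named character vector mapping chromosome names to
#'   sequences.
#' @return Data frame with `probe_id`, `chromosome`, `start`, `end`,
#'   `ensembl_id` (exactly one per probe) and `sequence`.
#' @export
feature_probes_from_annotation <- function(annotations, genome) {
  stopifnot(all(c("transcript_id", "chromosome", "start", "end") %in%
                  names(annotations)))
  miss <- setdiff(annotations$chromosome, names(genome))
  if (length(miss))
    stop("annotation on unknown chromosome(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lens <- nchar(genome)[annotations$chromosome]
  bad <- annotations$start < 1L | annotations$end > lens |
    annotations$start > annotations$end
  if (any(bad))
    stop("annotation out of chromosome bounds: ",
         paste(annotations$transcript_id[bad], collapse = ", "), call. = FALSE)
  data.frame(
    probe_id = sprintf("R%06d", seq_len(nrow(annotations))),
    chromosome = annotations$chromosome,
    start = annotations$start,
    end = annotations$end,
    ensembl_id = annotations$transcript_id,
    sequence = substr(genome[annotations$chromosome], annotations$start,
                      annotations$end),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Construct a count table
#'
#' @param probe_id Feature-probe identifiers.
#' @param length Probe lengths in bp.
#' @param raw_count Non-negative integer read counts.
#' @param sample Sample label (e.g. `"PRO1"`, or `"PRO"` for pooled data).
#' @param total_reads Library total used for RPKM; defaults to the sum of
#'   the raw counts (i.e. reads assigned to probes).
#' @return Data frame of class `count_table` with attributes `sample` and
#'   `total_reads`.
#' @export
count_table <- function(probe_id, length, raw_count, sample = "sample",
                        total_reads = sum(raw_count)) {
  if (any(raw_count < 0) || any(raw_count != round(raw_count)))
    stop("raw counts must be non-negative integers", call. = FALSE)
  if (anyDuplicated(probe_id)) stop("duplicate probe_id", call. = FALSE)
  out <- data.frame(probe_id = as.character(probe_id), length = length,
                    raw_count = raw_count, stringsAsFactors = FALSE)
  attr(out, "sample") <- sample
  attr(out, "total_reads") <- total_reads
  class(out) <- c("count_table", "data.frame")
  out
}

#' RPKM-normalize a count table
#'
#' Adds an `rpkm` column: `1e9 * raw_count / (length * total_reads)` (reads
#' per kilobase of transcript per million reads). Raw counts are preserved
#' alongside. The default total is the sum of reads assigned to probes;
#' supply `total_reads` to normalize against a genome-wide mapped total
#' instead.
#'
#' @param counts A [count_table()].
#' @param total_reads Optional override of the library total (> 0).
#' @return The count table with an `rpkm` column.
#' @export
#' @examples
#' ct <- count_table("p1", length = 2000, raw_count = 10, total_reads = 1e6)
#' rpkm_normalize(ct)$rpkm  # 5
rpkm_normalize <- function(counts, total_reads = attr(counts, "total_reads")) {
  stopifnot(inherits(counts, "count_table"))
  if (is.null(total_reads) || total_reads <= 0)
    stop("total_reads must be positive", call. = FALSE)
  counts$rpkm <- 1e9 * counts$raw_count / (counts$length * total_reads)
  attr(counts, "total_reads") <- total_reads
  counts
}

#' Pool two replicate count tables of the same state
#'
#' Raw counts are summed per probe (read-level pooling) and library totals
#' summed; RPKM is recomputed on the pooled totals.
#'
#' @param a,b [count_table()]s over the identical probe set.
#' @param sample Label for the pooled table.
#' @return The pooled, RPKM-normalized [count_table()].
#' @export
pool_replicates <- function(a, b, sample = paste0(attr(a, "sample"), "+",
                                                  attr(b, "sample"))) {
  stopifnot(inherits(a, "count_table"), inherits(b, "count_table"))
  if (!identical(sort(a$probe_id), sort(b$probe_id)))
    stop("replicates cover different probe sets", call. = FALSE)
  bi <- match(a$probe_id, b$probe_id)
  pooled <- count_table(a$probe_id, a$length, a$raw_count + b$raw_count[bi],
                        sample = sample,
                        total_reads = attr(a, "total_reads") +
                          attr(b, "total_reads"))
  rpkm_normalize(pooled)
}

#' RNA-seq fold changes with pseudocount
#'
#' `fc = (rpkm_qui + pseudocount) / (rpkm_pro + pseudocount)` per probe. The
#' pseudocount (default 0.05) is added to the normalized values to prevent
#' division by zero; with `pseudocount = 0` any zero denominator is an error.
#'
#' @param pro,qui RPKM-normalized [count_table()]s over the same probe set.
#' @param pseudocount Non-negative constant added to each RPKM value.
#' @return A [fold_change_table()] labelled `"rnaseq"`.
#' @export
#' @examples
#' pro <- rpkm_normalize(count_table("p1", 1000, 0, total_reads = 1e9))
#' qui <- rpkm_normalize(count_table("p1", 1000, 950, total_reads = 1e9))
#' seq_fold_changes(pro, qui)$fc  # (0.95 + 0.05) / 0.05 = 20
seq_fold_changes <- function(pro, qui, pseudocount = 0.05) {
  stopifnot(inherits(pro, "count_table"), inherits(qui, "count_table"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (is.null(pro$rpkm) || is.null(qui$rpkm))
    stop("count tables must be RPKM-normalized first", call. = FALSE)
  if (!identical(sort(pro$probe_id), sort(qui$probe_id)))
    stop("probe sets differ between states", call. = FALSE)
  qi <- match(pro$probe_id, qui$probe_id)
  denom <- pro$rpkm + pseudocount
  if (any(denom == 0))
    stop("zero denominator: increase the pseudocount", call. = FALSE)
  fold_change_table(pro$probe_id, (qui$rpkm[qi] + pseudocount) / denom,
                    source = "rnaseq")
}
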