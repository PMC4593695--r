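# Correspondence between microarray probes and RNA-seq feature probes:
# sequence-based matching restricted to the probe's chromosome, an
# Ensembl-transcript-ID fallback, and deterministic conflict resolution.

split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Sequence-based candidate mapping of array probes to feature probes
#'
#' For each array probe, candidates are exactly the feature probes on the
#' probe's recorded chromosome whose spanned sequence contains the probe
#' sequence as a contiguous substring; by default the reverse complement is
#' tested too (array probes may be antisense to the reference). Matching is
#' verbatim: no mismatches or gaps.
#'
#' @param array_probes Data frame with `probe_id`, `sequence`, `chromosome`.
#' @param seq_probes Feature probes with `probe_id`, `chromosome`, `start`,
#'   `end` and (optionally) `sequence`; sequences are sliced from `genome`
#'   when absent.
#' @param genome Named character vector of chromosome sequences (only needed
#'   when `seq_probes$sequence` is missing).
#' @param revcomp Also match the reverse complement (default `TRUE`).
#' @return Named list: for each array probe id, a sorted character vector of
#'   candidate feature-probe ids (possibly empty).
#' @export
map_by_sequence <- function(array_probes, seq_probes, genome = NULL,
                            revcomp = TRUE) {
  if (is.null(seq_probes$sequence)) {
    if (is.null(genome))
      stop("need a genome when seq probes carry no sequences", call. = FALSE)
    seq_probes$sequence <- substr(genome[seq_probes$chromosome],
                                  seq_probes$start, seq_probes$end)
  }
  out <- setNames(vector("list", nrow(array_probes)), array_probes$probe_id)
  for (chr in unique(array_probes$chromosome)) {
    ai <- which(array_probes$chromosome == chr)
    si <- which(seq_probes$chromosome == chr)
    if (!length(si)) {
      out[ai] <- list(character(0))
      next
    }
    subject <- Biostrings::DNAStringSet(seq_probes$sequence[si])
    for (i in ai) {
      pat <- Biostrings::DNAString(array_probes$sequence[i])
      hit <- Biostrings::vcountPattern(pat, subject) > 0
      if (revcomp)
        hit <- hit | Biostrings::vcountPattern(
          Biostrings::reverseComplement(pat), subject) > 0
      out[[i]] <- sort(seq_probes$probe_id[si][hit])
    }
  }
  out
}

#' Ensembl-ID fallback mapping for one array probe
#'
#' Iterates over the probe's Ensembl IDs in sorted order; the first ID equal
#' to some feature probe's ID yields that probe and no further IDs are
#' examined. Probes with no IDs cannot be mapped by this method. Should
#' several feature probes share the matching ID, the lexicographically
#' smallest feature-probe id is taken.
#'
#' @param ensembl_ids Character vector of the array probe's Ensembl IDs
#'   (possibly empty), or a single semicolon-joined string.
#' @param seq_probes Feature probes with `probe_id` and `ensembl_id`.
#' @return The matched feature-probe id, or `NULL` when no match exists.
#' @export
map_by_ensembl <- function(ensembl_ids, seq_probes) {
  if (length(ensembl_ids) == 1L && grepl(";", ensembl_ids, fixed = TRUE))
    ensembl_ids <- split_ids(ensembl_ids)
  ensembl_ids <- ensembl_ids[!is.na(ensembl_ids) & nzchar(ensembl_ids)]
  for (e in sort(ensembl_ids)) {
    hit <- seq_probes$probe_id[seq_probes$ensembl_id == e]
    if (length(hit)) return(min(hit))
  }
  NULL
}

#' Resolve the array-to-feature-probe mapping
#'
#' Per array probe:
#' * a single sequence candidate is taken as is;
#' * among multiple sequence candidates (typically splice variants of one
#'   gene), a candidate whose Ensembl ID is also one of the array probe's
#'   IDs is preferred; failing that, the candidate with the
#'   lexicographically smallest probe id is taken and the assignment is
#'   flagged ambiguous (a deterministic stand-in for an arbitrary pick);
#' * with no sequence candidate, the Ensembl-ID fallback
#'   ([map_by_ensembl()]) is attempted;
#' * otherwise the probe is unmapped.
#'
#' @inheritParams map_by_sequence
#' @return An object of class `probe_mapping`: list with `mapped` (data
#'   frame: `array_probe_id`, `seq_probe_id`, `method`
#'   (`"sequence"`/`"ensembl"`), `ambiguous`), `unmapped` (character vector)
#'   and the totals `n_array_probes`, `n_seq_probes`.
#' @export
resolve_mapping <- function(array_probes, seq_probes, genome = NULL,
                            revcomp = TRUE) {
  if (anyDuplicated(array_probes$probe_id))
    stop("duplicate array probe ids", call. = FALSE)
  # canonical input order so the result is row-order invariant
  array_probes <- array_probes[order(array_probes$probe_id, method = "radix"), ]
  cands <- map_by_sequence(array_probes, seq_probes, genome, revcomp)
  n <- nrow(array_probes)
  seq_probe_id <- character(n)
  method <- character(n)
  ambiguous <- logical(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    cc <- cands[[array_probes$probe_id[i]]]
    if (length(cc) >= 1L) {
      keep[i] <- TRUE
      method[i] <- "sequence"
      if (length(cc) == 1L) {
        seq_probe_id[i] <- cc
      } else {
        own <- split_ids(array_probes$ensembl_ids[i])
        consistent <- cc[seq_probes$ensembl_id[match(cc, seq_probes$probe_id)]
                         %in% own]
        pick_from <- if (length(consistent)) consistent else cc
        seq_probe_id[i] <- min(pick_from)
        ambiguous[i] <- length(pick_from) > 1L
      }
    } else {
      hit <- map_by_ensembl(split_ids(array_probes$ensembl_ids[i]), seq_probes)
      if (!is.null(hit)) {
        keep[i] <- TRUE
        method[i] <- "ensembl"
        seq_probe_id[i] <- hit
      }
    }
  }
  structure(list(
    mapped = data.frame(array_probe_id = array_probes$probe_id[keep],
                        seq_probe_id = seq_probe_id[keep],
                        method = method[keep],
                        ambiguous = ambiguous[keep],
                        stringsAsFactors = FALSE, row.names = NULL),
    unmapped = array_probes$probe_id[!keep],
    n_array_probes = n,
    n_seq_probes = nrow(seq_probes)),
    class = "probe_mapping")
}

#' @export
print.probe_mapping <- function(x, ...) {
  s <- mapping_summary(x)
  cat(sprintf("Probe mapping: %d/%d array probes mapped (%d%%); %d unique feature probes (%.1f%% of %d)\n",
              s$n_mapped, s$n_array_probes, s$percent_mapped,
              s$n_unique_seq_probes, s$percent_of_seq_probes, x$n_seq_probes))
  invisible(x)
}

#' Mapping percentages from raw counts
#'
#' The fraction of array probes mapped (reported to the nearest integer
#' percent) and the fraction of feature probes used (one decimal), the way
#' such mapping summaries are conventionally reported.
#'
#' @param n_mapped Number of array probes mapped by at least one method.
#' @param n_array_probes Total array probes.
#' @param n_unique_seq_probes Number of distinct feature probes matched.
#' @param n_seq_probes Total feature probes.
#' @return List with `percent_mapped` (integer percent) and
#'   `percent_of_seq_probes` (percent, one decimal).
#' @export
#' @examples
#' mapping_percentages(29007, 35355, 22041, 149135)  # 82, 14.8
mapping_percentages <- function(n_mapped, n_array_probes,
                                n_unique_seq_probes, n_seq_probes) {
  stopifnot(n_array_probes > 0, n_seq_probes > 0)
  list(percent_mapped = round(100 * n_mapped / n_array_probes),
       percent_of_seq_probes = round(100 * n_unique_seq_probes / n_seq_probes,
                                     1))
}

#' Summarize a probe mapping
#'
#' @param mapping A `probe_mapping` from [resolve_mapping()].
#' @return List with `n_array_probes`, `n_mapped`, `percent_mapped`,
#'   `n_unique_seq_probes`, `percent_of_seq_probes`.
#' @export
mapping_summary <- function(mapping) {
  stopifnot(inherits(mapping, "probe_mapping"))
  n_mapped <- nrow(mapping$mapped)
  n_unique <- length(unique(mapping$mapped$seq_probe_id))
  pct <- mapping_percentages(n_mapped, mapping$n_array_probes,
                             n_unique, mapping$n_seq_probes)
  list(n_array_probes = mapping$n_array_probes,
       n_mapped = n_mapped,
       percent_mapped = pct$percent_mapped,
       n_unique_seq_probes = n_unique,
       percent_of_seq_probes = pct$percent_of_seq_probes)
}
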