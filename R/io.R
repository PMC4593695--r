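# Flat-file handoff between stages: FASTA for the genome, TSV for tables,
# key=value text for run configurations.

#' Write / read a genome as FASTA
#'
#' @param genome Named character vector, chromosome name to sequence.
#' @param path Output file.
#' @return `write_genome_fasta` returns `path` invisibly;
#'   `read_genome_fasta` returns the named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read a data frame as tab-separated values
#'
#' Plain TSV with a header row, no quoting, no row names — the interchange
#' format used between pipeline stages.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` the data frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read an intensity table for one array scan
#'
#' Columns `probe_id`, `cy3`, `cy5`, `excluded`; the array id and dye
#' orientation travel in the file name and run manifest, not the table.
#'
#' @param scan An [array_scan()].
#' @param path File path.
#' @param array_id,orientation Metadata to attach when reading.
#' @return The scan (reading) or `path` invisibly (writing).
#' @export
write_intensities_tsv <- function(scan, path) {
  write_tsv(scan$intensities, path)
}

#' @rdname write_intensities_tsv
#' @export
read_intensities_tsv <- function(path, array_id, orientation) {
  array_scan(array_id, orientation, read_tsv(path))
}

#' Write / read a count table
#'
#' The sample label and library total are stored as `#`-prefixed header
#' comments so the table round-trips losslessly.
#'
#' @param counts A [count_table()].
#' @param path File path.
#' @return The count table (reading) or `path` invisibly (writing).
#' @export
write_counts_tsv <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sample=", attr(counts, "sample")),
               paste0("# total_reads=", format(attr(counts, "total_reads"),
                                               scientific = FALSE))), con)
  write.table(counts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- sub("^# ", "", hdr)
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ct <- count_table(df$probe_id, df$length, df$raw_count,
                    sample = vals[["sample"]],
                    total_reads = as.numeric(vals[["total_reads"]]))
  if (!is.null(df$rpkm)) ct$rpkm <- df$rpkm
  ct
}

#' Write / read a flat key=value run configuration
#'
#' One `key=value` per line; `#` starts a comment. Vector-valued settings
#' use comma-separated values.
#'
#' @param cfg Named list of scalar or vector settings.
#' @param path File path.
#' @return The named character list (reading) or `path` invisibly (writing).
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    paste0(k, "=", paste(format(cfg[[k]], scientific = FALSE, trim = TRUE),
                         collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  eq <- regexpr("=", lines, fixed = TRUE)
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))
  if (anyDuplicated(keys))
    stop("duplicate config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  setNames(as.list(vals), keys)
}
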