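# Independent brute-force oracles and hand-built toy designs used across
# the suite. Everything here is base R only, deliberately naive, and kept
# separate from the implementation paths it checks.

rc_base <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# All-pairs substring scan: candidate feature probes per array probe.
oracle_candidates <- function(array_probes, seq_probes, revcomp = TRUE) {
  res <- setNames(vector("list", nrow(array_probes)), array_probes$probe_id)
  for (i in seq_len(nrow(array_probes))) {
    hits <- character(0)
    for (j in seq_len(nrow(seq_probes))) {
      if (array_probes$chromosome[i] != seq_probes$chromosome[j]) next
      fwd <- grepl(array_probes$sequence[i], seq_probes$sequence[j],
                   fixed = TRUE)
      rev <- revcomp && grepl(rc_base(array_probes$sequence[i]),
                              seq_probes$sequence[j], fixed = TRUE)
      if (fwd || rev) hits <- c(hits, seq_probes$probe_id[j])
    }
    res[[i]] <- sort(hits)
  }
  res
}

oracle_split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

# Naive re-implementation of the resolution rules: single candidate taken;
# multiple candidates prefer Ensembl-consistent, else smallest id (flagged
# ambiguous); no candidate falls back to sorted Ensembl-ID lookup.
oracle_resolve <- function(array_probes, seq_probes, revcomp = TRUE) {
  cand <- oracle_candidates(array_probes, seq_probes, revcomp)
  rows <- list()
  unmapped <- character(0)
  for (pid in sort(array_probes$probe_id)) {
    i <- which(array_probes$probe_id == pid)
    cc <- cand[[pid]]
    own <- oracle_split_ids(array_probes$ensembl_ids[i])
    if (length(cc) >= 1L) {
      cons <- cc[vapply(cc, function(s)
        seq_probes$ensembl_id[seq_probes$probe_id == s] %in% own,
        logical(1))]
      pool <- if (length(cons)) cons else cc
      rows[[length(rows) + 1L]] <- data.frame(
        array_probe_id = pid, seq_probe_id = min(pool), method = "sequence",
        ambiguous = length(pool) > 1L, stringsAsFactors = FALSE)
    } else {
      hit <- NULL
      for (e in sort(own)) {
        m <- sort(seq_probes$probe_id[seq_probes$ensembl_id == e])
        if (length(m)) { hit <- m[1]; break }
      }
      if (is.null(hit)) {
        unmapped <- c(unmapped, pid)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          array_probe_id = pid, seq_probe_id = hit, method = "ensembl",
          ambiguous = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  list(mapped = do.call(rbind, rows), unmapped = unmapped)
}

# A hand-laid-out toy design: one chromosome, two transcripts that share a
# leading block (splice variants), one lone transcript on a second
# chromosome, plus probes covering every mapping path.
tiny_design <- function() {
  blockA <- "ACGTACGTGGATCCACGTTAGCAAGGCCTTAA"       # shared exon block
  tailA1 <- "TTTTCCCCGGGGAAAATTTTCCCCGGGGAAAA"
  tailA2 <- "GATTACAGATTACAGATTACAGATTACAGATT"
  tA1 <- paste0(blockA, tailA1)
  tA2 <- paste0(blockA, tailA2)
  tB  <- "CATGCATGCCCGGGAACCTTGGAACCTTGGCATGCATGAA"
  sp1 <- "AAAAAAAAAA"; sp2 <- "CCCCCCCCCC"
  chr1 <- paste0(sp1, tA1, sp2, tA2, sp1)
  chr2 <- paste0(sp2, tB, sp2)
  genome <- c(chr1 = chr1, chr2 = chr2)
  ann <- data.frame(
    transcript_id = c("ENST00000001", "ENST00000002", "ENST00000003"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(11L, 11L + nchar(tA1) + 10L, 11L),
    end = c(10L + nchar(tA1), 10L + nchar(tA1) + 10L + nchar(tA2),
            10L + nchar(tB)),
    strand = "+", stringsAsFactors = FALSE)
  seq_probes <- feature_probes_from_annotation(ann, genome)
  array_probes <- data.frame(
    probe_id = c("p_block",   # in the shared block: matches both variants
                 "p_tail1",   # unique to variant 1
                 "p_rc",      # reverse complement of a tB substring
                 "p_mut",     # genome-absent sequence, real ID -> fallback
                 "p_sorted",  # fallback with a bogus ID sorting first
                 "p_decoy",   # genome-absent, no IDs -> unmapped
                 "p_noid"),   # unique sequence, no IDs -> sequence method
    sequence = c(substr(blockA, 3, 22),
                 substr(tailA1, 3, 22),
                 rc_base(substr(tB, 5, 24)),
                 "ACACACACACACACACACAC",
                 "GTGTGTGTGTGTGTGTGTGT",
                 "TACGTACGATCGATCGTACG",
                 substr(tailA2, 5, 24)),
    chromosome = c("chr1", "chr1", "chr2", "chr1", "chr2", "chr1", "chr1"),
    ensembl_ids = c("ENST00000001", "", "", "ENST00000003",
                    "ENSA0ZZZ;ENST00000002", "", ""),
    decoy = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  list(genome = genome, annotations = ann, seq_probes = seq_probes,
       array_probes = array_probes)
}

# Small, fast simulation configuration shared by several tests; `...`
# overrides any default.
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chromosomes = 2L, n_transcripts = 50L,
               n_array_probes = 60L, n_genes_changed = 10L,
               n_splice_variants = 4L,
               transcript_length_range = c(150L, 600L),
               library_sizes = c(PRO1 = 1e5, PRO2 = 1e5,
                                 QUI1 = 1e5, QUI2 = 1e5))
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# Noise-free variant: all stochastic terms off, unit dye gains, no crosstalk.
noise_free_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, array_noise_sd = 0,
               dye_bias = c(cy3 = 1, cy5 = 1), crosstalk_alpha = 0,
               nb_dispersion = 0, qpcr_ct_noise_sd = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(small_config, args)
}
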