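# Synthetic-data generators: toy genome, probes, ground truth, platform
# measurements. All randomness is routed through withr::with_seed so each
# generator is a pure function of (config, seed).

DNA_ALPHABET <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# TRUE when `s` occurs nowhere in the genome, on either strand.
sequence_absent <- function(s, genome) {
  !any(vapply(genome, grepl, logical(1), pattern = s, fixed = TRUE)) &&
    !any(vapply(genome, grepl, logical(1), pattern = revcomp(s), fixed = TRUE))
}

# Point-mutate roughly every seventh base until the result is genome-absent.
mutate_until_absent <- function(s, genome, max_tries = 100L) {
  n <- nchar(s)
  for (i in seq_len(max_tries)) {
    pos <- seq(from = sample(3L, 1L), to = n, by = 7L)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(DNA_ALPHABET, b), 1L), "")
    cand <- paste(chars, collapse = "")
    if (sequence_absent(cand, genome)) return(cand)
  }
  stop("could not derive a genome-absent mutated sequence", call. = FALSE)
}

random_absent_dna <- function(n, genome, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    cand <- random_dna(n)
    if (sequence_absent(cand, genome)) return(cand)
  }
  stop("could not draw a genome-absent decoy sequence", call. = FALSE)
}

#' Simulate a toy genome, annotation and probe sets
#'
#' Builds `n_transcripts` transcript sequences (the last `n_splice_variants`
#' of which share a leading exon-like block with an earlier transcript on the
#' same chromosome), embeds them in chromosomes separated by random spacer
#' sequence, and derives two probe sets: microarray probes (~70-mers) and
#' RNA-seq feature probes spanning whole transcripts. Array probes come in
#' three classes:
#'
#' * `exact` — a verbatim substring of a transcript, carrying the source
#'   transcript's Ensembl-style ID (occasionally an extra spurious ID, or no
#'   ID at all);
#' * `mutated` — drawn from a transcript but point-mutated until absent from
#'   the genome, so it can only map through its retained Ensembl ID;
#' * `decoy` — random genome-absent sequence with no IDs, never mappable.
#'
#' Coordinates are 1-based inclusive on the forward strand.
#'
#' @param config A [simulation_config()].
#' @return A list with components `genome` (named character vector,
#'   chromosome name to sequence), `annotations` (data frame:
#'   `transcript_id`, `chromosome`, `start`, `end`, `strand`), `array_probes`
#'   (data frame: `probe_id`, `sequence`, `chromosome`, `ensembl_ids`
#'   (semicolon-joined, possibly empty), `decoy`, `probe_class`,
#'   `source_transcript`), and `seq_probes` as returned by
#'   [feature_probes_from_annotation()].
#' @export
#' @examples
#' sim <- simulate_genome(simulation_config(seed = 1, n_transcripts = 20,
#'                                          n_array_probes = 25,
#'                                          n_genes_changed = 5,
#'                                          n_splice_variants = 2))
#' names(sim)
simulate_genome <- function(config) {
  validate_simulation_config(config)
  withr::with_seed(config$seed, {
    n  <- config$n_transcripts
    nv <- config$n_splice_variants
    nb <- n - nv
    plen <- config$array_probe_length
    lens <- sample(seq(config$transcript_length_range[1],
                       config$transcript_length_range[2]),
                   nb, replace = TRUE)
    base_seqs <- vapply(lens, random_dna, "")
    ids <- sprintf("ENST%08d", seq_len(n))

    # Variant transcripts reuse the first `block_len` bases of a base
    # transcript so probes in that block match both by sequence.
    block_len <- max(plen + 30L, 150L)
    var_seqs <- character(nv)
    for (i in seq_len(nv)) {
      tail_len <- max(config$transcript_length_range[1] - block_len, 50L)
      var_seqs[i] <- paste0(substr(base_seqs[i], 1L, block_len),
                            random_dna(tail_len))
    }
    seqs <- c(base_seqs, var_seqs)
    chrom_idx <- c(ci <- sample(config$n_chromosomes, nb, replace = TRUE),
                   ci[seq_len(nv)])
    chrom_names <- paste0("chr", seq_len(config$n_chromosomes))

    ann <- data.frame(transcript_id = ids,
                      chromosome = chrom_names[chrom_idx],
                      start = NA_integer_, end = NA_integer_,
                      strand = "+", stringsAsFactors = FALSE)
    genome <- setNames(character(config$n_chromosomes), chrom_names)
    for (ci in seq_len(config$n_chromosomes)) {
      idx <- which(chrom_idx == ci)
      if (length(idx) > 1L) idx <- sample(idx)
      parts <- character(0)
      pos <- 0L
      for (t in idx) {
        sp <- random_dna(sample(50:200, 1L))
        parts <- c(parts, sp, seqs[t])
        ann$start[t] <- pos + nchar(sp) + 1L
        ann$end[t]   <- ann$start[t] + nchar(seqs[t]) - 1L
        pos <- ann$end[t]
      }
      parts <- c(parts, random_dna(sample(50:200, 1L)))
      genome[ci] <- paste(parts, collapse = "")
    }

    # ---- array probes -----------------------------------------------------
    np <- config$n_array_probes
    n_decoy <- round(config$decoy_fraction * np)
    n_mut   <- round(config$id_fallback_fraction * np)
    n_exact <- np - n_decoy - n_mut
    if (n_exact < 0L) stop("decoy and id-fallback fractions leave no exact probes",
                           call. = FALSE)

    draw_from <- function(t, within_block = FALSE) {
      s <- seqs[t]
      hi <- if (within_block) block_len - plen + 1L else nchar(s) - plen + 1L
      off <- sample(hi, 1L)
      substr(s, off, off + plen - 1L)
    }

    # exact probes: the first min(nv, n_exact) target shared variant blocks
    src_exact <- c(seq_len(min(nv, n_exact)),
                   if (n_exact > nv) sample(n, n_exact - nv, replace = TRUE))
    seq_exact <- vapply(seq_along(src_exact), function(i) {
      draw_from(src_exact[i], within_block = i <= nv)
    }, "")
    eid_exact <- ids[src_exact]
    # decorate: ~15% get an extra spurious ID, ~5% lose their IDs entirely
    u <- stats::runif(n_exact)
    extra <- u < 0.15
    eid_exact[extra] <- paste(eid_exact[extra],
                              sprintf("ENSTX%07d", sample(1e6, sum(extra))),
                              sep = ";")
    eid_exact[u > 0.95] <- ""

    src_mut <- if (n_mut > 0L) sample(n, n_mut, replace = TRUE) else integer(0)
    seq_mut <- vapply(src_mut, function(t)
      mutate_until_absent(draw_from(t), genome), "")
    eid_mut <- ids[src_mut]
    # half the mutated probes carry a non-existent ID that sorts before the
    # real one, exercising the sorted-iteration fallback
    if (n_mut > 0L) {
      first <- stats::runif(n_mut) < 0.5
      eid_mut[first] <- paste(sprintf("ENSA%08d", sample(1e6, sum(first))),
                              eid_mut[first], sep = ";")
    }

    seq_decoy <- vapply(seq_len(n_decoy), function(i)
      random_absent_dna(plen, genome), "")

    src_all <- c(src_exact, src_mut, rep(NA_integer_, n_decoy))
    ap <- data.frame(
      probe_id = sprintf("AP%05d", seq_len(np)),
      sequence = c(seq_exact, seq_mut, seq_decoy),
      chromosome = c(ann$chromosome[src_exact], ann$chromosome[src_mut],
                     sample(chrom_names, n_decoy, replace = TRUE)),
      ensembl_ids = c(eid_exact, eid_mut, rep("", n_decoy)),
      decoy = rep(c(FALSE, FALSE, TRUE), c(n_exact, n_mut, n_decoy)),
      probe_class = rep(c("exact", "mutated", "decoy"),
                        c(n_exact, n_mut, n_decoy)),
      source_transcript = ifelse(is.na(src_all), NA_character_, ids[src_all]),
      stringsAsFactors = FALSE)

    list(genome = genome,
         annotations = ann,
         array_probes = ap,
         seq_probes = feature_probes_from_annotation(ann, genome))
  })
}

#' Simulate ground-truth expression for both cell states
#'
#' Draws baseline log2 abundances from
#' Normal(`baseline_log2_mean`, `baseline_log2_sd`) and assigns exactly
#' `n_genes_changed` transcripts a log2 fold change of random sign with
#' magnitude `min_abs_log2_fc + Exp(1)`; all other transcripts have log2
#' fold change 0.
#'
#' @param config A [simulation_config()].
#' @param seed Seed for this draw; defaults to `config$seed + 1` so genome
#'   and expression draws are decoupled.
#' @return Data frame with `transcript_id`, `abundance_pro`, `abundance_qui`
#'   (positive, arbitrary units) and `true_log2_fc`
#'   (`log2(abundance_qui / abundance_pro)`).
#' @export
simulate_expression <- function(config, seed = config$seed + 1L) {
  validate_simulation_config(config)
  withr::with_seed(seed, {
    n <- config$n_transcripts
    base <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    lfc <- numeric(n)
    if (config$n_genes_changed > 0L) {
      changed <- sample(n, config$n_genes_changed)
      lfc[changed] <- sample(c(-1, 1), config$n_genes_changed, replace = TRUE) *
        (config$min_abs_log2_fc + rexp(config$n_genes_changed))
    }
    data.frame(transcript_id = sprintf("ENST%08d", seq_len(n)),
               abundance_pro = 2^base,
               abundance_qui = 2^(base + lfc),
               true_log2_fc = lfc,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a two-channel microarray scan
#'
#' Per probe, each channel's clean intensity is
#' `scale * abundance(state) * dye_bias(channel) * exp(eps)` with
#' `eps ~ Normal(0, array_noise_sd^2)`; the observed channels then mix
#' symmetrically, `observed_cy3 = clean_cy3 + alpha * clean_cy5` (and vice
#' versa). Which state lands on which dye is set by `orientation`. Decoy
#' probes receive background-only intensities.
#'
#' @param truth Ground truth from [simulate_expression()].
#' @param array_probes Array-probe table from [simulate_genome()].
#' @param orientation `"qui-cy5"` (QUI labelled with Cy5) or `"qui-cy3"`.
#' @param config A [simulation_config()]; uses `array_noise_sd`, `dye_bias`
#'   and `crosstalk_alpha`.
#' @param array_id Label for the scan (e.g. `"QP1"`).
#' @param seed Seed for the noise draw.
#' @return An [array_scan()] object.
#' @export
simulate_microarray <- function(truth, array_probes, orientation, config,
                                array_id = "QP1", seed = config$seed + 2L) {
  validate_simulation_config(config)
  orientation <- match.arg(orientation, c("qui-cy5", "qui-cy3"))
  bad <- is.na(array_probes$source_transcript) & !array_probes$decoy
  if (any(bad))
    stop("probe(s) without source transcript not flagged decoy: ",
         paste(array_probes$probe_id[bad], collapse = ", "), call. = FALSE)
  idx <- match(array_probes$source_transcript, truth$transcript_id)
  if (any(is.na(idx) & !array_probes$decoy))
    stop("source transcript absent from ground truth", call. = FALSE)

  scale <- 100
  background <- 0.5
  base_pro <- ifelse(array_probes$decoy, background,
                     scale * truth$abundance_pro[idx])
  base_qui <- ifelse(array_probes$decoy, background,
                     scale * truth$abundance_qui[idx])

  withr::with_seed(seed, {
    np <- nrow(array_probes)
    noise <- function() exp(rnorm(np, 0, config$array_noise_sd))
    if (orientation == "qui-cy5") {
      cy5 <- base_qui * config$dye_bias[["cy5"]] * noise()
      cy3 <- base_pro * config$dye_bias[["cy3"]] * noise()
    } else {
      cy3 <- base_qui * config$dye_bias[["cy3"]] * noise()
      cy5 <- base_pro * config$dye_bias[["cy5"]] * noise()
    }
    a <- config$crosstalk_alpha
    obs_cy3 <- cy3 + a * cy5
    obs_cy5 <- cy5 + a * cy3
    array_scan(array_id, orientation,
               data.frame(probe_id = array_probes$probe_id,
                          cy3 = obs_cy3, cy5 = obs_cy5,
                          excluded = FALSE, stringsAsFactors = FALSE))
  })
}

#' Simulate RNA-seq read counts for one replicate of one state
#'
#' Expected counts are proportional to abundance times probe length, scaled so
#' the expected total equals `library_size`; counts are drawn from a negative
#' binomial with the given dispersion (`dispersion = 0` gives Poisson).
#'
#' @param truth Ground truth from [simulate_expression()].
#' @param seq_probes Feature-probe table (see
#'   [feature_probes_from_annotation()]); one probe per transcript.
#' @param state `"pro"` or `"qui"`.
#' @param library_size Expected total read count (> 0).
#' @param nb_dispersion Dispersion >= 0.
#' @param seed Seed for the count draw.
#' @param sample_label Sample name recorded on the result (e.g. `"PRO1"`).
#' @return A [count_table()] with raw counts (RPKM not yet computed).
#' @export
simulate_rnaseq_counts <- function(truth, seq_probes, state, library_size,
                                   nb_dispersion = 0, seed = 1L,
                                   sample_label = toupper(state)) {
  state <- match.arg(state, c("pro", "qui"))
  if (length(library_size) != 1L || library_size <= 0)
    stop("library_size must be a single positive number", call. = FALSE)
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  idx <- match(seq_probes$ensembl_id, truth$transcript_id)
  if (any(is.na(idx)))
    stop("seq probe transcript absent from ground truth", call. = FALSE)
  ab <- if (state == "pro") truth$abundance_pro[idx] else truth$abundance_qui[idx]
  len <- seq_probes$end - seq_probes$start + 1L
  w <- ab * len
  mu <- library_size * w / sum(w)
  withr::with_seed(seed, {
    counts <- if (nb_dispersion == 0) rpois(length(mu), mu)
              else rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
    count_table(seq_probes$probe_id, len, counts, sample = sample_label)
  })
}

#' Simulate qRT-PCR cycle thresholds for both states
#'
#' The CT model is
#' `CT = qpcr_intercept + qpcr_slope * log2(abundance) + Normal(0, qpcr_ct_noise_sd^2)`,
#' one draw per gene, state and technical replicate. Normalizer genes must be
#' unchanged between states (true log2 FC of 0); this is enforced.
#'
#' @param truth Ground truth from [simulate_expression()].
#' @param genes Character vector of target gene (transcript) IDs.
#' @param normalizer_genes Character vector of normalizer gene IDs.
#' @param config A [simulation_config()].
#' @param seed Seed for the CT noise.
#' @return Long-format data frame: `gene`, `state` (`"pro"`/`"qui"`),
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(truth, genes, normalizer_genes, config,
                          seed = config$seed + 3L) {
  validate_simulation_config(config)
  all_genes <- c(genes, normalizer_genes)
  miss <- setdiff(all_genes, truth$transcript_id)
  if (length(miss))
    stop("gene(s) absent from ground truth: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ni <- match(normalizer_genes, truth$transcript_id)
  if (any(truth$true_log2_fc[ni] != 0))
    stop("normalizer genes must have true log2 FC = 0", call. = FALSE)
  idx <- match(all_genes, truth$transcript_id)
  grid <- expand.grid(gene = all_genes, state = c("pro", "qui"),
                      replicate = seq_len(config$qpcr_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ab <- ifelse(grid$state == "pro",
               truth$abundance_pro[idx[match(grid$gene, all_genes)]],
               truth$abundance_qui[idx[match(grid$gene, all_genes)]])
  withr::with_seed(seed, {
    grid$ct <- config$qpcr_intercept + config$qpcr_slope * log2(ab) +
      rnorm(nrow(grid), 0, config$qpcr_ct_noise_sd)
    grid
  })
}
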