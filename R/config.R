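#' Configuration for the synthetic two-platform study
#'
#' Bundles every tunable of the synthetic-data generator. The defaults emulate
#' a scaled-down two-state fibroblast design: a few hundred transcripts on a
#' small multi-chromosome genome, ~70-base array probes that are substrings of
#' transcripts (plus unmappable decoys), two-channel intensities with dye bias,
#' fluorophore crosstalk and multiplicative log-normal noise, negative-binomial
#' RNA-seq read counts for two replicates per state, and qPCR cycle thresholds.
#' A fifth of the transcripts change at least fivefold between states, the
#' regime in which the two platforms are expected to agree best.
#'
#' @param seed Integer seed; every simulator is a pure function of
#'   (config, seed) and fixed seeds give byte-identical outputs.
#' @param n_chromosomes Number of toy chromosomes.
#' @param n_transcripts Number of annotated mRNA transcripts (includes
#'   `n_splice_variants` variant transcripts).
#' @param transcript_length_range Length-2 integer vector, min/max transcript
#'   length in bp; the minimum must exceed `array_probe_length`.
#' @param array_probe_length Array probe length in bp (default 70).
#' @param n_array_probes Total number of array probes, including decoys.
#' @param decoy_fraction Proportion in \[0,1\] of array probes whose sequences
#'   are absent from the genome and which carry no Ensembl IDs (unmappable).
#' @param id_fallback_fraction Proportion of array probes whose sequences are
#'   point-mutated away from the genome but which keep their source
#'   transcript's Ensembl ID, so they can only map via the ID fallback.
#' @param n_splice_variants Number of transcripts generated as splice-like
#'   variants sharing a leading exon block with another transcript, so that
#'   probes in the shared block match several transcripts by sequence.
#' @param n_genes_changed Number of transcripts with a true fold change.
#' @param min_abs_log2_fc Minimum |log2 fold change| of changed transcripts
#'   (default `log2(5)`, i.e. at least fivefold).
#' @param baseline_log2_mean,baseline_log2_sd Normal parameters of baseline
#'   log2 abundance.
#' @param array_noise_sd Log-scale (natural log) sd of the multiplicative
#'   intensity noise per channel.
#' @param dye_bias Named length-2 vector `c(cy3 = , cy5 = )` of multiplicative
#'   channel biases.
#' @param crosstalk_alpha Symmetric cross-channel leakage proportion in
#'   \[0, 0.5).
#' @param library_sizes Named numeric vector of expected read totals for the
#'   four replicates `PRO1, PRO2, QUI1, QUI2`.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param qpcr_ct_noise_sd Cycle-threshold noise sd in cycles.
#' @param qpcr_slope Cycles per log2 abundance unit; -1 corresponds to 100%
#'   amplification efficiency.
#' @param qpcr_intercept CT intercept in cycles.
#' @param qpcr_replicates Technical qPCR replicates per gene and state.
#'
#' @return An object of class `simulation_config` (a validated named list).
#' @seealso [simulate_genome()], [simulate_expression()],
#'   [simulate_microarray()], [simulate_rnaseq_counts()], [simulate_qpcr()]
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_transcripts = 50, n_array_probes = 60)
#' cfg$n_transcripts
simulation_config <- function(seed = 1L,
                              n_chromosomes = 3L,
                              n_transcripts = 500L,
                              transcript_length_range = c(200L, 2000L),
                              array_probe_length = 70L,
                              n_array_probes = 600L,
                              decoy_fraction = 0.1,
                              id_fallback_fraction = 0.05,
                              n_splice_variants = 10L,
                              n_genes_changed = 100L,
                              min_abs_log2_fc = log2(5),
                              baseline_log2_mean = 4,
                              baseline_log2_sd = 2,
                              array_noise_sd = 0.5,
                              dye_bias = c(cy3 = 1, cy5 = 1.5),
                              crosstalk_alpha = 0.05,
                              library_sizes = c(PRO1 = 5e5, PRO2 = 5e5,
                                                QUI1 = 5e5, QUI2 = 5e5),
                              nb_dispersion = 0.05,
                              qpcr_ct_noise_sd = 0.15,
                              qpcr_slope = -1.0,
                              qpcr_intercept = 30,
                              qpcr_replicates = 3L) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              n_transcripts = as.integer(n_transcripts),
              transcript_length_range = as.integer(transcript_length_range),
              array_probe_length = as.integer(array_probe_length),
              n_array_probes = as.integer(n_array_probes),
              decoy_fraction = decoy_fraction,
              id_fallback_fraction = id_fallback_fraction,
              n_splice_variants = as.integer(n_splice_variants),
              n_genes_changed = as.integer(n_genes_changed),
              min_abs_log2_fc = min_abs_log2_fc,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              array_noise_sd = array_noise_sd,
              dye_bias = dye_bias,
              crosstalk_alpha = crosstalk_alpha,
              library_sizes = library_sizes,
              nb_dispersion = nb_dispersion,
              qpcr_ct_noise_sd = qpcr_ct_noise_sd,
              qpcr_slope = qpcr_slope,
              qpcr_intercept = qpcr_intercept,
              qpcr_replicates = as.integer(qpcr_replicates))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Range-checks every field of a [simulation_config()] and stops with an
#' informative message on the first violated constraint.
#'
#' @param cfg A `simulation_config` object.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg,
                                                 call. = FALSE)
  chk(length(cfg$seed) == 1L && is.finite(cfg$seed), "seed must be a single integer")
  chk(cfg$n_chromosomes >= 1L, "n_chromosomes must be >= 1")
  chk(cfg$n_transcripts >= 1L, "n_transcripts must be >= 1")
  chk(length(cfg$transcript_length_range) == 2L &&
        cfg$transcript_length_range[1] <= cfg$transcript_length_range[2],
      "transcript_length_range must be (min, max) with min <= max")
  chk(cfg$array_probe_length >= 1L, "array_probe_length must be >= 1")
  chk(cfg$transcript_length_range[1] > cfg$array_probe_length,
      "minimum transcript length must exceed array_probe_length")
  chk(cfg$n_array_probes >= 1L, "n_array_probes must be >= 1")
  chk(cfg$decoy_fraction >= 0 && cfg$decoy_fraction <= 1,
      "decoy_fraction must lie in [0, 1]")
  chk(cfg$id_fallback_fraction >= 0 && cfg$id_fallback_fraction <= 1,
      "id_fallback_fraction must lie in [0, 1]")
  chk(cfg$decoy_fraction + cfg$id_fallback_fraction <= 1,
      "decoy_fraction + id_fallback_fraction must not exceed 1")
  chk(cfg$n_splice_variants >= 0L &&
        cfg$n_splice_variants <= cfg$n_transcripts %/% 2L,
      "n_splice_variants must be between 0 and n_transcripts/2")
  chk(cfg$n_genes_changed >= 0L && cfg$n_genes_changed <= cfg$n_transcripts,
      "n_genes_changed must be between 0 and n_transcripts")
  chk(cfg$min_abs_log2_fc >= 0, "min_abs_log2_fc must be >= 0")
  chk(cfg$baseline_log2_sd >= 0, "baseline_log2_sd must be >= 0")
  chk(cfg$array_noise_sd >= 0, "array_noise_sd must be >= 0")
  chk(length(cfg$dye_bias) == 2L && all(cfg$dye_bias > 0) &&
        all(c("cy3", "cy5") %in% names(cfg$dye_bias)),
      "dye_bias must be a positive vector named cy3, cy5")
  chk(cfg$crosstalk_alpha >= 0 && cfg$crosstalk_alpha < 0.5,
      "crosstalk_alpha must lie in [0, 0.5)")
  chk(all(cfg$library_sizes > 0), "library_sizes must be positive")
  chk(all(c("PRO1", "PRO2", "QUI1", "QUI2") %in% names(cfg$library_sizes)),
      "library_sizes must be named PRO1, PRO2, QUI1, QUI2")
  chk(cfg$nb_dispersion >= 0, "nb_dispersion must be >= 0")
  chk(cfg$qpcr_ct_noise_sd >= 0, "qpcr_ct_noise_sd must be >= 0")
  chk(cfg$qpcr_slope != 0, "qpcr_slope must be non-zero")
  chk(cfg$qpcr_replicates >= 1L, "qpcr_replicates must be >= 1")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic two-platform study configuration\n")
  cat(sprintf("  %d transcripts on %d chromosome(s), %d array probes (%d bp)\n",
              x$n_transcripts, x$n_chromosomes, x$n_array_probes,
              x$array_probe_length))
  cat(sprintf("  %d changed genes (|log2 FC| >= %.3f), decoys %.0f%%, seed %d\n",
              x$n_genes_changed, x$min_abs_log2_fc, 100 * x$decoy_fraction,
              x$seed))
  invisible(x)
}
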