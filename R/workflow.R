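# Orchestration: a flat key=value run configuration drives
# simulate -> array processing -> RNA-seq processing -> probe mapping ->
# concordance statistics -> qPCR arbitration, with TSV/JSON handoff
# between stages and a manifest for reproducibility.

# key -> c(type, constraint description); constraints checked in validate_config
config_schema <- function() {
  list(
    seed                  = list("int",  function(v) is.finite(v)),
    n_chromosomes         = list("int",  function(v) v >= 1),
    n_transcripts         = list("int",  function(v) v >= 1),
    transcript_length_min = list("int",  function(v) v >= 1),
    transcript_length_max = list("int",  function(v) v >= 1),
    array_probe_length    = list("int",  function(v) v >= 1),
    n_array_probes        = list("int",  function(v) v >= 1),
    decoy_fraction        = list("num",  function(v) v >= 0 && v <= 1),
    id_fallback_fraction  = list("num",  function(v) v >= 0 && v <= 1),
    n_splice_variants     = list("int",  function(v) v >= 0),
    n_genes_changed       = list("int",  function(v) v >= 0),
    min_abs_log2_fc       = list("num",  function(v) v >= 0),
    baseline_log2_mean    = list("num",  function(v) is.finite(v)),
    baseline_log2_sd      = list("num",  function(v) v >= 0),
    array_noise_sd        = list("num",  function(v) v >= 0),
    dye_bias_cy3          = list("num",  function(v) v > 0),
    dye_bias_cy5          = list("num",  function(v) v > 0),
    crosstalk_alpha       = list("num",  function(v) v >= 0 && v < 0.5),
    library_sizes         = list("nums", function(v) length(v) == 4 && all(v > 0)),
    nb_dispersion         = list("num",  function(v) v >= 0),
    qpcr_ct_noise_sd      = list("num",  function(v) v >= 0),
    qpcr_slope            = list("num",  function(v) v != 0),
    qpcr_intercept        = list("num",  function(v) v > 0),
    qpcr_replicates       = list("int",  function(v) v >= 1),
    orientations          = list("strs", function(v)
      length(v) >= 1 && all(v %in% c("qui-cy5", "qui-cy3"))),
    lowess_span           = list("num",  function(v) v > 0 && v <= 1),
    pseudocount           = list("num",  function(v) v >= 0),
    k_values              = list("ints", function(v) all(v >= 1)),
    n_trials              = list("int",  function(v) v >= 1),
    fc_threshold          = list("num",  function(v) v > 0),
    n_qpcr_genes          = list("int",  function(v) v >= 4),
    revcomp               = list("flag", function(v) TRUE)
  )
}

parse_config_value <- function(raw, type) {
  switch(type,
         int  = suppressWarnings(as.integer(raw)),
         num  = suppressWarnings(as.numeric(raw)),
         nums = suppressWarnings(as.numeric(strsplit(raw, ",")[[1]])),
         ints = suppressWarnings(as.integer(strsplit(raw, ",")[[1]])),
         strs = trimws(strsplit(raw, ",")[[1]]),
         flag = tolower(raw) %in% c("true", "yes", "1"))
}

#' Validate a run configuration file
#'
#' Every parameter is range-checked; unknown keys are reported as errors.
#' Cross-field constraints (transcript length vs. probe length, largest k
#' vs. the number of transcripts, fraction budget) are checked too.
#'
#' @param path Path to a flat `key=value` configuration file (see
#'   [default_run_config()]).
#' @return Character vector of diagnostics, empty when the file is valid.
#' @export
validate_config <- function(path) {
  schema <- config_schema()
  raw <- tryCatch(read_run_config(path),
                  error = function(e) conditionMessage(e))
  if (is.character(raw)) return(raw)
  diags <- character(0)
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    diags <- c(diags, paste0("unknown key: ", unknown))
  missing <- setdiff(names(schema), names(raw))
  if (length(missing))
    diags <- c(diags, paste0("missing key: ", missing))
  vals <- list()
  for (k in intersect(names(raw), names(schema))) {
    v <- parse_config_value(raw[[k]], schema[[k]][[1]])
    if (any(is.na(v))) {
      diags <- c(diags, paste0(k, ": cannot parse '", raw[[k]], "'"))
    } else if (!isTRUE(schema[[k]][[2]](v))) {
      diags <- c(diags, paste0(k, ": value out of range (", raw[[k]], ")"))
    } else {
      vals[[k]] <- v
    }
  }
  both <- function(...) all(c(...) %in% names(vals))
  if (both("transcript_length_min", "transcript_length_max") &&
      vals$transcript_length_min > vals$transcript_length_max)
    diags <- c(diags, "transcript_length_min exceeds transcript_length_max")
  if (both("transcript_length_min", "array_probe_length") &&
      vals$transcript_length_min <= vals$array_probe_length)
    diags <- c(diags, "minimum transcript length must exceed array_probe_length")
  if (both("k_values", "n_transcripts") &&
      max(vals$k_values) > vals$n_transcripts)
    diags <- c(diags,
               "k_values: largest k exceeds n_transcripts (overlap universe)")
  if (both("decoy_fraction", "id_fallback_fraction") &&
      vals$decoy_fraction + vals$id_fallback_fraction > 1)
    diags <- c(diags, "decoy_fraction + id_fallback_fraction exceeds 1")
  if (both("n_genes_changed", "n_transcripts") &&
      vals$n_genes_changed > vals$n_transcripts)
    diags <- c(diags, "n_genes_changed exceeds n_transcripts")
  if (both("n_splice_variants", "n_transcripts") &&
      vals$n_splice_variants > vals$n_transcripts %/% 2)
    diags <- c(diags, "n_splice_variants exceeds n_transcripts/2")
  diags
}

#' Write the default demonstration run configuration
#'
#' A scaled-down two-platform study: 500 transcripts, 4 two-channel arrays
#' (arrays 2 and 4 dye-swapped), 2+2 RNA-seq replicates, 20 qPCR genes.
#'
#' @param path Destination file.
#' @param ... `key = value` overrides of individual settings.
#' @return `path`, invisibly.
#' @export
default_run_config <- function(path, ...) {
  cfg <- list(seed = 1L, n_chromosomes = 3L, n_transcripts = 500L,
              transcript_length_min = 200L, transcript_length_max = 2000L,
              array_probe_length = 70L, n_array_probes = 600L,
              decoy_fraction = 0.1, id_fallback_fraction = 0.05,
              n_splice_variants = 10L, n_genes_changed = 100L,
              min_abs_log2_fc = round(log2(5), 6), baseline_log2_mean = 4,
              baseline_log2_sd = 2, array_noise_sd = 0.5,
              dye_bias_cy3 = 1, dye_bias_cy5 = 1.5, crosstalk_alpha = 0.05,
              library_sizes = c(5e5, 5e5, 5e5, 5e5), nb_dispersion = 0.05,
              qpcr_ct_noise_sd = 0.15, qpcr_slope = -1, qpcr_intercept = 30,
              qpcr_replicates = 3L,
              orientations = c("qui-cy5", "qui-cy3", "qui-cy5", "qui-cy3"),
              lowess_span = 0.3, pseudocount = 0.05,
              k_values = c(10L, 50L, 100L), n_trials = 10000L,
              fc_threshold = 5, n_qpcr_genes = 20L, revcomp = "true")
  over <- list(...)
  cfg[names(over)] <- over
  write_run_config(cfg, path)
}

read_validated_config <- function(path) {
  diags <- validate_config(path)
  if (length(diags))
    stop("invalid run configuration:\n  ", paste(diags, collapse = "\n  "),
         call. = FALSE)
  raw <- read_run_config(path)
  schema <- config_schema()
  setNames(lapply(names(raw), function(k)
    parse_config_value(raw[[k]], schema[[k]][[1]])), names(raw))
}

# Per-seq-probe array fold changes: geometric mean over the array probes
# mapped to each feature probe, in feature-probe id space.
fc_in_seq_space <- function(fc_table, mapping) {
  m <- mapping$mapped
  idx <- match(m$array_probe_id, fc_table$probe_id)
  ok <- !is.na(idx)
  agg <- tapply(fc_table$log2_fc[idx[ok]], m$seq_probe_id[ok], mean)
  fold_change_table(names(agg), 2^as.numeric(agg),
                    source = attr(fc_table, "source"))
}

#' Run the full synthetic two-platform concordance analysis
#'
#' Executes simulate, array-normalize, seq-normalize, map-probes,
#' concordance and qPCR stages from one configuration file, writing
#' stage outputs (FASTA/TSV), five report tables, a mapping summary JSON
#' and a run manifest into `outdir`. Re-running with the same
#' configuration reproduces identical outputs byte for byte.
#'
#' @param config_path Path to a run configuration (see
#'   [default_run_config()], [validate_config()]).
#' @param outdir Output directory, created if needed.
#' @param seed Optional override of the configuration seed.
#' @return Invisibly, a list with all intermediate and final objects:
#'   simulation components, processed scans, fold-change tables, the probe
#'   mapping, report tables 1-5 analogues, overlap test results, the qPCR
#'   comparison and the manifest.
#' @export
run_full_analysis <- function(config_path, outdir, seed = NULL) {
  cfg <- read_validated_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)

  sim_cfg <- simulation_config(
    seed = cfg$seed, n_chromosomes = cfg$n_chromosomes,
    n_transcripts = cfg$n_transcripts,
    transcript_length_range = c(cfg$transcript_length_min,
                                cfg$transcript_length_max),
    array_probe_length = cfg$array_probe_length,
    n_array_probes = cfg$n_array_probes,
    decoy_fraction = cfg$decoy_fraction,
    id_fallback_fraction = cfg$id_fallback_fraction,
    n_splice_variants = cfg$n_splice_variants,
    n_genes_changed = cfg$n_genes_changed,
    min_abs_log2_fc = cfg$min_abs_log2_fc,
    baseline_log2_mean = cfg$baseline_log2_mean,
    baseline_log2_sd = cfg$baseline_log2_sd,
    array_noise_sd = cfg$array_noise_sd,
    dye_bias = c(cy3 = cfg$dye_bias_cy3, cy5 = cfg$dye_bias_cy5),
    crosstalk_alpha = cfg$crosstalk_alpha,
    library_sizes = setNames(cfg$library_sizes,
                             c("PRO1", "PRO2", "QUI1", "QUI2")),
    nb_dispersion = cfg$nb_dispersion,
    qpcr_ct_noise_sd = cfg$qpcr_ct_noise_sd, qpcr_slope = cfg$qpcr_slope,
    qpcr_intercept = cfg$qpcr_intercept,
    qpcr_replicates = cfg$qpcr_replicates)

  # ---- stage 1: simulate ------------------------------------------------
  sim <- simulate_genome(sim_cfg)
  truth <- simulate_expression(sim_cfg)
  write_genome_fasta(sim$genome, p("genome.fa"))
  write_tsv(sim$annotations, p("annotations.tsv"))
  write_tsv(sim$array_probes, p("array_probes.tsv"))
  write_tsv(sim$seq_probes, p("seq_probes.tsv"))
  write_tsv(truth, p("ground_truth.tsv"))

  orientations <- cfg$orientations
  n_arrays <- length(orientations)
  array_ids <- paste0("QP", seq_len(n_arrays))
  scans_raw <- lapply(seq_len(n_arrays), function(i)
    simulate_microarray(truth, sim$array_probes, orientations[i], sim_cfg,
                        array_id = array_ids[i],
                        seed = sim_cfg$seed + 10L + i))
  for (i in seq_len(n_arrays))
    write_intensities_tsv(scans_raw[[i]],
                          p(sprintf("intensities_%s.tsv", array_ids[i])))

  reps <- c("PRO1", "PRO2", "QUI1", "QUI2")
  counts <- setNames(lapply(seq_along(reps), function(i) {
    st <- if (grepl("^PRO", reps[i])) "pro" else "qui"
    simulate_rnaseq_counts(truth, sim$seq_probes, st,
                           sim_cfg$library_sizes[[reps[i]]],
                           sim_cfg$nb_dispersion,
                           seed = sim_cfg$seed + 20L + i,
                           sample_label = reps[i])
  }), reps)
  for (r in reps)
    write_counts_tsv(rpkm_normalize(counts[[r]]),
                     p(sprintf("counts_%s.tsv", r)))

  # ---- stage 2: array processing ---------------------------------------
  scans <- lapply(scans_raw, function(s)
    lowess_normalize(cross_channel_correct(s, cfg$crosstalk_alpha),
                     span = cfg$lowess_span))
  array_fc <- lapply(scans, array_fold_changes)
  names(array_fc) <- array_ids
  array_fc_all <- combine_arrays_geometric_mean(array_fc, source = "all")

  # ---- stage 3: RNA-seq processing -------------------------------------
  counts_n <- lapply(counts, rpkm_normalize)
  pooled_pro <- pool_replicates(counts_n$PRO1, counts_n$PRO2, sample = "PRO")
  pooled_qui <- pool_replicates(counts_n$QUI1, counts_n$QUI2, sample = "QUI")
  seq_fc <- seq_fold_changes(pooled_pro, pooled_qui,
                             pseudocount = cfg$pseudocount)
  seq_fc_rep1 <- seq_fold_changes(counts_n$PRO1, counts_n$QUI1,
                                  pseudocount = cfg$pseudocount)
  seq_fc_rep2 <- seq_fold_changes(counts_n$PRO2, counts_n$QUI2,
                                  pseudocount = cfg$pseudocount)

  # ---- stage 4: probe mapping ------------------------------------------
  mapping <- resolve_mapping(sim$array_probes, sim$seq_probes, sim$genome,
                             revcomp = cfg$revcomp)
  write_tsv(mapping$mapped, p("mapping.tsv"))
  msum <- mapping_summary(mapping)
  jsonlite::write_json(msum, p("mapping_summary.json"), auto_unbox = TRUE,
                       digits = NA)

  # ---- stage 5: concordance --------------------------------------------
  table1 <- reproducibility_report(array_fc)
  table1_intensity <- reproducibility_report(setNames(scans, array_ids))

  t2row <- function(label, x, y) {
    ct <- correlation_suite(x, y)
    data.frame(measure = label, pearson = ct$pearson,
               pearson_log2 = ct$pearson_log2, spearman = ct$spearman,
               n = ct$n)
  }
  eps <- cfg$pseudocount
  table2 <- rbind(
    t2row("read_count_pro", counts_n$PRO1$rpkm + eps, counts_n$PRO2$rpkm + eps),
    t2row("read_count_qui", counts_n$QUI1$rpkm + eps, counts_n$QUI2$rpkm + eps),
    t2row("fc", seq_fc_rep1$fc,
          seq_fc_rep2$fc[match(seq_fc_rep1$probe_id, seq_fc_rep2$probe_id)]))

  # cross-platform, in feature-probe space over the mapped universe
  array_fc_seqspace <- lapply(c(array_fc, list(all = array_fc_all)),
                              fc_in_seq_space, mapping = mapping)
  universe <- sort(unique(mapping$mapped$seq_probe_id))
  seq_fc_u <- seq_fc[match(universe, seq_fc$probe_id), ]
  pro_rpkm <- setNames(pooled_pro$rpkm + eps, pooled_pro$probe_id)[universe]
  qui_rpkm <- setNames(pooled_qui$rpkm + eps, pooled_qui$probe_id)[universe]
  table3 <- do.call(rbind, lapply(names(array_fc_seqspace), function(id) {
    afc <- array_fc_seqspace[[id]]
    ai <- match(universe, afc$probe_id)
    rows <- t2row(paste0("fc_", id), seq_fc_u$fc, afc$fc[ai])
    if (id != "all") {
      scan <- scans[[match(id, array_ids)]]
      for (state in c("pro", "qui")) {
        iv <- state_intensities(scan, state)
        iv <- tapply(iv[mapping$mapped$array_probe_id],
                     mapping$mapped$seq_probe_id, mean)[universe]
        rc <- if (state == "pro") pro_rpkm else qui_rpkm
        rows <- rbind(rows, t2row(paste0(state, "_count_vs_intensity_", id),
                                  rc, as.numeric(iv)))
      }
    }
    rows
  }))

  k_values <- cfg$k_values[cfg$k_values <= length(universe)]
  overlap <- list()
  table4 <- NULL
  for (direction in c("highest", "lowest")) {
    seq_top <- lapply(k_values, function(k)
      top_k_list(seq_fc_u, k, direction))
    for (id in names(array_fc_seqspace)) {
      afc <- array_fc_seqspace[[id]]
      afc <- afc[match(universe, afc$probe_id), ]
      for (ki in seq_along(k_values)) {
        k <- k_values[ki]
        res <- overlap_permutation_test(
          seq_top[[ki]], top_k_list(afc, k, direction),
          universe_size = length(universe), n_trials = cfg$n_trials,
          seed = cfg$seed + 100L + ki)
        overlap[[paste(direction, id, k, sep = "_")]] <- res
        table4 <- rbind(table4,
                        data.frame(direction = direction, source = id, k = k,
                                   n = res$n_observed, p_value = res$p_value))
      }
    }
  }

  thresh <- lapply(c(array_fc, list(all = array_fc_all)), function(afc)
    threshold_concordance(fc_in_seq_space(afc, mapping), seq_fc_u,
                          threshold = cfg$fc_threshold))
  table_thresh <- data.frame(
    source = names(thresh),
    n_array_above = vapply(thresh, `[[`, numeric(1), "n_a_above"),
    n_both_above = vapply(thresh, `[[`, numeric(1), "n_both_above"),
    percent = vapply(thresh, `[[`, numeric(1), "percent"),
    row.names = NULL)

  # ---- stage 6: qPCR arbitration ---------------------------------------
  gene_of_seq <- setNames(sim$seq_probes$ensembl_id, sim$seq_probes$probe_id)
  eligible <- sort(unique(gene_of_seq[mapping$mapped$seq_probe_id]))
  unchanged <- truth$transcript_id[truth$true_log2_fc == 0]
  normalizers <- head(intersect(eligible, unchanged), 4L)
  seq_gene_fc <- setNames(seq_fc$fc, gene_of_seq[seq_fc$probe_id])
  cand <- setdiff(eligible, normalizers)
  big <- cand[seq_gene_fc[cand] > cfg$fc_threshold |
                seq_gene_fc[cand] < 1 / cfg$fc_threshold]
  n_big <- min(length(big), cfg$n_qpcr_genes %/% 2L)
  genes <- c(head(big, n_big), head(setdiff(cand, big),
                                    cfg$n_qpcr_genes - n_big))
  ct <- simulate_qpcr(truth, genes, normalizers, sim_cfg)
  write_tsv(ct, p("qpcr_ct.tsv"))
  qfc <- qpcr_fold_changes(ct, normalizers)
  seq_probe_of_gene <- setNames(sim$seq_probes$probe_id,
                                sim$seq_probes$ensembl_id)
  m <- mapping$mapped
  gene_df <- data.frame(
    gene = qfc$probe_id,
    fc_qpcr = qfc$fc,
    fc_rnaseq = seq_fc$fc[match(seq_probe_of_gene[qfc$probe_id],
                                seq_fc$probe_id)],
    fc_array = vapply(qfc$probe_id, function(g) {
      probes <- m$array_probe_id[m$seq_probe_id == seq_probe_of_gene[[g]]]
      gene_level_array_fc(array_fc_all$fc[match(
        intersect(probes, array_fc_all$probe_id), array_fc_all$probe_id)])
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  qpcr_cmp <- platform_agreement(gene_df)
  table5 <- data.frame(
    comparison = c("qpcr_vs_rnaseq", "qpcr_vs_array"),
    pearson = c(qpcr_cmp$cor_qpcr_rnaseq$pearson,
                qpcr_cmp$cor_qpcr_array$pearson),
    pearson_log2 = c(qpcr_cmp$cor_qpcr_rnaseq$pearson_log2,
                     qpcr_cmp$cor_qpcr_array$pearson_log2),
    spearman = c(qpcr_cmp$cor_qpcr_rnaseq$spearman,
                 qpcr_cmp$cor_qpcr_array$spearman),
    n = qpcr_cmp$n_genes)

  for (nm in c("table1", "table1_intensity", "table2", "table3", "table4",
               "table_thresh", "table5"))
    write_tsv(get(nm), p(paste0(nm, ".tsv")))
  write_tsv(qpcr_cmp$genes, p("qpcr_genes.tsv"))

  # ---- manifest --------------------------------------------------------
  outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "concordia",
    version = as.character(packageVersion("concordia")),
    seed = cfg$seed,
    config = read_run_config(config_path),
    arrays = data.frame(array_id = array_ids, orientation = orientations,
                        dye_swapped = orientations != orientations[1]),
    checksums = as.list(tools::md5sum(file.path(outdir, outputs)) |>
                          setNames(outputs)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  invisible(list(config = cfg, sim_config = sim_cfg, sim = sim, truth = truth,
                 scans_raw = scans_raw, scans = scans,
                 array_fc = array_fc, array_fc_all = array_fc_all,
                 counts = counts_n, pooled = list(pro = pooled_pro,
                                                  qui = pooled_qui),
                 seq_fc = seq_fc, mapping = mapping,
                 mapping_summary = msum,
                 tables = list(table1 = table1,
                               table1_intensity = table1_intensity,
                               table2 = table2, table3 = table3,
                               table4 = table4, threshold = table_thresh,
                               table5 = table5),
                 overlap = overlap, threshold = thresh, qpcr = qpcr_cmp,
                 manifest = manifest))
}
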