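test_that("generator output follows the configuration and is deterministic", {
  cfg <- small_config(seed = 11)
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(sim1, sim2)

  expect_equal(nrow(sim1$seq_probes), 50L)
  expect_equal(nrow(sim1$array_probes), 60L)
  expect_equal(sum(sim1$array_probes$decoy), round(0.1 * 60))

  # written FASTA is byte-identical across reruns
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(sim1$genome, f1)
  write_genome_fasta(sim2$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_error(simulation_config(transcript_length_range = c(50L, 60L)),
               "exceed array_probe_length")
})

test_that("exact probes are substrings of their transcripts; decoys and mutated probes are genome-absent", {
  sim <- simulate_genome(small_config(seed = 3))
  ap <- sim$array_probes
  tx_seq <- setNames(sim$seq_probes$sequence, sim$seq_probes$ensembl_id)
  for (i in which(ap$probe_class == "exact")) {
    expect_true(grepl(ap$sequence[i], tx_seq[[ap$source_transcript[i]]],
                      fixed = TRUE),
                info = ap$probe_id[i])
  }
  for (i in which(ap$probe_class %in% c("decoy", "mutated"))) {
    fwd <- any(grepl(ap$sequence[i], sim$genome, fixed = TRUE))
    rev <- any(grepl(rc_base(ap$sequence[i]), sim$genome, fixed = TRUE))
    expect_false(fwd || rev, info = ap$probe_id[i])
  }
  # decoys carry no IDs and no source; mutated probes keep their source ID
  expect_true(all(ap$ensembl_ids[ap$decoy] == ""))
  expect_true(all(is.na(ap$source_transcript[ap$decoy])))
  mut <- ap[ap$probe_class == "mutated", ]
  expect_true(all(mapply(grepl, mut$source_transcript, mut$ensembl_ids,
                         MoreArgs = list(fixed = TRUE))))
})

test_that("ground truth has exactly the configured number of changed genes", {
  for (seed in c(1, 7, 23, 99)) {
    truth <- simulate_expression(small_config(seed = seed))
    changed <- truth$true_log2_fc != 0
    expect_equal(sum(changed), 10L)
    expect_true(all(abs(truth$true_log2_fc[changed]) >= log2(5)))
    fc <- truth$abundance_qui / truth$abundance_pro
    expect_true(all(fc[changed] >= 5 - 1e-9 | fc[changed] <= 1 / 5 + 1e-9))
  }
  none <- simulate_expression(small_config(n_genes_changed = 0L))
  expect_true(all(none$true_log2_fc == 0))
  expect_equal(none$abundance_pro, none$abundance_qui)
})

test_that("microarray model: noise-free fold changes are exact, crosstalk mixes linearly, dye swap is reciprocal", {
  cfg <- noise_free_config(seed = 5)
  sim <- simulate_genome(cfg)
  truth <- simulate_expression(cfg)
  scan <- simulate_microarray(truth, sim$array_probes, "qui-cy5", cfg)
  fc <- array_fold_changes(scan)
  src <- sim$array_probes$source_transcript[match(fc$probe_id,
                                                  sim$array_probes$probe_id)]
  keep <- !is.na(src)
  want <- truth$true_log2_fc[match(src[keep], truth$transcript_id)]
  expect_equal(fc$log2_fc[keep], want, tolerance = 1e-12)

  # crosstalk: observed = clean + alpha * other channel, both directions
  cfg_x <- noise_free_config(seed = 5, crosstalk_alpha = 0.1)
  mixed <- simulate_microarray(truth, sim$array_probes, "qui-cy5", cfg_x)
  expect_equal(mixed$intensities$cy3,
               scan$intensities$cy3 + 0.1 * scan$intensities$cy5)
  expect_equal(mixed$intensities$cy5,
               scan$intensities$cy5 + 0.1 * scan$intensities$cy3)

  # dye-swapped assay, noise-free: raw channel ratios are reciprocal, but
  # with the orientation recorded the state fold changes are identical
  swapped <- simulate_microarray(truth, sim$array_probes, "qui-cy3", cfg)
  expect_equal(swapped$intensities$cy5 / swapped$intensities$cy3,
               scan$intensities$cy3 / scan$intensities$cy5,
               tolerance = 1e-12)
  fc_sw <- array_fold_changes(swapped)
  expect_equal(fc_sw$fc[match(fc$probe_id, fc_sw$probe_id)], fc$fc,
               tolerance = 1e-12)

  # a probe with no source and no decoy flag is rejected
  bad <- sim$array_probes
  bad$decoy[1] <- FALSE
  bad$source_transcript[1] <- NA
  expect_error(simulate_microarray(truth, bad, "qui-cy5", cfg),
               "not flagged decoy")
})

test_that("RNA-seq counts: deterministic, zero abundance gives zero counts, RPKM tracks abundance at large depth", {
  cfg <- small_config(seed = 9)
  sim <- simulate_genome(cfg)
  truth <- simulate_expression(cfg)
  c1 <- simulate_rnaseq_counts(truth, sim$seq_probes, "pro", 1e5,
                               nb_dispersion = 0.1, seed = 4)
  c2 <- simulate_rnaseq_counts(truth, sim$seq_probes, "pro", 1e5,
                               nb_dispersion = 0.1, seed = 4)
  expect_identical(c1, c2)
  expect_error(simulate_rnaseq_counts(truth, sim$seq_probes, "pro", 1e5,
                                      nb_dispersion = -1), ">= 0")
  expect_error(simulate_rnaseq_counts(truth, sim$seq_probes, "pro", 0), "positive")

  zt <- truth
  zt$abundance_pro[3] <- 0
  cz <- simulate_rnaseq_counts(zt, sim$seq_probes, "pro", 1e5, seed = 2)
  zp <- sim$seq_probes$probe_id[sim$seq_probes$ensembl_id ==
                                  truth$transcript_id[3]]
  expect_equal(cz$raw_count[cz$probe_id == zp], 0L)

  # law of large numbers: RPKM / abundance constant across probes at 1e6 reads
  big <- rpkm_normalize(simulate_rnaseq_counts(truth, sim$seq_probes, "qui",
                                               1e6, nb_dispersion = 0,
                                               seed = 8))
  ab <- truth$abundance_qui[match(sim$seq_probes$ensembl_id,
                                  truth$transcript_id)]
  ratio <- big$rpkm / ab
  expect_lt(sd(ratio) / mean(ratio), 0.05)
})

test_that("qPCR CT model inverts exactly in the noise-free limit", {
  cfg <- noise_free_config(seed = 13)
  truth <- simulate_expression(cfg)
  normalizers <- head(truth$transcript_id[truth$true_log2_fc == 0], 4)
  genes <- head(truth$transcript_id[truth$true_log2_fc != 0], 6)
  ct <- simulate_qpcr(truth, genes, normalizers, cfg)
  wide <- average_ct(ct)

  # normalizer delta-CT identical across states when noise-free
  nw <- wide[wide$gene %in% normalizers, ]
  expect_equal(nw$ct_qui - nw$ct_pro, rep(0, nrow(nw)), tolerance = 1e-9)

  # downstream ddCT fold change equals the true fold change exactly
  qfc <- qpcr_fold_changes(ct, normalizers)
  want <- 2^truth$true_log2_fc[match(qfc$probe_id, truth$transcript_id)]
  expect_equal(qfc$fc, want, tolerance = 1e-9)

  # requesting an unknown gene or a changed normalizer is rejected
  expect_error(simulate_qpcr(truth, "ENSTnope", normalizers, cfg), "absent")
  expect_error(simulate_qpcr(truth, genes, genes[1], cfg),
               "true log2 FC = 0")
})

test_that("generated files round-trip through the package readers", {
  cfg <- small_config(seed = 21)
  sim <- simulate_genome(cfg)
  truth <- simulate_expression(cfg)
  dir <- withr::local_tempdir()

  fa <- file.path(dir, "g.fa")
  write_genome_fasta(sim$genome, fa)
  expect_identical(read_genome_fasta(fa), sim$genome)
  fa2 <- file.path(dir, "g2.fa")
  write_genome_fasta(read_genome_fasta(fa), fa2)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fa2, "raw", file.size(fa2)))

  tsv <- file.path(dir, "probes.tsv")
  write_tsv(sim$array_probes, tsv)
  back <- read_tsv(tsv)
  expect_equal(back$sequence, sim$array_probes$sequence)
  expect_equal(back$ensembl_ids, sim$array_probes$ensembl_ids)

  ct <- rpkm_normalize(simulate_rnaseq_counts(truth, sim$seq_probes, "pro",
                                              1e4, seed = 1,
                                              sample_label = "PRO1"))
  cf <- file.path(dir, "counts.tsv")
  write_counts_tsv(ct, cf)
  back_ct <- read_counts_tsv(cf)
  expect_equal(back_ct$raw_count, ct$raw_count)
  expect_equal(back_ct$rpkm, ct$rpkm)
  expect_identical(attr(back_ct, "sample"), "PRO1")
  expect_equal(attr(back_ct, "total_reads"), attr(ct, "total_reads"))

  rc <- file.path(dir, "run.cfg")
  write_run_config(list(a = 1, b = "x,y"), rc)
  expect_identical(read_run_config(rc), list(a = "1", b = "x,y"))
})
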