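test_that("identical configurations reproduce identical outputs", {
  cfg <- small_sim_config(seed = 9, reads = 500)
  s1 <- generate_genome(cfg)
  s2 <- generate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$annotation$instances, s2$annotation$instances)
  r1 <- generate_reads(s1, cfg)
  r2 <- generate_reads(s2, cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$truth, r2$truth)

  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(s1, r1, d1)
  write_simulation(s2, r2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero copies yield an annotation-free background genome", {
  cfg <- simulation_config(
    seed = 2, contig_lengths = 20000L,
    repeat_families = list(family_spec("SAT", 120, copy_number = 0,
                                       tandem = TRUE,
                                       baseline_expression = 0.1)),
    n_background_genes = 5L, reads_per_sample = 0L)
  sim <- generate_genome(cfg)
  expect_equal(nrow(sim$annotation$instances), 0L)
  expect_equal(nchar(sim$genome), c(ctg01 = 20000L))
})

test_that("zero divergence copies the consensus exactly into the genome", {
  cfg <- simulation_config(
    seed = 4, contig_lengths = 10000L,
    repeat_families = list(family_spec("EL", 200, copy_number = 1,
                                       divergence = 0,
                                       baseline_expression = 0.1)),
    n_background_genes = 0L, reads_per_sample = 0L)
  sim <- generate_genome(cfg)
  ins <- sim$annotation$instances
  expect_equal(nrow(ins), 1L)
  seq <- substr(sim$genome[ins$contig], ins$start + 1, ins$end)
  if (ins$strand == "-") seq <- oracle_revcomp(seq)
  expect_identical(unname(seq), unname(sim$annotation$families[["EL"]]))
})

test_that("tandem arrays are adjacent and diverge at the configured rate", {
  cfg <- simulation_config(
    seed = 7, contig_lengths = 50000L,
    repeat_families = list(family_spec("SATMIN_like", 120, copy_number = 20,
                                       divergence = 0.08, tandem = TRUE,
                                       baseline_expression = 0.1)),
    n_background_genes = 0L, reads_per_sample = 0L)
  sim <- generate_genome(cfg)
  ins <- sim$annotation$instances
  expect_equal(nrow(ins), 20L)
  ins <- ins[order(ins$start), ]
  expect_true(all(diff(ins$start) == 120L))
  expect_equal(sum(ins$end - ins$start), 2400L)
  # direct pairwise Hamming comparison of emitted copies vs consensus
  cons <- strsplit(sim$annotation$families[["SATMIN_like"]], "")[[1]]
  mism <- 0L
  for (i in seq_len(nrow(ins))) {
    copy <- strsplit(substr(sim$genome[ins$contig[i]], ins$start[i] + 1,
                            ins$end[i]), "")[[1]]
    mism <- mism + sum(copy != cons)
  }
  frac <- mism / 2400
  se <- sqrt(0.08 * 0.92 / 2400)
  expect_lt(abs(frac - 0.08), 3 * se)
})

test_that("footprint overflow and zero-length contigs are rejected", {
  expect_error(
    generate_genome(simulation_config(
      seed = 1, contig_lengths = 5000L,
      repeat_families = list(family_spec("BIG", 500, copy_number = 10,
                                         baseline_expression = 1)),
      n_background_genes = 0L, reads_per_sample = 0L)),
    "80%")
  expect_error(simulation_config(contig_lengths = 0L))
})

test_that("zero sequencing error makes every read an exact substring of its transcript", {
  cfg <- simulation_config(
    seed = 5, contig_lengths = 8000L,
    repeat_families = list(family_spec("EL", 400, copy_number = 1,
                                       divergence = 0,
                                       baseline_expression = 1,
                                       strand_symmetric = FALSE)),
    n_background_genes = 0L, reads_per_sample = 300L, error_rate = 0)
  sim <- generate_genome(cfg)
  rd <- generate_reads(sim, cfg)
  ins <- sim$annotation$instances
  tr <- substr(sim$genome[ins$contig], ins$start + 1, ins$end)
  if (ins$strand == "-") tr <- oracle_revcomp(tr)
  reads <- rd$samples[["control_1"]]
  expect_length(reads, 300L)
  expect_true(all(vapply(reads, function(r) grepl(r, tr, fixed = TRUE),
                         logical(1))))
})

test_that("provenance tag counts conserve the read total and empty designs work", {
  cfg <- small_sim_config(seed = 6, reads = 1500)
  sim <- generate_genome(cfg)
  rd <- generate_reads(sim, cfg)
  for (s in names(rd$samples)) {
    tr <- rd$truth[rd$truth$sample == s, ]
    expect_equal(sum(tr$read_count), 1500L)
    expect_equal(sum(tr$true_fraction), 1, tolerance = 1e-12)
  }
  cfg0 <- small_sim_config(seed = 6, reads = 0)
  rd0 <- generate_reads(generate_genome(cfg0), cfg0)
  expect_length(rd0$samples[["control_1"]], 0L)
})

test_that("an empty fold-change map gives identical pools for both conditions", {
  cfg <- small_sim_config(seed = 8, reads = 1000)
  rd <- generate_reads(generate_genome(cfg), cfg)
  expect_true(all(rd$fold_changes$true_fc == 1))
  ctl <- rd$truth[rd$truth$sample == "control_1", ]
  trt <- rd$truth[rd$truth$sample == "treated_1", ]
  expect_equal(ctl$true_fraction, trt$true_fraction)
  # samples still differ because their RNG streams differ
  expect_false(identical(unname(rd$samples[["control_1"]]),
                         unname(rd$samples[["treated_1"]])))
})

test_that("empirical family read fractions land in the exact binomial interval", {
  cfg <- simulation_config(
    seed = 11, contig_lengths = c(30000L, 30000L),
    repeat_families = list(
      family_spec("SATMIN_like", 120, copy_number = 20, tandem = TRUE,
                  baseline_expression = 0.02)),
    n_background_genes = 20L, background_expression = 0.98,
    reads_per_sample = 50000L, replicates_per_condition = 1L)
  sim <- generate_genome(cfg)
  rd <- generate_reads(sim, cfg)
  tags <- sub("^.*\\|", "", names(rd$samples[["control_1"]]))
  x <- sum(tags == "SATMIN_like")
  ci <- qbinom(c(0.005, 0.995), 50000L, 0.02)
  expect_gte(x, ci[1])
  expect_lte(x, ci[2])
})

test_that("transcripts shorter than the read length are excluded with a warning", {
  cfg <- simulation_config(
    seed = 3, contig_lengths = 20000L,
    repeat_families = list(
      family_spec("TINY", 10, copy_number = 2, baseline_expression = 0.05,
                  strand_symmetric = FALSE),
      family_spec("EL", 300, copy_number = 2, baseline_expression = 0.5,
                  strand_symmetric = FALSE)),
    n_background_genes = 0L, reads_per_sample = 100L)
  sim <- generate_genome(cfg)
  expect_warning(rd <- generate_reads(sim, cfg), "shorter than the read length")
  tags <- sub("^.*\\|", "", names(rd$samples[["control_1"]]))
  expect_false("TINY" %in% tags)
})
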