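test_that("flank extraction uses half the read length and respects coordinates", {
  set.seed(21)
  genome <- c(ctg = random_seq(1000))
  fams <- c(EL = random_seq(80))
  ins <- data.frame(family = "EL", contig = "ctg", start = 100, end = 150,
                    strand = "+", stringsAsFactors = FALSE)
  ref <- make_ref(fams, genome, ins, L = 26L)
  expect_equal(ref$flank, 13L)
  rec <- ref$records[["EL|ctg:100-150(+)"]]
  expect_equal(nchar(rec), 76L)                 # [87, 163)
  expect_identical(rec, substr(genome[["ctg"]], 88, 163))
})

test_that("flank extension clips at contig bounds", {
  set.seed(22)
  genome <- c(ctg = random_seq(60))
  fams <- c(EL = random_seq(40))
  ins <- data.frame(family = "EL", contig = "ctg", start = 5, end = 40,
                    strand = "+", stringsAsFactors = FALSE)
  ref <- make_ref(fams, genome, ins, L = 26L)
  rec <- ref$records[["EL|ctg:5-40(+)"]]
  expect_identical(rec, substr(genome[["ctg"]], 1, 53))  # [0, 53)
})

test_that("minus-strand instances are reverse-complemented after extraction", {
  set.seed(23)
  genome <- c(ctg = random_seq(500))
  fams <- c(EL = random_seq(60))
  ins <- data.frame(family = "EL", contig = "ctg", start = 200, end = 260,
                    strand = "-", stringsAsFactors = FALSE)
  ref <- make_ref(fams, genome, ins, L = 26L)
  rec <- ref$records[["EL|ctg:200-260(-)"]]
  expect_identical(rec, oracle_revcomp(substr(genome[["ctg"]], 188, 273)))
})

test_that("mask partition and extended instances tile every contig exactly once", {
  set.seed(24)
  for (rep_i in 1:5) {
    clen <- sample(500:2000, 1)
    genome <- c(ctg = random_seq(clen))
    n_ins <- sample(1:6, 1)
    starts <- sort(sample(0:(clen - 60), n_ins))
    ins <- data.frame(family = "EL", contig = "ctg", start = starts,
                      end = pmin(starts + sample(20:60, n_ins, TRUE), clen),
                      strand = "+", stringsAsFactors = FALSE)
    ref <- make_ref(c(EL = random_seq(50)), genome, ins, L = 26L)
    # per-base boolean oracle
    in_ext <- logical(clen)
    for (i in seq_len(nrow(ins))) {
      a <- max(ins$start[i] - 13, 0) + 1
      b <- min(ins$end[i] + 13, clen)
      in_ext[a:b] <- TRUE
    }
    in_mask <- logical(clen)
    m <- ref$mask
    for (i in seq_len(nrow(m))) in_mask[(m$start[i] + 1):m$end[i]] <- TRUE
    expect_true(all(xor(in_ext, in_mask)))
    expect_equal(sum(nchar(ref$mask_seqs)) + sum(in_ext), clen)
  }
})

test_that("malformed, unknown-family and out-of-bounds annotations are rejected", {
  set.seed(25)
  dir <- tempfile(); dir.create(dir)
  genome <- c(ctg = random_seq(300))
  writeLines(c(">ctg", genome), file.path(dir, "genome.fa"))
  writeLines(c(">EL", random_seq(50)), file.path(dir, "consensus.fa"))
  bed <- function(rows) {
    p <- file.path(dir, "repeats.bed")
    writeLines(rows, p)
    p
  }
  gfa <- file.path(dir, "genome.fa"); cfa <- file.path(dir, "consensus.fa")
  expect_error(load_annotation(cfa, bed("ctg\t50\t40\tEL\t0\t+"), gfa),
               "greater than start")
  expect_error(load_annotation(cfa, bed("ctg\t10\t60\tNOPE\t0\t+"), gfa),
               "NOPE")
  expect_error(load_annotation(cfa, bed("ctg\t250\t400\tEL\t0\t+"), gfa),
               "beyond contig end")
  # empty BED: families kept, zero instances
  ann <- load_annotation(cfa, bed(character(0)), gfa)
  expect_equal(nrow(ann$instances), 0L)
  expect_named(ann$families, "EL")
  unlink(dir, recursive = TRUE)
})

test_that("simulated datasets round-trip through the on-disk formats", {
  cfg <- small_sim_config(seed = 31, reads = 200)
  sim <- generate_genome(cfg)
  rd <- generate_reads(sim, cfg)
  dir <- tempfile()
  write_simulation(sim, rd, dir)
  ann <- load_annotation(file.path(dir, "consensus.fa"),
                         file.path(dir, "repeats.bed"),
                         file.path(dir, "genome.fa"))
  expect_identical(sort(names(ann$families)),
                   sort(names(sim$annotation$families)))
  expect_identical(unname(ann$families[names(sim$annotation$families)]),
                   unname(sim$annotation$families))
  a <- ann$instances[order(ann$instances$contig, ann$instances$start), ]
  b <- sim$annotation$instances[order(sim$annotation$instances$contig,
                                      sim$annotation$instances$start), ]
  rownames(a) <- rownames(b) <- NULL
  a$start <- as.numeric(a$start); a$end <- as.numeric(a$end)
  b$start <- as.numeric(b$start); b$end <- as.numeric(b$end)
  expect_equal(a, b)
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(g, sim$genome)
  fq <- read_fastq(file.path(dir, "sample_control_1.fastq"))
  expect_identical(fq, rd$samples[["control_1"]])
  unlink(dir, recursive = TRUE)
})

test_that("references round-trip and duplicate instances are deduplicated", {
  set.seed(26)
  genome <- c(ctg = random_seq(800))
  fams <- c(A = random_seq(60), B = random_seq(70))
  ins <- data.frame(family = c("A", "A", "B"), contig = "ctg",
                    start = c(100, 100, 400), end = c(160, 160, 470),
                    strand = "+", stringsAsFactors = FALSE)
  expect_message(ref <- make_ref(fams, genome, ins, L = 26L),
                 "deduplicated 1")
  expect_equal(sum(ref$record_kind == "instance"), 2L)
  dir <- tempfile()
  write_reference(ref, dir)
  ref2 <- load_reference(dir)
  expect_identical(ref2$records, ref$records)
  expect_identical(ref2$record_family, ref$record_family)
  expect_equal(ref2$flank, ref$flank)
  expect_identical(unname(ref2$mask_seqs), unname(ref$mask_seqs))
  unlink(dir, recursive = TRUE)
  # no instances: canonical records only
  ref0 <- make_ref(fams, genome, L = 26L)
  expect_setequal(names(ref0$records), c("A|consensus", "B|consensus"))
})

test_that("the reference build is a pure function of its inputs", {
  set.seed(27)
  genome <- c(c1 = random_seq(600), c2 = random_seq(400))
  fams <- c(A = random_seq(50))
  ins <- data.frame(family = "A", contig = c("c1", "c2"),
                    start = c(10, 100), end = c(60, 150),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  r1 <- make_ref(fams, genome, ins)
  r2 <- make_ref(fams, genome, ins)
  expect_identical(r1, r2)
})
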