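#' Describe one synthetic repeat family
#'
#' A family emulates a class of repetitive elements: tandem satellites
#' (major/minor satellite-like arrays), or interspersed LINE/SINE/ERV-like
#' elements.  Genomic instances are copies of a random consensus, diverged
#' by independent per-base substitutions.
#'
#' @param name Family identifier, e.g. `"SATMIN_like"`.
#' @param consensus_length Length of the canonical (consensus) sequence in bp.
#' @param copy_number Number of genomic instances.
#' @param divergence Per-base substitution rate of instances relative to the
#'   consensus, in `[0, 0.3]`.
#' @param tandem If `TRUE`, instances are placed as one adjacent array on a
#'   single contig (satellite-like); otherwise they are interspersed.
#' @param baseline_expression Relative transcription weight of the family in
#'   the control condition (unnormalized; see [simulation_config()]).
#' @param strand_symmetric If `TRUE`, transcripts are emitted from both
#'   strands (satellite arrays transcribe bidirectionally, yielding dsRNA).
#' @return A `family_spec` object.
#' @export
family_spec <- function(name, consensus_length, copy_number,
                        divergence = 0.05, tandem = FALSE,
                        baseline_expression = 1,
                        strand_symmetric = tandem) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            consensus_length >= 1, copy_number >= 0,
            divergence >= 0, divergence <= 0.3,
            is.logical(tandem), baseline_expression >= 0,
            is.logical(strand_symmetric))
  structure(list(name = name,
                 consensus_length = as.integer(consensus_length),
                 copy_number = as.integer(copy_number),
                 divergence = divergence,
                 tandem = tandem,
                 baseline_expression = baseline_expression,
                 strand_symmetric = strand_symmetric),
            class = "family_spec")
}

#' Default synthetic repeat families
#'
#' Four families emulating the repeat classes whose derepression the
#' pipeline is designed to detect: a major-satellite-like and a
#' minor-satellite-like tandem array (bidirectionally transcribed), a
#' LINE1-like long interspersed element, and a B1/SINE-like short
#' interspersed element.  Unit lengths approximate the mouse families
#' (234 bp major satellite, 120 bp minor satellite, ~135 bp B1); the
#' LINE1-like consensus is shortened to 1.2 kb to fit a desk-scale genome.
#' Baseline weights put the repeatome at ~12% of the transcript pool, with
#' the minor satellite rare (0.5%) so that strong derepression remains a
#' small fraction of the library.
#'
#' @return A list of [family_spec()] objects.
#' @export
default_repeat_families <- function() {
  list(
    family_spec("GSAT_like", consensus_length = 234, copy_number = 40,
                divergence = 0.05, tandem = TRUE,
                baseline_expression = 0.030, strand_symmetric = TRUE),
    family_spec("SATMIN_like", consensus_length = 120, copy_number = 40,
                divergence = 0.05, tandem = TRUE,
                baseline_expression = 0.005, strand_symmetric = TRUE),
    family_spec("LINE1_like", consensus_length = 1200, copy_number = 8,
                divergence = 0.10, tandem = FALSE,
                baseline_expression = 0.040, strand_symmetric = FALSE),
    family_spec("B1_like", consensus_length = 135, copy_number = 30,
                divergence = 0.08, tandem = FALSE,
                baseline_expression = 0.050, strand_symmetric = FALSE)
  )
}

#' Configuration of a synthetic repeatome experiment
#'
#' Defines the study conditions the simulator emulates: a small multi-contig
#' genome carrying tandem satellite arrays and interspersed elements,
#' background protein-coding-like genes (a fraction of which embed an
#' unannotated SINE fragment, creating decoy multi-mappers), and short
#' single-end reads for two conditions, where "treated" multiplies selected
#' family weights by a derepression fold change.
#'
#' @param seed Master seed; fixes every byte of the output.
#' @param contig_lengths Integer vector of contig lengths (bp).
#' @param repeat_families List of [family_spec()] objects.
#' @param n_background_genes Number of background gene loci.
#' @param read_length Read length L in bp.  Defaults to 26, twice the 13-bp
#'   flank used when building the combined reference.
#' @param reads_per_sample Reads per FASTQ sample.
#' @param error_rate Per-base substitution error probability in `[0, 1)`.
#' @param replicates_per_condition Biological replicates per condition
#'   (default 2).
#' @param condition_fold_changes Named numeric vector, family name to
#'   multiplicative fold change (>= 0) applied to that family's expression
#'   weight in the treated condition.  Families not named keep fold change 1.
#' @param background_expression Total unnormalized expression weight of the
#'   background genes (split equally among genes).
#' @param gene_length_range Length range (bp) of background gene loci.
#' @param sine_embed_fraction Fraction of background genes embedding one
#'   diverged, unannotated SINE fragment.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(seed = 1L,
                              contig_lengths = c(60000L, 60000L),
                              repeat_families = default_repeat_families(),
                              n_background_genes = 30L,
                              read_length = 26L,
                              reads_per_sample = 50000L,
                              error_rate = 0.005,
                              replicates_per_condition = 2L,
                              condition_fold_changes = numeric(0),
                              background_expression = 0.875,
                              gene_length_range = c(500L, 2000L),
                              sine_embed_fraction = 0.2) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            length(contig_lengths) >= 1L, all(contig_lengths >= 1L),
            length(repeat_families) >= 0L,
            n_background_genes >= 0L,
            read_length >= 1L,
            reads_per_sample >= 0L,
            error_rate >= 0, error_rate < 1,
            replicates_per_condition >= 1L,
            background_expression >= 0,
            length(gene_length_range) == 2L,
            gene_length_range[1] >= 1L,
            gene_length_range[2] >= gene_length_range[1],
            sine_embed_fraction >= 0, sine_embed_fraction <= 1)
  for (f in repeat_families) {
    if (!inherits(f, "family_spec")) stop("repeat_families must be family_spec objects")
  }
  fam_names <- vapply(repeat_families, `[[`, character(1), "name")
  if (anyDuplicated(fam_names)) stop("duplicated family names")
  if (length(condition_fold_changes)) {
    if (is.null(names(condition_fold_changes)) ||
        any(!nzchar(names(condition_fold_changes))))
      stop("condition_fold_changes must be a named vector")
    unknown <- setdiff(names(condition_fold_changes), fam_names)
    if (length(unknown))
      stop("condition_fold_changes names unknown: ", paste(unknown, collapse = ", "))
    if (any(!is.finite(condition_fold_changes)) || any(condition_fold_changes < 0))
      stop("fold changes must be finite and non-negative")
  }
  structure(list(seed = as.integer(seed),
                 contig_lengths = as.integer(contig_lengths),
                 repeat_families = repeat_families,
                 n_background_genes = as.integer(n_background_genes),
                 read_length = as.integer(read_length),
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 condition_fold_changes = condition_fold_changes,
                 background_expression = background_expression,
                 gene_length_range = as.integer(gene_length_range),
                 sine_embed_fraction = sine_embed_fraction),
            class = "simulation_config")
}

# find a free start for a feature of length len on some contig, keeping
# `margin` bp clear of previously placed features; occupied is a list of
# two-column matrices (start0, end0) per contig
place_feature <- function(occupied, contig_lengths, len, margin,
                          max_tries = 2000L) {
  ncontig <- length(contig_lengths)
  for (i in seq_len(max_tries)) {
    ctg <- sample.int(ncontig, 1L)
    room <- contig_lengths[ctg] - len
    if (room < 0) next
    start <- floor(runif(1) * (room + 1))
    lo <- start - margin
    hi <- start + len + margin
    occ <- occupied[[ctg]]
    if (is.null(occ) || nrow(occ) == 0L ||
        all(occ[, 2] <= lo | occ[, 1] >= hi)) {
      return(list(contig = ctg, start = start))
    }
  }
  stop("could not place a feature of ", len,
       " bp: genome too small for the requested repeat footprint; ",
       "increase contig_lengths or reduce copy numbers")
}

#' Generate a synthetic genome and repeat annotation
#'
#' Builds i.i.d. uniform background contigs, writes diverged copies of each
#' family consensus into them (tandem families as one adjacent array,
#' interspersed families at random positions and strands), and places
#' background gene loci, a fraction of which embed an unannotated SINE
#' fragment.  Coordinates are 0-based half-open.
#'
#' @param config A [simulation_config()].
#' @return A `sim_genome` object: list with `genome` (named character vector
#'   of contig sequences), `annotation` (a [repeat_annotation()]), and
#'   `genes` (data.frame of gene loci with an `embedded` flag).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fams <- config$repeat_families
  footprint <- sum(vapply(fams, function(f)
    as.numeric(f$consensus_length) * f$copy_number, numeric(1)))
  if (footprint > 0.8 * sum(config$contig_lengths))
    stop("repeat footprint (", footprint, " bp) exceeds 80% of the genome (",
         sum(config$contig_lengths), " bp); enlarge contigs or reduce copies")

  consensus <- with_stream(config$seed, "consensus", {
    setNames(
      vapply(fams, function(f) random_dna(f$consensus_length), character(1)),
      vapply(fams, `[[`, character(1), "name"))
  })

  contig_names <- sprintf("ctg%02d", seq_along(config$contig_lengths))
  contigs <- with_stream(config$seed, "background", {
    lapply(config$contig_lengths, random_bases)
  })
  names(contigs) <- contig_names

  margin <- config$read_length + 5L
  occupied <- rep(list(matrix(numeric(0), 0, 2)), length(contigs))
  note <- function(ctg, s, e) {
    occupied[[ctg]] <<- rbind(occupied[[ctg]], c(s, e))
  }

  inst <- list()
  with_stream(config$seed, "placement", {
    for (f in fams) {
      if (f$copy_number == 0L) next
      cons <- strsplit(consensus[[f$name]], "", fixed = TRUE)[[1]]
      if (f$tandem) {
        block <- f$consensus_length * f$copy_number
        at <- place_feature(occupied, config$contig_lengths, block, margin)
        note(at$contig, at$start, at$start + block)
        for (i in seq_len(f$copy_number)) {
          s <- at$start + (i - 1L) * f$consensus_length
          copy <- mutate_bases(cons, f$divergence)
          contigs[[at$contig]][(s + 1):(s + f$consensus_length)] <- copy
          inst[[length(inst) + 1L]] <- data.frame(
            family = f$name, contig = contig_names[at$contig],
            start = s, end = s + f$consensus_length, strand = "+",
            stringsAsFactors = FALSE)
        }
      } else {
        for (i in seq_len(f$copy_number)) {
          at <- place_feature(occupied, config$contig_lengths,
                              f$consensus_length, margin)
          note(at$contig, at$start, at$start + f$consensus_length)
          strand <- sample(c("+", "-"), 1L)
          copy <- mutate_bases(cons, f$divergence)
          seq <- paste(copy, collapse = "")
          if (strand == "-") seq <- revcomp(seq)
          contigs[[at$contig]][(at$start + 1):(at$start + f$consensus_length)] <-
            strsplit(seq, "", fixed = TRUE)[[1]]
          inst[[length(inst) + 1L]] <- data.frame(
            family = f$name, contig = contig_names[at$contig],
            start = at$start, end = at$start + f$consensus_length,
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  })

  genes <- data.frame(gene = character(0), contig = character(0),
                      start = numeric(0), end = numeric(0),
                      embedded = logical(0), stringsAsFactors = FALSE)
  if (config$n_background_genes > 0L) {
    # pick the SINE-like donor for embedded decoy fragments: the shortest
    # non-tandem family, if any
    donor <- NULL
    non_tandem <- Filter(function(f) !f$tandem, fams)
    if (length(non_tandem)) {
      lens <- vapply(non_tandem, `[[`, integer(1), "consensus_length")
      donor <- non_tandem[[which.min(lens)]]$name
    }
    with_stream(config$seed, "genes", {
      n_embed <- round(config$sine_embed_fraction * config$n_background_genes)
      for (g in seq_len(config$n_background_genes)) {
        len <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1L)
        at <- place_feature(occupied, config$contig_lengths, len, margin)
        note(at$contig, at$start, at$start + len)
        embedded <- FALSE
        if (!is.null(donor) && g <= n_embed) {
          cons <- consensus[[donor]]
          frag_len <- min(150L, nchar(cons), len - 2L)
          if (frag_len >= 30L) {
            fs <- sample.int(nchar(cons) - frag_len + 1L, 1L)
            frag <- mutate_seq(substr(cons, fs, fs + frag_len - 1L), 0.02)
            if (sample(c(TRUE, FALSE), 1L)) frag <- revcomp(frag)
            off <- sample.int(len - frag_len + 1L, 1L) - 1L
            contigs[[at$contig]][(at$start + off + 1):(at$start + off + frag_len)] <-
              strsplit(frag, "", fixed = TRUE)[[1]]
            embedded <- TRUE
          }
        }
        genes[nrow(genes) + 1L, ] <- list(
          sprintf("gene%03d", g), contig_names[at$contig],
          at$start, at$start + len, embedded)
      }
    })
  }

  genome <- vapply(contigs, paste, character(1), collapse = "")
  instances <- if (length(inst)) do.call(rbind, inst) else
    data.frame(family = character(0), contig = character(0),
               start = numeric(0), end = numeric(0), strand = character(0),
               stringsAsFactors = FALSE)
  structure(list(genome = genome,
                 annotation = repeat_annotation(consensus, instances),
                 genes = genes),
            class = "sim_genome")
}

# transcript pool for one condition: data.frame(seq, family, weight)
transcript_pool <- function(sim, config, condition) {
  fams <- config$repeat_families
  fc <- config$condition_fold_changes
  rows <- list()
  add <- function(seqs, family, total_weight) {
    if (!length(seqs) || total_weight <= 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      seq = seqs, family = family,
      weight = total_weight / length(seqs), stringsAsFactors = FALSE)
  }
  ann <- sim$annotation
  for (f in fams) {
    idx <- which(ann$instances$family == f$name)
    if (!length(idx)) next
    ins <- ann$instances[idx, , drop = FALSE]
    seqs <- extract_instances(sim$genome, ins, flank = 0L)
    if (f$tandem && nrow(ins) >= 2L) {
      # read-through concatemers of 2 and 3 adjacent units
      ord <- order(ins$start)
      s <- seqs[ord]
      for (u in 2:3) {
        if (nrow(ins) < u) break
        starts <- seq(1L, nrow(ins) - u + 1L, by = u)
        seqs <- c(seqs, vapply(starts, function(i)
          paste(s[i:(i + u - 1L)], collapse = ""), character(1)))
      }
    }
    if (f$strand_symmetric) seqs <- c(seqs, revcomp(seqs))
    w <- f$baseline_expression
    if (condition == "treated" && f$name %in% names(fc)) w <- w * fc[[f$name]]
    add(seqs, f$name, w)
  }
  if (nrow(sim$genes)) {
    gseq <- substr(rep(sim$genome[sim$genes$contig], 1L),
                   sim$genes$start + 1L, sim$genes$end)
    add(gseq, "background", config$background_expression)
  }
  pool <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq = character(0), family = character(0), weight = numeric(0))
  short <- nchar(pool$seq) < config$read_length
  if (any(short)) {
    warning(sum(short), " transcript(s) shorter than the read length excluded")
    pool <- pool[!short, , drop = FALSE]
  }
  if (nrow(pool) == 0L || sum(pool$weight) <= 0)
    stop("transcript pool is empty or has zero total weight")
  pool$weight <- pool$weight / sum(pool$weight)
  pool
}

#' Simulate reads for every sample of a two-condition design
#'
#' Draws reads from a condition-specific transcript pool: each family's
#' weight is its baseline expression, multiplied in "treated" by the
#' configured derepression fold change.  Satellite (tandem) families
#' transcribe read-through concatemers of up to three units;
#' strand-symmetric families contribute both orientations.  Substitution
#' errors are i.i.d. per base.  Read names carry a provenance tag
#' (`|family` or `|background`) used by validation oracles.
#'
#' @param sim A `sim_genome` from [generate_genome()].
#' @param config The same [simulation_config()].
#' @return A `sim_reads` object: list with `samples` (named list of named
#'   character vectors of read sequences), `sample_info` (data.frame),
#'   `truth` (per sample x family true read fractions and realized counts)
#'   and `fold_changes` (per family true treated/control fraction ratio).
#' @export
generate_reads <- function(sim, config) {
  stopifnot(inherits(sim, "sim_genome"), inherits(config, "simulation_config"))
  L <- config$read_length
  conditions <- c("control", "treated")
  # both pools hold the same transcripts (only weights differ), so any
  # short-transcript warning is raised once
  pools <- list(control = transcript_pool(sim, config, "control"),
                treated = suppressWarnings(
                  transcript_pool(sim, config, "treated")))

  fam_frac <- function(pool) {
    tapply(pool$weight, pool$family, sum)
  }
  fam_names <- sort(unique(c(unlist(lapply(pools, function(p) unique(p$family))))))

  samples <- list()
  sample_info <- data.frame(sample = character(0), condition = character(0),
                            replicate = integer(0), stringsAsFactors = FALSE)
  truth <- list()
  for (cond in conditions) {
    pool <- pools[[cond]]
    frac <- fam_frac(pool)
    for (rep_i in seq_len(config$replicates_per_condition)) {
      sname <- sprintf("%s_%d", cond, rep_i)
      reads <- with_stream(config$seed, paste0("reads/", sname), {
        n <- config$reads_per_sample
        if (n == 0L) {
          character(0)
        } else {
          tr <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight)
          maxs <- nchar(pool$seq)[tr] - L
          pos <- floor(runif(n) * (maxs + 1))
          out <- substr(pool$seq[tr], pos + 1L, pos + L)
          errs <- rbinom(n, L, config$error_rate)
          for (i in which(errs > 0L)) {
            b <- strsplit(out[i], "", fixed = TRUE)[[1]]
            at <- sample.int(L, errs[i])
            b[at] <- mutate_bases_forced(b[at])
            out[i] <- paste(b, collapse = "")
          }
          names(out) <- sprintf("%s_%07d|%s", sname, seq_len(n),
                                pool$family[tr])
          out
        }
      })
      samples[[sname]] <- reads
      sample_info[nrow(sample_info) + 1L, ] <-
        list(sname, cond, rep_i)
      tags <- sub("^.*\\|", "", names(reads))
      cnt <- table(factor(tags, levels = fam_names))
      truth[[length(truth) + 1L]] <- data.frame(
        sample = sname, condition = cond, replicate = rep_i,
        family = fam_names,
        true_fraction = as.numeric(frac[fam_names]),
        read_count = as.integer(cnt), stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  ctl <- fam_frac(pools$control)
  trt <- fam_frac(pools$treated)
  fold_changes <- data.frame(
    family = fam_names,
    control_fraction = as.numeric(ctl[fam_names]),
    treated_fraction = as.numeric(trt[fam_names]),
    true_fc = as.numeric(trt[fam_names] / ctl[fam_names]),
    stringsAsFactors = FALSE)

  structure(list(samples = samples, sample_info = sample_info,
                 truth = truth, fold_changes = fold_changes),
            class = "sim_reads")
}

# substitute each base to a uniformly random *different* base
mutate_bases_forced <- function(bases) {
  cur <- match(bases, DNA_BASES)
  cur[is.na(cur)] <- 1L
  shift <- sample.int(3L, length(bases), replace = TRUE)
  DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa` (60-column FASTA), `consensus.fa`, `repeats.bed`
#' (BED6: contig, start, end, family, 0, strand), `genes.bed`,
#' `sample_<condition>_<replicate>.fastq` (constant quality "I"),
#' `truth.tsv` and `fold_changes.tsv`.
#'
#' @param sim A `sim_genome` from [generate_genome()].
#' @param reads A `sim_reads` from [generate_reads()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, reads, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             consensus = file.path(outdir, "consensus.fa"),
             repeats = file.path(outdir, "repeats.bed"),
             genes = file.path(outdir, "genes.bed"),
             truth = file.path(outdir, "truth.tsv"),
             fold_changes = file.path(outdir, "fold_changes.tsv"))
  write_fasta(sim$genome, paths["genome"])
  write_fasta(sim$annotation$families, paths["consensus"])
  ins <- sim$annotation$instances
  write.table(
    data.frame(ins$contig, ins$start, ins$end, ins$family, 0L, ins$strand),
    paths["repeats"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write.table(
    data.frame(sim$genes$contig, sim$genes$start, sim$genes$end,
               sim$genes$gene, as.integer(sim$genes$embedded), "+"),
    paths["genes"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write.table(reads$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(reads$fold_changes, paths["fold_changes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (sname in names(reads$samples)) {
    p <- file.path(outdir, sprintf("sample_%s.fastq", sname))
    write_fastq(reads$samples[[sname]], p)
    paths[paste0("fastq_", sname)] <- p
  }
  invisible(paths)
}
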