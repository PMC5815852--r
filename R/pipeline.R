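#' Validate and normalize a run configuration
#'
#' Accepts a YAML/JSON file path or a list.  Exactly one of `simulation`
#' (parameters for the synthetic generator) or `inputs` (paths to real
#' genome/consensus/instances/FASTQ files) must be present.  Unknown keys
#' are errors, reported with their path into the document; defaults
#' (k = 17, read length 26, masking on, poly-A filter on, BH FDR) are
#' filled in.
#'
#' @param config Path to a YAML or JSON file, or a list with the same
#'   structure.
#' @return A normalized `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))

  allowed_top <- c("seed", "read_length", "simulation", "inputs", "assign",
                   "quant", "differential")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown)) note("unknown key(s): ", paste(unknown, collapse = ", "))

  check_keys <- function(x, allowed, where) {
    u <- setdiff(names(x), allowed)
    if (length(u)) note(where, ": unknown key(s): ", paste(u, collapse = ", "))
  }

  seed <- config$seed %||% 1L
  read_length <- config$read_length %||% 26L
  has_sim <- !is.null(config$simulation)
  has_real <- !is.null(config$inputs)
  if (has_sim && has_real)
    note("exactly one of 'simulation' and 'inputs' may be present, not both")
  if (!has_sim && !has_real)
    note("one of 'simulation' or 'inputs' is required")

  sim_cfg <- NULL
  if (has_sim && is.list(config$simulation)) {
    s <- config$simulation
    check_keys(s, c("contig_lengths", "families", "n_background_genes",
                    "reads_per_sample", "error_rate",
                    "replicates_per_condition", "fold_changes",
                    "background_expression", "gene_length_range",
                    "sine_embed_fraction"), "simulation")
    fams <- s$families
    if (is.null(fams) || identical(fams, "default")) {
      fams <- default_repeat_families()
    } else if (is.list(fams)) {
      fams <- lapply(seq_along(fams), function(i) {
        f <- fams[[i]]
        check_keys(f, c("name", "consensus_length", "copy_number",
                        "divergence", "tandem", "baseline_expression",
                        "strand_symmetric"),
                   paste0("simulation/families[", i, "]"))
        tryCatch(do.call(family_spec, f), error = function(e) {
          note("simulation/families[", i, "]: ", conditionMessage(e))
          NULL
        })
      })
    }
    fc <- unlist(s$fold_changes %||% list())
    if (length(fc) && (any(!is.finite(fc)) || any(fc < 0)))
      note("simulation/fold_changes: fold changes must be finite and >= 0")
    if (!length(errs)) {
      sim_cfg <- tryCatch(simulation_config(
        seed = seed,
        contig_lengths = unlist(s$contig_lengths %||% c(60000L, 60000L)),
        repeat_families = fams,
        n_background_genes = s$n_background_genes %||% 30L,
        read_length = read_length,
        reads_per_sample = s$reads_per_sample %||% 50000L,
        error_rate = s$error_rate %||% 0.005,
        replicates_per_condition = s$replicates_per_condition %||% 2L,
        condition_fold_changes = if (length(fc)) fc else numeric(0),
        background_expression = s$background_expression %||% 0.875,
        gene_length_range = unlist(s$gene_length_range %||% c(500L, 2000L)),
        sine_embed_fraction = s$sine_embed_fraction %||% 0.2),
        error = function(e) { note("simulation: ", conditionMessage(e)); NULL })
    }
  }

  inputs <- NULL
  if (has_real && is.list(config$inputs)) {
    inp <- config$inputs
    check_keys(inp, c("genome", "consensus", "instances", "fastq"), "inputs")
    for (key in c("genome", "consensus", "instances")) {
      if (is.null(inp[[key]])) note("inputs/", key, " is required")
      else if (!file.exists(inp[[key]]))
        note("inputs/", key, ": file not found: ", inp[[key]])
    }
    fq <- inp$fastq
    if (!is.list(fq) || is.null(fq$control) || is.null(fq$treated)) {
      note("inputs/fastq must list 'control' and 'treated' FASTQ paths")
    } else {
      check_keys(fq, c("control", "treated"), "inputs/fastq")
      for (cond in c("control", "treated"))
        for (p in unlist(fq[[cond]]))
          if (!file.exists(p)) note("inputs/fastq/", cond,
                                    ": file not found: ", p)
    }
    inputs <- inp
  }

  a <- config$assign %||% list()
  check_keys(a, c("k", "min_score", "masking"), "assign")
  k_assign <- a$k %||% 17L
  if (k_assign > read_length)
    note("assign/k (", k_assign, ") exceeds read_length (", read_length, ")")
  q <- config$quant %||% list()
  check_keys(q, c("k", "polyA_filter", "alpha0", "max_iter", "tol"), "quant")
  k_quant <- q$k %||% 17L
  if (k_quant > read_length)
    note("quant/k (", k_quant, ") exceeds read_length (", read_length, ")")
  d <- config$differential %||% list()
  check_keys(d, c("fdr", "alpha", "test"), "differential")
  fdr <- d$fdr %||% "BH"
  if (!toupper(fdr) %in% c("BH")) note("differential/fdr: only 'BH' is supported")

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))

  assign_cfg <- assign_params(k = k_assign,
                              min_score = a$min_score,
                              masking = a$masking %||% TRUE)
  quant_cfg <- quant_config(k = k_quant,
                            polyA_filter = q$polyA_filter %||% TRUE,
                            alpha0 = q$alpha0 %||% 0.01,
                            max_iter = q$max_iter %||% 1000L,
                            tol = q$tol %||% 1e-8)
  structure(list(seed = as.integer(seed),
                 read_length = as.integer(read_length),
                 mode = if (has_sim) "simulation" else "real",
                 simulation = sim_cfg,
                 inputs = inputs,
                 assign = assign_cfg,
                 quant = quant_cfg,
                 differential = list(fdr = "BH",
                                     alpha = d$alpha %||% 0.05,
                                     test = d$test %||% "auto")),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full repeat-quantification pipeline
#'
#' Orchestrates simulate (or load) -> build reference -> assign -> quantify
#' -> differential test, writing every stage's outputs under `outdir` in a
#' fixed layout, plus a machine-readable `manifest.json` with the config
#' hash, per-file checksums and per-stage read accounting.  Reruns with an
#' identical configuration reproduce identical checksums.
#'
#' @param config A `run_config` from [validate_config()], or anything it
#'   accepts.
#' @param outdir Output directory.
#' @return Invisibly, a list with the manifest, the differential table and
#'   the per-sample abundance tables.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(outdir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)), failed)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    manifest <- list(tool = "repeatquant",
                     version = as.character(utils::packageVersion("repeatquant")),
                     config_hash = config_hash(config),
                     stages = list())
    log_info <- function(...) message("[repeatquant] ", ...)
    log_info("mode=", config$mode, " seed=", config$seed,
             " L=", config$read_length,
             " k=", config$assign$k,
             " masking=", config$assign$masking,
             " polyA_filter=", config$quant$polyA_filter,
             " alpha0=", config$quant$alpha0, " fdr=BH")

    stage <- "simulate"
    if (config$mode == "simulation") {
      sim <- generate_genome(config$simulation)
      reads_obj <- generate_reads(sim, config$simulation)
      simdir <- file.path(outdir, "sim")
      write_simulation(sim, reads_obj, simdir)
      genome <- sim$genome
      annotation <- sim$annotation
      samples <- reads_obj$samples
      sample_condition <- reads_obj$sample_info$condition
      names(sample_condition) <- reads_obj$sample_info$sample
      manifest$stages$simulate <- list(
        n_samples = length(samples),
        reads_per_sample = config$simulation$reads_per_sample)
    } else {
      genome <- read_genome(config$inputs$genome)
      annotation <- load_annotation(config$inputs$consensus,
                                    config$inputs$instances,
                                    config$inputs$genome)
      samples <- list()
      sample_condition <- character(0)
      for (cond in c("control", "treated")) {
        paths <- unlist(config$inputs$fastq[[cond]])
        for (i in seq_along(paths)) {
          sname <- sprintf("%s_%d", cond, i)
          samples[[sname]] <- read_fastq(paths[i])
          sample_condition[sname] <- cond
        }
      }
      manifest$stages$load <- list(n_samples = length(samples))
    }

    stage <- "build-ref"
    ref <- build_combined_reference(annotation, genome, config$read_length)
    refdir <- file.path(outdir, "ref")
    write_reference(ref, refdir)
    manifest$stages$reference <- list(
      n_records = length(ref$records),
      n_mask_intervals = nrow(ref$mask),
      flank = ref$flank)

    stage <- "assign"
    assigndir <- file.path(outdir, "assign")
    dir.create(assigndir, showWarnings = FALSE)
    assignments <- list()
    acct <- list()
    for (sname in names(samples)) {
      at <- assign_reads(samples[[sname]], ref, config$assign)
      assignments[[sname]] <- at
      sdir <- file.path(assigndir, sname)
      write_assignments(at, sdir)
      s <- assignment_summary(at)
      acct[[sname]] <- list(input = s$n_reads, skipped = s$n_skipped,
                            discarded = s$n_discarded,
                            assigned = s$n_assigned)
    }
    manifest$stages$assign <- acct

    stage <- "quant"
    quantdir <- file.path(outdir, "quant")
    dir.create(quantdir, showWarnings = FALSE)
    abundances <- list()
    for (sname in names(samples)) {
      ab <- quantify(samples[[sname]], assignments[[sname]], ref,
                     config$quant)
      abundances[[sname]] <- ab
      write_abundance(ab, file.path(quantdir, paste0(sname, ".tsv")))
      acct[[sname]]$quantified <- attr(ab, "n_quantified")
    }
    manifest$stages$quant <- lapply(acct, function(a)
      list(assigned = a$assigned, quantified = a$quantified))

    stage <- "diff"
    cm <- count_matrix(abundances, sample_condition[names(abundances)])
    diff_tab <- differential_table(cm$x, cm$N, cm$condition,
                                   test = config$differential$test)
    diffdir <- file.path(outdir, "diff")
    dir.create(diffdir, showWarnings = FALSE)
    write.table(diff_tab, file.path(diffdir, "differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$differential <- list(
      n_families_tested = nrow(diff_tab),
      n_significant = sum(diff_tab$q < config$differential$alpha))

    stage <- "manifest"
    for (sname in names(acct)) {
      a <- acct[[sname]]
      if (a$input != a$skipped + a$discarded + a$assigned)
        stop("read accounting does not reconcile for sample ", sname)
    }
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    sums <- tools::md5sum(files)
    names(sums) <- sub(paste0("^", outdir, "/?"), "", names(sums))
    manifest$checksums <- as.list(sums)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(manifest = manifest, differential = diff_tab,
                   abundances = abundances))
  }, error = on_fail)
}

# stable hash of the normalized configuration
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

strip_classes <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}
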