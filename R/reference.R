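#' Repeat annotation: consensus sequences plus genomic instances
#'
#' @param families Named character vector: family name to canonical
#'   (consensus) sequence.
#' @param instances data.frame with columns `family`, `contig`, `start`,
#'   `end`, `strand` ("+"/"-"), coordinates 0-based half-open.
#' @return A `repeat_annotation` object.
#' @export
repeat_annotation <- function(families, instances) {
  stopifnot(is.character(families),
            !is.null(names(families)), all(nzchar(names(families))),
            is.data.frame(instances))
  need <- c("family", "contig", "start", "end", "strand")
  if (!all(need %in% names(instances)))
    stop("instances must have columns: ", paste(need, collapse = ", "))
  instances <- instances[, need, drop = FALSE]
  if (nrow(instances)) {
    unknown <- setdiff(unique(instances$family), names(families))
    if (length(unknown))
      stop("instances reference unknown families: ",
           paste(unknown, collapse = ", "))
    bad <- which(!(instances$start >= 0 & instances$end > instances$start))
    if (length(bad))
      stop("malformed instance interval(s) at row(s): ",
           paste(head(bad, 5), collapse = ", "))
    if (any(!instances$strand %in% c("+", "-")))
      stop("instance strand must be '+' or '-'")
  }
  structure(list(families = families, instances = instances),
            class = "repeat_annotation")
}

#' Load a repeat annotation from consensus FASTA, BED6 instances and genome
#'
#' Validates every BED row: the family name must exist in the consensus
#' FASTA and the interval must lie within its contig.  BED coordinates are
#' native 0-based half-open and kept that way throughout the package.
#'
#' @param consensus_fasta FASTA of canonical sequences, one per family.
#' @param instances_bed BED6 file (contig, start, end, family, score,
#'   strand).
#' @param genome_fasta Genome FASTA used to validate contigs and bounds.
#' @return A [repeat_annotation()].
#' @export
load_annotation <- function(consensus_fasta, instances_bed, genome_fasta) {
  families <- read_genome(consensus_fasta)
  genome <- read_genome(genome_fasta)
  bed <- tryCatch(
    read.table(instances_bed, sep = "\t", header = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(bed) || nrow(bed) == 0L) {
    instances <- data.frame(family = character(0), contig = character(0),
                            start = numeric(0), end = numeric(0),
                            strand = character(0), stringsAsFactors = FALSE)
    return(repeat_annotation(families, instances))
  }
  if (ncol(bed) < 6L) stop("instances BED must have 6 columns")
  instances <- data.frame(family = bed[[4]], contig = bed[[1]],
                          start = bed[[2]], end = bed[[3]],
                          strand = bed[[6]], stringsAsFactors = FALSE)
  unknown <- which(!instances$family %in% names(families))
  if (length(unknown))
    stop("BED row(s) ", paste(head(unknown, 5), collapse = ", "),
         ": family not present in consensus FASTA (",
         paste(unique(instances$family[unknown]), collapse = ", "), ")")
  badc <- which(!instances$contig %in% names(genome))
  if (length(badc))
    stop("BED row(s) ", paste(head(badc, 5), collapse = ", "),
         ": contig not present in genome")
  bad <- which(instances$end <= instances$start | instances$start < 0)
  if (length(bad))
    stop("BED row(s) ", paste(head(bad, 5), collapse = ", "),
         ": end must be greater than start and start non-negative")
  oob <- which(instances$end > nchar(genome)[match(instances$contig,
                                                   names(genome))])
  if (length(oob))
    stop("BED row(s) ", paste(head(oob, 5), collapse = ", "),
         ": interval beyond contig end")
  repeat_annotation(families, instances)
}

# extract instance sequences (flank-extended, clipped, oriented 5'->3' in
# repeat orientation) from a genome; returns a character vector
extract_instances <- function(genome, instances, flank) {
  if (nrow(instances) == 0L) return(character(0))
  clen <- nchar(genome)[match(instances$contig, names(genome))]
  s <- pmax(instances$start - flank, 0)
  e <- pmin(instances$end + flank, clen)
  out <- substr(genome[instances$contig], s + 1, e)
  minus <- instances$strand == "-"
  if (any(minus)) out[minus] <- revcomp(out[minus])
  unname(out)
}

#' Build the combined repeat reference and the masked genome partition
#'
#' The reference holds, per repeat type, one canonical (consensus) record
#' plus one record per annotated genomic instance extended by
#' `F = floor(L/2)` bp of flanking genomic sequence (clipped at contig
#' ends; minus-strand instances are reverse-complemented).  The mask
#' partition is the complement of the union of the flank-extended instance
#' intervals: the part of the genome not associated with any annotated
#' instance, against which the optional masking criterion is evaluated.
#'
#' @param annotation A [repeat_annotation()].
#' @param genome Named character vector of contig sequences (see
#'   [read_genome()]).
#' @param read_length Read length L; the flank is `floor(L/2)`.
#' @return A `combined_reference` object with elements `records` (named
#'   character vector of target sequences), `record_family` (named character
#'   vector mapping record id to family), `record_kind` ("canonical" or
#'   "instance"), `mask` (data.frame contig/start/end, 0-based half-open),
#'   `mask_seqs`, `flank`, `read_length`, `families` (consensus sequences).
#' @export
build_combined_reference <- function(annotation, genome, read_length = 26L) {
  stopifnot(inherits(annotation, "repeat_annotation"),
            is.character(genome), !is.null(names(genome)),
            read_length >= 1L)
  if (length(annotation$families) == 0L)
    stop("annotation has no families with consensus sequences")
  L <- as.integer(read_length)
  F <- L %/% 2L
  ins <- annotation$instances
  if (nrow(ins)) {
    missing_ctg <- setdiff(unique(ins$contig), names(genome))
    if (length(missing_ctg))
      stop("instance contig(s) absent from genome: ",
           paste(missing_ctg, collapse = ", "))
    if (any(ins$end > nchar(genome)[match(ins$contig, names(genome))]))
      stop("instance interval beyond contig end")
    key <- paste(ins$family, ins$contig, ins$start, ins$end, ins$strand)
    dup <- duplicated(key)
    if (any(dup)) {
      message("deduplicated ", sum(dup), " duplicate instance row(s)")
      ins <- ins[!dup, , drop = FALSE]
    }
    ins <- ins[order(ins$family, ins$contig, ins$start, ins$end, ins$strand), ,
               drop = FALSE]
    rownames(ins) <- NULL
  }

  fam_names <- sort(names(annotation$families))
  records <- character(0)
  record_family <- character(0)
  record_kind <- character(0)
  for (fam in fam_names) {
    cid <- paste0(fam, "|consensus")
    records[cid] <- unname(annotation$families[[fam]])
    record_family[cid] <- fam
    record_kind[cid] <- "canonical"
    sub <- ins[ins$family == fam, , drop = FALSE]
    if (nrow(sub)) {
      ids <- sprintf("%s|%s:%d-%d(%s)", fam, sub$contig,
                     as.integer(sub$start), as.integer(sub$end), sub$strand)
      seqs <- extract_instances(genome, sub, flank = F)
      records[ids] <- seqs
      record_family[ids] <- fam
      record_kind[ids] <- "instance"
    }
  }

  # mask partition: per contig, complement of the union of flank-extended
  # instance intervals
  mask <- list()
  for (ctg in names(genome)) {
    clen <- nchar(genome[[ctg]])
    sub <- ins[ins$contig == ctg, , drop = FALSE]
    if (nrow(sub)) {
      ext <- IRanges::reduce(IRanges::IRanges(
        start = pmax(sub$start - F, 0) + 1L,
        end = pmin(sub$end + F, clen)))
      comp <- IRanges::setdiff(IRanges::IRanges(1L, clen), ext)
    } else {
      comp <- IRanges::IRanges(1L, clen)
    }
    if (length(comp))
      mask[[length(mask) + 1L]] <- data.frame(
        contig = ctg, start = IRanges::start(comp) - 1L,
        end = IRanges::end(comp), stringsAsFactors = FALSE)
  }
  mask <- if (length(mask)) do.call(rbind, mask) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  mask <- mask[order(mask$contig, mask$start), , drop = FALSE]
  rownames(mask) <- NULL
  mask_seqs <- if (nrow(mask))
    substr(genome[mask$contig], mask$start + 1, mask$end) else character(0)
  names(mask_seqs) <- if (nrow(mask))
    sprintf("mask|%s:%d-%d", mask$contig, mask$start, mask$end) else character(0)

  structure(list(records = records,
                 record_family = record_family,
                 record_kind = record_kind,
                 mask = mask,
                 mask_seqs = mask_seqs,
                 flank = F,
                 read_length = L,
                 families = annotation$families[fam_names],
                 instances = ins),
            class = "combined_reference")
}

#' Write a combined reference to disk
#'
#' Emits `combined_repeats.fa` (record ids encode family and provenance),
#' `mask.bed` and `mask.fa` (the non-repeat genome partition),
#' `manifest.tsv` (record id, family, kind) and `reference_meta.json`
#' (read length and flank), in deterministic order.
#'
#' @param ref A [build_combined_reference()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_reference <- function(ref, outdir) {
  stopifnot(inherits(ref, "combined_reference"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(outdir, "combined_repeats.fa"),
             mask_bed = file.path(outdir, "mask.bed"),
             mask_fa = file.path(outdir, "mask.fa"),
             manifest = file.path(outdir, "manifest.tsv"),
             meta = file.path(outdir, "reference_meta.json"))
  write_fasta(ref$records, paths["records"])
  write.table(data.frame(ref$mask$contig, ref$mask$start, ref$mask$end),
              paths["mask_bed"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_fasta(ref$mask_seqs, paths["mask_fa"])
  write.table(data.frame(record_id = names(ref$records),
                         family = unname(ref$record_family),
                         kind = unname(ref$record_kind)),
              paths["manifest"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(read_length = ref$read_length, flank = ref$flank),
                       paths["meta"], auto_unbox = TRUE)
  invisible(paths)
}

#' Load a combined reference written by [write_reference()]
#'
#' @param outdir Directory containing the reference files.
#' @return A `combined_reference` object (without the `instances` table,
#'   which is not needed downstream).
#' @export
load_reference <- function(outdir) {
  records <- read_genome(file.path(outdir, "combined_repeats.fa"))
  man <- read.table(file.path(outdir, "manifest.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(outdir, "reference_meta.json"))
  mask_bed <- file.path(outdir, "mask.bed")
  mask <- tryCatch(
    read.table(mask_bed, sep = "\t", stringsAsFactors = FALSE,
               col.names = c("contig", "start", "end")),
    error = function(e) data.frame(contig = character(0), start = integer(0),
                                   end = integer(0), stringsAsFactors = FALSE))
  mask_seqs <- read_genome(file.path(outdir, "mask.fa"))
  record_family <- setNames(man$family, man$record_id)
  record_kind <- setNames(man$kind, man$record_id)
  records <- records[man$record_id]
  canonical <- man$kind == "canonical"
  families <- setNames(unname(records[canonical]), man$family[canonical])
  structure(list(records = records,
                 record_family = record_family,
                 record_kind = record_kind,
                 mask = mask,
                 mask_seqs = mask_seqs,
                 flank = as.integer(meta$flank),
                 read_length = as.integer(meta$read_length),
                 families = families,
                 instances = NULL),
            class = "combined_reference")
}
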