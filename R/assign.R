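#' Parameters of read-to-repeat-type assignment
#'
#' @param k k-mer size used throughout the pipeline (default 17).
#' @param min_score Minimum ungapped matching-base score for an alignment to
#'   count; default `L - 2` (resolved against the reference's read length),
#'   i.e. at most two mismatches at L = 26.
#' @param masking Whether the optional masking criterion is applied: a read
#'   matching the non-repeat genome partition as well as or better than its
#'   best repeat type is discarded (guards against unannotated repeat
#'   copies).
#' @return An `assign_params` object.
#' @export
assign_params <- function(k = 17L, min_score = NULL, masking = TRUE) {
  stopifnot(k >= 1L, is.logical(masking), length(masking) == 1L)
  if (!is.null(min_score)) stopifnot(min_score >= 1L)
  structure(list(k = as.integer(k),
                 min_score = if (is.null(min_score)) NULL else
                   as.integer(min_score),
                 masking = masking),
            class = "assign_params")
}

# a seed of this length is contained intact in every placement scoring at
# least min_score, so seeded scoring is exact for all scores >= min_score
seed_length <- function(L, min_score, k) {
  run <- ceiling(min_score / (L - min_score + 1))
  max(1L, min(as.integer(k), as.integer(run), 31L))
}

resolve_min_score <- function(params, L) {
  ms <- if (is.null(params$min_score)) L - 2L else params$min_score
  if (ms > L) stop("min_score (", ms, ") exceeds the read length (", L, ")")
  as.integer(max(1L, ms))
}

#' Best ungapped score of a read against one target
#'
#' The score is the maximum, over both orientations of the read and every
#' placement (ends may overhang the target, overhanging bases scoring 0),
#' of the number of matching bases.  Non-ACGT bases never match.  This
#' exhaustive definition is the scoring contract; [assign_reads()] computes
#' the same value through seeded search.
#'
#' @param read Read sequence (single string).
#' @param target Target sequence (single string).
#' @return Integer score in `[0, nchar(read)]`.
#' @export
score_read <- function(read, target) {
  stopifnot(is.character(read), length(read) == 1L,
            is.character(target), length(target) == 1L)
  if (!nzchar(read) || !nzchar(target)) return(0L)
  cpp_score_pair(read, target)
}

# score matrix reads x (families..., mask); groups order = c(fams, "mask")
score_matrix <- function(seqs, ref, params, method, include_mask) {
  fams <- names(ref$families)
  targets <- ref$records
  groups <- match(unname(ref$record_family), fams)
  if (include_mask && length(ref$mask_seqs)) {
    targets <- c(targets, ref$mask_seqs)
    groups <- c(groups, rep(length(fams) + 1L, length(ref$mask_seqs)))
  }
  n_groups <- length(fams) + 1L
  L <- ref$read_length
  ms <- resolve_min_score(params, L)
  if (method == "seeded") {
    ks <- seed_length(L, ms, params$k)
    S <- cpp_scores_seeded(unname(seqs), unname(targets),
                           as.integer(groups), n_groups, ks)
  } else {
    S <- cpp_scores_exhaustive(unname(seqs), unname(targets),
                               as.integer(groups), n_groups)
  }
  colnames(S) <- c(fams, "mask")
  S
}

# verdict logic shared by every scoring route; S has one column per family
# plus a final "mask" column
verdicts_from_scores <- function(S, min_score, masking) {
  nf <- ncol(S) - 1L
  fam_names <- colnames(S)[seq_len(nf)]
  SF <- S[, seq_len(nf), drop = FALSE]
  best <- SF[, 1L]
  for (j in seq_len(nf)[-1L]) best <- pmax(best, SF[, j])
  n_top <- rowSums(SF == best)
  top <- fam_names[max.col(SF, ties.method = "first")]
  mask_score <- S[, nf + 1L]
  verdict <- rep("assigned", nrow(S))
  family <- top
  reason <- rep(NA_character_, nrow(S))
  miss <- best < min_score
  verdict[miss] <- "discarded"; family[miss] <- NA; reason[miss] <- "no_hit"
  tie <- !miss & n_top >= 2L
  verdict[tie] <- "discarded"; family[tie] <- NA
  reason[tie] <- "cross_family_tie"
  gtie <- !miss & !tie & masking & mask_score >= best
  verdict[gtie] <- "discarded"; family[gtie] <- NA
  reason[gtie] <- "genome_tie"
  data.frame(verdict = verdict, family = family, reason = reason,
             best_score = as.integer(best), stringsAsFactors = FALSE)
}

#' Assign reads to repeat types under the uniqueness criteria
#'
#' Applies, per read, the three-criterion rule: (a) the read aligns (at one
#' or multiple locations) to the canonical sequence or flank-extended
#' annotated instances of one repeat type with score at least `min_score`;
#' (b) no alignment of equal or better score exists to any other repeat
#' type (ties discard the read as `cross_family_tie`); (c) optionally, no
#' alignment of equal or better score exists to the non-repeat genome
#' partition (otherwise `genome_tie`).  Reads below `min_score` everywhere
#' are discarded as `no_hit`; reads not of the reference's read length are
#' kept in the table as `skipped`.
#'
#' @param reads Named character vector of read sequences (see
#'   [read_fastq()]), or a `DNAStringSet`.
#' @param ref A [build_combined_reference()] result.
#' @param params An [assign_params()].
#' @param method `"seeded"` (production scorer: shared seed k-mers propose
#'   placements, rescored exactly) or `"exhaustive"` (every placement of
#'   every target scored; reference route for validation).
#' @return An `assignment_table`: data.frame with columns `read_id`,
#'   `verdict`, `family`, `reason`, `best_score`, with a `summary`
#'   attribute (per-family and per-reason counts) and the parameters in
#'   effect.
#' @export
assign_reads <- function(reads, ref, params = assign_params(),
                         method = c("seeded", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(inherits(ref, "combined_reference"),
            inherits(params, "assign_params"))
  if (methods::is(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  L <- ref$read_length
  ms <- resolve_min_score(params, L)
  ok <- nchar(reads) == L
  out <- data.frame(read_id = as.character(names(reads)),
                    verdict = rep("skipped", length(reads)),
                    family = rep(NA_character_, length(reads)),
                    reason = as.character(ifelse(ok, NA_character_,
                                                 "wrong_length")),
                    best_score = rep(NA_integer_, length(reads)),
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    S <- score_matrix(reads[ok], ref, params, method,
                      include_mask = params$masking)
    if (!params$masking) S[, ncol(S)] <- 0L
    v <- verdicts_from_scores(S, ms, params$masking)
    out$verdict[ok] <- v$verdict
    out$family[ok] <- v$family
    out$reason[ok] <- v$reason
    out$best_score[ok] <- v$best_score
  }
  if (sum(!ok))
    message(sum(!ok), " read(s) not of length ", L, " skipped")
  fam_counts <- table(factor(out$family, levels = names(ref$families)))
  reason_counts <- table(factor(
    out$reason, levels = c("no_hit", "cross_family_tie", "genome_tie",
                           "wrong_length")))
  structure(out,
            summary = list(n_reads = nrow(out),
                           n_assigned = sum(out$verdict == "assigned"),
                           n_discarded = sum(out$verdict == "discarded"),
                           n_skipped = sum(out$verdict == "skipped"),
                           family_counts = fam_counts,
                           reason_counts = reason_counts),
            params = list(k = params$k, min_score = ms,
                          masking = params$masking, method = method),
            class = c("assignment_table", "data.frame"))
}

#' Assign a single read
#'
#' @inheritParams assign_reads
#' @param read A single read sequence.
#' @return A list with `verdict`, `family`, `reason`, `best_score`.
#' @export
assign_read <- function(read, ref, params = assign_params()) {
  tab <- assign_reads(c(read1 = unname(read)), ref, params)
  list(verdict = tab$verdict[1], family = tab$family[1],
       reason = tab$reason[1], best_score = tab$best_score[1])
}

#' Summary counts of an assignment table
#'
#' @param x An `assignment_table` from [assign_reads()].
#' @return The summary list stored on the table.
#' @export
assignment_summary <- function(x) attr(x, "summary")

#' Write an assignment table and its summary
#'
#' @param x An `assignment_table`.
#' @param outdir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_assignments <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(outdir, "assignments.tsv")
  write.table(as.data.frame(x), p1, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  s <- assignment_summary(x)
  p2 <- file.path(outdir, "summary.tsv")
  sm <- data.frame(
    key = c("n_reads", "n_assigned", "n_discarded", "n_skipped",
            paste0("family:", names(s$family_counts)),
            paste0("reason:", names(s$reason_counts))),
    value = c(s$n_reads, s$n_assigned, s$n_discarded, s$n_skipped,
              as.integer(s$family_counts), as.integer(s$reason_counts)))
  write.table(sm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(assignments = p1, summary = p2))
}
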