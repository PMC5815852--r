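# Independent oracles and fixture builders shared across the suite.

# pure-R reverse complement (kept independent of the package's Biostrings
# route)
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", s), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force ungapped score: every placement of both read orientations on
# the target, overhangs scoring zero
oracle_score <- function(read, target) {
  one <- function(r, t) {
    rb <- strsplit(r, "", fixed = TRUE)[[1]]
    tb <- strsplit(t, "", fixed = TRUE)[[1]]
    L <- length(rb); n <- length(tb)
    best <- 0L
    for (d0 in (2L - L):n) {           # target index of read base 1
      i <- seq_len(L)
      tpos <- d0 + i - 1L
      ok <- tpos >= 1L & tpos <= n
      s <- sum(rb[ok] == tb[tpos[ok]] & rb[ok] %in% c("A", "C", "G", "T"))
      if (s > best) best <- s
    }
    best
  }
  max(one(read, target), one(oracle_revcomp(read), target))
}

# oracle assignment of one read: exhaustive scores per family and mask,
# then the three-criterion rule
oracle_assign <- function(read, ref, min_score, masking) {
  fams <- names(ref$families)
  sf <- vapply(fams, function(f) {
    rec <- ref$records[unname(ref$record_family) == f]
    if (!length(rec)) return(0L)
    max(vapply(rec, oracle_score, integer(1), read = read))
  }, integer(1))
  sg <- if (masking && length(ref$mask_seqs))
    max(vapply(ref$mask_seqs, oracle_score, integer(1), read = read)) else 0L
  best <- max(sf)
  if (best < min_score) return(list(verdict = "discarded", family = NA,
                                    reason = "no_hit"))
  top <- fams[sf == best]
  if (length(top) > 1L) return(list(verdict = "discarded", family = NA,
                                    reason = "cross_family_tie"))
  if (masking && sg >= best) return(list(verdict = "discarded", family = NA,
                                         reason = "genome_tie"))
  list(verdict = "assigned", family = top, reason = NA)
}

# independently coded standard EM over equivalence classes, iterated to a
# tight fixed point
oracle_em <- function(counts, sets, eff, fams, tol = 1e-12,
                      max_iter = 100000L) {
  th <- setNames(rep(1 / length(fams), length(fams)), fams)
  for (it in seq_len(max_iter)) {
    nf <- setNames(rep(0, length(fams)), fams)
    for (i in seq_along(counts)) {
      w <- th[sets[[i]]] / eff[sets[[i]]]
      if (sum(w) == 0) w <- rep(1, length(w))
      nf[sets[[i]]] <- nf[sets[[i]]] + counts[i] * w / sum(w)
    }
    th2 <- nf / sum(nf)
    if (max(abs(th2 - th)) < tol) return(th2)
    th <- th2
  }
  th
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# hand-built reference: named consensus sequences, a named genome and an
# instance table (0-based half-open)
make_ref <- function(families, genome, instances = NULL, L = 26L) {
  if (is.null(instances))
    instances <- data.frame(family = character(0), contig = character(0),
                            start = numeric(0), end = numeric(0),
                            strand = character(0), stringsAsFactors = FALSE)
  build_combined_reference(repeat_annotation(families, instances), genome, L)
}

# reads sampled from family consensus sequences with a fixed number of
# substitution errors; names carry the source family
sample_family_reads <- function(families, n, L = 26L, max_errors = 3L,
                                p_random = 0.25) {
  reads <- character(n)
  src <- character(n)
  fam_names <- names(families)
  for (i in seq_len(n)) {
    if (runif(1) < p_random) {
      reads[i] <- random_seq(L)
      src[i] <- "random"
    } else {
      f <- sample(fam_names, 1)
      s <- families[[f]]
      pos <- sample(nchar(s) - L + 1L, 1)
      rd <- substr(s, pos, pos + L - 1L)
      nerr <- sample(0:max_errors, 1)
      if (nerr > 0) {
        b <- strsplit(rd, "", fixed = TRUE)[[1]]
        at <- sample(L, nerr)
        b[at] <- sample(c("A", "C", "G", "T"), nerr, replace = TRUE)
        rd <- paste(b, collapse = "")
      }
      if (runif(1) < 0.5) rd <- oracle_revcomp(rd)
      reads[i] <- rd
      src[i] <- f
    }
  }
  names(reads) <- sprintf("r%04d|%s", seq_len(n), src)
  reads
}

# small simulation config used by several files
small_sim_config <- function(seed = 1L, reads = 2000L, ...) {
  simulation_config(seed = seed, reads_per_sample = reads,
                    n_background_genes = 10L, ...)
}
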