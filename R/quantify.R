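#' Quantification configuration
#'
#' @param k k-mer size for equivalence classes (default 17).
#' @param polyA_filter Discard k-mers consisting of k consecutive A's or
#'   T's (default on).
#' @param alpha0 Symmetric Dirichlet prior concentration of the variational
#'   Bayes EM, per repeat type (default 0.01).
#' @param max_iter Iteration cap of the VBEM (default 1000).
#' @param tol Convergence threshold on `max |delta theta|` (default 1e-8).
#' @return A `quant_config` object.
#' @export
quant_config <- function(k = 17L, polyA_filter = TRUE, alpha0 = 0.01,
                         max_iter = 1000L, tol = 1e-8) {
  stopifnot(k >= 1L, k <= 26L, is.logical(polyA_filter), alpha0 > 0,
            max_iter >= 1L, tol > 0)
  structure(list(k = as.integer(k), polyA_filter = polyA_filter,
                 alpha0 = alpha0, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "quant_config")
}

#' Canonical k-mers of a sequence
#'
#' Emits every length-k window of the sequence in canonical form (the
#' lexicographically smaller of the window and its reverse complement).
#' With the poly-A filter, windows that are runs of k A's or k T's are
#' discarded.  Windows containing non-ACGT characters are skipped.
#'
#' @param sequence A single DNA string.
#' @param config A [quant_config()].
#' @return Character vector of canonical k-mers (with multiplicity);
#'   empty if the sequence is shorter than k.
#' @export
kmerize <- function(sequence, config = quant_config()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- config$k
  n <- nchar(sequence)
  if (n < k) return(character(0))
  w <- substring(sequence, 1:(n - k + 1), k:n)
  keep <- !grepl("[^ACGTacgt]", w)
  w <- toupper(w[keep])
  if (config$polyA_filter)
    w <- w[w != strrep("A", k) & w != strrep("T", k)]
  if (!length(w)) return(character(0))
  rc <- revcomp(w)
  pmin(w, rc)
}

# numeric canonical k-mer profiles (exact doubles) per sequence
kmer_profiles <- function(seqs, config) {
  cpp_kmer_windows(unname(seqs), config$k, config$polyA_filter)
}

#' Build k-mer equivalence classes for assigned reads
#'
#' Each read's class is the set of repeat types whose reference records
#' (canonical plus instances) share at least `ceil(0.8 * (L - k + 1))` of
#' the read's filtered k-mers.  Reads with an empty filtered k-mer set
#' (e.g. pure poly-A) or an empty compatible set are dropped from
#' quantification with a logged count.
#'
#' @param reads Named character vector of read sequences.
#' @param assignments An `assignment_table` from [assign_reads()] for the
#'   same reads; only assigned reads are quantified.
#' @param ref A [build_combined_reference()] result.
#' @param config A [quant_config()].
#' @return A list with `classes` (data.frame: `families` key string,
#'   `count`), `class_members` (list of family-name vectors parallel to
#'   `classes`), `read_family` (assigned family of each quantified read),
#'   `n_quantified`, `n_dropped_empty`, `n_dropped_incompatible`.
#' @export
build_equivalence_classes <- function(reads, assignments, ref,
                                      config = quant_config()) {
  stopifnot(inherits(ref, "combined_reference"))
  L <- ref$read_length
  if (config$k > L)
    stop("k (", config$k, ") exceeds the read length (", L, ")")
  assigned <- assignments$verdict == "assigned"
  ids <- assignments$read_id[assigned]
  fams <- names(ref$families)
  empty <- list(classes = data.frame(families = character(0),
                                     count = integer(0),
                                     stringsAsFactors = FALSE),
                class_members = list(),
                read_family = character(0),
                n_quantified = 0L, n_dropped_empty = 0L,
                n_dropped_incompatible = 0L)
  if (!length(ids)) return(empty)
  seqs <- reads[ids]
  threshold <- ceiling(0.8 * (L - config$k + 1))

  fam_sets <- lapply(fams, function(f) {
    rec <- ref$records[unname(ref$record_family) == f]
    sort(unique(unlist(kmer_profiles(rec, config))))
  })
  names(fam_sets) <- fams

  prof <- kmer_profiles(seqs, config)
  nk <- lengths(prof)
  flat <- unlist(prof, use.names = FALSE)
  read_idx <- rep(seq_along(prof), nk)

  member <- matrix(FALSE, length(seqs), length(fams),
                   dimnames = list(NULL, fams))
  if (length(flat)) {
    for (f in fams) {
      hit <- flat %in% fam_sets[[f]]
      cnt <- integer(length(seqs))
      if (any(hit)) {
        t <- tapply(hit, read_idx, sum)
        cnt[as.integer(names(t))] <- as.integer(t)
      }
      member[, f] <- cnt >= threshold
    }
  }
  drop_empty <- nk == 0L
  drop_incomp <- !drop_empty & rowSums(member) == 0L
  keep <- !drop_empty & !drop_incomp
  if (sum(drop_empty))
    message(sum(drop_empty), " read(s) with empty filtered k-mer set dropped")
  if (sum(drop_incomp))
    message(sum(drop_incomp),
            " read(s) compatible with no repeat type dropped")
  if (!sum(keep)) return(empty)

  keysets <- apply(member[keep, , drop = FALSE], 1L, function(m)
    paste(fams[m], collapse = ","))
  tab <- table(keysets)
  classes <- data.frame(families = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  classes <- classes[order(classes$families), , drop = FALSE]
  rownames(classes) <- NULL
  list(classes = classes,
       class_members = strsplit(classes$families, ",", fixed = TRUE),
       read_family = assignments$family[assigned][keep],
       n_quantified = sum(keep),
       n_dropped_empty = sum(drop_empty),
       n_dropped_incompatible = sum(drop_incomp))
}

#' Variational Bayes EM over equivalence classes
#'
#' Iterates the collapsed variational update with a symmetric Dirichlet
#' prior: responsibilities of a class toward family f are proportional to
#' `exp(digamma(alpha_f)) / eff_length_f`, restricted to the class's
#' family set and normalized; `alpha_f = alpha0 + sum(count * r)`; the
#' abundance estimate is `theta_f = (alpha_f - alpha0) / sum(alpha - alpha0)`.
#' Stops when `max |delta theta| <= tol` or at `max_iter` (with a warning
#' flag on the result).
#'
#' @param classes data.frame with a `count` column, or the list returned by
#'   [build_equivalence_classes()].
#' @param class_members List of family-name vectors, one per class (not
#'   needed if `classes` is the full list).
#' @param eff_length Named numeric vector of effective lengths per family.
#' @param config A [quant_config()].
#' @return Named numeric vector `theta` summing to 1, with attributes
#'   `iterations` and `converged`.
#' @export
vbem <- function(classes, eff_length, config = quant_config(),
                 class_members = NULL) {
  if (is.list(classes) && !is.data.frame(classes) &&
      !is.null(classes$class_members)) {
    class_members <- classes$class_members
    classes <- classes$classes
  }
  stopifnot(is.data.frame(classes), !is.null(class_members),
            length(class_members) == nrow(classes),
            !is.null(names(eff_length)), all(eff_length >= 1))
  fams <- names(eff_length)
  nf <- length(fams)
  counts <- classes$count
  theta <- setNames(rep(0, nf), fams)
  if (!nrow(classes) || sum(counts) == 0) {
    attr(theta, "iterations") <- 0L
    attr(theta, "converged") <- TRUE
    return(theta)
  }
  M <- matrix(FALSE, nrow(classes), nf, dimnames = list(NULL, fams))
  for (i in seq_len(nrow(classes))) {
    m <- match(class_members[[i]], fams)
    if (anyNA(m)) stop("class references unknown family: ",
                       paste(class_members[[i]][is.na(m)], collapse = ", "))
    M[i, m] <- TRUE
  }
  total <- sum(counts)
  alpha <- config$alpha0 + colSums(M * (counts / rowSums(M)))
  theta <- (alpha - config$alpha0) / total
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    w <- exp(digamma(alpha)) / eff_length
    R <- M * rep(w, each = nrow(M))
    R <- R / rowSums(R)
    alpha <- config$alpha0 + colSums(R * counts)
    theta_new <- (alpha - config$alpha0) / total
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta <= config$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("VBEM did not converge within ", config$max_iter, " iterations")
  theta <- setNames(as.numeric(theta), fams)
  attr(theta, "iterations") <- iter
  attr(theta, "converged") <- converged
  theta
}

#' Transcripts-per-million from abundances and effective lengths
#'
#' `tpm_i = (x_i / eff_i) / sum_j (x_j / eff_j) * 1e6`, where `x` may be
#' either VBEM theta estimates or read counts (the formula is scale
#' invariant).  TPM is independent of the mean expressed transcript
#' length: multiplying all effective lengths by a constant leaves it
#' unchanged.
#'
#' @param x Named numeric vector of theta values or counts.
#' @param eff_length Named numeric vector of effective lengths (>= 1),
#'   matching `names(x)`.
#' @return Named numeric vector of TPM values summing to 1e6 (all zero,
#'   with a warning, if `x` is all zero).
#' @export
compute_tpm <- function(x, eff_length) {
  stopifnot(!is.null(names(x)), all(names(x) %in% names(eff_length)),
            all(eff_length >= 1), all(x >= 0))
  eff <- eff_length[names(x)]
  rate <- x / eff
  total <- sum(rate)
  if (total <= 0) {
    warning("all abundances are zero; TPM set to zero")
    return(setNames(rep(0, length(x)), names(x)))
  }
  rate / total * 1e6
}

#' Quantify repeat-type abundance for one sample
#'
#' Combines equivalence-class construction, the VBEM and TPM computation.
#' Effective lengths are `max(canonical_length - L + 1, 1)`.
#'
#' @param reads Named character vector of the sample's read sequences.
#' @param assignments The `assignment_table` for those reads.
#' @param ref A [build_combined_reference()] result.
#' @param config A [quant_config()].
#' @return An `abundance_table` data.frame, one row per repeat family:
#'   `family`, `count` (quantified reads assigned to the family), `length`
#'   (canonical), `eff_length`, `theta`, `tpm`; attributes `n_quantified`,
#'   `n_dropped_empty`, `n_dropped_incompatible`, `converged`.
#' @export
quantify <- function(reads, assignments, ref, config = quant_config()) {
  stopifnot(inherits(ref, "combined_reference"))
  fams <- names(ref$families)
  L <- ref$read_length
  len <- nchar(ref$families)
  eff <- pmax(len - L + 1, 1)
  names(eff) <- fams
  ec <- build_equivalence_classes(reads, assignments, ref, config)
  theta <- vbem(ec, eff, config)
  tpm <- if (ec$n_quantified > 0) compute_tpm(theta, eff) else
    setNames(rep(0, length(fams)), fams)
  counts <- table(factor(ec$read_family, levels = fams))
  out <- data.frame(family = fams,
                    count = as.integer(counts),
                    length = as.integer(len),
                    eff_length = as.numeric(eff),
                    theta = as.numeric(theta[fams]),
                    tpm = as.numeric(tpm[fams]),
                    stringsAsFactors = FALSE)
  structure(out,
            n_quantified = ec$n_quantified,
            n_dropped_empty = ec$n_dropped_empty,
            n_dropped_incompatible = ec$n_dropped_incompatible,
            converged = attr(theta, "converged"),
            class = c("abundance_table", "data.frame"))
}

#' Write an abundance table
#'
#' @param x An `abundance_table` from [quantify()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_abundance <- function(x, path) {
  y <- as.data.frame(x)
  y$theta <- sprintf("%.6f", y$theta)
  y$tpm <- sprintf("%.6f", y$tpm)
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
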