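#' Derive a reproducible seed for a named random stream
#'
#' All randomness in the package flows from one master seed; each logical
#' stage (consensus generation, placement, per-sample reads, ...) draws from
#' its own named stream so that regenerating one sample does not disturb the
#' others.  The stream seed is a deterministic hash of the master seed and
#' the stream name, kept below 2^31.
#'
#' @param master Master integer seed.
#' @param name Stream name, e.g. `"reads/treated_1"`.
#' @return An integer seed.
#' @export
stream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer((((master %% m) * 2654435) %% m + h * 97 + 1) %% m)
}

# evaluate expr under the given stream seed, restoring the caller's RNG state
with_stream <- function(master, name, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(master, name))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# random i.i.d. uniform DNA as a character vector of single bases
random_bases <- function(n) {
  if (n <= 0) return(character(0))
  sample(DNA_BASES, n, replace = TRUE)
}

random_dna <- function(n) paste(random_bases(n), collapse = "")

# substitute each base independently with probability `rate`, always to a
# different base
mutate_bases <- function(bases, rate) {
  if (rate <= 0 || length(bases) == 0) return(bases)
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    cur <- match(bases[hit], DNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    bases[hit] <- DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
  }
  bases
}

mutate_seq <- function(seq, rate) {
  paste(mutate_bases(strsplit(seq, "", fixed = TRUE)[[1]], rate), collapse = "")
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# named character vector -> DNAStringSet
as_dna_set <- function(x) {
  s <- Biostrings::DNAStringSet(unname(x))
  names(s) <- names(x)
  s
}

#' Read a genome FASTA into a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_genome <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

write_fasta <- function(x, path, width = 60L) {
  Biostrings::writeXStringSet(as_dna_set(x), path, width = width)
  invisible(path)
}

write_fastq <- function(x, path) {
  s <- as_dna_set(x)
  qual <- Biostrings::BStringSet(vapply(
    Biostrings::width(s), function(w) strrep("I", w), character(1)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' Qualities are ignored; read names keep everything up to the first space.
#'
#' @param path Path to a FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}
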