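## Low-level sequence helpers. Genomes are plain uppercase character strings;
## all intervals are 0-based half-open unless a writer converts them.

BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a private RNG stream
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so deterministic builders do not perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Extract a 0-based half-open slice of a sequence string
#' @param seq character scalar.
#' @param start,end 0-based half-open bounds.
#' @keywords internal
seq_slice <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

seq_len_bp <- function(seq) nchar(seq)

#' Reverse complement of a DNA string
#' @param seq character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Hamming distance between equal-length strings
#' @keywords internal
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

split_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Substitution-mutate a sequence at a per-site rate
#'
#' Each site is substituted independently with probability `rate`;
#' transitions are drawn twice as often as each transversion (ts:tv 2:1
#' overall), a crude nod to real LTR divergence spectra. Uses the current
#' RNG stream.
#'
#' @param seq character scalar.
#' @param rate per-site substitution probability.
#' @return mutated character scalar.
#' @keywords internal
mutate_seq <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  ch <- split_chars(seq)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in hit) {
    b <- ch[i]
    if (!b %in% BASES) next
    if (stats::runif(1) < 0.5) {
      ch[i] <- transition[[b]]
    } else {
      tv <- setdiff(BASES, c(b, transition[[b]]))
      ch[i] <- sample(tv, 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Read / write FASTA via Biostrings
#' @param path file path.
#' @return named character vector of sequences.
#' @keywords internal
read_fasta_chr <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @keywords internal
write_fasta_chr <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

## longest k <= window with a[1..k] == b[1..k] (prefix agreement)
longest_prefix_match <- function(a, b, window = Inf) {
  k <- min(nchar(a), nchar(b), window)
  if (k <= 0) return(0L)
  av <- charToRaw(substr(a, 1L, k))
  bv <- charToRaw(substr(b, 1L, k))
  neq <- which(av != bv)
  if (!length(neq)) return(as.integer(k))
  neq[1L] - 1L
}

longest_suffix_match <- function(a, b, window = Inf) {
  k <- min(nchar(a), nchar(b), window)
  if (k <= 0) return(0L)
  av <- rev(charToRaw(substr(a, nchar(a) - k + 1L, nchar(a))))
  bv <- rev(charToRaw(substr(b, nchar(b) - k + 1L, nchar(b))))
  neq <- which(av != bv)
  if (!length(neq)) return(as.integer(k))
  neq[1L] - 1L
}
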