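# Internal helpers shared across modules.

#' Reverse complement of a DNA string
#'
#' Strand convention used throughout the package: the repeat unit read on the
#' 5' strand of a chromosome end is the reverse complement of the unit read at
#' the opposite end, e.g. `revcomp("ACCCCGCC") == "GGCGGGGT"`.
#'
#' @param seq A character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' revcomp("ACCCCGCC")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  out <- vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  out
}

# deterministic per-operation RNG stream: adding one feature to the generator
# must not perturb the random draws of another
with_op_seed <- function(seed, op, expr) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  s <- (as.integer(seed) %% 1000003L) * 2011L + (h %% 65521L)
  s <- s %% 2147483647L
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(s)
  force(expr)
}

# random DNA with a target GC content
random_dna <- function(n, gc = 0.48) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# 0-based half-open interval data.frame constructor/validator
interval_df <- function(contig, start, end, strand = "+") {
  stopifnot(all(start >= 0), all(end > start))
  data.frame(contig = as.character(contig), start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

# does [s1,e1) overlap [s2,e2)?
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

subseq_chr <- function(seq, start, end) {
  # 0-based half-open extraction from a character scalar
  substr(seq, start + 1L, end)
}

# replace [start,end) of seq with replacement
splice_chr <- function(seq, start, end, replacement) {
  paste0(substr(seq, 1L, start), replacement,
         substr(seq, end + 1L, nchar(seq)))
}

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "") {
    return(data.frame(op = character(0), len = integer(0)))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}
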