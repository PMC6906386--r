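#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over `A`,`C`,`G`,`T`,`N`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAT"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

# Random DNA string of length n at the given GC content.
rand_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# All k-mers of a string (forward strand), possibly with duplicates removed.
kmers <- function(x, k, unique = TRUE) {
  n <- nchar(x)
  if (n < k) return(character(0))
  out <- substring(x, 1:(n - k + 1), k:n)
  if (unique) unique(out) else out
}

# Overlap length of two half-open intervals [s1,e1) and [s2,e2).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Phred+33 decoding of a quality string into integer scores.
phred33 <- function(qual) {
  if (is.na(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

# Zero-padded read identifiers.
make_ids <- function(prefix, n) {
  if (n == 0) return(character(0))
  sprintf("%s_%0*d", prefix, max(4L, nchar(as.character(n))), seq_len(n))
}

# Minimal union-find used for duplicate-collapse components.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}
uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}
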