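# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars over {A,C,G,T,N} unless stated otherwise;
# coordinates are 0-based half-open on the plus strand.

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string (IUPAC ambiguity codes allowed).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# vectorised base counts; N and other ambiguity codes are never counted
base_counts <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  b <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  c(A = sum(b == "A"), T = sum(b == "T"),
    G = sum(b == "G"), C = sum(b == "C"),
    N = sum(!b %in% c("A", "T", "G", "C")))
}

# substring by 0-based half-open interval, wrapping around the origin of a
# circular sequence when end > nchar(x)
circ_substr <- function(x, start, end) {
  n <- nchar(x)
  stopifnot(start >= 0L, end >= start, end - start <= n)
  if (end <= n) return(substr(x, start + 1L, end))
  paste0(substr(x, start + 1L, n), substr(x, 1L, end - n))
}

# rotate a circular sequence so that 0-based position `by` becomes position 0
rotate_seq <- function(x, by) {
  n <- nchar(x)
  by <- ((by %% n) + n) %% n
  if (by == 0L) return(x)
  paste0(substr(x, by + 1L, n), substr(x, 1L, by))
}

# random DNA of length n with the given per-base probabilities (A,T,G,C)
random_dna <- function(n, probs) {
  stopifnot(length(probs) == 4L, abs(sum(probs) - 1) < 1e-8)
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# point-mutate a DNA string to approximately `identity` expected identity
mutate_to_identity <- function(x, identity) {
  b <- strsplit(x, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(b)) > identity
  if (any(hit)) {
    alt <- c("A", "T", "G", "C")
    b[hit] <- vapply(b[hit], function(ch) sample(setdiff(alt, ch), 1L), "")
  }
  paste(b, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
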