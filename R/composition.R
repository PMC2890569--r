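# Nucleotide composition and strand compositional asymmetry.
#
# AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C), both computed on
# the strand named by the scope. The insect-ancestral condition is a
# negative GC skew on the majority strand; a positive majority-strand GC
# skew is read as reversal of strand asymmetry.

#' AT/GC skew and A+T content of a sequence
#'
#' `N` and other ambiguity characters are excluded from every count. A skew
#' whose denominator is zero is reported as `NA` (absent), never as 0.
#'
#' @param sequence DNA string.
#' @return list with `at_skew`, `gc_skew`, `at_content` (percent) and the
#'   integer `counts` (A, T, G, C, N).
#' @export
skew <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence: composition undefined")
  ct <- base_counts(sequence)
  acgt <- sum(ct[c("A", "T", "G", "C")])
  if (acgt == 0L) stop("all-ambiguous sequence: composition undefined")
  at <- ct[["A"]] + ct[["T"]]
  gc <- ct[["G"]] + ct[["C"]]
  list(at_skew = if (at > 0L) (ct[["A"]] - ct[["T"]]) / at else NA_real_,
       gc_skew = if (gc > 0L) (ct[["G"]] - ct[["C"]]) / gc else NA_real_,
       at_content = 100 * at / acgt,
       counts = ct)
}

#' Majority strand of an annotated genome
#'
#' The strand encoding the greater number of genes (the control region is
#' excluded from the count); ties are broken toward the strand carrying
#' `cox1`.
#'
#' @param g a [mito_genome].
#' @return `"+"` or `"-"`.
#' @export
majority_strand <- function(g) {
  f <- g$features
  f <- f[!f$duplicate & !is.na(f$name) & f$name != "CR", , drop = FALSE]
  if (!nrow(f)) stop("no annotated genes in ", g$id)
  plus <- sum(f$strand == "+")
  minus <- sum(f$strand == "-")
  if (plus > minus) return("+")
  if (minus > plus) return("-")
  i <- which(f$name == "cox1")
  if (length(i)) f$strand[i[1L]] else "+"
}

#' Skew profile for a named scope of a genome
#'
#' Scopes: `"whole_genome"` measures the majority strand of the full
#' circular sequence; `"all_PCGs"` concatenates the 13 protein-coding genes,
#' each read in majority-strand orientation (the majority-strand image of
#' the gene's span) by default, or in its own sense orientation with
#' `pcg_orientation = "sense"`; `"gene:<label>"` measures a single gene in
#' sense orientation; `"region:<start>-<end>"` a plus-strand interval
#' (0-based half-open).
#'
#' @param g a [mito_genome].
#' @param scope scope string as above.
#' @param pcg_orientation `"majority"` or `"sense"`, for the `all_PCGs`
#'   scope.
#' @return a `skew_profile` list: `id`, `scope`, `at_skew`, `gc_skew`,
#'   `at_content`, `counts`.
#' @export
skew_profile <- function(g, scope = "whole_genome",
                         pcg_orientation = c("majority", "sense")) {
  pcg_orientation <- match.arg(pcg_orientation)
  maj <- majority_strand(g)
  if (scope == "whole_genome") {
    s <- if (maj == "+") g$sequence else revcomp(g$sequence)
  } else if (scope == "all_PCGs") {
    f <- g$features
    f <- f[!f$duplicate & f$kind %in% "PCG" & !is.na(f$name), , drop = FALSE]
    missing <- setdiff(canonical_labels("PCG"), f$name)
    if (length(missing) == length(canonical_labels("PCG")))
      stop("no protein-coding genes annotated in ", g$id)
    parts <- vapply(f$name, function(nm) {
      if (pcg_orientation == "sense") gene_seq(g, nm, "sense")
      else {
        s <- gene_seq(g, nm, "plus")
        if (maj == "-") revcomp(s) else s
      }
    }, "")
    s <- paste(parts, collapse = "")
  } else if (startsWith(scope, "gene:")) {
    nm <- sub("^gene:", "", scope)
    if (!nm %in% g$features$name)
      stop("scope error: gene '", nm, "' absent from ", g$id)
    s <- gene_seq(g, nm, "sense")
  } else if (startsWith(scope, "region:")) {
    iv <- as.integer(strsplit(sub("^region:", "", scope), "-")[[1L]])
    s <- circ_substr(g$sequence, iv[1L], iv[2L])
  } else stop("unknown scope: ", scope)
  k <- skew(s)
  structure(list(id = g$id, scope = scope, at_skew = k$at_skew,
                 gc_skew = k$gc_skew, at_content = k$at_content,
                 counts = k$counts, majority_strand = maj),
            class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, digits = 2, ...) {
  cat(sprintf("<skew_profile> %s [%s]\n", x$id, x$scope))
  cat(sprintf("  AT skew %s  GC skew %s  A+T%% %s\n",
              format(round(x$at_skew, digits), nsmall = digits),
              format(round(x$gc_skew, digits), nsmall = digits),
              format(round(x$at_content, digits), nsmall = digits)))
  invisible(x)
}

#' Call reversal of strand asymmetry from a skew profile
#'
#' The ancestral insect majority-strand GC skew is negative; a clearly
#' positive GC skew therefore indicates reversal of strand asymmetry
#' (typically via inversion of the replication origin in the control
#' region). Skews within `epsilon` of zero are called indeterminate.
#'
#' @param p a `skew_profile` (conventionally whole-genome, majority strand).
#' @param epsilon dead band around zero (default 0.02).
#' @return an `asymmetry_call` list: `id`, `gc_skew_majority`, `call`,
#'   `epsilon`.
#' @export
call_asymmetry <- function(p, epsilon = 0.02) {
  stopifnot(inherits(p, "skew_profile"))
  if (is.na(p$gc_skew)) stop("GC skew undefined for ", p$id)
  call <- if (p$gc_skew > epsilon) "reversed"
          else if (p$gc_skew < -epsilon) "normal"
          else "indeterminate"
  structure(list(id = p$id, gc_skew_majority = p$gc_skew, call = call,
                 epsilon = epsilon),
            class = "asymmetry_call")
}

#' @export
print.asymmetry_call <- function(x, ...) {
  cat(sprintf("<asymmetry_call> %s: GC skew %+0.3f -> %s (epsilon %0.3f)\n",
              x$id, x$gc_skew_majority, x$call, x$epsilon))
  invisible(x)
}

#' Composition table for a set of genomes
#'
#' One row per genome with whole-genome and all-PCG skews, rounded for
#' reporting (rounding is applied only here, never internally).
#'
#' @param genomes list of [mito_genome] objects.
#' @param digits rounding for the report (default 2).
#' @param pcg_orientation passed to [skew_profile()].
#' @return data.frame.
#' @export
composition_table <- function(genomes, digits = 2,
                              pcg_orientation = "majority") {
  rows <- lapply(genomes, function(g) {
    w <- skew_profile(g, "whole_genome")
    p <- skew_profile(g, "all_PCGs", pcg_orientation = pcg_orientation)
    data.frame(id = g$id,
               at_skew = round(w$at_skew, digits),
               gc_skew = round(w$gc_skew, digits),
               at_pct = round(w$at_content, digits),
               pcg_at_skew = round(p$at_skew, digits),
               pcg_gc_skew = round(p$gc_skew, digits),
               pcg_at_pct = round(p$at_content, digits),
               asymmetry = call_asymmetry(w)$call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
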