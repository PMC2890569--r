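# Nei-Gojobori estimation of synonymous and nonsynonymous substitution
# rates under the invertebrate mitochondrial genetic code (translation
# table 5), with Jukes-Cantor correction and unweighted pathway averaging.
# Stop-codon targets are excluded from site denominators and pathways
# through stop codons are excluded from averaging, matching the classic
# implementation defaults.

.ng_cache <- new.env(parent = emptyenv())

mito_code <- function() {
  if (is.null(.ng_cache$code)) {
    gc5 <- Biostrings::getGeneticCode("5")  # invertebrate mitochondrial
    .ng_cache$code <- gc5
    .ng_cache$codons <- names(gc5)
    .ng_cache$stops <- names(gc5)[gc5 == "*"]
  }
  .ng_cache$code
}

codon_index <- function(codon) match(codon, names(mito_code()))

is_stop <- function(codon) {
  code <- mito_code()
  unname(code[codon] == "*")
}

# all nine single-base neighbors of a codon, by position
codon_neighbors <- function(codon, pos) {
  b <- strsplit(codon, "")[[1L]]
  alt <- setdiff(c("A", "C", "G", "T"), b[pos])
  vapply(alt, function(x) {
    b2 <- b; b2[pos] <- x; paste(b2, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three positions, the synonymous fraction is the share of
#' the possible single-base changes that preserve the encoded amino acid,
#' with changes to stop codons excluded from the denominator. `s` is the
#' sum over positions and `n = 3 - s`.
#'
#' @param codon a sense codon over `A,C,G,T` (invertebrate mitochondrial
#'   code; `TGA` is Trp, not stop).
#' @return list with `s` and `n`.
#' @export
codon_sites <- function(codon) {
  codon <- toupper(codon)
  code <- mito_code()
  if (!codon %in% names(code)) stop("not a codon: ", codon)
  if (is_stop(codon)) stop("stop codon has no site decomposition: ", codon)
  s <- 0
  for (pos in 1:3) {
    nb <- codon_neighbors(codon, pos)
    sense <- nb[!is_stop(nb)]
    if (length(sense))
      s <- s + sum(code[sense] == code[codon]) / length(sense)
  }
  list(s = s, n = 3 - s)
}

# cached per-codon site counts for all sense codons
sites_table <- function() {
  if (is.null(.ng_cache$sites)) {
    code <- mito_code()
    sense <- names(code)[code != "*"]
    tab <- vapply(sense, function(c0) codon_sites(c0)$s, 0)
    .ng_cache$sites <- tab
  }
  .ng_cache$sites
}

#' Pathway-averaged substitution counts between two codons
#'
#' For `k` differing positions, all `k!` orderings of single-base steps are
#' enumerated; orderings passing through a stop codon are discarded, and
#' synonymous/nonsynonymous step counts are averaged with equal weights
#' over the remaining valid pathways.
#'
#' @param a,b sense codons.
#' @return list with `sd`, `nd` (`sd + nd == hamming(a, b)` when at least
#'   one valid pathway exists) and `valid_paths`; `sd`/`nd` are `NA` when
#'   no pathway avoids stop codons.
#' @export
codon_diffs <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  code <- mito_code()
  if (is_stop(a) || is_stop(b)) stop("stop codon in codon pair")
  pa <- strsplit(a, "")[[1L]]; pb <- strsplit(b, "")[[1L]]
  diff_pos <- which(pa != pb)
  k <- length(diff_pos)
  if (k == 0L) return(list(sd = 0, nd = 0, valid_paths = 1L))
  perms <- permutations_of(diff_pos)
  sds <- numeric(0); nds <- numeric(0)
  for (p in perms) {
    cur <- pa
    sd <- 0; nd <- 0
    ok <- TRUE
    for (pos in p) {
      nxt <- cur; nxt[pos] <- pb[pos]
      c_from <- paste(cur, collapse = ""); c_to <- paste(nxt, collapse = "")
      if (is_stop(c_to)) { ok <- FALSE; break }
      if (code[c_from] == code[c_to]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (!length(sds)) return(list(sd = NA_real_, nd = NA_real_,
                                valid_paths = 0L))
  list(sd = mean(sds), nd = mean(nds), valid_paths = length(sds))
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# cached 64x64 sd/nd matrices (NA where undefined)
diffs_tables <- function() {
  if (is.null(.ng_cache$sd_mat)) {
    code <- mito_code()
    codons <- names(code)
    m <- length(codons)
    sd_mat <- matrix(NA_real_, m, m, dimnames = list(codons, codons))
    nd_mat <- sd_mat
    sense <- which(code != "*")
    for (i in sense) for (j in sense) {
      d <- codon_diffs(codons[i], codons[j])
      sd_mat[i, j] <- d$sd
      nd_mat[i, j] <- d$nd
    }
    .ng_cache$sd_mat <- sd_mat
    .ng_cache$nd_mat <- nd_mat
  }
  list(sd = .ng_cache$sd_mat, nd = .ng_cache$nd_mat)
}

split_codons <- function(s) {
  s <- toupper(s)
  if (nchar(s) %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Nei-Gojobori Ka/Ks for a pair of aligned coding sequences
#'
#' Codons containing gaps or ambiguity characters in either sequence are
#' excluded pairwise, as are the (rare) codon pairs admitting no
#' stop-free pathway. Site totals `S` and `N` are averaged over the two
#' sequences; proportions are Jukes-Cantor corrected:
#' `Ks = -(3/4) log(1 - (4/3) ps)` and likewise for `Ka`. The ratio is
#' undefined (`NA`) when `Ks == 0`.
#'
#' @param seq1,seq2 gap-aligned coding sequences (equal length, length
#'   divisible by 3).
#' @param gene optional label used in messages and the result.
#' @param min_codons minimum comparable codons (default 30).
#' @return a `rate_estimate` list: `gene`, `codons`, `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ks`, `Ka`, `ratio`.
#' @export
nei_gojobori <- function(seq1, seq2, gene = NA_character_, min_codons = 30L) {
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  if (length(c1) != length(c2)) stop("aligned sequences differ in length")
  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  clean <- clean & !is_stop(ifelse(clean, c1, "TAA")) &
    !is_stop(ifelse(clean, c2, "TAA"))
  c1 <- c1[clean]; c2 <- c2[clean]
  if (length(c1) < min_codons)
    stop("insufficient data", if (!is.na(gene)) paste0(" for ", gene),
         ": ", length(c1), " comparable codons (need >= ", min_codons, ")")
  st <- sites_table()
  S <- (sum(st[c1]) + sum(st[c2])) / 2
  N <- 3 * length(c1) - S
  dt <- diffs_tables()
  sd_v <- dt$sd[cbind(c1, c2)]
  nd_v <- dt$nd[cbind(c1, c2)]
  usable <- !is.na(sd_v)
  if (any(!usable))
    warning(sum(!usable), " codon pair(s) without a stop-free pathway ",
            "skipped")
  Sd <- sum(sd_v[usable]); Nd <- sum(nd_v[usable])
  ps <- Sd / S; pn <- Nd / N
  if (ps >= 0.75 || pn >= 0.75)
    stop("saturation", if (!is.na(gene)) paste0(" in ", gene),
         ": ps = ", signif(ps, 3), ", pn = ", signif(pn, 3))
  jc <- function(p) if (p == 0) 0 else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps); Ka <- jc(pn)
  structure(list(gene = gene, codons = length(c1), S = S, N = N,
                 Sd = Sd, Nd = Nd, ps = ps, pn = pn, Ks = Ks, Ka = Ka,
                 ratio = if (Ks > 0) Ka / Ks else NA_real_),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate>%s %d codons\n",
              if (!is.na(x$gene)) paste0(" ", x$gene) else "", x$codons))
  cat(sprintf("  S %.1f N %.1f | Sd %.2f Nd %.2f | Ks %.4f Ka %.4f | Ka/Ks %s\n",
              x$S, x$N, x$Sd, x$Nd, x$Ks, x$Ka,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Genome-level Ka/Ks against a reference genome
#'
#' For each shared annotated protein-coding gene, the sense sequences are
#' stripped of terminal (possibly truncated) stop codons, trimmed to a
#' common codon count, compared with [nei_gojobori()], and the comparable
#' codons pooled into a concatenated estimate. Genes raising saturation or
#' insufficient-data errors are flagged and excluded from the concatenated
#' estimate.
#'
#' @param g,ref [mito_genome] objects.
#' @param genes gene labels to use (default: all 13 PCGs).
#' @param exclude labels to drop (e.g. `"nad2"`).
#' @param min_codons per-gene comparable-codon floor (default 30).
#' @return list with `per_gene` (list of `rate_estimate`), `concatenated`
#'   (`rate_estimate`), `flagged` (character).
#' @export
genome_rates <- function(g, ref, genes = canonical_labels("PCG"),
                         exclude = character(0), min_codons = 30L) {
  f1 <- g$features; f2 <- ref$features
  shared <- intersect(intersect(genes, f1$name[f1$kind == "PCG"]),
                      f2$name[f2$kind == "PCG"])
  shared <- setdiff(shared, exclude)
  if (!length(shared)) stop("no shared protein-coding genes between ",
                            g$id, " and ", ref$id)
  per_gene <- list()
  flagged <- character(0)
  cat1 <- character(0); cat2 <- character(0)
  for (nm in shared) {
    s1 <- strip_stop(gene_seq(g, nm, "sense"))
    s2 <- strip_stop(gene_seq(ref, nm, "sense"))
    ncod <- min(nchar(s1), nchar(s2)) %/% 3L
    s1 <- substr(s1, 1L, 3L * ncod)
    s2 <- substr(s2, 1L, 3L * ncod)
    est <- tryCatch(nei_gojobori(s1, s2, gene = nm,
                                 min_codons = min_codons),
                    error = function(e) e)
    if (inherits(est, "error")) {
      flagged <- c(flagged, nm)
      attr(flagged, nm) <- conditionMessage(est)
    } else {
      per_gene[[nm]] <- est
      cat1 <- c(cat1, s1); cat2 <- c(cat2, s2)
    }
  }
  if (!length(cat1)) stop("no usable genes for concatenated estimate")
  concat <- nei_gojobori(paste(cat1, collapse = ""),
                         paste(cat2, collapse = ""),
                         gene = paste0(g$id, "_vs_", ref$id),
                         min_codons = min_codons)
  list(per_gene = per_gene, concatenated = concat, flagged = flagged)
}

# drop a terminal complete or truncated stop (TAA, TA, T) if present
strip_stop <- function(s) {
  rem <- nchar(s) %% 3L
  if (rem > 0L) {
    tail <- substr(s, nchar(s) - rem + 1L, nchar(s))
    if (tail %in% c("T", "TA")) return(substr(s, 1L, nchar(s) - rem))
    stop("coding sequence length not divisible by 3 and tail is not a ",
         "truncated stop")
  }
  last <- substr(s, nchar(s) - 2L, nchar(s))
  if (last %in% c("TAA", "TAG")) substr(s, 1L, nchar(s) - 3L) else s
}

#' Rate table for a set of genomes against a reference
#'
#' @param genomes list of [mito_genome] objects.
#' @param ref reference [mito_genome].
#' @param ... passed to [genome_rates()].
#' @return data.frame with one row per genome: concatenated `Ks`, `Ka`,
#'   `ratio`, number of genes used and flagged.
#' @export
rates_table <- function(genomes, ref, ...) {
  rows <- lapply(genomes, function(g) {
    r <- genome_rates(g, ref, ...)
    data.frame(id = g$id, ref = ref$id,
               genes = length(r$per_gene), flagged = length(r$flagged),
               Ks = r$concatenated$Ks, Ka = r$concatenated$Ka,
               ratio = r$concatenated$ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
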