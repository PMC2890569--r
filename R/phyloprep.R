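# Construction of codon-partitioned phylogenetic supermatrices from
# per-gene codon alignments: amino acid (aa), Pos12, Pos123 and Pos12RY3
# datasets, concatenated in the ancestral insect mitochondrial gene order,
# with NEXUS/PHYLIP/FASTA export. "?" is missing, "-" is gap, bit-exact
# across writers.

#' Translate a coding sequence with the invertebrate mitochondrial code
#'
#' Gap codons (`---`) map to `-`; a terminal complete (`TAA`/`TAG`) or
#' truncated (`TA`/`T`) stop is dropped; an internal stop is an error
#' naming its codon position. Codons containing ambiguity map to `X`.
#'
#' @param seq coding nucleotide string (gaps allowed in multiples of 3).
#' @return amino acid string.
#' @export
translate_mt <- function(seq) {
  s <- toupper(seq)
  rem <- nchar(s) %% 3L
  if (rem > 0L) {
    tail <- substr(s, nchar(s) - rem + 1L, nchar(s))
    if (!tail %in% c("T", "TA"))
      stop("length not divisible by 3 and tail '", tail,
           "' is not a truncated stop")
    s <- substr(s, 1L, nchar(s) - rem)
  }
  codons <- split_codons(s)
  code <- mito_code()
  aa <- vapply(codons, function(c0) {
    if (c0 == "---") return("-")
    if (!grepl("^[ACGT]{3}$", c0)) return("X")
    unname(code[c0])
  }, "", USE.NAMES = FALSE)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  internal_stop <- which(aa == "*")
  if (length(internal_stop))
    stop("internal stop codon at codon position ", internal_stop[1L])
  paste(aa, collapse = "")
}

#' Back-align unaligned coding sequences onto an amino acid alignment
#'
#' Each taxon's translation must equal its amino acid row with gaps
#' removed; every amino acid gap expands to a codon gap `---`, so columns
#' correspond 3:1.
#'
#' @param nt named character vector of unaligned coding sequences.
#' @param aa_aln named character vector of aligned amino acid rows (same
#'   taxa).
#' @return named character vector of codon-aligned nucleotide rows.
#' @export
back_align <- function(nt, aa_aln) {
  taxa <- names(aa_aln)
  stopifnot(!is.null(taxa), all(taxa %in% names(nt)))
  out <- vapply(taxa, function(tx) {
    aa <- strsplit(aa_aln[[tx]], "")[[1L]]
    cods <- split_codons(strip_stop(toupper(nt[[tx]])))
    tr <- translate_mt(nt[[tx]])
    if (tr != paste(aa[aa != "-"], collapse = ""))
      stop("translation mismatch for taxon '", tx, "' at aligned position ",
           first_mismatch(tr, paste(aa[aa != "-"], collapse = "")))
    res <- character(length(aa))
    j <- 1L
    for (i in seq_along(aa)) {
      if (aa[i] == "-") res[i] <- "---"
      else { res[i] <- cods[j]; j <- j + 1L }
    }
    paste(res, collapse = "")
  }, "")
  names(out) <- taxa
  out
}

first_mismatch <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  i <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(i)) i[1L] else n + 1L
}

#' RY-recode a nucleotide string
#'
#' Purines (`A`, `G`) become `R`, pyrimidines (`C`, `T`) become `Y`; gaps
#' are preserved; anything else becomes the missing symbol `?`. Idempotent.
#'
#' @param seq nucleotide (or already RY-coded) string.
#' @return RY string over `R,Y,-,?`.
#' @export
ry_recode <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1L]]
  out <- ifelse(b %in% c("A", "G", "R"), "R",
         ifelse(b %in% c("C", "T", "Y"), "Y",
         ifelse(b == "-", "-", "?")))
  paste(out, collapse = "")
}

#' Build a phylogenetic supermatrix from per-gene codon alignments
#'
#' Genes are concatenated following the ancestral insect mitochondrial gene
#' order. Column masks (0-based half-open intervals on the gene's aligned
#' nucleotide columns) are removed first; the remaining length must stay
#' divisible by 3. Dataset kinds: `Pos123` keeps all positions, `Pos12`
#' positions 1-2 of each codon, `Pos12RY3` all positions with position 3
#' RY-recoded, `aa` the translations. Partitions are per gene and codon
#' position (stride 3 over the gene's range) for nucleotide kinds and per
#' gene for `aa`; for `Pos12RY3` the third-position partition has character
#' type `RY` (emitted as one charset per gene by default). Taxa missing a
#' gene are padded with `?` and reported.
#'
#' @param alignments named list (gene label -> named character vector of
#'   aligned codon sequences keyed by taxon).
#' @param kind one of `"aa"`, `"Pos12"`, `"Pos123"`, `"Pos12RY3"`.
#' @param exclude_genes labels dropped before concatenation (e.g. `nad2`).
#' @param masks named list (gene -> integer matrix/list of `c(start, end)`
#'   0-based half-open column intervals to remove).
#' @return a `phylo_matrix`: `kind`, `taxa`, `sequences` (named character
#'   vector), `partitions` (data.frame `name`, `start`, `end`, `step`,
#'   `type`, 1-based inclusive), `provenance`.
#' @export
build_matrix <- function(alignments, kind = c("Pos123", "Pos12", "Pos12RY3",
                                              "aa"),
                         exclude_genes = character(0), masks = list()) {
  kind <- match.arg(kind)
  genes <- names(alignments)
  stopifnot(!is.null(genes))
  order_labels <- ancestral_order()$labels
  genes <- genes[order(match(genes, order_labels))]
  genes <- setdiff(genes, exclude_genes)
  if (!length(genes)) stop("no genes left after exclusion")
  taxa <- sort(unique(unlist(lapply(alignments, names))))
  if (!length(taxa)) stop("empty taxon set")
  padded <- character(0)
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  col <- 0L
  for (g0 in genes) {
    aln <- alignments[[g0]]
    len <- unique(nchar(aln))
    if (length(len) != 1L)
      stop("unequal aligned lengths within gene ", g0)
    aln <- apply_mask(aln, masks[[g0]])
    len <- unique(nchar(aln))
    if (len %% 3L != 0L)
      stop("gene ", g0, ": masked alignment length not divisible by 3")
    ncod <- len %/% 3L
    block <- stats::setNames(rep(strrep("?", switch(kind, aa = ncod,
                                                    Pos12 = 2L * ncod,
                                                    len)),
                                 length(taxa)), taxa)
    for (tx in names(aln)) {
      nt <- aln[[tx]]
      block[tx] <- switch(kind,
        aa = translate_aligned(nt),
        Pos12 = drop_third(nt),
        Pos123 = nt,
        Pos12RY3 = recode_third(nt))
    }
    miss <- setdiff(taxa, names(aln))
    if (length(miss)) padded <- unique(c(padded, miss))
    width <- nchar(block[[1L]])
    rows <- paste0(rows, block[taxa])
    names(rows) <- taxa
    parts <- c(parts, gene_partitions(g0, kind, col, ncod))
    col <- col + width
  }
  partitions <- do.call(rbind, parts)
  rownames(partitions) <- NULL
  structure(list(kind = kind, taxa = taxa, sequences = rows,
                 partitions = partitions,
                 provenance = list(genes = genes,
                                   exclude_genes = exclude_genes,
                                   masks = names(masks),
                                   padded_taxa = padded)),
            class = "phylo_matrix")
}

apply_mask <- function(aln, mask) {
  if (is.null(mask) || !length(mask)) return(aln)
  if (is.matrix(mask)) mask <- lapply(seq_len(nrow(mask)),
                                      function(i) mask[i, ])
  len <- nchar(aln[[1L]])
  keep <- rep(TRUE, len)
  for (iv in mask) keep[(iv[1L] + 1L):iv[2L]] <- FALSE
  vapply(aln, function(s) {
    paste(strsplit(s, "")[[1L]][keep], collapse = "")
  }, "")
}

translate_aligned <- function(nt) {
  cods <- split_codons(nt)
  aa <- vapply(cods, function(c0) {
    if (c0 == "---") "-"
    else if (!grepl("^[ACGT]{3}$", c0)) "?"
    else {
      v <- unname(mito_code()[c0])
      if (v == "*") stop("stop codon in aligned gene sequence") else v
    }
  }, "", USE.NAMES = FALSE)
  paste(aa, collapse = "")
}

drop_third <- function(nt) {
  b <- strsplit(nt, "")[[1L]]
  paste(b[(seq_along(b) - 1L) %% 3L != 2L], collapse = "")
}

recode_third <- function(nt) {
  b <- strsplit(toupper(nt), "")[[1L]]
  third <- (seq_along(b) - 1L) %% 3L == 2L
  ry <- strsplit(ry_recode(paste(b[third], collapse = "")), "")[[1L]]
  b[third] <- ry
  paste(b, collapse = "")
}

gene_partitions <- function(gene, kind, col, ncod) {
  p <- function(name, start, end, step, type)
    data.frame(name = name, start = start, end = end, step = step,
               type = type, stringsAsFactors = FALSE)
  if (kind == "aa")
    return(list(p(gene, col + 1L, col + ncod, 1L, "protein")))
  if (kind == "Pos12")
    return(list(p(paste0(gene, "_pos1"), col + 1L, col + 2L * ncod - 1L,
                  2L, "DNA"),
                p(paste0(gene, "_pos2"), col + 2L, col + 2L * ncod, 2L,
                  "DNA")))
  len <- 3L * ncod
  list(p(paste0(gene, "_pos1"), col + 1L, col + len - 2L, 3L, "DNA"),
       p(paste0(gene, "_pos2"), col + 2L, col + len - 1L, 3L, "DNA"),
       p(paste0(gene, "_pos3", if (kind == "Pos12RY3") "RY" else ""),
         col + 3L, col + len, 3L,
         if (kind == "Pos12RY3") "RY" else "DNA"))
}

#' @export
print.phylo_matrix <- function(x, ...) {
  cat(sprintf("<phylo_matrix> %s: %d taxa x %d characters, %d partitions\n",
              x$kind, length(x$taxa), nchar(x$sequences[[1L]]),
              nrow(x$partitions)))
  if (length(x$provenance$padded_taxa))
    cat("  taxa padded with missing data:",
        paste(x$provenance$padded_taxa, collapse = ", "), "\n")
  invisible(x)
}

# machine check of the partition tiling invariant
partition_columns <- function(m) {
  cols <- integer(0)
  for (i in seq_len(nrow(m$partitions)))
    cols <- c(cols, seq(m$partitions$start[i], m$partitions$end[i],
                        by = m$partitions$step[i]))
  cols
}

#' Write a matrix as aligned FASTA
#' @param m a `phylo_matrix`.
#' @param path output file.
#' @export
write_fasta_matrix <- function(m, path) {
  out <- character(0)
  for (tx in m$taxa)
    out <- c(out, paste0(">", tx), m$sequences[[tx]])
  writeLines(out, path)
  invisible(path)
}

#' Write a matrix as relaxed PHYLIP
#' @param m a `phylo_matrix`.
#' @param path output file.
#' @export
write_phylip <- function(m, path) {
  out <- sprintf("%d %d", length(m$taxa), nchar(m$sequences[[1L]]))
  for (tx in m$taxa)
    out <- c(out, paste0(tx, "  ", m$sequences[[tx]]))
  writeLines(out, path)
  invisible(path)
}

#' Write a matrix as NEXUS with a sets block of character partitions
#'
#' Codon-position partitions are emitted as stride charsets
#' (`charset g_pos1 = 1-100\3;`).
#'
#' @param m a `phylo_matrix`.
#' @param path output file.
#' @export
write_nexus <- function(m, path) {
  nchar_tot <- nchar(m$sequences[[1L]])
  datatype <- if (m$kind == "aa") "protein" else "dna"
  out <- c("#NEXUS", "", "begin data;",
           sprintf("  dimensions ntax=%d nchar=%d;", length(m$taxa),
                   nchar_tot),
           sprintf("  format datatype=%s missing=? gap=-;", datatype),
           "  matrix")
  w <- max(nchar(m$taxa)) + 2L
  for (tx in m$taxa)
    out <- c(out, sprintf("    %-*s%s", w, tx, m$sequences[[tx]]))
  out <- c(out, "  ;", "end;", "", "begin sets;")
  for (i in seq_len(nrow(m$partitions))) {
    p <- m$partitions[i, ]
    rng <- if (p$step == 1L) sprintf("%d-%d", p$start, p$end)
           else sprintf("%d-%d\\%d", p$start, p$end, p$step)
    out <- c(out, sprintf("  charset %s = %s;", p$name, rng))
  }
  out <- c(out, "end;")
  writeLines(out, path)
  invisible(path)
}

#' Read per-gene alignments from FASTA files
#'
#' @param paths named character vector (gene label -> FASTA path).
#' @return named list of named character vectors, suitable for
#'   [build_matrix()].
#' @export
read_gene_alignments <- function(paths) {
  stopifnot(!is.null(names(paths)))
  out <- lapply(paths, function(p) {
    lines <- readLines(p, warn = FALSE)
    hdr <- grep("^>", lines)
    stopifnot(length(hdr) >= 1L)
    ends <- c(hdr[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    }, "")
    names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
    toupper(seqs)
  })
  names(out) <- names(paths)
  out
}
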