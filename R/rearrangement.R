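# Signed circular gene orders and rearrangement classification against the
# ancestral hexapod arrangement.
#
# Orders are normalized deterministically: rotated so cox1 comes first and
# reflected (order reversed, all signs flipped) if needed so cox1 carries
# sign +. Neighbor comparisons are side-aware (predecessor and successor in
# the normalized reading direction) but strand-blind on the neighbors'
# labels: "position" is about location, not orientation.

#' Construct a signed circular gene order
#'
#' @param labels character vector of canonical labels (unique).
#' @param signs integer vector of +1/-1, same length.
#' @param id genome id.
#' @return a `gene_order` object, normalized to the cox1/+ anchor.
#' @export
new_gene_order <- function(labels, signs, id = "order") {
  stopifnot(length(labels) == length(signs), !anyDuplicated(labels))
  signs <- as.integer(signs)
  stopifnot(all(signs %in% c(-1L, 1L)))
  a <- match("cox1", labels)
  if (is.na(a)) stop("anchor error: cox1 absent from gene order of ", id)
  if (signs[a] < 0L) {           # reflect
    labels <- rev(labels)
    signs <- -rev(signs)
    a <- match("cox1", labels)
  }
  idx <- c(a:length(labels), seq_len(a - 1L))[seq_along(labels)]
  structure(list(id = id, labels = labels[idx], signs = signs[idx]),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%d genes)\n", x$id, length(x$labels)))
  s <- ifelse(x$signs < 0L, paste0(x$labels, "(-)"), x$labels)
  cat(" ", paste(s, collapse = " "), "\n")
  invisible(x)
}

#' @export
format.gene_order <- function(x, ...) {
  paste(ifelse(x$signs < 0L, paste0(x$labels, "(-)"), x$labels),
        collapse = " ")
}

#' Extract the signed gene order of an annotated genome
#'
#' Genes are sorted by start position around the circle; signs are strands
#' relative to the orientation that makes cox1 `+`. Duplicate-flagged and
#' unmapped features are excluded.
#'
#' @param g a [mito_genome].
#' @return a `gene_order`.
#' @export
extract_order <- function(g) {
  f <- g$features
  f <- f[!f$duplicate & !is.na(f$name), , drop = FALSE]
  if (anyDuplicated(f$name))
    stop("order error: unresolved duplicate labels in ", g$id, ": ",
         paste(unique(f$name[duplicated(f$name)]), collapse = ", "))
  if (!"cox1" %in% f$name) stop("anchor error: cox1 not annotated in ", g$id)
  f <- f[order(f$start), , drop = FALSE]
  new_gene_order(f$name, ifelse(f$strand == "+", 1L, -1L), id = g$id)
}

# canonical encoding of signed circular adjacencies: the pair
# (a,sa) -> (b,sb) read the other way is (b,-sb) -> (a,-sa)
adjacency_set <- function(o) {
  n <- length(o$labels)
  nxt <- c(2:n, 1L)
  enc <- function(a, sa, b, sb) paste0(sa, a, ">", sb, b)
  vapply(seq_len(n), function(i) {
    a <- o$labels[i]; sa <- o$signs[i]
    b <- o$labels[nxt[i]]; sb <- o$signs[nxt[i]]
    e1 <- enc(a, sa, b, sb)
    e2 <- enc(b, -sb, a, -sa)
    if (e1 <= e2) e1 else e2
  }, "")
}

#' Breakpoint distance between two signed circular gene orders
#'
#' The number of signed circular adjacencies present in `a` but absent from
#' `b`. Symmetric, and zero exactly when the normalized orders are equal.
#'
#' @param a,b `gene_order` objects over the same label set.
#' @return integer.
#' @export
breakpoint_distance <- function(a, b) {
  if (!setequal(a$labels, b$labels))
    stop("label-set mismatch: only in a: ",
         paste(setdiff(a$labels, b$labels), collapse = ", "),
         "; only in b: ", paste(setdiff(b$labels, a$labels), collapse = ", "))
  length(setdiff(adjacency_set(a), adjacency_set(b)))
}

# restrict an order to a label subset, preserving relative order
restrict_order <- function(o, labels) {
  keep <- o$labels %in% labels
  new_gene_order(o$labels[keep], o$signs[keep], id = o$id)
}

# per-gene classification of one restricted order against another
classify_core <- function(obs, anc, window) {
  n <- length(obs$labels)
  stopifnot(setequal(obs$labels, anc$labels))
  o_rank <- match(anc$labels, obs$labels)       # observed rank per anc label
  prv <- function(v, i) v[if (i == 1L) length(v) else i - 1L]
  nxt <- function(v, i) v[if (i == length(v)) 1L else i + 1L]
  out <- data.frame(gene = anc$labels,
                    kind = label_kind(anc$labels),
                    sign_ancestral = anc$signs,
                    sign_observed = obs$signs[o_rank],
                    stringsAsFactors = FALSE)
  status <- character(n)
  displacement <- integer(n)
  circ_dist <- function(a, b) min((a - b) %% n, (b - a) %% n)
  for (k in seq_len(n)) {
    lab <- anc$labels[k]
    i_obs <- o_rank[k]
    sign_same <- anc$signs[k] == obs$signs[i_obs]
    pred_ok <- identical(prv(obs$labels, i_obs), prv(anc$labels, k))
    succ_ok <- identical(nxt(obs$labels, i_obs), nxt(anc$labels, k))
    # displacement relative to the gene's own ancestral context: distance
    # from the observed position to the slot next to either ancestral
    # neighbor's observed position (rotation/anchor independent)
    kp <- if (k == 1L) n else k - 1L
    ks <- if (k == n) 1L else k + 1L
    d <- min(circ_dist(i_obs, o_rank[kp] + 1L),
             circ_dist(i_obs, o_rank[ks] - 1L))
    displacement[k] <- d
    status[k] <-
      if (sign_same && (pred_ok || succ_ok)) "ancestral"
      else if (sign_same && d <= window) "shuffled"
      else if (sign_same) "translocation"
      else if (pred_ok && succ_ok) "local_inversion"
      else "remote_inversion"
  }
  out$status <- status
  out$displacement <- displacement
  out
}

#' Classify gene rearrangements against an ancestral order
#'
#' Per-gene classification into the event taxonomy of hymenopteran
#' mitogenomics: `ancestral` (at least one ancestral flanking gene preserved
#' on its own side, orientation preserved), `local_inversion` (both
#' neighbors preserved, orientation flipped -- inverted but remaining in
#' position), `shuffled` (orientation preserved, both flanks changed,
#' circular rank displacement at most `window`), `translocation`
#' (orientation preserved, displacement beyond `window`), and
#' `remote_inversion` (orientation flipped and relocated). Genes absent
#' from the observed order (unsequenced regions) are skipped and listed;
#' their former neighbors bridge over the gap.
#'
#' A second classification is computed on the PCG+rRNA(+CR) projection of
#' both orders (tRNAs removed before neighbor comparison) so that tRNA
#' movement alone never marks a protein-coding gene as changed.
#'
#' Maximal runs of adjacent genes sharing a non-ancestral status are merged
#' into block events (e.g. a multi-gene inversion reported as one block).
#'
#' @param order a `gene_order` (or a [mito_genome], from which the order is
#'   extracted).
#' @param ancestral baseline `gene_order`; defaults to [ancestral_order()].
#' @param window shuffle-vs-translocation displacement threshold in gene
#'   ranks (default 3).
#' @return a `rearrangement_report`.
#' @export
classify_rearrangements <- function(order, ancestral = ancestral_order(),
                                    window = 3L) {
  if (inherits(order, "mito_genome")) order <- extract_order(order)
  stopifnot(inherits(order, "gene_order"))
  shared <- intersect(ancestral$labels, order$labels)
  missing <- setdiff(ancestral$labels, order$labels)
  extra <- setdiff(order$labels, ancestral$labels)
  obs <- restrict_order(order, shared)
  anc <- restrict_order(ancestral, shared)
  genes <- classify_core(obs, anc, window)

  proj_labels <- shared[label_kind(shared) != "tRNA"]
  proj <- classify_core(restrict_order(order, proj_labels),
                        restrict_order(ancestral, proj_labels), window)

  count_changed <- function(df) {
    ch <- df[df$status != "ancestral", , drop = FALSE]
    c(PCG = sum(ch$kind == "PCG"), tRNA = sum(ch$kind == "tRNA"),
      rRNA = sum(ch$kind == "rRNA"),
      control_region = sum(ch$kind == "control_region"))
  }

  # block events: maximal runs of adjacent changed genes sharing a status
  blocks <- find_blocks(obs, anc, genes)

  structure(list(id = order$id, genes = genes, projection = proj,
                 changed_counts = list(full = count_changed(genes),
                                       pcg_projection = count_changed(proj)),
                 blocks = blocks, missing = missing, extra = extra,
                 window = window),
            class = "rearrangement_report")
}

find_blocks <- function(obs, anc, genes) {
  n <- length(obs$labels)
  st <- genes$status[match(obs$labels, genes$gene)]
  changed <- st != "ancestral"
  if (!any(changed))
    return(data.frame(event = character(), genes = character(),
                      source_junction = character(),
                      destination_junction = character(),
                      annotation = character(), stringsAsFactors = FALSE))
  # find runs on the circle of equal non-ancestral status
  runs <- list()
  i <- 1L
  visited <- rep(FALSE, n)
  # start scanning at an unchanged gene if one exists to avoid splitting a
  # run across the arbitrary linearization point
  start <- if (any(!changed)) which(!changed)[1L] else 1L
  ordidx <- c(start:n, seq_len(start - 1L))
  cur <- integer(0)
  for (i in ordidx) {
    if (changed[i] && (length(cur) == 0L || st[i] == st[cur[length(cur)]]))
      cur <- c(cur, i)
    else {
      if (length(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- if (changed[i]) i else integer(0)
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  rows <- lapply(runs, function(r) {
    labs <- obs$labels[r]
    a_first <- match(labs[1L], anc$labels)
    a_last <- match(labs[length(labs)], anc$labels)
    wrap <- function(v, i) v[((i - 1L) %% length(v)) + 1L]
    data.frame(event = st[r[1L]],
               genes = paste(labs, collapse = ","),
               source_junction = paste0(wrap(anc$labels, a_first - 1L), "|",
                                        wrap(anc$labels, a_last + 1L)),
               destination_junction = paste0(wrap(obs$labels, r[1L] - 1L),
                                             "|",
                                             wrap(obs$labels,
                                                  r[length(r)] + 1L)),
               annotation = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("<rearrangement_report> %s (window %d)\n", x$id, x$window))
  ch <- x$genes[x$genes$status != "ancestral", , drop = FALSE]
  cat(sprintf("  changed genes: %d of %d", nrow(ch), nrow(x$genes)))
  cc <- x$changed_counts$full
  cat(sprintf("  (PCG %d, tRNA %d, rRNA %d, CR %d)\n",
              cc[["PCG"]], cc[["tRNA"]], cc[["rRNA"]],
              cc[["control_region"]]))
  if (nrow(ch)) {
    for (i in seq_len(nrow(ch)))
      cat(sprintf("    %-6s %-15s displacement %d\n", ch$gene[i],
                  ch$status[i], ch$displacement[i]))
  }
  if (length(x$missing))
    cat("  missing (skipped):", paste(x$missing, collapse = ", "), "\n")
  if (nrow(x$blocks)) {
    cat("  block events:\n")
    for (i in seq_len(nrow(x$blocks)))
      cat(sprintf("    %s: %s -> %s [%s]\n", x$blocks$event[i],
                  x$blocks$source_junction[i],
                  x$blocks$destination_junction[i], x$blocks$genes[i]))
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## Pseudogene remnant search

#' Search intergenic spacers for degraded remnants of a gene
#'
#' Locally aligns the annotated gene's sense sequence, and its reverse
#' complement, against every feature-free interval of at least `min_len`
#' bp. A hit requires identity at or above `min_identity` over an aligned
#' span of at least `min_span_frac` of the gene length (the span floor
#' suppresses the short chance matches that A+T-rich spacers produce
#' freely). Hit strand `"+"` means the spacer carries the gene's sense
#' sequence on the plus strand, `"-"` the reverse complement.
#'
#' @param g a [mito_genome].
#' @param gene canonical label of the query gene (must be annotated).
#' @param min_identity minimum fractional identity (default 0.6).
#' @param min_len minimum spacer length searched (default 20).
#' @param min_span_frac minimum aligned span as a fraction of gene length
#'   (default 0.65).
#' @return data.frame of hits: `gene`, `start`, `end`, `strand`,
#'   `identity`, `span`.
#' @export
find_pseudogene <- function(g, gene, min_identity = 0.6, min_len = 20L,
                            min_span_frac = 0.65) {
  query <- gene_seq(g, gene, "sense")
  ivs <- intergenic_intervals(g, min_len)
  hits <- list()
  if (nrow(ivs)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    for (i in seq_len(nrow(ivs))) {
      spacer <- circ_substr(g$sequence, ivs$start[i], ivs$end[i])
      best <- NULL
      for (strand in c("+", "-")) {
        q <- if (strand == "+") query else revcomp(query)
        aln <- Biostrings::pairwiseAlignment(q, spacer, type = "local",
                                             substitutionMatrix = mat,
                                             gapOpening = 2, gapExtension = 1)
        wid <- nchar(as.character(Biostrings::alignedPattern(aln)))
        if (wid == 0L) next
        ident <- Biostrings::nmatch(aln) / wid
        if (ident >= min_identity && wid >= min_span_frac * nchar(query) &&
              (is.null(best) || ident * wid > best$identity * best$span))
          # an A+T-rich remnant can pass on both strands; keep the better
          best <- data.frame(gene = gene, start = ivs$start[i],
                             end = ivs$end[i], strand = strand,
                             identity = ident, span = wid,
                             stringsAsFactors = FALSE)
      }
      if (!is.null(best)) hits[[length(hits) + 1L]] <- best
    }
  }
  if (!length(hits))
    return(data.frame(gene = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), span = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# feature-free intervals (0-based half-open; may wrap) of length >= min_len
intergenic_intervals <- function(g, min_len = 20L) {
  f <- g$features
  n <- g$length
  if (!nrow(f))
    return(data.frame(start = 0L, end = n))
  f <- f[order(f$start), , drop = FALSE]
  gaps <- list()
  for (i in seq_len(nrow(f))) {
    this_end <- f$end[i]
    next_start <- if (i < nrow(f)) f$start[i + 1L] else f$start[1L] + n
    # clip against features that wrap past this one
    if (next_start - this_end >= min_len)
      gaps[[length(gaps) + 1L]] <- c(this_end %% n,
                                     this_end %% n + (next_start - this_end))
  }
  if (!length(gaps)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, gaps)
  data.frame(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]))
}
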