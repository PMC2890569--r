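# Structural annotation of the A+T-rich (control) region: the five
# canonical insect elements -- a 5' polyT stretch, a [TA(A)]n-like stretch,
# a stem-loop, TATA and G(A)nT motifs flanking the stem-loop, and a
# downstream G+A-rich tract -- plus tandem-repeat detection and orientation
# inference. Element thresholds are qualitative in the source literature;
# the numeric defaults here are deliberate choices, exposed as arguments.

.CR_KIND_RANK <- c(polyT = 1, TAA_repeat = 2, stem_loop = 3,
                   TATA_motif = 3, GAnT_motif = 3, GA_rich = 4)

#' Locate the control region of a genome
#'
#' Returns the annotated CR feature if one exists; otherwise, for a
#' complete genome, the largest feature-free span.
#'
#' @param g a [mito_genome].
#' @param min_len smallest acceptable feature-free span (default 100 bp).
#' @return list with `start`, `end` (0-based half-open, may wrap) and
#'   `source` (`"annotation"` or `"largest_gap"`).
#' @export
locate_region <- function(g, min_len = 100L) {
  f <- g$features
  i <- which(f$kind == "control_region" & !f$duplicate)
  if (length(i))
    return(list(start = f$start[i[1L]], end = f$end[i[1L]],
                source = "annotation"))
  gaps <- intergenic_intervals(g, min_len = min_len)
  if (!nrow(gaps))
    stop("control region not found in ", g$id,
         ": no CR feature and no feature-free span >= ", min_len, " bp")
  j <- which.max(gaps$end - gaps$start)
  list(start = gaps$start[j], end = gaps$end[j], source = "largest_gap")
}

# integer encoding for fast window arithmetic
seq_to_int <- function(s) {
  b <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  match(b, c("A", "C", "G", "T"))  # NA for ambiguity
}

#' Scan a control-region sequence for canonical structural elements
#'
#' Both strands are searched (the minus strand via the reverse complement;
#' minus-strand intervals are reported in plus-strand coordinates).
#' Detectors, with their score semantics:
#' * `polyT`: longest run of `T` tolerating at most one single-base
#'   interruption; reported if at least `min_polyt` long (score = run
#'   length).
#' * `TAA_repeat`: maximal region formed by concatenated `TA`/`TAA` units
#'   with at least `min_taa_copies` units (score = unit count).
#' * `stem_loop`: best DNA hairpin with stem `stem_range` bp, loop
#'   `loop_range` bp and at most one mismatch, Watson-Crick pairing only
#'   (score = stem length).
#' * `TATA_motif` / `GAnT_motif`: literal `TATA` and `G A{1,6} T` within
#'   `flank_window` bp of a reported stem-loop (score = match length).
#' * `GA_rich`: maximal window of at least `min_ga_len` bp downstream of
#'   the stem-loop with purine fraction at least `min_purine` (score =
#'   purine fraction).
#'
#' @param region_seq control-region DNA string (>= 50 bp).
#' @param min_polyt,min_taa_copies,stem_range,loop_range,max_mismatch,flank_window,min_ga_len,min_purine detector thresholds (see above).
#' @return data.frame: `kind`, `start`, `end` (0-based half-open on the
#'   plus strand of `region_seq`), `strand`, `score`.
#' @export
scan_elements <- function(region_seq, min_polyt = 12L, min_taa_copies = 6L,
                          stem_range = c(10L, 25L), loop_range = c(3L, 30L),
                          max_mismatch = 1L, flank_window = 30L,
                          min_ga_len = 20L, min_purine = 0.7) {
  stopifnot(nchar(region_seq) >= 50L)
  n <- nchar(region_seq)
  plus <- scan_one_strand(toupper(region_seq), min_polyt, min_taa_copies,
                          stem_range, loop_range, max_mismatch, flank_window,
                          min_ga_len, min_purine)
  if (nrow(plus)) plus$strand <- "+"
  minus <- scan_one_strand(revcomp(region_seq), min_polyt, min_taa_copies,
                           stem_range, loop_range, max_mismatch, flank_window,
                           min_ga_len, min_purine)
  if (nrow(minus)) {
    minus$strand <- "-"
    # map back to plus-strand coordinates
    s <- n - minus$end
    minus$end <- n - minus$start
    minus$start <- s
  }
  out <- rbind(plus, minus)
  rownames(out) <- NULL
  out
}

scan_one_strand <- function(s, min_polyt, min_taa_copies, stem_range,
                            loop_range, max_mismatch, flank_window,
                            min_ga_len, min_purine) {
  hits <- list()
  add <- function(kind, start, end, score)
    hits[[length(hits) + 1L]] <<- data.frame(kind = kind, start = start,
                                             end = end, strand = "+",
                                             score = score,
                                             stringsAsFactors = FALSE)
  ## polyT: T-runs merged across a single 1-bp interruption
  m <- gregexpr("T+", s)[[1L]]
  if (m[1L] != -1L) {
    st <- as.integer(m); len <- attr(m, "match.length")
    best <- c(0L, 0L)  # (start0, len)
    for (i in seq_along(st)) {
      tot <- len[i]; s0 <- st[i]
      if (i < length(st) && st[i + 1L] == st[i] + len[i] + 1L)
        tot <- tot + 1L + len[i + 1L]
      if (tot > best[2L]) best <- c(s0 - 1L, tot)
    }
    if (best[2L] >= min_polyt)
      add("polyT", best[1L], best[1L] + best[2L], best[2L])
  }
  ## TAA repeat: maximal concatenation of TA/TAA units
  m <- gregexpr("(?:TAA?)+", s)[[1L]]
  if (m[1L] != -1L) {
    st <- as.integer(m); len <- attr(m, "match.length")
    copies <- vapply(seq_along(st), function(i) {
      sub <- substr(s, st[i], st[i] + len[i] - 1L)
      length(gregexpr("TAA?", sub)[[1L]])
    }, 0L)
    ok <- copies >= min_taa_copies
    if (any(ok)) {
      i <- which(ok)[which.max(copies[ok])]
      add("TAA_repeat", st[i] - 1L, st[i] - 1L + len[i], copies[i])
    }
  }
  ## stem-loops: top non-overlapping hairpins, each with its own flanks
  ## (a chance hairpin can outscore the functional one, so candidate
  ## layouts are kept for all of them)
  for (sl in top_hairpins(s, stem_range, loop_range, max_mismatch)) {
    add("stem_loop", sl$start, sl$end, sl$stem)
    ## flanking motifs within flank_window of the hairpin
    lo <- max(0L, sl$start - flank_window)
    hi <- min(nchar(s), sl$end + flank_window)
    ctx <- substr(s, lo + 1L, hi)
    mt <- regexpr("TATA", ctx, fixed = TRUE)
    if (mt != -1L)
      add("TATA_motif", lo + as.integer(mt) - 1L,
          lo + as.integer(mt) + 3L, 4)
    mg <- regexpr("GA{1,6}T", ctx)
    if (mg != -1L)
      add("GAnT_motif", lo + as.integer(mg) - 1L,
          lo + as.integer(mg) - 1L + attr(mg, "match.length"),
          attr(mg, "match.length"))
    ## G+A-rich window downstream of the stem-loop
    ga <- ga_rich_window(s, sl$end, min_ga_len, min_purine)
    if (!is.null(ga)) add("GA_rich", ga$start, ga$end, ga$frac)
  }
  if (!length(hits))
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# exhaustive hairpin search on the integer-encoded sequence; returns up to
# `k` non-overlapping hairpins ordered by stem length (ties: fewest
# mismatches, then leftmost)
top_hairpins <- function(s, stem_range, loop_range, max_mismatch, k = 3L) {
  x <- seq_to_int(s)
  n <- length(x)
  comp <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  cands <- list()
  for (stem in seq(stem_range[2L], stem_range[1L])) {
    for (loop in seq(loop_range[1L], loop_range[2L])) {
      span <- 2L * stem + loop
      if (span > n) next
      starts <- seq_len(n - span + 1L)
      mm <- integer(length(starts))
      for (kk in seq_len(stem)) {
        left <- x[starts + (kk - 1L)]
        right <- x[starts + span - kk]
        mm <- mm + as.integer(is.na(left) | is.na(right) |
                                comp[left] != right)
      }
      i <- which(mm <= max_mismatch)
      if (length(i)) {
        i <- i[which.min(mm[i])]
        cands[[length(cands) + 1L]] <-
          list(start = starts[i] - 1L, end = starts[i] - 1L + span,
               stem = stem, loop = loop, mismatches = mm[i])
      }
    }
    if (length(cands) >= 4L * k) break
  }
  if (!length(cands)) return(list())
  ord <- order(-vapply(cands, `[[`, 0L, "stem"),
               vapply(cands, `[[`, 0L, "mismatches"),
               vapply(cands, `[[`, 0L, "start"))
  picked <- list()
  for (c0 in cands[ord]) {
    clash <- any(vapply(picked, function(p)
      min(p$end, c0$end) - max(p$start, c0$start) > 0L, TRUE))
    if (!clash) picked[[length(picked) + 1L]] <- c0
    if (length(picked) >= k) break
  }
  picked
}

ga_rich_window <- function(s, from, min_len, min_purine) {
  x <- seq_to_int(substr(s, from + 1L, nchar(s)))
  if (length(x) < min_len) return(NULL)
  pur <- as.integer(!is.na(x) & (x == 1L | x == 3L))  # A or G
  cs <- c(0L, cumsum(pur))
  nn <- length(pur)
  best <- NULL
  for (i in seq_len(nn - min_len + 1L)) {
    frac <- (cs[i + min_len] - cs[i]) / min_len
    if (frac >= min_purine) {
      # extend right while the running fraction stays above threshold
      j <- i + min_len
      while (j < nn + 1L && (cs[j + 1L] - cs[i]) / (j + 1L - i) >= min_purine)
        j <- j + 1L
      cand <- list(start = from + i - 1L, end = from + j - 1L,
                   frac = (cs[j] - cs[i]) / (j - i))
      if (is.null(best) || (cand$end - cand$start) >
            (best$end - best$start)) best <- cand
    }
  }
  best
}

## ---------------------------------------------------------------------------
## Tandem repeats

#' Detect tandem repeats in a control-region sequence
#'
#' Seed-and-extend over k-mer diagonals: repeated k-mers propose candidate
#' unit lengths (the distance between occurrences); each candidate anchor
#' is extended into a maximal array of consecutive copies whose identity to
#' the first copy stays at or above `min_identity`. Overlapping tracks are
#' merged keeping the highest copies x identity product.
#'
#' @param region_seq DNA string (>= 2 * `min_unit` bp).
#' @param min_unit minimum repeat unit length (default 20 bp).
#' @param min_copies minimum copy number (default 2).
#' @param min_identity minimum mean identity between copies (default 0.85).
#' @param k seed k-mer size (default 12).
#' @return data.frame: `start`, `end`, `unit_length`, `copies` (fractional),
#'   `identity`, `consensus`.
#' @export
find_repeats <- function(region_seq, min_unit = 20L, min_copies = 2L,
                         min_identity = 0.85, k = 12L) {
  s <- toupper(region_seq)
  n <- nchar(s)
  stopifnot(n >= 2L * min_unit)
  x <- seq_to_int(s)
  max_unit <- n %/% min_copies
  kmers <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  occ <- split(seq_along(kmers), kmers)
  cand <- list()
  for (pos in occ) {
    if (length(pos) < 2L) next
    d <- diff(pos)
    for (j in seq_along(d)) {
      u <- d[j]
      if (u >= min_unit && u <= max_unit)
        cand[[length(cand) + 1L]] <- c(pos[j], u)
    }
  }
  if (!length(cand))
    return(empty_repeat_df())
  cand <- unique(do.call(rbind, cand))
  tracks <- list()
  seen <- character(0)
  ident <- function(i, j, u) {
    a <- x[i:(i + u - 1L)]; b <- x[j:(j + u - 1L)]
    mean(!is.na(a) & !is.na(b) & a == b)
  }
  for (r in seq_len(nrow(cand))) {
    u <- cand[r, 2L]
    # walk the anchor back to the leftmost copy
    i <- cand[r, 1L]
    while (i - u >= 1L && ident(i - u, i, u) >= min_identity) i <- i - u
    key <- paste(i, u)
    if (key %in% seen) next
    seen <- c(seen, key)
    # extend forward copy by copy
    copies <- 1L
    ids <- numeric(0)
    j <- i + u
    while (j + u - 1L <= n && ident(i, j, u) >= min_identity) {
      ids <- c(ids, ident(i, j, u))
      copies <- copies + 1L
      j <- j + u
    }
    if (copies < min_copies) next
    # fractional tail copy
    tail_len <- min(u, n - j + 1L)
    frac <- 0
    if (tail_len >= k) {
      tid <- mean(!is.na(x[i:(i + tail_len - 1L)]) &
                    !is.na(x[j:(j + tail_len - 1L)]) &
                    x[i:(i + tail_len - 1L)] == x[j:(j + tail_len - 1L)])
      if (tid >= min_identity) frac <- tail_len / u
    }
    end <- j - 1L + if (frac > 0) tail_len else 0L
    cons <- consensus_unit(x, i, u, copies)
    tracks[[length(tracks) + 1L]] <-
      data.frame(start = i - 1L, end = end, unit_length = u,
                 copies = copies + frac, identity = mean(c(1, ids)),
                 consensus = cons, stringsAsFactors = FALSE)
  }
  if (!length(tracks)) return(empty_repeat_df())
  tr <- do.call(rbind, tracks)
  merge_tracks(tr)
}

empty_repeat_df <- function()
  data.frame(start = integer(), end = integer(), unit_length = integer(),
             copies = numeric(), identity = numeric(),
             consensus = character(), stringsAsFactors = FALSE)

consensus_unit <- function(x, i, u, copies) {
  m <- matrix(NA_integer_, nrow = copies, ncol = u)
  for (c0 in seq_len(copies)) {
    idx <- (i + (c0 - 1L) * u):(i + c0 * u - 1L)
    m[c0, ] <- x[idx]
  }
  cons <- apply(m, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return("N")
    c("A", "C", "G", "T")[as.integer(names(which.max(table(col))))]
  })
  paste(cons, collapse = "")
}

merge_tracks <- function(tr) {
  tr <- tr[order(-(tr$copies * tr$identity)), , drop = FALSE]
  kept <- tr[0L, ]
  for (i in seq_len(nrow(tr))) {
    ov <- FALSE
    if (nrow(kept))
      ov <- any(pmin(kept$end, tr$end[i]) - pmax(kept$start, tr$start[i]) >
                  0.5 * tr$unit_length[i])
    if (!ov) kept <- rbind(kept, tr[i, ])
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

## ---------------------------------------------------------------------------
## Orientation

#' Infer the orientation of a control region from its element layout
#'
#' The layout of a strand is the longest chain of distinct element kinds
#' on that strand that (i) starts with a 5' anchor (`polyT` or
#' `TAA_repeat`) and (ii) proceeds in the canonical 5'->3' order polyT,
#' [TA(A)]n, stem-loop (with its flanking TATA / G(A)nT motifs), G+A-rich
#' tract. A strand with fewer than `min_kinds` chained kinds scores 0 (a
#' sub-threshold layout is no layout); otherwise its layout score is the
#' sum over chained elements of their quality relative to the detection
#' threshold (run length / `min_polyt`, copies / `min_taa_copies`, stem
#' length / minimum stem, purine fraction / `min_purine`, 1 for the
#' literal motifs), each capped at 2. Quality weighting is what separates
#' a genuine layout from its mirror image: the hairpin and the TATA motif
#' are strand-symmetric, and the complement of a G+A tract resembles a
#' polyT stretch, so bare kind counts on the two strands of an inverted
#' region are nearly always tied. The call is the argmax strand; ties
#' (including two zero scores) are `indeterminate`.
#'
#' @param region_seq DNA string.
#' @param min_kinds minimum chained element kinds for a callable layout
#'   (default 5).
#' @param min_polyt,min_taa_copies,stem_range,min_purine detector
#'   thresholds, also used for quality normalization.
#' @param ... further thresholds passed to [scan_elements()].
#' @return list with `orientation` (`forward`, `inverted`,
#'   `indeterminate`), `score_forward`, `score_reverse`, `elements`.
#' @export
infer_orientation <- function(region_seq, min_kinds = 5L, min_polyt = 14L,
                              min_taa_copies = 7L, stem_range = c(10L, 25L),
                              min_purine = 0.7, ...) {
  el <- scan_elements(region_seq, min_polyt = min_polyt,
                      min_taa_copies = min_taa_copies,
                      stem_range = stem_range, min_purine = min_purine, ...)
  quality <- function(e) {
    q <- switch(e$kind,
                polyT = e$score / min_polyt,
                TAA_repeat = e$score / min_taa_copies,
                stem_loop = e$score / stem_range[1L],
                GA_rich = e$score / min_purine,
                1)
    min(q, 2)
  }
  chain <- function(e) {
    # longest nondecreasing-rank chain of distinct kinds anchored at a
    # polyT or TAA stretch, scored by summed quality
    if (!nrow(e) || !any(e$kind %in% c("polyT", "TAA_repeat")))
      return(c(0L, 0))
    ranks <- .CR_KIND_RANK[e$kind]
    best_n <- 0L
    best_q <- 0
    for (a in which(e$kind %in% c("polyT", "TAA_repeat"))) {
      len <- 1L
      q <- quality(e[a, ])
      last <- ranks[a]
      if (a < nrow(e)) for (i in (a + 1L):nrow(e)) {
        if (ranks[i] >= last) {
          len <- len + 1L
          q <- q + quality(e[i, ])
          last <- ranks[i]
        }
      }
      if (len > best_n || (len == best_n && q > best_q)) {
        best_n <- len
        best_q <- q
      }
    }
    c(best_n, best_q)
  }
  score <- function(strand) {
    e <- el[el$strand == strand, , drop = FALSE]
    if (!nrow(e)) return(0)
    # orient positions 5'->3' on the scored strand
    pos <- if (strand == "+") e$start else -e$end
    e <- e[order(pos), , drop = FALSE]
    stems <- which(e$kind == "stem_loop")
    if (!length(stems)) {
      r <- chain(e[!duplicated(e$kind), , drop = FALSE])
      return(if (r[1L] >= min_kinds) r[2L] else 0)
    }
    # one candidate layout per hairpin: that hairpin, its nearest flanking
    # motifs/GA tract, and the best 5' anchors
    best <- 0
    for (si in stems) {
      keep <- rep(FALSE, nrow(e))
      keep[si] <- TRUE
      for (kind in c("TATA_motif", "GAnT_motif", "GA_rich")) {
        j <- which(e$kind == kind)
        if (length(j)) {
          dist <- abs((e$start[j] + e$end[j]) - (e$start[si] + e$end[si]))
          keep[j[which.min(dist)]] <- TRUE
        }
      }
      keep[e$kind %in% c("polyT", "TAA_repeat")] <- TRUE
      e2 <- e[keep, , drop = FALSE]
      e2 <- e2[!duplicated(e2$kind), , drop = FALSE]
      r <- chain(e2)
      if (r[1L] >= min_kinds) best <- max(best, r[2L])
    }
    best
  }
  sf <- score("+")
  sr <- score("-")
  orientation <- if (sf == sr) "indeterminate"
                 else if (sf > sr) "forward" else "inverted"
  list(orientation = orientation, score_forward = sf,
       score_reverse = sr, elements = el)
}

#' Full control-region annotation of a genome
#'
#' Locates the region, scans elements on both strands, detects tandem
#' repeats, and infers orientation.
#'
#' @param g a [mito_genome].
#' @param ... thresholds passed to [scan_elements()] / [find_repeats()].
#' @return a `cr_annotation` list: `id`, `start`, `end`, `length`,
#'   `at_content`, `elements`, `repeats`, `orientation`, `scores`.
#' @export
annotate_control_region <- function(g, ...) {
  iv <- locate_region(g)
  s <- circ_substr(g$sequence, iv$start, iv$end)
  ori <- infer_orientation(s)
  reps <- if (nchar(s) >= 40L) find_repeats(s) else empty_repeat_df()
  k <- skew(s)
  structure(list(id = g$id, start = iv$start, end = iv$end,
                 length = nchar(s), at_content = k$at_content,
                 elements = ori$elements, repeats = reps,
                 orientation = ori$orientation,
                 scores = c(forward = ori$score_forward,
                            reverse = ori$score_reverse)),
            class = "cr_annotation")
}

#' @export
print.cr_annotation <- function(x, ...) {
  cat(sprintf("<cr_annotation> %s: %d bp at [%d,%d), A+T %.1f%%\n", x$id,
              x$length, x$start, x$end, x$at_content))
  cat(sprintf("  orientation: %s (layout scores +%.1f / -%.1f)\n",
              x$orientation, x$scores[["forward"]], x$scores[["reverse"]]))
  if (nrow(x$elements)) {
    for (i in seq_len(nrow(x$elements)))
      cat(sprintf("    %-10s [%4d,%4d) %s score %.2f\n",
                  x$elements$kind[i], x$elements$start[i], x$elements$end[i],
                  x$elements$strand[i], x$elements$score[i]))
  }
  if (nrow(x$repeats))
    cat(sprintf("  repeats: %d track(s), unit %s bp\n", nrow(x$repeats),
                paste(x$repeats$unit_length, collapse = "/")))
  invisible(x)
}
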