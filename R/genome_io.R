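# Reading, validating and normalizing annotated mitochondrial genomes.
#
# Internal coordinates are 0-based half-open on the plus strand of the file.
# A feature crossing the origin of a circular genome keeps start in
# [0, length) and end in (length, start + length]; its sequence wraps.

#' Construct an annotated mitochondrial genome
#'
#' The central container of the package: a circular (or partial) DNA
#' sequence plus a table of typed gene features with canonical labels.
#'
#' @param id accession or label.
#' @param sequence DNA string over `A,C,G,T,N`.
#' @param features data.frame with columns `name` (canonical label or `NA`
#'   for unmapped), `start`, `end` (0-based half-open, plus strand),
#'   `strand` (`"+"`/`"-"`), `kind` (`PCG`, `tRNA`, `rRNA`,
#'   `control_region`), and optionally `raw_name`, `anticodon`, `duplicate`.
#' @param circular logical; is the molecule circular?
#' @param completeness `"complete"` or `"partial"`.
#' @param max_overlap bp of overlap tolerated between distinct genes before
#'   a warning is raised (mitochondrial genes commonly overlap by <= 7 bp).
#' @return an object of class `mito_genome`.
#' @export
mito_genome <- function(id, sequence, features, circular = TRUE,
                        completeness = c("complete", "partial"),
                        max_overlap = 10L) {
  completeness <- match.arg(completeness)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stopifnot(n > 0L, is.data.frame(features))
  for (col in c("name", "start", "end", "strand", "kind")) {
    if (!col %in% names(features))
      stop("feature table lacks column '", col, "'")
  }
  if (is.null(features$raw_name)) features$raw_name <- features$name
  if (is.null(features$anticodon)) features$anticodon <- NA_character_
  if (is.null(features$duplicate)) features$duplicate <- FALSE
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    # circular normalization of the start coordinate
    features$end <- features$end - (features$start %/% n) * n
    features$start <- features$start %% n
    bad <- features$end <= features$start | features$end - features$start > n
    if (any(bad))
      stop("invalid feature interval(s): ",
           paste(features$name[bad], collapse = ", "))
    if (!circular && any(features$end > n))
      stop("feature crosses the origin of a non-circular genome")
    # mark duplicated canonical labels (all copies after the longest)
    dup_lab <- stats::na.omit(unique(features$name[duplicated(features$name) &
                                                   !is.na(features$name)]))
    for (lab in dup_lab) {
      i <- which(features$name == lab & !features$duplicate)
      if (length(i) > 1L) {
        keep <- i[which.max(features$end[i] - features$start[i])]
        features$duplicate[setdiff(i, keep)] <- TRUE
      }
    }
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
    ov <- overlap_matrix(features, n)
    if (any(ov > max_overlap))
      warning(sum(ov > max_overlap), " feature pair(s) overlap by more than ",
              max_overlap, " bp in ", id)
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 length = n, features = features,
                 completeness = completeness),
            class = "mito_genome")
}

# pairwise overlaps between consecutive primary features (bp)
overlap_matrix <- function(features, n) {
  f <- features[!features$duplicate & !is.na(features$name), , drop = FALSE]
  if (nrow(f) < 2L) return(integer(0))
  f <- f[order(f$start), , drop = FALSE]
  ov <- pmax(0L, f$end[-nrow(f)] - f$start[-1L])
  # wrap-around pair
  wrap <- pmax(0L, f$end[nrow(f)] - n - f$start[1L])
  c(ov, wrap)
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %s bp, %s, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", x$completeness))
  f <- x$features
  cat(sprintf("  %d features (%d PCG, %d tRNA, %d rRNA, %d CR, %d unmapped)\n",
              nrow(f), sum(f$kind == "PCG", na.rm = TRUE),
              sum(f$kind == "tRNA", na.rm = TRUE),
              sum(f$kind == "rRNA", na.rm = TRUE),
              sum(f$kind == "control_region", na.rm = TRUE),
              sum(is.na(f$name))))
  invisible(x)
}

#' @export
summary.mito_genome <- function(object, ...) {
  print(object)
  print(utils::head(object$features, 40L))
  invisible(object)
}

#' Extract the oriented sequence of an annotated gene
#'
#' @param g a [mito_genome].
#' @param name canonical gene label.
#' @param orientation `"sense"` (reading strand of the gene) or `"plus"`
#'   (plus-strand image of the span).
#' @return a DNA string.
#' @export
gene_seq <- function(g, name, orientation = c("sense", "plus")) {
  orientation <- match.arg(orientation)
  f <- g$features
  i <- which(f$name == name & !f$duplicate)
  if (!length(i)) stop("gene '", name, "' not annotated in ", g$id)
  i <- i[1L]
  s <- circ_substr(g$sequence, f$start[i], f$end[i])
  if (orientation == "sense" && f$strand[i] == "-") s <- revcomp(s)
  s
}

## ---------------------------------------------------------------------------
## Gene-name normalization

.make_alias_table <- function() {
  al <- new.env(parent = emptyenv())
  put <- function(keys, val) for (k in keys) assign(k, val, envir = al)
  num <- function(stem, n, val) {
    rom <- c("I", "II", "III", "IV", "V", "VI")
    put(paste0(stem, n), val); put(paste0(stem, rom[n]), val)
  }
  for (k in 1:3) {
    v <- paste0("cox", k)
    num("CO", k, v); num("COX", k, v)
    num("CYTOCHROMECOXIDASESUBUNIT", k, v)
    num("CYTOCHROMEOXIDASESUBUNIT", k, v)
  }
  put(c("COB", "CYTB", "CYB", "CYTOCHROMEB", "CYTOCHROMEBAPOENZYME"), "cob")
  for (k in 1:6) {
    v <- paste0("nad", k)
    num("ND", k, v); num("NAD", k, v); num("NADH", k, v)
    num("NADHDEHYDROGENASESUBUNIT", k, v)
  }
  put(c("ND4L", "NAD4L", "NADH4L", "NADHDEHYDROGENASESUBUNIT4L"), "nad4l")
  put(c("ATP6", "ATPASE6", "ATPSYNTHASEF0SUBUNIT6", "ATPSYNTHASESUBUNIT6"),
      "atp6")
  put(c("ATP8", "ATPASE8", "ATPSYNTHASEF0SUBUNIT8", "ATPSYNTHASESUBUNIT8"),
      "atp8")
  put(c("RRNL", "LRRNA", "16S", "16SRRNA", "16SRIBOSOMALRNA",
        "LARGESUBUNITRIBOSOMALRNA", "LSURRNA"), "rrnL")
  put(c("RRNS", "SRRNA", "12S", "12SRRNA", "12SRIBOSOMALRNA",
        "SMALLSUBUNITRIBOSOMALRNA", "SSURRNA"), "rrnS")
  put(c("CR", "DLOOP", "ATRICHREGION", "ATRICH", "CONTROLREGION",
        "PUTATIVECONTROLREGION"), "CR")
  # direct canonical spellings
  for (v in .ALL_LABELS) put(toupper(v), v)
  al
}
.ALIASES <- .make_alias_table()

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

#' Map a free-text gene or product name to its canonical label
#'
#' Case- and punctuation-insensitive: `"COI"` and `"cytochrome oxidase
#' subunit 1"` both map to `cox1`, `"CYTB"` to `cob`, `"l-rRNA"` to `rrnL`,
#' `"D-loop"` and `"A+T-rich region"` to `CR`. tRNA isoacceptors are
#' disambiguated by their codon family: Leu(CUN) is `trnL1`, Leu(UUR)
#' `trnL2`, Ser(AGY) `trnS1`, Ser(UCN) `trnS2`. A total function: anything
#' unrecognized returns the sentinel `"unmapped"`.
#'
#' @param raw character vector of free-text names.
#' @return character vector of canonical labels or `"unmapped"`.
#' @export
normalize_gene_name <- function(raw) {
  vapply(as.character(raw), normalize_one_name, "", USE.NAMES = FALSE)
}

normalize_one_name <- function(raw) {
  if (is.na(raw) || !nzchar(raw)) return("unmapped")
  up <- toupper(raw)
  clean <- gsub("[^A-Z0-9]", "", up)
  hit <- mget(clean, envir = .ALIASES, ifnotfound = list(NULL))[[1L]]
  if (!is.null(hit)) return(hit)
  # tRNA forms: tRNA-Leu(UUR), trnL2, trnS(UCN), transfer RNA serine ...
  if (grepl("^(TRNA?|TRANSFERRNA)", clean)) {
    body <- sub("^(TRNA|TRN|TRANSFERRNA)", "", clean)
    fam <- regmatches(up, regexpr("(CUN|UUR|AGY|UCN|CTN|TTR|AGT|TCN)", up))
    aa <- NA_character_
    aa3 <- regmatches(body, regexpr(paste(names(.AA3), collapse = "|"), body))
    if (length(aa3)) aa <- .AA3[[aa3]]
    else if (grepl("^[A-Z][0-9]?", body) && nzchar(body))
      aa <- substr(body, 1L, 1L)
    if (length(fam)) {
      fam <- chartr("T", "U", fam)   # CTN -> CUN etc.
      key <- switch(fam, CUN = "trnL1", UUR = "trnL2",
                    AGY = "trnS1", UCN = "trnS2", NULL)
      if (!is.null(key)) return(key)
    }
    if (!is.na(aa)) {
      if (grepl(paste0("^", substr(body, 1L, 1L), "?(L1|L2|S1|S2)"), body)) {
        iso <- regmatches(body, regexpr("(L1|L2|S1|S2)", body))
        return(paste0("trn", iso))
      }
      if (aa %in% c("L", "S")) return("unmapped")  # ambiguous isoacceptor
      cand <- paste0("trn", aa)
      if (cand %in% .TRNA_LABELS) return(cand)
    }
  }
  "unmapped"
}

## ---------------------------------------------------------------------------
## GenBank flat-file reader

#' Read an annotated mitochondrial genome from a GenBank flat file
#'
#' Parses LOCUS, FEATURES and ORIGIN, converts coordinates from 1-based
#' inclusive to the package's 0-based half-open convention, merges
#' `join(...)` locations that cross the origin of a circular molecule into a
#' single wrapping feature, and maps gene/product qualifiers to canonical
#' labels via [normalize_gene_name()]. Features whose qualifiers match no
#' canonical label are retained with `name = NA` and a collected warning.
#'
#' @param path path to a GenBank flat file (single record).
#' @param quiet suppress the unmapped-feature warning.
#' @return a [mito_genome].
#' @export
read_genbank <- function(path, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1L]), "[[:space:]]+")[[1L]]
  id <- toks[2L]
  circular <- any(grepl("circular", locus[1L], ignore.case = TRUE))
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("GenBank record has no ORIGIN sequence: ", path)
  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  n <- nchar(sequence)

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
    # a new feature starts at column 6 with a key
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    for (j in seq_along(idx)) {
      from <- idx[j]
      to <- if (j < length(idx)) idx[j + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1L])
      if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature", "gene"))
        next
      loc <- sub("^ {5}\\S+\\s+", "", chunk[1L])
      qual_at <- grep("^\\s+/", chunk)
      if (length(qual_at) && qual_at[1L] > 2L)
        loc <- paste0(loc, paste(trimws(chunk[2:(qual_at[1L] - 1L)]),
                                 collapse = ""))
      quals <- parse_qualifiers(chunk)
      feats[[length(feats) + 1L]] <-
        c(list(key = key, loc = loc), quals)
    }
  }
  ft <- build_feature_table(feats, n, circular, id, quiet = quiet)
  completeness <- if (all(canonical_labels() %in% ft$name)) "complete"
                  else "partial"
  mito_genome(id, sequence, ft, circular = circular,
              completeness = completeness)
}

parse_qualifiers <- function(chunk) {
  txt <- paste(trimws(chunk[-1L]), collapse = "\n")
  starts <- gregexpr("(^|\n)/", txt)[[1L]]
  if (starts[1L] == -1L) return(list())
  pieces <- strsplit(txt, "(^|\n)/")[[1L]]
  pieces <- pieces[nzchar(pieces)]
  out <- list()
  for (p in pieces) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq == -1L) { out[[p]] <- TRUE; next }
    k <- substr(p, 1L, eq - 1L)
    v <- substr(p, eq + 1L, nchar(p))
    v <- gsub("\n", " ", v)
    v <- gsub("^\"|\"$", "", v)
    out[[k]] <- v
  }
  out
}

# parse a GenBank location string into (start, end, strand) 0-based half-open
parse_location <- function(loc, n, circular) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    segs <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    iv <- t(vapply(segs, parse_span, integer(2L)))
    # contiguous around the origin of a circular molecule?
    if (circular && nrow(iv) == 2L && iv[1L, 2L] == n && iv[2L, 1L] == 0L)
      return(list(start = iv[1L, 1L], end = n + iv[2L, 2L], strand = strand))
    return(list(start = min(iv[, 1L]), end = max(iv[, 2L]), strand = strand))
  }
  iv <- parse_span(loc)
  list(start = iv[1L], end = iv[2L], strand = strand)
}

parse_span <- function(s) {
  s <- trimws(s)
  if (grepl("\\.\\.", s)) {
    ab <- as.integer(strsplit(s, "..", fixed = TRUE)[[1L]])
    c(ab[1L] - 1L, ab[2L])
  } else {
    p <- as.integer(s)
    c(p - 1L, p)
  }
}

build_feature_table <- function(feats, n, circular, id, quiet = FALSE) {
  empty <- data.frame(name = character(), raw_name = character(),
                      start = integer(), end = integer(),
                      strand = character(), kind = character(),
                      anticodon = character(), duplicate = logical(),
                      stringsAsFactors = FALSE)
  if (!length(feats)) return(empty)
  rows <- lapply(feats, function(f) {
    pos <- parse_location(f$loc, n, circular)
    raw <- f$gene %||% f$product %||% f$note %||% NA_character_
    name <- normalize_one_name(raw %||% NA_character_)
    kind <- switch(f$key,
                   CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   `D-loop` = "control_region",
                   misc_feature = if (identical(name, "CR")) "control_region"
                                  else NA_character_,
                   gene = NA_character_)
    if (f$key == "D-loop") name <- "CR"
    anticodon <- NA_character_
    if (!is.null(f$anticodon)) {
      m <- regmatches(f$anticodon,
                      regexpr("seq:([acgtuACGTU]{3})", f$anticodon))
      if (length(m)) anticodon <- toupper(chartr("Uu", "Tt", sub("seq:", "", m)))
      else if (grepl("^[acgtuACGTU]{3}$", f$anticodon))
        anticodon <- toupper(chartr("Uu", "Tt", f$anticodon))
    }
    data.frame(name = if (name == "unmapped") NA_character_ else name,
               raw_name = raw %||% NA_character_,
               start = pos$start, end = pos$end, strand = pos$strand,
               kind = kind, anticodon = anticodon,
               key = f$key, duplicate = FALSE, stringsAsFactors = FALSE)
  })
  ft <- do.call(rbind, rows)
  # 'gene' keys only fill gaps left by typed features
  typed <- ft[ft$key != "gene", , drop = FALSE]
  genes <- ft[ft$key == "gene", , drop = FALSE]
  keep_gene <- genes[!is.na(genes$name) & !genes$name %in% typed$name, ,
                     drop = FALSE]
  if (nrow(keep_gene)) {
    keep_gene$kind <- label_kind(keep_gene$name)
    typed <- rbind(typed, keep_gene)
  }
  unmapped <- typed$raw_name[is.na(typed$name) & !is.na(typed$raw_name)]
  typed <- typed[!(is.na(typed$name) & is.na(typed$kind)), , drop = FALSE]
  if (length(unmapped) && !quiet)
    warning("unmapped feature name(s) in ", id, ": ",
            paste(unique(unmapped), collapse = ", "))
  typed$key <- NULL
  rownames(typed) <- NULL
  typed
}

## ---------------------------------------------------------------------------
## Alternative plain-text input: FASTA + feature table

#' Read a genome from FASTA plus a tab-separated feature table
#'
#' The feature table has columns `gene`, `start`, `end`, `strand`, `kind`
#' with coordinates 0-based half-open on the plus strand (the package's
#' internal convention).
#'
#' @param fasta path to a single-sequence FASTA file.
#' @param table path to the TSV feature table.
#' @param circular logical.
#' @return a [mito_genome].
#' @export
read_genome_table <- function(fasta, table, circular = TRUE) {
  lines <- readLines(fasta, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) != 1L) stop("expected exactly one FASTA record in ", fasta)
  id <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  sequence <- toupper(paste(lines[-hdr], collapse = ""))
  tb <- utils::read.delim(table, stringsAsFactors = FALSE)
  names(tb)[names(tb) == "gene"] <- "name"
  tb$name <- normalize_gene_name(tb$name)
  tb$name[tb$name == "unmapped"] <- NA_character_
  if (is.null(tb$kind)) tb$kind <- label_kind(tb$name)
  completeness <- if (all(canonical_labels() %in% tb$name)) "complete"
                  else "partial"
  mito_genome(id, sequence, tb, circular = circular,
              completeness = completeness)
}

#' Write the normalized feature table as TSV
#'
#' @param g a [mito_genome].
#' @param path output file.
#' @export
write_feature_table <- function(g, path) {
  utils::write.table(g$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## GenBank writer (round-trip partner of read_genbank)

#' Write a genome as a GenBank flat file
#'
#' Coordinates are converted back to 1-based inclusive; features wrapping
#' the origin are emitted as `join(a..n,1..b)`.
#'
#' @param g a [mito_genome].
#' @param path output file.
#' @export
write_genbank <- function(g, path) {
  n <- g$length
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                   g$id, n, if (g$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s mitochondrion.", g$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  f <- g$features
  for (i in seq_len(nrow(f))) {
    loc <- if (f$end[i] <= n)
      sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    else
      sprintf("join(%d..%d,1..%d)", f$start[i] + 1L, n, f$end[i] - n)
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    key <- switch(f$kind[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "D-loop", "misc_feature")
    lab <- if (is.na(f$name[i])) f$raw_name[i] else f$name[i]
    out <- c(out, sprintf("     %-15s %s", key, loc),
             sprintf("                     /gene=\"%s\"", lab))
    if (!is.na(f$anticodon[i]))
      out <- c(out, sprintf("                     /anticodon=\"(seq:%s)\"",
                            tolower(f$anticodon[i])))
    if (isTRUE(f$duplicate[i]))
      out <- c(out, "                     /note=\"duplicated copy\"")
  }
  out <- c(out, "ORIGIN")
  s <- tolower(g$sequence)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", off, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Validation

#' Validate an annotated genome against mitochondrial conventions
#'
#' Report-only checks: missing and duplicated canonical genes; protein-coding
#' genes whose first codon is not `ATN` or whose terminal codon is not a
#' complete `TAA` or a truncated `TA`/`T` stop; tRNA anticodon anomalies
#' (`trnK` is expected to use `TTT` and `trnS2` `TCT`), checked only when
#' anticodon metadata is present.
#'
#' @param g a [mito_genome].
#' @return a `validation_report` list with elements `id`, `missing`,
#'   `duplicated`, `codon_anomalies` (data.frame), `anticodon_anomalies`
#'   (data.frame), `unmapped`.
#' @export
validate_genome <- function(g) {
  f <- g$features
  present <- unique(stats::na.omit(f$name[!f$duplicate]))
  missing <- setdiff(canonical_labels(), present)
  dups <- unique(f$name[f$duplicate & !is.na(f$name)])
  codon <- data.frame(gene = character(), start_codon = character(),
                      stop_codon = character(), stringsAsFactors = FALSE)
  expected_anti <- c(trnK = "TTT", trnS2 = "TCT")
  anti <- data.frame(tRNA = character(), observed = character(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(f))) {
    if (f$duplicate[i] || is.na(f$name[i])) next
    if (identical(f$kind[i], "PCG")) {
      s <- gene_seq(g, f$name[i])
      first <- substr(s, 1L, 3L)
      rem <- nchar(s) %% 3L
      last <- substr(s, nchar(s) - (if (rem == 0L) 2L else rem - 1L), nchar(s))
      ok_start <- grepl("^AT[ACGT]$", first)
      ok_stop <- last %in% c("TAA", "TA", "T")
      if (!ok_start || !ok_stop)
        codon <- rbind(codon, data.frame(gene = f$name[i], start_codon = first,
                                         stop_codon = last,
                                         stringsAsFactors = FALSE))
    }
    if (identical(f$kind[i], "tRNA") && f$name[i] %in% names(expected_anti) &&
        !is.na(f$anticodon[i]) &&
        f$anticodon[i] != expected_anti[[f$name[i]]])
      anti <- rbind(anti, data.frame(tRNA = f$name[i],
                                     observed = f$anticodon[i],
                                     stringsAsFactors = FALSE))
  }
  structure(list(id = g$id, missing = missing, duplicated = dups,
                 codon_anomalies = codon, anticodon_anomalies = anti,
                 unmapped = unique(f$raw_name[is.na(f$name)])),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s\n", x$id))
  cat("  missing genes:   ",
      if (length(x$missing)) paste(x$missing, collapse = ", ") else "none",
      "\n")
  cat("  duplicated:      ",
      if (length(x$duplicated)) paste(x$duplicated, collapse = ", ")
      else "none", "\n")
  cat("  codon anomalies: ", nrow(x$codon_anomalies), "\n")
  cat("  anticodon anomalies:", nrow(x$anticodon_anomalies), "\n")
  invisible(x)
}
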