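# The ancestral (plesiomorphic) hexapod mitochondrial gene arrangement: the
# pancrustacean ground plan shared by e.g. Drosophila and the symphytan
# Hymenoptera, used as the comparison baseline for rearrangement analysis.

.PCG_LABELS  <- c("cox1", "cox2", "cox3", "cob", "nad1", "nad2", "nad3",
                  "nad4", "nad4l", "nad5", "nad6", "atp6", "atp8")
.TRNA_LABELS <- c("trnI", "trnQ", "trnM", "trnW", "trnC", "trnY", "trnL2",
                  "trnK", "trnD", "trnG", "trnA", "trnR", "trnN", "trnS1",
                  "trnE", "trnF", "trnH", "trnT", "trnP", "trnS2", "trnL1",
                  "trnV")
.RRNA_LABELS <- c("rrnL", "rrnS")
.ALL_LABELS  <- c(.PCG_LABELS, .TRNA_LABELS, .RRNA_LABELS, "CR")

.ANCESTRAL_GENES <- c("trnI",  "trnQ",  "trnM",  "nad2",  "trnW",  "trnC",
                      "trnY",  "cox1",  "trnL2", "cox2",  "trnK",  "trnD",
                      "atp8",  "atp6",  "cox3",  "trnG",  "nad3",  "trnA",
                      "trnR",  "trnN",  "trnS1", "trnE",  "trnF",  "nad5",
                      "trnH",  "nad4",  "nad4l", "trnT",  "trnP",  "nad6",
                      "cob",   "trnS2", "nad1",  "trnL1", "rrnL",  "trnV",
                      "rrnS",  "CR")
.ANCESTRAL_SIGNS <- c(+1L, -1L, +1L, +1L, +1L, -1L,
                      -1L, +1L, +1L, +1L, +1L, +1L,
                      +1L, +1L, +1L, +1L, +1L, +1L,
                      +1L, +1L, +1L, +1L, -1L, -1L,
                      -1L, -1L, -1L, +1L, -1L, +1L,
                      +1L, +1L, -1L, -1L, -1L, -1L,
                      -1L, +1L)

#' Canonical gene labels
#'
#' The closed set of 38 canonical labels for insect mitochondrial genes:
#' 13 protein-coding genes, 22 tRNAs (with `trnL1` = Leu(CUN), `trnL2` =
#' Leu(UUR), `trnS1` = Ser(AGY), `trnS2` = Ser(UCN)), two rRNAs, and the
#' A+T-rich control region `CR`.
#'
#' @param kind optionally restrict to one of `"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"control_region"`.
#' @return character vector of canonical labels.
#' @export
canonical_labels <- function(kind = NULL) {
  if (is.null(kind)) return(.ALL_LABELS)
  switch(match.arg(kind, c("PCG", "tRNA", "rRNA", "control_region")),
         PCG = .PCG_LABELS, tRNA = .TRNA_LABELS, rRNA = .RRNA_LABELS,
         control_region = "CR")
}

# kind of a canonical label
label_kind <- function(label) {
  ifelse(label %in% .PCG_LABELS, "PCG",
    ifelse(label %in% .TRNA_LABELS, "tRNA",
      ifelse(label %in% .RRNA_LABELS, "rRNA",
        ifelse(label == "CR", "control_region", NA_character_))))
}

#' Ancestral hexapod gene order
#'
#' The signed circular gene order of the ancestral insect mitochondrial
#' genome (37 genes plus the control region), written from `trnI` with
#' majority-strand genes as `+1`. This is the baseline every observed order
#' is classified against.
#'
#' @return a [gene_order] object (anchored at `cox1`, sign `+`).
#' @export
ancestral_order <- function() {
  new_gene_order(.ANCESTRAL_GENES, .ANCESTRAL_SIGNS, id = "ancestral")
}
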