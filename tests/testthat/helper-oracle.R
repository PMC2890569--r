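# brute-force pathway oracle, written independently of the package's
# codon machinery: walks every ordering of the differing positions as an
# explicit codon path, discards paths through stops, averages per path
ng_oracle <- function(a, b) {
  code <- Biostrings::getGeneticCode("5")
  pa <- strsplit(a, "")[[1]]
  pb <- strsplit(b, "")[[1]]
  dp <- which(pa != pb)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  orderings <- if (length(dp) == 1) list(dp) else {
    perms <- as.matrix(expand.grid(rep(list(dp), length(dp))))
    perms <- perms[apply(perms, 1, function(r) !anyDuplicated(r)), ,
                   drop = FALSE]
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  }
  sd <- nd <- numeric(0)
  for (ord in orderings) {
    cur <- pa
    s <- n <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- pb[pos]
      if (code[[paste(nxt, collapse = "")]] == "*") { ok <- FALSE; break }
      if (code[[paste(cur, collapse = "")]] ==
            code[[paste(nxt, collapse = "")]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { sd <- c(sd, s); nd <- c(nd, n) }
  }
  if (!length(sd)) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = mean(sd), nd = mean(nd))
}

# site oracle: enumerate the nine single-base changes directly
sites_oracle <- function(codon) {
  code <- Biostrings::getGeneticCode("5")
  b <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; sense <- 0
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      b2 <- b; b2[pos] <- alt
      c2 <- paste(b2, collapse = "")
      if (code[[c2]] == "*") next
      sense <- sense + 1
      if (code[[c2]] == code[[codon]]) syn <- syn + 1
    }
    if (sense > 0) s <- s + syn / sense
  }
  s
}

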