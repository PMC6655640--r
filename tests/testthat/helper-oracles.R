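# Independent oracles used by the tests. These are deliberately separate
# implementations: a hand-transcribed codon map, a direct six-frame ORF
# enumerator, a Gotoh affine-gap aligner with co-optimal enumeration, and
# brute-force motif scans.

# NCBI standard genetic code, transcribed by hand (not taken from the package
# or from Biostrings)
oracle_codon_map <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(nt, mito = FALSE) {
  map <- oracle_codon_map
  if (mito) map["TGA"] <- "W"
  n <- nchar(nt)
  cods <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  aa <- map[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(nt, "")[[1]]]), collapse = "")
}

# direct six-frame enumerator with the same ORF definition as the package:
# one ORF per stop-bounded region, from the 5'-most ATG (or region start)
oracle_orfs <- function(nt, mito = FALSE, min_aa = 1L, require_start = TRUE) {
  map <- oracle_codon_map
  if (mito) map["TGA"] <- "W"
  L <- nchar(nt)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nt else oracle_revcomp(nt)
    for (fr in 0:2) {
      nc <- (L - fr) %/% 3
      if (nc < 1) next
      cods <- substring(s, fr + 1 + 3 * (seq_len(nc) - 1), fr + 3 * seq_len(nc))
      aa <- map[cods]; aa[is.na(aa)] <- "X"
      stops <- which(aa == "*")
      r0s <- c(1, stops + 1); r1s <- c(stops, nc)
      for (k in seq_along(r0s)) {
        r0 <- r0s[k]; r1 <- r1s[k]
        has_stop <- k <= length(stops)
        lastc <- if (has_stop) r1 - 1 else r1
        if (lastc < r0) next
        if (require_start) {
          m <- which(cods[r0:lastc] == "ATG")
          if (length(m) == 0) next
          c0 <- r0 + m[1] - 1
        } else c0 <- r0
        prot <- paste(aa[c0:lastc], collapse = "")
        if (nchar(prot) < min_aa) next
        c1 <- if (has_stop) r1 else lastc
        a <- fr + 3 * (c0 - 1); b <- fr + 3 * c1
        if (strand == "-") { tmp <- L - b; b <- L - a; a <- tmp }
        out[[length(out) + 1]] <- data.frame(
          start = a, end = b, strand = strand, frame = fr, aa = prot,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      aa = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(-nchar(df$aa), df$start, df$strand), , drop = FALSE]
}

# Gotoh global affine aligner matching the gapOpening + L*gapExtension
# convention; enumerates identities of all co-optimal alignments (capped)
oracle_global_identities <- function(a, b, submat, gap_open, gap_ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + gap_ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + gap_ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- submat[A[i], B[j]]
    M[i + 1, j + 1] <- sc + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                           X[i, j + 1] - gap_ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                           Y[i + 1, j] - gap_ext)
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  idents <- new.env(); idents$v <- numeric(0); idents$count <- 0
  eps <- 1e-6
  # traceback enumerating co-optimal alignments (capped at 200)
  walk2 <- function(i, j, state, match_cols, total_cols) {
    if (idents$count > 200) return()
    if (state == "X" && j == 0) {
      # remaining prefix of A aligned to gaps
      idents$count <- idents$count + 1
      idents$v <- c(idents$v, 100 * match_cols / total_cols)
      return()
    }
    if (state == "Y" && i == 0) {
      idents$count <- idents$count + 1
      idents$v <- c(idents$v, 100 * match_cols / total_cols)
      return()
    }
    if (i == 0 && j == 0 && state == "M") {
      idents$count <- idents$count + 1
      idents$v <- c(idents$v, 100 * match_cols / total_cols)
      return()
    }
    if (state == "M") {
      if (i > 0 && j > 0) {
        sc <- submat[A[i], B[j]]
        for (prev in c("M", "X", "Y")) {
          pm <- switch(prev, M = M[i, j], X = X[i, j], Y = Y[i, j])
          if (pm > NEG / 2 && abs(M[i + 1, j + 1] - (sc + pm)) < eps)
            walk2(i - 1, j - 1, prev,
                  match_cols + (A[i] == B[j]), total_cols + 1)
        }
      }
    } else if (state == "X") {
      if (i > 0) {
        if (M[i, j + 1] > NEG / 2 &&
            abs(X[i + 1, j + 1] - (M[i, j + 1] - gap_open - gap_ext)) < eps)
          walk2(i - 1, j, "M", match_cols, total_cols)
        if (X[i, j + 1] > NEG / 2 &&
            abs(X[i + 1, j + 1] - (X[i, j + 1] - gap_ext)) < eps)
          walk2(i - 1, j, "X", match_cols, total_cols)
      }
    } else {
      if (j > 0) {
        if (M[i + 1, j] > NEG / 2 &&
            abs(Y[i + 1, j + 1] - (M[i + 1, j] - gap_open - gap_ext)) < eps)
          walk2(i, j - 1, "M", match_cols, total_cols)
        if (Y[i + 1, j] > NEG / 2 &&
            abs(Y[i + 1, j + 1] - (Y[i + 1, j] - gap_ext)) < eps)
          walk2(i, j - 1, "Y", match_cols, total_cols)
      }
    }
  }
  for (state in c("M", "X", "Y")) {
    v <- switch(state, M = M[n + 1, m + 1], X = X[n + 1, m + 1],
                Y = Y[n + 1, m + 1])
    if (abs(v - best) < eps) walk2(n, m, state, 0, 0)
  }
  list(score = best, identities = unique(round(idents$v, 6)))
}

# brute-force slippery heptamer scan (plain loop, no regex machinery)
oracle_slippery <- function(nt, from0, to0) {
  ch <- strsplit(nt, "")[[1]]
  pos <- integer(0)
  p <- from0
  while (p + 7 <= to0) {
    h <- ch[(p + 1):(p + 7)]
    if (h[1] == h[2] && h[2] == h[3] && h[4] == h[5] && h[5] == h[6])
      pos <- c(pos, p)
    p <- p + 1
  }
  as.integer(pos)
}

# brute-force degenerate motif scan via hand-transcribed IUPAC sets
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_motif_scan <- function(nt, pattern) {
  sc <- strsplit(nt, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(sc); k <- length(pc)
  hits <- integer(0)
  if (L < k) return(hits)
  for (p in 0:(L - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(sc[p + j] %in% oracle_iupac_sets[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# exhaustive in-order non-overlapping placement of <= 2 PSSM blocks
oracle_block_chain <- function(aa, model) {
  ch <- strsplit(toupper(aa), "")[[1]]
  idx_score <- function(pssm, start) {
    s <- 0
    for (j in seq_len(ncol(pssm))) {
      r <- ch[start + j - 1]
      if (!(r %in% rownames(pssm))) r <- "X"
      s <- s + pssm[r, j]
    }
    s
  }
  n <- length(ch)
  B <- length(model$blocks)
  stopifnot(B <= 2)
  l1 <- ncol(model$blocks[[1]]$pssm)
  best <- -Inf; bs <- NULL
  if (B == 1) {
    for (i in seq_len(n - l1 + 1)) {
      s <- idx_score(model$blocks[[1]]$pssm, i)
      if (s > best) { best <- s; bs <- c(i) }
    }
  } else {
    l2 <- ncol(model$blocks[[2]]$pssm)
    for (i in seq_len(n - l1 + 1)) {
      s1 <- idx_score(model$blocks[[1]]$pssm, i)
      for (j in seq(i + l1, n - l2 + 1)) {
        s <- s1 + idx_score(model$blocks[[2]]$pssm, j)
        if (s > best) { best <- s; bs <- c(i, j) }
      }
    }
  }
  list(score = unname(best), starts = bs)
}

# shared test utilities -------------------------------------------------------

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# forward-strand primary gene models of a segment, mirroring the
# characterization stage's spurious-ORF filter
primary_fwd_orfs <- function(seg, codon_table = "standard") {
  orfs <- find_orfs(seg, codon_table, min_len_aa = 100L)
  fwd <- orfs[orfs$strand == "+", , drop = FALSE]
  fwd <- fwd[order(fwd$end), , drop = FALSE]
  if (nrow(fwd) > 0L)
    fwd <- fwd[nchar(fwd$aa) >= 0.3 * max(nchar(fwd$aa)), , drop = FALSE]
  fwd
}
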