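# Family-diagnostic feature detectors: translational recoding signals,
# UTR conservation, read coverage, and read-based contig extension/stitching.

seq_chars <- function(seq) strsplit(as_nuc_seq(seq)$residues, "", fixed = TRUE)[[1]]

#' Find -1 ribosomal frameshift slippery sites
#'
#' Scans a window for heptamers of the form X XXY YYZ (three identical bases,
#' three identical bases, any base). Homopolymer heptamers (X equal to Y) are
#' admitted and flagged as low complexity.
#'
#' @param seq A `nuc_seq` or character scalar.
#' @param window Integer vector `c(start, end)`, 0-based half-open; default
#'   the whole sequence.
#' @return data.frame with `position` (0-based heptamer start), `heptamer`,
#'   `x`, `y`, `z`, `low_complexity`, in ascending position.
#' @export
find_slippery_sites <- function(seq, window = NULL) {
  seq <- as_nuc_seq(seq)
  if (is.null(window)) window <- c(0L, seq$length)
  if (window[1] < 0L || window[2] > seq$length || window[1] > window[2])
    mv_stop("WindowOutOfBounds", "window [%d,%d) outside sequence of %d nt",
            window[1], window[2], seq$length)
  ch <- seq_chars(seq)
  out <- list()
  if (window[2] - window[1] >= 7L) {
    for (p in seq(window[1], window[2] - 7L)) {
      h <- ch[(p + 1L):(p + 7L)]
      if (h[1] == h[2] && h[2] == h[3] && h[4] == h[5] && h[5] == h[6]) {
        out[[length(out) + 1L]] <- data.frame(
          position = as.integer(p), heptamer = paste(h, collapse = ""),
          x = h[1], y = h[4], z = h[7], low_complexity = h[1] == h[4],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(position = integer(), heptamer = character(),
                      x = character(), y = character(), z = character(),
                      low_complexity = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify the stop/start junction between two ORFs
#'
#' Recognizes the termination-reinitiation geometries of victorivirus-like
#' genomes: the AUGA tetramer (ORF2 start overlapping the first two bases of
#' the ORF1 stop, -1 frame), one-base stop/start overlaps such as UGAUG or
#' UAAUG (-1 frame), and a start codon slightly preceding the stop with a
#' short spacer (+1 frame). ORF2 starts further than 10 nt from the ORF1 stop
#' are treated as independent ORFs (NULL).
#'
#' @param orf1,orf2 Single rows of a [find_orfs()] data.frame, ORF1 upstream
#'   of ORF2, both on the + strand.
#' @param seq The `nuc_seq` both ORFs were called on.
#' @return List of class `junction_motif` (`kind`, `orf1_stop_pos`,
#'   `orf2_start_pos`, `frame_shift`, `junction_string`) or NULL.
#' @export
find_junction <- function(orf1, orf2, seq) {
  seq <- as_nuc_seq(seq)
  if (orf1$strand != "+" || orf2$strand != "+" || orf2$end < orf1$end)
    mv_stop("OrfOrderViolation",
            "orf1 must precede orf2 on the + strand")
  stop_start <- orf1$end - 3L            # 0-based start of the stop codon
  sub <- function(a, b) substr(seq$residues, a + 1L, b)  # 0-based half-open
  # candidate ORF2 starts: the called start plus any in-frame ATG inside the
  # junction window (ORF calls extended upstream of the reinitiation codon
  # would otherwise hide the geometry)
  cands <- orf2$start
  for (p in seq(max(0L, stop_start - 8L), min(seq$length - 3L, stop_start + 2L))) {
    if ((p - orf2$start) %% 3L == 0L && sub(p, p + 3L) == "ATG")
      cands <- c(cands, p)
  }
  cands <- sort(unique(cands))
  for (p in cands) {
    delta <- p - stop_start
    if (abs(delta) > 10L) next
    frame_diff <- ((p - orf1$start) %% 3L)
    jct <- function(kind, shift, a, b) {
      structure(list(kind = kind, orf1_stop_pos = stop_start,
                     orf2_start_pos = p, frame_shift = shift,
                     junction_string = sub(a, b)),
                class = "junction_motif")
    }
    if (delta == -1L && frame_diff == 2L && sub(p, p + 3L) == "ATG") {
      # ATG overlapping the stop's first two bases: ...ATGA...
      return(jct("tetramer_AUGA", -1L, p, orf1$end))
    }
    if (delta == 2L && frame_diff == 2L && sub(p, p + 3L) == "ATG") {
      # stop's last base is the start's first base: TGATG / TAATG
      return(jct("pentamer_overlap", -1L, stop_start, p + 3L))
    }
    if (delta <= -4L && delta >= -8L && frame_diff == 1L &&
        sub(p, p + 3L) == "ATG") {
      # start codon precedes the stop with a short spacer, +1 frame
      return(jct("spaced", 1L, p, orf1$end))
    }
  }
  NULL
}

#' Detect amber stop-codon readthrough
#'
#' Flags a forward-strand ORF that terminates in TAG when coding continues in
#' the same frame to a second stop at least `min_len_aa` codons downstream
#' (the ambiguivirus ORF1-RdRP fusion arrangement).
#'
#' @param orfs [find_orfs()] data.frame for `seq` (forward strand rows used).
#' @param seq The `nuc_seq`.
#' @param min_len_aa Minimum downstream continuation, in codons (default 50).
#' @return List of class `readthrough_call` (`stop_codon`, `orf1_start`,
#'   `orf1_end`, `orf2_in_same_frame`, `fused_length_aa`) or NULL.
#' @export
find_readthrough <- function(orfs, seq, min_len_aa = 50L) {
  seq <- as_nuc_seq(seq)
  fwd <- orfs[orfs$strand == "+" & orfs$has_stop, , drop = FALSE]
  if (nrow(fwd) == 0L) return(NULL)
  fwd <- fwd[order(fwd$start), , drop = FALSE]
  code <- genetic_code_table("standard")
  for (i in seq_len(nrow(fwd))) {
    o <- fwd[i, ]
    stop_codon <- substr(seq$residues, o$end - 2L, o$end)
    if (stop_codon != "TAG") next
    # walk the same frame past the amber stop
    pos <- o$end          # 0-based start of the first codon after the stop
    n_cont <- 0L
    while (pos + 3L <= seq$length) {
      cod <- substr(seq$residues, pos + 1L, pos + 3L)
      aa <- code[cod]
      if (!is.na(aa) && aa == "*") break
      n_cont <- n_cont + 1L
      pos <- pos + 3L
    }
    if (n_cont >= min_len_aa) {
      fused <- (pos - o$start) %/% 3L - 1L  # ORF1 aa + readthrough aa + cont.
      return(structure(list(stop_codon = stop_codon, orf1_start = o$start,
                            orf1_end = o$end, orf2_in_same_frame = TRUE,
                            fused_length_aa = fused),
                       class = "readthrough_call"))
    }
  }
  NULL
}

#' Extract 5' and 3' UTRs around the annotated ORFs
#'
#' @param segment A `nuc_seq`.
#' @param orfs [find_orfs()] data.frame; forward-strand rows delimit the UTRs.
#' @return List with `utr5` and `utr3` (`nuc_seq`, possibly zero length:
#'   `residues = ""`).
#' @export
extract_utrs <- function(segment, orfs) {
  segment <- as_nuc_seq(segment)
  fwd <- orfs[orfs$strand == "+", , drop = FALSE]
  if (nrow(fwd) == 0L)
    mv_stop("NoForwardOrf", "no forward-strand ORF on '%s'", segment$id)
  a <- min(fwd$start)
  b <- max(fwd$end)
  mk <- function(res, tag) structure(
    list(id = paste0(segment$id, tag), residues = res, length = nchar(res)),
    class = "nuc_seq")
  list(utr5 = mk(substr(segment$residues, 1L, a), "_5utr"),
       utr3 = mk(substr(segment$residues, b + 1L, segment$length), "_3utr"))
}

iupac_code_for <- function(bases) {
  map <- Biostrings::IUPAC_CODE_MAP
  sets <- strsplit(map, "", fixed = TRUE)
  want <- sort(unique(bases))
  sizes <- vapply(sets, length, integer(1))
  ok <- vapply(sets, function(s) all(want %in% s), logical(1))
  names(map)[ok][which.min(sizes[ok])]
}

#' Find the most conserved gapless block shared by a set of UTRs
#'
#' Anchors on exact k-mers shared by every UTR and extends each anchor along
#' its diagonal to the maximum-sum interval of per-column conservation scored
#' against a softer per-column threshold; the block is reported when it
#' reaches `min_len` and its mean per-position conservation (fraction of
#' sequences agreeing with the modal base) reaches `min_conservation`.
#' Blocks without an exact shared anchor are never reported, which keeps
#' chance agreement between unrelated sequences from qualifying.
#'
#' @param utrs List of `nuc_seq` (at least 2, each at least `min_len` nt).
#' @param min_len Minimum block length (default 13).
#' @param min_conservation Minimum mean conservation (default 0.85, which
#'   admits a pairwise comparison of segments sharing a motif with a few
#'   degenerate positions).
#' @param anchor_k Exact k-mer length used for anchoring (default 6; capped
#'   at `min_len`).
#' @return List of class `utr_consensus` (`consensus` IUPAC string with
#'   below-threshold positions in lowercase, `conservation` per-position
#'   vector, `positions` 0-based block start per UTR, `length`) or NULL.
#' @export
conserved_utr_motif <- function(utrs, min_len = 13L, min_conservation = 0.85,
                                anchor_k = 6L) {
  utrs <- lapply(utrs, as_nuc_seq)
  if (length(utrs) < 2L) mv_stop("BadParameter", "need at least 2 UTRs")
  lens <- vapply(utrs, function(u) u$length, integer(1))
  if (any(lens < min_len)) return(NULL)
  mats <- lapply(utrs, seq_chars)
  n_seq <- length(utrs)
  k <- min(anchor_k, min_len)

  col_cons_at <- function(starts, off) {
    # conservation of the single column at offset `off` from block starts
    col <- vapply(seq_len(n_seq), function(s) mats[[s]][starts[s] + off],
                  character(1))
    max(table(col)) / n_seq
  }

  # grow a block around anchor `starts` (1-based, anchor length k): on the
  # anchored diagonal, score each column as conservation minus the threshold
  # and take the maximum-sum contiguous interval containing the anchor; the
  # interval's mean conservation is then guaranteed >= min_conservation and
  # its edges are conserved columns
  grow <- function(starts) {
    lo <- -(min(starts) - 1L)
    hi <- min(lens - starts) + 0L
    offs <- lo:hi
    v <- vapply(offs, function(o) col_cons_at(starts, o), numeric(1))
    # columns join at a softer per-column threshold (degenerate positions of
    # a real motif sit well below the block-level mean requirement); the
    # block as a whole must still clear min_conservation on average
    tau_grow <- max(0.5, 2 * min_conservation - 1)
    ex <- v - tau_grow
    ai <- which(offs == 0L)
    ae <- which(offs == k - 1L)
    # best interval containing the anchor, scored at the growth threshold,
    # subject to the block-level mean conservation requirement
    cs_ex <- cumsum(c(0, ex))
    cs_v <- cumsum(c(0, v))
    blk <- NULL
    for (a in seq(ai, 1L)) {
      for (b in seq(ae, length(offs))) {
        len <- b - a + 1L
        if (len < min_len) next
        if ((cs_v[b + 1L] - cs_v[a]) / len < min_conservation) next
        sc <- cs_ex[b + 1L] - cs_ex[a]
        if (is.null(blk) || sc > blk$sc) blk <- list(a = a, b = b, sc = sc)
      }
    }
    if (is.null(blk)) return(NULL)
    sel <- blk$a:blk$b
    list(starts = starts + offs[blk$a], len = length(sel), cons = v[sel],
         score = blk$sc)
  }

  kmers_of <- function(m) {
    n <- length(m) - k + 1L
    vapply(seq_len(n), function(i) paste(m[i:(i + k - 1L)], collapse = ""),
           character(1))
  }
  ref_kmers <- kmers_of(mats[[1]])
  other_kmers <- lapply(mats[-1], kmers_of)

  best <- NULL
  consider <- function(blk) {
    if (!is.null(blk) && (is.null(best) || blk$score > best$score))
      best <<- blk
  }
  # exact k-mer anchors shared by every UTR; a block without such an anchor
  # is not reported (guards against chance 'conservation' between unrelated
  # sequences)
  for (i in seq_along(ref_kmers)) {
    km <- ref_kmers[i]
    starts <- integer(n_seq); starts[1] <- i
    ok <- TRUE
    for (s in 2:n_seq) {
      j <- match(km, other_kmers[[s - 1L]])
      if (is.na(j)) { ok <- FALSE; break }
      starts[s] <- j
    }
    if (ok) consider(grow(starts))
  }
  if (is.null(best)) return(NULL)
  cols <- vapply(seq_len(best$len), function(p)
    vapply(seq_len(n_seq), function(s) mats[[s]][best$starts[s] + p - 1L],
           character(1)), character(n_seq))
  consensus <- vapply(seq_len(best$len), function(p) {
    code <- iupac_code_for(cols[, p])
    if (best$cons[p] >= min_conservation) code else tolower(code)
  }, character(1))
  structure(list(consensus = paste(consensus, collapse = ""),
                 conservation = best$cons,
                 positions = best$starts - 1L,
                 length = best$len),
            class = "utr_consensus")
}

#' Search for a degenerate (IUPAC) motif
#'
#' @param seq A `nuc_seq` or character scalar.
#' @param pattern IUPAC nucleotide pattern (e.g. `"TYTCATTARR"`).
#' @return Integer vector of 0-based match start positions (overlaps
#'   included).
#' @export
search_degenerate_motif <- function(seq, pattern) {
  seq <- as_nuc_seq(seq)
  if (!is.character(pattern) || nchar(pattern) == 0L)
    mv_stop("IllegalPatternCharacter", "pattern must be a non-empty string")
  pattern <- chartr("U", "T", toupper(pattern))
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(pc %in% IUPAC_NT))
    mv_stop("IllegalPatternCharacter", "illegal IUPAC code '%s' in pattern",
            pc[which(!(pc %in% IUPAC_NT))[1]])
  hits <- Biostrings::matchPattern(pattern,
                                   Biostrings::DNAString(seq$residues),
                                   fixed = FALSE)
  as.integer(IRanges::start(hits)) - 1L
}

#' Build a normalized per-base coverage track
#'
#' @param counts Non-negative integer vector of per-base read counts, one per
#'   genome position.
#' @param genome_length Expected genome length; defaults to `length(counts)`.
#' @param read_length Read length used to convert summed per-base hits into a
#'   total read count (optional).
#' @return List of class `coverage_track`: `counts`, `normalized` (counts
#'   divided by their maximum; all zero when no reads), `total_reads` (NA
#'   unless `read_length` given), `mean_coverage`.
#' @export
coverage_track <- function(counts, genome_length = length(counts),
                           read_length = NULL) {
  if (length(counts) != genome_length)
    mv_stop("LengthMismatch", "counts length %d != genome length %d",
            length(counts), genome_length)
  if (any(counts < 0)) mv_stop("BadParameter", "negative counts")
  mx <- max(counts)
  normalized <- if (mx > 0) counts / mx else counts * 0
  total_reads <- if (!is.null(read_length)) round(sum(counts) / read_length)
                 else NA_integer_
  structure(list(counts = counts, normalized = normalized,
                 total_reads = total_reads,
                 mean_coverage = mean(counts)),
            class = "coverage_track")
}

#' Read a two-column per-base coverage TSV (pos, count)
#'
#' Positions are 1-based in the file; missing positions get count 0.
#'
#' @param path TSV path.
#' @param genome_length Genome length (defaults to the maximum position).
#' @return Integer vector of per-base counts.
#' @export
read_coverage_tsv <- function(path, genome_length = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("pos", "count"))
  if (is.null(genome_length)) genome_length <- max(df$pos)
  counts <- integer(genome_length)
  counts[df$pos] <- df$count
  counts
}

#' Per-base coverage from a SAM file (minimal reader)
#'
#' Counts each reference base covered by an aligned read, consuming CIGAR
#' operations M, =, X (covered) and D (deleted; advances the reference
#' without counting). Secondary (0x100) and supplementary (0x800) alignments
#' are excluded.
#'
#' @param path SAM path.
#' @param genome_length Reference length.
#' @return Integer vector of per-base counts.
#' @export
read_sam_coverage <- function(path, genome_length) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- integer(genome_length)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) next
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x4) != 0L || bitwAnd(flag, 0x100) != 0L ||
        bitwAnd(flag, 0x800) != 0L) next
    pos <- as.integer(f[4])
    cigar <- f[6]
    if (cigar == "*") next
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    ref <- pos
    for (op in ops) {
      n <- as.integer(sub("[MIDNSHP=X]$", "", op))
      type <- substr(op, nchar(op), nchar(op))
      if (type %in% c("M", "=", "X")) {
        idx <- ref:(ref + n - 1L)
        idx <- idx[idx >= 1L & idx <= genome_length]
        counts[idx] <- counts[idx] + 1L
        ref <- ref + n
      } else if (type %in% c("D", "N")) {
        ref <- ref + n
      }
      # I, S, H, P consume no reference
    }
  }
  counts
}

# overlap length between suffix of `a` and prefix of `b` with <= max_mismatch
# mismatches, preferring the longest; returns 0 when none qualifies
best_overlap <- function(a, b, min_overlap, max_mismatch) {
  la <- length(a); lb <- length(b)
  if (min(la, lb) < min_overlap) return(0L)
  for (o in seq(min(la, lb), min_overlap)) {
    mism <- sum(a[(la - o + 1L):la] != b[1:o])
    if (mism <= max_mismatch) return(o)
  }
  0L
}

#' Extend contigs with reads and stitch them into one sequence
#'
#' Greedy read-based extension: at each step the read (either orientation)
#' overlapping the growing 3' end by at least `min_overlap` bases with at most
#' `max_mismatch` mismatches and giving the longest extension is appended;
#' ties on extension length are broken by input order. When the second contig
#' overlaps the growing end it is merged and the walk stops. Deterministic
#' given input order and parameters.
#'
#' @param contigs List of one or two `nuc_seq` (in genome order).
#' @param reads List of `nuc_seq` reads (either strand).
#' @param min_overlap Minimum overlap in nt (>= 15; default 30).
#' @param max_mismatch Maximum mismatches tolerated in an overlap (default 1).
#' @return Merged `nuc_seq`, or NULL when no read chain bridges the contigs.
#' @export
extend_and_stitch <- function(contigs, reads, min_overlap = 30L,
                              max_mismatch = 1L) {
  if (min_overlap < 15L) mv_stop("BadParameter", "min_overlap must be >= 15")
  contigs <- lapply(contigs, as_nuc_seq)
  reads <- lapply(reads, as_nuc_seq)
  cur <- seq_chars(contigs[[1]])
  target <- if (length(contigs) >= 2L) seq_chars(contigs[[2]]) else NULL
  read_chars <- lapply(reads, seq_chars)
  rc_chars <- lapply(reads, function(r) seq_chars(reverse_complement(r)))
  max_steps <- 10000L
  for (step in seq_len(max_steps)) {
    if (!is.null(target)) {
      o <- best_overlap(cur, target, min_overlap, max_mismatch)
      if (o > 0L) {
        merged <- c(cur, target[(o + 1L):length(target)])
        res <- paste(merged, collapse = "")
        return(structure(list(id = paste0(contigs[[1]]$id, "_stitched"),
                              residues = res, length = nchar(res)),
                         class = "nuc_seq"))
      }
    }
    best_ext <- 0L; best_tail <- NULL; n_best <- 0L
    for (i in seq_along(reads)) {
      for (rc in list(read_chars[[i]], rc_chars[[i]])) {
        o <- best_overlap(cur, rc, min_overlap, max_mismatch)
        ext <- if (o > 0L) length(rc) - o else 0L
        if (ext > best_ext) {
          best_ext <- ext
          best_tail <- rc[(o + 1L):length(rc)]
          n_best <- 1L
        } else if (ext > 0L && ext == best_ext &&
                   !identical(rc[(o + 1L):length(rc)], best_tail)) {
          n_best <- n_best + 1L
        }
      }
    }
    if (best_ext == 0L) {
      if (is.null(target) && step > 1L) {
        res <- paste(cur, collapse = "")
        return(structure(list(id = paste0(contigs[[1]]$id, "_extended"),
                              residues = res, length = nchar(res)),
                         class = "nuc_seq"))
      }
      return(NULL)
    }
    if (n_best > 1L)
      mv_stop("AmbiguousExtension",
              "two incompatible extensions of equal support at step %d", step)
    cur <- c(cur, best_tail)
  }
  NULL
}
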