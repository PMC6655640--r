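# Sequence primitives: normalization, dual genetic codes, six-frame ORF
# discovery, composition statistics. All coordinates are 0-based half-open
# internally; report layers convert to 1-based inclusive.

IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

# classed conditions so callers and tests can catch specific failures
mv_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "mycovir_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Normalize a raw nucleotide string into a NucSeq
#'
#' Uppercases, strips whitespace, converts RNA (U) to the DNA alphabet (T) and
#' rejects anything that is not an IUPAC nucleotide code.
#'
#' @param raw Character scalar, the raw sequence (DNA or RNA, any case).
#' @param id Identifier attached to the sequence.
#' @return A `nuc_seq` object: list with `id`, `residues`, `length`.
#' @examples
#' normalize_sequence("augc")$residues # "ATGC"
#' @export
normalize_sequence <- function(raw, id = "seq") {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    mv_stop("EmptySequence", "sequence must be a single character string")
  s <- gsub("[[:space:]]+", "", raw)
  if (nchar(s) == 0L)
    mv_stop("EmptySequence", "sequence '%s' is empty after whitespace removal", id)
  s <- unname(chartr("U", "T", toupper(s)))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% IUPAC_NT))
  if (length(bad) > 0L)
    mv_stop("IllegalCharacter",
            "illegal character '%s' at offset %d in sequence '%s'",
            ch[bad[1]], bad[1] - 1L, id)
  structure(list(id = id, residues = s, length = nchar(s)),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq> %s (%d nt)\n", x$id, x$length))
  invisible(x)
}

as_nuc_seq <- function(x, id = "seq") {
  if (inherits(x, "nuc_seq")) x else normalize_sequence(x, id = id)
}

#' Reverse complement of a nucleotide sequence
#'
#' IUPAC degeneracy codes are complemented correctly.
#'
#' @param seq A `nuc_seq` or character scalar.
#' @return A `nuc_seq` on the opposite strand.
#' @export
reverse_complement <- function(seq) {
  seq <- as_nuc_seq(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq$residues)))
  structure(list(id = seq$id, residues = rc, length = seq$length),
            class = "nuc_seq")
}

# genetic code tables; the mold-mitochondrial code differs from the standard
# code only at TGA (-> Trp)
genetic_code_table <- function(codon_table = c("standard", "mold_mito")) {
  codon_table <- match.arg(codon_table)
  Biostrings::getGeneticCode(if (codon_table == "standard") "1" else "4")
}

split_codons <- function(residues) {
  n <- nchar(residues)
  substring(residues, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a nucleotide sequence
#'
#' Codons containing degenerate codes (including N) translate to `X`; stop
#' codons render as `*`. Under the mold-mitochondrial code TGA encodes
#' tryptophan instead of stop.
#'
#' @param seq A `nuc_seq` or character scalar; length must be a multiple of 3.
#' @param codon_table `"standard"` or `"mold_mito"`.
#' @return Protein string (single character scalar).
#' @examples
#' translate_seq("ATGTGA", "mold_mito") # "MW"
#' @export
translate_seq <- function(seq, codon_table = c("standard", "mold_mito")) {
  seq <- as_nuc_seq(seq)
  codon_table <- match.arg(codon_table)
  if (seq$length %% 3L != 0L)
    mv_stop("LengthNotMultipleOfThree",
            "length of '%s' (%d) is not a multiple of 3", seq$id, seq$length)
  code <- genetic_code_table(codon_table)
  aa <- code[split_codons(seq$residues)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find open reading frames in all six frames
#'
#' Each stop-bounded region of a reading frame yields at most one ORF, running
#' from its 5'-most ATG (or from the region start when `require_start` is
#' FALSE) to the next in-frame stop codon or the sequence end. Codons with
#' degenerate bases translate to `X` and never terminate an ORF. The stop
#' codon is included in `[start, end)` but not in the translation.
#'
#' @param seq A `nuc_seq` or character scalar.
#' @param codon_table `"standard"` or `"mold_mito"`.
#' @param min_len_aa Minimum protein length to report (default 100, the
#'   conventional triage cutoff; configurable down to 1).
#' @param require_start If TRUE (default) an ORF must begin with ATG.
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open, forward-strand coordinates), `strand`, `frame` (0-2 within
#'   strand), `codon_table`, `aa`, `has_start`, `has_stop`, sorted by
#'   descending protein length, then ascending start, then strand (+ first).
#' @export
find_orfs <- function(seq, codon_table = c("standard", "mold_mito"),
                      min_len_aa = 100L, require_start = TRUE) {
  seq <- as_nuc_seq(seq)
  codon_table <- match.arg(codon_table)
  if (min_len_aa < 1L) mv_stop("BadParameter", "min_len_aa must be >= 1")
  code <- genetic_code_table(codon_table)
  L <- seq$length
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq$residues else reverse_complement(seq)$residues
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3L
      if (n_codons < 1L) next
      codons <- substring(s, frame + 1L + 3L * (seq_len(n_codons) - 1L),
                          frame + 3L * seq_len(n_codons))
      aa <- code[codons]
      aa[is.na(aa)] <- "X"
      stops <- which(aa == "*")
      region_starts <- c(1L, stops + 1L)
      region_ends <- c(stops, n_codons)   # stop codon index closes region
      for (k in seq_along(region_starts)) {
        r0 <- region_starts[k]; r1 <- region_ends[k]
        has_stop <- k <= length(stops)
        last_coding <- if (has_stop) r1 - 1L else r1
        if (last_coding < r0) next
        if (require_start) {
          m <- which(codons[r0:last_coding] == "ATG")
          if (length(m) == 0L) next
          c0 <- r0 + m[1] - 1L
        } else c0 <- r0
        prot <- paste(aa[c0:last_coding], collapse = "")
        if (nchar(prot) < min_len_aa) next
        c1 <- if (has_stop) r1 else last_coding   # last codon in [start,end)
        nt_start <- frame + 3L * (c0 - 1L)
        nt_end <- frame + 3L * c1
        if (strand == "-") {
          tmp <- L - nt_end
          nt_end <- L - nt_start
          nt_start <- tmp
        }
        out[[length(out) + 1L]] <- data.frame(
          seq_id = seq$id, start = nt_start, end = nt_end, strand = strand,
          frame = frame, codon_table = codon_table, aa = prot,
          has_start = codons[c0] == "ATG", has_stop = has_stop,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), codon_table = character(),
                      aa = character(), has_start = logical(),
                      has_stop = logical(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  ord <- order(-nchar(df$aa), df$start, df$strand)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' A+T (A+U) content of a nucleotide sequence
#'
#' @param seq A `nuc_seq` or character scalar.
#' @return Percent in `[0, 100]`; degenerate codes count only in the
#'   denominator.
#' @export
at_content <- function(seq) {
  seq <- as_nuc_seq(seq)
  if (seq$length == 0L) mv_stop("EmptySequence", "empty sequence")
  ch <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  100 * sum(ch == "A" | ch == "T") / length(ch)
}

#' Binned amino-acid composition profile
#'
#' Splits a protein into contiguous bins and reports, per bin, the fraction of
#' residues belonging to a set of interest (e.g. the A/G/P enrichment toward
#' the C-terminus of victorivirus coat proteins).
#'
#' @param aa Protein string.
#' @param residues Character vector of amino-acid letters of interest.
#' @param n_bins Number of contiguous bins; remainder residues join the final
#'   bin.
#' @return List of class `composition_profile` with `residues_of_interest`,
#'   `n_bins`, `bin_fractions`.
#' @export
binned_composition <- function(aa, residues = c("A", "G", "P"), n_bins = 10L) {
  if (n_bins < 1L) mv_stop("BadParameter", "n_bins must be >= 1")
  n <- nchar(aa)
  if (n < n_bins)
    mv_stop("ProteinShorterThanBins",
            "protein length %d < n_bins %d", n, n_bins)
  ch <- strsplit(toupper(aa), "", fixed = TRUE)[[1]]
  size <- n %/% n_bins
  starts <- (seq_len(n_bins) - 1L) * size + 1L
  ends <- c(starts[-1L] - 1L, n)
  fr <- vapply(seq_len(n_bins), function(i) {
    b <- ch[starts[i]:ends[i]]
    mean(b %in% residues)
  }, numeric(1))
  structure(list(residues_of_interest = residues, n_bins = n_bins,
                 bin_fractions = fr),
            class = "composition_profile")
}

#' Read a multi-record FASTA file
#'
#' @param path File path.
#' @param normalize Normalize records as nucleotide sequences (default TRUE);
#'   set FALSE for protein FASTA, which is returned as a named character
#'   vector.
#' @return List of `nuc_seq` (or named character vector when
#'   `normalize = FALSE`).
#' @export
read_fasta <- function(path, normalize = TRUE) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (!normalize) {
    names(seqs) <- ids
    return(seqs)
  }
  out <- lapply(seq_along(seqs), function(i) normalize_sequence(seqs[i], ids[i]))
  names(out) <- ids
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs List of `nuc_seq`, or named character vector (protein or
#'   nucleotide).
#' @param path Output file path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs) && length(seqs) > 0L && inherits(seqs[[1]], "nuc_seq")) {
    v <- vapply(seqs, function(s) s$residues, character(1))
    names(v) <- vapply(seqs, function(s) s$id, character(1))
  } else {
    v <- unlist(seqs)
  }
  set <- Biostrings::BStringSet(v)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
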