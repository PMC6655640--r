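# Percent identity, alignment trimming, genome-class lookup, and the
# ICTV-style species demarcation engine.

# fixed alignment scoring, kept here so identity values are reproducible:
# BLOSUM62 / gap open 10 / extend 0.5 for proteins; match 2, mismatch -3,
# gap open 5, extend 2 for nucleotides
alignment_params <- function(alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "aa") {
    list(substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  } else {
    list(substitutionMatrix =
           Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE),
         gapOpening = 5, gapExtension = 2)
  }
}

#' Percent identity between two sequences from a global alignment
#'
#' Needleman-Wunsch global alignment with affine gaps; identity is 100 times
#' the number of identical columns over the columns where neither sequence is
#' gapped.
#'
#' @param a,b Sequences (character scalars, or `nuc_seq` for nucleotides).
#' @param alphabet `"aa"` (default) or `"nt"`.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  a <- if (inherits(a, "nuc_seq")) a$residues else as.character(a)
  b <- if (inherits(b, "nuc_seq")) b$residues else as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    mv_stop("EmptySequence", "both sequences must be non-empty")
  p <- alignment_params(alphabet)
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = p$substitutionMatrix,
    gapOpening = p$gapOpening, gapExtension = p$gapExtension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- pa != "-" & sa != "-"
  if (!any(both)) return(0)
  100 * sum(pa[both] == sa[both]) / sum(both)
}

#' All-vs-all percent identity matrix
#'
#' Row/column ordering follows the input order.
#'
#' @param seqs Named list or named character vector of sequences.
#' @param alphabet `"aa"` or `"nt"`.
#' @return List of class `identity_matrix` with `labels` and `values`
#'   (symmetric square matrix of percents, diagonal 100).
#' @export
identity_matrix <- function(seqs, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) < 2L) mv_stop("BadParameter", "need at least 2 sequences")
  labels <- names(seqs)
  if (is.null(labels) || any(labels == ""))
    mv_stop("BadParameter", "all sequences must be labeled")
  if (anyDuplicated(labels))
    mv_stop("DuplicateLabel", "duplicate label '%s'",
            labels[duplicated(labels)][1])
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    v <- pairwise_identity(seqs[[i]], seqs[[j]], alphabet = alphabet)
    m[i, j] <- v
    m[j, i] <- v
  }
  structure(list(labels = labels, values = m), class = "identity_matrix")
}

#' Trim alignment columns by gap occupancy
#'
#' Retains columns whose non-gap fraction is at least `gap_threshold` (0.9
#' allows a gap in up to 10 percent of the rows).
#'
#' @param msa Character vector of equal-length gapped sequences (`-` or `.`
#'   as gap).
#' @param gap_threshold Minimum non-gap fraction for a column to be kept.
#' @return Character vector of trimmed rows, order and names preserved.
#' @export
trim_alignment <- function(msa, gap_threshold = 0.9) {
  if (length(msa) == 0L) return(msa)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L)
    mv_stop("RaggedAlignment", "alignment rows differ in length")
  rows <- strsplit(msa, "", fixed = TRUE)
  mat <- do.call(rbind, rows)
  nongap <- colMeans(mat != "-" & mat != ".")
  keep <- nongap >= gap_threshold
  out <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(msa)
  out
}

#' Default species demarcation rules
#'
#' Per-taxon percent-identity thresholds combined with the unique-fungal-host
#' criterion. A candidate qualifies as a new species only when every set
#' identity falls below its threshold (at or below, for taxa whose published
#' criterion is inclusive) and the host is new. Thresholds are editable; the
#' `note` column records each rule's basis in field convention.
#'
#' @return data.frame with columns `taxon`, `rdrp_threshold`, `cp_threshold`,
#'   `nt_threshold`, `orf1_threshold`, `comparator` (`"lt"` strict, `"le"`
#'   inclusive), `host_required`, `note`.
#' @export
default_rules <- function() {
  r <- function(taxon, rdrp = NA, cp = NA, nt = NA, orf1 = NA,
                comparator = "lt", note = "") {
    data.frame(taxon = taxon, rdrp_threshold = rdrp, cp_threshold = cp,
               nt_threshold = nt, orf1_threshold = orf1,
               comparator = comparator, host_required = TRUE, note = note,
               stringsAsFactors = FALSE)
  }
  rbind(
    r("Totivirus", rdrp = 50,
      note = "RdRP <50% plus distinct host as species proxy"),
    r("Victorivirus", rdrp = 90, cp = 80,
      note = "recommended stringent thresholds: RdRP 90%, CP 80%"),
    r("Unirnavirus", rdrp = 75, orf1 = 70,
      note = "proposed: RdRP 75%, ORF1 70%, unique host"),
    r("Alphapartitivirus", rdrp = 90, cp = 80, comparator = "le",
      note = "genus criterion, inclusive: RdRP <=90%, CP <=80%"),
    r("Betapartitivirus", rdrp = 90, cp = 80,
      note = "genus criterion: RdRP 90%, CP 80%"),
    r("Gammapartitivirus", rdrp = 90, cp = 80,
      note = "genus criterion: RdRP 90%, CP 80%"),
    r("Epsilonpartitivirus", rdrp = 85, cp = 75,
      note = "proposed genus: RdRP 85%, CP 75%"),
    r("Zetapartitivirus", rdrp = 90, cp = 80,
      note = "proposed genus: RdRP 90%, CP 80%"),
    r("Chrysovirus", rdrp = 70, cp = 53,
      note = "genus criterion: RdRP 70%, CP 53%"),
    r("Alphaendornavirus", nt = 75,
      note = "overall nucleotide identity below 75%"),
    r("Betaendornavirus", rdrp = 75,
      note = "75% on either the RdRP or methyltransferase motif"),
    r("Betahypovirus", rdrp = 70,
      note = "suggested RdRP threshold 70%"),
    r("Fusarivirus", rdrp = 60, comparator = "le",
      note = "recommended: RdRP <=60% plus unique host"),
    r("Mitovirus", rdrp = 90,
      note = "above 90% RdRP identity treated as same species"),
    r("Yadokarivirus", rdrp = 95,
      note = "95% RdRP identity separates species within the group")
  )
}

normalize_binomial <- function(host) {
  w <- strsplit(trimws(tolower(gsub("[*_]", "", host))), "[[:space:]]+")[[1]]
  w <- w[!(w %in% c("strain", "isolate", "cv.", "sp."))]
  paste(utils::head(w, 2L), collapse = " ")
}

host_genus <- function(host) strsplit(normalize_binomial(host), " ")[[1]][1]

#' Species demarcation verdict for a candidate virus
#'
#' Applies the per-taxon identity thresholds and the host criterion. A
#' candidate is a `new_species` when every threshold set for its taxon passes
#' and its host (species binomial; strain differences ignored) is absent from
#' the known hosts. It is a `known_species` when at least one identity sits at
#' or above its threshold and the host is the same species, or the same genus
#' (a related-genus advisory is recorded in the rationale). Anything else is
#' `indeterminate`. Taxa for which no demarcation criterion has been
#' established (Alternavirus) return `indeterminate` directly.
#'
#' @param candidate List with `taxon`, `identities` (named numeric vector with
#'   any of `rdrp`, `cp`, `nt`, `orf1`: percent identity to the nearest known
#'   virus), `host`, `known_hosts` (character vector of hosts of the nearest
#'   known viruses).
#' @param rules Rules table, see [default_rules()].
#' @return List of class `species_call`: `status`, `taxon`, `rationale`
#'   (data.frame of evaluated criteria).
#' @export
demarcate <- function(candidate, rules = default_rules()) {
  taxon <- candidate$taxon
  if (identical(taxon, "Alternavirus")) {
    return(structure(list(
      status = "indeterminate", taxon = taxon,
      rationale = data.frame(
        criterion = "taxon", value = NA_real_, threshold = NA_real_,
        comparator = NA_character_, pass = NA,
        note = "no demarcation criterion established for Alternavirus",
        stringsAsFactors = FALSE)), class = "species_call"))
  }
  rule <- rules[rules$taxon == taxon, , drop = FALSE]
  if (nrow(rule) != 1L)
    mv_stop("UnknownTaxon", "no demarcation rule for taxon '%s'", taxon)
  ids <- candidate$identities
  slots <- c(rdrp = "rdrp_threshold", cp = "cp_threshold",
             nt = "nt_threshold", orf1 = "orf1_threshold")
  rat <- list()
  seq_pass <- TRUE; seq_fail <- FALSE; evaluated <- 0L
  for (metric in names(slots)) {
    thr <- rule[[slots[[metric]]]]
    if (is.na(thr)) next
    val <- if (metric %in% names(ids)) as.numeric(ids[[metric]]) else NA_real_
    if (is.na(val)) {
      rat[[length(rat) + 1L]] <- data.frame(
        criterion = metric, value = NA_real_, threshold = thr,
        comparator = rule$comparator, pass = NA,
        note = "identity not supplied", stringsAsFactors = FALSE)
      seq_pass <- FALSE
      next
    }
    evaluated <- evaluated + 1L
    ok <- if (rule$comparator == "le") val <= thr else val < thr
    rat[[length(rat) + 1L]] <- data.frame(
      criterion = metric, value = val, threshold = thr,
      comparator = rule$comparator, pass = ok, note = "",
      stringsAsFactors = FALSE)
    seq_pass <- seq_pass && ok
    seq_fail <- seq_fail || !ok
  }
  host <- normalize_binomial(candidate$host)
  known <- vapply(candidate$known_hosts, normalize_binomial, character(1))
  same_species <- host %in% known
  same_genus <- !same_species &&
    host_genus(candidate$host) %in% vapply(candidate$known_hosts, host_genus,
                                           character(1))
  rat[[length(rat) + 1L]] <- data.frame(
    criterion = "host", value = NA_real_, threshold = NA_real_,
    comparator = NA_character_, pass = !same_species,
    note = if (same_species) "same host species" else if (same_genus)
      "advisory: host genus shared with a known host" else "new host",
    stringsAsFactors = FALSE)
  status <- if (seq_pass && evaluated > 0L && !same_species) {
    "new_species"
  } else if (seq_fail && (same_species || same_genus)) {
    "known_species"
  } else {
    "indeterminate"
  }
  structure(list(status = status, taxon = taxon,
                 rationale = do.call(rbind, rat)),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("<species_call> %s: %s\n", x$taxon, x$status))
  print(x$rationale)
  invisible(x)
}

#' Genome class (nucleic acid / strandedness) for a virus family
#'
#' @param family Family or genus-level group name.
#' @return One of `"dsRNA"`, `"(+)ssRNA"`, `"ssRNA"`.
#' @export
assign_genome_class <- function(family) {
  key <- gsub("[^a-z]", "", tolower(family))
  lookup <- c(
    totiviridae = "dsRNA", totivirus = "dsRNA", victorivirus = "dsRNA",
    partitiviridae = "dsRNA", partitivirus = "dsRNA",
    chrysoviridae = "dsRNA", chrysovirus = "dsRNA",
    endornaviridae = "dsRNA", endornavirus = "dsRNA",
    alternaviridae = "dsRNA", alternavirus = "dsRNA",
    unclassifieddsrna = "dsRNA", unirnavirus = "dsRNA",
    hypoviridae = "(+)ssRNA", hypovirus = "(+)ssRNA",
    fusariviridae = "(+)ssRNA", fusarivirus = "(+)ssRNA",
    yadokariviridae = "(+)ssRNA", yadokarivirus = "(+)ssRNA",
    mitovirus = "(+)ssRNA", narnaviridae = "(+)ssRNA",
    ourmialikevirus = "(+)ssRNA", ourmialike = "(+)ssRNA",
    tobamolikevirus = "(+)ssRNA", tobamolike = "(+)ssRNA",
    ambiguiviridae = "ssRNA", ambiguivirus = "ssRNA",
    unclassifiedssrna = "ssRNA")
  if (!(key %in% names(lookup)))
    mv_stop("UnknownFamily", "no genome class known for family '%s'", family)
  unname(lookup[[key]])
}
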