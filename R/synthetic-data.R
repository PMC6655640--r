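# Ground-truthed synthetic inputs: archetype viral genomes per family, decoy
# host transcripts, and simulated reads. Every planted feature is recorded in
# the returned truth and is recoverable by the corresponding detector.

# codon lists per amino acid (standard code, stops excluded)
codons_by_aa <- function() {
  if (!is.null(.mv_env$codons_by_aa)) return(.mv_env$codons_by_aa)
  code <- genetic_code_table("standard")
  code <- code[code != "*"]
  .mv_env$codons_by_aa <- split(names(code), unname(code))
  .mv_env$codons_by_aa
}

sample_bases <- function(n, p_at = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(p_at / 2, p_at / 2, (1 - p_at) / 2, (1 - p_at) / 2)),
        collapse = "")
}

# random protein with catalytic-triad look-alikes removed so planted triads
# stay unambiguous
random_protein <- function(n, probs = NULL, sanitize = TRUE) {
  if (n <= 0L) return("")
  if (is.null(probs)) probs <- rep(1 / 20, 20)
  s <- paste(sample(AA20, n, replace = TRUE, prob = probs), collapse = "")
  if (sanitize) {
    while (grepl("[GSA]DD|GDN", s)) {
      s <- sub("([GSA])DD", "\\1ED", s)
      s <- sub("GDN", "GEN", s)
    }
  }
  s
}

# reverse-translate; `force` is a named list mapping 1-based residue index to
# a fixed codon; W residues become TGA when w_tga (mold-mitochondrial usage)
revtrans <- function(protein, p_at = NULL, force = list(), w_tga = FALSE) {
  tab <- codons_by_aa()
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  cods <- character(length(ch))
  for (i in seq_along(ch)) {
    fi <- as.character(i)
    if (fi %in% names(force)) { cods[i] <- force[[fi]]; next }
    if (w_tga && ch[i] == "W") { cods[i] <- "TGA"; next }
    opts <- tab[[ch[i]]]
    if (is.null(opts)) mv_stop("BadParameter", "cannot encode residue '%s'", ch[i])
    if (is.null(p_at)) {
      cods[i] <- opts[sample.int(length(opts), 1L)]
    } else {
      at <- vapply(opts, function(cd)
        sum(strsplit(cd, "")[[1]] %in% c("A", "T")), numeric(1))
      w <- (p_at / (1 - p_at))^at
      cods[i] <- opts[sample.int(length(opts), 1L, prob = w)]
    }
  }
  paste(cods, collapse = "")
}

# RdRP bait protein: the model's consensus blocks joined by random linkers,
# with random flanks; starts with M. Optionally mutate the block-C triad.
rdrp_protein <- function(model, total_aa = 500L, triad = c("GDD", "ADD", "GDN"),
                         linker_len = 25L) {
  triad <- match.arg(triad)
  cons <- vapply(model$blocks, function(b) b$consensus, character(1))
  if (triad != "GDD") {
    cons[3] <- sub("GDD", triad, cons[3], fixed = TRUE)
  }
  core_len <- sum(nchar(cons)) + 2L * linker_len
  flank <- max(10L, total_aa - 1L - core_len)
  f1 <- flank %/% 2L; f2 <- flank - f1
  prot <- paste0("M", random_protein(f1),
                 cons[1], random_protein(linker_len),
                 cons[2], random_protein(linker_len),
                 cons[3], random_protein(f2))
  # segment boundaries can spell accidental triads; neutralize every
  # catalytic-triad look-alike except the planted one in block C
  planted_at <- 1L + f1 + nchar(cons[1]) + linker_len + nchar(cons[2]) +
    linker_len + as.integer(regexpr(triad, cons[3], fixed = TRUE))
  repeat {
    hits <- gregexpr("[GSA]DD|GDN", prot)[[1]]
    bad <- hits[hits != -1L & hits != planted_at]
    if (length(bad) == 0L) break
    substr(prot, bad[1] + 1L, bad[1] + 1L) <- "E"
  }
  prot
}

# random 5' UTR ending in an in-frame stop so called ORFs begin at the
# planted ATG; optional motif planted at a fixed offset
make_utr5 <- function(len, motif = NULL, motif_at = 5L, p_at = 0.5) {
  stopifnot(len >= 8L)
  body <- sample_bases(len - 3L, p_at)
  if (!is.null(motif)) {
    stopifnot(motif_at + nchar(motif) <= len - 3L)
    substr(body, motif_at + 1L, motif_at + nchar(motif)) <- motif
  }
  paste0(body, "TAA")
}

new_seg <- function(id, residues) normalize_sequence(residues, id = id)

#' Simulate a synthetic mycovirus genome of a family archetype
#'
#' Each archetype carries the genome organization and diagnostic features of
#' its family: segment count and length ranges, an RdRP bait built from the
#' bundled profile-model consensus blocks (so the triage scanner fires), and
#' the family's recoding/UTR/composition features. The returned truth records
#' every planted feature with coordinates so detectors can be verified
#' against it.
#'
#' @param archetype One of `"totivirus"`, `"victorivirus"`, `"unirnavirus"`,
#'   `"partitivirus"`, `"chrysovirus"`, `"alternavirus"`, `"mitovirus"`,
#'   `"ambiguivirus"`, `"hypovirus"`, `"endornavirus"`, `"fusarivirus"`,
#'   `"yadokarivirus"`, `"ourmia_like"`.
#' @param seed Integer seed; output is deterministic given
#'   `(archetype, seed, overrides)`.
#' @param overrides Named list; currently `length` (target length of segment
#'   1, must fall in the archetype range).
#' @return List with `segments` (list of `nuc_seq`) and `truth` (list:
#'   `archetype`, `genome_class`, `codon_table`, `rdrp_segment`,
#'   `rdrp_model`, `orfs`, `features`).
#' @export
make_virus <- function(archetype, seed, overrides = list()) {
  archetypes <- names(archetype_table())
  if (!(archetype %in% archetypes))
    mv_stop("BadParameter", "unknown archetype '%s'", archetype)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(seed)
  info <- archetype_table()[[archetype]]
  pick_len <- function(rng, k = 1L) {
    v <- info$segment_length_ranges[[k]]
    if (k == 1L && !is.null(overrides$length)) {
      if (overrides$length < v[1] || overrides$length > v[2])
        mv_stop("OverrideOutOfRange",
                "length %d outside [%d, %d]", overrides$length, v[1], v[2])
      return(as.integer(overrides$length))
    }
    sample(seq(v[1], v[2]), 1L)
  }
  builder <- get(paste0(".arch_", archetype), mode = "function")
  res <- builder(info, pick_len)
  res$truth$archetype <- archetype
  res$truth$seed <- seed
  res$truth$genome_class <- info$genome_class
  res
}

#' Archetype definitions: segment length ranges and genome classes
#'
#' Length ranges follow the catalog of sequenced family members.
#'
#' @return Named list, one entry per archetype.
#' @export
archetype_table <- function() {
  list(
    totivirus = list(segment_length_ranges = list(c(4900L, 5364L)),
                     genome_class = "dsRNA"),
    victorivirus = list(segment_length_ranges = list(c(4900L, 5364L)),
                        genome_class = "dsRNA"),
    unirnavirus = list(segment_length_ranges = list(c(3000L, 3300L)),
                       genome_class = "dsRNA"),
    partitivirus = list(segment_length_ranges = list(c(1700L, 2284L),
                                                     c(1504L, 2297L)),
                        genome_class = "dsRNA"),
    chrysovirus = list(segment_length_ranges = list(c(3478L, 3501L),
                                                    c(3120L, 3143L),
                                                    c(2955L, 3069L),
                                                    c(2770L, 2980L)),
                       genome_class = "dsRNA"),
    alternavirus = list(segment_length_ranges = list(c(3400L, 3600L),
                                                     c(2600L, 2800L),
                                                     c(2300L, 2500L)),
                        genome_class = "dsRNA"),
    mitovirus = list(segment_length_ranges = list(c(2283L, 2595L)),
                     genome_class = "(+)ssRNA"),
    ambiguivirus = list(segment_length_ranges = list(c(2798L, 3911L)),
                        genome_class = "ssRNA"),
    hypovirus = list(segment_length_ranges = list(c(9069L, 14211L)),
                     genome_class = "(+)ssRNA"),
    endornavirus = list(segment_length_ranges = list(c(14296L, 16495L)),
                        genome_class = "dsRNA"),
    fusarivirus = list(segment_length_ranges = list(c(5969L, 7835L)),
                       genome_class = "(+)ssRNA"),
    yadokarivirus = list(segment_length_ranges = list(c(3507L, 3621L)),
                         genome_class = "(+)ssRNA"),
    ourmia_like = list(segment_length_ranges = list(c(2650L, 2750L)),
                       genome_class = "(+)ssRNA"))
}

# -- per-archetype builders ---------------------------------------------------

# generic single-RdRP-ORF genome (mono-segment, + strand)
.simple_rdrp_genome <- function(id, L, model_name, utr5_len = 80L,
                                utr5_motif = NULL, rdrp_frac = 0.82,
                                p_at = NULL) {
  model <- default_models()[[model_name]]
  n_aa <- as.integer((L * rdrp_frac) %/% 3L)
  prot <- rdrp_protein(model, total_aa = n_aa)
  utr5 <- make_utr5(utr5_len, motif = utr5_motif,
                    p_at = if (is.null(p_at)) 0.5 else p_at)
  orf <- revtrans(prot, p_at = p_at, force = list("1" = "ATG"))
  body <- paste0(utr5, orf, "TAA")
  pad <- L - nchar(body)
  if (pad < 0L) mv_stop("BadParameter", "genome plan exceeds target length")
  seqs <- paste0(body, sample_bases(pad, if (is.null(p_at)) 0.5 else p_at))
  orf_start <- utr5_len
  orf_end <- orf_start + nchar(orf) + 3L
  list(segment = new_seg(id, seqs),
       prot = prot,
       orf = data.frame(segment = id, start = orf_start, end = orf_end,
                        aa_len = nchar(prot), stringsAsFactors = FALSE),
       utr5_motif_pos = if (is.null(utr5_motif)) NA_integer_ else 5L)
}

.arch_simple <- function(info, pick_len, id, model_name, codon_table,
                         utr5_motif = NULL, rdrp_frac = 0.82) {
  L <- pick_len(info$segment_length_ranges[[1]])
  g <- .simple_rdrp_genome(id, L, model_name, utr5_motif = utr5_motif,
                           rdrp_frac = rdrp_frac)
  feats <- list(triad = list(label = "GDD"))
  if (!is.null(utr5_motif))
    feats$utr5_motif <- list(pattern = utr5_motif, position = 5L)
  list(segments = list(g$segment),
       truth = list(codon_table = codon_table, rdrp_segment = 1L,
                    rdrp_model = model_name, orfs = g$orf,
                    features = feats))
}

.arch_hypovirus <- function(info, pick_len) {
  # polyprotein genome; conserved 15-mer in the 5' UTR
  .arch_simple(info, pick_len, "hypovirus_seg1", "RdRP_4", "standard",
               utr5_motif = "CTGGTTTATACTCTG")
}

.arch_endornavirus <- function(info, pick_len)
  .arch_simple(info, pick_len, "endornavirus_seg1", "RdRP_1", "standard")

.arch_yadokarivirus <- function(info, pick_len)
  .arch_simple(info, pick_len, "yadokarivirus_seg1", "RdRP_5", "standard")

.arch_ourmia_like <- function(info, pick_len)
  .arch_simple(info, pick_len, "ourmia_seg1", "RdRP_5", "standard",
               rdrp_frac = 0.78)

.arch_mitovirus <- function(info, pick_len) {
  # single ORF intact only under the mold-mitochondrial code (internal
  # TGA-tryptophans); coding strand A+U inside 62-73%
  L <- pick_len(info$segment_length_ranges[[1]])
  model <- default_models()[["Mitovir_RNA_pol"]]
  target_at <- 0.675
  n_aa <- as.integer((L * 0.85) %/% 3L)
  prot <- rdrp_protein(model, total_aa = n_aa)
  # sprinkle tryptophans through the N-terminal flank (clear of the motif
  # blocks); they are encoded as TGA, interrupting the standard-code ORF
  pch <- strsplit(prot, "", fixed = TRUE)[[1]]
  pch[seq(5L, 45L, by = 8L)] <- "W"
  prot <- paste(pch, collapse = "")
  n_tga <- sum(pch == "W")
  orf <- revtrans(prot, p_at = 0.72, force = list("1" = "ATG"),
                  w_tga = TRUE)
  utr5_len <- 60L
  coding <- paste0(orf, "TAA")
  utr_total <- L - utr5_len - nchar(coding)
  if (utr_total < 20L) mv_stop("BadParameter", "mitovirus plan too long")
  at_coding <- sum(strsplit(coding, "")[[1]] %in% c("A", "T"))
  need <- target_at * L - at_coding
  p_utr <- min(0.95, max(0.05, need / (utr5_len + utr_total)))
  utr5 <- make_utr5(utr5_len, p_at = p_utr)
  utr3 <- sample_bases(utr_total, p_utr)
  seqs <- paste0(utr5, coding, utr3)
  seg <- new_seg("mitovirus_seg1", seqs)
  list(segments = list(seg),
       truth = list(codon_table = "mold_mito", rdrp_segment = 1L,
                    rdrp_model = "Mitovir_RNA_pol",
                    orfs = data.frame(segment = seg$id, start = utr5_len,
                                      end = utr5_len + nchar(coding),
                                      aa_len = nchar(prot),
                                      stringsAsFactors = FALSE),
                    features = list(triad = list(label = "GDD"),
                                    at_range = c(62, 73),
                                    n_internal_tga = n_tga)))
}

.arch_totivirus <- function(info, pick_len, id_prefix = "totivirus",
                            slippery = "GGGTTTT") {
  # CP ORF with a slippery heptamer near its 3' end, RdRP ORF downstream
  L <- pick_len(info$segment_length_ranges[[1]])
  model <- default_models()[["RdRP_1"]]
  utr5_len <- 80L
  cp_aa <- 620L
  rdrp_aa <- as.integer((L - utr5_len - 3L * cp_aa - 120L) %/% 3L)
  cp <- paste0("M", random_protein(cp_aa - 1L))
  # force G,F,F twelve residues from the end; codons GGG TTT TTC spell the
  # X XXY YYZ heptamer at a codon boundary
  k <- cp_aa - 12L
  substr(cp, k, k + 2L) <- "GFF"
  force <- list("1" = "ATG")
  force[[as.character(k)]] <- "GGG"
  force[[as.character(k + 1L)]] <- "TTT"
  force[[as.character(k + 2L)]] <- "TTC"
  cp_nt <- revtrans(cp, force = force)
  rdrp <- rdrp_protein(model, total_aa = rdrp_aa)
  rdrp_nt <- revtrans(rdrp, force = list("1" = "ATG"))
  utr5 <- make_utr5(utr5_len, motif = "AGGGTTCC", motif_at = 10L)
  spacer <- "CCTCC"
  body <- paste0(utr5, cp_nt, "TGA", spacer, rdrp_nt, "TAA")
  pad <- L - nchar(body)
  if (pad < 0L) mv_stop("BadParameter", "totivirus plan exceeds length")
  seqs <- paste0(body, sample_bases(pad))
  seg <- new_seg(paste0(id_prefix, "_seg1"), seqs)
  orf1_start <- utr5_len
  orf1_end <- orf1_start + nchar(cp_nt) + 3L
  orf2_start <- orf1_end + nchar(spacer)
  orf2_end <- orf2_start + nchar(rdrp_nt) + 3L
  slip_pos <- orf1_start + 3L * (k - 1L)
  list(segments = list(seg),
       truth = list(codon_table = "standard", rdrp_segment = 1L,
                    rdrp_model = "RdRP_1",
                    orfs = data.frame(segment = seg$id,
                                      start = c(orf1_start, orf2_start),
                                      end = c(orf1_end, orf2_end),
                                      aa_len = c(nchar(cp), nchar(rdrp)),
                                      stringsAsFactors = FALSE),
                    features = list(
                      triad = list(label = "GDD"),
                      slippery = list(position = slip_pos,
                                      heptamer = slippery),
                      utr5_motif = list(pattern = "AGGGTTCC",
                                        position = 10L))))
}

.arch_unirnavirus <- function(info, pick_len) {
  # single segment, two ORFs, slippery site near the ORF1/ORF2 boundary
  res <- .arch_totivirus(
    list(segment_length_ranges = info$segment_length_ranges), pick_len,
    id_prefix = "unirnavirus")
  res$segments[[1]]$id <- "unirnavirus_seg1"
  res$truth$orfs$segment <- "unirnavirus_seg1"
  res$truth$features$utr5_motif <- NULL
  res
}

.arch_victorivirus <- function(info, pick_len) {
  # CP with A/G/P-rich C-terminus; termination-reinitiation junction with the
  # RdRP ORF in the -1 (tetramer/pentamer) or +1 (spaced) frame
  L <- pick_len(info$segment_length_ranges[[1]])
  model <- default_models()[["RdRP_1"]]
  utr5_len <- 80L
  cp_aa <- 620L
  kind <- sample(c("tetramer_AUGA", "pentamer_overlap", "spaced"), 1L)
  base_p <- stats::setNames(rep(0.85 / 17, 20), AA20)
  base_p[c("A", "G", "P")] <- 0.05
  rich_p <- stats::setNames(rep(0.4 / 17, 20), AA20)
  rich_p[c("A", "G", "P")] <- 0.2
  n_rich <- as.integer(cp_aa * 0.2)
  cp <- paste0("M", random_protein(cp_aa - 1L - n_rich, probs = base_p),
               random_protein(n_rich, probs = rich_p))
  force_cp <- list("1" = "ATG")
  if (kind == "tetramer_AUGA") {
    substr(cp, cp_aa, cp_aa) <- "K"
    force_cp[[as.character(cp_aa)]] <- "AAA"   # ...A | TGA -> ATGA overlap
    stop1 <- "TGA"
  } else if (kind == "pentamer_overlap") {
    stop1 <- "TAA"                             # TAATG: stop's A starts ATG
  } else {
    # spaced: ...?AT GCA TGA with ORF2 ATG five bases before the stop
    substr(cp, cp_aa - 1L, cp_aa) <- "HA"
    force_cp[[as.character(cp_aa - 1L)]] <- "CAT"
    force_cp[[as.character(cp_aa)]] <- "GCA"
    stop1 <- "TGA"
  }
  cp_nt <- revtrans(cp, force = force_cp)
  rdrp_aa <- as.integer((L - utr5_len - 3L * cp_aa - 150L) %/% 3L)
  rdrp <- rdrp_protein(model, total_aa = rdrp_aa)
  utr5 <- make_utr5(utr5_len, motif = "AGGGTTCC", motif_at = 10L)
  orf1_start <- utr5_len
  orf1_end <- orf1_start + nchar(cp_nt) + 3L
  stop_start <- orf1_end - 3L
  if (kind == "tetramer_AUGA") {
    # ORF2 = ATG (A from CP tail, TG from the stop) + A?? using stop's A
    rest <- revtrans(substr(rdrp, 3L, nchar(rdrp)))
    tail_nt <- paste0("CA", rest, "TAA")       # codon2 = A + CA = ACA (T)
    orf2_start <- stop_start - 1L
  } else if (kind == "pentamer_overlap") {
    rest <- revtrans(substr(rdrp, 2L, nchar(rdrp)))
    tail_nt <- paste0("TG", rest, "TAA")       # ATG built from stop's A + TG
    orf2_start <- stop_start + 2L
  } else {
    rest <- revtrans(substr(rdrp, 4L, nchar(rdrp)))
    tail_nt <- paste0("T", rest, "TAA")        # codons 2,3 = CAT, GA+T
    orf2_start <- stop_start - 5L
  }
  body <- paste0(utr5, cp_nt, stop1, tail_nt)
  pad <- L - nchar(body)
  if (pad < 0L) mv_stop("BadParameter", "victorivirus plan exceeds length")
  seqs <- paste0(body, sample_bases(pad))
  seg <- new_seg("victorivirus_seg1", seqs)
  orf2_aa <- nchar(rdrp)   # ORF2 protein keeps the bait's length
  orf2_end <- orf2_start + 3L * (orf2_aa + 1L)
  list(segments = list(seg),
       truth = list(codon_table = "standard", rdrp_segment = 1L,
                    rdrp_model = "RdRP_1",
                    orfs = data.frame(segment = seg$id,
                                      start = c(orf1_start, orf2_start),
                                      end = c(orf1_end, orf2_end),
                                      aa_len = c(nchar(cp), orf2_aa),
                                      stringsAsFactors = FALSE),
                    features = list(
                      triad = list(label = "GDD"),
                      junction = list(kind = kind,
                                      orf1_stop_pos = stop_start,
                                      orf2_start_pos = orf2_start,
                                      frame_shift = if (kind == "spaced") 1L
                                                    else -1L),
                      cp_agp_rich = TRUE,
                      utr5_motif = list(pattern = "AGGGTTCC",
                                        position = 10L))))
}

.arch_ambiguivirus <- function(info, pick_len) {
  # ORF1 ends in the amber stop TAG; the RdRP ORF continues in the same frame
  # (readthrough fusion); RdRP carries the GDN triad
  L <- pick_len(info$segment_length_ranges[[1]])
  model <- default_models()[["RdRP_2"]]
  utr5_len <- 60L
  orf1_aa <- 300L
  rdrp_aa <- as.integer((L - utr5_len - 3L * orf1_aa - 120L) %/% 3L)
  orf1 <- paste0("M", random_protein(orf1_aa - 1L))
  rdrp <- rdrp_protein(model, total_aa = rdrp_aa, triad = "GDN")
  orf1_nt <- revtrans(orf1, force = list("1" = "ATG"))
  rdrp_nt <- revtrans(rdrp, force = list("1" = "ATG"))
  utr5 <- make_utr5(utr5_len)
  body <- paste0(utr5, orf1_nt, "TAG", rdrp_nt, "TAA")
  pad <- L - nchar(body)
  if (pad < 0L) mv_stop("BadParameter", "ambiguivirus plan exceeds length")
  seqs <- paste0(body, sample_bases(pad))
  seg <- new_seg("ambiguivirus_seg1", seqs)
  orf1_start <- utr5_len
  orf1_end <- orf1_start + 3L * orf1_aa + 3L
  orf2_start <- orf1_end
  orf2_end <- orf2_start + 3L * rdrp_aa + 3L
  list(segments = list(seg),
       truth = list(codon_table = "standard", rdrp_segment = 1L,
                    rdrp_model = "RdRP_2",
                    orfs = data.frame(segment = seg$id,
                                      start = c(orf1_start, orf2_start),
                                      end = c(orf1_end, orf2_end),
                                      aa_len = c(orf1_aa, rdrp_aa),
                                      stringsAsFactors = FALSE),
                    features = list(
                      triad = list(label = "GDN"),
                      readthrough = list(stop_codon = "TAG",
                                         orf1_end = orf1_end,
                                         fused_length_aa = orf1_aa + rdrp_aa))))
}

.arch_partitivirus <- function(info, pick_len) {
  # two segments sharing a degenerate 13-nt 5' UTR motif; conserved 10-mer in
  # both 3' UTRs; RdRP on segment 1, CP on segment 2
  L1 <- pick_len(NULL, 1L)
  L2 <- pick_len(NULL, 2L)
  model <- default_models()[["RdRP_3"]]
  u5a <- "TCACAATATCACA"; u5b <- "TCACAACATTATA"
  u3a <- "TTTCATTAGA"; u3b <- "TCTCATTAAG"
  utr5_len <- 70L
  rdrp_aa <- as.integer((L1 - utr5_len - 120L) %/% 3L)
  cp_aa <- as.integer((L2 - utr5_len - 120L) %/% 3L)
  rdrp <- rdrp_protein(model, total_aa = rdrp_aa)
  cp <- paste0("M", random_protein(cp_aa - 1L))
  seg_nt <- function(utr5_motif, prot, L, u3motif, id) {
    utr5 <- make_utr5(utr5_len, motif = utr5_motif, motif_at = 5L)
    orf <- paste0(revtrans(prot, force = list("1" = "ATG")), "TAA")
    pad <- L - utr5_len - nchar(orf)
    if (pad < nchar(u3motif) + 2L)
      mv_stop("BadParameter", "partitivirus plan exceeds length")
    utr3 <- sample_bases(pad)
    substr(utr3, 3L, 2L + nchar(u3motif)) <- u3motif
    new_seg(id, paste0(utr5, orf, utr3))
  }
  s1 <- seg_nt(u5a, rdrp, L1, u3a, "partitivirus_seg1")
  s2 <- seg_nt(u5b, cp, L2, u3b, "partitivirus_seg2")
  list(segments = list(s1, s2),
       truth = list(codon_table = "standard", rdrp_segment = 1L,
                    rdrp_model = "RdRP_3",
                    orfs = data.frame(segment = c(s1$id, s2$id),
                                      start = utr5_len,
                                      end = utr5_len + 3L * c(rdrp_aa, cp_aa) + 3L,
                                      aa_len = c(rdrp_aa, cp_aa),
                                      stringsAsFactors = FALSE),
                    features = list(
                      triad = list(label = "GDD"),
                      utr5_motif = list(consensus = "TCACAAYATYAYA",
                                        position = 5L,
                                        instances = c(u5a, u5b)),
                      utr3_motif = list(pattern = "TYTCATTARR",
                                        instances = c(u3a, u3b)))))
}

.arch_chrysovirus <- function(info, pick_len) {
  # four segments; identical "Box 1" block plus a CAA-repeat region in every
  # 5' UTR; RdRP on segment 1
  model <- default_models()[["RdRP_3"]]
  box1 <- sample_bases(40L)
  caa <- strrep("CAA", 5L)
  utr5_len <- 110L
  segs <- vector("list", 4L)
  orfs <- list()
  for (k in 1:4) {
    L <- pick_len(NULL, k)
    n_aa <- as.integer((L - utr5_len - 120L) %/% 3L)
    prot <- if (k == 1L) rdrp_protein(model, total_aa = n_aa)
            else paste0("M", random_protein(n_aa - 1L))
    utr5 <- make_utr5(utr5_len, motif = paste0(box1, "TT", caa), motif_at = 10L)
    orf <- paste0(revtrans(prot, force = list("1" = "ATG")), "TAA")
    pad <- L - utr5_len - nchar(orf)
    if (pad < 0L) mv_stop("BadParameter", "chrysovirus plan exceeds length")
    id <- paste0("chrysovirus_seg", k)
    segs[[k]] <- new_seg(id, paste0(utr5, orf, sample_bases(pad)))
    orfs[[k]] <- data.frame(segment = id, start = utr5_len,
                            end = utr5_len + nchar(orf), aa_len = n_aa,
                            stringsAsFactors = FALSE)
  }
  list(segments = segs,
       truth = list(codon_table = "standard", rdrp_segment = 1L,
                    rdrp_model = "RdRP_3",
                    orfs = do.call(rbind, orfs),
                    features = list(
                      triad = list(label = "GDD"),
                      utr5_motif = list(consensus = box1, position = 10L),
                      caa_repeat = list(pattern = caa))))
}

.arch_alternavirus <- function(info, pick_len) {
  # three segments with an identical 25-nt 5' UTR block; RdRP (segment 1)
  # carries the ADD triad in place of the canonical GDD
  model <- default_models()[["RdRP_4"]]
  shared <- sample_bases(25L)
  utr5_len <- 60L
  segs <- vector("list", 3L)
  orfs <- list()
  for (k in 1:3) {
    L <- pick_len(NULL, k)
    n_aa <- as.integer((L - utr5_len - 120L) %/% 3L)
    prot <- if (k == 1L) rdrp_protein(model, total_aa = n_aa, triad = "ADD")
            else paste0("M", random_protein(n_aa - 1L))
    utr5 <- make_utr5(utr5_len, motif = shared, motif_at = 5L)
    orf <- paste0(revtrans(prot, force = list("1" = "ATG")), "TAA")
    pad <- L - utr5_len - nchar(orf)
    if (pad < 0L) mv_stop("BadParameter", "alternavirus plan exceeds length")
    id <- paste0("alternavirus_seg", k)
    segs[[k]] <- new_seg(id, paste0(utr5, orf, sample_bases(pad)))
    orfs[[k]] <- data.frame(segment = id, start = utr5_len,
                            end = utr5_len + nchar(orf), aa_len = n_aa,
                            stringsAsFactors = FALSE)
  }
  list(segments = segs,
       truth = list(codon_table = "standard", rdrp_segment = 1L,
                    rdrp_model = "RdRP_4",
                    orfs = do.call(rbind, orfs),
                    features = list(
                      triad = list(label = "ADD"),
                      utr5_motif = list(consensus = shared, position = 5L))))
}

.arch_fusarivirus <- function(info, pick_len) {
  # large RdRP ORF1 plus a downstream ORF2
  L <- pick_len(info$segment_length_ranges[[1]])
  model <- default_models()[["RdRP_2"]]
  utr5_len <- 80L
  orf2_aa <- 450L
  rdrp_aa <- as.integer((L - utr5_len - 3L * orf2_aa - 200L) %/% 3L)
  rdrp <- rdrp_protein(model, total_aa = rdrp_aa)
  orf2 <- paste0("M", random_protein(orf2_aa - 1L))
  utr5 <- make_utr5(utr5_len)
  spacer <- paste0(sample_bases(20L), "TAA")   # in-frame stop guard for ORF2
  o1 <- paste0(revtrans(rdrp, force = list("1" = "ATG")), "TAA")
  o2 <- paste0(revtrans(orf2, force = list("1" = "ATG")), "TAA")
  body <- paste0(utr5, o1, spacer, o2)
  pad <- L - nchar(body)
  if (pad < 0L) mv_stop("BadParameter", "fusarivirus plan exceeds length")
  seg <- new_seg("fusarivirus_seg1", paste0(body, sample_bases(pad)))
  s1 <- utr5_len
  s2 <- utr5_len + nchar(o1) + nchar(spacer)
  list(segments = list(seg),
       truth = list(codon_table = "standard", rdrp_segment = 1L,
                    rdrp_model = "RdRP_2",
                    orfs = data.frame(segment = seg$id, start = c(s1, s2),
                                      end = c(s1 + nchar(o1), s2 + nchar(o2)),
                                      aa_len = c(rdrp_aa, orf2_aa),
                                      stringsAsFactors = FALSE),
                    features = list(triad = list(label = "GDD"))))
}

#' Build a synthetic contig pool: decoy transcripts plus viral segments
#'
#' Decoys are random-composition ORF-bearing transcripts without RdRP motif
#' blocks, emulating the host contigs left after genome subtraction and
#' assembly. Contigs are shuffled deterministically.
#'
#' @param n_decoys Number of decoy transcripts.
#' @param viruses List of [make_virus()] results (may be empty).
#' @param seed Integer seed.
#' @return List with `contigs` (list of `nuc_seq`) and `truth` (data.frame
#'   `contig_id`, `type`, `archetype`, `is_rdrp`).
#' @export
make_transcriptome <- function(n_decoys, viruses = list(), seed = 1L) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(seed + 7L)
  contigs <- list()
  truth <- list()
  for (v in viruses) {
    for (k in seq_along(v$segments)) {
      s <- v$segments[[k]]
      contigs[[length(contigs) + 1L]] <- s
      truth[[length(truth) + 1L]] <- data.frame(
        contig_id = s$id, type = "virus", archetype = v$truth$archetype,
        is_rdrp = k == v$truth$rdrp_segment, stringsAsFactors = FALSE)
    }
  }
  if (n_decoys > 0L) for (i in seq_len(n_decoys)) {
    len <- sample(600:3000, 1L)
    n_aa <- sample(120:min(300L, (len - 80L) %/% 3L), 1L)
    prot <- paste0("M", random_protein(n_aa - 1L, sanitize = FALSE))
    utr5 <- make_utr5(40L)
    orf <- paste0(revtrans(prot, force = list("1" = "ATG")), "TAA")
    pad <- max(0L, len - 40L - nchar(orf))
    id <- sprintf("decoy_%03d", i)
    contigs[[length(contigs) + 1L]] <- new_seg(id, paste0(utr5, orf,
                                                          sample_bases(pad)))
    truth[[length(truth) + 1L]] <- data.frame(
      contig_id = id, type = "decoy", archetype = NA_character_,
      is_rdrp = FALSE, stringsAsFactors = FALSE)
  }
  if (length(contigs) == 0L)
    return(list(contigs = list(),
                truth = data.frame(contig_id = character(),
                                   type = character(),
                                   archetype = character(),
                                   is_rdrp = logical(),
                                   stringsAsFactors = FALSE)))
  ord <- sample.int(length(contigs))
  list(contigs = contigs[ord], truth = do.call(rbind, truth)[ord, ,
                                                             drop = FALSE])
}

#' Simulate reads from genome segments with truth coverage
#'
#' Uniform start positions on both strands, substitution errors at
#' `error_rate`, constant quality `I`.
#'
#' @param segments List of `nuc_seq`.
#' @param depth Mean fold coverage (> 0).
#' @param read_len Read length (>= 30).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return List with `reads` (list of `nuc_seq`; id encodes segment, start,
#'   strand), `quality` (constant character), `coverage` (named list of
#'   per-base truth counts per segment).
#' @export
make_reads <- function(segments, depth = 30, read_len = 100L,
                       error_rate = 0, seed = 1L) {
  if (depth <= 0) mv_stop("BadParameter", "depth must be > 0")
  if (read_len < 30L) mv_stop("BadParameter", "read_len must be >= 30")
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(seed + 13L)
  segments <- lapply(segments, as_nuc_seq)
  reads <- list()
  coverage <- list()
  for (seg in segments) {
    if (read_len > seg$length)
      mv_stop("ReadLongerThanSegment", "read_len %d > segment %s (%d nt)",
              read_len, seg$id, seg$length)
    n <- max(1L, round(depth * seg$length / read_len))
    counts <- integer(seg$length)
    for (i in seq_len(n)) {
      s0 <- sample.int(seg$length - read_len + 1L, 1L) - 1L
      counts[(s0 + 1L):(s0 + read_len)] <- counts[(s0 + 1L):(s0 + read_len)] + 1L
      r <- substr(seg$residues, s0 + 1L, s0 + read_len)
      if (error_rate > 0) {
        ch <- strsplit(r, "", fixed = TRUE)[[1]]
        err <- which(stats::runif(read_len) < error_rate)
        for (e in err) ch[e] <- sample(setdiff(c("A", "C", "G", "T"), ch[e]), 1L)
        r <- paste(ch, collapse = "")
      }
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-")
        r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
      reads[[length(reads) + 1L]] <- new_seg(
        sprintf("%s_read%05d_%d%s", seg$id, i, s0, strand), r)
    }
    coverage[[seg$id]] <- counts
  }
  list(reads = reads, quality = "I", coverage = coverage)
}

#' Write reads to FASTQ (constant quality)
#'
#' @param reads List of `nuc_seq` as from [make_reads()].
#' @param path Output path.
#' @param quality Quality character (default `"I"`).
#' @export
write_fastq <- function(reads, path, quality = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    writeLines(c(paste0("@", r$id), r$residues, "+",
                 strrep(quality, r$length)), con)
  }
  invisible(path)
}
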