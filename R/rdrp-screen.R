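# Triage of predicted proteins for viral RdRP motif signatures: a
# position-specific score matrix (PSSM) block scanner with decoy-calibrated
# e-value-like statistics, plus ingestion of HMMER3 per-domain tabular output
# for bit-exact parity with an external profile search.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.mv_env <- new.env(parent = emptyenv())

# log2-odds PSSM from a consensus string: consensus residue probability 0.7,
# remaining mass spread over the other 19; uniform background. The extra "X"
# row scores unknown residues as mismatches.
block_pssm <- function(consensus) {
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  p_cons <- 0.7
  p_miss <- (1 - p_cons) / 19
  hit <- log2(p_cons * 20)
  miss <- log2(p_miss * 20)
  m <- matrix(miss, nrow = 21L, ncol = length(ch),
              dimnames = list(c(AA20, "X"), NULL))
  for (j in seq_along(ch)) m[ch[j], j] <- hit
  m
}

#' Construct an RdRP profile model from ordered motif blocks
#'
#' @param name Model name.
#' @param block_consensus Character vector of consensus peptides, one per
#'   ungapped motif block, in genome order.
#' @return Uncalibrated `profile_model`; calibrate with [calibrate_model()].
#' @export
profile_model <- function(name, block_consensus) {
  blocks <- lapply(block_consensus, function(cs)
    list(consensus = cs, pssm = block_pssm(cs),
         max_score = sum(apply(block_pssm(cs), 2L, max))))
  structure(list(name = name, blocks = blocks,
                 background = stats::setNames(rep(1 / 20, 20), AA20),
                 calibration = NULL),
            class = "profile_model")
}

aa_index <- function(aa) {
  idx <- match(strsplit(toupper(aa), "", fixed = TRUE)[[1]], AA20)
  idx[is.na(idx)] <- 21L
  idx
}

# sliding-window block scores: score of the block starting at each position
block_scores <- function(aa_idx, pssm) {
  n <- length(aa_idx)
  Lb <- ncol(pssm)
  if (n < Lb) return(numeric(0))
  n_pos <- n - Lb + 1L
  s <- numeric(n_pos)
  for (j in seq_len(Lb)) s <- s + unname(pssm[aa_idx[j:(j + n_pos - 1L)], j])
  s
}

# best in-order, non-overlapping placement of all blocks; returns the chain
# score, per-block placements (1-based starts) and per-block scores
best_chain <- function(aa_idx, blocks) {
  B <- length(blocks)
  svecs <- lapply(blocks, function(b) block_scores(aa_idx, b$pssm))
  if (any(vapply(svecs, length, integer(1)) == 0L)) return(NULL)
  lens <- vapply(blocks, function(b) ncol(b$pssm), integer(1))
  n1 <- length(svecs[[1]])
  best <- svecs[[1]]
  arg <- list(seq_len(n1))
  for (b in seq_len(B - 1L)) {
    nb <- length(svecs[[b + 1L]])
    # running max of best over block-b starts ending before position i
    prev_best <- rep(-Inf, nb)
    prev_arg <- rep(0L, nb)
    run <- -Inf; run_arg <- 0L; scanned <- 0L
    for (i in seq_len(nb)) {
      limit <- min(i - lens[b], length(best))
      while (scanned < limit) {
        scanned <- scanned + 1L
        if (best[scanned] > run) { run <- best[scanned]; run_arg <- scanned }
      }
      prev_best[i] <- run
      prev_arg[i] <- run_arg
    }
    best <- svecs[[b + 1L]] + prev_best
    arg[[b + 1L]] <- prev_arg
  }
  if (!any(is.finite(best))) return(NULL)
  i <- which.max(best)
  score <- best[i]
  starts <- integer(B)
  starts[B] <- i
  if (B > 1L) for (b in seq(B - 1L, 1L)) starts[b] <- arg[[b + 1L]][starts[b + 1L]]
  list(score = score,
       starts = starts,
       block_scores = vapply(seq_len(B),
                             function(b) svecs[[b]][starts[b]], numeric(1)),
       ends = starts + lens - 1L)
}

#' Calibrate a profile model on shuffled decoys
#'
#' Scores `n_decoys` random background proteins, fits a Gumbel null by the
#' method of moments, and stores it; the e-value-like statistic of a hit is
#' the Gumbel exceedance probability scaled by the search size.
#'
#' @param model A `profile_model`.
#' @param n_decoys Number of decoys (default 200).
#' @param decoy_len Decoy protein length (default 300).
#' @param seed RNG seed recorded in the calibration.
#' @return The calibrated model.
#' @export
calibrate_model <- function(model, n_decoys = 200L, decoy_len = 300L,
                            seed = 20001L) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  scores <- vapply(seq_len(n_decoys), function(i) {
    idx <- sample.int(20L, decoy_len, replace = TRUE)
    ch <- best_chain(idx, model$blocks)
    if (is.null(ch)) -Inf else ch$score
  }, numeric(1))
  scores <- scores[is.finite(scores)]
  sc <- stats::sd(scores) * sqrt(6) / pi
  loc <- mean(scores) - 0.5772156649 * sc
  model$calibration <- list(location = loc, scale = sc,
                            n_decoys = n_decoys, decoy_len = decoy_len,
                            seed = seed)
  model
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

gumbel_exceedance <- function(s, calibration) {
  z <- (s - calibration$location) / calibration$scale
  # 1 - exp(-exp(-z)), stable for large z
  if (z > 30) exp(-z) else 1 - exp(-exp(-z))
}

#' Bundled RdRP profile models
#'
#' Six toy motif-block profiles named after the viral RdRP profile families
#' used for triage (RdRP_1 to RdRP_5 and Mitovir_RNA_pol). Each carries three
#' ungapped blocks mimicking the conserved polymerase motifs (an aspartate-rich
#' motif A, a glycine/serine motif B, and the catalytic triad context of motif
#' C). They are designed for synthetic-data recovery; real profile HMMs enter
#' through the external domtblout path. Models are calibrated once per session
#' (seeds recorded in each model).
#'
#' @return Named list of calibrated `profile_model` objects.
#' @export
default_models <- function() {
  if (!is.null(.mv_env$models)) return(.mv_env$models)
  spec <- list(
    RdRP_1 = c("DFSKFDQSQG", "SGQPGTSLGN", "SLYGDDSLIS"),
    RdRP_2 = c("DYDDFNSQHS", "GLPSGSPITS", "VMSGDDSLMI"),
    RdRP_3 = c("DWSAFDKSQH", "TGSPGTSILN", "AIMGDDSVEG"),
    RdRP_4 = c("DASRFDQHVS", "GMPSGMPLTS", "TLQGDDVLIA"),
    RdRP_5 = c("DLSAFDSSVS", "NGMPSGSYFT", "CVHGDDLIVS"),
    Mitovir_RNA_pol = c("DLFSFDASVS", "RGSPMSSILS", "KFAGDDVFLT"))
  models <- vector("list", length(spec))
  names(models) <- names(spec)
  for (i in seq_along(spec)) {
    m <- profile_model(names(spec)[i], spec[[i]])
    models[[i]] <- calibrate_model(m, seed = 20000L + i)
  }
  .mv_env$models <- models
  models
}

#' Scan one ORF protein against a profile model
#'
#' Finds the best-scoring in-order, non-overlapping placement of the model's
#' motif blocks. A hit is reported only when every block reaches
#' `floor_frac` of its maximum attainable score; the e-value-like statistic
#' is the calibrated Gumbel exceedance of the chain score times
#' `search_size`.
#'
#' @param aa ORF protein string (or a [find_orfs()] row, from which `aa` is
#'   taken).
#' @param model Calibrated `profile_model`.
#' @param search_size Number of ORFs in the enclosing search (default 1).
#' @param floor_frac Per-block score floor as a fraction of the block maximum
#'   (default 0.6).
#' @return List of class `profile_hit` (`model_name`, `bit_score`, `evalue`,
#'   `ali_start`, `ali_end` 0-based half-open aa coordinates,
#'   `block_starts`), or NULL.
#' @export
scan_orf <- function(aa, model, search_size = 1L, floor_frac = 0.6) {
  if (is.null(model$calibration))
    mv_stop("UncalibratedModel", "model '%s' is not calibrated", model$name)
  if (is.data.frame(aa)) aa <- aa$aa[1]
  idx <- aa_index(aa)
  ch <- best_chain(idx, model$blocks)
  if (is.null(ch)) return(NULL)
  floors <- floor_frac * vapply(model$blocks, function(b) b$max_score,
                                numeric(1))
  if (any(ch$block_scores < floors)) return(NULL)
  ev <- search_size * gumbel_exceedance(ch$score, model$calibration)
  structure(list(model_name = model$name, bit_score = ch$score, evalue = ev,
                 ali_start = ch$starts[1] - 1L, ali_end = ch$ends[length(ch$ends)],
                 block_starts = ch$starts - 1L),
            class = "profile_hit")
}

#' Parse HMMER3 per-domain tabular output (domtblout)
#'
#' One hit per domain row; `#` comment lines are skipped. Field mapping:
#' target name (the profile), query name (the protein), i-Evalue, domain
#' score, and alignment coordinates converted from 1-based inclusive to
#' 0-based half-open.
#'
#' @param path File path (or connection) of domtblout text.
#' @return data.frame with `seq_id`, `model_name`, `bit_score`, `evalue`,
#'   `ali_start`, `ali_end`.
#' @export
parse_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) < 22L)
      mv_stop("MalformedRow", "domtblout row %d has %d columns (need >= 22)",
              i, length(f))
    out[[i]] <- data.frame(
      seq_id = f[4], model_name = f[1],
      bit_score = as.numeric(f[14]), evalue = as.numeric(f[13]),
      ali_start = as.integer(f[18]) - 1L, ali_end = as.integer(f[19]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(), model_name = character(),
                      bit_score = numeric(), evalue = numeric(),
                      ali_start = integer(), ali_end = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  if (any(!is.finite(df$evalue)) || any(df$evalue < 0))
    mv_stop("MalformedRow", "non-finite or negative i-Evalue in domtblout")
  df
}

#' Write hits in the HMMER3 domtblout dialect (fixture writer)
#'
#' @param hits data.frame as returned by [parse_domtblout()].
#' @param path Output path.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", "target name", "accession", "tlen", "query name",
                   "accession", "qlen", "E-value", "score", "bias", "#",
                   "of", "c-Evalue", "i-Evalue", "score", "bias", "from",
                   "to", "from", "to", "from", "to", "acc",
                   "description of target", sep = " "), con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    qlen <- h$ali_end + 10L
    writeLines(sprintf(
      "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 1 %d %d %d %d %d 0.90 -",
      h$model_name, 100L, h$seq_id, qlen, h$evalue, h$bit_score,
      h$evalue, h$evalue, h$bit_score, h$ali_end - h$ali_start,
      h$ali_start + 1L, h$ali_end, h$ali_start + 1L, h$ali_end), con)
  }
  invisible(path)
}

#' Classify the RdRP catalytic triad
#'
#' Searches for the motif-C/VI tripeptide: canonical GDD, the SDD and ADD
#' variants, or the GDN triad. When a profile hit is supplied, matches inside
#' its alignment are preferred; otherwise the first match wins.
#'
#' @param aa Protein string.
#' @param window Optional 0-based half-open aa range `c(start, end)` to
#'   restrict the search.
#' @param hit Optional `profile_hit` whose alignment range is preferred.
#' @return List of class `triad_call`: `label` (`"GDD"`, `"SDD"`, `"ADD"`,
#'   `"GDN"`, or `"none"`) and `position` (0-based offset of the first
#'   residue, NA for none).
#' @export
classify_triad <- function(aa, window = NULL, hit = NULL) {
  if (!nzchar(aa)) mv_stop("EmptySequence", "empty protein")
  s <- toupper(aa)
  if (!is.null(window)) {
    s <- substr(s, window[1] + 1L, window[2])
    offset <- window[1]
  } else offset <- 0L
  m <- gregexpr("GDD|SDD|ADD|GDN", s)[[1]]
  if (m[1] == -1L)
    return(structure(list(label = "none", position = NA_integer_),
                     class = "triad_call"))
  pos <- as.integer(m) - 1L + offset
  labels <- regmatches(s, gregexpr("GDD|SDD|ADD|GDN", s))[[1]]
  pick <- 1L
  if (!is.null(hit)) {
    inside <- which(pos >= hit$ali_start & pos + 3L <= hit$ali_end)
    if (length(inside) > 0L) pick <- inside[1]
  }
  structure(list(label = labels[pick], position = pos[pick]),
            class = "triad_call")
}

#' Triage contigs for RdRP-bearing ORFs
#'
#' Predicts ORFs under both genetic codes, scans every ORF against every
#' model (or joins externally supplied profile-search hits by sequence/ORF
#' id), and keeps each contig's best hit at or below the e-value cutoff. The
#' permissive default cutoff of 10 follows the over-inclusive screening
#' convention for distant RdRP similarity.
#'
#' @param contigs List of `nuc_seq`.
#' @param models Named list of calibrated models (default
#'   [default_models()]).
#' @param evalue_max Keep hits with evalue at or below this (default 10).
#' @param external_hits Optional data.frame from [parse_domtblout()]; when
#'   supplied the internal scanner is not run and `seq_id` values of the form
#'   `"<contig>|orf<k>"` (or plain contig ids) are joined back to contigs.
#' @param min_len_aa Minimum ORF length for the internal scan (default 100).
#' @return data.frame with one row per flagged contig: `seq_id`, `orf_index`,
#'   `orf_start`, `orf_end`, `strand`, `codon_table`, `model_name`,
#'   `bit_score`, `evalue`, ordered by ascending evalue then `seq_id`.
#' @export
triage_contigs <- function(contigs, models = default_models(),
                           evalue_max = 10, external_hits = NULL,
                           min_len_aa = 100L) {
  if (length(contigs) == 0L) mv_stop("BadParameter", "no contigs supplied")
  contigs <- lapply(contigs, as_nuc_seq)
  ids <- vapply(contigs, function(x) x$id, character(1))
  empty <- data.frame(seq_id = character(), orf_index = integer(),
                      orf_start = integer(), orf_end = integer(),
                      strand = character(), codon_table = character(),
                      model_name = character(), bit_score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE)
  rows <- list()
  if (is.null(external_hits)) {
    all_orfs <- lapply(contigs, function(ctg) {
      o1 <- find_orfs(ctg, "standard", min_len_aa = min_len_aa)
      o2 <- find_orfs(ctg, "mold_mito", min_len_aa = min_len_aa)
      o <- rbind(o1, o2)
      # the two codes agree except across TGA; drop duplicated calls
      o[!duplicated(o[, c("start", "end", "strand", "aa")]), , drop = FALSE]
    })
    n_orfs_total <- sum(vapply(all_orfs, nrow, integer(1)))
    for (ci in seq_along(contigs)) {
      orfs <- all_orfs[[ci]]
      best <- NULL
      for (oi in seq_len(nrow(orfs))) {
        for (m in models) {
          h <- scan_orf(orfs$aa[oi], m, search_size = max(1L, n_orfs_total))
          if (is.null(h) || h$evalue > evalue_max) next
          better <- is.null(best) || h$evalue < best$evalue ||
            (h$evalue == best$evalue &&
               (h$bit_score > best$bit_score ||
                  (h$bit_score == best$bit_score &&
                     h$model_name < best$model_name)))
          if (better) best <- c(h, list(orf_index = oi))
        }
      }
      if (!is.null(best)) {
        oi <- best$orf_index
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = ids[ci], orf_index = oi,
          orf_start = orfs$start[oi], orf_end = orfs$end[oi],
          strand = orfs$strand[oi], codon_table = orfs$codon_table[oi],
          model_name = best$model_name, bit_score = best$bit_score,
          evalue = best$evalue, stringsAsFactors = FALSE)
      }
    }
  } else {
    hits <- external_hits[external_hits$evalue <= evalue_max, , drop = FALSE]
    if (nrow(hits) > 0L) {
      contig_of <- sub("\\|orf[0-9]+$", "", hits$seq_id)
      orf_of <- suppressWarnings(
        as.integer(sub("^.*\\|orf([0-9]+)$", "\\1", hits$seq_id)))
      orf_of[is.na(orf_of)] <- 1L
      for (ci in seq_along(contigs)) {
        sel <- which(contig_of == ids[ci])
        if (length(sel) == 0L) next
        sel <- sel[order(hits$evalue[sel], -hits$bit_score[sel],
                         hits$model_name[sel])]
        h <- hits[sel[1], ]
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = ids[ci], orf_index = orf_of[sel[1]],
          orf_start = NA_integer_, orf_end = NA_integer_,
          strand = NA_character_, codon_table = NA_character_,
          model_name = h$model_name, bit_score = h$bit_score,
          evalue = h$evalue, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  df <- do.call(rbind, rows)
  df <- df[order(df$evalue, df$seq_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
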