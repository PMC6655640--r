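# Machine-readable catalog of the 59 mycoviral genomes, summary statistics,
# candidate characterization, and the end-to-end pipeline driver.

CATALOG_COLUMNS <- c("host", "virus_family", "virus_name", "abbrev",
                     "virus_class", "bioproject_sra", "segment_number",
                     "length_nt", "accession", "protein_id", "length_aa")

#' Path of the packaged mycovirus catalog
#'
#' @return File path of the catalog TSV shipped with the package.
#' @export
catalog_path <- function() {
  system.file("extdata", "mycovirus_catalog.tsv", package = "mycovir",
              mustWork = TRUE)
}

#' Load a mycovirus catalog TSV
#'
#' One input row per protein; rows sharing a virus abbreviation are grouped
#' into a single entry whose `segments` table lists each (segment, protein).
#'
#' @param path TSV path (default: the packaged catalog).
#' @return List of `catalog_entry` objects (`host`, `virus_family`,
#'   `virus_name`, `abbrev`, `virus_class`, `bioproject_sra`, `segments`
#'   data.frame).
#' @export
load_catalog <- function(path = catalog_path()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(CATALOG_COLUMNS, colnames(df))
  if (length(missing) > 0L)
    mv_stop("MissingColumn", "catalog lacks column(s): %s",
            paste(missing, collapse = ", "))
  if (!all(df$virus_class %in% c("dsRNA", "(+)ssRNA", "ssRNA")))
    mv_stop("InvalidClass", "virus_class outside {dsRNA, (+)ssRNA, ssRNA}")
  if (any(df$length_nt <= 0) || any(df$length_aa <= 0))
    mv_stop("InvalidClass", "non-positive segment or protein length")
  entries <- lapply(split(df, factor(df$abbrev, levels = unique(df$abbrev))),
                    function(g) {
    structure(list(
      host = g$host[1], virus_family = g$virus_family[1],
      virus_name = g$virus_name[1], abbrev = g$abbrev[1],
      virus_class = g$virus_class[1], bioproject_sra = g$bioproject_sra[1],
      segments = data.frame(segment_number = g$segment_number,
                            length_nt = g$length_nt,
                            accession = g$accession,
                            protein_id = g$protein_id,
                            length_aa = g$length_aa,
                            stringsAsFactors = FALSE)),
      class = "catalog_entry")
  })
  unname(entries)
}

#' Summary statistics over a virus catalog
#'
#' Tallies viruses, unique hosts (distinct species + strain strings), genome
#' classes and families; computes per-virus combined genome length (the sum
#' of its distinct segment lengths) and the two-way strand shares used for
#' genome-type breakdowns, where genomes of undetermined polarity (`ssRNA`)
#' are grouped with the positive-strand class. Percentages are rounded to the
#' nearest integer, half away from zero.
#'
#' @param entries List of `catalog_entry` from [load_catalog()].
#' @return List of class `summary_stats`: `n_viruses`, `n_hosts`,
#'   `class_counts`, `family_counts`, `class_percent` (three-way),
#'   `share_dsRNA` / `share_ssRNA_positive` (two-way percents),
#'   `combined_length_nt` (named per virus).
#' @export
summarize_catalog <- function(entries) {
  if (length(entries) == 0L) mv_stop("BadParameter", "empty catalog")
  abbrev <- vapply(entries, function(e) e$abbrev, character(1))
  hosts <- vapply(entries, function(e) e$host, character(1))
  cls <- vapply(entries, function(e) e$virus_class, character(1))
  fam <- vapply(entries, function(e) e$virus_family, character(1))
  combined <- vapply(entries, function(e) {
    segs <- unique(e$segments[, c("segment_number", "length_nt")])
    sum(segs$length_nt)
  }, numeric(1))
  names(combined) <- abbrev
  n <- length(entries)
  class_counts <- table(factor(cls, levels = c("dsRNA", "(+)ssRNA", "ssRNA")))
  round_half_up <- function(x) floor(x + 0.5)
  class_percent <- round_half_up(100 * as.numeric(class_counts) / n)
  names(class_percent) <- names(class_counts)
  n_ds <- sum(cls == "dsRNA")
  structure(list(
    n_viruses = n,
    n_hosts = length(unique(hosts)),
    class_counts = class_counts,
    family_counts = sort(table(fam), decreasing = TRUE),
    class_percent = class_percent,
    share_dsRNA = round_half_up(100 * n_ds / n),
    share_ssRNA_positive = round_half_up(100 * (n - n_ds) / n),
    combined_length_nt = combined), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> %d viruses from %d hosts\n",
              x$n_viruses, x$n_hosts))
  print(x$class_counts)
  cat(sprintf("dsRNA %d%%, (+)ssRNA (incl. undetermined polarity) %d%%\n",
              x$share_dsRNA, x$share_ssRNA_positive))
  invisible(x)
}

#' Characterize a candidate viral genome
#'
#' Runs the feature detectors on one (possibly multi-segment) candidate:
#' ORFs under both genetic codes, RdRP triage hit and catalytic triad, A+U
#' content, slippery sites near the first ORF junction, stop/start junction
#' classification, amber readthrough, UTR extraction, and the conserved 5'
#' UTR block for multi-segment candidates.
#'
#' @param segments List of `nuc_seq`.
#' @param models Profile models (default [default_models()]).
#' @param family Optional family name to attach a genome class.
#' @param min_len_aa Minimum ORF length (default 100).
#' @return List of class `genome_report`.
#' @export
characterize_genome <- function(segments, models = default_models(),
                                family = NULL, min_len_aa = 100L) {
  segments <- lapply(segments, as_nuc_seq)
  seg_reports <- lapply(segments, function(seg) {
    orfs <- rbind(find_orfs(seg, "standard", min_len_aa = min_len_aa),
                  find_orfs(seg, "mold_mito", min_len_aa = min_len_aa))
    orfs <- orfs[!duplicated(orfs[, c("start", "end", "strand", "aa")]), ,
                 drop = FALSE]
    best_hit <- NULL; best_orf <- NA_integer_
    for (i in seq_len(nrow(orfs))) {
      for (m in models) {
        h <- scan_orf(orfs$aa[i], m)
        if (!is.null(h) && (is.null(best_hit) || h$evalue < best_hit$evalue)) {
          best_hit <- h; best_orf <- i
        }
      }
    }
    triad <- if (!is.null(best_hit))
      classify_triad(orfs$aa[best_orf], hit = best_hit) else NULL
    fwd <- orfs[orfs$strand == "+", , drop = FALSE]
    fwd <- fwd[order(fwd$end), , drop = FALSE]
    # primary gene models: drop short spurious calls relative to the
    # segment's largest ORF before junction/UTR interpretation
    if (nrow(fwd) > 0L)
      fwd <- fwd[nchar(fwd$aa) >= 0.3 * max(nchar(fwd$aa)), , drop = FALSE]
    junction <- NULL; readthrough <- NULL; slippery <- NULL
    if (nrow(fwd) >= 2L) {
      for (i in seq_len(nrow(fwd) - 1L)) {
        for (j in seq(i + 1L, nrow(fwd))) {
          junction <- find_junction(fwd[i, ], fwd[j, ], seg)
          if (!is.null(junction)) break
        }
        if (!is.null(junction)) break
      }
      win <- c(max(0L, fwd$end[1] - 60L), min(seg$length, fwd$end[1] + 7L))
      sl <- find_slippery_sites(seg, window = win)
      if (nrow(sl) > 0L) slippery <- sl
    }
    if (nrow(fwd) >= 1L) readthrough <- find_readthrough(fwd, seg)
    utrs <- if (nrow(fwd) >= 1L) extract_utrs(seg, fwd) else NULL
    list(id = seg$id, length = seg$length, orfs = orfs,
         at_percent = at_content(seg), hit = best_hit, triad = triad,
         junction = junction, readthrough = readthrough,
         slippery = slippery, utrs = utrs)
  })
  utr5s <- Filter(function(u) !is.null(u) && u$length >= 13L,
                  lapply(seg_reports, function(r)
                    if (is.null(r$utrs)) NULL else r$utrs$utr5))
  utr_block <- if (length(utr5s) >= 2L)
    conserved_utr_motif(utr5s, min_len = 13L)
    else NULL
  structure(list(
    segments = seg_reports,
    utr5_consensus = utr_block,
    genome_class = if (!is.null(family)) assign_genome_class(family)
                   else NA_character_,
    family = family), class = "genome_report")
}

#' Validate detector outputs on user-downloaded reference genomes
#'
#' Runs the slippery-site detector and coding-strand A+U computation on
#' sequences the user has fetched (e.g. GenBank records saved as FASTA).
#' This path exists for cross-checking published genome features; it never
#' downloads anything itself.
#'
#' @param fasta Path to a FASTA of reference genome sequences.
#' @return data.frame with one row per record: `id`, `length`, `at_percent`,
#'   `first_slippery_pos_1based` (NA when none found) and
#'   `slippery_positions_1based` (all non-homopolymer sites in the window
#'   upstream of the first ORF's stop, `;`-joined).
#' @export
validate_genome_features <- function(fasta) {
  if (!file.exists(fasta))
    mv_stop("MissingInput",
            "reference FASTA '%s' not found; download the records first",
            fasta)
  seqs <- read_fasta(fasta)
  rows <- lapply(seqs, function(s) {
    orfs <- find_orfs(s, "standard", min_len_aa = 100L)
    fwd <- orfs[orfs$strand == "+", , drop = FALSE]
    slip <- NA_integer_; all_slip <- ""
    if (nrow(fwd) > 0L) {
      fwd <- fwd[order(fwd$end), , drop = FALSE]
      fwd <- fwd[nchar(fwd$aa) >= 0.3 * max(nchar(fwd$aa)), , drop = FALSE]
      win <- c(max(0L, fwd$end[1] - 80L), min(s$length, fwd$end[1] + 7L))
      sl <- find_slippery_sites(s, window = win)
      sl <- sl[!sl$low_complexity, , drop = FALSE]
      if (nrow(sl) > 0L) {
        slip <- sl$position[1] + 1L                     # report 1-based
        all_slip <- paste(sl$position + 1L, collapse = ";")
      }
    }
    data.frame(id = s$id, length = s$length, at_percent = at_content(s),
               first_slippery_pos_1based = slip,
               slippery_positions_1based = all_slip, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the post-assembly discovery pipeline on a contig set
#'
#' Triage (internal scanner or external profile-search hits), per-candidate
#' characterization, and optional species demarcation when reference
#' identities are supplied. Deterministic given the same configuration.
#'
#' @param config List (or path to a flat `key = value` text file) with
#'   entries: `contigs` (FASTA path) or `contig_seqs` (list of `nuc_seq`);
#'   optional `domtblout` (external hits path), `evalue_max` (default 10),
#'   `min_len_aa` (default 100), `identities` (data.frame for
#'   [demarcate()]: columns `taxon`, `rdrp`, `cp`, `nt`, `orf1`, `host`,
#'   `known_hosts` semicolon-separated), `seed` (recorded in the log).
#' @return List of class `pipeline_report`: `candidates` (triage table),
#'   `reports` (per-candidate `genome_report`), `species_calls`, `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_flat_config(config)
  contigs <- if (!is.null(config$contig_seqs)) {
    lapply(config$contig_seqs, as_nuc_seq)
  } else if (!is.null(config$contigs)) {
    read_fasta(config$contigs)
  } else mv_stop("BadParameter", "config must name contigs or contig_seqs")
  evalue_max <- if (is.null(config$evalue_max)) 10 else
    as.numeric(config$evalue_max)
  min_len_aa <- if (is.null(config$min_len_aa)) 100L else
    as.integer(config$min_len_aa)
  external <- if (!is.null(config$domtblout)) parse_domtblout(config$domtblout)
              else NULL
  models <- default_models()
  cand <- triage_contigs(contigs, models = models, evalue_max = evalue_max,
                         external_hits = external, min_len_aa = min_len_aa)
  by_id <- stats::setNames(contigs, vapply(contigs, function(x) x$id,
                                           character(1)))
  reports <- lapply(cand$seq_id, function(id)
    characterize_genome(list(by_id[[id]]), models = models,
                        min_len_aa = min_len_aa))
  names(reports) <- cand$seq_id
  species_calls <- NULL
  if (!is.null(config$identities)) {
    ids <- config$identities
    species_calls <- lapply(seq_len(nrow(ids)), function(i) {
      met <- c("rdrp", "cp", "nt", "orf1")
      vals <- unlist(ids[i, intersect(met, colnames(ids))])
      vals <- vals[!is.na(vals)]
      demarcate(list(taxon = ids$taxon[i], identities = vals,
                     host = ids$host[i],
                     known_hosts = strsplit(ids$known_hosts[i], ";")[[1]]))
    })
  }
  structure(list(
    candidates = cand, reports = reports, species_calls = species_calls,
    log = list(version = as.character(utils::packageVersion("mycovir")),
               evalue_max = evalue_max, min_len_aa = min_len_aa,
               seed = config$seed,
               model_seeds = vapply(models, function(m) m$calibration$seed,
                                    numeric(1)))), class = "pipeline_report")
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(cfg) <- vapply(kv, function(p) trimws(p[1]), character(1))
  cfg
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    schema = "mycovir-report-1",
    log = report$log,
    candidates = report$candidates,
    species_calls = lapply(report$species_calls, function(sc)
      list(taxon = sc$taxon, status = sc$status)),
    features = lapply(report$reports, function(r) {
      seg <- r$segments[[1]]
      list(id = seg$id, length = seg$length,
           at_percent = seg$at_percent,
           model = if (is.null(seg$hit)) NA else seg$hit$model_name,
           evalue = if (is.null(seg$hit)) NA else seg$hit$evalue,
           triad = if (is.null(seg$triad)) NA else seg$triad$label)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
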