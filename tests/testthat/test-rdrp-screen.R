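test_that("domtblout parsing maps fields and round-trips through the writer", {
  hits <- data.frame(
    seq_id = c("contig1|orf1", "contig2|orf1", "contig9|orf3"),
    model_name = c("RdRP_1", "Mitovir_RNA_pol", "RdRP_4"),
    bit_score = c(133.6, 55.2, 20.1),
    evalue = c(3.2e-40, 1e-6, 0.5),
    ali_start = c(11L, 0L, 5L), ali_end = c(301L, 100L, 80L),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".domtblout")
  write_domtblout(hits, f)
  back <- parse_domtblout(f)
  expect_equal(back, hits)
  expect_equal(back$ali_start[1], 11L)   # 1-based 12 in the file
  expect_equal(back$ali_end[1], 301L)
  # comment-only stream
  f2 <- tempfile()
  writeLines(c("# domtblout", "# nothing here"), f2)
  expect_equal(nrow(parse_domtblout(f2)), 0L)
  # malformed row
  f3 <- tempfile()
  writeLines("model - 1 query", f3)
  expect_error(parse_domtblout(f3), class = "MalformedRow")
})

test_that("consensus emissions hit their model strongly; shuffles almost never do", {
  models <- default_models()
  m <- models$RdRP_1
  set.seed(31)
  cons <- vapply(m$blocks, function(b) b$consensus, character(1))
  prot <- paste0(random_aa(40), cons[1], random_aa(25), cons[2],
                 random_aa(25), cons[3], random_aa(40))
  h <- scan_orf(prot, m)
  expect_false(is.null(h))
  expect_lte(h$evalue, 1e-3)
  # length-matched shuffled decoys: null (or weak) in at least 95% of 200
  ch <- strsplit(prot, "")[[1]]
  set.seed(77)
  weak <- vapply(1:200, function(i) {
    d <- paste(sample(ch), collapse = "")
    hd <- scan_orf(d, m)
    is.null(hd) || hd$evalue > 10
  }, logical(1))
  expect_gte(mean(weak), 0.95)
})

test_that("block chain scoring equals an exhaustive placement oracle on small proteins", {
  two <- profile_model("toy2", c("DFSKFD", "GDDSL"))
  two <- calibrate_model(two, n_decoys = 50, decoy_len = 60, seed = 5)
  set.seed(12)
  n_hits <- 0
  for (i in 1:30) {
    aa <- if (i %% 2 == 0) {
      paste0(random_aa(sample(5:15, 1)), "DFSKFD",
             random_aa(sample(3:10, 1)), "GDDSL", random_aa(sample(3:10, 1)))
    } else random_aa(sample(20:60, 1))
    orc <- oracle_block_chain(aa, two)
    h <- scan_orf(aa, two)
    floors <- 0.6 * vapply(two$blocks, function(b) b$max_score, numeric(1))
    block_score_at <- function(b, start) {
      ch <- strsplit(aa, "")[[1]]
      sum(vapply(seq_len(ncol(b$pssm)), function(j) {
        r <- ch[start + j - 1]
        if (!(r %in% rownames(b$pssm))) r <- "X"
        b$pssm[r, j]
      }, numeric(1)))
    }
    if (!is.null(h)) {
      n_hits <- n_hits + 1
      expect_equal(h$bit_score, orc$score, tolerance = 1e-9)
      expect_equal(h$ali_start, orc$starts[1] - 1L)
    } else if (is.finite(orc$score)) {
      # a null with a feasible chain means some block missed its floor at
      # the optimum (the chain and the floor share the same optimum here
      # only when block scores are maximized jointly, so check the chain's
      # own placements)
      per_block <- vapply(seq_along(two$blocks), function(b)
        block_score_at(two$blocks[[b]], orc$starts[b]), numeric(1))
      expect_true(any(per_block < floors))
    }
  }
  expect_gte(n_hits, 10)
})

test_that("weakening one block's match strictly lowers the chain score", {
  m <- default_models()$RdRP_2
  cons <- vapply(m$blocks, function(b) b$consensus, character(1))
  set.seed(8)
  linkers <- replicate(4, random_aa(20))
  prot <- paste0(linkers[1], cons[1], linkers[2], cons[2], linkers[3],
                 cons[3], linkers[4])
  h0 <- scan_orf(prot, m)
  # mutate one residue inside block 2
  pos <- nchar(linkers[1]) + nchar(cons[1]) + nchar(linkers[2]) + 3L
  mutated <- prot
  substr(mutated, pos, pos) <- if (substr(prot, pos, pos) == "A") "C" else "A"
  h1 <- scan_orf(mutated, m)
  expect_false(is.null(h0)); expect_false(is.null(h1))
  expect_lt(h1$bit_score, h0$bit_score)
})

test_that("triage flags planted viral contigs and only those", {
  vs <- list(make_virus("mitovirus", 11), make_virus("yadokarivirus", 12),
             make_virus("ambiguivirus", 13))
  tx <- make_transcriptome(20, vs, seed = 42)
  tri <- triage_contigs(tx$contigs)
  expect_setequal(tri$seq_id, tx$truth$contig_id[tx$truth$is_rdrp])
  expect_equal(nrow(tri), 3L)
  # e-value threshold of zero empties the table; raising it is monotone
  expect_equal(nrow(triage_contigs(tx$contigs, evalue_max = 0)), 0L)
  tri_tight <- triage_contigs(tx$contigs, evalue_max = 1e-6)
  expect_true(all(tri_tight$seq_id %in% tri$seq_id))
})

test_that("externally supplied profile hits reproduce the internal flag set", {
  vs <- list(make_virus("mitovirus", 21), make_virus("fusarivirus", 22))
  tx <- make_transcriptome(10, vs, seed = 5)
  internal <- triage_contigs(tx$contigs)
  ext <- data.frame(seq_id = paste0(internal$seq_id, "|orf",
                                    internal$orf_index),
                    model_name = internal$model_name,
                    bit_score = internal$bit_score,
                    evalue = internal$evalue,
                    ali_start = 0L, ali_end = 100L,
                    stringsAsFactors = FALSE)
  f <- tempfile(); write_domtblout(ext, f)
  via_ext <- triage_contigs(tx$contigs, external_hits = parse_domtblout(f))
  expect_setequal(via_ext$seq_id, internal$seq_id)
})

test_that("catalytic triads are classified case-insensitively with profile-hit preference", {
  expect_identical(classify_triad("LKSLKGDDLIW")$label, "GDD")
  expect_identical(classify_triad("lkslkgddliw")$label, "GDD")
  expect_identical(classify_triad("PQADDNW")$label, "ADD")
  expect_identical(classify_triad("PQGDNQW")$label, "GDN")
  expect_identical(classify_triad("PQSDDQW")$label, "SDD")
  expect_identical(classify_triad("PQRSTW")$label, "none")
  tc <- classify_triad("AAGDDAA")
  expect_equal(tc$position, 2L)
  # flanking content does not change the call
  expect_identical(classify_triad(paste0(random_aa(30, seed = 2), "GDN",
                                         "QQQ"))$label,
                   classify_triad("GDN")$label)
  # a hit window steers the pick past an earlier match
  hit <- structure(list(ali_start = 10L, ali_end = 20L), class = "profile_hit")
  both <- "AAGDDAAAAAAAGDNAAAAAA"
  expect_identical(classify_triad(both, hit = hit)$label, "GDN")
  expect_identical(classify_triad(both)$label, "GDD")
})

test_that("scanning an uncalibrated model is an error", {
  raw <- profile_model("raw", c("DFSKFD"))
  expect_error(scan_orf("DFSKFDAAAA", raw), class = "UncalibratedModel")
})
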