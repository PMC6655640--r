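test_that("slippery-site detection matches a brute-force heptamer scan", {
  base <- random_dna(200, seed = 15)
  seq1 <- paste0(substr(base, 1, 50), "GGGTTTT", substr(base, 58, 200))
  sites <- find_slippery_sites(seq1, window = c(40L, 70L))
  expect_true(50 %in% sites$position)
  row <- sites[sites$position == 50, ]
  expect_identical(row$x, "G"); expect_identical(row$y, "T")
  expect_false(row$low_complexity)
  # homopolymer heptamer admitted but flagged
  s2 <- find_slippery_sites("CCAAAAAACGG")
  expect_true(any(s2$x == "A" & s2$y == "A" & s2$low_complexity))
  # full scans equal the oracle
  for (seed in c(3, 8)) {
    nt <- random_dna(2000, seed = seed)
    got <- find_slippery_sites(nt)
    expect_identical(got$position, oracle_slippery(nt, 0L, 2000L))
  }
  expect_error(find_slippery_sites("ACGT", window = c(0L, 10L)),
               class = "WindowOutOfBounds")
})

test_that("stop/start junction geometries are classified as in victorivirus genomes", {
  orf <- function(start, end) data.frame(start = start, end = end,
                                         strand = "+", stringsAsFactors = FALSE)
  # tetramer AUGA: ORF2 ATG overlaps the first two bases of the TGA stop
  g1 <- paste0("ATGAAACCA", "TGA", "CCCAAATAA")  # ORF1 [0,12); ATG at 8
  j1 <- find_junction(orf(0, 12), orf(8, 20), g1)
  expect_identical(j1$kind, "tetramer_AUGA")
  expect_equal(j1$frame_shift, -1L)
  expect_identical(j1$junction_string, "ATGA")
  # pentamer overlap: stop TAA shares its last base with the ATG
  g2 <- paste0("ATGAAACCC", "TAA", "TG", "CCCAAATAA")
  j2 <- find_junction(orf(0, 12), orf(11, 23), g2)
  expect_identical(j2$kind, "pentamer_overlap")
  expect_equal(j2$frame_shift, -1L)
  expect_identical(j2$junction_string, "TAATG")
  # spaced: start codon, 2-nt spacer, then the stop (+1 frame)
  g3 <- paste0("ATGAAACCCCATGCATGA", "TCCCTTTAAATAA")
  # ORF1 [0,18) ends ...ATG-CA-TGA; ORF2 ATG at 10
  j3 <- find_junction(orf(0, 18), orf(10, 31), g3)
  expect_identical(j3$kind, "spaced")
  expect_equal(j3$frame_shift, 1L)
  expect_identical(j3$junction_string, "ATGCATGA")
  # distant ORFs are independent
  g4 <- paste0("ATGAAATAA", strrep("C", 30), "ATGCCCTAA")
  expect_null(find_junction(orf(0, 9), orf(39, 48), g4))
  expect_error(find_junction(orf(10, 30), orf(0, 9), g4),
               class = "OrfOrderViolation")
})

test_that("amber readthrough requires a TAG stop and an in-frame continuation", {
  v <- make_virus("ambiguivirus", 3)
  seg <- v$segments[[1]]
  rt <- find_readthrough(primary_fwd_orfs(seg), seg)
  expect_false(is.null(rt))
  expect_identical(rt$stop_codon, "TAG")
  expect_true(rt$orf2_in_same_frame)
  expect_equal(rt$fused_length_aa,
               v$truth$features$readthrough$fused_length_aa)
  # TAA-terminated ORF is not readthrough
  g <- paste0("ATG", strrep("GCA", 60), "TAA", strrep("GCA", 60), "TAA")
  orfs <- find_orfs(g, min_len_aa = 10)
  expect_null(find_readthrough(orfs[orfs$strand == "+", ], g))
  # downstream ORF in the -1 frame (the amber frame closes immediately)
  g2 <- paste0("ATG", strrep("GCA", 60), "TAG", "TAACC",
               "ATG", strrep("GCA", 60), "TAA")
  orfs2 <- find_orfs(g2, min_len_aa = 10)
  expect_null(find_readthrough(orfs2[orfs2$strand == "+", ], g2))
})

test_that("UTR extraction slices around the forward ORFs", {
  g <- paste0("GCCGCCGCCG", "ATG", strrep("GGA", 28), "TAA",
              "CCGGCCGGCCGGCCGGCCGG")
  orfs <- find_orfs(g, min_len_aa = 10)
  u <- extract_utrs(g, orfs[orfs$strand == "+", ])
  expect_equal(u$utr5$length, 10L)
  expect_equal(u$utr3$length, 20L)
  expect_identical(paste0(u$utr5$residues,
                          substr(g, 11, 100),
                          u$utr3$residues), g)
  # ORF starting at 0 gives an empty 5' UTR
  g2 <- paste0("ATG", strrep("GGA", 28), "TAA")
  o2 <- find_orfs(g2, min_len_aa = 10)
  u2 <- extract_utrs(g2, o2[o2$strand == "+", ])
  expect_equal(u2$utr5$length, 0L)
  expect_error(extract_utrs("ACGTACGT", find_orfs("ACGTACGT")),
               class = "NoForwardOrf")
})

test_that("the conserved UTR block recovers a planted degenerate 13-mer pair", {
  # dissimilar flanks: the planted pair is the only shared signal
  u1 <- paste0(strrep("G", 25), "TCACAATATCACA", strrep("G", 30))
  u2 <- paste0(strrep("C", 18), "TCACAACATTATA", strrep("C", 37))
  cm <- conserved_utr_motif(list(normalize_sequence(u1, "u1"),
                                 normalize_sequence(u2, "u2")),
                            min_len = 13)
  expect_false(is.null(cm))
  expect_identical(toupper(cm$consensus), "TCACAAYATYAYA")
  expect_equal(cm$positions, c(25L, 18L))
  # identical UTRs: the whole UTR comes back fully conserved
  u <- normalize_sequence(random_dna(40, seed = 6), "u")
  cm2 <- conserved_utr_motif(list(u, u, u), min_len = 13)
  expect_identical(cm2$consensus, u$residues)
  expect_true(all(cm2$conservation == 1))
})

test_that("unrelated random UTRs rarely produce a conserved block at strict settings", {
  # UTRs at the length scale of partitivirus-like segments
  set.seed(1234)
  nulls <- vapply(1:100, function(i) {
    a <- normalize_sequence(random_dna(80), "a")
    b <- normalize_sequence(random_dna(80), "b")
    is.null(conserved_utr_motif(list(a, b), min_len = 13,
                                min_conservation = 0.9))
  }, logical(1))
  expect_gte(mean(nulls), 0.95)
})

test_that("degenerate motif search equals the set-containment oracle", {
  expect_equal(search_degenerate_motif("TTTCATTAGA", "TYTCATTARR"), 0L)
  u <- paste0(random_dna(40, seed = 2), "AGGGTTCC", random_dna(40))
  expect_true(40 %in% search_degenerate_motif(u, "AGGGTTCC"))
  expect_equal(search_degenerate_motif("ACGT", "N"), 0:3)
  for (pat in c("TYTCATTARR", "CTGGTTTATACTCTG", "WSNRY")) {
    nt <- random_dna(3000, seed = nchar(pat))
    expect_identical(search_degenerate_motif(nt, pat),
                     oracle_motif_scan(nt, pat))
  }
  expect_error(search_degenerate_motif("ACGT", "AZ"),
               class = "IllegalPatternCharacter")
})

test_that("coverage tracks normalize to the maximum and respect degenerate input", {
  ct <- coverage_track(c(2, 4, 4, 2))
  expect_equal(ct$normalized, c(0.5, 1, 1, 0.5))
  expect_equal(ct$mean_coverage, 3)
  z <- coverage_track(c(0, 0, 0))
  expect_equal(z$normalized, c(0, 0, 0))
  expect_equal(z$mean_coverage, 0)
  expect_error(coverage_track(c(1, 2), genome_length = 3),
               class = "LengthMismatch")
  # simulated reads at nominal depth land near the target
  v <- make_virus("partitivirus", 5)
  rd <- make_reads(v$segments, depth = 50, read_len = 100, seed = 2)
  for (seg in v$segments) {
    ct <- coverage_track(rd$coverage[[seg$id]], read_length = 100)
    expect_lt(abs(ct$mean_coverage - 50) / 50, 0.2)
  }
})

test_that("SAM and TSV coverage readers agree with hand-computed counts", {
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:ref\tLN:20",
           paste("r1", 0, "ref", 1, 60, "5M", "*", 0, 0, "ACGTA", "*",
                 sep = "\t"),
           paste("r2", 16, "ref", 4, 60, "3M2D3M", "*", 0, 0, "ACGTAC", "*",
                 sep = "\t"),
           paste("r3", 256, "ref", 1, 60, "5M", "*", 0, 0, "ACGTA", "*",
                 sep = "\t"),  # secondary: skipped
           paste("r4", 4, "ref", 0, 0, "*", "*", 0, 0, "ACGTA", "*",
                 sep = "\t"))  # unmapped: skipped
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  counts <- read_sam_coverage(f, 20L)
  exp <- integer(20)
  exp[1:5] <- exp[1:5] + 1L            # r1
  exp[c(4:6, 9:11)] <- exp[c(4:6, 9:11)] + 1L  # r2: 3M, 2D skipped, 3M
  expect_equal(counts, exp)
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("3\t5", "7\t2"), f2)
  expect_equal(read_coverage_tsv(f2, 8L), c(0L, 0L, 5L, 0L, 0L, 0L, 2L, 0L))
})

test_that("read-based extension stitches a split genome back together", {
  set.seed(90)
  genome <- normalize_sequence(random_dna(1000), "genome")
  c1 <- normalize_sequence(substr(genome$residues, 1, 400), "left")
  c2 <- normalize_sequence(substr(genome$residues, 551, 1000), "right")
  rd <- make_reads(list(genome), depth = 30, read_len = 100,
                   error_rate = 0, seed = 3)
  st <- extend_and_stitch(list(c1, c2), rd$reads, min_overlap = 30,
                          max_mismatch = 1)
  expect_false(is.null(st))
  expect_identical(st$residues, genome$residues)
  # every read is an exact substring of its segment (or its reverse
  # complement) when the error rate is zero
  fwd_ok <- vapply(rd$reads, function(r) {
    grepl(r$residues, genome$residues, fixed = TRUE) ||
      grepl(reverse_complement(r)$residues, genome$residues, fixed = TRUE)
  }, logical(1))
  expect_true(all(fwd_ok))
  # reads that never reach the gap cannot bridge it
  pos <- vapply(rd$reads, function(r)
    as.integer(sub("^.*_([0-9]+)[+-]$", "\\1", r$id)), numeric(1))
  far <- rd$reads[which(pos < 250 | pos > 700)]
  expect_null(extend_and_stitch(list(c1, c2), far, 30, 1))
})

test_that("reverse-complement reads extend as well as forward reads", {
  set.seed(91)
  genome <- normalize_sequence(random_dna(600), "g")
  c1 <- normalize_sequence(substr(genome$residues, 1, 250), "a")
  c2 <- normalize_sequence(substr(genome$residues, 351, 600), "b")
  # hand-built bridging reads, all on the minus strand
  starts <- seq(180, 320, by = 35)
  reads <- lapply(seq_along(starts), function(i) {
    r <- substr(genome$residues, starts[i], starts[i] + 99)
    reverse_complement(normalize_sequence(r, paste0("rc", i)))
  })
  st <- extend_and_stitch(list(c1, c2), reads, min_overlap = 30,
                          max_mismatch = 0)
  expect_false(is.null(st))
  expect_identical(st$residues, genome$residues)
})
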