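test_that("percent identity follows its definition on gap-free cases", {
  expect_equal(pairwise_identity("MKVLITGAQW", "MKVLITGAQW"), 100)
  expect_equal(pairwise_identity("MKVLITGAQW", "MKVLITGAQF"), 90)
  # exactly 2 mismatches over 10 aligned columns
  expect_equal(pairwise_identity("MKVLITGAQW", "MKVLITGEQF"), 80)
  nt_id <- pairwise_identity("ACGTACGT", "ACGTACGA", alphabet = "nt")
  expect_equal(nt_id, 87.5)
  expect_error(pairwise_identity("", "A"), class = "EmptySequence")
})

test_that("percent identity agrees with an exhaustive affine-gap aligner on short proteins", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(57)
  n_checked <- 0
  for (i in 1:25) {
    a <- random_aa(sample(5:12, 1))
    b <- random_aa(sample(5:12, 1))
    if (runif(1) < 0.5) {
      # make the pair related so alignments are non-trivial
      b <- paste0(substr(a, 1, 4), random_aa(3), substr(a, 5, nchar(a)))
    }
    orc <- oracle_global_identities(a, b, BLOSUM62, 10, 0.5)
    got <- pairwise_identity(a, b)
    ok_ids <- orc$identities[!is.nan(orc$identities)]
    if (length(ok_ids) == 0) next
    n_checked <- n_checked + 1
    expect_true(any(abs(got - ok_ids) < 1e-6),
                info = sprintf("%s vs %s: got %.4f, oracle {%s}", a, b, got,
                               paste(round(ok_ids, 2), collapse = ", ")))
  }
  expect_gte(n_checked, 20)
})

test_that("identity matrices are symmetric, 100 on the diagonal, and consistent with pairwise calls", {
  seqs <- c(a = "MKVLITGAWCDE", b = "MKVLITGAWCDE", c = "PQRSTNHYFILK")
  im <- identity_matrix(seqs)
  expect_true(isSymmetric(im$values))
  expect_equal(unname(diag(im$values)), c(100, 100, 100))
  expect_equal(im$values["a", "b"], 100)
  expect_equal(im$values["a", "c"], pairwise_identity(seqs["a"], seqs["c"]))
  # permuting the input permutes rows and columns consistently
  im2 <- identity_matrix(seqs[c(3, 1, 2)])
  expect_equal(im2$values[im$labels, im$labels], im$values)
  expect_error(identity_matrix(c(a = "MK", a = "MK")), class = "DuplicateLabel")
})

test_that("alignment trimming keeps exactly the columns clearing the gap threshold", {
  rows <- c("ACTG", "ACTG", "ACTG", "ACTG", "ACTG",
            "ACTG", "ACTG", "ACTG", "ACTG", "AC-G")
  # one gap in ten rows: column retained at 0.9
  expect_identical(trim_alignment(rows, 0.9), rows)
  rows2 <- rows; rows2[9] <- "AC-G"
  # two gaps in ten rows: column dropped
  expect_identical(unname(trim_alignment(rows2, 0.9)),
                   rep(c("ACG", "ACG"), c(8, 2)))
  expect_identical(trim_alignment(c("AC", "AC"), 1), c("AC", "AC"))
  # threshold 0 returns the input, threshold 1 keeps only gap-free columns
  msa <- c("A-CG", "AT-G", "ATCG")
  expect_identical(trim_alignment(msa, 0), msa)
  expect_identical(trim_alignment(msa, 1), c("AG", "AG", "AG"))
  expect_error(trim_alignment(c("AC", "ACG")), class = "RaggedAlignment")
})

test_that("the demarcation rules table carries every published threshold", {
  rules <- default_rules()
  expect_gte(nrow(rules), 13)
  expect_true(all(rules$host_required))
  chry <- rules[rules$taxon == "Chrysovirus", ]
  expect_equal(chry$rdrp_threshold, 70)
  expect_equal(chry$cp_threshold, 53)
  expect_equal(rules$rdrp_threshold[rules$taxon == "Totivirus"], 50)
  expect_equal(rules$orf1_threshold[rules$taxon == "Unirnavirus"], 70)
  expect_equal(rules$nt_threshold[rules$taxon == "Alphaendornavirus"], 75)
  expect_identical(rules$comparator[rules$taxon == "Fusarivirus"], "le")
  expect_identical(rules$comparator[rules$taxon == "Alphapartitivirus"], "le")
  expect_identical(rules$comparator[rules$taxon == "Victorivirus"], "lt")
  set_thr <- rowSums(!is.na(rules[, c("rdrp_threshold", "cp_threshold",
                                      "nt_threshold", "orf1_threshold")]))
  expect_true(all(set_thr >= 1))
})

test_that("demarcation reproduces the published worked cases", {
  # a victorivirus at 97/98 percent identity from the same host species
  v <- demarcate(list(taxon = "Victorivirus",
                      identities = c(rdrp = 97, cp = 98),
                      host = "Penicillium digitatum KH8",
                      known_hosts = "Penicillium digitatum"))
  expect_identical(v$status, "known_species")
  # a gammapartitivirus at 95/95 from a host in a related genus
  g <- demarcate(list(taxon = "Gammapartitivirus",
                      identities = c(rdrp = 95, cp = 95),
                      host = "Penicillium digitatum strain HS-F6",
                      known_hosts = "Penicillium stoloniferum"))
  expect_identical(g$status, "known_species")
  expect_true(any(grepl("genus", g$rationale$note)))
  # alphapartitiviruses far below both thresholds from new hosts
  a <- demarcate(list(taxon = "Alphapartitivirus",
                      identities = c(rdrp = 40, cp = 30),
                      host = "Clohesyomyces aquaticus",
                      known_hosts = c("Rosellinia necatrix",
                                      "Heterobasidion annosum")))
  expect_identical(a$status, "new_species")
  # inclusive comparator: equality passes for taxa published with <=
  eq <- demarcate(list(taxon = "Alphapartitivirus",
                       identities = c(rdrp = 90, cp = 80),
                       host = "Clohesyomyces aquaticus",
                       known_hosts = "Rosellinia necatrix"))
  expect_identical(eq$status, "new_species")
  # strict comparator: equality fails elsewhere
  st <- demarcate(list(taxon = "Betapartitivirus",
                       identities = c(rdrp = 90, cp = 80),
                       host = "Trichoderma citrinoviride",
                       known_hosts = "Fusarium poae"))
  expect_false(identical(st$status, "new_species"))
  # no rule exists for Alternavirus: indeterminate by design
  alt <- demarcate(list(taxon = "Alternavirus",
                        identities = c(rdrp = 93),
                        host = "Aspergillus heteromorphus",
                        known_hosts = "Aspergillus foetidus"))
  expect_identical(alt$status, "indeterminate")
  expect_error(demarcate(list(taxon = "Novavirus", identities = c(rdrp = 1),
                              host = "a b", known_hosts = "c d")),
               class = "UnknownTaxon")
})

test_that("lowering identities never flips a new-species call to known", {
  set.seed(33)
  rules <- default_rules()
  rank <- c(new_species = 2, indeterminate = 1, known_species = 0)
  for (i in 1:60) {
    taxon <- sample(rules$taxon, 1)
    ids <- c(rdrp = runif(1, 20, 100), cp = runif(1, 20, 100),
             nt = runif(1, 20, 100), orf1 = runif(1, 20, 100))
    same_host <- runif(1) < 0.5
    cand <- list(taxon = taxon, identities = ids,
                 host = "Alpha beta", known_hosts = if (same_host)
                   "Alpha beta" else "Gamma delta")
    s1 <- demarcate(cand, rules)$status
    cand$identities <- ids - runif(4, 0, 15)
    s2 <- demarcate(cand, rules)$status
    expect_gte(rank[[s2]], rank[[s1]])
  }
})

test_that("genome classes map families to their nucleic-acid type", {
  expect_identical(assign_genome_class("Partitiviridae"), "dsRNA")
  expect_identical(assign_genome_class("Hypoviridae"), "(+)ssRNA")
  expect_identical(assign_genome_class("Ambiguiviridae"), "ssRNA")
  expect_identical(assign_genome_class("Mitovirus"), "(+)ssRNA")
  expect_identical(assign_genome_class("Unclassified dsRNA"), "dsRNA")
  expect_identical(assign_genome_class("Tobamo-like virus"), "(+)ssRNA")
  expect_error(assign_genome_class("Retroviridae"), class = "UnknownFamily")
})
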