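test_that("lambda solves the Karlin-Altschul constraint", {
  # closed form: 1/4 e^lambda + 3/4 e^-lambda = 1 has root ln 3
  s1 <- scoring_scheme(match = 1, mismatch = -1)
  expect_equal(s1$lambda, log(3), tolerance = 1e-9)
  # default scheme: residual of the constraint below the bisection tolerance
  s <- scoring_scheme()
  p <- s$background
  pm <- sum(p^2)
  resid <- pm * exp(s$lambda * s$match) + (1 - pm) * exp(s$lambda * s$mismatch) - 1
  expect_lt(abs(resid), 1e-10)
  # scale invariance: doubling all scores halves lambda
  s2 <- scoring_scheme(match = 2, mismatch = -2)
  expect_equal(s2$lambda, s1$lambda / 2, tolerance = 1e-9)
  # positive expected score has no calibration
  expect_error(scoring_scheme(match = 3, mismatch = -1), "negative")
})

test_that("perfect and reverse-complement matches are found exactly", {
  s <- scoring_scheme()
  q <- "ACGTACGTACGTACG"
  subj <- genome_sequence("c1", paste0(strrep("T", 50), q, strrep("G", 50)))
  h <- local_align(q, subj, s, min_raw_score = 20)
  expect_equal(nrow(h), 1L)
  expect_equal(h$raw_score, 15L * 2L)
  expect_equal(h$identity_fraction, 1)
  expect_equal(c(h$s_start, h$s_end), c(50L, 65L))
  expect_equal(h$query_coverage, 1)

  subj_rc <- genome_sequence("c1", paste0(strrep("T", 50), rc(q), strrep("G", 50)))
  h2 <- local_align(q, subj_rc, s, min_raw_score = 20)
  expect_equal(h2$strand, "-")
  expect_equal(h2$raw_score, 30L)
  expect_equal(h2$identity_fraction, 1)
  expect_equal(c(h2$s_start, h2$s_end), c(50L, 65L))
})

test_that("reference Smith-Waterman agrees with an independent implementation", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  s <- scoring_scheme()
  set.seed(77)
  for (i in 1:20) {
    pair <- planted_pair(qlen = sample(50:120, 1), slen = sample(200:600, 1),
                         d = runif(1, 0, 0.15))
    sw <- smith_waterman(pair$query, pair$subject, s)
    ref <- Biostrings::pairwiseAlignment(pair$query, pair$subject,
                                         type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    expect_equal(sw$score, Biostrings::score(ref))
  }
})

test_that("seeded aligner reproduces full Smith-Waterman best scores", {
  s <- scoring_scheme(word_size = 8)
  set.seed(123)
  for (i in 1:40) {
    pair <- planted_pair(qlen = sample(60:200, 1), slen = sample(500:2000, 1),
                         d = runif(1, 0, 0.10))
    sw <- smith_waterman(pair$query, pair$subject, s)
    h <- local_align(pair$query, genome_sequence("c", pair$subject), s,
                     min_raw_score = 25)
    expect_equal(max(h$raw_score), sw$score)
  }
})

test_that("strand symmetry: reverse-complementing the subject mirrors hits", {
  s <- scoring_scheme(word_size = 8)
  set.seed(31)
  for (i in 1:10) {
    pair <- planted_pair(qlen = 150, slen = 1000, d = 0.05)
    L <- nchar(pair$subject)
    h1 <- local_align(pair$query, genome_sequence("c", pair$subject), s,
                      min_raw_score = 30)
    h2 <- local_align(pair$query, genome_sequence("c", rc(pair$subject)), s,
                      min_raw_score = 30)
    expect_equal(sort(h1$raw_score), sort(h2$raw_score))
    o1 <- h1[order(h1$s_start), ]
    o2 <- h2[order(-h2$s_end), ]
    expect_equal(o1$s_start, L - o2$s_end)
    expect_equal(o1$s_end, L - o2$s_start)
    expect_equal(o1$strand, chartr("+-", "-+", o2$strand))
  }
})

test_that("bit scores and E-values follow the stated formulas", {
  sch <- scoring_scheme(lambda = log(2), K = 0.5)
  h <- make_hit(raw_score = 10L)
  h <- attach_evalue(h, sch, m = 100, n = 100)
  expect_equal(h$bit_score, (10 * log(2) - log(0.5)) / log(2))  # = 11 bits
  expect_equal(h$bit_score, 11)
  expect_equal(h$e_value, 1e4 * 2^-11)

  sch2 <- scoring_scheme()
  hs <- attach_evalue(make_hit(raw_score = c(40L, 50L, 60L)), sch2, 100, 1e5)
  expect_true(all(diff(hs$e_value) < 0))  # strictly decreasing in raw score
  h_n <- attach_evalue(make_hit(raw_score = 40L), sch2, 100, 1e5)
  h_2n <- attach_evalue(make_hit(raw_score = 40L), sch2, 100, 2e5)
  expect_equal(h_2n$e_value, 2 * h_n$e_value)  # linear in search space
})

test_that("search_all unions per-query hits against the whole assembly", {
  cfg <- simulation_config(seed = 7, substitution_rate = 0, indel_rate = 0,
                           n_numts = 3L, fragment_length_range = c(400L, 900L),
                           gene_weights = c(cox1 = 1))
  g <- simulate_genome(cfg)
  genes <- extract_genes(g$mito, g$annotations)
  cox1 <- genes[[which(vapply(genes, function(x) x$gene_id, "") == "cox1")]]
  hits <- search_all(list(cox1, g$mito), g$assembly)
  expect_true(all(c("cox1", "mitogenome") %in% hits$query_id))
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    cov <- hits$subject_id == tr$contig & hits$s_start < tr$end &
      hits$s_end > tr$start
    # the cox1 query and the full-mitogenome query find the same intervals
    expect_true(any(cov & hits$query_id == "cox1"))
    expect_true(any(cov & hits$query_id == "mitogenome"))
    # the unmutated copy is recovered in full: the best overlapping
    # mitogenome-query hit matches every planted base (the local alignment
    # may add a few lucky matched/mismatched columns beyond the insertion)
    mh <- hits[cov & hits$query_id == "mitogenome", ]
    expect_gte(max(mh$matches), tr$fragment_length)
    expect_gte(max(mh$identity_fraction), 0.99)
  }
  expect_equal(nrow(search_all(list(cox1), list())), 0L)
})

test_that("no seeds means no hits", {
  s <- scoring_scheme()
  expect_equal(nrow(local_align("ACGTACGT", genome_sequence("c", random_dna(500)), s)),
               0L)  # query shorter than the word size
})
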