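test_that("the filter cascade enforces the four boundary rules", {
  t <- filter_thresholds()
  # E-value threshold is inclusive
  expect_equal(nrow(filter_hits(make_hit(e_value = 1e-4), t)), 1L)
  expect_equal(nrow(filter_hits(make_hit(e_value = 1.01e-4), t)), 0L)
  # matched length <= 50 removed, 51 kept
  expect_equal(nrow(filter_hits(make_hit(aligned_length = 50L, matches = 45L), t)), 0L)
  expect_equal(nrow(filter_hits(make_hit(aligned_length = 51L, matches = 45L), t)), 1L)
  # similarity strictly greater than 60%
  expect_equal(nrow(filter_hits(make_hit(aligned_length = 100L, matches = 60L), t)), 0L)
  expect_equal(nrow(filter_hits(make_hit(aligned_length = 100L, matches = 61L), t)), 1L)
  # 100% query coverage excluded (unless disabled)
  expect_equal(nrow(filter_hits(make_hit(query_coverage = 1), t)), 0L)
  keep_cov <- filter_thresholds(exclude_full_query_coverage = FALSE)
  expect_equal(nrow(filter_hits(make_hit(query_coverage = 1), keep_cov)), 1L)
  # the fully-passing reference hit survives
  expect_equal(nrow(filter_hits(make_hit(e_value = 1e-5, aligned_length = 120L,
                                         matches = 102L, query_coverage = 0.4), t)),
               1L)
})

test_that("filtering is idempotent, order-preserving and a subset", {
  set.seed(8)
  hits <- do.call(rbind, lapply(1:50, function(i)
    make_hit(query_id = sample(c("cox1", "cob"), 1),
             e_value = 10^runif(1, -12, -2),
             aligned_length = sample(20:300, 1),
             matches = 0L, query_coverage = runif(1))))
  hits$matches <- as.integer(round(hits$aligned_length * runif(50, 0.4, 1)))
  hits$identity_fraction <- hits$matches / hits$aligned_length
  hits$tag <- seq_len(50)
  t <- filter_thresholds()
  f1 <- filter_hits(hits, t)
  expect_true(all(f1$tag %in% hits$tag))
  expect_false(is.unsorted(f1$tag))
  expect_equal(filter_hits(f1, t), f1)
})

test_that("hits merge into disjoint loci by >= 1 bp subject overlap", {
  h <- rbind(make_hit(s_start = 100L, s_end = 200L),
             make_hit(s_start = 150L, s_end = 300L))
  loci <- merge_to_loci(h)
  expect_equal(nrow(loci), 1L)
  expect_equal(c(loci$start, loci$end, loci$length), c(100L, 300L, 200L))

  # abutting half-open intervals do not merge
  h2 <- rbind(make_hit(s_start = 100L, s_end = 200L),
              make_hit(s_start = 200L, s_end = 300L))
  expect_equal(nrow(merge_to_loci(h2)), 2L)

  # gene + full-genome query at the same interval: one locus, gene label only
  h3 <- rbind(make_hit(query_id = "cox1", s_start = 100L, s_end = 250L),
              make_hit(query_id = "mitogenome", s_start = 100L, s_end = 250L))
  loci3 <- merge_to_loci(h3, gene_ids = c("cox1", "cob"))
  expect_equal(nrow(loci3), 1L)
  expect_equal(loci3$source_genes[[1]], "cox1")
  expect_equal(loci3$n_hits, 2L)
})

test_that("locus merging is permutation-invariant and loci stay disjoint", {
  set.seed(14)
  for (rep in 1:5) {
    hits <- do.call(rbind, lapply(1:40, function(i) {
      st <- sample(0:5000, 1)
      make_hit(subject_id = sample(c("c1", "c2"), 1), s_start = st,
               s_end = st + sample(30:400, 1),
               raw_score = sample(40:200, 1))
    }))
    loci <- merge_to_loci(hits)
    shuffled <- hits[sample(nrow(hits)), ]
    reshuffled <- merge_to_loci(shuffled)
    # hit_rows index the (permuted) input, so compare everything else
    cols <- setdiff(names(loci), "hit_rows")
    expect_equal(reshuffled[, cols], loci[, cols])
    for (sid in unique(loci$subject_id)) {
      l <- loci[loci$subject_id == sid, ]
      expect_true(all(l$start[-1] >= l$end[-nrow(l)]))  # pairwise disjoint
    }
    expect_true(all(vapply(seq_len(nrow(loci)), function(k) {
      rows <- loci$hit_rows[[k]]
      all(hits[rows, "s_start"] < loci$end[k] & hits[rows, "s_end"] > loci$start[k])
    }, TRUE)))
  }
})

test_that("gene attribution counts loci per source gene", {
  h <- rbind(make_hit(query_id = "cox1", s_start = 100L, s_end = 250L),
             make_hit(query_id = "cox1", s_start = 1000L, s_end = 1200L),
             make_hit(query_id = "cox1", s_start = 2000L, s_end = 2300L),
             make_hit(query_id = "cob", s_start = 5000L, s_end = 5200L),
             make_hit(query_id = "nad5", s_start = 5100L, s_end = 5400L))
  loci <- merge_to_loci(h, gene_ids = c("cox1", "cob", "nad5", "atp8"))
  counts <- attribute_genes(loci, genes = c("cox1", "cob", "nad5", "atp8"))
  expect_equal(counts, c(cox1 = 3L, cob = 1L, nad5 = 1L, atp8 = 0L))
  # the junction locus increments both cob and nad5
  junction <- loci[loci$start == 5000L, ]
  expect_equal(junction$source_genes[[1]], c("cob", "nad5"))
})

test_that("species summaries report count, length, percentage and histogram", {
  h <- rbind(make_hit(s_start = 0L, s_end = 100L),
             make_hit(s_start = 500L, s_end = 700L))
  loci <- merge_to_loci(h)
  s <- summarize_species(loci, assembly_length = 30000L)
  expect_equal(s$count, 2L)
  expect_equal(s$total_length, 300L)
  expect_equal(sprintf("%.5f", s$pct), "1.00000")
  hist <- s$length_histogram
  expect_equal(hist$count[hist$bin == "1-100"], 1L)
  expect_equal(hist$count[hist$bin == "101-200"], 1L)
  expect_equal(sum(hist$count), 2L)

  s0 <- summarize_species(merge_to_loci(make_hit()[0, ]), 30000L)
  expect_equal(s0$count, 0L)
  expect_equal(sprintf("%.5f", s0$pct), "0.00000")

  # boundary lengths fall in the stated bins
  h3 <- rbind(make_hit(s_start = 0L, s_end = 1500L),
              make_hit(s_start = 2000L, s_end = 3501L))
  s3 <- summarize_species(merge_to_loci(h3), 1e6)
  hist3 <- s3$length_histogram
  expect_equal(hist3$count[hist3$bin == "1401-1500"], 1L)
  expect_equal(hist3$count[hist3$bin == ">1500"], 1L)
})

test_that("printed per-species row is consistent under inverse arithmetic", {
  # a published row reads 207 Numts / 76,799 bp / 0.01035%; the implied
  # assembly length is 100 * 76799 / 0.01035 ~ 7.42e8 bp
  implied <- 100 * 76799 / 0.01035
  expect_equal(implied, 7.42e8, tolerance = 0.001)
  h <- make_hit(s_start = 0L, s_end = 76799L)
  s <- summarize_species(merge_to_loci(h), assembly_length = round(implied))
  expect_equal(sprintf("%.5f", s$pct), "0.01035")
})
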