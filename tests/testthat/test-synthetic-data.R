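test_that("generation is deterministic for a fixed config", {
  cfg <- simulation_config(seed = 99, n_numts = 5L)
  a1 <- simulate_genome(cfg)
  a2 <- simulate_genome(cfg)
  expect_identical(vapply(a1$assembly, function(x) x$residues, ""),
                   vapply(a2$assembly, function(x) x$residues, ""))
  expect_identical(a1$mito$residues, a2$mito$residues)
  expect_identical(a1$truth, a2$truth)
})

test_that("assembly composition matches the configured GC", {
  cfg <- simulation_config(seed = 2, n_contigs = 1L, contig_lengths = 1e5L,
                           gc_content = 0.5)
  asm <- generate_assembly(cfg)
  gc <- gc_content(asm[[1]]$residues)
  # binomial 3-sigma bound on the empirical GC
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5))
  cfg0 <- simulation_config(seed = 2, n_contigs = 1L, contig_lengths = 2000L,
                            gc_content = 0)
  expect_equal(gc_content(generate_assembly(cfg0)[[1]]$residues), 0)
})

test_that("hotspots raise local AT where planted", {
  cfg <- simulation_config(seed = 5, n_contigs = 1L, contig_lengths = 50000L,
                           gc_content = 0.38,
                           hotspots = list(count = 10, length = 400,
                                           at_level = 0.9))
  asm <- generate_assembly(cfg)
  at <- at_content(asm[[1]]$residues)
  expect_gt(at, 0.62)  # above the background expectation
  expect_equal(nchar(asm[[1]]$residues), 50000L)
})

test_that("the mitogenome carries the full annotated gene complement", {
  cfg <- simulation_config(seed = 12)
  mg <- generate_mitogenome(cfg)
  expect_equal(nchar(mg$mito$residues), cfg$mito_length)
  expect_equal(mg$mito$topology, "circular")
  expect_equal(nrow(mg$annotations), 37L)
  expect_equal(sum(mg$annotations$category == "PCG"), 13L)
  expect_equal(sum(mg$annotations$category == "rRNA"), 2L)
  expect_equal(sum(mg$annotations$category == "tRNA"), 22L)
  # annotations are non-overlapping and within bounds
  a <- mg$annotations[order(mg$annotations$start), ]
  expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  expect_true(all(a$end <= cfg$mito_length))
  expect_error(generate_mitogenome(simulation_config(seed = 1, mito_length = 10000L)),
               "too short")
})

test_that("planted fragments respect divergence, spacing and conservation", {
  cfg <- simulation_config(seed = 42)
  clean <- generate_assembly(cfg)
  mg <- generate_mitogenome(cfg)
  pl <- plant_numts(clean, mg$mito, mg$annotations, cfg)
  truth <- pl$truth
  expect_equal(nrow(truth), 20L)
  # conservation: final length = initial + sum of realized fragment lengths
  expect_equal(sum(vapply(pl$assembly, function(x) nchar(x$residues), 0L)),
               sum(cfg$contig_lengths) + sum(truth$fragment_length))
  # truth intervals are disjoint and at least min_site_distance apart
  for (ctg in unique(truth$contig)) {
    tr <- truth[truth$contig == ctg, ]
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1)
      expect_true(all(tr$start[-1] - tr$end[-nrow(tr)] >= cfg$min_site_distance))
  }
  # the planted subsequence is recovered verbatim from the truth coordinates
  for (i in c(1L, nrow(truth))) {
    ctg <- pl$assembly[[match(truth$contig[i],
                              vapply(pl$assembly, function(x) x$id, ""))]]
    frag <- substr(ctg$residues, truth$start[i] + 1L, truth$end[i])
    expect_equal(nchar(frag), truth$fragment_length[i])
  }
  # realized identity reflects the substitution rate (3-sigma binomial bound)
  expect_true(all(abs(truth$realized_identity - 0.94) < 0.94 * 0.2))
  big <- truth[truth$fragment_length > 600, ]
  p_keep <- mean(big$realized_identity)
  expect_lt(abs(p_keep - (1 - cfg$substitution_rate) /
                  (1 + cfg$indel_rate * cfg$indel_length_mean)), 0.03)
})

test_that("undiverged fragments have realized identity exactly 1", {
  cfg <- simulation_config(seed = 13, substitution_rate = 0, indel_rate = 0,
                           n_numts = 10L)
  g <- simulate_genome(cfg)
  expect_true(all(g$truth$realized_identity == 1))
  # and the fragment text matches the mitogenome source verbatim
  i <- which.max(g$truth$fragment_length)
  ctg <- g$assembly[[match(g$truth$contig[i],
                           vapply(g$assembly, function(x) x$id, ""))]]
  frag <- substr(ctg$residues, g$truth$start[i] + 1L, g$truth$end[i])
  L <- nchar(g$mito$residues)
  src <- numtr:::.circular_substr(g$mito$residues, g$truth$source_start[i],
                                  g$truth$source_end[i])
  expect_equal(frag, src)
})

test_that("gene-biased sampling concentrates fragments on the chosen gene", {
  cfg <- simulation_config(seed = 17, gene_weights = cox1_biased_weights(),
                           n_numts = 30L, fragment_length_range = c(150L, 500L))
  g <- simulate_genome(cfg)
  tab <- table(g$truth$source_gene)
  expect_equal(names(which.max(tab)), "cox1")
})

test_that("call evaluation scores recall and precision", {
  truth <- data.frame(contig = "c1", start = c(100L, 1000L),
                      end = c(400L, 1600L))
  perfect <- data.frame(subject_id = "c1", start = c(120L, 990L),
                        end = c(380L, 1610L))
  ev <- evaluate_calls(perfect, truth)
  expect_equal(c(ev$recall, ev$precision), c(1, 1))
  none <- perfect[0, ]
  expect_equal(evaluate_calls(none, truth)$recall, 0)
  off <- data.frame(subject_id = "c1", start = 5000L, end = 5100L)
  ev2 <- evaluate_calls(off, truth)
  expect_equal(ev2$recall, 0)
  expect_equal(ev2$precision, 0)
  # minimum-overlap rule
  touch <- data.frame(subject_id = "c1", start = 399L, end = 450L)
  expect_equal(evaluate_calls(touch, truth, min_overlap = 1L)$recall, 0.5)
  expect_equal(evaluate_calls(touch, truth, min_overlap = 2L)$recall, 0)
})
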