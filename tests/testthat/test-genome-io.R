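test_that("FASTA reading normalizes records and preserves order", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGT"), p)
  s <- read_fasta(p)
  expect_length(s, 1L)
  expect_equal(s[[1]]$id, "c1")
  expect_equal(s[[1]]$residues, "ACGT")

  writeLines(c(">b first", "acgt", "acg", ">a", "TTTT"), p)
  s <- read_fasta(p)
  expect_equal(vapply(s, function(x) x$id, ""), c(b = "b", a = "a"))
  expect_equal(s[[1]]$residues, "ACGTACG")  # case + line breaks normalized
})

test_that("FASTA round-trip is identity up to line wrapping", {
  p <- withr::local_tempfile(fileext = ".fasta")
  set.seed(5)
  seqs <- list(genome_sequence("x", random_dna(251)),
               genome_sequence("y", random_dna(70)))
  write_fasta(seqs, p, width = 60)
  back <- read_fasta(p)
  expect_equal(lapply(back, `[`, c("id", "residues")),
               lapply(seqs, `[`, c("id", "residues")),
               ignore_attr = TRUE)
})

test_that("malformed FASTA input is reported with a line number", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">c1"), p)
  expect_error(read_fasta(p), "line 1")
  writeLines(c(">c1", "ACGT", ">c2", "AC9T"), p)
  expect_error(read_fasta(p), "line 4")
  writeLines(c(">c1", "ACGT", ">c1", "AAAA"), p)
  expect_error(read_fasta(p), "duplicate")
  writeLines(c(">c1", "ACGT", ">c2", "AAAA"), p)
  expect_error(read_fasta(p, topology = "circular"), "single-record")
})

test_that("annotation coordinate conventions normalize to 0-based half-open", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "mt\tx\tgene\t1\t3\t.\t+\t.\tID=g1;gene=cox1;category=PCG",
               "mt\tx\tgene\t10\t30\t.\t-\t.\tID=g2;gene=cob;category=PCG"),
             gff)
  a <- suppressWarnings(read_annotation(gff, "gff3"))
  expect_equal(a$start, c(0L, 9L))
  expect_equal(a$end, c(3L, 30L))
  expect_equal(a$strand, c("+", "-"))

  bed <- withr::local_tempfile(fileext = ".tsv")
  writeLines("0\t3", bed)
  b <- suppressWarnings(read_annotation(bed, "bed_tsv"))
  expect_equal(c(b$start, b$end), c(0L, 3L))

  writeLines("mt\t5\t11\tcox1\t0\t-\tPCG", bed)
  b6 <- suppressWarnings(read_annotation(bed, "bed_tsv"))
  expect_equal(b6$gene_id, "cox1")
  expect_equal(b6$strand, "-")
})

test_that("GFF3 -> internal -> GFF3 round-trip is the identity", {
  mg <- generate_mitogenome(simulation_config(seed = 11))
  p <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(mg$annotations, p, seqid = "mitogenome", dialect = "gff3")
  back <- read_annotation(p, "gff3", seq_length = nchar(mg$mito$residues))
  expect_equal(back[, c("gene_id", "start", "end", "strand", "category")],
               mg$annotations[, c("gene_id", "start", "end", "strand", "category")])
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(back, p2, seqid = "mitogenome", dialect = "gff3")
  expect_identical(readLines(p), readLines(p2))
})

test_that("annotation error and warning contracts hold", {
  bed <- withr::local_tempfile(fileext = ".tsv")
  writeLines("mt\t10\t5\tg1\t0\t+", bed)
  expect_error(suppressWarnings(read_annotation(bed, "bed_tsv")), "end <= start")
  writeLines("mt\t0\t70\ttrnX\t0\t+\nmt\t100\t200\tmystery\t0\t+", bed)
  w <- capture_warnings(a <- read_annotation(bed, "bed_tsv"))
  expect_match(w, "without a known category", all = FALSE)
  expect_match(w, "13/2/22", all = FALSE)
  expect_equal(a$category, c("tRNA", "PCG"))  # inferred from name prefix
  # wrap flag requires the sequence length
  writeLines("mt\t90\t105\tg1\t0\t+", bed)
  a <- suppressWarnings(read_annotation(bed, "bed_tsv", seq_length = 100L))
  expect_true(a$wraps)
})

test_that("tabular hits round-trip losslessly and decode strand", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cox1\tchr1\t97.5\t120\t3\t0\t1\t120\t900\t850\t3e-10\t150.2",
               "cob\tchr2\t61\t51\t19\t1\t5\t55\t100\t151\t1e-5\t40"), p)
  h <- read_tabular_hits(p)
  expect_equal(nrow(h), 2L)
  expect_equal(h$e_value[1], 3e-10)
  expect_true(h$s_start[1] > h$s_end[1])  # minus strand preserved verbatim
  internal <- tabular_to_hits(h, query_lengths = c(cox1 = 1533L, cob = 1140L))
  expect_equal(internal$strand, c("-", "+"))
  expect_equal(internal$s_start[1], 849L)  # 0-based forward-strand interval
  expect_equal(internal$s_end[1], 900L)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(h, p2)
  expect_equal(read_tabular_hits(p2), h)
})

test_that("tabular hit parse errors and empty input behave as specified", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), p)
  expect_equal(nrow(read_tabular_hits(p)), 0L)
  writeLines(c("a\tb\t90\t60\t6\t0\t1\t60\t1\t60\t1e-9\t80",
               "a\tb\t90\t60"), p)
  expect_error(read_tabular_hits(p), "line 2")
})

test_that("internal hits convert to the tabular layout bit-exactly", {
  set.seed(42)
  q <- random_dna(80)
  subj <- paste0(random_dna(150), q, random_dna(150))
  hits <- local_align(q, genome_sequence("chr", subj), scoring_scheme(),
                      min_raw_score = 30)
  hits <- attach_evalue(hits, scoring_scheme(), 80, nchar(subj))
  tab <- hits_to_tabular(hits)
  expect_equal(tab$q_start, hits$q_start + 1L)
  expect_equal(tab$aln_length, hits$aligned_length)
  back <- tabular_to_hits(tab, query_lengths = c(query = 80L))
  expect_equal(back$s_start, hits$s_start)
  expect_equal(back$s_end, hits$s_end)
  expect_equal(back$query_coverage, hits$query_coverage)
})

test_that("write_report emits BED, TSVs and JSON with the stated formats", {
  dir <- withr::local_tempdir()
  hits <- rbind(make_hit(query_id = "cox1", s_start = 100L, s_end = 250L),
                make_hit(query_id = "mitogenome", s_start = 120L, s_end = 230L))
  loci <- merge_to_loci(hits, gene_ids = "cox1")
  # assembly length chosen so the percentage prints as 0.00269
  s <- summarize_species(loci, assembly_length = round(150 / 0.00269 * 100),
                         species = "toy", genes = c("cox1", "cob"))
  files <- write_report(s, loci, dir)
  bed <- read.delim(files["bed"], header = FALSE)
  expect_equal(unlist(bed[1, 1:3], use.names = FALSE), c("s", 100L, 250L))
  expect_true(bed[1, 2] >= 0 && bed[1, 2] < bed[1, 3])
  tsv <- read.delim(files["summary"], colClasses = "character")
  expect_equal(tsv$numt_pct_of_genome, "0.00269")
  genes <- read.delim(files["genes"])
  expect_equal(genes$numt_count[genes$gene == "cox1"], 1L)
  expect_equal(genes$numt_count[genes$gene == "cob"], 0L)
  js <- jsonlite::read_json(files["json"])
  expect_equal(js$numt_count, 1L)

  # empty locus set: header-only files, zero counts
  empty <- merge_to_loci(make_hit()[0, ])
  s0 <- summarize_species(empty, 30000L)
  files0 <- write_report(s0, empty, withr::local_tempdir())
  expect_equal(length(readLines(files0["bed"])), 0L)
  expect_equal(read.delim(files0["summary"])$numt_count, 0L)
})
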