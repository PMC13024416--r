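# Shared test helpers: random sequences, controlled mutation, hit records.

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Substitution-only mutation at per-site rate d (always changes the base).
mutate_dna <- function(x, d) {
  b <- strsplit(x, "")[[1]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in which(runif(length(b)) < d)) b[i] <- sample(alt[[b[i]]], 1)
  paste(b, collapse = "")
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# One alignment-hit row with sensible defaults, overridable per test.
make_hit <- function(query_id = "q", subject_id = "s", strand = "+",
                     q_start = 0L, q_end = 40L, s_start = 100L, s_end = 220L,
                     raw_score = 80L, bit_score = 50, e_value = 1e-10,
                     aligned_length = 120L, matches = 102L,
                     identity_fraction = matches / aligned_length,
                     query_coverage = 0.4, query_length = 100L,
                     cigar = "120M") {
  data.frame(query_id = query_id, subject_id = subject_id, strand = strand,
             q_start = q_start, q_end = q_end, s_start = s_start,
             s_end = s_end, raw_score = raw_score, bit_score = bit_score,
             e_value = e_value, aligned_length = aligned_length,
             matches = matches, identity_fraction = identity_fraction,
             query_coverage = query_coverage, query_length = query_length,
             cigar = cigar, stringsAsFactors = FALSE)
}

# Build a query/subject pair with a diverged copy of part of the query
# planted in an otherwise random subject; returns the pair.
planted_pair <- function(qlen, slen, d, min_plant = 40L) {
  q <- random_dna(qlen)
  plen <- sample(min_plant:qlen, 1)
  p0 <- sample(qlen - plen + 1L, 1)
  planted <- mutate_dna(substr(q, p0, p0 + plen - 1L), d)
  pos <- sample(slen - nchar(planted), 1)
  subj <- paste0(random_dna(pos), planted,
                 random_dna(slen - pos - nchar(planted)))
  list(query = q, subject = subj)
}

# Per-species synthetic study used by the flank AT-bias tests: one 50-kb
# contig, planted Numts via the generator, flank AT measured at the truth
# coordinates, genome AT on the pre-insertion contig.
flank_study_species <- function(seed, beta, hotspots, mg,
                                contig_length = 50000L, n_numts = 10L,
                                frag_range = c(150L, 400L)) {
  cfg <- simulation_config(seed = seed, n_contigs = 1L,
                           contig_lengths = contig_length,
                           hotspots = hotspots, n_numts = n_numts,
                           fragment_length_range = frag_range,
                           insertion_bias_beta = beta)
  asm <- generate_assembly(cfg)
  pl <- plant_numts(asm, mg$mito, mg$annotations, cfg)
  loci <- pl$truth
  names(loci)[names(loci) == "contig"] <- "subject_id"
  fl <- extract_flanks(loci, pl$assembly)
  c(flank = flank_at_summary(fl)$flank_at,
    genome = at_content(asm[[1]]$residues))
}
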