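#' Scoring scheme for nucleotide local alignment
#'
#' Defaults follow the standard parameterization of BLASTN's `blastn` task:
#' match +2, mismatch -3, gap open 5, gap extend 2 (a gap of length k costs
#' `gap_open + k * gap_extend`), word size 11. `lambda` is the Karlin-Altschul
#' scale in nats per score unit, solved from the ungapped score constraint by
#' [solve_lambda()] unless supplied; `K` is the search-space scaling constant
#' (exact replication of NCBI's gapped calibration and length adjustment is
#' out of scope, so E-values are comparable but not bit-identical to BLASTN).
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open,gap_extend Gap costs (> 0).
#' @param word_size Seed word length.
#' @param lambda Karlin-Altschul lambda; solved from the scheme if `NULL`.
#' @param K Karlin-Altschul K.
#' @param background Per-base background probabilities (A, C, G, T).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L, word_size = 11L, lambda = NULL,
                           K = 0.41, background = rep(0.25, 4)) {
  stopifnot(match > 0, mismatch < 0, gap_open > 0, gap_extend > 0,
            word_size >= 4L, K > 0, length(background) == 4L,
            abs(sum(background) - 1) < 1e-9)
  s <- structure(list(match = as.integer(match),
                      mismatch = as.integer(mismatch),
                      gap_open = as.integer(gap_open),
                      gap_extend = as.integer(gap_extend),
                      word_size = as.integer(word_size),
                      lambda = lambda, K = K, background = background),
                 class = "scoring_scheme")
  if (is.null(s$lambda)) s$lambda <- solve_lambda(s)
  stopifnot(s$lambda > 0)
  s
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(paste0("<scoring_scheme> match %+d / mismatch %+d, gap %d+%dk, ",
                     "word %d, lambda %.4f, K %.3f\n"),
              x$match, x$mismatch, x$gap_open, x$gap_extend, x$word_size,
              x$lambda, x$K))
  invisible(x)
}

#' Solve the Karlin-Altschul lambda for a scoring scheme
#'
#' Finds the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s(i, j)) = 1`, where `s` is the
#' match/mismatch score and `p` the background base frequencies, by bisection
#' to a constraint residual below `tol`. Requires negative expected
#' per-column score (otherwise E-values are undefined).
#'
#' @param scheme A [scoring_scheme()] (only match/mismatch/background used).
#' @param tol Residual tolerance.
#' @return lambda, in nats per score unit.
#' @export
solve_lambda <- function(scheme, tol = 1e-10) {
  p <- scheme$background
  p_match <- sum(p^2)
  p_mismatch <- 1 - p_match
  expected <- p_match * scheme$match + p_mismatch * scheme$mismatch
  if (expected >= 0)
    stop("expected per-column score must be negative for E-value calibration")
  f <- function(lam)
    p_match * exp(lam * scheme$match) + p_mismatch * exp(lam * scheme$mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  # f(0) = 0 with negative slope, so step off zero to bracket the positive root
  lo <- hi / 2
  while (f(lo) > 0) lo <- lo / 2
  while (hi - lo > 1e-15 && abs(f((lo + hi) / 2)) > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Reference Smith-Waterman local alignment
#'
#' Full dynamic-programming local alignment with affine gaps (Gotoh), used
#' as the exact reference for the seeded heuristic in [local_align()]. Plus
#' strand only. Quadratic time and memory; intended for moderate sizes.
#'
#' @param query,subject DNA strings (or `genome_sequence`/`gene_sequence`).
#' @param scheme A [scoring_scheme()].
#' @return A list with `score`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (0-based half-open), `matches`, `aln_length`, `cigar`.
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme()) {
  q <- if (is.character(query)) query else query$residues
  s <- if (is.character(subject)) subject else subject$residues
  .sw_align_cpp(toupper(q), toupper(s), scheme$match, scheme$mismatch,
                scheme$gap_open, scheme$gap_extend)
}

.empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             strand = character(), q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(), raw_score = integer(),
             bit_score = numeric(), e_value = numeric(),
             aligned_length = integer(), matches = integer(),
             identity_fraction = numeric(), query_coverage = numeric(),
             query_length = integer(), cigar = character(),
             stringsAsFactors = FALSE)
}

# Drop hits whose subject interval is wholly contained in a higher-scoring
# hit's interval (strand-agnostic non-redundancy reduction).
.reduce_contained <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  ord <- order(-hits$raw_score, hits$s_start, hits$s_end)
  keep_rows <- integer(0)
  for (i in ord) {
    contained <- FALSE
    for (j in keep_rows) {
      if (hits$s_start[j] <= hits$s_start[i] && hits$s_end[i] <= hits$s_end[j] &&
          hits$raw_score[i] < hits$raw_score[j]) {
        contained <- TRUE
        break
      }
    }
    if (!contained) keep_rows <- c(keep_rows, i)
  }
  hits[sort(keep_rows), , drop = FALSE]
}

#' Seed-and-extend local alignment of one query against one subject
#'
#' Mirrors the BLASTN strategy: exact `word_size` seeding, ungapped X-drop
#' extension, then banded gapped extension around the seeded diagonals. Both
#' strands are searched (the query is reverse-complemented for the minus
#' strand; subject coordinates always refer to the forward strand).
#' Overlapping alignments are reduced to a non-redundant set: no hit whose
#' subject interval is wholly contained in a higher-scoring hit's interval
#' is kept. E-values are not attached here; see [attach_evalue()].
#'
#' @param query A `gene_sequence`/`genome_sequence` or DNA string. A plain
#'   string is labelled `"query"`.
#' @param subject A `genome_sequence` or DNA string (labelled `"subject"`).
#' @param scheme A [scoring_scheme()].
#' @param min_raw_score Minimum raw score for a reported hit.
#' @param x_drop Ungapped extension X-drop, in score units.
#' @param band Half-width of the gapped extension band, in columns.
#' @param pad Query padding added around the seeded window before banded
#'   extension.
#' @return An alignment-hit data.frame (0-based half-open coordinates),
#'   one row per hit; zero rows if nothing scores above `min_raw_score`.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        min_raw_score = 40L, x_drop = 20L, band = 40L,
                        pad = 100L) {
  qid <- if (is.character(query)) "query" else (query$gene_id %||% query$id)
  sid <- if (is.character(subject)) "subject" else subject$id
  q <- toupper(if (is.character(query)) query else query$residues)
  s <- toupper(if (is.character(subject)) subject else subject$residues)
  qlen <- nchar(q)
  if (qlen < scheme$word_size) return(.empty_hits())
  one_strand <- function(qseq, strand) {
    raw <- .seed_extend_cpp(qseq, s, scheme$match, scheme$mismatch,
                            scheme$gap_open, scheme$gap_extend,
                            scheme$word_size, x_drop, band,
                            as.integer(min_raw_score), pad, 400L)
    if (nrow(raw) == 0L) return(.empty_hits())
    if (strand == "-") {
      q_start <- qlen - raw$q_end
      q_end <- qlen - raw$q_start
    } else {
      q_start <- raw$q_start
      q_end <- raw$q_end
    }
    data.frame(query_id = qid, subject_id = sid, strand = strand,
               q_start = q_start, q_end = q_end,
               s_start = raw$s_start, s_end = raw$s_end,
               raw_score = raw$raw_score, bit_score = NA_real_,
               e_value = NA_real_, aligned_length = raw$aligned_length,
               matches = raw$matches,
               identity_fraction = raw$matches / raw$aligned_length,
               query_coverage = (q_end - q_start) / qlen,
               query_length = qlen, cigar = raw$cigar,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(one_strand(q, "+"), one_strand(revcomp(q), "-"))
  if (nrow(hits) == 0L) return(hits)
  hits <- .reduce_contained(hits)
  hits <- hits[order(hits$s_start, hits$s_end, -hits$raw_score), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Attach Karlin-Altschul bit scores and E-values to hits
#'
#' `bit_score = (lambda * raw_score - ln K) / ln 2` and
#' `e_value = m * n * 2^(-bit_score)`, so the E-value doubles when the
#' search space doubles and decreases monotonically in the raw score.
#'
#' @param hits Alignment-hit data.frame with a `raw_score` column.
#' @param scheme A [scoring_scheme()] carrying calibrated `lambda` and `K`.
#' @param m Query length (bp).
#' @param n Total subject length (bp): the full searched assembly.
#' @return `hits` with `bit_score` and `e_value` filled in.
#' @export
attach_evalue <- function(hits, scheme, m, n) {
  stopifnot(m > 0, n > 0)
  hits$bit_score <- (scheme$lambda * hits$raw_score - log(scheme$K)) / log(2)
  hits$e_value <- as.numeric(m) * as.numeric(n) * 2^(-hits$bit_score)
  hits
}

#' Search all mitochondrial queries against a nuclear assembly
#'
#' Runs [local_align()] for every query (typically the 37 extracted gene
#' sequences plus the full mitogenome) against every contig of the assembly
#' and attaches E-values computed against the total assembly length.
#'
#' @param queries A list of `gene_sequence`/`genome_sequence` queries.
#' @param assembly A list of `genome_sequence` contigs.
#' @param scheme A [scoring_scheme()].
#' @param ... Passed to [local_align()] (`min_raw_score`, `x_drop`, `band`,
#'   `pad`).
#' @return A single alignment-hit data.frame, each hit labelled with its
#'   query id.
#' @export
search_all <- function(queries, assembly, scheme = scoring_scheme(), ...) {
  n_total <- sum(vapply(assembly, function(x) nchar(x$residues), 0))
  if (length(assembly) == 0L) return(.empty_hits())
  out <- lapply(queries, function(qr) {
    m <- nchar(if (is.character(qr)) qr else qr$residues)
    per_contig <- lapply(assembly, function(ctg) local_align(qr, ctg, scheme, ...))
    hits <- do.call(rbind, per_contig)
    if (nrow(hits)) hits <- attach_evalue(hits, scheme, m, n_total)
    hits
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
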