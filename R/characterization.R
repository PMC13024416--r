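#' AT content of a DNA string
#'
#' `(A+T) / (A+C+G+T)`; IUPAC ambiguity codes (including N) are excluded
#' from both numerator and denominator. Empty or fully ambiguous input
#' yields `NA`.
#'
#' @param seq DNA string.
#' @return Fraction in \[0, 1\], or `NA_real_`.
#' @export
at_content <- function(seq) {
  seq <- toupper(seq)
  at <- nchar(gsub("[^AT]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  if (acgt == 0L) return(NA_real_)
  at / acgt
}

#' GC content of a DNA string
#'
#' Complement of [at_content()] on unambiguous bases.
#' @param seq DNA string.
#' @return Fraction in \[0, 1\], or `NA_real_`.
#' @export
gc_content <- function(seq) {
  a <- at_content(seq)
  if (is.na(a)) NA_real_ else 1 - a
}

# Base-weighted pooled AT over a character vector of sequences.
pooled_at <- function(seqs) {
  seqs <- toupper(seqs)
  at <- sum(nchar(gsub("[^AT]", "", seqs)))
  acgt <- sum(nchar(gsub("[^ACGT]", "", seqs)))
  if (acgt == 0L) return(NA_real_)
  at / acgt
}

#' Extract flanking sequences around Numt loci
#'
#' For each locus, the `window` bp immediately upstream (ending at the locus
#' start) and downstream (starting at the locus end) of the insertion, with
#' truncation at contig edges flagged via `clipped`.
#'
#' @param loci A `numt_loci` data.frame.
#' @param assembly List of `genome_sequence` contigs (or a single one).
#' @param window Flank window in bp (default 100).
#' @return A data.frame with one row per locus: `subject_id`, `start`,
#'   `end`, `upstream_seq`, `downstream_seq`, `upstream_at`,
#'   `downstream_at`, `clipped`.
#' @export
extract_flanks <- function(loci, assembly, window = 100L) {
  if (inherits(assembly, "genome_sequence")) assembly <- list(assembly)
  seqs <- setNames(vapply(assembly, function(x) x$residues, ""),
                   vapply(assembly, function(x) x$id, ""))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    sid <- loci$subject_id[i]
    if (!sid %in% names(seqs)) stop("locus on unknown contig: ", sid)
    ctg <- seqs[[sid]]
    L <- nchar(ctg)
    if (loci$start[i] < 0L || loci$end[i] > L)
      stop("locus outside its contig: ", sid)
    up_from <- max(0L, loci$start[i] - window)
    up <- substr(ctg, up_from + 1L, loci$start[i])
    down_to <- min(L, loci$end[i] + window)
    down <- substr(ctg, loci$end[i] + 1L, down_to)
    data.frame(subject_id = sid, start = loci$start[i], end = loci$end[i],
               upstream_seq = up, downstream_seq = down,
               upstream_at = at_content(up), downstream_at = at_content(down),
               clipped = nchar(up) < window || nchar(down) < window,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' Species-level flank AT summary
#'
#' Pools bases (weighted by actual flank lengths, so clipped flanks
#' contribute what they have) over all upstream and downstream flanks of one
#' species.
#'
#' @param flanks Data.frame from [extract_flanks()].
#' @return A list with `flank_at` (upstream + downstream pooled),
#'   `upstream_at`, `downstream_at`.
#' @export
flank_at_summary <- function(flanks) {
  list(flank_at = pooled_at(c(flanks$upstream_seq, flanks$downstream_seq)),
       upstream_at = pooled_at(flanks$upstream_seq),
       downstream_at = pooled_at(flanks$downstream_seq))
}

#' Paired t-test of flank AT content against a reference
#'
#' Each species contributes one flank AT value (base-weighted pooled over
#' all its flanks) and one reference value (typically the genome-wide AT
#' content); the two vectors are compared by a paired t-test, one-tailed
#' "greater" by default (flanks more AT-rich than the genome). The same
#' function serves the upstream-versus-downstream comparison. Identical
#' vectors give statistic 0 and one-tailed p = 0.5.
#'
#' @param x,y Equal-length paired vectors (n >= 2), e.g. per-species flank
#'   AT and per-species genome AT.
#' @param tail `"greater"` (x > y), `"less"`, or `"two_sided"`.
#' @return A `ttest_result` object with `statistic`, `df`, `p_value`,
#'   `tail`, `paired = TRUE`, `mean_difference`, `n`.
#' @export
flank_bias_test <- function(x, y, tail = c("greater", "less", "two_sided")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("paired t-test needs at least 2 complete pairs")
  d <- x - y
  alt <- c(greater = "greater", less = "less", two_sided = "two.sided")[[tail]]
  if (stats::var(d) == 0) {
    # degenerate: zero variance of differences
    md <- mean(d)
    stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) {
      if (tail == "two_sided") 1 else 0.5
    } else if (tail == "two_sided") 0
    else if ((tail == "greater") == (md > 0)) 0 else 1
    res <- list(statistic = stat, df = n - 1L, p_value = p)
  } else {
    tt <- t.test(x, y, paired = TRUE, alternative = alt)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  structure(c(res, list(tail = tail, paired = TRUE, mean_difference = mean(d),
                        n = n)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Paired t-test (%s): t = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$tail, x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation on average-ranked values (ties get mean ranks), with the
#' two-sided p-value from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom (the
#' asymptotic method of `cor.test`; it can differ in the second significant
#' digit from exact/Edgeworth p-values).
#'
#' @param x,y Equal-length numeric vectors, n >= 3 for a p-value.
#' @return A `cor_result` object with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs at least 3 pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    rho <- NA_real_
    p <- NA_real_
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(rho = rho, p_value = p, n = n), class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Spearman correlation: rho = %.4g, p = %.4g (n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Correlate Numt abundance with genome lengths across species
#'
#' Spearman correlations of per-species Numt counts against nuclear genome
#' lengths and against mitochondrial genome lengths.
#'
#' @param counts Per-species Numt counts (or a list of `species_summary`
#'   objects, from which counts are taken).
#' @param genome_lengths Nuclear genome lengths, same order.
#' @param mito_lengths Optional mitogenome lengths, same order.
#' @return A list with elements `nuclear` and (if `mito_lengths` given)
#'   `mito`, each a `cor_result`.
#' @export
correlate_abundance <- function(counts, genome_lengths, mito_lengths = NULL) {
  if (is.list(counts) && !is.null(counts[[1]]$count))
    counts <- vapply(counts, function(s) s$count, 0)
  out <- list(nuclear = spearman_cor(counts, genome_lengths))
  if (!is.null(mito_lengths)) out$mito <- spearman_cor(counts, mito_lengths)
  out
}
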