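#' Filter thresholds for Numt calling
#'
#' The four-part cascade applied to homology hits: E-value at most
#' `max_evalue` (inclusive), matched length strictly greater than
#' `min_length_exclusive`, identity strictly greater than
#' `min_identity_exclusive`, and (optionally) exclusion of hits covering
#' 100% of their own query. Defaults are E <= 1e-4, length > 50 bp,
#' identity > 0.60, full-coverage hits excluded.
#'
#' @param max_evalue Inclusive E-value ceiling.
#' @param min_length_exclusive Matched lengths at or below this are removed.
#' @param min_identity_exclusive Identities at or below this fraction are
#'   removed.
#' @param exclude_full_query_coverage Remove hits whose alignment spans the
#'   whole query.
#' @return A `filter_thresholds` object.
#' @export
filter_thresholds <- function(max_evalue = 1e-4, min_length_exclusive = 50L,
                              min_identity_exclusive = 0.60,
                              exclude_full_query_coverage = TRUE) {
  stopifnot(max_evalue > 0, min_length_exclusive >= 0,
            min_identity_exclusive >= 0, min_identity_exclusive <= 1)
  structure(list(max_evalue = max_evalue,
                 min_length_exclusive = as.integer(min_length_exclusive),
                 min_identity_exclusive = min_identity_exclusive,
                 exclude_full_query_coverage = isTRUE(exclude_full_query_coverage)),
            class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat(sprintf("<filter_thresholds> E <= %g, length > %d bp, identity > %g%s\n",
              x$max_evalue, x$min_length_exclusive,
              x$min_identity_exclusive,
              if (x$exclude_full_query_coverage)
                ", 100% query coverage excluded" else ""))
  invisible(x)
}

#' Apply the Numt filter cascade to alignment hits
#'
#' Keeps exactly the hits with `e_value <= max_evalue`,
#' `aligned_length > min_length_exclusive`,
#' `identity_fraction > min_identity_exclusive`, and (when enabled)
#' `query_coverage < 1`. Order-preserving and idempotent.
#'
#' @param hits Alignment-hit data.frame carrying `e_value`,
#'   `aligned_length`, `identity_fraction`, `query_coverage`.
#' @param thresholds A [filter_thresholds()] object.
#' @return The subset of `hits` passing all filters, in input order.
#' @export
filter_hits <- function(hits, thresholds = filter_thresholds()) {
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$e_value <= thresholds$max_evalue &
    hits$aligned_length > thresholds$min_length_exclusive &
    hits$identity_fraction > thresholds$min_identity_exclusive
  if (thresholds$exclude_full_query_coverage)
    keep <- keep & hits$query_coverage < 1
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge filtered hits into disjoint Numt loci
#'
#' On each subject sequence, hits whose subject intervals overlap by at
#' least 1 bp (strand-agnostic, transitively closed) form one locus whose
#' interval is the union span. Abutting half-open intervals do not merge.
#' One insertion found by several queries (a gene and the full mitogenome)
#' therefore counts once: the Numt count is query-set independent.
#'
#' @param hits Filtered alignment-hit data.frame.
#' @param gene_ids Optional character vector of gene query ids; only these
#'   contribute to `source_genes` (the full-mitogenome query contributes no
#'   gene label). `NULL` means every query id is a gene label.
#' @return A `numt_loci` data.frame ordered by subject id then start, with
#'   columns `subject_id`, `start`, `end`, `length`, `n_hits`,
#'   `best_bit_score`, and list-columns `source_genes` and `hit_rows`
#'   (row indices into `hits`).
#' @export
merge_to_loci <- function(hits, gene_ids = NULL) {
  empty <- data.frame(subject_id = character(), start = integer(),
                      end = integer(), length = integer(), n_hits = integer(),
                      best_bit_score = numeric(), stringsAsFactors = FALSE)
  empty$source_genes <- list()
  empty$hit_rows <- list()
  class(empty) <- c("numt_loci", "data.frame")
  if (nrow(hits) == 0L) return(empty)
  loci <- lapply(sort(unique(hits$subject_id)), function(sid) {
    idx <- which(hits$subject_id == sid)
    ir <- IRanges::IRanges(start = hits$s_start[idx] + 1L, end = hits$s_end[idx])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # >= 1 bp overlap only
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    do.call(rbind, lapply(seq_along(red), function(k) {
      rows <- idx[grp == k]
      qids <- unique(hits$query_id[rows])
      genes <- if (is.null(gene_ids)) qids else intersect(qids, gene_ids)
      score <- if (all(is.na(hits$bit_score[rows]))) max(hits$raw_score[rows])
               else max(hits$bit_score[rows], na.rm = TRUE)
      out <- data.frame(subject_id = sid,
                        start = IRanges::start(red)[k] - 1L,
                        end = IRanges::end(red)[k],
                        length = IRanges::width(red)[k],
                        n_hits = length(rows),
                        best_bit_score = score,
                        stringsAsFactors = FALSE)
      out$source_genes <- list(sort(genes))
      out$hit_rows <- list(rows)
      out
    }))
  })
  res <- do.call(rbind, loci)
  res <- res[order(res$subject_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("numt_loci", "data.frame")
  res
}

#' @export
print.numt_loci <- function(x, ...) {
  cat(sprintf("<numt_loci> %d locus/loci, %d bp total\n",
              nrow(x), sum(x$length)))
  if (nrow(x)) {
    show <- data.frame(subject_id = x$subject_id, start = x$start,
                       end = x$end, length = x$length, n_hits = x$n_hits,
                       source_genes = vapply(x$source_genes, paste,
                                             collapse = ",", ""))
    print(head(show, 10))
    if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  }
  invisible(x)
}

#' Count Numt loci attributed to each source gene
#'
#' For each gene, the count is the number of loci whose `source_genes`
#' contains it; a locus spanning a multi-gene fragment increments every gene
#' it carries hits from. Hits from the full-mitogenome query carry no gene
#' label by themselves.
#'
#' @param loci A `numt_loci` data.frame.
#' @param genes Optional character vector fixing the genes (and their order)
#'   in the result; genes without loci report 0.
#' @return Named integer vector of per-gene locus counts.
#' @export
attribute_genes <- function(loci, genes = NULL) {
  lab <- unlist(lapply(loci$source_genes, unique))
  counts <- table(lab)
  if (is.null(genes)) {
    setNames(as.integer(counts), names(counts))
  } else {
    out <- setNames(integer(length(genes)), genes)
    common <- intersect(names(counts), genes)
    out[common] <- as.integer(counts[common])
    out
  }
}

#' Summarize called Numt loci for one assembly
#'
#' One row of the cross-species abundance table: locus count, total length,
#' percentage of the genome (reported to 5 decimals), per-gene counts, and a
#' length histogram (default 100-bp bins up to 1500 bp plus an open-ended
#' ">1500" bin).
#'
#' @param loci A `numt_loci` data.frame.
#' @param assembly_length Total assembly length in bp (> 0).
#' @param species Label for the assembly.
#' @param genes Optional gene set for [attribute_genes()].
#' @param bin_width,bin_max Histogram bin width and right edge of the last
#'   closed bin.
#' @return A `species_summary` object.
#' @export
summarize_species <- function(loci, assembly_length, species = "assembly",
                              genes = NULL, bin_width = 100L, bin_max = 1500L) {
  stopifnot(assembly_length > 0)
  breaks <- seq(0L, bin_max, by = bin_width)
  labels <- c(sprintf("%d-%d", breaks[-length(breaks)] + 1L, breaks[-1]),
              sprintf(">%d", bin_max))
  counts <- integer(length(labels))
  if (nrow(loci)) {
    bin <- pmin(ceiling(loci$length / bin_width), length(labels))
    bin[loci$length > bin_max] <- length(labels)
    tab <- table(factor(bin, levels = seq_along(labels)))
    counts <- as.integer(tab)
  }
  total <- if (nrow(loci)) sum(loci$length) else 0L
  structure(list(
    species = species,
    count = nrow(loci),
    total_length = total,
    assembly_length = assembly_length,
    pct = 100 * total / assembly_length,
    gene_counts = attribute_genes(loci, genes),
    length_histogram = data.frame(bin = labels, count = counts,
                                  stringsAsFactors = FALSE)
  ), class = "species_summary")
}

#' @export
print.species_summary <- function(x, ...) {
  cat(sprintf("<species_summary> %s: %d Numts, %d bp (%.5f%% of %d bp)\n",
              x$species, x$count, x$total_length, x$pct, x$assembly_length))
  invisible(x)
}
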