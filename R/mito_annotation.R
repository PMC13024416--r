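#' Extract annotated gene sequences from a mitogenome
#'
#' Returns one record per annotation row, in annotation order, with residues
#' in reading direction: minus-strand genes are reverse-complemented and
#' genes wrapping the origin of a circular mitogenome are concatenated
#' across the junction before strand correction.
#'
#' @param mito A [genome_sequence()] (circular for wrapping genes).
#' @param annotations Annotation data.frame from [read_annotation()] (0-based
#'   half-open; a wrapping gene has `end` > mitogenome length).
#' @return A list of `gene_sequence` objects with fields `gene_id`,
#'   `residues` (reading direction), `start`, `end`, `strand`, `category`,
#'   `wraps`.
#' @export
extract_genes <- function(mito, annotations) {
  L <- nchar(mito$residues)
  wraps <- annotations$end > L
  if (any(wraps) && mito$topology != "circular")
    stop("gene wrapping the origin requires circular topology")
  if (any(annotations$start < 0L | annotations$start >= L))
    stop("annotation start outside the mitogenome")
  if (any(annotations$end > 2L * L))
    stop("annotation end beyond one full wrap of the mitogenome")
  lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    res <- if (a$end <= L) {
      substr(mito$residues, a$start + 1L, a$end)
    } else {
      paste0(substr(mito$residues, a$start + 1L, L),
             substr(mito$residues, 1L, a$end - L))
    }
    if (a$strand == "-") res <- revcomp(res)
    structure(list(gene_id = a$gene_id, residues = res,
                   start = a$start, end = a$end, strand = a$strand,
                   category = a$category, wraps = a$end > L),
              class = "gene_sequence")
  })
}

#' @export
print.gene_sequence <- function(x, ...) {
  cat(sprintf("<gene_sequence> %s (%s, %s strand): %d bp\n",
              x$gene_id, x$category, x$strand, nchar(x$residues)))
  invisible(x)
}

.start_codon_levels <- c("ATG", "ATT", "ATC", "ATA", "CGA", "other")
.stop_codon_levels <- c("TAA", "TAG", "TGA", "T", "TA", "other")

#' Tabulate start and stop codon usage of protein-coding genes
#'
#' The start codon is the first 3 residues of each reading-direction PCG
#' sequence. The stop codon is the final 3 residues when the length is a
#' multiple of 3, otherwise the trailing 1-2 residues are classified as an
#' incomplete stop (`T` or `TA`, completed to TAA by transcript
#' polyadenylation). Recognized start codons include CGA, a known
#' lepidopteran cox1 feature. Genes shorter than 6 residues are skipped with
#' a warning.
#'
#' @param genes A list of `gene_sequence` objects (non-PCG entries are
#'   ignored).
#' @return A `codon_usage` object: start/stop counts and relative
#'   frequencies over the categories ATG/ATT/ATC/ATA/CGA/other and
#'   TAA/TAG/TGA/T/TA/other.
#' @export
tabulate_codons <- function(genes) {
  pcgs <- Filter(function(g) identical(g$category, "PCG"), genes)
  short <- vapply(pcgs, function(g) nchar(g$residues) < 6L, TRUE)
  if (any(short)) {
    warning(sum(short), " PCG(s) shorter than 6 residues skipped",
            call. = FALSE)
    pcgs <- pcgs[!short]
  }
  starts <- vapply(pcgs, function(g) substr(g$residues, 1L, 3L), "")
  stops <- vapply(pcgs, function(g) {
    len <- nchar(g$residues)
    r <- len %% 3L
    if (r == 0L) substr(g$residues, len - 2L, len)
    else substr(g$residues, len - r + 1L, len)
  }, "")
  start_class <- ifelse(starts %in% .start_codon_levels, starts, "other")
  stop_class <- ifelse(stops %in% .stop_codon_levels, stops, "other")
  start_counts <- table(factor(start_class, levels = .start_codon_levels))
  stop_counts <- table(factor(stop_class, levels = .stop_codon_levels))
  n <- length(pcgs)
  structure(list(
    n_genes = n,
    start_counts = setNames(as.integer(start_counts), names(start_counts)),
    stop_counts = setNames(as.integer(stop_counts), names(stop_counts)),
    start_freq = setNames(as.numeric(start_counts) / max(n, 1L),
                          names(start_counts)),
    stop_freq = setNames(as.numeric(stop_counts) / max(n, 1L),
                         names(stop_counts))
  ), class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("Codon usage over %d protein-coding genes\n", x$n_genes))
  cat("Start codons:\n")
  print(data.frame(codon = names(x$start_counts), count = x$start_counts,
                   frequency = round(x$start_freq, 4), row.names = NULL))
  cat("Stop codons (T/TA = incomplete):\n")
  print(data.frame(codon = names(x$stop_counts), count = x$stop_counts,
                   frequency = round(x$stop_freq, 4), row.names = NULL))
  invisible(x)
}

#' Write a codon usage table as TSV
#'
#' @param usage A `codon_usage` object from [tabulate_codons()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_codon_usage <- function(usage, path) {
  df <- rbind(
    data.frame(kind = "start", codon = names(usage$start_counts),
               count = usage$start_counts, frequency = usage$start_freq),
    data.frame(kind = "stop", codon = names(usage$stop_counts),
               count = usage$stop_counts, frequency = usage$stop_freq))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
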