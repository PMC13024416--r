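#' Create a genome sequence record
#'
#' The basic sequence container used throughout the package: a named DNA
#' string with linear or circular topology. All coordinates in the package
#' are 0-based half-open on these sequences; 1-based inclusive coordinates
#' appear only at format boundaries (GFF3, BLAST-style tabular hits).
#'
#' @param id Sequence identifier, unique within an assembly.
#' @param residues DNA string over the IUPAC alphabet (upper-cased).
#' @param topology `"linear"` or `"circular"`. Circular topology is intended
#'   for single-record mitochondrial genomes.
#' @return An object of class `genome_sequence`.
#' @export
genome_sequence <- function(id, residues, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("residues must be non-empty for sequence '", id, "'")
  if (!is_dna_string(residues))
    stop("illegal characters in sequence '", id, "'")
  structure(list(id = id, residues = residues, topology = topology),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp (%s)\n",
              x$id, nchar(x$residues), x$topology))
  invisible(x)
}

#' @export
length.genome_sequence <- function(x) nchar(x$residues)

#' Read a (multi-)FASTA file
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record (circular only for
#'   single-record mitochondrial input).
#' @return A list of [genome_sequence()] records, order preserved, residues
#'   upper-cased.
#' @export
read_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(list())
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("malformed FASTA: line ", nonblank[1], " is not a header")
  for (i in nonblank) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (nchar(trimws(ln)) < 2L)
        stop("malformed FASTA header at line ", i)
    } else if (!is_dna_string(gsub("[ \t]", "", ln))) {
      stop("illegal sequence characters at line ", i)
    }
  }
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  if (topology == "circular" && length(set) != 1L)
    stop("circular topology is only permitted for single-record input")
  mapply(function(id, seq) genome_sequence(id, seq, topology),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write sequences to FASTA
#'
#' @param seqs A list of [genome_sequence()] records (or a named character
#'   vector of residues).
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    set <- Biostrings::DNAStringSet(seqs)
  } else {
    set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$residues, ""))
    names(set) <- vapply(seqs, function(s) s$id, "")
  }
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.infer_category <- function(gene_id) {
  ifelse(grepl("^trn", gene_id, ignore.case = TRUE), "tRNA",
         ifelse(grepl("^rrn", gene_id, ignore.case = TRUE), "rRNA", "PCG"))
}

.check_gene_complement <- function(ann) {
  tab <- table(factor(ann$category, levels = c("PCG", "rRNA", "tRNA")))
  if (!(tab[["PCG"]] == 13L && tab[["rRNA"]] == 2L && tab[["tRNA"]] == 22L))
    warning(sprintf(
      "annotation has %d PCG / %d rRNA / %d tRNA genes; a complete mitogenome annotation has 13/2/22",
      tab[["PCG"]], tab[["rRNA"]], tab[["tRNA"]]), call. = FALSE)
  invisible(ann)
}

#' Read a mitochondrial gene annotation table
#'
#' Accepts GFF3 (1-based inclusive) or a BED-like TSV (0-based half-open);
#' both are normalized to the package-internal 0-based half-open convention.
#' A gene crossing the origin of a circular mitogenome is encoded with
#' `end` greater than the sequence length (coordinates continue past the
#' origin); pass `seq_length` to have such genes flagged via the `wraps`
#' column and coordinates validated.
#'
#' @param path Annotation file.
#' @param dialect `"gff3"` or `"bed_tsv"`. BED-like TSVs may have 2 columns
#'   (start, end), 4+ columns (chrom, start, end, name, \[score, strand,
#'   category\]).
#' @param seq_length Optional mitogenome length used for validation and wrap
#'   detection.
#' @return A data.frame with columns `gene_id`, `start`, `end` (0-based
#'   half-open), `strand`, `category`, `wraps`.
#' @export
read_annotation <- function(path, dialect = c("gff3", "bed_tsv"),
                            seq_length = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gff3") {
    g <- as.data.frame(rtracklayer::readGFF(path))
    gene_id <- rep(NA_character_, nrow(g))
    for (col in c("gene", "Name", "ID")) {
      if (col %in% names(g)) {
        v <- as.character(g[[col]])
        gene_id <- ifelse(is.na(gene_id) & !is.na(v), v, gene_id)
      }
    }
    if (anyNA(gene_id)) stop("GFF3 records without gene/Name/ID attribute")
    ann <- data.frame(
      gene_id = gene_id,
      start = as.integer(g$start) - 1L,  # GFF3 1-based inclusive -> 0-based half-open
      end = as.integer(g$end),
      strand = ifelse(as.character(g$strand) == "-", "-", "+"),
      category = if ("category" %in% names(g)) as.character(g$category)
                 else NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    ncol_file <- max(count.fields(path, sep = "\t", comment.char = "#"))
    b <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
    if (ncol_file == 2L) {
      ann <- data.frame(
        gene_id = paste0("gene", seq_len(nrow(b))),
        start = as.integer(b[[1]]), end = as.integer(b[[2]]),
        strand = "+", category = NA_character_, stringsAsFactors = FALSE)
    } else if (ncol_file >= 4L) {
      ann <- data.frame(
        gene_id = as.character(b[[4]]),
        start = as.integer(b[[2]]), end = as.integer(b[[3]]),
        strand = if (ncol_file >= 6L) ifelse(b[[6]] == "-", "-", "+") else "+",
        category = if (ncol_file >= 7L) as.character(b[[7]]) else NA_character_,
        stringsAsFactors = FALSE)
    } else {
      stop("BED-like TSV must have 2 or >= 4 columns, got ", ncol_file)
    }
  }
  miss <- is.na(ann$category) | !(ann$category %in% c("PCG", "rRNA", "tRNA"))
  if (any(miss)) {
    warning(sprintf("%d annotation(s) without a known category; inferring from gene name prefix",
                    sum(miss)), call. = FALSE)
    ann$category[miss] <- .infer_category(ann$gene_id[miss])
  }
  if (any(ann$end <= ann$start))
    stop("annotation with end <= start: ",
         paste(ann$gene_id[ann$end <= ann$start], collapse = ", "))
  if (!is.null(seq_length)) {
    if (any(ann$start < 0L | ann$start >= seq_length))
      stop("annotation start outside the mitogenome")
    ann$wraps <- ann$end > seq_length
    if (any(ann$end[!ann$wraps] > seq_length))
      stop("annotation end outside the mitogenome")
  } else {
    ann$wraps <- FALSE
  }
  .check_gene_complement(ann)
  ann
}

#' Write a gene annotation table
#'
#' @param ann Annotation data.frame as returned by [read_annotation()].
#' @param path Output file.
#' @param seqid Sequence id the annotations refer to.
#' @param dialect `"gff3"` (1-based inclusive) or `"bed_tsv"` (0-based
#'   half-open BED6 plus a category column).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, seqid = "mitogenome",
                             dialect = c("gff3", "bed_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    lines <- c("##gff-version 3",
               sprintf("%s\tnumtr\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s;category=%s",
                       seqid, ann$start + 1L, ann$end, ann$strand,
                       ann$gene_id, ann$gene_id, ann$category))
    writeLines(lines, path)
  } else {
    df <- data.frame(seqid, ann$start, ann$end, ann$gene_id, 0L, ann$strand,
                     ann$category)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

.tabular_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
                   "mismatches", "gap_opens", "q_start", "q_end",
                   "s_start", "s_end", "e_value", "bit_score")

#' Read 12-column tabular homology hits
#'
#' The standard 12-column tab-separated hit layout (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore), as
#' produced by BLASTN and by [write_tabular_hits()]. Coordinates are 1-based
#' inclusive; a subject start greater than the subject end encodes a
#' minus-strand match and is preserved verbatim.
#'
#' @param path Tab-separated file, no header.
#' @return A data.frame with the 12 standard columns (empty if the file has
#'   no records).
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- as.data.frame(setNames(
    list(character(), character(), numeric(), integer(), integer(), integer(),
         integer(), integer(), integer(), integer(), numeric(), numeric()),
    .tabular_cols), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  nf <- count.fields(path, sep = "\t", comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0L) return(empty)
  bad <- which(nf != 12L)
  if (length(bad))
    stop("expected 12 tab-separated columns, got ", nf[bad[1]],
         " at line ", bad[1])
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "numeric", "integer",
                                 "integer", "integer", "integer", "integer",
                                 "integer", "integer", "numeric", "numeric"))
  names(d) <- .tabular_cols
  if (any(d$aln_length < 1L)) stop("tabular hit with aln_length < 1")
  if (any(d$pct_identity < 0 | d$pct_identity > 100))
    stop("tabular hit with pct_identity outside [0, 100]")
  if (any(d$q_start > d$q_end)) stop("tabular hit with q_start > q_end")
  d
}

#' Write hits in the 12-column tabular layout
#'
#' @param hits Either a 12-column tabular data.frame (from
#'   [read_tabular_hits()]) or an internal alignment-hit data.frame (from
#'   [local_align()]/[search_all()]), which is converted with
#'   [hits_to_tabular()] first.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  if (!all(.tabular_cols %in% names(hits))) hits <- hits_to_tabular(hits)
  d <- hits[, .tabular_cols]
  d$e_value <- vapply(d$e_value, function(e) format(e, digits = 15), "")
  d$pct_identity <- vapply(d$pct_identity, function(p) format(p, digits = 15), "")
  d$bit_score <- vapply(d$bit_score, function(b) format(b, digits = 15), "")
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert internal alignment hits to the 12-column tabular layout
#'
#' @param hits Alignment-hit data.frame from [local_align()] or
#'   [search_all()] (0-based half-open coordinates, explicit strand).
#' @return A data.frame with the 12 standard tabular columns (1-based
#'   inclusive coordinates; minus strand encoded as s_start > s_end).
#' @export
hits_to_tabular <- function(hits) {
  n_m <- vapply(strsplit(hits$cigar, "(?<=[MID])", perl = TRUE), function(ops) {
    lens <- as.integer(sub("[MID]$", "", ops))
    sum(lens[grepl("M$", ops)])
  }, 0L)
  gap_opens <- vapply(gregexpr("[0-9]+[ID]", hits$cigar), function(m)
    if (m[1] == -1L) 0L else length(m), 0L)
  minus <- hits$strand == "-"
  data.frame(
    query_id = hits$query_id,
    subject_id = hits$subject_id,
    pct_identity = 100 * hits$matches / hits$aligned_length,
    aln_length = hits$aligned_length,
    mismatches = n_m - hits$matches,
    gap_opens = gap_opens,
    q_start = hits$q_start + 1L,
    q_end = hits$q_end,
    s_start = ifelse(minus, hits$s_end, hits$s_start + 1L),
    s_end = ifelse(minus, hits$s_start + 1L, hits$s_end),
    e_value = hits$e_value,
    bit_score = hits$bit_score,
    stringsAsFactors = FALSE
  )
}

#' Convert 12-column tabular hits to internal alignment hits
#'
#' @param tab Tabular data.frame from [read_tabular_hits()].
#' @param query_lengths Optional named vector of query lengths, required to
#'   recompute query coverage (NA otherwise).
#' @return An alignment-hit data.frame in the internal convention (0-based
#'   half-open, explicit strand column).
#' @export
tabular_to_hits <- function(tab, query_lengths = NULL) {
  minus <- tab$s_start > tab$s_end
  qlen <- if (is.null(query_lengths)) rep(NA_integer_, nrow(tab))
          else unname(query_lengths[tab$query_id])
  matches <- as.integer(round(tab$pct_identity / 100 * tab$aln_length))
  data.frame(
    query_id = tab$query_id,
    subject_id = tab$subject_id,
    strand = ifelse(minus, "-", "+"),
    q_start = tab$q_start - 1L,
    q_end = tab$q_end,
    s_start = ifelse(minus, tab$s_end - 1L, tab$s_start - 1L),
    s_end = ifelse(minus, tab$s_start, tab$s_end),
    raw_score = NA_real_,
    bit_score = tab$bit_score,
    e_value = tab$e_value,
    aligned_length = tab$aln_length,
    matches = matches,
    identity_fraction = tab$pct_identity / 100,
    query_coverage = (tab$q_end - tab$q_start + 1L) / qlen,
    query_length = qlen,
    cigar = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write the per-species report files
#'
#' Emits four artifacts under `dir`: the called loci as BED6
#' (`loci.bed`, 0-based half-open, score = best bit score), a one-row
#' per-species summary TSV (`species_summary.tsv`, percentage formatted to 5
#' decimals), per-gene Numt counts (`gene_counts.tsv`), and a
#' machine-readable JSON of all statistics (`stats.json`).
#'
#' @param summary A `species_summary` object from [summarize_species()].
#' @param loci A `numt_loci` data.frame from [merge_to_loci()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(summary, loci, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2) != 0L) stop("cannot write to ", dir)
  bed_path <- file.path(dir, "loci.bed")
  if (nrow(loci)) {
    bed <- data.frame(loci$subject_id, loci$start, loci$end,
                      sprintf("numt_%04d", seq_len(nrow(loci))),
                      round(loci$best_bit_score, 1), ".")
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(character(), bed_path)
  }
  sum_path <- file.path(dir, "species_summary.tsv")
  srow <- data.frame(species = summary$species,
                     numt_count = summary$count,
                     numt_total_length = summary$total_length,
                     numt_pct_of_genome = sprintf("%.5f", summary$pct))
  write.table(srow, sum_path, sep = "\t", quote = FALSE, row.names = FALSE)
  gene_path <- file.path(dir, "gene_counts.tsv")
  gc <- data.frame(gene = names(summary$gene_counts),
                   numt_count = as.integer(summary$gene_counts))
  write.table(gc, gene_path, sep = "\t", quote = FALSE, row.names = FALSE)
  json_path <- file.path(dir, "stats.json")
  stats <- list(
    species = summary$species,
    numt_count = summary$count,
    numt_total_length = summary$total_length,
    numt_pct_of_genome = summary$pct,
    assembly_length = summary$assembly_length,
    gene_counts = as.list(summary$gene_counts),
    length_histogram = summary$length_histogram,
    at_convention = "AT/GC fractions computed over unambiguous bases only"
  )
  jsonlite::write_json(stats, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(bed = bed_path, summary = sum_path, genes = gene_path,
              json = json_path))
}

#' Published Numt survey of 27 Tortricidae species
#'
#' Per-species Numt content (count, total length, percentage of the nuclear
#' genome) for 27 leaf-roller moth (Tortricidae) species, as printed in a
#' published genome survey. Used as a worked-example input for the
#' aggregation and correlation operations; nuclear genome lengths can be
#' reconstructed as `100 * numt_total_length / numt_pct_of_genome`.
#'
#' @return A 27-row data.frame with columns `species`, `subfamily`,
#'   `numt_count`, `numt_total_length`, `numt_pct_of_genome`.
#' @export
tortricidae_numt_survey <- function() {
  path <- system.file("extdata", "tortricidae_numts.tsv", package = "numtr",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
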