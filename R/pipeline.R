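# Pipeline orchestration: each stage reads its inputs from files (either
# user-supplied paths or artifacts of earlier stages under the output
# directory), so stages can be run in isolation or chained. All randomness
# flows from the single top-level seed via named substreams per stage.

#' Build a pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param assembly,mitogenome,annotation Input paths (FASTA, FASTA, GFF3);
#'   defaulted to the simulate-stage artifacts under `out_dir` when absent.
#' @param annotation_dialect `"gff3"` or `"bed_tsv"`.
#' @param species Label used in reports.
#' @param seed Top-level seed.
#' @param scheme Named list of [scoring_scheme()] overrides.
#' @param thresholds Named list of [filter_thresholds()] overrides.
#' @param search Named list of [local_align()] tuning overrides
#'   (`min_raw_score`, `x_drop`, `band`, `pad`).
#' @param flank_window Flank window in bp.
#' @param simulation Named list of [simulation_config()] overrides; presence
#'   enables the simulate stage (an empty list uses the defaults).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, assembly = NULL, mitogenome = NULL,
                            annotation = NULL, annotation_dialect = "gff3",
                            species = "assembly", seed = 1L, scheme = list(),
                            thresholds = list(), search = list(),
                            flank_window = 100L, simulation = NULL) {
  structure(list(out_dir = out_dir, assembly = assembly,
                 mitogenome = mitogenome, annotation = annotation,
                 annotation_dialect = annotation_dialect, species = species,
                 seed = as.integer(seed), scheme = scheme,
                 thresholds = thresholds, search = search,
                 flank_window = as.integer(flank_window),
                 simulation = simulation),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.cfg_scheme <- function(cfg) do.call(scoring_scheme, cfg$scheme %||% list())
.cfg_thresholds <- function(cfg) do.call(filter_thresholds, cfg$thresholds %||% list())
.cfg_simulation <- function(cfg) {
  args <- cfg$simulation %||% list()
  if (is.null(args$seed)) args$seed <- cfg$seed
  if (!is.null(args$fragment_length_range))
    args$fragment_length_range <- unlist(args$fragment_length_range)
  if (!is.null(args$contig_lengths))
    args$contig_lengths <- unlist(args$contig_lengths)
  do.call(simulation_config, args)
}

.artifact <- function(cfg, name) file.path(cfg$out_dir, name)

.input_path <- function(cfg, key, default_artifact) {
  p <- cfg[[key]] %||% .artifact(cfg, default_artifact)
  if (!file.exists(p)) stop("missing input for stage: ", p)
  p
}

.write_manifest <- function(cfg, stage, extra = list()) {
  scheme <- .cfg_scheme(cfg)
  thr <- .cfg_thresholds(cfg)
  manifest <- c(list(
    stage = stage,
    package = "numtr",
    version = as.character(packageVersion("numtr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    species = cfg$species,
    scoring = list(match = scheme$match, mismatch = scheme$mismatch,
                   gap_open = scheme$gap_open, gap_extend = scheme$gap_extend,
                   word_size = scheme$word_size, lambda = scheme$lambda,
                   K = scheme$K),
    thresholds = list(max_evalue = thr$max_evalue,
                      min_length_exclusive = thr$min_length_exclusive,
                      min_identity_exclusive = thr$min_identity_exclusive,
                      exclude_full_query_coverage = thr$exclude_full_query_coverage),
    flank_window = cfg$flank_window,
    inputs = list(assembly = cfg$assembly, mitogenome = cfg$mitogenome,
                  annotation = cfg$annotation)
  ), extra)
  jsonlite::write_json(manifest, .artifact(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.read_assembly <- function(cfg)
  read_fasta(.input_path(cfg, "assembly", "assembly.fasta"))

.read_mito <- function(cfg) {
  seqs <- read_fasta(.input_path(cfg, "mitogenome", "mitogenome.fasta"),
                     topology = "circular")
  seqs[[1]]
}

.read_ann <- function(cfg, mito = NULL) {
  read_annotation(.input_path(cfg, "annotation", "annotation.gff3"),
                  dialect = cfg$annotation_dialect,
                  seq_length = if (is.null(mito)) NULL else nchar(mito$residues))
}

.write_loci_tsv <- function(loci, path) {
  df <- data.frame(subject_id = loci$subject_id, start = loci$start,
                   end = loci$end, length = loci$length, n_hits = loci$n_hits,
                   best_bit_score = loci$best_bit_score,
                   source_genes = vapply(loci$source_genes, paste,
                                         collapse = ",", ""))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_loci_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer", "integer",
                                  "integer", "numeric", "character"))
  genes <- strsplit(df$source_genes, ",", fixed = TRUE)
  genes[df$source_genes == "" | is.na(df$source_genes)] <- list(character(0))
  df$source_genes <- genes
  class(df) <- c("numt_loci", "data.frame")
  df
}

.stage_simulate <- function(cfg) {
  sim <- .cfg_simulation(cfg)
  g <- simulate_genome(sim)
  write_fasta(g$assembly, .artifact(cfg, "assembly.fasta"))
  write_fasta(list(g$mito), .artifact(cfg, "mitogenome.fasta"))
  write_annotation(g$annotations, .artifact(cfg, "annotation.gff3"),
                   seqid = g$mito$id, dialect = "gff3")
  write.table(g$truth, .artifact(cfg, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  bed <- data.frame(g$truth$contig, g$truth$start, g$truth$end,
                    g$truth$source_gene,
                    round(1000 * g$truth$realized_identity), "+")
  write.table(bed, .artifact(cfg, "truth.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(unclass(sim), .artifact(cfg, "simulation_config.yaml"))
  c("assembly.fasta", "mitogenome.fasta", "annotation.gff3", "truth.tsv",
    "truth.bed", "simulation_config.yaml")
}

.stage_extract_genes <- function(cfg) {
  mito <- .read_mito(cfg)
  ann <- .read_ann(cfg, mito)
  genes <- extract_genes(mito, ann)
  set <- setNames(vapply(genes, function(g) g$residues, ""),
                  vapply(genes, function(g) g$gene_id, ""))
  write_fasta(set, .artifact(cfg, "genes.fasta"))
  "genes.fasta"
}

.stage_codons <- function(cfg) {
  mito <- .read_mito(cfg)
  ann <- .read_ann(cfg, mito)
  usage <- tabulate_codons(extract_genes(mito, ann))
  write_codon_usage(usage, .artifact(cfg, "codon_usage.tsv"))
  "codon_usage.tsv"
}

.stage_search <- function(cfg) {
  mito <- .read_mito(cfg)
  ann <- .read_ann(cfg, mito)
  assembly <- .read_assembly(cfg)
  genes <- extract_genes(mito, ann)
  queries <- c(genes, list(mito))
  scheme <- .cfg_scheme(cfg)
  hits <- do.call(search_all,
                  c(list(queries = queries, assembly = assembly,
                         scheme = scheme), cfg$search %||% list()))
  write_tabular_hits(hits, .artifact(cfg, "hits.tsv"))
  "hits.tsv"
}

.stage_call <- function(cfg) {
  mito <- .read_mito(cfg)
  ann <- .read_ann(cfg, mito)
  assembly <- .read_assembly(cfg)
  tab <- read_tabular_hits(.artifact(cfg, "hits.tsv"))
  genes <- extract_genes(mito, ann)
  qlen <- c(setNames(vapply(genes, function(g) nchar(g$residues), 0L),
                     vapply(genes, function(g) g$gene_id, "")),
            setNames(nchar(mito$residues), mito$id))
  hits <- tabular_to_hits(tab, query_lengths = qlen)
  kept <- filter_hits(hits, .cfg_thresholds(cfg))
  loci <- merge_to_loci(kept, gene_ids = ann$gene_id)
  total_len <- sum(vapply(assembly, function(x) nchar(x$residues), 0))
  summary <- summarize_species(loci, total_len, species = cfg$species,
                               genes = ann$gene_id[ann$category == "PCG"])
  write_report(summary, loci, cfg$out_dir)
  .write_loci_tsv(loci, .artifact(cfg, "loci.tsv"))
  c("loci.bed", "loci.tsv", "species_summary.tsv", "gene_counts.tsv",
    "stats.json")
}

.stage_flanks <- function(cfg) {
  assembly <- .read_assembly(cfg)
  loci <- .read_loci_tsv(.artifact(cfg, "loci.tsv"))
  fl <- extract_flanks(loci, assembly, window = cfg$flank_window)
  if (nrow(fl)) {
    seqs <- c(setNames(fl$upstream_seq,
                       sprintf("numt_%04d_up", seq_len(nrow(fl)))),
              setNames(fl$downstream_seq,
                       sprintf("numt_%04d_down", seq_len(nrow(fl)))))
    write_fasta(seqs[nzchar(seqs)], .artifact(cfg, "flanks.fasta"))
  } else {
    writeLines(character(), .artifact(cfg, "flanks.fasta"))
  }
  write.table(fl[, c("subject_id", "start", "end", "upstream_at",
                     "downstream_at", "clipped")],
              .artifact(cfg, "flank_at.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  c("flanks.fasta", "flank_at.tsv")
}

.stage_stats <- function(cfg) {
  assembly <- .read_assembly(cfg)
  loci <- .read_loci_tsv(.artifact(cfg, "loci.tsv"))
  fl <- extract_flanks(loci, assembly, window = cfg$flank_window)
  genome_at <- pooled_at(vapply(assembly, function(x) x$residues, ""))
  flank <- if (nrow(fl)) flank_at_summary(fl)
           else list(flank_at = NA_real_, upstream_at = NA_real_,
                     downstream_at = NA_real_)
  stats <- list(species = cfg$species,
                numt_count = nrow(loci),
                numt_total_length = sum(loci$length),
                genome_at = genome_at,
                flank_at = flank$flank_at,
                upstream_at = flank$upstream_at,
                downstream_at = flank$downstream_at,
                at_convention = "unambiguous bases only")
  jsonlite::write_json(stats, .artifact(cfg, "analysis.json"),
                       auto_unbox = TRUE, digits = NA)
  "analysis.json"
}

.stage_evaluate <- function(cfg) {
  loci <- .read_loci_tsv(.artifact(cfg, "loci.tsv"))
  truth <- read.delim(.artifact(cfg, "truth.tsv"), stringsAsFactors = FALSE)
  ev <- evaluate_calls(loci, truth)
  jsonlite::write_json(list(recall = ev$recall, precision = ev$precision,
                            n_truth = nrow(truth), n_loci = nrow(loci)),
                       .artifact(cfg, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  "evaluation.json"
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic benchmark generation), `extract-genes`,
#' `codons`, `search`, `call`, `flanks`, `stats`, `evaluate`, and `pipeline`
#' (chains simulate, when a simulation block is present, then
#' extract-genes, codons, search, call, flanks, stats and, when a truth
#' table exists, evaluate). A `manifest.json` recording all effective
#' parameter values is always written; partially written stage artifacts
#' are removed on failure.
#'
#' @param name Stage name.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_subcommand <- function(name, cfg) {
  stages <- list("simulate" = .stage_simulate,
                 "extract-genes" = .stage_extract_genes,
                 "codons" = .stage_codons,
                 "search" = .stage_search,
                 "call" = .stage_call,
                 "flanks" = .stage_flanks,
                 "stats" = .stage_stats,
                 "evaluate" = .stage_evaluate)
  if (!name %in% c(names(stages), "pipeline"))
    stop("unknown subcommand: ", name)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "pipeline") {
    chain <- c(if (!is.null(cfg$simulation)) "simulate",
               "extract-genes", "codons", "search", "call", "flanks", "stats")
    arts <- unlist(lapply(chain, run_subcommand, cfg = cfg))
    if (file.exists(.artifact(cfg, "truth.tsv")))
      arts <- c(arts, run_subcommand("evaluate", cfg))
    .write_manifest(cfg, "pipeline")
    return(invisible(arts))
  }
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(cfg$out_dir, written)))
  written <- stages[[name]](cfg)
  ok <- TRUE
  .write_manifest(cfg, name)
  invisible(file.path(cfg$out_dir, written))
}

#' Run the full pipeline
#'
#' Equivalent to `run_subcommand("pipeline", cfg)`.
#' @param cfg A [pipeline_config()] (or path to a YAML config).
#' @return Invisibly, the artifact paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  run_subcommand("pipeline", cfg)
}
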