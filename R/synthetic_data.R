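# Synthetic benchmark generator: a random nuclear assembly (optionally with
# AT-rich hotspots), an annotated circular mitogenome (13 PCG + 2 rRNA +
# 22 tRNA), and planted mtDNA fragments with controlled divergence and
# insertion-site AT bias, plus the ground-truth table used for
# recall/precision evaluation.

# Gene inventory in a typical insect mitogenome order. PCG lengths include
# start and (full) stop codons and are multiples of 3.
.mito_genes <- data.frame(
  gene_id = c("trnM", "trnI", "trnQ", "nad2", "trnW", "trnC", "trnY", "cox1",
              "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3", "trnG",
              "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF", "nad5",
              "trnH", "nad4", "nad4l", "trnT", "trnP", "nad6", "cob", "trnS2",
              "nad1", "trnL1", "rrnL", "trnV", "rrnS"),
  category = c("tRNA", "tRNA", "tRNA", "PCG", "tRNA", "tRNA", "tRNA", "PCG",
               "tRNA", "PCG", "tRNA", "tRNA", "PCG", "PCG", "PCG", "tRNA",
               "PCG", "tRNA", "tRNA", "tRNA", "tRNA", "tRNA", "tRNA", "PCG",
               "tRNA", "PCG", "PCG", "tRNA", "tRNA", "PCG", "PCG", "tRNA",
               "PCG", "tRNA", "rRNA", "tRNA", "rRNA"),
  strand = c("+", "+", "-", "+", "+", "-", "-", "+",
             "+", "+", "+", "+", "+", "+", "+", "+",
             "+", "+", "+", "+", "+", "+", "-", "-",
             "-", "-", "-", "+", "-", "+", "+", "+",
             "-", "-", "-", "-", "-"),
  length = c(66L, 66L, 66L, 1023L, 66L, 66L, 66L, 1533L,
             66L, 681L, 66L, 66L, 165L, 678L, 789L, 66L,
             354L, 66L, 66L, 66L, 66L, 66L, 66L, 1740L,
             66L, 1341L, 294L, 66L, 66L, 528L, 1137L, 66L,
             939L, 66L, 1350L, 66L, 780L),
  stringsAsFactors = FALSE
)

.sample_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE, prob = p)]
}

#' Configuration for the synthetic Numt benchmark
#'
#' The defaults define the standard benchmark: a 120-kb assembly in three
#' contigs at lepidopteran-like nuclear GC (0.38), an AT-rich (~19% GC)
#' 15.6-kb circular mitogenome with the full 37-gene complement, and 20
#' planted fragments of 150-1500 bp at 5% substitution and 0.5% indel
#' divergence with unbiased (beta = 0) insertion sites.
#'
#' @param seed Top-level RNG seed; every stage derives a named substream
#'   from it.
#' @param n_contigs,contig_lengths Assembly shape (lengths recycled to
#'   `n_contigs`).
#' @param gc_content Nuclear background GC fraction.
#' @param hotspots `NULL`, or `list(count=, length=, at_level=)`: AT-rich
#'   windows overwritten into the assembly.
#' @param mito_length,mito_gc Mitogenome length (must fit 37 genes; typical
#'   insect mitogenomes are 15-17 kb) and GC.
#' @param n_numts Number of planted fragments.
#' @param fragment_length_range Min/max planted fragment length (bp).
#' @param gene_weights Named sampling weights for the source gene; `NULL`
#'   means uniform over the 13 protein-coding genes. See
#'   [cox1_biased_weights()] for the cox1-dominated preset.
#' @param substitution_rate Per-site substitution probability (substitutions
#'   always change the base, uniformly over the 3 alternatives).
#' @param indel_rate Per-site indel initiation probability; lengths are
#'   geometric with mean `indel_length_mean`.
#' @param indel_length_mean Mean indel length (bp).
#' @param insertion_bias_beta Insertion-site weight exponent: sites are
#'   chosen with probability proportional to (local AT over a 100-bp
#'   centered window)^beta; 0 = uniform.
#' @param min_site_distance Minimum distance between insertion sites on one
#'   contig (keeps the 100-bp flank windows of one Numt clear of its
#'   neighbours).
#' @param edge_margin Insertion sites are kept this far from contig ends.
#' @param start_codon_weights,stop_codon_weights Sampling weights for PCG
#'   start codons (ATG/ATT/ATC/ATA/CGA) and stop codons (TAA/TAG/TGA plus
#'   incomplete T/TA).
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(seed = 1L,
                              n_contigs = 3L,
                              contig_lengths = c(50000L, 40000L, 30000L),
                              gc_content = 0.38,
                              hotspots = NULL,
                              mito_length = 15600L,
                              mito_gc = 0.19,
                              n_numts = 20L,
                              fragment_length_range = c(150L, 1500L),
                              gene_weights = NULL,
                              substitution_rate = 0.05,
                              indel_rate = 0.005,
                              indel_length_mean = 2,
                              insertion_bias_beta = 0,
                              min_site_distance = 200L,
                              edge_margin = 150L,
                              start_codon_weights = c(ATG = 0.55, ATT = 0.15,
                                                      ATC = 0.05, ATA = 0.15,
                                                      CGA = 0.10),
                              stop_codon_weights = c(TAA = 0.60, TAG = 0.15,
                                                     TGA = 0.05, T = 0.12,
                                                     TA = 0.08)) {
  contig_lengths <- rep_len(as.integer(contig_lengths), n_contigs)
  stopifnot(all(contig_lengths > 0), gc_content >= 0, gc_content <= 1,
            mito_length > 0, mito_gc >= 0, mito_gc <= 1, n_numts >= 0,
            length(fragment_length_range) == 2L,
            fragment_length_range[1] >= 1L,
            fragment_length_range[1] <= fragment_length_range[2],
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1, indel_length_mean >= 1,
            insertion_bias_beta >= 0, min_site_distance >= 0)
  if (!is.null(gene_weights)) {
    stopifnot(all(gene_weights >= 0), any(gene_weights > 0),
              !is.null(names(gene_weights)))
  }
  if (!is.null(hotspots))
    stopifnot(is.list(hotspots), hotspots$count >= 0, hotspots$length > 0,
              hotspots$at_level >= 0, hotspots$at_level <= 1)
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_lengths = contig_lengths, gc_content = gc_content,
                 hotspots = hotspots, mito_length = as.integer(mito_length),
                 mito_gc = mito_gc, n_numts = as.integer(n_numts),
                 fragment_length_range = as.integer(fragment_length_range),
                 gene_weights = gene_weights,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 insertion_bias_beta = insertion_bias_beta,
                 min_site_distance = as.integer(min_site_distance),
                 edge_margin = as.integer(edge_margin),
                 start_codon_weights = start_codon_weights,
                 stop_codon_weights = stop_codon_weights),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> seed %d: %d contig(s) (%s bp, GC %.2f), ",
                     "mito %d bp, %d numts (%d-%d bp, d = %g, g = %g, beta = %g)\n"),
              x$seed, x$n_contigs, paste(x$contig_lengths, collapse = "+"),
              x$gc_content, x$mito_length, x$n_numts,
              x$fragment_length_range[1], x$fragment_length_range[2],
              x$substitution_rate, x$indel_rate, x$insertion_bias_beta))
  invisible(x)
}

#' cox1-dominated gene sampling weights
#'
#' A preset for [simulation_config()] `gene_weights` in which cox1 is the
#' most likely source gene (weight 5) over the other 12 protein-coding genes
#' (weight 1 each), emulating the cox1-dominated transfer profile reported
#' in insect Numt surveys.
#'
#' @return Named numeric weight vector over the 13 PCGs.
#' @export
cox1_biased_weights <- function() {
  pcgs <- .mito_genes$gene_id[.mito_genes$category == "PCG"]
  w <- setNames(rep(1, length(pcgs)), pcgs)
  w["cox1"] <- 5
  w
}

#' Generate a random nuclear assembly
#'
#' I.i.d. bases at the configured GC; optional AT-rich hotspot windows are
#' overwritten into random non-overlapping positions. Deterministic for a
#' fixed config (seed substream "assembly").
#'
#' @param cfg A [simulation_config()].
#' @return List of `genome_sequence` contigs named `contig_1`, ...
#' @export
generate_assembly <- function(cfg) {
  with_seed(stage_seed(cfg$seed, "assembly"), {
    contigs <- lapply(seq_len(cfg$n_contigs), function(i) {
      len <- cfg$contig_lengths[i]
      bases <- .sample_bases(len, cfg$gc_content)
      genome_sequence(sprintf("contig_%d", i), paste(bases, collapse = ""))
    })
    if (!is.null(cfg$hotspots) && cfg$hotspots$count > 0) {
      hl <- as.integer(cfg$hotspots$length)
      total <- sum(cfg$contig_lengths)
      for (k in seq_len(cfg$hotspots$count)) {
        ci <- sample.int(cfg$n_contigs, 1L, prob = cfg$contig_lengths / total)
        len <- cfg$contig_lengths[ci]
        if (len <= hl + 2L) next
        at_gc <- 1 - cfg$hotspots$at_level
        start <- sample.int(len - hl, 1L)
        window <- paste(.sample_bases(hl, at_gc), collapse = "")
        res <- contigs[[ci]]$residues
        contigs[[ci]]$residues <- paste0(substr(res, 1L, start - 1L), window,
                                         substr(res, start + hl, len))
      }
    }
    contigs
  })
}

.sample_codon <- function(weights) {
  names(weights)[sample.int(length(weights), 1L, prob = weights)]
}

#' Generate an annotated circular mitogenome
#'
#' Packs the full 37-gene complement (13 protein-coding genes, 2 rRNAs, 22
#' tRNAs) in a typical insect gene order with short random spacers, filling
#' the remainder with an AT-rich control-region-like tail. Each PCG gets a
#' known start codon (sampled from `start_codon_weights`) and stop codon
#' (full TAA/TAG/TGA or incomplete T/TA, shortening the gene by 2 or 1 bp);
#' the assignment is returned as `codon_truth` so codon tabulation can be
#' verified in closed loop. Deterministic for a fixed config (seed substream
#' "mitogenome").
#'
#' @param cfg A [simulation_config()].
#' @param wrap_origin If `TRUE`, rotate the circle so the first gene spans
#'   the origin (exercises the coordinate-wrapping path).
#' @return List with `mito` (a circular `genome_sequence`), `annotations`
#'   (0-based half-open, `wraps` flagged), and `codon_truth` (gene_id,
#'   start_codon, stop_codon).
#' @export
generate_mitogenome <- function(cfg, wrap_origin = FALSE) {
  with_seed(stage_seed(cfg$seed, "mitogenome"), {
    genes <- .mito_genes
    spacers <- sample.int(21L, nrow(genes), replace = TRUE) - 1L
    pieces <- character(0)
    ann <- vector("list", nrow(genes))
    truth <- vector("list", nrow(genes))
    cursor <- 0L
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      sp <- spacers[i]
      if (sp > 0L) pieces <- c(pieces, paste(.sample_bases(sp, cfg$mito_gc),
                                             collapse = ""))
      cursor <- cursor + sp
      if (g$category == "PCG") {
        start_codon <- .sample_codon(cfg$start_codon_weights)
        stop_codon <- .sample_codon(cfg$stop_codon_weights)
        body <- paste(.sample_bases(g$length - 6L, cfg$mito_gc), collapse = "")
        reading <- paste0(start_codon, body, stop_codon)
        truth[[i]] <- data.frame(gene_id = g$gene_id,
                                 start_codon = start_codon,
                                 stop_codon = stop_codon,
                                 stringsAsFactors = FALSE)
      } else {
        reading <- paste(.sample_bases(g$length, cfg$mito_gc), collapse = "")
      }
      glen <- nchar(reading)
      genomic <- if (g$strand == "-") revcomp(reading) else reading
      pieces <- c(pieces, genomic)
      ann[[i]] <- data.frame(gene_id = g$gene_id, start = cursor,
                             end = cursor + glen, strand = g$strand,
                             category = g$category, wraps = FALSE,
                             stringsAsFactors = FALSE)
      cursor <- cursor + glen
    }
    if (cursor + 100L > cfg$mito_length)
      stop("mito_length ", cfg$mito_length,
           " too short to pack the 37-gene complement (needs > ",
           cursor + 100L, " bp)")
    tail_len <- cfg$mito_length - cursor
    pieces <- c(pieces, paste(.sample_bases(tail_len, 0.1), collapse = ""))
    seq <- paste(pieces, collapse = "")
    annotations <- do.call(rbind, ann)
    if (wrap_origin) {
      # rotate so the first gene spans the origin
      L <- cfg$mito_length
      widths <- annotations$end - annotations$start
      rot <- (annotations$start[1] + widths[1] %/% 2L) %% L
      seq <- paste0(substr(seq, rot + 1L, L), substr(seq, 1L, rot))
      annotations$start <- (annotations$start - rot) %% L
      annotations$end <- annotations$start + widths
      annotations$wraps <- annotations$end > L
    }
    list(mito = genome_sequence("mitogenome", seq, "circular"),
         annotations = annotations,
         codon_truth = do.call(rbind, truth))
  })
}

# Circular substring: 0-based half-open [from, to) with to possibly > L.
.circular_substr <- function(res, from, to) {
  L <- nchar(res)
  if (to <= L) substr(res, from + 1L, to)
  else paste0(substr(res, from + 1L, L), substr(res, 1L, to - L))
}

# Apply substitutions (rate d, uniform over alternatives) and indels
# (rate g, geometric lengths) to a fragment; returns the mutated sequence
# and the realized identity = matches / alignment columns.
.mutate_fragment <- function(frag, d, g, indel_mean) {
  bases <- strsplit(frag, "")[[1]]
  n <- length(bases)
  alternatives <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                       G = c("A", "C", "T"), T = c("A", "C", "G"))
  sub_mask <- stats::runif(n) < d
  for (i in which(sub_mask)) {
    alt <- alternatives[[bases[i]]]
    if (!is.null(alt)) bases[i] <- alt[sample.int(3L, 1L)]
    else sub_mask[i] <- FALSE  # ambiguity code left untouched
  }
  kept <- rep(TRUE, n)
  pieces <- vector("list", n)
  n_ins <- 0L
  if (g > 0) {
    ev <- stats::runif(n) < g
    i <- 1L
    while (i <= n) {
      if (ev[i] && kept[i]) {
        len <- stats::rgeom(1L, 1 / indel_mean) + 1L
        if (stats::runif(1) < 0.5) {
          drop <- i:min(n, i + len - 1L)
          kept[drop] <- FALSE
          i <- i + length(drop)
          next
        } else {
          ins <- .sample_bases(len, 0.5)
          pieces[[i]] <- c(ins, bases[i])
          n_ins <- n_ins + len
          i <- i + 1L
          next
        }
      }
      i <- i + 1L
    }
  }
  out <- character(n)
  for (i in seq_len(n)) {
    if (!kept[i]) next
    out[i] <- if (is.null(pieces[[i]])) bases[i]
              else paste(pieces[[i]], collapse = "")
  }
  n_del <- sum(!kept)
  matches <- sum(kept & !sub_mask)
  columns <- sum(kept) + n_ins + n_del
  list(seq = paste(out[kept | nzchar(out)], collapse = ""),
       realized_identity = matches / columns)
}

# Rolling AT fraction over a centered window (used for biased site choice).
.window_at_profile <- function(res, half = 50L) {
  v <- as.integer(strsplit(res, "")[[1]] %in% c("A", "T"))
  n <- length(v)
  cs <- c(0L, cumsum(v))
  pos <- seq_len(n)
  lo <- pmax(0L, pos - half)
  hi <- pmin(n, pos + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Plant diverged mitochondrial fragments into an assembly
#'
#' For each of `n_numts` fragments: a source gene is sampled by weight, a
#' fragment of random length starting inside that gene is cut from the
#' (circular) mitogenome, mutated at the configured substitution and indel
#' rates, and inserted at a site chosen with probability proportional to
#' (local 100-bp AT)^beta, respecting a minimum distance between sites.
#' Insertions never overlap; truth coordinates are reported in the final
#' (post-insertion) coordinate system. Deterministic for a fixed config
#' (seed substream "plant").
#'
#' @param assembly List of `genome_sequence` contigs (pre-insertion).
#' @param mito The mitogenome `genome_sequence`.
#' @param annotations Mitogenome annotation data.frame.
#' @param cfg A [simulation_config()].
#' @return List with `assembly` (mutated contigs) and `truth` (one row per
#'   planted Numt: contig, 0-based half-open interval, source gene and
#'   coordinates, rates, realized identity).
#' @export
plant_numts <- function(assembly, mito, annotations, cfg) {
  with_seed(stage_seed(cfg$seed, "plant"), {
    n <- cfg$n_numts
    truth_template <- data.frame(
      contig = character(), start = integer(), end = integer(),
      source_gene = character(), source_start = integer(),
      source_end = integer(), fragment_length = integer(),
      substitution_rate = numeric(), indel_rate = numeric(),
      realized_identity = numeric(), stringsAsFactors = FALSE)
    if (n == 0L)
      return(list(assembly = assembly, truth = truth_template))
    weights <- cfg$gene_weights
    if (is.null(weights)) {
      pcgs <- annotations$gene_id[annotations$category == "PCG"]
      weights <- setNames(rep(1, length(pcgs)), pcgs)
    }
    if (!all(names(weights) %in% annotations$gene_id))
      stop("gene_weights refer to genes absent from the annotation")
    L <- nchar(mito$residues)
    contig_lengths <- vapply(assembly, function(x) nchar(x$residues), 0L)
    contig_of <- sample.int(length(assembly), n, replace = TRUE,
                            prob = contig_lengths / sum(contig_lengths))
    # per-contig site weights (computed once, on the pre-insertion sequence)
    profiles <- lapply(seq_along(assembly), function(ci) {
      if (cfg$insertion_bias_beta == 0) return(NULL)
      .window_at_profile(assembly[[ci]]$residues)^cfg$insertion_bias_beta
    })
    sites <- integer(n)
    frags <- character(n)
    meta <- vector("list", n)
    chosen <- lapply(seq_along(assembly), function(i) integer(0))
    for (k in seq_len(n)) {
      gene <- names(weights)[sample.int(length(weights), 1L, prob = weights)]
      a <- annotations[annotations$gene_id == gene, ][1, ]
      frag_len <- sample(seq(cfg$fragment_length_range[1],
                             cfg$fragment_length_range[2]), 1L)
      src_start <- a$start + sample.int(max(1L, a$end - a$start), 1L) - 1L
      src_start <- src_start %% L
      src_end <- src_start + frag_len
      if (src_end > 2L * L) src_end <- 2L * L  # cap at one full wrap
      frag <- .circular_substr(mito$residues, src_start, src_end)
      mut <- .mutate_fragment(frag, cfg$substitution_rate, cfg$indel_rate,
                              cfg$indel_length_mean)
      ci <- contig_of[k]
      clen <- contig_lengths[ci]
      lo <- cfg$edge_margin
      hi <- clen - cfg$edge_margin
      if (hi <= lo) stop("contig ", ci, " too short for edge_margin")
      placed <- FALSE
      for (try in seq_len(1000L)) {
        if (is.null(profiles[[ci]])) {
          site <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        } else {
          w <- profiles[[ci]][(lo + 1L):(hi + 1L)]
          site <- lo + sample.int(length(w), 1L, prob = pmax(w, 1e-12)) - 1L
        }
        if (all(abs(site - chosen[[ci]]) >= cfg$min_site_distance)) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("cannot place insertion ", k,
             " without violating min_site_distance after 1000 tries")
      chosen[[ci]] <- c(chosen[[ci]], site)
      sites[k] <- site
      frags[k] <- mut$seq
      meta[[k]] <- data.frame(
        contig = assembly[[ci]]$id, contig_idx = ci, site = site,
        source_gene = gene, source_start = src_start, source_end = src_end,
        fragment_length = nchar(mut$seq),
        substitution_rate = cfg$substitution_rate,
        indel_rate = cfg$indel_rate,
        realized_identity = mut$realized_identity,
        stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, meta)
    meta$frag <- frags
    out_assembly <- assembly
    truth <- vector("list", n)
    for (ci in seq_along(assembly)) {
      rows <- which(meta$contig_idx == ci)
      if (!length(rows)) next
      rows <- rows[order(meta$site[rows])]
      res <- assembly[[ci]]$residues
      pieces <- character(0)
      prev <- 0L
      offset <- 0L
      for (r in rows) {
        site <- meta$site[r]
        pieces <- c(pieces, substr(res, prev + 1L, site), meta$frag[r])
        start_final <- site + offset
        truth[[r]] <- data.frame(
          contig = meta$contig[r], start = start_final,
          end = start_final + meta$fragment_length[r],
          source_gene = meta$source_gene[r],
          source_start = meta$source_start[r],
          source_end = meta$source_end[r],
          fragment_length = meta$fragment_length[r],
          substitution_rate = meta$substitution_rate[r],
          indel_rate = meta$indel_rate[r],
          realized_identity = meta$realized_identity[r],
          stringsAsFactors = FALSE)
        offset <- offset + meta$fragment_length[r]
        prev <- site
      }
      pieces <- c(pieces, substr(res, prev + 1L, nchar(res)))
      out_assembly[[ci]]$residues <- paste(pieces, collapse = "")
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(assembly = out_assembly, truth = truth)
  })
}

#' Generate the complete synthetic benchmark
#'
#' Convenience wrapper chaining [generate_assembly()],
#' [generate_mitogenome()] and [plant_numts()].
#'
#' @param cfg A [simulation_config()].
#' @param wrap_origin Passed to [generate_mitogenome()].
#' @return List with `assembly` (post-insertion contigs), `clean_assembly`
#'   (pre-insertion), `mito`, `annotations`, `codon_truth`, `truth`.
#' @export
simulate_genome <- function(cfg = simulation_config(), wrap_origin = FALSE) {
  clean <- generate_assembly(cfg)
  mg <- generate_mitogenome(cfg, wrap_origin = wrap_origin)
  planted <- plant_numts(clean, mg$mito, mg$annotations, cfg)
  list(assembly = planted$assembly, clean_assembly = clean, mito = mg$mito,
       annotations = mg$annotations, codon_truth = mg$codon_truth,
       truth = planted$truth)
}

#' Compare called loci against the planted truth
#'
#' A truth record is recovered if at least one locus overlaps it by
#' `min_overlap` bp; a locus is a true positive if it overlaps any truth
#' record.
#'
#' @param loci A `numt_loci` data.frame (post-insertion coordinates).
#' @param truth Truth table from [plant_numts()].
#' @param min_overlap Minimum overlap in bp.
#' @return List with `recall`, `precision`, `truth_matched` (per-record
#'   logical), `locus_matched`, and `truth_locus_counts` (loci overlapping
#'   each truth record).
#' @export
evaluate_calls <- function(loci, truth, min_overlap = 1L) {
  truth_matched <- rep(FALSE, nrow(truth))
  truth_counts <- rep(0L, nrow(truth))
  locus_matched <- rep(FALSE, nrow(loci))
  for (sid in unique(c(truth$contig, loci$subject_id))) {
    ti <- which(truth$contig == sid)
    li <- which(loci$subject_id == sid)
    if (!length(ti) || !length(li)) next
    tr <- IRanges::IRanges(start = truth$start[ti] + 1L, end = truth$end[ti])
    lr <- IRanges::IRanges(start = loci$start[li] + 1L, end = loci$end[li])
    ov <- IRanges::findOverlaps(tr, lr, minoverlap = min_overlap)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    truth_matched[ti[unique(qh)]] <- TRUE
    truth_counts[ti] <- truth_counts[ti] + as.integer(table(factor(qh, levels = seq_along(ti))))
    locus_matched[li[unique(sh)]] <- TRUE
  }
  list(recall = if (nrow(truth)) mean(truth_matched) else NA_real_,
       precision = if (nrow(loci)) mean(locus_matched) else NA_real_,
       truth_matched = truth_matched,
       locus_matched = locus_matched,
       truth_locus_counts = truth_counts)
}
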