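#' A random mitochondrial-genome-like reference sequence
#'
#' Uniform random A/C/G/T sequence, by default at the 16,299-bp length of
#' the mouse mitochondrial genome. Used as the backbone for simulated
#' cohorts; the packaged annotation ([mito_annotation()]) matches this
#' length.
#'
#' @param length Genome length in bp.
#' @param seed Random seed.
#' @param name Sequence name.
#' @return An [mt_genome()].
#' @export
synthetic_mito_genome <- function(length = 16299L, seed = 1L,
                                  name = "chrM") {
  set.seed(substream_seed(seed, "genome", length))
  mt_genome(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = ""), name = name)
}

#' The packaged mouse-like mtDNA annotation
#'
#' A 38-feature annotation (13 protein genes, 22 tRNAs, 2 rRNAs, D-loop)
#' whose gene order, sizes, strands, and characteristic overlaps
#' (ATP8/ATP6, ND4L/ND4, ND5/ND6) follow the mouse mitochondrial gene
#' map on a 16,299-bp genome. Coordinates are synthetic approximations
#' of that layout, not a curated gene build.
#'
#' @param genome An [mt_genome()] of length 16299 to validate against.
#' @return A [gene_annotation()].
#' @export
mito_annotation <- function(genome) {
  path <- system.file("extdata", "mouse_like_mtdna_genes.bed",
                      package = "mitomut", mustWork = TRUE)
  suppressWarnings(read_annotation(path, genome))
}

#' Study-condition simulation presets
#'
#' `g10_config()` describes a G>=10-like mouse (ten maternal
#' transmissions through mutator-line dams); `g1_config()` a G1-like
#' founder from a wild-type dam (no inherited mutator variants). All
#' other parameters come from the [sim_config()] defaults.
#'
#' @param polg_genotype Nuclear genotype.
#' @param ... Further arguments passed to [sim_config()].
#' @return A [sim_config()].
#' @export
g10_config <- function(polg_genotype = "mut/mut", ...) {
  sim_config(polg_genotype = polg_genotype, generation_count = 10L, ...)
}

#' @rdname g10_config
#' @export
g1_config <- function(polg_genotype = "mut/mut", ...) {
  sim_config(polg_genotype = polg_genotype, generation_count = 0L, ...)
}

#' A balanced cohort grid
#'
#' @param n_per_genotype Mice per nuclear genotype (the emulated study
#'   uses 4).
#' @param generation_count Shared transmission count (10 for a
#'   G>=10-like cohort, 0 for G1-like).
#' @return Data frame with columns `mouse_id, polg_genotype,
#'   generation_count` suitable for [simulate_cohort()].
#' @export
cohort_grid <- function(n_per_genotype = 4L, generation_count = 10L) {
  gts <- c("+/+", "+/mut", "mut/mut")
  tags <- c("wt", "het", "hom")
  glab <- if (generation_count == 0L) "G1" else paste0("G", generation_count)
  do.call(rbind, lapply(seq_along(gts), function(i) {
    data.frame(
      mouse_id = sprintf("%s_%s_%d", glab, tags[i],
                         seq_len(n_per_genotype)),
      polg_genotype = gts[i], generation_count = generation_count)
  }))
}

.mutate_sequence <- function(seq, rate, keep = integer(0)) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  idx <- setdiff(which(stats::runif(n) < rate), keep)
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Synthetic human/mouse-like mitochondrial ortholog pair
#'
#' Builds two synthetic genomes that reproduce the coordinate geometry of
#' the real human (16,569 bp) and mouse (16,299 bp) mitochondrial
#' references for three ortholog pairs: ATP6 (human 8527-9207, mouse
#' 7927-8607, both plus strand), tRNA-Leu(UUR) (human 3230-3304, mouse
#' TrnL1), and ND6 (minus strand in both species, with a 6-bp length
#' difference so the alignment must place gaps). Gene bodies share ~92%
#' identity; ATP6 carries an identical window around in-gene position 467
#' with a T at human position 8993 and mouse position 8393, the
#' homologous site of the classic pathogenic T8993 mutations. The
#' sequences are synthetic stand-ins generated in code, not the real
#' references; only the gene layout is real.
#'
#' @param seed Random seed.
#' @return List with `genome_a`/`annot_a` (human-like; catalog side) and
#'   `genome_b`/`annot_b` (mouse-like).
#' @export
synthetic_ortholog_pair <- function(seed = 1L) {
  set.seed(substream_seed(seed, "orthologs"))
  mouse <- synthetic_mito_genome(16299L, seed = seed, name = "chrM_mouse")
  # force the focal ATP6 base (mouse m.8393, in-gene 467) to T
  mseq <- mouse$sequence
  substr(mseq, 8393, 8393) <- "T"
  mouse <- mt_genome(mseq, name = "chrM_mouse")
  annot_b <- mito_annotation(mouse)

  m_atp6 <- substr(mouse$sequence, 7927, 8607)            # plus strand
  m_trnl1 <- substr(mouse$sequence, 2676, 2750)           # plus strand
  nd6_rec <- list(start = 13552, end = 14070, strand = "-")
  m_nd6 <- .revcomp(substr(mouse$sequence, nd6_rec$start, nd6_rec$end))

  h_atp6 <- .mutate_sequence(m_atp6, rate = 0.08, keep = 457:477)
  h_trnl1 <- .mutate_sequence(m_trnl1, rate = 0.08)
  ins_at <- 400L
  h_nd6 <- paste0(substr(m_nd6, 1, ins_at),
                  paste(sample(c("A", "C", "G", "T"), 6L, replace = TRUE),
                        collapse = ""),
                  substr(m_nd6, ins_at + 1L, nchar(m_nd6)))
  h_nd6 <- .mutate_sequence(h_nd6, rate = 0.06)

  L_h <- 16569L
  back <- sample(c("A", "C", "G", "T"), L_h, replace = TRUE)
  hseq <- paste(back, collapse = "")
  put <- function(s, seg, start) {
    substr(s, start, start + nchar(seg) - 1L) <- seg
    s
  }
  hseq <- put(hseq, h_trnl1, 3230L)                       # TrnL1 +
  hseq <- put(hseq, h_atp6, 8527L)                        # ATP6 +
  hseq <- put(hseq, .revcomp(h_nd6), 14149L)              # ND6 -
  human <- mt_genome(hseq, name = "chrM_human")
  annot_a <- gene_annotation(
    gene = c("TrnL1", "ATP6", "ND6"),
    class = c("tRNA", "protein", "protein"),
    start = c(3230L, 8527L, 14149L),
    end = c(3304L, 9207L, 14149L + nchar(h_nd6) - 1L),
    strand = c("+", "+", "-"),
    genome = human)
  list(genome_a = human, annot_a = annot_a,
       genome_b = mouse, annot_b = annot_b)
}

#' Path to the packaged pathogenic-catalog excerpt
#'
#' Ten confirmed human pathogenic mtDNA mutations in MITOMAP-style
#' columns (locus, allele, status).
#'
#' @return File path.
#' @export
pathogenic_catalog_excerpt <- function() {
  system.file("extdata", "mitomap_excerpt.tsv", package = "mitomut",
              mustWork = TRUE)
}
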