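#' Per-position region lookup
#'
#' Resolves each genome position to the first annotation record (in file
#' order) covering it; uncovered positions get class `"other"` and no gene.
#' Overlapping records (e.g. ATP8/ATP6) trigger a single warning.
#'
#' @param annotation A [gene_annotation()].
#' @param length Genome length.
#' @param warn Warn when records overlap (the warning is normally issued
#'   once, at annotation construction).
#' @return List with vectors `class`, `gene`, `record` (row index or NA).
#' @keywords internal
region_lookup <- function(annotation, length, warn = FALSE) {
  cls <- rep("other", length)
  gene <- rep(NA_character_, length)
  rec <- rep(NA_integer_, length)
  covered <- integer(length)
  # assign in reverse so earlier records win
  for (i in rev(seq_len(nrow(annotation)))) {
    idx <- annotation$start[i]:annotation$end[i]
    covered[idx] <- covered[idx] + 1L
    cls[idx] <- annotation$class[i]
    gene[idx] <- annotation$gene[i]
    rec[idx] <- i
  }
  if (warn && any(covered > 1L))
    warning("overlapping annotation records; first record in file order ",
            "takes precedence", call. = FALSE)
  list(class = cls, gene = gene, record = rec)
}

.ref_vector <- function(genome) strsplit(genome$sequence, "", fixed = TRUE)[[1]]

.ref_count_vector <- function(table, ref) {
  m <- as.matrix(table$counts[c("A", "C", "G", "T")])
  m[cbind(seq_len(nrow(m)), match(ref, c("A", "C", "G", "T")))]
}

#' Enumerate per-site alternative alleles
#'
#' For every position with positive depth and every base differing from the
#' reference with a positive count, emits one variant row with frequency
#' `100 * count / depth` (percent). Up to three variants per site.
#'
#' @param table An [allele_counts()] object.
#' @param genome The matching [mt_genome()].
#' @param annotation A [gene_annotation()] used to assign region and gene.
#' @return A `site_variants` data frame with columns `pos, ref, alt, depth,
#'   alt_count, frequency_percent, region, gene, effect,
#'   pathogenic_human_pos` (the last two NA until filled by
#'   [classify_variants()] / [annotate_pathogenic()]).
#' @export
site_variants <- function(table, genome, annotation) {
  stopifnot(inherits(table, "allele_counts"), inherits(genome, "mt_genome"))
  if (table$length != genome$length)
    stop("count table and genome lengths differ", call. = FALSE)
  ref <- .ref_vector(genome)
  lk <- region_lookup(annotation, genome$length, warn = FALSE)
  cts <- table$counts
  rows <- vector("list", 4L)
  for (b in c("A", "C", "G", "T")) {
    keep <- which(cts[[b]] > 0L & ref != b & cts$depth > 0L)
    rows[[b]] <- data.frame(
      pos = cts$pos[keep], ref = ref[keep], alt = rep(b, length(keep)),
      depth = cts$depth[keep], alt_count = cts[[b]][keep])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out$frequency_percent <- 100 * out$alt_count / out$depth
  out$region <- lk$class[out$pos]
  out$gene <- lk$gene[out$pos]
  out$effect <- rep(NA_character_, nrow(out))
  out$pathogenic_human_pos <- rep(NA_integer_, nrow(out))
  class(out) <- c("site_variants", "data.frame")
  out
}

#' Total mtDNA mutation frequency (percent)
#'
#' The core statistic: `100 x (base calls differing from the reference) /
#' (total base calls)`. Positions with zero depth contribute to neither
#' numerator nor denominator; indel-supporting reads are excluded from both
#' and reported by [indel_frequency()].
#'
#' @param table An [allele_counts()] object.
#' @param genome The matching [mt_genome()].
#' @return Frequency in percent.
#' @export
total_mutation_frequency <- function(table, genome) {
  stopifnot(inherits(table, "allele_counts"), inherits(genome, "mt_genome"))
  if (table$length != genome$length)
    stop("count table and genome lengths differ", call. = FALSE)
  depth <- table$counts$depth
  if (sum(depth) == 0)
    stop("all positions have zero depth; mutation frequency undefined",
         call. = FALSE)
  mism <- depth - .ref_count_vector(table, .ref_vector(genome))
  100 * sum(as.numeric(mism)) / sum(as.numeric(depth))
}

#' Mutation frequency per gene and per region class
#'
#' Applies the total-frequency formula restricted to the positions of each
#' annotated gene and of each aggregate class (protein, tRNA, rRNA, dloop,
#' other). Unannotated positions count under `"other"`. Regions with zero
#' sequenced bases report `NA`.
#'
#' @inheritParams site_variants
#' @return Data frame with columns `name, level ("gene"/"class"),
#'   mismatches, bases, frequency_percent`.
#' @export
region_mutation_frequency <- function(table, genome, annotation) {
  stopifnot(inherits(table, "allele_counts"))
  if (table$length != genome$length)
    stop("count table and genome lengths differ", call. = FALSE)
  depth <- as.numeric(table$counts$depth)
  if (sum(depth) == 0)
    stop("all positions have zero depth; mutation frequency undefined",
         call. = FALSE)
  mism <- depth - .ref_count_vector(table, .ref_vector(genome))
  lk <- region_lookup(annotation, genome$length)
  agg <- function(fac, level) {
    b <- tapply(depth, fac, sum)
    m <- tapply(mism, fac, sum)
    b[is.na(b)] <- 0
    m[is.na(m)] <- 0
    data.frame(name = names(b), level = level,
               mismatches = as.numeric(m), bases = as.numeric(b),
               frequency_percent = ifelse(b > 0, 100 * m / b, NA_real_))
  }
  gene_fac <- factor(ifelse(is.na(lk$gene), "(intergenic)", lk$gene))
  out <- rbind(agg(factor(lk$class, levels = .region_classes), "class"),
               agg(gene_fac, "gene"))
  rownames(out) <- NULL
  out
}

#' Insertion and deletion frequencies (percent)
#'
#' Insertions share the base-call denominator (`100 * sum(ins) /
#' sum(depth)`); deletion-supporting reads are not part of `depth`, so the
#' deletion denominator is `sum(depth) + sum(del)`.
#'
#' @param table An [allele_counts()] object.
#' @return List with elements `insertion` and `deletion`, both percent.
#' @export
indel_frequency <- function(table) {
  stopifnot(inherits(table, "allele_counts"))
  d <- sum(as.numeric(table$counts$depth))
  del <- sum(as.numeric(table$counts$del))
  ins <- sum(as.numeric(table$counts$ins))
  if (d == 0) stop("zero total depth; indel frequency undefined", call. = FALSE)
  list(insertion = 100 * ins / d, deletion = 100 * del / (d + del))
}

#' Sequencing QC metrics
#'
#' @param table An [allele_counts()] object.
#' @return A `qc_metrics` list: `total_bases` (sum of depth),
#'   `average_depth` (total bases / genome length), `coverage_rate`
#'   (percent of positions with depth >= 1).
#' @export
qc_metrics <- function(table) {
  stopifnot(inherits(table, "allele_counts"))
  depth <- table$counts$depth
  L <- table$length
  structure(list(
    total_bases = sum(as.numeric(depth)),
    average_depth = if (L > 0) sum(as.numeric(depth)) / L else 0,
    coverage_rate = if (L > 0) 100 * mean(depth >= 1L) else 0),
    class = "qc_metrics")
}

#' Assemble the per-sample readout
#'
#' Computes the total and per-region mutation frequencies, indel
#' frequencies, QC metrics, and the counts of non-synonymous and
#' pathogenic-homologous variants above the frequency threshold.
#'
#' @inheritParams site_variants
#' @param catalog Optional pathogenic catalog
#'   (see [load_pathogenic_catalog()]); when `NULL`, `n_pathogenic_gt1` is
#'   `NA`.
#' @param map Optional [build_homology_map()] with the catalog species as
#'   side A and this genome as side B.
#' @param threshold Percent frequency threshold, strict (`> threshold`);
#'   default 1.
#' @return A `sample_summary` object.
#' @export
sample_summary <- function(table, genome, annotation, catalog = NULL,
                           map = NULL, threshold = 1) {
  vars <- site_variants(table, genome, annotation)
  vars <- classify_variants(vars, genome, annotation)
  n_patho <- NA_integer_
  if (!is.null(catalog) && !is.null(map)) {
    vars <- annotate_pathogenic(vars, catalog, map, genome = genome)
    n_patho <- count_pathogenic(vars, catalog, map, threshold = threshold,
                                genome = genome)$n_hits
  }
  rf <- region_mutation_frequency(table, genome, annotation)
  rfv <- rf$frequency_percent
  names(rfv) <- rf$name
  indel <- indel_frequency(table)
  ns <- sum(vars$frequency_percent > threshold &
              vars$effect == "nonsynonymous", na.rm = TRUE)
  structure(list(
    meta = table$meta,
    total_mut_freq = total_mutation_frequency(table, genome),
    region_mut_freq = rfv,
    insertion_freq = indel$insertion,
    deletion_freq = indel$deletion,
    n_nonsyn_gt1 = as.integer(ns),
    n_pathogenic_gt1 = n_patho,
    qc = qc_metrics(table),
    variants = vars),
    class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> %s %s (%s, %s)\n", x$meta$mouse_id,
              x$meta$organ, x$meta$polg_genotype, x$meta$generation))
  cat(sprintf("  total mutation frequency: %.4f%%\n", x$total_mut_freq))
  cat(sprintf("  insertion / deletion frequency: %.4g%% / %.4g%%\n",
              x$insertion_freq, x$deletion_freq))
  cat(sprintf("  non-synonymous >1%%: %d; pathogenic-homologous >1%%: %s\n",
              x$n_nonsyn_gt1, format(x$n_pathogenic_gt1)))
  cat(sprintf("  QC: %.0f bases, mean depth %.1f, coverage %.2f%%\n",
              x$qc$total_bases, x$qc$average_depth, x$qc$coverage_rate))
  invisible(x)
}
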