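#' Construct a mitochondrial genome object
#'
#' A light container for a (typically circular) mtDNA reference sequence.
#' The sequence is uppercased and must contain only the four unambiguous
#' bases A/C/G/T; ambiguity codes are rejected because every downstream
#' statistic counts exact base matches against the reference.
#'
#' @param sequence Character scalar, the reference sequence.
#' @param name Sequence name (e.g. `"chrM"`).
#' @param circular Logical; mtDNA is circular, but no packaged annotation
#'   spans the origin, so interval logic stays linear.
#' @return An object of class `mt_genome` with fields `name`, `sequence`,
#'   `length`, `circular`.
#' @export
mt_genome <- function(sequence, name = "chrM", circular = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("`sequence` must be a single character string", call. = FALSE)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("empty reference sequence", call. = FALSE)
  bad <- gsub("[ACGT]", "", sequence)
  if (nchar(bad) > 0L)
    stop("reference contains non-ACGT characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "), call. = FALSE)
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular)),
    class = "mt_genome")
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf("<mt_genome> %s: %d bp%s\n", x$name, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Read a single-record FASTA reference
#'
#' @param path Path to a FASTA file holding exactly one record.
#' @return An [mt_genome()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (length(set) > 1L)
    stop("expected a single-record FASTA, found ", length(set),
         " records in ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(set)[1])
  mt_genome(as.character(set[[1]]), name = nm)
}

#' Write an [mt_genome()] to FASTA
#' @param genome An `mt_genome`.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "mt_genome"))
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

.region_classes <- c("protein", "tRNA", "rRNA", "dloop", "other")

.normalize_class <- function(x) {
  y <- tolower(x)
  y[y %in% c("d-loop", "d_loop", "dloop", "control")] <- "dloop"
  y[y == "trna"] <- "tRNA"
  y[y == "rrna"] <- "rRNA"
  y[y %in% c("protein", "cds", "protein_coding")] <- "protein"
  y
}

#' Construct a gene/region annotation table
#'
#' Coordinates are 1-based inclusive on the reference strand, matching
#' mtDNA "m.8993"-style numbering. Protein records whose span is not a
#' multiple of 3 are flagged `incomplete` with a warning (several real
#' mitochondrial genes end on an incomplete stop codon completed by
#' polyadenylation), not rejected.
#'
#' @param gene Character vector of feature names.
#' @param class Region class, one of protein/tRNA/rRNA/dloop/other.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"` (reference-strand coordinates either way;
#'   reverse complementation happens only at translation time).
#' @param genome An [mt_genome()] used to range-check coordinates.
#' @return A `gene_annotation` data frame with columns
#'   `gene`, `class`, `start`, `end`, `strand`, `incomplete`.
#' @export
gene_annotation <- function(gene, class, start, end, strand, genome) {
  stopifnot(inherits(genome, "mt_genome"))
  class <- .normalize_class(class)
  n <- length(gene)
  if (!all(lengths(list(class, start, end, strand)) == n))
    stop("annotation columns have unequal lengths", call. = FALSE)
  bad <- setdiff(unique(class), .region_classes)
  if (length(bad))
    stop("unknown region class: ", paste(bad, collapse = ", "), call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end > genome$length) || any(end < start))
    stop("annotation coordinates out of range for genome of length ",
         genome$length, call. = FALSE)
  if (!all(strand %in% c("+", "-")))
    stop('strand must be "+" or "-"', call. = FALSE)
  incomplete <- class == "protein" & ((end - start + 1L) %% 3L != 0L)
  if (any(incomplete))
    warning("protein record(s) with length not divisible by 3 flagged incomplete: ",
            paste(gene[incomplete], collapse = ", "), call. = FALSE)
  out <- data.frame(gene = as.character(gene), class = class,
                    start = start, end = end, strand = as.character(strand),
                    incomplete = incomplete)
  cov <- integer(genome$length)
  for (i in seq_len(nrow(out))) {
    idx <- out$start[i]:out$end[i]
    cov[idx] <- cov[idx] + 1L
  }
  if (any(cov > 1L))
    warning("overlapping annotation records (e.g. ATP8/ATP6-style ",
            "overlaps); positions resolve to the first record in file ",
            "order", call. = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  attr(out, "genome_length") <- genome$length
  out
}

#' Read a BED-style annotation file
#'
#' Accepts BED with 0-based half-open coordinates and either
#' `chrom start end name strand class` (6 columns) or
#' `chrom start end name score strand class` (7 columns). Coordinates are
#' converted to 1-based inclusive on read.
#'
#' @param path BED file path.
#' @param genome An [mt_genome()] for validation.
#' @return A [gene_annotation()] table in file order.
#' @export
read_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) == 6L && all(raw[[5]] %in% c("+", "-"))) {
    nm <- raw[[4]]; strand <- raw[[5]]; cls <- raw[[6]]
  } else if (ncol(raw) >= 7L) {
    nm <- raw[[4]]; strand <- raw[[6]]; cls <- raw[[7]]
  } else {
    stop("expected BED with name/strand/class columns (6 or 7 fields)",
         call. = FALSE)
  }
  gene_annotation(gene = nm, class = cls,
                  start = as.integer(raw[[2]]) + 1L,
                  end = as.integer(raw[[3]]),
                  strand = strand, genome = genome)
}

#' Write a [gene_annotation()] back to BED (0-based half-open, 7 columns)
#' @param annotation A `gene_annotation`.
#' @param path Output path.
#' @param chrom Chromosome label for column 1.
#' @export
write_annotation <- function(annotation, path, chrom = "chrM") {
  df <- data.frame(chrom = chrom, start = annotation$start - 1L,
                   end = annotation$end, name = annotation$gene,
                   score = 0L, strand = annotation$strand,
                   class = annotation$class)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-sample metadata
#'
#' @param mouse_id Animal identifier.
#' @param organ Organ/tissue name (e.g. heart, kidney, soleus).
#' @param polg_genotype One of `"+/+"`, `"+/mut"`, `"mut/mut"` (nuclear
#'   genotype at the proofreading-deficient polymerase-gamma locus).
#' @param generation Generation label, e.g. `"G1"` or `"G10plus"`.
#' @return A `sample_meta` object.
#' @export
sample_meta <- function(mouse_id, organ, polg_genotype, generation) {
  if (!polg_genotype %in% c("+/+", "+/mut", "mut/mut"))
    stop('polg_genotype must be one of "+/+", "+/mut", "mut/mut"',
         call. = FALSE)
  structure(list(mouse_id = as.character(mouse_id),
                 organ = as.character(organ),
                 polg_genotype = polg_genotype,
                 generation = as.character(generation)),
            class = "sample_meta")
}

#' Construct a per-site allele-count table
#'
#' One row per reference position 1..L. `depth` is the base-call depth and
#' must equal `A + C + G + T`. Reads supporting a deletion of a position are
#' recorded in `del` and are *not* part of `depth`; reads supporting an
#' insertion immediately after a position are counted in `depth` at the
#' anchor and additionally in `ins`. This keeps the substitution
#' denominator purely base-call based.
#'
#' @param counts Data frame with columns `pos, depth, A, C, G, T, ins, del`.
#' @param meta A [sample_meta()].
#' @param genome The [mt_genome()] the counts refer to.
#' @return An `allele_counts` object.
#' @export
allele_counts <- function(counts, meta, genome) {
  stopifnot(inherits(meta, "sample_meta"), inherits(genome, "mt_genome"))
  need <- c("pos", "depth", "A", "C", "G", "T", "ins", "del")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  counts <- counts[need]
  for (cn in need) counts[[cn]] <- as.integer(counts[[cn]])
  if (anyDuplicated(counts$pos))
    stop("duplicate positions in count table", call. = FALSE)
  if (any(counts$pos < 1L | counts$pos > genome$length))
    stop("count-table position out of range 1..", genome$length, call. = FALSE)
  if (any(unlist(counts[c("depth", "A", "C", "G", "T", "ins", "del")]) < 0L))
    stop("negative counts are not allowed", call. = FALSE)
  # fill absent positions with zero rows, then enforce the depth invariant
  full <- data.frame(pos = seq_len(genome$length), depth = 0L,
                     A = 0L, C = 0L, G = 0L, T = 0L, ins = 0L, del = 0L)
  full[counts$pos, ] <- counts
  bad <- which(full$A + full$C + full$G + full$T != full$depth)
  if (length(bad))
    stop("depth != A+C+G+T at position(s) ",
         paste(utils::head(full$pos[bad], 5L), collapse = ", "), call. = FALSE)
  structure(list(meta = meta, counts = full, genome_name = genome$name,
                 length = genome$length),
            class = "allele_counts")
}

#' Read an allele-count TSV
#'
#' Expects a header line `pos depth A C G T ins del` (tab-separated).
#' Positions absent from the file are filled with all-zero rows.
#'
#' @param path TSV path.
#' @param genome An [mt_genome()].
#' @param meta A [sample_meta()].
#' @return An [allele_counts()] object.
#' @export
read_counts <- function(path, genome, meta) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  allele_counts(df, meta, genome)
}

#' Write an allele-count table as TSV
#' @param table An [allele_counts()] object.
#' @param path Output path.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "allele_counts"))
  utils::write.table(table$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.variant_cols <- c("pos", "ref", "alt", "depth", "alt_count",
                   "frequency_percent", "region", "gene", "effect",
                   "pathogenic_human_pos")

#' Write site variants as a VCF-like TSV
#'
#' Deterministic column order: pos, ref, alt, depth, alt_count,
#' frequency_percent, region, gene, effect, pathogenic_human_pos.
#' Frequencies are serialized at full double precision.
#'
#' @param variants A `site_variants` data frame (see [site_variants()]).
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  df <- as.data.frame(variants)
  for (cn in setdiff(.variant_cols, names(df))) df[[cn]] <- NA
  df <- df[.variant_cols]
  df$frequency_percent <- vapply(df$frequency_percent, function(x)
    if (is.na(x)) NA_character_ else format(x, digits = 15), "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variants written by [write_variants()]
#' @param path TSV path.
#' @return A `site_variants` data frame.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer", ref = "character",
                                         alt = "character", depth = "integer",
                                         alt_count = "integer",
                                         frequency_percent = "numeric",
                                         region = "character",
                                         gene = "character",
                                         effect = "character",
                                         pathogenic_human_pos = "integer"))
  class(df) <- c("site_variants", "data.frame")
  df
}

#' Write a per-sample summary as a one-row TSV
#'
#' Region/gene frequencies are flattened to columns prefixed `freq_`.
#'
#' @param summary A `sample_summary` (see [sample_summary()]).
#' @param path Output path.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "sample_summary"))
  row <- data.frame(
    mouse_id = summary$meta$mouse_id, organ = summary$meta$organ,
    polg_genotype = summary$meta$polg_genotype,
    generation = summary$meta$generation,
    total_mut_freq = summary$total_mut_freq,
    insertion_freq = summary$insertion_freq,
    deletion_freq = summary$deletion_freq,
    n_nonsyn_gt1 = summary$n_nonsyn_gt1,
    n_pathogenic_gt1 = summary$n_pathogenic_gt1,
    total_bases = summary$qc$total_bases,
    average_depth = summary$qc$average_depth,
    coverage_rate = summary$qc$coverage_rate)
  rf <- summary$region_mut_freq
  if (length(rf)) for (nm in names(rf)) row[[paste0("freq_", nm)]] <- rf[[nm]]
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a summary written by [write_summary()]
#' @param path TSV path.
#' @return A `sample_summary` object.
#' @export
read_summary <- function(path) {
  row <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(nrow(row) == 1L)
  rf_cols <- grep("^freq_", names(row), value = TRUE)
  rf <- as.numeric(row[1, rf_cols])
  names(rf) <- sub("^freq_", "", rf_cols)
  structure(list(
    meta = sample_meta(row$mouse_id, row$organ, row$polg_genotype,
                       row$generation),
    total_mut_freq = row$total_mut_freq,
    region_mut_freq = rf,
    insertion_freq = row$insertion_freq,
    deletion_freq = row$deletion_freq,
    n_nonsyn_gt1 = row$n_nonsyn_gt1,
    n_pathogenic_gt1 = row$n_pathogenic_gt1,
    qc = structure(list(total_bases = row$total_bases,
                        average_depth = row$average_depth,
                        coverage_rate = row$coverage_rate),
                   class = "qc_metrics")),
    class = "sample_summary")
}
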