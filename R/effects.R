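#' The vertebrate mitochondrial genetic code
#'
#' NCBI translation table 2: relative to the standard code, ATA encodes
#' Met, TGA encodes Trp, and AGA/AGG are stops.
#'
#' @return Named character vector mapping the 64 DNA codons to one-letter
#'   amino acids (`"*"` for stop).
#' @export
mito_genetic_code <- function() {
  code <- Biostrings::getGeneticCode("2")
  names(code) <- chartr("U", "T", names(code))
  code
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(.COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

#' Classify substitutions at given positions (vectorized core)
#'
#' For positions inside a protein record the codon is located from the
#' record's start and strand (minus-strand genes are read on the reverse
#' complement), the reference and mutated codons are translated with the
#' vertebrate mitochondrial code, and the variant is called synonymous or
#' nonsynonymous (stop gain/loss counts as nonsynonymous). Positions in
#' tRNA/rRNA/D-loop/unannotated regions get the matching noncoding class.
#' Positions falling in the trailing partial codon of a record flagged
#' incomplete are classified `NA` with a warning.
#'
#' @param genome An [mt_genome()].
#' @param annotation A [gene_annotation()].
#' @param pos Integer vector of 1-based positions.
#' @param alt Character vector of alternative bases (reference strand).
#' @return Data frame with columns `pos, alt, ref, gene, region,
#'   codon_index, ref_codon, alt_codon, ref_aa, alt_aa, effect,
#'   partial_codon`.
#' @export
classify_positions <- function(genome, annotation, pos, alt) {
  stopifnot(inherits(genome, "mt_genome"))
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > genome$length))
    stop("position outside genome (1..", genome$length, ")", call. = FALSE)
  ref <- .ref_vector(genome)[pos]
  if (any(alt == ref))
    stop("alt equals the reference base at position(s) ",
         paste(utils::head(pos[alt == ref], 5L), collapse = ", "),
         call. = FALSE)
  if (!all(alt %in% c("A", "C", "G", "T")))
    stop("alt bases must be A/C/G/T", call. = FALSE)
  lk <- region_lookup(annotation, genome$length)
  n <- length(pos)
  out <- data.frame(pos = pos, alt = alt, ref = ref,
                    gene = lk$gene[pos], region = lk$class[pos],
                    codon_index = NA_integer_,
                    ref_codon = NA_character_, alt_codon = NA_character_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    effect = NA_character_, partial_codon = FALSE)
  noncod <- c(tRNA = "noncoding_tRNA", rRNA = "noncoding_rRNA",
              dloop = "noncoding_dloop", other = "noncoding_other")
  is_nc <- out$region %in% names(noncod)
  out$effect[is_nc] <- noncod[out$region[is_nc]]

  ip <- which(out$region == "protein")
  if (length(ip)) {
    rec <- lk$record[pos[ip]]
    start <- annotation$start[rec]; end <- annotation$end[rec]
    minus <- annotation$strand[rec] == "-"
    # index along the coding strand, 1-based
    i_cod <- ifelse(minus, end - pos[ip], pos[ip] - start) + 1L
    ci <- (i_cod - 1L) %/% 3L + 1L
    off <- (i_cod - 1L) %% 3L + 1L
    # reference-strand position of the codon's first coding base
    p1 <- ifelse(minus, end - (ci - 1L) * 3L, start + (ci - 1L) * 3L)
    step <- ifelse(minus, -1L, 1L)
    p2 <- p1 + step; p3 <- p2 + step
    refv <- .ref_vector(genome)
    partial <- pmin(p1, p3) < start | pmax(p1, p3) > end
    base_at <- function(p) {
      b <- refv[pmax(pmin(p, genome$length), 1L)]
      ifelse(minus, .COMP[b], b)
    }
    codon <- paste0(base_at(p1), base_at(p2), base_at(p3))
    alt_cod <- ifelse(minus, .COMP[alt[ip]], alt[ip])
    mut <- codon
    substr(mut, off, off) <- alt_cod
    code <- mito_genetic_code()
    out$codon_index[ip] <- ci
    out$ref_codon[ip] <- codon
    out$alt_codon[ip] <- mut
    ok <- !partial
    out$ref_aa[ip[ok]] <- unname(code[codon[ok]])
    out$alt_aa[ip[ok]] <- unname(code[mut[ok]])
    out$effect[ip[ok]] <- ifelse(out$ref_aa[ip[ok]] == out$alt_aa[ip[ok]],
                                 "synonymous", "nonsynonymous")
    out$partial_codon[ip] <- partial
    if (any(partial))
      warning(sum(partial), " variant(s) in a trailing partial codon of an ",
              "incomplete protein record; effect set to NA", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Classify a single substitution
#'
#' Convenience wrapper around [classify_positions()] for one position.
#'
#' @inheritParams classify_positions
#' @param pos 1-based position.
#' @param alt Alternative base on the reference strand.
#' @return One-row data frame (see [classify_positions()]).
#' @export
classify_substitution <- function(genome, annotation, pos, alt) {
  stopifnot(length(pos) == 1L, length(alt) == 1L)
  classify_positions(genome, annotation, pos, alt)
}

#' Fill the `effect` column of a variant table
#'
#' @param variants A `site_variants` data frame from [site_variants()].
#' @inheritParams classify_positions
#' @return The variant table with `effect` (and codon fields) filled.
#' @export
classify_variants <- function(variants, genome, annotation) {
  if (nrow(variants) == 0L) {
    variants$effect <- character(0)
    return(variants)
  }
  cls <- classify_positions(genome, annotation, variants$pos, variants$alt)
  variants$effect <- cls$effect
  attr(variants, "classification") <- cls
  variants
}

#' Count non-synonymous substitutions above a frequency threshold
#'
#' The threshold is strict: only variants whose per-site alternative-allele
#' frequency *exceeds* `threshold` percent are counted, each (pos, alt)
#' pair once.
#'
#' @param variants A `site_variants` table (classified or not; it is
#'   classified here if the `effect` column is empty).
#' @inheritParams classify_positions
#' @param threshold Percent threshold, default 1.
#' @return Integer count.
#' @export
count_nonsynonymous <- function(variants, genome, annotation, threshold = 1) {
  if (nrow(variants) == 0L) return(0L)
  if (all(is.na(variants$effect)))
    variants <- classify_variants(variants, genome, annotation)
  keep <- variants$frequency_percent > threshold &
    !is.na(variants$effect) & variants$effect == "nonsynonymous"
  sum(!duplicated(variants[keep, c("pos", "alt")]))
}

#' Heteroplasmy-frequency histogram of classified variants
#'
#' Bins variant frequencies into (1,10], (10,20], ..., (90,100] percent
#' (decile bins above the counting threshold), for either the
#' non-synonymous or the pathogenic-homologous variant class.
#'
#' @param variants A classified `site_variants` table
#'   ([classify_variants()]; for `"pathogenic"` also
#'   [annotate_pathogenic()]).
#' @param variant_class `"nonsynonymous"` or `"pathogenic"`.
#' @param threshold Lower edge of the first bin (percent), default 1.
#' @return A `freq_histogram`: list with `bin_edges`, `counts`,
#'   `variant_class`.
#' @export
frequency_histogram <- function(variants,
                                variant_class = c("nonsynonymous",
                                                  "pathogenic"),
                                threshold = 1) {
  variant_class <- match.arg(variant_class)
  edges <- c(threshold, seq(10, 100, by = 10))
  keep <- if (variant_class == "nonsynonymous") {
    !is.na(variants$effect) & variants$effect == "nonsynonymous"
  } else {
    !is.na(variants$pathogenic_human_pos)
  }
  f <- variants$frequency_percent[keep]
  f <- f[f > threshold & f <= 100]
  counts <- as.integer(table(cut(f, breaks = edges, right = TRUE)))
  structure(list(bin_edges = edges, counts = counts,
                 variant_class = variant_class),
            class = "freq_histogram")
}

#' @export
print.freq_histogram <- function(x, ...) {
  lab <- paste0("(", utils::head(x$bin_edges, -1), ",",
                utils::tail(x$bin_edges, -1), "]")
  cat(sprintf("<freq_histogram> %s variants\n", x$variant_class))
  print(stats::setNames(x$counts, lab))
  invisible(x)
}

#' @export
plot.freq_histogram <- function(x, ...) {
  lab <- paste0("(", utils::head(x$bin_edges, -1), ",",
                utils::tail(x$bin_edges, -1), "]")
  graphics::barplot(x$counts, names.arg = lab, las = 2,
                    ylab = sprintf("number of %s variants", x$variant_class),
                    xlab = "mutation frequency (%)", ...)
  invisible(x)
}
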