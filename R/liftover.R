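#' Globally align two region sequences and extract the position map
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (match +2, mismatch -1, gap open -5, gap extend -1 per gapped position
#' by default), as provided by [Biostrings::pairwiseAlignment()]. Both
#' sequences must be given in the same orientation (the coding strand of
#' the region).
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return A `homology_alignment` data frame with columns `pos_a`, `pos_b`
#'   (1-based within each sequence; `NA` marks a gap), and attributes
#'   `identity` (percent matches among both-aligned columns) and `score`.
#' @export
align_region <- function(seq_a, seq_b, match = 2, mismatch = -1,
                         gap_open = 5, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("cannot align an empty sequence", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seq_a)), Biostrings::DNAString(toupper(seq_b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  ca <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  pos_a <- cumsum(ca != "-"); pos_a[ca == "-"] <- NA_integer_
  pos_b <- cumsum(cb != "-"); pos_b[cb == "-"] <- NA_integer_
  out <- data.frame(pos_a = as.integer(pos_a), pos_b = as.integer(pos_b))
  both <- !is.na(out$pos_a) & !is.na(out$pos_b)
  attr(out, "identity") <- 100 * sum(ca[both] == cb[both]) / max(sum(both), 1)
  attr(out, "score") <- Biostrings::score(al)
  class(out) <- c("homology_alignment", "data.frame")
  out
}

.extract_region <- function(genome, rec) {
  s <- substr(genome$sequence, rec$start, rec$end)
  if (rec$strand == "-") s <- .revcomp(s) else s
}

#' Build a per-gene homology map between two mitochondrial genomes
#'
#' Each paired region is extracted on its coding strand (minus-strand
#' records are reverse complemented), globally aligned, and the aligned
#' coding positions are converted back to reference-strand coordinates of
#' each genome. Inter-genic positions remain unmapped. By convention side
#' A is the catalog species (e.g. human) and side B the study species
#' (e.g. mouse).
#'
#' @param genome_a,annot_a Genome and annotation of species A.
#' @param genome_b,annot_b Genome and annotation of species B.
#' @param pairs Optional data frame with columns `name_a`, `name_b` naming
#'   the regions to pair; default pairs identically named genes.
#' @return A `homology_map` data frame with columns `region, pos_a, pos_b,
#'   strand_a, strand_b` and attribute `regions` (per-region identity).
#' @export
build_homology_map <- function(genome_a, annot_a, genome_b, annot_b,
                               pairs = NULL) {
  if (is.null(pairs)) {
    shared <- intersect(annot_a$gene, annot_b$gene)
    if (!length(shared))
      stop("no identically named regions to pair; supply `pairs`",
           call. = FALSE)
    pairs <- data.frame(name_a = shared, name_b = shared)
  }
  missing_a <- setdiff(pairs$name_a, annot_a$gene)
  missing_b <- setdiff(pairs$name_b, annot_b$gene)
  if (length(missing_a) || length(missing_b))
    stop("unpaired region name(s): ",
         paste(c(missing_a, missing_b), collapse = ", "), call. = FALSE)
  frags <- vector("list", nrow(pairs))
  info <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ra <- annot_a[match(pairs$name_a[i], annot_a$gene), ]
    rb <- annot_b[match(pairs$name_b[i], annot_b$gene), ]
    al <- align_region(.extract_region(genome_a, ra),
                       .extract_region(genome_b, rb))
    to_ref <- function(p, rec)
      if (rec$strand == "-") rec$end - p + 1L else rec$start + p - 1L
    frags[[i]] <- data.frame(
      region = pairs$name_a[i],
      pos_a = to_ref(al$pos_a, ra), pos_b = to_ref(al$pos_b, rb),
      strand_a = ra$strand, strand_b = rb$strand)
    info[[i]] <- data.frame(region = pairs$name_a[i],
                            identity = attr(al, "identity"))
  }
  out <- do.call(rbind, frags)
  rownames(out) <- NULL
  attr(out, "regions") <- do.call(rbind, info)
  class(out) <- c("homology_map", "data.frame")
  out
}

#' Lift a position through a homology map
#'
#' @param map A [build_homology_map()] result.
#' @param pos Integer vector of 1-based positions in the `from` genome.
#' @param from `"a"` or `"b"`: which side `pos` refers to.
#' @return Integer vector of partner positions; `NA` for positions aligned
#'   to a gap or outside every paired region ("unmapped").
#' @export
lift_position <- function(map, pos, from = c("a", "b")) {
  from <- match.arg(from)
  src <- if (from == "a") map$pos_a else map$pos_b
  dst <- if (from == "a") map$pos_b else map$pos_a
  dst[match(pos, src)]
}

.parse_allele <- function(x) {
  x <- toupper(gsub("\\s", "", x))
  x <- chartr("U", "T", x)
  m <- regmatches(x, regexec("^([ACGT])(\\d+)([ACGT])$", x))[[1]]
  if (length(m) == 4L)
    return(list(pos = as.integer(m[3]), ref = m[2], alt = m[4]))
  m <- regmatches(x, regexec("^M\\.(\\d+)([ACGT])>([ACGT])$", x))[[1]]
  if (length(m) == 4L)
    return(list(pos = as.integer(m[2]), ref = m[3], alt = m[4]))
  NULL
}

#' Load a MITOMAP-style pathogenic-mutation catalog
#'
#' Accepts tab- or comma-separated files with columns for locus, allele
#' change, and status. Both `"T8993G"` and `"m.8993T>G"` allele notations
#' are parsed (RNA-gene `U` alleles are normalized to DNA). With a header
#' line, columns named (case-insensitively) `locus`, `allele`, `status`
#' are used; without one, that column order is assumed.
#'
#' @param path Catalog file path.
#' @param statuses Keep only entries whose status is in this set; default
#'   `"Cfrm"` (confirmed). `NULL` keeps everything.
#' @return Data frame with columns `human_pos, human_ref, human_alt,
#'   locus, status`.
#' @export
load_pathogenic_catalog <- function(path, statuses = "Cfrm") {
  if (!file.exists(path)) stop("catalog not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           quote = "\"", comment.char = "")
  header <- any(tolower(as.character(raw[1, ])) %in%
                  c("locus", "allele", "status", "position"))
  if (header) {
    names(raw) <- tolower(as.character(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    locus <- raw[["locus"]]; allele <- raw[["allele"]]
    status <- raw[["status"]]
  } else {
    if (ncol(raw) < 2L) stop("catalog needs locus and allele columns",
                             call. = FALSE)
    locus <- raw[[1]]; allele <- raw[[2]]
    status <- if (ncol(raw) >= 3L) raw[[3]] else rep(NA_character_, nrow(raw))
  }
  parsed <- lapply(allele, .parse_allele)
  bad <- which(vapply(parsed, is.null, TRUE))
  if (length(bad))
    stop("unparseable allele string(s) at line ",
         paste(bad + header, collapse = ", "), ": ",
         paste(allele[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(
    human_pos = vapply(parsed, `[[`, 1L, "pos"),
    human_ref = vapply(parsed, `[[`, "", "ref"),
    human_alt = vapply(parsed, `[[`, "", "alt"),
    locus = as.character(locus), status = as.character(status))
  if (any(out$human_ref == out$human_alt))
    stop("catalog entry with identical ref and alt allele", call. = FALSE)
  if (!is.null(statuses)) out <- out[out$status %in% statuses, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Translate a catalog allele (side-A plus strand) into the expected
# side-B plus-strand base, honoring each region's strand.
.strand_map_base <- function(base, strand_a, strand_b) {
  coding <- ifelse(strand_a == "-", .COMP[base], base)
  unname(ifelse(strand_b == "-", .COMP[coding], coding))
}

#' Count variants homologous to catalog pathogenic mutations
#'
#' A variant is a hit when its position is the side-B image of a catalog
#' position under the homology map, its frequency strictly exceeds the
#' threshold, and (in the default `"position+allele"` mode) its
#' alternative base equals the catalog alternative after strand
#' normalization. Mapped sites where the side-B reference base does not
#' correspond to the catalog (human) reference base are recorded as
#' reference mismatches and excluded unless `include_ref_mismatch = TRUE`.
#'
#' @param variants A `site_variants` table for the side-B genome.
#' @param catalog A [load_pathogenic_catalog()] data frame.
#' @param map A [build_homology_map()] with the catalog species as side A.
#' @param threshold Percent frequency threshold (strict), default 1.
#' @param match_mode `"position+allele"` (default) or `"position_only"`.
#' @param genome Optional side-B [mt_genome()] enabling the
#'   reference-base concordance check.
#' @param include_ref_mismatch Count hits at reference-discordant sites.
#' @return List with `n_hits` (distinct hits) and `hits` (data frame:
#'   catalog fields, `mouse_pos`, `ref_mismatch`, and matched-variant
#'   columns).
#' @export
count_pathogenic <- function(variants, catalog, map, threshold = 1,
                             match_mode = c("position+allele",
                                            "position_only"),
                             genome = NULL, include_ref_mismatch = FALSE) {
  match_mode <- match.arg(match_mode)
  empty <- list(n_hits = 0L, hits = data.frame())
  if (nrow(catalog) == 0L || nrow(variants) == 0L) return(empty)
  b_pos <- lift_position(map, catalog$human_pos, from = "a")
  hit_rows <- list()
  refv <- if (!is.null(genome)) .ref_vector(genome) else NULL
  for (i in seq_len(nrow(catalog))) {
    if (is.na(b_pos[i])) next
    mrow <- map[match(catalog$human_pos[i], map$pos_a), ]
    exp_alt <- .strand_map_base(catalog$human_alt[i],
                                mrow$strand_a, mrow$strand_b)
    exp_ref <- .strand_map_base(catalog$human_ref[i],
                                mrow$strand_a, mrow$strand_b)
    ref_mm <- if (is.null(refv)) FALSE else refv[b_pos[i]] != exp_ref
    if (ref_mm && !include_ref_mismatch) next
    cand <- variants$pos == b_pos[i] &
      variants$frequency_percent > threshold
    if (match_mode == "position+allele")
      cand <- cand & variants$alt == exp_alt
    for (j in which(cand)) {
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        human_pos = catalog$human_pos[i], human_ref = catalog$human_ref[i],
        human_alt = catalog$human_alt[i], locus = catalog$locus[i],
        mouse_pos = b_pos[i], mouse_ref = variants$ref[j],
        mouse_alt = variants$alt[j],
        frequency_percent = variants$frequency_percent[j],
        match_mode = match_mode, ref_mismatch = ref_mm)
    }
  }
  if (!length(hit_rows)) return(empty)
  hits <- do.call(rbind, hit_rows)
  hits <- hits[!duplicated(hits[c("human_pos", "human_alt",
                                  "mouse_pos", "mouse_alt")]), , drop = FALSE]
  rownames(hits) <- NULL
  list(n_hits = nrow(hits), hits = hits)
}

#' Flag variants homologous to catalog pathogenic mutations
#'
#' Fills the `pathogenic_human_pos` column of a variant table for every
#' variant matching a catalog entry by mapped position and
#' strand-normalized alternative allele (no frequency threshold; the
#' threshold is applied when counting).
#'
#' @inheritParams count_pathogenic
#' @return The variant table with `pathogenic_human_pos` filled.
#' @export
annotate_pathogenic <- function(variants, catalog, map, genome = NULL,
                                include_ref_mismatch = FALSE) {
  res <- count_pathogenic(variants, catalog, map, threshold = -Inf,
                          match_mode = "position+allele", genome = genome,
                          include_ref_mismatch = include_ref_mismatch)
  if (res$n_hits > 0L) {
    idx <- match(paste(variants$pos, variants$alt),
                 paste(res$hits$mouse_pos, res$hits$mouse_alt))
    hit <- !is.na(idx)
    variants$pathogenic_human_pos[hit] <- res$hits$human_pos[idx[hit]]
  }
  variants
}
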