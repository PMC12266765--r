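test_that("identical sequences align to the identity map at 100% identity", {
  s <- "ACGTACGGTTACGATC"
  al <- align_region(s, s)
  expect_equal(al$pos_a, seq_len(nchar(s)))
  expect_equal(al$pos_b, seq_len(nchar(s)))
  expect_equal(attr(al, "identity"), 100)
  expect_error(align_region("", s), "empty")
})

test_that("small alignments match the hand-solved dynamic program", {
  for (case in list(c("ACGT", "ACT"), c("GATTACA", "GCATGCT"),
                    c("ACGTACGT", "ACGCGT"))) {
    got <- align_region(case[1], case[2])
    want <- oracle_nw(case[1], case[2])
    expect_equal(got$pos_a, want$pos_a, label = paste(case, collapse = "/"))
    expect_equal(got$pos_b, want$pos_b, label = paste(case, collapse = "/"))
  }
  # "ACGT" vs "ACT": the G pairs with a gap, other positions in order
  al <- align_region("ACGT", "ACT")
  expect_equal(al$pos_b[al$pos_a == 3], NA_integer_)
  expect_equal(al$pos_b[match(c(1, 2, 4), al$pos_a)], c(1L, 2L, 3L))
})

test_that("swapping the argument order transposes the mapping", {
  a <- "ACGGTTAACCGTACGT"; b <- "ACGTTACCGTAGT"
  al <- align_region(a, b)
  rev <- align_region(b, a)
  expect_equal(rev$pos_a, al$pos_b)
  expect_equal(rev$pos_b, al$pos_a)
})

load_toy_pair <- function() {
  ga <- read_fasta(toy_extdata("toy_ortholog_a.fa"))
  gb <- read_fasta(toy_extdata("toy_ortholog_b.fa"))
  list(genome_a = ga, annot_a = read_annotation(toy_extdata("toy_ortholog_a.bed"), ga),
       genome_b = gb, annot_b = read_annotation(toy_extdata("toy_ortholog_b.bed"), gb))
}

test_that("the packaged toy ortholog pair maps colinearly and round-trips", {
  fx <- load_toy_pair()
  map <- build_homology_map(fx$genome_a, fx$annot_a, fx$genome_b, fx$annot_b)
  expect_setequal(unique(map$region), c("g1", "g2"))
  for (rg in c("g1", "g2")) {
    sub <- map[map$region == rg & !is.na(map$pos_a) & !is.na(map$pos_b), ]
    # colinear in coding order on both sides (monotone in ref coordinates,
    # direction set by strand)
    expect_true(all(diff(sub$pos_a) != 0))
    expect_true(!is.unsorted(sub$pos_a) || !is.unsorted(rev(sub$pos_a)))
    expect_true(!is.unsorted(sub$pos_b) || !is.unsorted(rev(sub$pos_b)))
  }
  mapped_a <- map$pos_a[!is.na(map$pos_a) & !is.na(map$pos_b)]
  lifted <- lift_position(map, mapped_a, from = "a")
  back <- lift_position(map, lifted, from = "b")
  expect_equal(back, mapped_a)
  # inter-genic and gap-aligned positions are unmapped
  expect_true(is.na(lift_position(map, 1L, from = "a")))
  # g1 has a 3-bp deletion in species B at coding positions 16-18
  expect_equal(lift_position(map, 11L, from = "a"), 6L)     # gene starts
  expect_true(all(is.na(lift_position(map, 26:28, from = "a"))))
  expect_equal(lift_position(map, 29L, from = "a"), 21L)    # offset by 3
})

test_that("a genome aligned to itself gives the identity liftover", {
  fx <- load_toy_pair()
  map <- build_homology_map(fx$genome_a, fx$annot_a, fx$genome_a, fx$annot_a)
  in_gene <- c(11:40, 61:100)
  expect_equal(lift_position(map, in_gene, from = "a"), in_gene)
  expect_equal(attr(map, "regions")$identity, c(100, 100))
})

test_that("minus-strand regions map like plus-strand reverse complements", {
  fx <- load_toy_pair()
  map <- build_homology_map(fx$genome_a, fx$annot_a, fx$genome_b, fx$annot_b)
  # align the coding strands directly and re-derive the reference mapping
  g2a <- oracle_revcomp(substr(fx$genome_a$sequence, 61, 100))
  g2b <- oracle_revcomp(substr(fx$genome_b$sequence, 51, 90))
  al <- align_region(g2a, g2b)
  manual_a <- 100 - al$pos_a + 1L
  manual_b <- 90 - al$pos_b + 1L
  sub <- map[map$region == "g2", ]
  expect_equal(sub$pos_a, manual_a)
  expect_equal(sub$pos_b, manual_b)
})

test_that("unpaired region names are an error", {
  fx <- load_toy_pair()
  expect_error(
    build_homology_map(fx$genome_a, fx$annot_a, fx$genome_b, fx$annot_b,
                       pairs = data.frame(name_a = "g1", name_b = "gX")),
    "unpaired")
})

test_that("catalog parsing handles both allele notations and filters status", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("MT-ATP6, T8993G, Cfrm",
               "MT-TL1, m.3243A>G, Cfrm",
               "MT-ND1, G3460A, Reported"), p)
  cat <- load_pathogenic_catalog(p, statuses = NULL)
  expect_equal(cat$human_pos, c(8993L, 3243L, 3460L))
  expect_equal(cat$human_ref, c("T", "A", "G"))
  expect_equal(cat$human_alt, c("G", "G", "A"))
  expect_equal(nrow(load_pathogenic_catalog(p)), 2L)   # Cfrm only

  writeLines("MT-ATP6, X8993G, Cfrm", p)
  expect_error(load_pathogenic_catalog(p), "line 1")

  cat10 <- load_pathogenic_catalog(pathogenic_catalog_excerpt())
  expect_equal(nrow(cat10), 10L)
  expect_true(all(cat10$status == "Cfrm"))
  expect_true(8993L %in% cat10$human_pos)
})

test_that("pathogenic counting needs position, allele, and threshold to agree", {
  fx <- load_toy_pair()
  map <- build_homology_map(fx$genome_a, fx$annot_a, fx$genome_b, fx$annot_b)
  # catalog entry inside g1: species-A position 20 (coding pos 10)
  refa <- strsplit(fx$genome_a$sequence, "")[[1]]
  b_pos <- lift_position(map, 20L, from = "a")
  refb <- strsplit(fx$genome_b$sequence, "")[[1]]
  alt <- setdiff(c("A", "C", "G", "T"), c(refa[20], refb[b_pos]))[1]
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("MT-G1\t%s20%s\tCfrm", refa[20], alt), p)
  cat <- load_pathogenic_catalog(p)

  mkvar <- function(freq, altb = alt) {
    v <- data.frame(pos = b_pos, ref = refb[b_pos], alt = altb,
                    depth = 1000L, alt_count = round(10 * freq),
                    frequency_percent = freq, region = "protein",
                    gene = "g1", effect = NA_character_,
                    pathogenic_human_pos = NA_integer_)
    class(v) <- c("site_variants", "data.frame"); v
  }
  expect_equal(count_pathogenic(mkvar(2), cat[0, ], map)$n_hits, 0L)
  expect_equal(count_pathogenic(mkvar(2), cat, map)$n_hits, 1L)
  expect_equal(count_pathogenic(mkvar(0.8), cat, map)$n_hits, 0L)
  # allele mismatch fails in position+allele mode, passes in position_only
  other <- setdiff(c("A", "C", "G", "T"), c(alt, refb[b_pos]))[1]
  expect_equal(count_pathogenic(mkvar(2, other), cat, map)$n_hits, 0L)
  expect_equal(count_pathogenic(mkvar(2, other), cat, map,
                                match_mode = "position_only")$n_hits, 1L)
  # annotate_pathogenic stamps the human position regardless of frequency
  v <- annotate_pathogenic(mkvar(0.5), cat, map)
  expect_equal(v$pathogenic_human_pos, 20L)
})

test_that("reference-discordant sites are excluded unless requested", {
  fx <- load_toy_pair()
  map <- build_homology_map(fx$genome_a, fx$annot_a, fx$genome_b, fx$annot_b)
  refa <- strsplit(fx$genome_a$sequence, "")[[1]]
  refb <- strsplit(fx$genome_b$sequence, "")[[1]]
  # species B carries a planted substitution at its g1 coding position 21,
  # which sits opposite species-A coding position 24 (the 3-bp deletion
  # shifts the frame of reference)
  a_pos <- 34L   # gene a starts at 11: coding 24
  b_pos <- lift_position(map, a_pos, from = "a")
  expect_false(refa[a_pos] == refb[b_pos])
  alt <- setdiff(c("A", "C", "G", "T"), c(refa[a_pos], refb[b_pos]))[1]
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("MT-G1\t%s%d%s\tCfrm", refa[a_pos], a_pos, alt), p)
  cat <- load_pathogenic_catalog(p)
  v <- data.frame(pos = b_pos, ref = refb[b_pos], alt = alt, depth = 1000L,
                  alt_count = 20L, frequency_percent = 2,
                  region = "protein", gene = "g1", effect = NA_character_,
                  pathogenic_human_pos = NA_integer_)
  class(v) <- c("site_variants", "data.frame")
  expect_equal(count_pathogenic(v, cat, map, genome = fx$genome_b)$n_hits, 0L)
  res <- count_pathogenic(v, cat, map, genome = fx$genome_b,
                          include_ref_mismatch = TRUE)
  expect_equal(res$n_hits, 1L)
  expect_true(res$hits$ref_mismatch)
  # without a genome the concordance check is unavailable and the hit counts
  expect_equal(count_pathogenic(v, cat, map)$n_hits, 1L)
})

test_that("high-identity ortholog mapping is robust to the gap penalty", {
  pair <- synthetic_ortholog_pair(seed = 5)
  for (go in c(2.5, 5, 10)) {
    al <- align_region(
      substr(pair$genome_a$sequence, 8527, 9207),
      substr(pair$genome_b$sequence, 7927, 8607),
      gap_open = go)
    expect_equal(al$pos_b[match(467L, al$pos_a)], 467L,
                 label = sprintf("gap_open=%g", go))
  }
})
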