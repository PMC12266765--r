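# Independent oracles and fixture builders used across the suite.

# Vertebrate mitochondrial genetic code, hand-typed from the published
# table (Met at ATA, Trp at TGA, stops at AGA/AGG), independent of the
# implementation's source of the code.
oracle_mito_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(s)
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")

# Translate a full coding sequence with the oracle code.
oracle_translate <- function(s) {
  n <- nchar(s) %/% 3
  paste(oracle_mito_code[substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))],
        collapse = "")
}

# Affine-gap Needleman-Wunsch (Gotoh) with deterministic traceback
# (diagonal > up > left); a gap of length k costs open + k * ext.
# Returns a data frame of aligned position pairs (NA marks a gap).
oracle_nw <- function(a, b, match = 2, mismatch = -1, open = 5, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M   # X: gap in b, Y: gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  # traceback
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  pa <- integer(0); pb <- integer(0)
  while (i > 0 || j > 0) {
    if (state == 1 && i > 0 && j > 0) {
      pa <- c(i, pa); pb <- c(j, pb)
      s <- if (A[i] == B[j]) match else mismatch
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which.max(abs(prev - (M[i + 1, j + 1] - s)) < 1e-9)
      i <- i - 1; j <- j - 1
    } else if (state == 2 && i > 0) {
      pa <- c(i, pa); pb <- c(NA, pb)
      from_m <- abs(M[i, j + 1] - open - ext - X[i + 1, j + 1]) < 1e-9
      state <- if (from_m) 1 else 2
      i <- i - 1
    } else {
      pa <- c(NA, pa); pb <- c(j, pb)
      from_m <- abs(M[i + 1, j] - open - ext - Y[i + 1, j + 1]) < 1e-9
      state <- if (from_m) 1 else 3
      j <- j - 1
    }
  }
  data.frame(pos_a = pa, pos_b = pb)
}

# Minimal heteroplasmy-only Wright-Fisher bottleneck re-simulation
# (neutral): Poisson(mu) new variants per transmission entering at 1/nb,
# binomial resampling, loss at 0, fixation at 1 leaves the set.
# Returns the vector of final heteroplasmies.
oracle_wf <- function(mu, nb, gens) {
  h <- numeric(0)
  for (g in seq_len(gens)) {
    h <- c(h, rep(1 / nb, rpois(1, mu)))
    if (length(h)) {
      h <- rbinom(length(h), nb, h) / nb
      h <- h[h > 0 & h < 1]
    }
  }
  h
}

# Studentized-range upper tail by direct double integration.
oracle_ptukey_upper <- function(q, k, df) {
  range_cdf <- function(x) {
    f <- function(z) dnorm(z) * (pnorm(z) - pnorm(z - x))^(k - 1)
    k * integrate(f, -Inf, Inf, rel.tol = 1e-11)$value
  }
  fs <- function(s) {
    dens <- exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
                  (df - 1) * log(s) - df * s^2 / 2)
    dens * vapply(s, function(si) range_cdf(q * si), 0)
  }
  1 - integrate(fs, 0, Inf, rel.tol = 1e-10)$value
}

# --- fixture builders -------------------------------------------------

fixture_genome <- function(seq) mt_genome(seq, name = "toy")

# A random genome with a random annotation that partitions positions
# into contiguous gene segments of the five region classes.
fixture_random_table <- function(L = 200, depth_mean = 60, n_regions = 5) {
  g <- mt_genome(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = ""))
  cuts <- sort(sample(seq_len(L - 1), n_regions - 1))
  start <- c(1L, cuts + 1L); end <- c(cuts, L)
  ann <- suppressWarnings(gene_annotation(
    gene = paste0("r", seq_len(n_regions)),
    class = sample(c("protein", "tRNA", "rRNA", "dloop", "other"),
                   n_regions, replace = TRUE),
    start = start, end = end,
    strand = sample(c("+", "-"), n_regions, replace = TRUE),
    genome = g))
  depth <- rpois(L, depth_mean)
  ref <- strsplit(g$sequence, "")[[1]]
  counts <- t(vapply(seq_len(L), function(i) {
    p <- rep(0.01, 4)
    p[match(ref[i], c("A", "C", "G", "T"))] <- 0.97
    as.integer(rmultinom(1, depth[i], p))
  }, integer(4)))
  tab <- allele_counts(
    data.frame(pos = seq_len(L), depth = depth,
               A = counts[, 1], C = counts[, 2], G = counts[, 3],
               T = counts[, 4],
               ins = rbinom(L, 2, 0.02), del = rbinom(L, 2, 0.02)),
    sample_meta("m1", "heart", "+/+", "G1"), g)
  list(genome = g, annotation = ann, table = tab)
}

# Single plus-strand gene covering an entire small genome.
fixture_single_gene <- function(seq) {
  g <- mt_genome(seq)
  ann <- gene_annotation("gene1", "protein", 1L, nchar(seq), "+", g)
  list(genome = g, annotation = ann)
}

# Small table builder: explicit base counts at given positions, the rest
# pure reference at a constant depth.
fixture_table <- function(genome, depth = 100L, override = NULL,
                          meta = sample_meta("m1", "heart", "+/+", "G1")) {
  L <- genome$length
  ref <- strsplit(genome$sequence, "")[[1]]
  df <- data.frame(pos = seq_len(L), depth = depth, A = 0L, C = 0L,
                   G = 0L, T = 0L, ins = 0L, del = 0L)
  for (i in seq_len(L)) df[i, ref[i]] <- depth
  if (!is.null(override)) {
    for (r in seq_len(nrow(override))) {
      i <- override$pos[r]
      for (cn in intersect(names(override), c("depth", "A", "C", "G", "T",
                                              "ins", "del")))
        df[i, cn] <- override[[cn]][r]
    }
  }
  allele_counts(df, meta, genome)
}

toy_extdata <- function(file)
  system.file("extdata", file, package = "mitomut", mustWork = TRUE)
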