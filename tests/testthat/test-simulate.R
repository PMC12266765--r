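small_fixture <- function(L = 600, seed = 2) {
  g <- synthetic_mito_genome(length = L, seed = seed)
  ann <- suppressWarnings(gene_annotation(
    c("p1", "t1", "d1"), c("protein", "tRNA", "dloop"),
    c(1L, 301L, 361L), c(300L, 360L, L), c("+", "+", "+"), g))
  list(genome = g, annotation = ann)
}

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(polg_genotype = "het"), "polg_genotype")
  expect_error(sim_config(error_rate = 0.05), "error_rate")
  expect_error(sim_config(somatic_freq_mean = 1.2), "somatic_freq_mean")
  expect_error(sim_config(selection_s = -0.1), "selection_s")
  expect_error(sim_config(mu_germline = c(wt = -1, het = 1, hom = 1)),
               "non-negative")
})

test_that("no transmissions or no mutation source give an empty germline", {
  fx <- small_fixture()
  cfg <- sim_config(polg_genotype = "mut/mut", generation_count = 0L,
                    genome_length = fx$genome$length, seed = 3)
  expect_equal(nrow(simulate_pedigree(cfg, fx$genome, fx$annotation)), 0L)

  cfg <- sim_config(polg_genotype = "mut/mut", generation_count = 12L,
                    genome_length = fx$genome$length,
                    mu_germline = c(wt = 0, het = 0, hom = 0), seed = 3)
  expect_equal(nrow(simulate_pedigree(cfg, fx$genome, fx$annotation)), 0L)
})

test_that("bottleneck drift matches an independent re-simulation", {
  fx <- small_fixture(L = 6000)
  cfg <- sim_config(polg_genotype = "mut/mut", generation_count = 10L,
                    genome_length = fx$genome$length,
                    mu_germline = c(wt = 0, het = 0, hom = 30),
                    bottleneck_size = 20L, selection_s = 0,
                    indel_fraction = 0, seed = 1)
  reps <- 120
  frac_pkg <- numeric(reps); n_pkg <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg$seed <- r
    germ <- simulate_pedigree(cfg, fx$genome, fx$annotation)
    n_pkg[r] <- nrow(germ)
    frac_pkg[r] <- if (nrow(germ)) mean(germ$heteroplasmy > 0.1) else 0
  }
  set.seed(991)
  frac_wf <- numeric(reps); n_wf <- numeric(reps)
  for (r in seq_len(reps)) {
    h <- oracle_wf(30, 20, 10)
    n_wf[r] <- length(h)
    frac_wf[r] <- if (length(h)) mean(h > 0.1) else 0
  }
  # surviving-variant counts and the >10% heteroplasmy fraction agree
  # within Monte-Carlo error
  se_n <- sqrt(var(n_pkg) / reps + var(n_wf) / reps)
  expect_lt(abs(mean(n_pkg) - mean(n_wf)), 3 * se_n)
  se_f <- sqrt(var(frac_pkg) / reps + var(frac_wf) / reps)
  expect_lt(abs(mean(frac_pkg) - mean(frac_wf)), 3 * se_f)
})

test_that("germline variants are shared across organs at identical heteroplasmy", {
  fx <- small_fixture()
  cfg <- sim_config(polg_genotype = "mut/mut", generation_count = 8L,
                    genome_length = fx$genome$length,
                    mu_germline = c(wt = 0, het = 0, hom = 10),
                    mu_somatic = c(wt = 3, het = 3, hom = 6), seed = 7)
  germ <- simulate_pedigree(cfg, fx$genome, fx$annotation)
  expect_gt(nrow(germ), 0)
  sets <- simulate_soma(germ, cfg, fx$genome, fx$annotation)
  expect_setequal(names(sets), cfg$organs)
  for (organ in cfg$organs) {
    gl <- sets[[organ]][sets[[organ]]$origin == "germline", ]
    expect_equal(gl$pos, germ$pos)
    expect_equal(gl$heteroplasmy, germ$heteroplasmy)
    som <- sets[[organ]][sets[[organ]]$origin == "somatic", ]
    expect_true(all(som$organ == organ))
    expect_true(all(som$heteroplasmy > 0 & som$heteroplasmy < 1))
  }
  # no somatic source: every organ's set equals the germline set exactly
  cfg0 <- cfg; cfg0$mu_somatic <- c(wt = 0, het = 0, hom = 0)
  sets0 <- simulate_soma(germ, cfg0, fx$genome, fx$annotation)
  for (organ in cfg$organs)
    expect_equal(sets0[[organ]], germ, ignore_attr = TRUE)
})

test_that("somatic variant counts follow the configured Poisson mean", {
  fx <- small_fixture()
  cfg <- sim_config(polg_genotype = "mut/mut",
                    genome_length = fx$genome$length,
                    mu_somatic = c(wt = 5, het = 5, hom = 50),
                    organs = "heart", seed = 1)
  germ <- simulate_pedigree(cfg, fx$genome, fx$annotation)
  n <- vapply(seq_len(100), function(r) {
    cfg$seed <- r
    nrow(simulate_soma(germ, cfg, fx$genome, fx$annotation)$heart)
  }, 0)
  se <- sqrt(50 / 100)
  expect_lt(abs(mean(n) - 50), 3 * se)
})

test_that("selection suppresses non-synonymous germline accumulation", {
  fx <- small_fixture()
  counts <- vapply(c(0, 0.9), function(s) {
    tot <- 0
    for (r in 1:15) {
      cfg <- sim_config(polg_genotype = "mut/mut", generation_count = 10L,
                        genome_length = fx$genome$length,
                        mu_germline = c(wt = 0, het = 0, hom = 20),
                        selection_s = s, indel_fraction = 0, seed = r)
      germ <- simulate_pedigree(cfg, fx$genome, fx$annotation)
      tot <- tot + sum(germ$effect_truth == "nonsynonymous")
    }
    tot
  }, 0)
  expect_gt(counts[1], counts[2])
})

test_that("count simulation is exact in the noiseless limits", {
  fx <- small_fixture()
  cfg <- sim_config(genome_length = fx$genome$length, error_rate = 0,
                    depth_mean = 200, organs = "heart", seed = 5)
  # no variants, e = 0: all calls are reference
  tab <- simulate_counts(.subset_truth <- data.frame(
    pos = integer(0), ref = character(0), alt = character(0),
    origin = character(0), organ = character(0),
    heteroplasmy = numeric(0), effect_truth = character(0)), cfg, fx$genome)
  expect_equal(total_mutation_frequency(tab, fx$genome), 0)
  expect_equal(sum(tab$counts$ins), 0L)
  expect_equal(sum(tab$counts$del), 0L)

  # one variant at h = 0.5, deep coverage: frequency within 3 binomial SE
  cfg2 <- sim_config(genome_length = fx$genome$length, error_rate = 0,
                     depth_mean = 10000, organs = "heart", seed = 6)
  ref <- strsplit(fx$genome$sequence, "")[[1]]
  truth <- data.frame(pos = 50L, ref = ref[50],
                      alt = setdiff(c("A", "C", "G", "T"), ref[50])[1],
                      origin = "germline", organ = "all",
                      heteroplasmy = 0.5, effect_truth = "synonymous")
  tab <- simulate_counts(truth, cfg2, fx$genome)
  d <- tab$counts$depth[50]
  f <- 100 * (d - tab$counts[50, ref[50]]) / d
  expect_lt(abs(f - 50), 3 * 100 * sqrt(0.25 / d))
})

test_that("the sequencing-error floor recovers 100 e percent", {
  fx <- small_fixture(L = 2000)
  cfg <- sim_config(genome_length = fx$genome$length, error_rate = 0.003,
                    depth_mean = 500, organs = "heart", seed = 8)
  empty <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), origin = character(0),
                      organ = character(0), heteroplasmy = numeric(0),
                      effect_truth = character(0))
  tab <- simulate_counts(empty, cfg, fx$genome)
  f <- total_mutation_frequency(tab, fx$genome)
  n <- sum(tab$counts$depth)
  se <- 100 * sqrt(0.003 * 0.997 / n)
  expect_lt(abs(f - 0.3), 3 * se)
})

test_that("indel-bearing truth lands in ins/del with their conventions", {
  fx <- small_fixture()
  cfg <- sim_config(genome_length = fx$genome$length, error_rate = 0,
                    depth_mean = 1000, organs = "heart", seed = 9)
  ref <- strsplit(fx$genome$sequence, "")[[1]]
  truth <- data.frame(pos = c(10L, 20L), ref = ref[c(10, 20)],
                      alt = c("+A", "-"), origin = "somatic",
                      organ = "heart", heteroplasmy = c(0.2, 0.3),
                      effect_truth = "indel")
  tab <- simulate_counts(truth, cfg, fx$genome)
  expect_gt(tab$counts$ins[10], 0)
  expect_gt(tab$counts$del[20], 0)
  # deletion reads are excluded from the base-call depth
  expect_equal(tab$counts$depth[20] + 0L,
               sum(unlist(tab$counts[20, c("A", "C", "G", "T")])))
  # substitutions untouched elsewhere
  expect_equal(total_mutation_frequency(tab, fx$genome), 0)
})

test_that("cohort simulation is deterministic and complete", {
  fx <- small_fixture(L = 400)
  grid <- data.frame(mouse_id = c("m1", "m2"),
                     polg_genotype = c("+/+", "mut/mut"),
                     generation_count = c(0L, 3L))
  base <- sim_config(genome_length = 400L, depth_mean = 30,
                     organs = c("heart", "kidney"),
                     mu_germline = c(wt = 0.1, het = 0.1, hom = 5),
                     mu_somatic = c(wt = 1, het = 1, hom = 3), seed = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- simulate_cohort(grid, fx$genome, fx$annotation, d1, base)
  f2 <- simulate_cohort(grid, fx$genome, fx$annotation, d2, base)
  expect_equal(nrow(f1), 4L)   # 2 mice x 2 organs
  for (i in seq_len(nrow(f1))) {
    expect_identical(readLines(f1$counts[i]), readLines(f2$counts[i]))
    expect_identical(readLines(f1$truth[i]), readLines(f2$truth[i]))
  }
  # files are readable back into valid objects
  meta <- sample_meta("m1", "heart", "+/+", "G1")
  tab <- read_counts(f1$counts[1], fx$genome, meta)
  expect_s3_class(tab, "allele_counts")
})

test_that("more generations cannot reduce expected high-heteroplasmy counts", {
  fx <- small_fixture()
  n10 <- 0; n0 <- 0
  for (r in 1:25) {
    mk <- function(gens) {
      cfg <- sim_config(polg_genotype = "mut/mut", generation_count = gens,
                        genome_length = fx$genome$length,
                        mu_germline = c(wt = 0, het = 0, hom = 20),
                        seed = r)
      germ <- simulate_pedigree(cfg, fx$genome, fx$annotation)
      sum(germ$heteroplasmy > 0.1)
    }
    n10 <- n10 + mk(10L); n0 <- n0 + mk(0L)
  }
  expect_gte(n10, n0)
  expect_equal(n0, 0)
})
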