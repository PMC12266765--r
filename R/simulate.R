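# Deterministic named substream seeds: one root seed drives independent,
# order-insensitive streams per stage/mouse/organ.
substream_seed <- function(root, ...) {
  parts <- paste(c(root, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

.genotype_key <- c("+/+" = "wt", "+/mut" = "het", "mut/mut" = "hom")

#' Simulation configuration for a mutator-mouse cohort
#'
#' Defaults describe the emulated study conditions: a 16,299-bp
#' mouse-like mitochondrial genome sequenced to ~2000x with a per-base
#' error rate that puts wild-type samples near a 0.4% total-frequency
#' floor; homozygous-mutator dams inject tens of new germline point
#' mutations per transmission, which drift through an effective
#' germline bottleneck of 20 segregating genome copies; somatic
#' mutations are organ-private and mostly low-frequency; 1-bp indels
#' arise at a small fraction of the point-mutation rate.
#'
#' @param polg_genotype `"+/+"`, `"+/mut"`, or `"mut/mut"`.
#' @param generation_count Number of maternal transmissions through
#'   mutator dams: 0 for a G1-like founder from a wild-type dam, >= 9 for
#'   a G>=10-like history.
#' @param genome_length Genome length in bp (used only for validation
#'   against the supplied genome).
#' @param mu_germline Expected new germline point mutations per
#'   transmission, named triple `c(wt=, het=, hom=)`. The heterozygote
#'   rate defaults to the wild-type rate (heterozygous mutator dams
#'   empirically transmit wild-type-like mtDNA).
#' @param bottleneck_size Effective number of segregating mtDNA copies
#'   per transmission (binomial resampling unit); new mutations enter at
#'   `1/bottleneck_size`.
#' @param selection_s Coefficient in \[0,1\] reducing transmission of
#'   non-synonymous variants each generation.
#' @param mu_somatic Expected organ-private somatic point mutations,
#'   named triple `c(wt=, het=, hom=)`.
#' @param somatic_freq_mean Mean heteroplasmy of a somatic variant
#'   (truncated-exponential law on (0,1)).
#' @param indel_fraction Probability that a new mutation is a 1-bp indel
#'   instead of a substitution.
#' @param organs Organ names.
#' @param depth_mean Mean per-site read depth (Poisson).
#' @param error_rate Per-base-call sequencing error probability; must be
#'   <= 0.01.
#' @param transition_bias When `TRUE`, alternative bases are drawn with a
#'   2:1 transition:transversion-total weighting instead of uniformly.
#' @param mouse_id Identifier stamped into simulated sample metadata.
#' @param seed Root random seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(polg_genotype = "+/+",
                       generation_count = 0L,
                       genome_length = 16299L,
                       mu_germline = c(wt = 0.1, het = 0.1, hom = 80),
                       bottleneck_size = 20L,
                       selection_s = 0,
                       mu_somatic = c(wt = 2, het = 2, hom = 300),
                       somatic_freq_mean = 0.02,
                       indel_fraction = 0.02,
                       organs = c("heart", "kidney", "soleus"),
                       depth_mean = 2000,
                       error_rate = 0.004,
                       transition_bias = FALSE,
                       mouse_id = "sim1",
                       seed = 1L) {
  if (!polg_genotype %in% names(.genotype_key))
    stop('polg_genotype must be "+/+", "+/mut" or "mut/mut"', call. = FALSE)
  stopifnot(generation_count >= 0, genome_length > 0, bottleneck_size >= 1)
  if (!all(c("wt", "het", "hom") %in% names(mu_germline)) ||
      !all(c("wt", "het", "hom") %in% names(mu_somatic)))
    stop("mu_germline and mu_somatic need elements wt, het, hom",
         call. = FALSE)
  if (any(c(mu_germline, mu_somatic) < 0))
    stop("mutation rates must be non-negative", call. = FALSE)
  if (selection_s < 0 || selection_s > 1)
    stop("selection_s must lie in [0, 1]", call. = FALSE)
  if (somatic_freq_mean <= 0 || somatic_freq_mean >= 1)
    stop("somatic_freq_mean must lie in (0, 1)", call. = FALSE)
  if (indel_fraction < 0 || indel_fraction > 1)
    stop("indel_fraction must lie in [0, 1]", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.01)
    stop("error_rate must lie in [0, 0.01]", call. = FALSE)
  structure(list(
    polg_genotype = polg_genotype,
    generation_count = as.integer(generation_count),
    genome_length = as.integer(genome_length),
    mu_germline = mu_germline, bottleneck_size = as.integer(bottleneck_size),
    selection_s = selection_s, mu_somatic = mu_somatic,
    somatic_freq_mean = somatic_freq_mean, indel_fraction = indel_fraction,
    organs = organs, depth_mean = depth_mean, error_rate = error_rate,
    transition_bias = transition_bias, mouse_id = as.character(mouse_id),
    seed = as.integer(seed)),
    class = "sim_config")
}

.generation_label <- function(config) {
  g <- config$generation_count
  if (g == 0L) "G1" else if (g >= 9L) "G10plus" else paste0("G", g)
}

.empty_truth <- function() {
  data.frame(pos = integer(0), ref = character(0), alt = character(0),
             origin = character(0), organ = character(0),
             heteroplasmy = numeric(0), effect_truth = character(0))
}

# draw alt bases for substitutions; uniform over the 3 non-reference bases,
# or transition-weighted when config$transition_bias is on
.draw_alt <- function(ref, transition_bias) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  vapply(ref, function(r) {
    alts <- setdiff(c("A", "C", "G", "T"), r)
    w <- if (transition_bias) ifelse(alts == ts[[r]], 2, 0.5) else rep(1, 3)
    sample(alts, 1L, prob = w)
  }, "", USE.NAMES = FALSE)
}

# draw new mutation records (substitutions + 1-bp indels)
.draw_new_mutations <- function(n, config, genome, annotation, origin,
                                organ) {
  if (n == 0L) return(.empty_truth())
  refv <- .ref_vector(genome)
  pos <- sample.int(genome$length, n, replace = TRUE)
  ref <- refv[pos]
  is_indel <- stats::runif(n) < config$indel_fraction
  alt <- character(n)
  if (any(!is_indel))
    alt[!is_indel] <- .draw_alt(ref[!is_indel], config$transition_bias)
  if (any(is_indel)) {
    ins <- stats::runif(sum(is_indel)) < 0.5
    alt[is_indel][ins] <- paste0("+", sample(c("A", "C", "G", "T"),
                                             sum(ins), replace = TRUE))
    alt[is_indel][!ins] <- "-"
  }
  eff <- rep("indel", n)
  if (any(!is_indel)) {
    # partial-codon sites (a few bases at the tail of incomplete genes)
    # classify to NA and are labelled noncoding in the truth
    cls <- suppressWarnings(
      classify_positions(genome, annotation, pos[!is_indel],
                         alt[!is_indel]))
    eff[!is_indel] <- ifelse(cls$effect %in% c("synonymous", "nonsynonymous"),
                             cls$effect, "noncoding")
  }
  data.frame(pos = pos, ref = ref, alt = alt, origin = origin,
             organ = organ, heteroplasmy = NA_real_, effect_truth = eff)
}

#' Simulate the maternal germline variant set of one mouse
#'
#' Forward-simulates `generation_count` maternal transmissions. Each
#' transmission (1) injects `Poisson(mu)` new mutations at uniform random
#' positions, entering at heteroplasmy `1/bottleneck_size`; (2)
#' down-weights each segregating non-synonymous variant's frequency by
#' `(1 - selection_s)` against the remaining population (purifying
#' selection); (3) resamples every heteroplasmy as
#' `Binomial(bottleneck_size, h) / bottleneck_size` (the germline
#' bottleneck). Variants drifting to 0 are lost; variants fixing at 1
#' become reference replacements and leave the heteroplasmic set (kept in
#' `attr(, "fixed")`).
#'
#' @param config A [sim_config()].
#' @param genome An [mt_genome()] of matching length.
#' @param annotation A [gene_annotation()] (used to classify each new
#'   mutation for the selection step and the ground-truth label).
#' @return Ground-truth data frame (`pos, ref, alt, origin, organ,
#'   heteroplasmy, effect_truth`) with `origin = "germline"`,
#'   `organ = "all"`. `generation_count = 0` gives an empty set.
#' @export
simulate_pedigree <- function(config, genome, annotation) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "mt_genome"))
  if (genome$length != config$genome_length)
    stop("genome length does not match config$genome_length", call. = FALSE)
  set.seed(substream_seed(config$seed, "germline", config$mouse_id))
  mu <- config$mu_germline[[.genotype_key[[config$polg_genotype]]]]
  nb <- config$bottleneck_size
  vars <- .empty_truth()
  fixed <- .empty_truth()
  for (g in seq_len(config$generation_count)) {
    new <- .draw_new_mutations(stats::rpois(1L, mu), config, genome,
                               annotation, "germline", "all")
    new$heteroplasmy <- rep(1 / nb, nrow(new))
    # discard re-draws of an already segregating (pos, alt)
    new <- new[!paste(new$pos, new$alt) %in% paste(vars$pos, vars$alt), ,
               drop = FALSE]
    vars <- rbind(vars, new)
    if (nrow(vars) == 0L) next
    ns <- vars$effect_truth == "nonsynonymous"
    if (config$selection_s > 0 && any(ns)) {
      s <- config$selection_s
      h <- vars$heteroplasmy[ns]
      vars$heteroplasmy[ns] <- h * (1 - s) / (1 - s * h)
    }
    vars$heteroplasmy <- stats::rbinom(nrow(vars), nb,
                                       vars$heteroplasmy) / nb
    fixed <- rbind(fixed, vars[vars$heteroplasmy >= 1, , drop = FALSE])
    vars <- vars[vars$heteroplasmy > 0 & vars$heteroplasmy < 1, ,
                 drop = FALSE]
  }
  rownames(vars) <- NULL
  attr(vars, "fixed") <- fixed
  vars
}

#' Add organ-private somatic variants to a germline set
#'
#' Every organ inherits each germline variant at its germline
#' heteroplasmy exactly (maternal variants are organ-shared); on top,
#' each organ receives `Poisson(mu_somatic)` private variants with
#' heteroplasmies from an exponential law with mean `somatic_freq_mean`,
#' truncated to (0, 1).
#'
#' @param germline Output of [simulate_pedigree()].
#' @param config A [sim_config()].
#' @param genome,annotation As in [simulate_pedigree()].
#' @return Named list, one ground-truth data frame per organ.
#' @export
simulate_soma <- function(germline, config, genome, annotation) {
  stopifnot(inherits(config, "sim_config"))
  mu <- config$mu_somatic[[.genotype_key[[config$polg_genotype]]]]
  out <- list()
  for (organ in config$organs) {
    set.seed(substream_seed(config$seed, "soma", config$mouse_id, organ))
    som <- .draw_new_mutations(stats::rpois(1L, mu), config, genome,
                               annotation, "somatic", organ)
    if (nrow(som)) {
      h <- stats::rexp(nrow(som), rate = 1 / config$somatic_freq_mean)
      while (any(h >= 1))
        h[h >= 1] <- stats::rexp(sum(h >= 1),
                                 rate = 1 / config$somatic_freq_mean)
      som$heteroplasmy <- h
      # keep one record per (pos, alt), germline takes precedence
      som <- som[!paste(som$pos, som$alt) %in%
                   paste(germline$pos, germline$alt), , drop = FALSE]
    }
    organ_set <- rbind(germline, som)
    rownames(organ_set) <- NULL
    out[[organ]] <- organ_set
  }
  out
}

#' Simulate an allele-count table from one organ's true variant set
#'
#' Per site, depth is Poisson(`depth_mean`); each read base is drawn from
#' the site's true allele mixture (reference mass `1 - sum(h)`), then
#' flipped with probability `error_rate` to one of the three other bases
#' uniformly. Insertion-supporting reads are Binomial(depth, h) at the
#' anchor position (and counted in depth); deletion-supporting reads are
#' drawn from an independent Poisson read total and removed from the
#' base-call depth, matching the count-table convention.
#'
#' @param organ_variants One organ's ground-truth data frame (from
#'   [simulate_soma()], or a germline set).
#' @param config A [sim_config()].
#' @param genome An [mt_genome()].
#' @return An [allele_counts()] object.
#' @export
simulate_counts <- function(organ_variants, config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "mt_genome"))
  organs <- setdiff(unique(organ_variants$organ), "all")
  organ <- if (length(organs) == 1L) organs else "all"
  set.seed(substream_seed(config$seed, "counts", config$mouse_id, organ))
  L <- genome$length
  e <- config$error_rate
  refv <- .ref_vector(genome)
  base_idx <- match(refv, c("A", "C", "G", "T"))
  depth <- stats::rpois(L, config$depth_mean)
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  ins <- integer(L); del <- integer(L)

  is_sub <- organ_variants$alt %in% c("A", "C", "G", "T")
  sub <- organ_variants[is_sub, , drop = FALSE]
  var_sites <- unique(sub$pos)

  # deletion-supporting reads never enter the base-call depth: draw the
  # spanning-read total first and split it
  dels <- organ_variants[organ_variants$alt == "-", , drop = FALSE]
  for (i in seq_len(nrow(dels))) {
    span <- stats::rpois(1L, config$depth_mean)
    d <- stats::rbinom(1L, span, dels$heteroplasmy[i])
    del[dels$pos[i]] <- del[dels$pos[i]] + d
    depth[dels$pos[i]] <- max(span - d, 0L)
  }

  # error-only sites, vectorized: split Binomial errors over the 3
  # non-reference bases
  plain <- setdiff(which(depth > 0L), var_sites)
  n_err <- stats::rbinom(length(plain), depth[plain], e)
  e1 <- stats::rbinom(length(plain), n_err, 1 / 3)
  e2 <- stats::rbinom(length(plain), n_err - e1, 1 / 2)
  e3 <- n_err - e1 - e2
  err <- cbind(e1, e2, e3)
  others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  ri <- base_idx[plain]
  counts[cbind(plain, ri)] <- depth[plain] - n_err
  for (j in 1:3) {
    cj <- cbind(plain, others[cbind(ri, j)])
    counts[cj] <- counts[cj] + err[, j]
  }

  # sites carrying true substitutions: full 4-way multinomial with error
  for (p in var_sites) {
    if (depth[p] == 0L) next
    rows <- sub[sub$pos == p, , drop = FALSE]
    m <- numeric(4L)
    m[match(rows$alt, c("A", "C", "G", "T"))] <- rows$heteroplasmy
    m[base_idx[p]] <- max(1 - sum(rows$heteroplasmy), 0)
    m <- m / sum(m)
    pfin <- m * (1 - e) + (1 - m) * e / 3
    counts[p, ] <- as.integer(stats::rmultinom(1L, depth[p], pfin))
  }

  inss <- organ_variants[startsWith(organ_variants$alt, "+"), , drop = FALSE]
  for (i in seq_len(nrow(inss))) {
    p <- inss$pos[i]
    ins[p] <- ins[p] + stats::rbinom(1L, depth[p], inss$heteroplasmy[i])
  }

  meta <- sample_meta(config$mouse_id, organ, config$polg_genotype,
                      .generation_label(config))
  allele_counts(data.frame(pos = seq_len(L), depth = depth,
                           A = counts[, 1], C = counts[, 2],
                           G = counts[, 3], T = counts[, 4],
                           ins = ins, del = del),
                meta, genome)
}

#' Simulate and write a full cohort
#'
#' Runs pedigree, soma, and count simulation for every mouse in the grid
#' and writes one allele-count TSV per mouse and organ
#' (`counts_<mouse>_<organ>.tsv`) plus one ground-truth TSV per mouse
#' (`truth_<mouse>.tsv`). Deterministic for a fixed base seed: every
#' mouse gets a named substream derived from `base_config$seed` (or an
#' explicit `seed` column in the grid).
#'
#' @param grid Data frame with columns `mouse_id`, `polg_genotype`,
#'   `generation_count`, and optionally `seed`.
#' @param genome,annotation Reference and annotation.
#' @param out_dir Output directory (created if needed).
#' @param base_config A [sim_config()] supplying all other parameters.
#' @return Invisibly, a data frame listing the written files with mouse
#'   and organ.
#' @export
simulate_cohort <- function(grid, genome, annotation, out_dir,
                            base_config = sim_config()) {
  need <- c("mouse_id", "polg_genotype", "generation_count")
  if (!all(need %in% names(grid)))
    stop("grid needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  files <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$mouse_id <- as.character(grid$mouse_id[i])
    cfg$polg_genotype <- as.character(grid$polg_genotype[i])
    cfg$generation_count <- as.integer(grid$generation_count[i])
    cfg$seed <- if ("seed" %in% names(grid)) as.integer(grid$seed[i])
      else substream_seed(base_config$seed, "mouse", cfg$mouse_id)
    germ <- simulate_pedigree(cfg, genome, annotation)
    organ_sets <- simulate_soma(germ, cfg, genome, annotation)
    truth <- do.call(rbind, organ_sets)
    truth <- truth[!duplicated(truth[c("pos", "alt", "organ")]), ,
                   drop = FALSE]
    tpath <- file.path(out_dir, sprintf("truth_%s.tsv", cfg$mouse_id))
    utils::write.table(truth, tpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (organ in cfg$organs) {
      tab <- simulate_counts(organ_sets[[organ]], cfg, genome)
      cpath <- file.path(out_dir,
                         sprintf("counts_%s_%s.tsv", cfg$mouse_id, organ))
      write_counts(tab, cpath)
      files[[length(files) + 1L]] <- data.frame(
        mouse_id = cfg$mouse_id, organ = organ, counts = cpath,
        truth = tpath)
    }
  }
  invisible(do.call(rbind, files))
}
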