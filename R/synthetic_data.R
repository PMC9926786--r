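# Seeded synthetic methylomes with planted ground truth.
#
# The generator emulates the statistical shape of replicate WGBS count data:
# irregular CpG positions, U-shaped per-CpG baseline methylation (Beta
# distributed, mean ~0.74 matching bulk liver), Poisson (or negative
# binomial) per-sample coverage, binomial methylated counts, and planted
# CpG-dense differential regions wired to specific condition contrasts.
# Six conditions are simulated: three ages at baseline (A2R0, A8R0, A16R0)
# and three regeneration time points of the young liver (A2R1, A2R2, A2R4),
# all regeneration contrasts sharing the A2R0 reference.

.SIM_CONDITIONS <- c("A2R0", "A8R0", "A16R0", "A2R1", "A2R2", "A2R4")

.SIM_CONTRASTS <- list(
  "A8:A2" = c(test = "A8R0", ref = "A2R0"),
  "A16:A8" = c(test = "A16R0", ref = "A8R0"),
  "A16:A2" = c(test = "A16R0", ref = "A2R0"),
  "R1:R0" = c(test = "A2R1", ref = "A2R0"),
  "R2:R0" = c(test = "A2R2", ref = "A2R0"),
  "R4:R0" = c(test = "A2R4", ref = "A2R0"))

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: four replicates per condition at ~10x mean coverage, a planted
#' methylation shift of 0.3, and planted regions of 8-14 CpGs within at
#' most `region_span_bp` base pairs (CpG-island-like density, as observed
#' for real DMRs, which keeps every planted region recoverable under the
#' 300-bp assembly window).
#'
#' @param seed Integer RNG seed; a fixed seed makes the run byte-identical.
#' @param n_chroms,chrom_length_bp Genome shape.
#' @param n_cpgs Background CpG count (uniform positions without
#'   replacement, sorted), in addition to planted CpG clusters.
#' @param n_genes Background genes (their promoters are kept clear of
#'   planted loci).
#' @param n_repeats,n_cgi Random repeat / CpG-island intervals; planted
#'   clusters are also recorded as CpG islands.
#' @param n_replicates Biological replicates per condition.
#' @param mean_coverage Mean per-sample per-CpG read coverage.
#' @param coverage_model `"poisson"` or `"negbin"`.
#' @param nb_dispersion Negative-binomial size parameter when
#'   `coverage_model = "negbin"`.
#' @param baseline_shape Beta shape pair for per-CpG baseline methylation;
#'   the default (0.7, 0.25) has mean 0.737, matching a ~74\% global
#'   methylation level.
#' @param effect Planted methylation shift magnitude (delta-beta).
#' @param region_cpg_range Inclusive range of CpGs per planted region.
#' @param region_span_bp Maximum span of a planted CpG cluster.
#' @param n_early_single,n_late_single,n_progressive,n_inverse Planted
#'   aging regions per temporal category (split evenly between hyper and
#'   hypo early directions).
#' @param n_regen Planted regions per regeneration contrast (split evenly
#'   between hyper and hypo).
#' @param n_flip_up,n_flip_down Planted flip genes (up-DEG with early-hypo
#'   / late-hyper promoter region; down-DEG mirrored).
#' @param n_sync_deg Planted DEGs with a direction-concordant regeneration
#'   DMR in their promoter.
#' @param n_discordant Planted DEGs with a direction-discordant promoter
#'   DMR (never linked).
#' @param deg_log2fc Planted DEG |log2 fold change|.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length_bp = 5e6,
                       n_cpgs = 30000L, n_genes = 80L, n_repeats = 300L,
                       n_cgi = 60L, n_replicates = 4L, mean_coverage = 10,
                       coverage_model = c("poisson", "negbin"),
                       nb_dispersion = 5, baseline_shape = c(0.7, 0.25),
                       effect = 0.3, region_cpg_range = c(8L, 14L),
                       region_span_bp = 280L,
                       n_early_single = 20L, n_late_single = 20L,
                       n_progressive = 10L, n_inverse = 20L, n_regen = 20L,
                       n_flip_up = 3L, n_flip_down = 3L, n_sync_deg = 6L,
                       n_discordant = 4L, deg_log2fc = 1.5) {
  coverage_model <- match.arg(coverage_model)
  stopifnot(seed == as.integer(seed), n_chroms >= 1, chrom_length_bp >= 1e4,
            n_cpgs >= 100, n_replicates >= 1, mean_coverage > 0,
            length(baseline_shape) == 2L, all(baseline_shape > 0),
            effect > 0, effect < 0.5,
            region_cpg_range[1L] >= 3L,
            region_span_bp <= 300L)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 n_cpgs = as.integer(n_cpgs), n_genes = as.integer(n_genes),
                 n_repeats = as.integer(n_repeats), n_cgi = as.integer(n_cgi),
                 n_replicates = as.integer(n_replicates),
                 mean_coverage = mean_coverage,
                 coverage_model = coverage_model,
                 nb_dispersion = nb_dispersion,
                 baseline_shape = baseline_shape, effect = effect,
                 region_cpg_range = as.integer(region_cpg_range),
                 region_span_bp = as.integer(region_span_bp),
                 n_early_single = as.integer(n_early_single),
                 n_late_single = as.integer(n_late_single),
                 n_progressive = as.integer(n_progressive),
                 n_inverse = as.integer(n_inverse),
                 n_regen = as.integer(n_regen),
                 n_flip_up = as.integer(n_flip_up),
                 n_flip_down = as.integer(n_flip_down),
                 n_sync_deg = as.integer(n_sync_deg),
                 n_discordant = as.integer(n_discordant),
                 deg_log2fc = deg_log2fc),
            class = "sim_config")
}

# Condition shift multipliers (x effect) per planted category.
# Aging conditions accumulate along the A2 -> A8 -> A16 chain so that only
# the intended contrasts carry a difference.
.category_shifts <- function(category, early_dir) {
  s <- if (early_dir == "hyper") 1 else -1
  z <- stats::setNames(rep(0, length(.SIM_CONDITIONS)), .SIM_CONDITIONS)
  switch(category,
    early_single = { z[c("A8R0", "A16R0")] <- s },
    late_single = { z["A16R0"] <- s },
    progressive = { z["A8R0"] <- s; z["A16R0"] <- 2 * s },
    inverse = { z["A8R0"] <- s },
    r1 = { z["A2R1"] <- s },
    r2 = { z["A2R2"] <- s },
    r4 = { z["A2R4"] <- s },
    .stopf("unknown planted category '%s'", category))
  z
}

# Reservation-based placement: draw a window of `width` bp on a random
# chromosome, at least `pad` bp away from every previously reserved window.
.make_reserver <- function(n_chroms, chrom_len) {
  reserved <- stats::setNames(
    lapply(seq_len(n_chroms), function(i) matrix(numeric(0), ncol = 2L)),
    paste0("chr", seq_len(n_chroms)))
  reserve <- function(width, pad = 2000L) {
    for (attempt in seq_len(2000L)) {
      ch <- paste0("chr", sample.int(length(reserved), 1L))
      start <- sample.int(chrom_len - width - 1L, 1L)
      occ <- reserved[[ch]]
      if (nrow(occ) == 0L ||
          all(start + width + pad <= occ[, 1L] | start >= occ[, 2L] + pad)) {
        reserved[[ch]] <<- rbind(occ, c(start, start + width))
        return(list(chrom = ch, start = start, end = start + width))
      }
    }
    .stopf("simulate_methylomes: could not place a %d-bp window; genome too crowded", width)
  }
  reserve
}

# Draw a CpG cluster of k positions within at most span bp.
.draw_cluster <- function(start, k, span) {
  pos <- sort(sample(seq.int(start, start + span - 1L), k))
  as.integer(pos)
}

#' Simulate a synthetic methylome study with planted truth
#'
#' Generates per-sample CpG count tables for all six conditions, gene
#' models, repeat and CpG-island tracks, a DEG table, and a complete truth
#' table of planted regions and genes. Identical configurations produce
#' byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory; when given, all tables are written as
#'   plain-text files (sample TSVs, gene TSV, BED tracks, chrom sizes,
#'   DEG TSV, truth TSVs).
#' @return A `methylome_sim` list: `samples` (condition -> list of
#'   `cpg_counts`), `genes`, `repeats`, `cgi`, `chrom_sizes`, `degs`,
#'   `cpg_info` (per-CpG baseline methylation and planted-locus index),
#'   `truth` (list of `regions`, `region_contrasts`, `genes`), `config`.
#' @export
simulate_methylomes <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- stats::setNames(rep(config$chrom_length_bp, config$n_chroms), chroms)
  reserve <- .make_reserver(config$n_chroms, config$chrom_length_bp)

  # ---- plan planted loci ------------------------------------------------
  split_dirs <- function(n) rep(c("hyper", "hypo"), length.out = n)
  plan <- list()
  add_locus <- function(category, early_dir, gene_pattern = NA_character_,
                        deg_direction = NA_character_) {
    plan[[length(plan) + 1L]] <<- list(category = category,
                                       early_dir = early_dir,
                                       gene_pattern = gene_pattern,
                                       deg_direction = deg_direction)
  }
  for (d in split_dirs(config$n_early_single)) add_locus("early_single", d)
  for (d in split_dirs(config$n_late_single)) add_locus("late_single", d)
  for (d in split_dirs(config$n_progressive)) add_locus("progressive", d)
  for (d in split_dirs(config$n_inverse)) add_locus("inverse", d)
  for (cat in c("r1", "r2", "r4"))
    for (d in split_dirs(config$n_regen)) add_locus(cat, d)
  # flip genes: up-DEG needs early hypo + late hyper = inverse locus with
  # early_dir hypo; down-DEG mirrored
  for (i in seq_len(config$n_flip_up))
    add_locus("inverse", "hypo", "early_sync_late_inverse", "up")
  for (i in seq_len(config$n_flip_down))
    add_locus("inverse", "hyper", "early_sync_late_inverse", "down")
  # sync DEGs: concordant regeneration DMR in the promoter (R2:R0)
  for (d in split_dirs(config$n_sync_deg))
    add_locus("r2", d, "sync_only", if (d == "hypo") "up" else "down")
  # discordant DEGs: promoter DMR direction matches, expression opposes
  for (d in split_dirs(config$n_discordant))
    add_locus("r2", d, "discordant", if (d == "hypo") "down" else "up")

  # ---- place loci, build CpG clusters and genes -------------------------
  n_loci <- length(plan)
  region_rows <- vector("list", n_loci)
  contrast_rows <- list()
  gene_rows <- list()
  cluster_pos <- list()
  cluster_shift <- list()
  cluster_baseline <- list()
  margin <- 0.03
  for (i in seq_len(n_loci)) {
    L <- plan[[i]]
    k <- sample(seq.int(config$region_cpg_range[1L], config$region_cpg_range[2L]), 1L)
    span <- sample(seq.int(max(3L * k, 60L), config$region_span_bp), 1L)
    has_gene <- !is.na(L$gene_pattern)
    if (has_gene) {
      gene_len <- sample(3000:20000, 1L)
      strand <- sample(c("+", "-"), 1L)
      block <- reserve(gene_len + 10000L, pad = 12000L)
      if (strand == "+") {
        tss <- block$start + 7000L
        tx_start <- tss; tx_end <- tss + gene_len
        lo <- tss - 7000L + 20L; hi <- tss + 3000L - 20L - span
      } else {
        tx_start <- block$start; tx_end <- block$start + gene_len
        tss <- tx_end
        lo <- tss - 3000L + 20L; hi <- tss + 7000L - 20L - span
      }
      rs <- sample(seq.int(lo, hi), 1L)
      gene_id <- sprintf("pg%03d", length(gene_rows) + 1L)
      gene_rows[[length(gene_rows) + 1L]] <-
        list(gene_id = gene_id, chrom = block$chrom, strand = strand,
             tx_start = tx_start, tx_end = tx_end,
             pattern = L$gene_pattern, deg_direction = L$deg_direction)
      ch <- block$chrom
    } else {
      w <- reserve(span, pad = 2000L)
      ch <- w$chrom; rs <- w$start
      gene_id <- NA_character_
    }
    pos <- .draw_cluster(rs, k, span)
    shifts <- .category_shifts(L$category, L$early_dir) * config$effect
    lo_b <- 0.02 - min(c(0, shifts)) + margin
    hi_b <- 0.98 - max(c(0, shifts)) - margin
    baseline <- stats::runif(k, lo_b, hi_b)
    cluster_pos[[i]] <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    cluster_shift[[i]] <- shifts
    cluster_baseline[[i]] <- baseline
    region_rows[[i]] <- data.frame(
      region_id = sprintf("pr%03d", i), chrom = ch,
      start = pos[1L], end = pos[k] + 1L, n_cpgs = k,
      category = L$category, early_dir = L$early_dir,
      gene_id = gene_id, stringsAsFactors = FALSE)
    diffs <- vapply(names(.SIM_CONTRASTS), function(nm) {
      pair <- .SIM_CONTRASTS[[nm]]
      shifts[pair["test"]] - shifts[pair["ref"]]
    }, numeric(1))
    hit <- which(abs(diffs) > 1e-9)
    if (length(hit))
      contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
        region_id = sprintf("pr%03d", i),
        contrast = names(.SIM_CONTRASTS)[hit],
        direction = ifelse(diffs[hit] > 0, "hyper", "hypo"),
        stringsAsFactors = FALSE)
  }
  truth_regions <- do.call(rbind, region_rows)
  truth_contrasts <- if (length(contrast_rows)) do.call(rbind, contrast_rows) else
    data.frame(region_id = character(), contrast = character(),
               direction = character(), stringsAsFactors = FALSE)
  rownames(truth_contrasts) <- NULL

  # ---- background genes (promoters kept clear of planted loci) ----------
  for (i in seq_len(config$n_genes)) {
    gene_len <- sample(3000:30000, 1L)
    strand <- sample(c("+", "-"), 1L)
    block <- reserve(gene_len + 10000L, pad = 2000L)
    if (strand == "+") {
      tx_start <- block$start + 7000L; tx_end <- tx_start + gene_len
    } else {
      tx_start <- block$start + 3000L; tx_end <- tx_start + gene_len
    }
    gene_rows[[length(gene_rows) + 1L]] <-
      list(gene_id = sprintf("bg%03d", i), chrom = block$chrom,
           strand = strand, tx_start = tx_start, tx_end = tx_end,
           pattern = "none", deg_direction = NA_character_)
  }
  genes <- .build_gene_models(gene_rows)

  # ---- CpG universe -----------------------------------------------------
  per_chrom <- floor(config$n_cpgs / config$n_chroms)
  bg <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch,
               pos = sort(sample.int(config$chrom_length_bp - 2L, per_chrom)),
               stringsAsFactors = FALSE)
  }))
  planted <- do.call(rbind, cluster_pos)
  bg_key <- paste(bg$chrom, bg$pos)
  bg <- bg[!bg_key %in% paste(planted$chrom, planted$pos), , drop = FALSE]
  n_bg <- nrow(bg)
  shape <- config$baseline_shape
  bg_baseline <- pmin(pmax(stats::rbeta(n_bg, shape[1L], shape[2L]), 0.02), 0.98)
  cpgs <- rbind(
    data.frame(bg, baseline = bg_baseline, locus = 0L, stringsAsFactors = FALSE),
    data.frame(planted, baseline = unlist(cluster_baseline),
               locus = rep(seq_len(n_loci), vapply(cluster_pos, nrow, integer(1))),
               stringsAsFactors = FALSE))
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
  rownames(cpgs) <- NULL

  # per-condition beta matrix
  beta <- matrix(rep(cpgs$baseline, length(.SIM_CONDITIONS)),
                 ncol = length(.SIM_CONDITIONS),
                 dimnames = list(NULL, .SIM_CONDITIONS))
  pl <- which(cpgs$locus > 0L)
  for (j in pl) {
    beta[j, ] <- pmin(pmax(cpgs$baseline[j] + cluster_shift[[cpgs$locus[j]]], 0.02), 0.98)
  }

  # ---- replicate count tables ------------------------------------------
  n_cpg_total <- nrow(cpgs)
  draw_cov <- function(n) {
    if (config$coverage_model == "poisson") stats::rpois(n, config$mean_coverage)
    else stats::rnbinom(n, size = config$nb_dispersion, mu = config$mean_coverage)
  }
  samples <- stats::setNames(vector("list", length(.SIM_CONDITIONS)), .SIM_CONDITIONS)
  for (cond in .SIM_CONDITIONS) {
    reps <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      cov <- draw_cov(n_cpg_total)
      meth <- stats::rbinom(n_cpg_total, cov, beta[, cond])
      keep <- cov > 0L
      tab <- data.frame(chrom = cpgs$chrom[keep], pos = cpgs$pos[keep],
                        meth = meth[keep], total = cov[keep],
                        stringsAsFactors = FALSE)
      reps[[r]] <- new_cpg_counts(tab, sprintf("%s_rep%d", cond, r))
    }
    samples[[cond]] <- reps
  }

  # ---- tracks -----------------------------------------------------------
  repeat_classes <- c("SINE", "LINE", "LTR", "Simple_repeat")
  rep_w <- sample(100:1000, config$n_repeats, replace = TRUE)
  rep_ch <- sample(chroms, config$n_repeats, replace = TRUE)
  rep_s <- vapply(rep_w, function(w) sample.int(config$chrom_length_bp - w, 1L), integer(1))
  repeats <- data.frame(chrom = rep_ch, start = rep_s, end = rep_s + rep_w,
                        name = sample(repeat_classes, config$n_repeats, replace = TRUE),
                        stringsAsFactors = FALSE)
  repeats <- repeats[order(repeats$chrom, repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL
  class(repeats) <- c("region_track", "data.frame")
  cgi_w <- sample(300:1500, config$n_cgi, replace = TRUE)
  cgi_ch <- sample(chroms, config$n_cgi, replace = TRUE)
  cgi_s <- vapply(cgi_w, function(w) sample.int(config$chrom_length_bp - w, 1L), integer(1))
  cgi <- data.frame(chrom = c(cgi_ch, truth_regions$chrom),
                    start = c(cgi_s, truth_regions$start),
                    end = c(cgi_s + cgi_w, truth_regions$end),
                    name = "cgi", stringsAsFactors = FALSE)
  cgi <- cgi[order(cgi$chrom, cgi$start), , drop = FALSE]
  rownames(cgi) <- NULL
  class(cgi) <- c("region_track", "data.frame")

  # ---- DEG table --------------------------------------------------------
  planted_gene <- vapply(gene_rows, function(g) g$pattern, character(1)) != "none"
  deg_dir <- vapply(gene_rows, function(g) g$deg_direction, character(1))
  gene_ids <- vapply(gene_rows, function(g) g$gene_id, character(1))
  log2fc <- stats::rnorm(length(gene_ids), 0, 0.4)
  p_raw <- stats::runif(length(gene_ids))
  for (i in which(planted_gene & !is.na(deg_dir))) {
    sgn <- if (deg_dir[i] == "up") 1 else -1
    log2fc[i] <- sgn * stats::runif(1L, config$deg_log2fc, config$deg_log2fc + 1)
    p_raw[i] <- stats::runif(1L, 1e-8, 1e-5)
  }
  degs <- data.frame(gene_id = gene_ids, log2fc = log2fc, p_raw = p_raw,
                     q = NA_real_, stringsAsFactors = FALSE)
  truth_genes <- data.frame(
    gene_id = gene_ids,
    pattern = vapply(gene_rows, function(g) g$pattern, character(1)),
    deg_direction = deg_dir, stringsAsFactors = FALSE)

  cpg_info <- data.frame(chrom = cpgs$chrom, pos = cpgs$pos,
                         baseline = cpgs$baseline, locus = cpgs$locus,
                         stringsAsFactors = FALSE)
  sim <- structure(list(samples = samples, genes = genes, repeats = repeats,
                        cgi = cgi, chrom_sizes = chrom_sizes, degs = degs,
                        cpg_info = cpg_info,
                        truth = list(regions = truth_regions,
                                     region_contrasts = truth_contrasts,
                                     genes = truth_genes),
                        config = config),
                   class = "methylome_sim")
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

# Assemble gene_models from planted/background gene descriptors, with
# random exon structures.
.build_gene_models <- function(gene_rows) {
  n <- length(gene_rows)
  exon_starts <- vector("list", n); exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gene_rows[[i]]
    k <- sample(2:6, 1L)
    pts <- sort(sample(seq.int(g$tx_start + 1L, g$tx_end - 1L), 2L * k - 2L))
    bnd <- c(g$tx_start, pts, g$tx_end)
    exon_starts[[i]] <- as.integer(bnd[seq(1L, 2L * k, by = 2L)])
    exon_ends[[i]] <- as.integer(bnd[seq(2L, 2L * k, by = 2L)])
  }
  df <- data.frame(gene_id = vapply(gene_rows, function(g) g$gene_id, character(1)),
                   chrom = vapply(gene_rows, function(g) g$chrom, character(1)),
                   strand = vapply(gene_rows, function(g) g$strand, character(1)),
                   tx_start = vapply(gene_rows, function(g) g$tx_start, numeric(1)),
                   tx_end = vapply(gene_rows, function(g) g$tx_end, numeric(1)),
                   cds_start = NA_integer_, cds_end = NA_integer_,
                   stringsAsFactors = FALSE)
  df$tx_start <- as.integer(df$tx_start)
  df$tx_end <- as.integer(df$tx_end)
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write a simulated study to disk as plain-text tables
#'
#' @param sim A `methylome_sim` from [simulate_methylomes()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(sim$samples)) {
    for (r in seq_along(sim$samples[[cond]])) {
      write_cpg_table(sim$samples[[cond]][[r]],
                      file.path(out_dir, sprintf("%s_rep%d.tsv", cond, r)))
    }
  }
  write_gene_models(sim$genes, file.path(out_dir, "genes.tsv"))
  writeLines(sprintf("%s\t%d\t%d\t%s", sim$repeats$chrom, sim$repeats$start,
                     sim$repeats$end, sim$repeats$name),
             file.path(out_dir, "repeats.bed"))
  writeLines(sprintf("%s\t%d\t%d\t%s", sim$cgi$chrom, sim$cgi$start,
                     sim$cgi$end, sim$cgi$name),
             file.path(out_dir, "cgi.bed"))
  writeLines(sprintf("%s\t%d", names(sim$chrom_sizes), sim$chrom_sizes),
             file.path(out_dir, "chrom_sizes.tsv"))
  write_deg_table(sim$degs, file.path(out_dir, "degs.tsv"))
  utils::write.table(sim$truth$regions, file.path(out_dir, "truth_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$region_contrasts,
                     file.path(out_dir, "truth_region_contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(out_dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Score DMR recovery against planted truth
#'
#' A planted region counts as recovered when a called DMR of the correct
#' direction overlaps it by at least one bp in the region's contrast; a
#' called DMR counts as a true positive when it overlaps a planted region
#' of its own direction in its contrast.
#'
#' @param truth The `truth` element of a `methylome_sim`.
#' @param catalogs Named list of `dmr_catalog`s keyed by contrast label.
#' @return A list with `per_contrast` (data frame: contrast, n_planted,
#'   n_recovered, n_called, n_true_calls, sensitivity, precision) and
#'   overall `sensitivity` and `precision`.
#' @export
score_recovery <- function(truth, catalogs) {
  rc <- merge(truth$region_contrasts, truth$regions[, c("region_id", "chrom", "start", "end")],
              by = "region_id")
  rows <- list()
  for (ct in sort(unique(rc$contrast))) {
    planted <- rc[rc$contrast == ct, , drop = FALSE]
    called <- catalogs[[ct]]
    n_rec <- 0L; n_true <- 0L; n_called <- 0L
    if (!is.null(called)) {
      n_called <- nrow(called)
      if (nrow(called) && nrow(planted)) {
        hits <- .overlap_hits(planted, called, compare_params())
        ok <- planted$direction[hits$q] == called$direction[hits$s]
        n_rec <- length(unique(hits$q[ok]))
        n_true <- length(unique(hits$s[ok]))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = ct, n_planted = nrow(planted), n_recovered = n_rec,
      n_called = n_called, n_true_calls = n_true,
      sensitivity = if (nrow(planted)) n_rec / nrow(planted) else NA_real_,
      precision = if (n_called) n_true / n_called else NA_real_,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  list(per_contrast = per,
       sensitivity = sum(per$n_recovered) / sum(per$n_planted),
       precision = if (sum(per$n_called)) sum(per$n_true_calls) / sum(per$n_called) else NA_real_)
}
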