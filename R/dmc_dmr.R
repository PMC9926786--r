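# DMC calling and sliding-window DMR assembly.

#' Parameters for DMC calling
#'
#' @param delta_threshold Minimum absolute methylation difference for a DMC
#'   (strict inequality), default 0.2.
#' @param p_threshold Maximum p-value (strict inequality), default 0.05.
#'   DMC p-values are deliberately not multiplicity-adjusted; a note is
#'   emitted once per call of [call_dmcs()].
#' @param min_coverage Minimum pooled read count required in *both* groups
#'   for a CpG to be tested, default 3.
#' @param statistic `"fisher"` (two-sided exact test on the pooled 2x2
#'   table) or `"credible"` (lower bound of the central 95\% posterior
#'   interval of the absolute methylation difference under independent
#'   Jeffreys-Beta posteriors, used in place of the raw difference; the
#'   p-value is still the Fisher p).
#' @return A `dmc_params` list.
#' @export
dmc_params <- function(delta_threshold = 0.2, p_threshold = 0.05,
                       min_coverage = 3L, statistic = c("fisher", "credible")) {
  statistic <- match.arg(statistic)
  stopifnot(delta_threshold > 0, delta_threshold < 1,
            p_threshold > 0, p_threshold < 1, min_coverage >= 1)
  structure(list(delta_threshold = delta_threshold, p_threshold = p_threshold,
                 min_coverage = as.integer(min_coverage), statistic = statistic),
            class = "dmc_params")
}

#' Parameters for DMR assembly
#'
#' A DMR is a maximal merged set of window seeds, where a seed is any run of
#' `min_dmcs` consecutive same-direction DMCs whose positional span does not
#' exceed `window_bp` (inclusive), with the window slid at `step_nt`
#' nucleotide steps.
#'
#' @param window_bp Window size in bp, default 300.
#' @param min_dmcs Minimum DMCs per seed, default 3.
#' @param step_nt Window step in nt, default 1.
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(window_bp = 300L, min_dmcs = 3L, step_nt = 1L) {
  stopifnot(window_bp >= 1, min_dmcs >= 2, step_nt >= 1)
  structure(list(window_bp = as.integer(window_bp),
                 min_dmcs = as.integer(min_dmcs),
                 step_nt = as.integer(step_nt)),
            class = "dmr_params")
}

#' Pool replicate CpG count tables for one condition group
#'
#' Sums methylated and total counts across samples at each CpG present in
#' any sample (union of coordinates). The pooled methylation fraction at a
#' CpG equals the coverage-weighted mean of the per-sample fractions.
#'
#' @param tables List of `cpg_counts` tables (see [read_cpg_table()]).
#' @return A data frame `chrom`, `pos`, `meth`, `total` sorted by
#'   (chrom, pos).
#' @export
pool_group <- function(tables) {
  if (!length(tables)) .stopf("pool_group: need at least one sample")
  df <- do.call(rbind, lapply(tables, function(x) {
    as.data.frame(x)[, c("chrom", "pos", "meth", "total")]
  }))
  if (any(df$meth < 0 | df$total < 0)) .stopf("pool_group: negative counts")
  agg <- stats::aggregate(cbind(meth, total) ~ chrom + pos, data = df, FUN = sum)
  agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Two-sided Fisher exact p for 2x2 tables, vectorised over rows.
.fisher_p <- function(ma, na_, mb, nb) {
  n <- length(ma)
  p <- numeric(n)
  for (i in seq_len(n)) {
    tab <- matrix(c(ma[i], na_[i] - ma[i], mb[i], nb[i] - mb[i]), nrow = 2L)
    p[i] <- stats::fisher.test(tab)$p.value
  }
  p
}

#' Lower credible bound of the absolute methylation difference
#'
#' Posterior of each group's methylation level is Beta(meth + 1/2,
#' unmeth + 1/2) (Jeffreys prior); the statistic is the lower endpoint of
#' the central `level` posterior interval of |beta_a - beta_b|, i.e. the
#' (1 - level)/2 quantile of the absolute difference of the two independent
#' posteriors, capped at the raw pooled absolute difference so that the
#' statistic only ever discounts sampling noise.
#'
#' @param meth_a,total_a Pooled counts in group A.
#' @param meth_b,total_b Pooled counts in group B.
#' @param level Central interval mass, default 0.95.
#' @param grid_n Quadrature grid size, default 2001.
#' @return Numeric vector of lower credible bounds in `[0, 1]`, capped at
#'   the raw pooled absolute difference.
#' @export
credible_diff_lower <- function(meth_a, total_a, meth_b, total_b,
                                level = 0.95, grid_n = 2001L) {
  stopifnot(length(meth_a) == length(total_a),
            length(meth_b) == length(total_b),
            length(meth_a) == length(meth_b))
  alpha <- (1 - level) / 2
  u <- (seq_len(grid_n) - 0.5) / grid_n
  w <- 1 / grid_n
  raw <- abs(meth_a / total_a - meth_b / total_b)
  bound <- vapply(seq_along(meth_a), function(i) {
    a1 <- meth_a[i] + 0.5; b1 <- total_a[i] - meth_a[i] + 0.5
    a2 <- meth_b[i] + 0.5; b2 <- total_b[i] - meth_b[i] + 0.5
    dens <- stats::dbeta(u, a1, b1) * w
    # P(|beta_a - beta_b| <= d) marginalised over the group-A posterior
    Fabs <- function(d) {
      sum(dens * (stats::pbeta(u + d, a2, b2) - stats::pbeta(u - d, a2, b2)))
    }
    # Fabs is nondecreasing from 0 to 1 on [0, 1]
    if (Fabs(0) >= alpha) return(0)
    stats::uniroot(function(d) Fabs(d) - alpha, lower = 0, upper = 1,
                   tol = 1e-8)$root
  }, numeric(1))
  # shrinkage can nudge the quantile past the raw difference for tiny,
  # discrepant counts; the statistic discounts noise, never adds evidence
  pmin(bound, raw)
}

#' Call differentially methylated cytosines between two pooled groups
#'
#' Only CpGs with pooled coverage of at least `min_coverage` in both groups
#' are tested. A CpG is a DMC iff its methylation difference statistic
#' strictly exceeds `delta_threshold` and the two-sided Fisher exact
#' p-value on the pooled 2x2 count table is strictly below `p_threshold`.
#' With `statistic = "credible"` the lower 95\% credible bound of the
#' absolute difference replaces the raw absolute difference in the first
#' condition.
#'
#' @param group_a Pooled counts for the test group (see [pool_group()]).
#' @param group_b Pooled counts for the reference group.
#' @param params A [dmc_params()] object.
#' @param quiet Suppress the no-multiplicity-adjustment note.
#' @return A `dmc_set` data frame: `chrom`, `pos` (0-based), `beta_a`,
#'   `beta_b`, `delta` (= beta_a - beta_b), `p_value`, `direction`
#'   (`hyper` iff delta > 0), sorted by (chrom, pos).
#' @export
call_dmcs <- function(group_a, group_b, params = dmc_params(), quiet = FALSE) {
  if (!nrow(group_a) || !nrow(group_b))
    .stopf("call_dmcs: both groups must be non-empty")
  if (any(group_a$meth < 0 | group_a$total < 0 | group_b$meth < 0 | group_b$total < 0))
    .stopf("call_dmcs: negative counts")
  if (!quiet)
    message("call_dmcs: DMC p-values are raw (no multiple-testing adjustment)")
  key_a <- paste(group_a$chrom, group_a$pos)
  key_b <- paste(group_b$chrom, group_b$pos)
  idx <- match(key_a, key_b)
  keep <- !is.na(idx)
  a <- group_a[keep, , drop = FALSE]
  b <- group_b[idx[keep], , drop = FALSE]
  tested <- a$total >= params$min_coverage & b$total >= params$min_coverage
  a <- a[tested, , drop = FALSE]
  b <- b[tested, , drop = FALSE]
  beta_a <- a$meth / a$total
  beta_b <- b$meth / b$total
  delta <- beta_a - beta_b
  # the credible bound never exceeds |delta|, so |delta| > threshold is a
  # valid pre-filter for both statistics
  cand <- abs(delta) > params$delta_threshold
  if (params$statistic == "credible" && any(cand)) {
    cred <- credible_diff_lower(a$meth[cand], a$total[cand],
                                b$meth[cand], b$total[cand])
    cand[cand] <- cred > params$delta_threshold
  }
  p <- rep(NA_real_, length(delta))
  if (any(cand))
    p[cand] <- .fisher_p(a$meth[cand], a$total[cand], b$meth[cand], b$total[cand])
  hit <- cand & !is.na(p) & p < params$p_threshold
  out <- data.frame(chrom = a$chrom[hit], pos = a$pos[hit],
                    beta_a = beta_a[hit], beta_b = beta_b[hit],
                    delta = delta[hit], p_value = p[hit],
                    direction = ifelse(delta[hit] > 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- sum(tested)
  attr(out, "params") <- params
  class(out) <- c("dmc_set", "data.frame")
  out
}

# Merge seed index runs on one chromosome / one direction.
# pos: sorted 0-based positions. Returns data.frame(first, last) of member
# index ranges of merged components, or NULL.
.dmr_components <- function(pos, window_bp, min_dmcs) {
  n <- length(pos)
  if (n < min_dmcs) return(NULL)
  k <- min_dmcs
  first <- seq_len(n - k + 1L)
  span_ok <- pos[first + k - 1L] - pos[first] <= window_bp
  seeds <- first[span_ok]
  if (!length(seeds)) return(NULL)
  # seed i covers indices [i, i+k-1]; seeds sharing an index merge
  comp_first <- integer(0); comp_last <- integer(0)
  cur_first <- seeds[1L]; cur_last <- seeds[1L] + k - 1L
  for (s in seeds[-1L]) {
    if (s <= cur_last) {            # shares at least one DMC
      cur_last <- s + k - 1L
    } else {
      comp_first <- c(comp_first, cur_first)
      comp_last <- c(comp_last, cur_last)
      cur_first <- s; cur_last <- s + k - 1L
    }
  }
  comp_first <- c(comp_first, cur_first)
  comp_last <- c(comp_last, cur_last)
  data.frame(first = comp_first, last = comp_last)
}

#' Assemble DMRs from called DMCs by the sliding-window rule
#'
#' Hyper- and hypo-DMCs are processed independently. Every run of
#' `min_dmcs` consecutive same-direction DMCs whose positional span
#' (last - first) is at most `window_bp` seeds a region; seeds sharing any
#' DMC are merged transitively; each merged component becomes one DMR
#' spanning its outermost member DMCs (end exclusive = last position + 1).
#'
#' @param dmcs A `dmc_set` (sorted by chrom, pos) from [call_dmcs()].
#' @param params A [dmr_params()] object.
#' @param contrast Contrast label stored with the catalog.
#' @return A `dmr_catalog` (see [new_dmr_catalog()]).
#' @export
assemble_dmrs <- function(dmcs, params = dmr_params(), contrast = "A:B") {
  if (nrow(dmcs) &&
      any(order(dmcs$chrom, dmcs$pos) != seq_len(nrow(dmcs))))
    .stopf("assemble_dmrs: DMCs must be sorted by (chrom, pos)")
  rows <- list()
  for (dir in c("hyper", "hypo")) {
    d <- dmcs[dmcs$direction == dir, , drop = FALSE]
    for (ch in unique(d$chrom)) {
      dc <- d[d$chrom == ch, , drop = FALSE]
      comp <- .dmr_components(dc$pos, params$window_bp, params$min_dmcs)
      if (is.null(comp)) next
      for (j in seq_len(nrow(comp))) {
        i1 <- comp$first[j]; i2 <- comp$last[j]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch,
          start = dc$pos[i1],
          end = dc$pos[i2] + 1L,
          direction = dir,
          dmc_count = i2 - i1 + 1L,
          mean_delta = mean(dc$delta[i1:i2]),
          min_p = min(dc$p_value[i1:i2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               direction = character(), dmc_count = integer(),
               mean_delta = numeric(), min_p = numeric())
  new_dmr_catalog(df, contrast)
}
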