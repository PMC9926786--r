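# Independent oracles and fixture builders used across the suite.

# Brute-force sliding-window DMR oracle for one chromosome and one
# direction: enumerate every window [s, s + window_bp] at 1-nt steps, mark
# windows holding >= min_dmcs DMCs, and merge marked DMC index sets that
# share members. Returns a list of integer index vectors (members of each
# region), in positional order.
oracle_window_dmrs <- function(pos, window_bp = 300L, min_dmcs = 3L) {
  n <- length(pos)
  if (n < min_dmcs) return(list())
  stopifnot(!is.unsorted(pos, strictly = TRUE))
  s <- seq.int(min(pos) - window_bp, max(pos))
  hi <- findInterval(s + window_bp, pos)
  lo <- findInterval(s - 1L, pos) + 1L
  ok <- hi - lo + 1L >= min_dmcs
  if (!any(ok)) return(list())
  grp <- unique(data.frame(lo = lo[ok], hi = hi[ok]))
  grp <- grp[order(grp$lo, grp$hi), , drop = FALSE]
  out <- list()
  cur_lo <- grp$lo[1L]; cur_hi <- grp$hi[1L]
  for (i in seq_len(nrow(grp))[-1L]) {
    if (grp$lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, grp$hi[i])
    } else {
      out[[length(out) + 1L]] <- seq.int(cur_lo, cur_hi)
      cur_lo <- grp$lo[i]; cur_hi <- grp$hi[i]
    }
  }
  out[[length(out) + 1L]] <- seq.int(cur_lo, cur_hi)
  out
}

# Two-sided Fisher exact p-value by full enumeration of the hypergeometric
# support of the 2x2 margin: sum the probabilities of all tables no more
# probable than the observed one.
oracle_fisher_p <- function(ma, na_, mb, nb) {
  m <- ma + mb
  supp <- max(0L, m - nb):min(m, na_)
  probs <- dhyper(supp, na_, nb, m)
  pobs <- dhyper(ma, na_, nb, m)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up q-values, written out directly.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Overlap-connected components by exhaustive graph traversal (BFS over an
# all-pairs adjacency), for small interval sets.
oracle_components <- function(df, min_overlap_bp = 1L) {
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && df$chrom[i] == df$chrom[j]) {
      ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
      adj[i, j] <- ov >= min_overlap_bp
    }
  }
  comp <- rep(0L, n); cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# Quick DMR-catalog construction from coordinate vectors.
make_catalog <- function(chrom, start, end, direction, contrast = "X:Y") {
  n <- length(start)
  new_dmr_catalog(data.frame(
    chrom = rep_len(chrom, n), start = as.integer(start),
    end = as.integer(end), direction = rep_len(direction, n),
    dmc_count = rep(3L, n),
    mean_delta = ifelse(rep_len(direction, n) == "hyper", 0.3, -0.3),
    min_p = rep(0.01, n), stringsAsFactors = FALSE), contrast)
}

# Pooled-count frame construction.
make_pooled <- function(pos, meth, total, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             meth = as.integer(meth), total = as.integer(total),
             stringsAsFactors = FALSE)
}

# Build three same-direction catalogs realizing given Venn cell counts.
# cells: named vector with n1, n2, n3 (exclusive), n12, n13, n23
# (pairwise-exclusive), n123. Every cell unit occupies its own disjoint
# 100-bp block; multi-membership cells place the identical block in each
# member catalog.
build_venn_catalogs <- function(cells, labels = c("R1:R0", "R2:R0", "R4:R0"),
                                direction = "hyper") {
  sets <- list(`1` = list(), `2` = list(), `3` = list())
  slot <- 0L
  place <- function(members, count) {
    for (u in seq_len(count)) {
      slot <<- slot + 1L
      iv <- c(slot * 1000L, slot * 1000L + 100L)
      for (m in members) sets[[m]][[length(sets[[m]]) + 1L]] <<- iv
    }
  }
  place("1", cells[["n1"]]); place("2", cells[["n2"]]); place("3", cells[["n3"]])
  place(c("1", "2"), cells[["n12"]])
  place(c("1", "3"), cells[["n13"]])
  place(c("2", "3"), cells[["n23"]])
  place(c("1", "2", "3"), cells[["n123"]])
  lapply(1:3, function(i) {
    m <- do.call(rbind, sets[[as.character(i)]])
    make_catalog("chr1", m[, 1L], m[, 2L], direction, labels[i])
  })
}

# Random DMC set on one chromosome for assembler property tests.
random_dmcs <- function(n, max_pos = 4000L) {
  pos <- sort(sample.int(max_pos, n))
  data.frame(chrom = "chr1", pos = pos,
             beta_a = 0.8, beta_b = 0.4, delta = 0.4, p_value = 0.001,
             direction = sample(c("hyper", "hypo"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
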