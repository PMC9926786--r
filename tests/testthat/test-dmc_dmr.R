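test_that("pooling sums counts across replicates over the coordinate union", {
  t1 <- new_cpg_counts(make_pooled(c(999, 2000), c(5, 1), c(10, 2)), "a1")
  t2 <- new_cpg_counts(make_pooled(999, 4, 10), "a2")
  p <- pool_group(list(t1, t2))
  expect_identical(p$meth, c(9L, 1L))
  expect_identical(p$total, c(20L, 2L))
  expect_error(pool_group(list()), "at least one")
})

test_that("pooled fraction equals the coverage-weighted mean of sample fractions", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 15L
    tabs <- lapply(1:4, function(i) {
      tot <- sample(1:30, n, replace = TRUE)
      new_cpg_counts(make_pooled(seq_len(n) * 10L, rbinom(n, tot, 0.5), tot),
                     paste0("s", i))
    })
    p <- pool_group(tabs)
    manual <- sapply(seq_len(n), function(j) {
      ms <- sapply(tabs, function(t) t$meth[j])
      ts <- sapply(tabs, function(t) t$total[j])
      sum(ms / ts * ts) / sum(ts)
    })
    expect_equal(p$meth / p$total, manual)
  }
})

test_that("Fisher DMC call matches the exact hypergeometric enumeration oracle", {
  a <- make_pooled(100, 19, 20)
  b <- make_pooled(100, 5, 20)
  dmcs <- call_dmcs(a, b, dmc_params(), quiet = TRUE)
  expect_identical(nrow(dmcs), 1L)
  expect_equal(dmcs$delta, 0.7)
  expect_identical(dmcs$direction, "hyper")
  expect_equal(dmcs$p_value, oracle_fisher_p(19, 20, 5, 20), tolerance = 1e-10)

  # random tables: p always agrees with enumeration
  set.seed(7)
  for (i in 1:50) {
    na_ <- sample(5:40, 1); nb <- sample(5:40, 1)
    ma <- rbinom(1, na_, 0.8); mb <- rbinom(1, nb, 0.2)
    d <- ma / na_ - mb / nb
    if (abs(d) <= 0.2) next
    got <- call_dmcs(make_pooled(1, ma, na_), make_pooled(1, mb, nb),
                     dmc_params(p_threshold = 0.999999), quiet = TRUE)
    expect_equal(got$p_value, oracle_fisher_p(ma, na_, mb, nb), tolerance = 1e-9)
  }
})

test_that("DMC thresholds are strict and the coverage filter applies to both groups", {
  # identical groups: delta 0, never a DMC
  expect_identical(nrow(call_dmcs(make_pooled(1, 10, 20), make_pooled(1, 10, 20),
                                  quiet = TRUE)), 0L)
  # delta exactly at the threshold is not a DMC (strict inequality)
  a <- make_pooled(1, 120, 200); b <- make_pooled(1, 80, 200)  # delta = 0.2
  expect_identical(nrow(call_dmcs(a, b, quiet = TRUE)), 0L)
  # coverage below 3 in both groups: site not tested
  got <- call_dmcs(make_pooled(1, 2, 2), make_pooled(1, 0, 2), quiet = TRUE)
  expect_identical(nrow(got), 0L)
  expect_identical(attr(got, "n_tested"), 0L)
  # but tested when both reach min_coverage
  got2 <- call_dmcs(make_pooled(1, 3, 3), make_pooled(1, 0, 3), quiet = TRUE)
  expect_identical(attr(got2, "n_tested"), 1L)
})

test_that("raising the delta threshold never increases the DMC count", {
  set.seed(11)
  n <- 300L
  tot_a <- rpois(n, 30) + 3L; tot_b <- rpois(n, 30) + 3L
  theta <- runif(n)
  a <- make_pooled(seq_len(n) * 7L, rbinom(n, tot_a, pmin(theta + 0.2, 1)), tot_a)
  b <- make_pooled(seq_len(n) * 7L, rbinom(n, tot_b, theta), tot_b)
  counts <- sapply(c(0.1, 0.2, 0.3, 0.4), function(thr)
    nrow(call_dmcs(a, b, dmc_params(delta_threshold = thr), quiet = TRUE)))
  expect_true(all(diff(counts) <= 0))
})

test_that("credible difference bound never exceeds the raw pooled difference", {
  set.seed(5)
  for (i in 1:40) {
    na_ <- sample(3:60, 1); nb <- sample(3:60, 1)
    ma <- sample(0:na_, 1); mb <- sample(0:nb, 1)
    cred <- credible_diff_lower(ma, na_, mb, nb)
    expect_lte(cred, abs(ma / na_ - mb / nb) + 1e-8)
    expect_gte(cred, 0)
  }
  # strong signal at high coverage: bound approaches but stays below delta
  cred <- credible_diff_lower(190, 200, 20, 200)
  expect_gt(cred, 0.7)
  expect_lt(cred, 0.85)
})

test_that("credible statistic is more conservative than the raw delta filter", {
  a <- make_pooled(c(10, 20), c(4, 90), c(5, 100))
  b <- make_pooled(c(10, 20), c(1, 30), c(5, 100))
  pars_raw <- dmc_params(statistic = "fisher", p_threshold = 0.5)
  pars_cred <- dmc_params(statistic = "credible", p_threshold = 0.5)
  raw <- call_dmcs(a, b, pars_raw, quiet = TRUE)
  cred <- call_dmcs(a, b, pars_cred, quiet = TRUE)
  # every credible call is also a raw call
  expect_true(all(cred$pos %in% raw$pos))
  # the weak 5-read site passes the raw delta filter but its posterior is
  # too wide for the credible bound
  expect_true(10 %in% raw$pos)
  expect_false(10 %in% cred$pos)
  expect_true(20 %in% cred$pos)
})

test_that("DMR assembly reproduces the worked window examples", {
  mk <- function(pos, dir) data.frame(
    chrom = "chr1", pos = as.integer(pos), beta_a = 0.8, beta_b = 0.4,
    delta = ifelse(dir == "hyper", 0.4, -0.4), p_value = 0.001,
    direction = dir, stringsAsFactors = FALSE)
  # three DMCs spanning exactly the window
  cat1 <- assemble_dmrs(mk(c(100, 200, 300), "hyper"), dmr_params(), "T")
  expect_identical(nrow(cat1), 1L)
  expect_identical(c(cat1$start, cat1$end), c(100L, 301L))
  expect_identical(cat1$dmc_count, 3L)
  # two DMCs only: below min_dmcs
  expect_identical(nrow(assemble_dmrs(mk(c(100, 200), "hyper"), dmr_params(), "T")), 0L)
  # chain-merging triples into one region
  cat2 <- assemble_dmrs(mk(c(100, 200, 350, 500, 650), "hyper"), dmr_params(), "T")
  expect_identical(nrow(cat2), 1L)
  expect_identical(c(cat2$start, cat2$end), c(100L, 651L))
  expect_identical(cat2$dmc_count, 5L)
  # hyper and hypo runs are independent and may overlap
  mixed <- rbind(mk(c(100, 200, 300), "hyper"), mk(c(150, 250, 290), "hypo"))
  mixed <- mixed[order(mixed$pos), ]
  cat3 <- assemble_dmrs(mixed, dmr_params(), "T")
  expect_identical(nrow(cat3), 2L)
  expect_setequal(cat3$direction, c("hyper", "hypo"))
  # span just over the window does not seed
  expect_identical(nrow(assemble_dmrs(mk(c(100, 200, 401), "hyper"),
                                      dmr_params(), "T")), 0L)
  # unsorted input is rejected
  expect_error(assemble_dmrs(mk(c(300, 100, 200), "hyper"), dmr_params(), "T"),
               "sorted")
})

test_that("assembler equals the brute-force window-enumeration oracle", {
  set.seed(101)
  for (i in 1:150) {
    dmcs <- random_dmcs(sample(3:60, 1))
    cat <- assemble_dmrs(dmcs, dmr_params(), "T")
    for (dir in c("hyper", "hypo")) {
      sub <- dmcs[dmcs$direction == dir, , drop = FALSE]
      comps <- oracle_window_dmrs(sub$pos)
      got <- cat[cat$direction == dir, , drop = FALSE]
      expect_identical(nrow(got), length(comps))
      if (length(comps)) {
        expect_identical(got$start, vapply(comps, function(ix) sub$pos[ix[1]], integer(1)))
        expect_identical(got$end,
                         vapply(comps, function(ix) sub$pos[ix[length(ix)]] + 1L, integer(1)))
        expect_identical(got$dmc_count, lengths(comps))
      }
    }
  }
})

test_that("widening the assembly window never shrinks DMC coverage by DMRs", {
  set.seed(33)
  for (i in 1:20) {
    dmcs <- random_dmcs(40)
    covered <- sapply(c(100, 200, 300, 500), function(w) {
      cat <- assemble_dmrs(dmcs, dmr_params(window_bp = w), "T")
      sum(cat$dmc_count)
    })
    expect_true(all(diff(covered) >= 0))
  }
})
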