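make_genes <- function(gene_id, chrom, strand, tx_start, tx_end,
                       exon_starts = NULL, exon_ends = NULL,
                       cds_start = NA_integer_, cds_end = NA_integer_) {
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id, chrom = rep_len(chrom, n),
                   strand = rep_len(strand, n),
                   tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
                   cds_start = rep_len(as.integer(cds_start), n),
                   cds_end = rep_len(as.integer(cds_end), n),
                   stringsAsFactors = FALSE)
  df$exon_starts <- if (is.null(exon_starts))
    lapply(seq_len(n), function(i) df$tx_start[i]) else exon_starts
  df$exon_ends <- if (is.null(exon_ends))
    lapply(seq_len(n), function(i) df$tx_end[i]) else exon_ends
  class(df) <- c("gene_models", "data.frame")
  df
}

sizes1 <- c(chr1 = 1000000L)

# most fixtures carry no CDS; the FpUTR/TpUTR warning is tested separately
drt <- function(...) suppressWarnings(derive_region_tracks(...))

test_that("TSS windows follow the plus-strand worked example", {
  g <- make_genes("g1", "chr1", "+", 10000, 20000)
  tr <- drt(g, chrom_sizes = sizes1)
  expect_identical(c(tr$TSSup1k$start, tr$TSSup1k$end), c(9000L, 10000L))
  expect_identical(c(tr$TSSdn1k$start, tr$TSSdn1k$end), c(10000L, 11000L))
  expect_identical(c(tr$Prom1k$start, tr$Prom1k$end), c(9000L, 11000L))
  expect_identical(c(tr$`TSS-7k`$start, tr$`TSS-7k`$end), c(3000L, 10000L))
  expect_identical(c(tr$TTS1k$start, tr$TTS1k$end), c(19000L, 21000L))
  # central 60% of the span
  expect_identical(c(tr$Center30ct$start, tr$Center30ct$end), c(12000L, 18000L))
})

test_that("minus-strand tracks mirror the plus-strand ones", {
  # reflect a '+' gene about the midpoint of [0, 30000) and flip the strand:
  # every track must be the mirror image of the '+' track
  L <- 30000L
  gp <- make_genes("g", "chr1", "+", 10000, 20000,
                   list(c(10000L, 15000L)), list(c(12000L, 20000L)))
  gm <- make_genes("g", "chr1", "-", L - 20000L, L - 10000L,
                   list(L - c(20000L, 12000L)), list(L - c(15000L, 10000L)))
  trp <- drt(gp, chrom_sizes = c(chr1 = L))
  trm <- drt(gm, chrom_sizes = c(chr1 = L))
  for (nm in c("Gene", "ExtGene", "TSSup1k", "TSSdn1k", "Prom1k", "TSS-7k",
               "TTSup1k", "TTSdn1k", "TTS1k", "1stExon", "1stIntron",
               "Genf", "ExtGenf", "Exon", "Intron")) {
    p <- trp[[nm]]; m <- trm[[nm]]
    expect_identical(nrow(p), nrow(m))
    if (nrow(p)) {
      mirrored <- data.frame(start = sort(L - p$end), end = sort(L - p$start))
      expect_identical(m$start, mirrored$start)
      expect_identical(m$end, mirrored$end)
    }
  }
  # the '-' gene's TSS sits at tx_end: upstream window has larger coordinates
  expect_identical(c(trm$TSSup1k$start, trm$TSSup1k$end), c(20000L, 21000L))
})

test_that("windows clip at chromosome boundaries", {
  g <- make_genes("g1", "chr1", "+", 500, 2000)
  tr <- drt(g, chrom_sizes = c(chr1 = 2100L))
  expect_identical(c(tr$`TSS-7k`$start, tr$`TSS-7k`$end), c(0L, 500L))
  expect_identical(c(tr$TTS1k$start, tr$TTS1k$end), c(1000L, 2100L))
  # no chrom sizes -> clip warning (the CDS-less fixture also warns on UTRs)
  expect_warning(expect_warning(derive_region_tracks(g), "clipped at 0"),
                 "FpUTR")
})

test_that("containment and union invariants hold across random gene structures", {
  set.seed(9)
  contains <- function(outer, inner) {
    all(vapply(seq_len(nrow(inner)), function(i) {
      any(outer$chrom == inner$chrom[i] & outer$start <= inner$start[i] &
            outer$end >= inner$end[i])
    }, logical(1)))
  }
  for (i in 1:15) {
    strand <- sample(c("+", "-"), 1)
    tx_start <- sample(20000:40000, 1)
    tx_end <- tx_start + sample(5000:20000, 1)
    k <- sample(1:5, 1)
    pts <- sort(sample(seq(tx_start + 1, tx_end - 1), 2 * k - 2))
    bnd <- c(tx_start, pts, tx_end)
    es <- as.integer(bnd[seq(1, 2 * k, 2)]); ee <- as.integer(bnd[seq(2, 2 * k, 2)])
    g <- make_genes("g", "chr1", strand, tx_start, tx_end, list(es), list(ee))
    tr <- drt(g, chrom_sizes = c(chr1 = 100000L))
    expect_true(contains(tr$Exon, tr$`1stExon`))
    expect_true(contains(tr$Gene, tr$Exon))
    expect_true(contains(tr$ExtGene, tr$Gene))
    expect_true(contains(tr$Gene, tr$Genf))
    if (nrow(tr$`1stIntron`)) expect_true(contains(tr$Intron, tr$`1stIntron`))
    # TSSup1k and TSSdn1k tile Prom1k
    expect_identical(sort(c(tr$TSSup1k$start, tr$TSSdn1k$start))[1], tr$Prom1k$start)
    expect_identical(sum(tr$TSSup1k$end - tr$TSSup1k$start) +
                       sum(tr$TSSdn1k$end - tr$TSSdn1k$start),
                     sum(tr$Prom1k$end - tr$Prom1k$start))
  }
})

test_that("single-exon genes have Genf spanning the sole exon and no 1st intron", {
  g <- make_genes("g1", "chr1", "+", 1000, 3000)
  tr <- drt(g, chrom_sizes = sizes1)
  expect_identical(c(tr$Genf$start, tr$Genf$end), c(1000L, 3000L))
  expect_identical(nrow(tr$`1stIntron`), 0L)
  expect_identical(nrow(tr$Intron), 0L)
})

test_that("UTR tracks derive from CDS and are empty with a warning when CDS is absent", {
  g <- make_genes("g1", "chr1", "+", 1000, 9000,
                  list(c(1000L, 4000L, 8000L)), list(c(2000L, 5000L, 9000L)),
                  cds_start = 1500L, cds_end = 8500L)
  tr <- drt(g, chrom_sizes = sizes1)
  expect_identical(c(tr$FpUTR$start, tr$FpUTR$end), c(1000L, 1500L))
  expect_identical(c(tr$TpUTR$start, tr$TpUTR$end), c(8500L, 9000L))
  g2 <- make_genes("g1", "chr1", "+", 1000, 9000)
  expect_warning(derive_region_tracks(g2, chrom_sizes = sizes1), "FpUTR/TpUTR")
})

test_that("hotspot report counts multi-membership and matches an all-pairs scan", {
  g <- make_genes("g1", "chr1", "+", 10000, 20000)
  reps <- structure(data.frame(chrom = "chr1", start = 11000L, end = 11200L,
                               name = "SINE", stringsAsFactors = FALSE),
                    class = c("region_track", "data.frame"))
  tr <- drt(g, repeats = reps, chrom_sizes = sizes1)
  cat1 <- make_catalog("chr1", 11050, 11100, "hyper", "A8:A2")
  hs <- hotspot_report(cat1, tr)
  get <- function(region, dir = "hyper")
    hs[hs$region == region & hs$direction == dir, ]
  expect_identical(get("Gene")$count, 1L)
  expect_identical(get("rmsk")$count, 1L)
  expect_identical(get("SINE")$count, 1L)
  expect_identical(get("Prom1k")$count, 0L)
  # percent arithmetic: 1 of 4 hypo DMRs on a track
  cat2 <- make_catalog("chr1", c(11000, 50000, 60000, 70000),
                       c(11100, 50100, 60100, 70100), "hypo", "A8:A2")
  hs2 <- hotspot_report(cat2, tr)
  expect_equal(hs2[hs2$region == "SINE" & hs2$direction == "hypo", "percent"], 25)
  # brute-force overlap scan agrees on a random catalog
  set.seed(14)
  s <- sample.int(40000, 30)
  rnd <- make_catalog("chr1", s, s + sample(50:500, 30, replace = TRUE),
                      sample(c("hyper", "hypo"), 30, replace = TRUE), "A8:A2")
  hs3 <- hotspot_report(rnd, tr)
  for (nm in names(tr)) {
    for (dir in c("hyper", "hypo")) {
      sub <- rnd[rnd$direction == dir, ]
      manual <- sum(vapply(seq_len(nrow(sub)), function(i) {
        any(tr[[nm]]$chrom == sub$chrom[i] &
              pmin(tr[[nm]]$end, sub$end[i]) - pmax(tr[[nm]]$start, sub$start[i]) >= 1)
      }, logical(1)))
      expect_identical(hs3[hs3$region == nm & hs3$direction == dir, "count"], manual)
    }
  }
  # hotspot counts are invariant to splitting a track interval in two
  tr_split <- tr
  tr_split$SINE <- data.frame(chrom = c("chr1", "chr1"),
                              start = c(11000L, 11100L), end = c(11100L, 11200L))
  hs4 <- hotspot_report(rnd, tr_split)
  expect_identical(hs4[hs4$region == "SINE", "count"], hs3[hs3$region == "SINE", "count"])
})

test_that("promoter and gene-body mapping follow the strand-aware window rule", {
  g <- make_genes(c("gp", "gm"), "chr1", c("+", "-"),
                  c(10000, 50000), c(30000, 60000))
  # '+' promoter = [3000, 13000); '-' TSS at 60000, promoter = [57000, 67000)
  hit <- map_dmrs_to_genes(make_catalog("chr1", 2990, 3100, "hypo", "R1:R0"), g)
  expect_identical(hit$gene_id, "gp")
  expect_identical(hit$zone, "promoter")
  miss <- map_dmrs_to_genes(make_catalog("chr1", 2900, 3000, "hypo", "R1:R0"), g)
  expect_identical(nrow(miss), 0L)
  both <- map_dmrs_to_genes(make_catalog("chr1", 12000, 12100, "hyper", "R1:R0"), g)
  expect_setequal(both$zone, c("promoter", "gBody"))
  minus_up <- map_dmrs_to_genes(make_catalog("chr1", 66900, 67100, "hypo", "R1:R0"), g)
  expect_identical(nrow(minus_up), 1L)
  expect_identical(minus_up$gene_id, "gm")
  minus_out <- map_dmrs_to_genes(make_catalog("chr1", 67000, 67100, "hypo", "R1:R0"), g)
  expect_identical(nrow(minus_out), 0L)
  # intronic DMR: gBody only
  g2 <- make_genes("g1", "chr1", "+", 100000, 160000,
                   list(c(100000L, 150000L)), list(c(110000L, 160000L)))
  intronic <- map_dmrs_to_genes(make_catalog("chr1", 120000, 120200, "hyper", "R1:R0"), g2)
  expect_identical(intronic$zone, "gBody")
})
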