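# All genomic coordinates are held 0-based half-open in memory. CpG input
# positions are 1-based (bedGraph / CX-report style) and converted on read;
# report writers restore 1-based inclusive coordinates.

.read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a per-CpG methylation count table
#'
#' Reads a five-column TSV (chrom, 1-based position of the CpG cytosine,
#' strand, methylated read count, total read count) for one biological
#' sample. Records on the minus strand are taken to report the paired
#' cytosine of the same CpG dyad and are merged into the plus-strand record
#' at position - 1 by summing counts, so that each CpG dyad yields a single
#' record. Positions are converted to 0-based.
#'
#' @param path Path to a tab-separated file. Lines starting with `#` are
#'   skipped. No quoting is honoured.
#' @param sample_id Identifier stored with the table.
#' @param merge_strands Merge `-`-strand records into the paired `+`-strand
#'   cytosine (default `TRUE`).
#' @return A `cpg_counts` data frame with columns `chrom`, `pos` (0-based),
#'   `meth`, `total`, sorted by (chrom, pos), with attribute `sample_id`.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t1000\t+\t5\t10", "chr1\t2000\t+\t2\t8"), f)
#' read_cpg_table(f, "s1")
#' @export
read_cpg_table <- function(path, sample_id, merge_strands = TRUE) {
  tl <- .read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer())
    return(new_cpg_counts(out, sample_id))
  }
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5L)) {
    bad <- which(nf != 5L)[1L]
    .stopf("%s: line %d: expected 5 tab-separated fields, found %d",
           path, tl$lineno[bad], nf[bad])
  }
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  chrom <- m[, 1L]
  pos1 <- suppressWarnings(as.integer(m[, 2L]))
  strand <- m[, 3L]
  meth <- suppressWarnings(as.integer(m[, 4L]))
  total <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(pos1) | is.na(meth) | is.na(total))
  if (length(bad)) {
    .stopf("%s: line %d: non-integer position or count field",
           path, tl$lineno[bad[1L]])
  }
  if (any(pos1 < 1L)) {
    .stopf("%s: line %d: position must be >= 1",
           path, tl$lineno[which(pos1 < 1L)[1L]])
  }
  if (!all(strand %in% c("+", "-", "."))) {
    .stopf("%s: line %d: strand must be one of '+', '-', '.'",
           path, tl$lineno[which(!strand %in% c("+", "-", "."))[1L]])
  }
  if (any(meth < 0L) || any(total < 0L)) {
    .stopf("%s: line %d: negative count",
           path, tl$lineno[which(meth < 0L | total < 0L)[1L]])
  }
  if (any(meth > total)) {
    .stopf("%s: line %d: methylated count exceeds total coverage",
           path, tl$lineno[which(meth > total)[1L]])
  }
  key <- paste(chrom, pos1, strand)
  if (anyDuplicated(key)) {
    .stopf("%s: line %d: duplicate (chrom, pos, strand) record",
           path, tl$lineno[which(duplicated(key))[1L]])
  }
  if (merge_strands) {
    minus <- strand == "-"
    if (any(pos1[minus] < 2L)) .stopf("%s: minus-strand record at position 1 has no paired cytosine", path)
    pos1[minus] <- pos1[minus] - 1L
    df <- data.frame(chrom = chrom, pos = pos1, meth = meth, total = total,
                     stringsAsFactors = FALSE)
    agg <- stats::aggregate(cbind(meth, total) ~ chrom + pos, data = df, FUN = sum)
  } else {
    agg <- data.frame(chrom = chrom, pos = pos1, meth = meth, total = total,
                      stringsAsFactors = FALSE)
    if (anyDuplicated(paste(agg$chrom, agg$pos)))
      .stopf("%s: duplicate (chrom, pos) record", path)
  }
  agg$pos <- as.integer(agg$pos - 1L)  # to 0-based
  agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  new_cpg_counts(agg[, c("chrom", "pos", "meth", "total")], sample_id)
}

#' @keywords internal
new_cpg_counts <- function(df, sample_id) {
  stopifnot(all(c("chrom", "pos", "meth", "total") %in% names(df)))
  attr(df, "sample_id") <- sample_id
  class(df) <- c("cpg_counts", "data.frame")
  df
}

#' Write a per-CpG methylation count table
#'
#' Inverse of [read_cpg_table()]: writes 1-based positions with strand `+`.
#'
#' @param x A `cpg_counts` data frame (0-based positions).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cpg_table <- function(x, path) {
  out <- sprintf("%s\t%d\t+\t%d\t%d", x$chrom, x$pos + 1L, x$meth, x$total)
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a refFlat-like TSV
#'
#' Columns: gene_id, chrom, strand, txStart, txEnd, exonStarts, exonEnds,
#' and optionally cdsStart, cdsEnd. Coordinates are 0-based half-open as in
#' UCSC refFlat; exon coordinate fields are comma-separated parallel lists.
#'
#' @param path Path to the TSV file. `#` comment lines are skipped.
#' @return A `gene_models` data frame with columns `gene_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, list-columns `exon_starts` and
#'   `exon_ends`, and `cds_start`/`cds_end` (`NA` when absent).
#' @export
read_gene_models <- function(path) {
  tl <- .read_tsv_lines(path)
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (length(parts) && !all(nf %in% c(7L, 9L))) {
    bad <- which(!nf %in% c(7L, 9L))[1L]
    .stopf("%s: line %d: expected 7 or 9 fields, found %d",
           path, tl$lineno[bad], nf[bad])
  }
  n <- length(parts)
  split_coords <- function(s) as.integer(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1L]])
  gene_id <- character(n); chrom <- character(n); strand <- character(n)
  tx_start <- integer(n); tx_end <- integer(n)
  exon_starts <- vector("list", n); exon_ends <- vector("list", n)
  cds_start <- rep(NA_integer_, n); cds_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    f <- parts[[i]]
    gene_id[i] <- f[1L]; chrom[i] <- f[2L]; strand[i] <- f[3L]
    if (!strand[i] %in% c("+", "-"))
      .stopf("%s: line %d: strand must be '+' or '-'", path, tl$lineno[i])
    tx_start[i] <- as.integer(f[4L]); tx_end[i] <- as.integer(f[5L])
    if (is.na(tx_start[i]) || is.na(tx_end[i]) || tx_start[i] >= tx_end[i])
      .stopf("%s: line %d: invalid transcript interval", path, tl$lineno[i])
    es <- split_coords(f[6L]); ee <- split_coords(f[7L])
    if (length(es) != length(ee))
      .stopf("%s: line %d: exonStarts and exonEnds lengths differ", path, tl$lineno[i])
    if (length(es) == 0L || anyNA(es) || anyNA(ee))
      .stopf("%s: line %d: malformed exon coordinate list", path, tl$lineno[i])
    if (any(es >= ee))
      .stopf("%s: line %d: exon start not before exon end", path, tl$lineno[i])
    if (is.unsorted(es, strictly = TRUE) || any(es[-1L] < ee[-length(ee)]))
      .stopf("%s: line %d: exons must be sorted and non-overlapping", path, tl$lineno[i])
    if (es[1L] < tx_start[i] || ee[length(ee)] > tx_end[i])
      .stopf("%s: line %d: exon outside transcript bounds", path, tl$lineno[i])
    exon_starts[[i]] <- es; exon_ends[[i]] <- ee
    if (length(f) == 9L) {
      cds_start[i] <- as.integer(f[8L]); cds_end[i] <- as.integer(f[9L])
    }
  }
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tx_start = tx_start, tx_end = tx_end,
                   cds_start = cds_start, cds_end = cds_end,
                   stringsAsFactors = FALSE)
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models to the refFlat-like TSV dialect
#' @param genes A `gene_models` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    base <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s",
                    genes$gene_id[i], genes$chrom[i], genes$strand[i],
                    genes$tx_start[i], genes$tx_end[i],
                    paste(genes$exon_starts[[i]], collapse = ","),
                    paste(genes$exon_ends[[i]], collapse = ","))
    if (!is.na(genes$cds_start[i]))
      base <- sprintf("%s\t%d\t%d", base, genes$cds_start[i], genes$cds_end[i])
    base
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED region track
#'
#' BED3 or BED4; with four columns the name column carries the region class
#' (e.g. a repeat family such as SINE/LINE/LTR/Simple_repeat).
#'
#' @param path Path to the BED file.
#' @param name Track name used when the file has no name column.
#' @return A `region_track` data frame with columns `chrom`, `start`, `end`,
#'   `name`, sorted by (chrom, start).
#' @export
read_region_track <- function(path, name = NA_character_) {
  tl <- .read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     name = character())
    class(df) <- c("region_track", "data.frame")
    return(df)
  }
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    .stopf("%s: line %d: expected at least 3 BED fields",
           path, tl$lineno[which(nf < 3L)[1L]])
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- as.integer(vapply(parts, `[[`, character(1), 2L))
  end <- as.integer(vapply(parts, `[[`, character(1), 3L))
  if (anyNA(start) || anyNA(end) || any(start >= end))
    .stopf("%s: invalid interval (requires start < end)", path)
  nm <- ifelse(nf >= 4L,
               vapply(parts, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, character(1)),
               name)
  df <- data.frame(chrom = chrom, start = start, end = end, name = nm,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_track", "data.frame")
  df
}

#' Read a DEG table
#'
#' Header line required: `gene_id`, `log2fc`, `p_raw`, optionally `q`.
#' `log2fc > 0` means higher expression in the later/treated condition.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `gene_id`, `log2fc`, `p_raw`, `q`
#'   (`q` is `NA` when the column is absent).
#' @export
read_deg_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "log2fc", "p_raw")
  if (!all(need %in% names(df)))
    .stopf("%s: DEG table must have columns gene_id, log2fc, p_raw", path)
  if (anyDuplicated(df$gene_id))
    .stopf("%s: duplicate gene_id in DEG table", path)
  if (anyNA(df$p_raw) || any(df$p_raw < 0 | df$p_raw > 1))
    .stopf("%s: p_raw must be present and within [0, 1]", path)
  if (!"q" %in% names(df)) df$q <- NA_real_
  if (any(!is.na(df$q) & (df$q < 0 | df$q > 1)))
    .stopf("%s: q must lie within [0, 1]", path)
  df[, c("gene_id", "log2fc", "p_raw", "q")]
}

#' Write a DEG table
#' @param degs Data frame with `gene_id`, `log2fc`, `p_raw` and optional `q`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(degs, path) {
  cols <- c("gene_id", "log2fc", "p_raw")
  if ("q" %in% names(degs) && !all(is.na(degs$q))) cols <- c(cols, "q")
  utils::write.table(degs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a DMR catalog
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `direction` (`hyper`/`hypo`), `dmc_count`, `mean_delta`,
#'   `min_p`.
#' @param contrast Contrast label, e.g. `"A8:A2"` or `"R2:R0"`.
#' @return A `dmr_catalog` data frame sorted by (chrom, start) with a
#'   `dmr_id` column and `contrast` attribute.
#' @export
new_dmr_catalog <- function(df, contrast) {
  need <- c("chrom", "start", "end", "direction", "dmc_count", "mean_delta", "min_p")
  stopifnot(all(need %in% names(df)))
  if (nrow(df)) {
    stopifnot(all(df$direction %in% c("hyper", "hypo")),
              all(df$end - df$start >= 1L))
  }
  df <- df[order(df$chrom, df$start, df$end), need, drop = FALSE]
  rownames(df) <- NULL
  df$dmr_id <- if (nrow(df)) {
    sprintf("%s|%s:%d-%d|%s", contrast, df$chrom, df$start + 1L, df$end, df$direction)
  } else character(0)
  attr(df, "contrast") <- contrast
  class(df) <- c("dmr_catalog", "data.frame")
  df
}

#' Write a DMR catalog as BED6+3
#'
#' Columns: chrom, start (0-based), end (half-open), name (contrast label),
#' score (number of member DMCs), strand (`.`), direction, mean delta, min p.
#'
#' @param catalog A `dmr_catalog`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dmr_bed <- function(catalog, path) {
  contrast <- attr(catalog, "contrast")
  if (nrow(catalog) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t%s\t%s",
                   catalog$chrom, catalog$start, catalog$end, contrast,
                   catalog$dmc_count, catalog$direction,
                   format(catalog$mean_delta, digits = 15, scientific = FALSE, trim = TRUE),
                   format(catalog$min_p, digits = 15, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a DMR catalog written by [write_dmr_bed()]
#'
#' @param path Path to the BED6+3 file.
#' @param contrast Contrast label; when `NULL`, taken from the name column.
#' @return A `dmr_catalog`.
#' @export
read_dmr_bed <- function(path, contrast = NULL) {
  tl <- .read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                        direction = character(), dmc_count = integer(),
                        mean_delta = numeric(), min_p = numeric())
    return(new_dmr_catalog(empty, contrast %||% NA_character_))
  }
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L))
    .stopf("%s: expected 9 BED6+3 fields per row", path)
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  if (is.null(contrast)) contrast <- m[1L, 4L]
  df <- data.frame(chrom = m[, 1L],
                   start = as.integer(m[, 2L]),
                   end = as.integer(m[, 3L]),
                   direction = m[, 7L],
                   dmc_count = as.integer(m[, 5L]),
                   mean_delta = as.numeric(m[, 8L]),
                   min_p = as.numeric(m[, 9L]),
                   stringsAsFactors = FALSE)
  new_dmr_catalog(df, contrast)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
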