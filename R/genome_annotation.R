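# Hotspot region vocabulary, genomic distributions, and DMR-to-gene mapping.

#' Parameters for DMR-to-gene mapping
#'
#' The promoter window spans `promoter_upstream_bp` upstream to
#' `promoter_downstream_bp` downstream of the TSS, strand-aware (defaults
#' -7 kb / +3 kb).
#'
#' @param promoter_upstream_bp Upstream extent in bp, default 7000.
#' @param promoter_downstream_bp Downstream extent in bp, default 3000.
#' @return A `gene_map_params` list.
#' @export
gene_map_params <- function(promoter_upstream_bp = 7000L,
                            promoter_downstream_bp = 3000L) {
  stopifnot(promoter_upstream_bp >= 0, promoter_downstream_bp >= 0)
  structure(list(promoter_upstream_bp = as.integer(promoter_upstream_bp),
                 promoter_downstream_bp = as.integer(promoter_downstream_bp)),
            class = "gene_map_params")
}

.clip_intervals <- function(df, chrom_sizes) {
  if (!nrow(df)) return(df)
  if (is.null(chrom_sizes)) {
    df$start <- pmax(df$start, 0L)
    return(df[df$start < df$end, , drop = FALSE])
  }
  lim <- chrom_sizes[df$chrom]
  df$start <- pmax(df$start, 0L)
  df$end <- pmin(df$end, ifelse(is.na(lim), df$end, lim))
  df[df$start < df$end, , drop = FALSE]
}

.iv <- function(chrom, start, end) {
  keep <- !is.na(start) & !is.na(end) & start < end
  data.frame(chrom = chrom[keep], start = as.integer(start[keep]),
             end = as.integer(end[keep]), stringsAsFactors = FALSE)
}

#' Derive the hotspot region vocabulary from gene models
#'
#' Produces the named interval tracks used for hotspot analysis. All
#' "upstream"/"downstream"/"1st" notions are strand-aware: for a `-` gene
#' the TSS sits at `tx_end`, upstream means larger coordinates and the 1st
#' exon is the rightmost one.
#'
#' Gene-structure tracks: `Gene` (transcript span), `ExtGene` (span plus/minus 1 kb),
#' `Genf` (start of the 1st exon to the start of the 2nd exon; the sole
#' exon for single-exon genes), `ExtGenf`, `1stExon`, `1stIntron`, `Exon`,
#' `Intron`, `FpUTR`, `TpUTR` (exonic UTRs, empty with a warning when CDS
#' coordinates are absent), `Prom1k`, `TSSup1k`, `TSSdn1k`, `TTS1k`,
#' `TTSup1k`, `TTSdn1k`, `Center30ct` (the central 60\% of the transcript
#' span, boundaries rounded toward the centre), `TSS-7k` (7 kb upstream of
#' the TSS). Repeat tracks are passed through as `rmsk` (union of all
#' repeat intervals) plus one track per repeat class present, and `cgi`.
#'
#' @param genes A `gene_models` data frame (see [read_gene_models()]).
#' @param repeats Optional `region_track` whose `name` column carries the
#'   repeat class (SINE, LINE, LTR, Simple_repeat, ...).
#' @param cgi Optional `region_track` of CpG islands.
#' @param chrom_sizes Optional named integer vector of chromosome lengths;
#'   windows are clipped to `[0, length)` when provided, else clipped at 0
#'   only, with a warning.
#' @return Named list of interval data frames (`chrom`, `start`, `end`).
#' @export
derive_region_tracks <- function(genes, repeats = NULL, cgi = NULL,
                                 chrom_sizes = NULL) {
  if (is.null(chrom_sizes))
    warning("derive_region_tracks: no chromosome sizes supplied; windows are clipped at 0 only")
  n <- nrow(genes)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$tx_start, genes$tx_end)
  tts <- ifelse(plus, genes$tx_end, genes$tx_start)
  ch <- genes$chrom
  tracks <- list()
  tracks[["Gene"]] <- .iv(ch, genes$tx_start, genes$tx_end)
  tracks[["ExtGene"]] <- .iv(ch, genes$tx_start - 1000L, genes$tx_end + 1000L)
  tracks[["TSSup1k"]] <- .iv(ch, ifelse(plus, tss - 1000L, tss),
                             ifelse(plus, tss, tss + 1000L))
  tracks[["TSSdn1k"]] <- .iv(ch, ifelse(plus, tss, tss - 1000L),
                             ifelse(plus, tss + 1000L, tss))
  tracks[["Prom1k"]] <- .iv(ch, tss - 1000L, tss + 1000L)
  tracks[["TTSup1k"]] <- .iv(ch, ifelse(plus, tts - 1000L, tts),
                             ifelse(plus, tts, tts + 1000L))
  tracks[["TTSdn1k"]] <- .iv(ch, ifelse(plus, tts, tts - 1000L),
                             ifelse(plus, tts + 1000L, tts))
  tracks[["TTS1k"]] <- .iv(ch, tts - 1000L, tts + 1000L)
  tracks[["TSS-7k"]] <- .iv(ch, ifelse(plus, tss - 7000L, tss),
                            ifelse(plus, tss, tss + 7000L))
  ctr <- (genes$tx_start + genes$tx_end) / 2
  half <- 0.3 * (genes$tx_end - genes$tx_start)
  tracks[["Center30ct"]] <- .iv(ch, as.integer(ceiling(ctr - half)),
                                as.integer(floor(ctr + half)))
  # exon-derived tracks
  ex_rows <- list(); in_rows <- list(); fe_rows <- list(); fi_rows <- list()
  gf_rows <- list(); fputr <- list(); tputr <- list()
  for (i in seq_len(n)) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    k <- length(es)
    ex_rows[[i]] <- .iv(rep(ch[i], k), es, ee)
    if (k > 1L) {
      in_rows[[i]] <- .iv(rep(ch[i], k - 1L), ee[-k], es[-1L])
      if (plus[i]) {
        fe_rows[[i]] <- .iv(ch[i], es[1L], ee[1L])
        fi_rows[[i]] <- .iv(ch[i], ee[1L], es[2L])
        gf_rows[[i]] <- .iv(ch[i], es[1L], es[2L])
      } else {
        fe_rows[[i]] <- .iv(ch[i], es[k], ee[k])
        fi_rows[[i]] <- .iv(ch[i], ee[k - 1L], es[k])
        gf_rows[[i]] <- .iv(ch[i], ee[k - 1L], ee[k])
      }
    } else {
      fe_rows[[i]] <- .iv(ch[i], es[1L], ee[1L])
      gf_rows[[i]] <- .iv(ch[i], es[1L], ee[1L])
    }
    if (!is.na(genes$cds_start[i])) {
      cs <- genes$cds_start[i]; ce <- genes$cds_end[i]
      # exonic UTR pieces on the TSS (Fp) and TTS (Tp) side
      five_lo <- if (plus[i]) genes$tx_start[i] else ce
      five_hi <- if (plus[i]) cs else genes$tx_end[i]
      three_lo <- if (plus[i]) ce else genes$tx_start[i]
      three_hi <- if (plus[i]) genes$tx_end[i] else cs
      fputr[[i]] <- .iv(rep(ch[i], k), pmax(es, five_lo), pmin(ee, five_hi))
      tputr[[i]] <- .iv(rep(ch[i], k), pmax(es, three_lo), pmin(ee, three_hi))
    }
  }
  bind <- function(lst) {
    lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
    if (!length(lst)) return(.iv(character(0), integer(0), integer(0)))
    do.call(rbind, lst)
  }
  tracks[["Exon"]] <- bind(ex_rows)
  tracks[["Intron"]] <- bind(in_rows)
  tracks[["1stExon"]] <- bind(fe_rows)
  tracks[["1stIntron"]] <- bind(fi_rows)
  tracks[["Genf"]] <- bind(gf_rows)
  gf <- tracks[["Genf"]]
  tracks[["ExtGenf"]] <- .iv(gf$chrom, gf$start - 1000L, gf$end + 1000L)
  if (all(is.na(genes$cds_start))) {
    warning("derive_region_tracks: no CDS coordinates; FpUTR/TpUTR tracks are empty")
    tracks[["FpUTR"]] <- .iv(character(0), integer(0), integer(0))
    tracks[["TpUTR"]] <- .iv(character(0), integer(0), integer(0))
  } else {
    tracks[["FpUTR"]] <- bind(fputr)
    tracks[["TpUTR"]] <- bind(tputr)
  }
  if (!is.null(repeats) && nrow(repeats)) {
    tracks[["rmsk"]] <- .iv(repeats$chrom, repeats$start, repeats$end)
    for (cls in unique(repeats$name[!is.na(repeats$name)])) {
      sel <- repeats[!is.na(repeats$name) & repeats$name == cls, , drop = FALSE]
      tracks[[cls]] <- .iv(sel$chrom, sel$start, sel$end)
    }
  }
  if (!is.null(cgi) && nrow(cgi))
    tracks[["cgi"]] <- .iv(cgi$chrom, cgi$start, cgi$end)
  lapply(tracks, function(tr) {
    tr <- .clip_intervals(tr, chrom_sizes)
    tr <- tr[order(tr$chrom, tr$start, tr$end), , drop = FALSE]
    rownames(tr) <- NULL
    tr
  })
}

#' Hotspot report: DMR counts and percentages per genomic region class
#'
#' A DMR counts toward a region class if it overlaps any interval of that
#' track by at least `min_overlap_bp`; classes are not mutually exclusive,
#' so percentages need not sum to 100.
#'
#' @param catalog A `dmr_catalog`.
#' @param tracks Named list of interval tracks from
#'   [derive_region_tracks()].
#' @param params A [compare_params()] object.
#' @return Data frame: `direction`, `region`, `count`, `percent` (of that
#'   direction's total DMRs in the catalog; 0 when the catalog is empty).
#' @export
hotspot_report <- function(catalog, tracks, params = compare_params()) {
  out <- list()
  for (dir in c("hyper", "hypo")) {
    sub <- catalog[catalog$direction == dir, , drop = FALSE]
    total <- nrow(sub)
    for (nm in names(tracks)) {
      hits <- .overlap_hits(sub, tracks[[nm]], params)
      cnt <- length(unique(hits$q))
      out[[length(out) + 1L]] <- data.frame(
        direction = dir, region = nm, count = cnt,
        percent = if (total > 0) 100 * cnt / total else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Map DMRs to genes via promoter and gene-body windows
#'
#' The promoter window of a `+` gene is `[TSS - upstream, TSS + downstream)`
#' and of a `-` gene `[TSS - downstream, TSS + upstream)` with the TSS at
#' `tx_end`; the gene body is `[tx_start, tx_end)`. One row is emitted per
#' (gene, DMR, zone) pair with at least `min_overlap_bp` shared base pairs,
#' so a pair may appear with both zones. Multi-isoform rows are treated
#' independently; deduplicate by `gene_id` for gene-level counts.
#'
#' @param catalog A `dmr_catalog`.
#' @param genes A `gene_models` data frame.
#' @param map_params A [gene_map_params()] object.
#' @param params A [compare_params()] object.
#' @return A `gene_dmr_map` data frame: `gene_id`, `dmr_id`, `zone`
#'   (`promoter`/`gBody`), `direction`, `contrast`.
#' @export
map_dmrs_to_genes <- function(catalog, genes, map_params = gene_map_params(),
                              params = compare_params()) {
  contrast <- attr(catalog, "contrast") %||% NA_character_
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$tx_start, genes$tx_end)
  up <- map_params$promoter_upstream_bp
  dn <- map_params$promoter_downstream_bp
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(ifelse(plus, tss - up, tss - dn), 0L),
                     end = ifelse(plus, tss + dn, tss + up),
                     stringsAsFactors = FALSE)
  body <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                     end = genes$tx_end, stringsAsFactors = FALSE)
  zone_rows <- function(windows, zone) {
    keep <- windows$start < windows$end
    idx <- which(keep)
    h <- .overlap_hits(catalog, windows[keep, , drop = FALSE], params)
    if (!nrow(h)) return(NULL)
    data.frame(gene_id = genes$gene_id[idx[h$s]],
               dmr_id = catalog$dmr_id[h$q],
               zone = zone,
               direction = catalog$direction[h$q],
               contrast = contrast,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(zone_rows(prom, "promoter"), zone_rows(body, "gBody"))
  if (is.null(rows))
    rows <- data.frame(gene_id = character(), dmr_id = character(),
                       zone = character(), direction = character(),
                       contrast = character(), stringsAsFactors = FALSE)
  rows <- unique(rows)
  rows <- rows[order(rows$gene_id, rows$dmr_id, rows$zone), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("gene_dmr_map", "data.frame")
  rows
}
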