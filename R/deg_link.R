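# DEG filtering and direction-matched DMR-to-DEG linkage.

#' Parameters for DEG classification
#'
#' Thresholds are inclusive: a gene is differential when its corrected p
#' (q) is <= `q_threshold` and its absolute fold change is >= `min_abs_fc`.
#'
#' @param q_threshold Corrected-p cutoff, default 0.05.
#' @param min_abs_fc Minimum absolute (linear) fold change, default 2.
#' @param adjust_if_missing `"bh"` (Benjamini-Hochberg over all raw p in
#'   the table when the q column is absent) or `"none"`.
#' @return A `deg_params` list.
#' @export
deg_params <- function(q_threshold = 0.05, min_abs_fc = 2,
                       adjust_if_missing = c("bh", "none")) {
  adjust_if_missing <- match.arg(adjust_if_missing)
  stopifnot(q_threshold > 0, q_threshold < 1, min_abs_fc >= 1)
  structure(list(q_threshold = q_threshold, min_abs_fc = min_abs_fc,
                 adjust_if_missing = adjust_if_missing),
            class = "deg_params")
}

#' Classify genes as up-, down-regulated or not significant
#'
#' When a gene already carries a q value it is used as-is (no
#' re-adjustment); when the q column is entirely absent and
#' `adjust_if_missing = "bh"`, Benjamini-Hochberg q values are computed
#' over all raw p values in the table. Rows with non-finite fold changes
#' are dropped with a warning. `log2fc > 0` means higher expression in the
#' later/treated condition.
#'
#' @param table DEG data frame (`gene_id`, `log2fc`, `p_raw`, optional
#'   `q`), see [read_deg_table()].
#' @param params A [deg_params()] object.
#' @return The table with a `q` column filled in and a `direction` column
#'   (`up`, `down`, `ns`).
#' @export
filter_degs <- function(table, params = deg_params()) {
  bad <- !is.finite(table$log2fc)
  if (any(bad)) {
    warning(sprintf("filter_degs: dropping %d rows with non-finite log2fc", sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  if (!"q" %in% names(table) || all(is.na(table$q))) {
    table$q <- if (params$adjust_if_missing == "bh")
      stats::p.adjust(table$p_raw, method = "BH") else table$p_raw
  }
  sig <- table$q <= params$q_threshold
  fc_up <- 2^table$log2fc >= params$min_abs_fc
  fc_dn <- 2^(-table$log2fc) >= params$min_abs_fc
  table$direction <- ifelse(sig & fc_up, "up",
                            ifelse(sig & fc_dn, "down", "ns"))
  rownames(table) <- NULL
  table
}

#' Link DMRs to DEGs with direction matching
#'
#' Retains only the coherent (hypo-DMR, up-DEG) and (hyper-DMR, down-DEG)
#' pairs among the gene/DMR rows of a [map_dmrs_to_genes()] result, in the
#' requested zones.
#'
#' @param genemap A `gene_dmr_map`.
#' @param degs A classified DEG table from [filter_degs()].
#' @param zone_filter `"promoter"` (default) or `"promoter+gBody"`.
#' @return A `linked_genes` data frame: `gene_id`, `deg_direction`,
#'   `dmr_id`, `dmr_direction`, `contrast`, `zone`, with attributes
#'   `n_dmrs` (distinct linked DMRs) and `n_genes` (distinct linked genes).
#' @export
link_dmrs_to_degs <- function(genemap, degs,
                              zone_filter = c("promoter", "promoter+gBody")) {
  zone_filter <- match.arg(zone_filter)
  zones <- if (zone_filter == "promoter") "promoter" else c("promoter", "gBody")
  gm <- genemap[genemap$zone %in% zones, , drop = FALSE]
  idx <- match(gm$gene_id, degs$gene_id)
  keep <- !is.na(idx)
  gm <- gm[keep, , drop = FALSE]
  deg_dir <- degs$direction[idx[keep]]
  matched <- (gm$direction == "hypo" & deg_dir == "up") |
             (gm$direction == "hyper" & deg_dir == "down")
  out <- data.frame(gene_id = gm$gene_id[matched],
                    deg_direction = deg_dir[matched],
                    dmr_id = gm$dmr_id[matched],
                    dmr_direction = gm$direction[matched],
                    contrast = gm$contrast[matched],
                    zone = gm$zone[matched],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$gene_id, out$dmr_id, out$zone), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dmrs") <- length(unique(out$dmr_id))
  attr(out, "n_genes") <- length(unique(out$gene_id))
  class(out) <- c("linked_genes", "data.frame")
  out
}

#' Find flip genes: early-synchronous, late-inverse promoter methylation
#'
#' A flip gene is a differentially expressed gene whose promoter carries an
#' early-aging DMR synchronous with its expression direction and a
#' mid-to-late-aging DMR inverse to it: an up-DEG with at least one early
#' hypo-DMR and one late hyper-DMR, or a down-DEG with at least one early
#' hyper-DMR and one late hypo-DMR.
#'
#' @param early_map `gene_dmr_map` for the early aging contrast (A8:A2),
#'   promoter rows are used.
#' @param late_map `gene_dmr_map` for the late aging contrast (A16:A8).
#' @param degs Classified DEG table from [filter_degs()].
#' @return Data frame: `gene_id`, `deg_direction`, `early_dmr_ids`,
#'   `late_dmr_ids` (comma-separated).
#' @export
find_flip_genes <- function(early_map, late_map, degs) {
  em <- early_map[early_map$zone == "promoter", , drop = FALSE]
  lm <- late_map[late_map$zone == "promoter", , drop = FALSE]
  degs <- degs[degs$direction %in% c("up", "down"), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(degs))) {
    g <- degs$gene_id[i]
    want_early <- if (degs$direction[i] == "up") "hypo" else "hyper"
    want_late <- if (degs$direction[i] == "up") "hyper" else "hypo"
    e_ids <- em$dmr_id[em$gene_id == g & em$direction == want_early]
    l_ids <- lm$dmr_id[lm$gene_id == g & lm$direction == want_late]
    if (length(e_ids) && length(l_ids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, deg_direction = degs$direction[i],
        early_dmr_ids = paste(sort(e_ids), collapse = ","),
        late_dmr_ids = paste(sort(l_ids), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), deg_direction = character(),
               early_dmr_ids = character(), late_dmr_ids = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
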