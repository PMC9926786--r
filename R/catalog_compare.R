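# Cross-contrast DMR classification: overlap detection, temporal categories,
# synchronous/inverse cross records, and three-set Venn accounting.

#' Parameters for catalog comparison
#'
#' @param min_overlap_bp Minimum shared base pairs for two DMRs to count as
#'   overlapping; default 1 (shared regions are "defined by at least one
#'   overlapping bp").
#' @return A `compare_params` list.
#' @export
compare_params <- function(min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1)
  structure(list(min_overlap_bp = as.integer(min_overlap_bp)),
            class = "compare_params")
}

# GRanges view of a catalog-like data.frame (0-based half-open in memory,
# IRanges are 1-based closed).
.as_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# Overlap pairs (query, subject indices) honouring min_overlap_bp.
.overlap_hits <- function(a, b, params) {
  if (!nrow(a) || !nrow(b))
    return(data.frame(q = integer(), s = integer()))
  h <- GenomicRanges::findOverlaps(.as_gr(a), .as_gr(b),
                                   minoverlap = params$min_overlap_bp)
  data.frame(q = S4Vectors::queryHits(h), s = S4Vectors::subjectHits(h))
}

#' Do two DMRs overlap?
#'
#' True iff both records lie on the same chromosome and the overlap length
#' `min(a.end, b.end) - max(a.start, b.start)` is at least
#' `min_overlap_bp`. Intervals are half-open, so abutting regions do not
#' overlap.
#'
#' @param a,b Single-row data frames (or one-row subsets of a
#'   `dmr_catalog`) with `chrom`, `start`, `end`.
#' @param params A [compare_params()] object.
#' @return Logical scalar.
#' @export
dmr_overlaps <- function(a, b, params = compare_params()) {
  if (a$chrom[1L] != b$chrom[1L]) return(FALSE)
  ov <- min(a$end[1L], b$end[1L]) - max(a$start[1L], b$start[1L])
  ov >= params$min_overlap_bp
}

#' Classify aging DMRs into temporal categories
#'
#' Each DMR of the early contrast is labelled `inverse` if it overlaps any
#' opposite-direction late DMR (inverse takes precedence), else
#' `progressive` if it overlaps any same-direction late DMR, else
#' `early_single`. Late DMRs with no early partner are reported as
#' `late_single`; late DMRs that do overlap early ones appear only in the
#' early DMRs' partner lists, so every DMR receives exactly one row.
#'
#' @param early `dmr_catalog` for the early contrast (e.g. A8:A2).
#' @param late `dmr_catalog` for the late contrast (e.g. A16:A8).
#' @param params A [compare_params()] object.
#' @return Data frame with one row per call: `dmr_id`, `contrast`, `chrom`,
#'   `start`, `end`, `direction`, `category`, `partner_ids`
#'   (comma-separated, empty for singles).
#' @export
classify_temporal <- function(early, late, params = compare_params()) {
  if (nrow(early) && nrow(late) &&
      !length(intersect(unique(early$chrom), unique(late$chrom))))
    warning("classify_temporal: catalogs share no chromosome names")
  hits <- .overlap_hits(early, late, params)
  n_e <- nrow(early)
  category <- rep("early_single", n_e)
  partners <- rep("", n_e)
  if (nrow(hits)) {
    for (i in unique(hits$q)) {
      hi <- hits[hits$q == i, , drop = FALSE]
      opp <- early$direction[i] != late$direction[hi$s]
      category[i] <- if (any(opp)) "inverse" else "progressive"
      partners[i] <- paste(late$dmr_id[hi$s], collapse = ",")
    }
  }
  early_rows <- data.frame(dmr_id = early$dmr_id,
                           contrast = attr(early, "contrast") %||% NA_character_,
                           chrom = early$chrom, start = early$start,
                           end = early$end, direction = early$direction,
                           category = category, partner_ids = partners,
                           stringsAsFactors = FALSE)
  matched_late <- unique(hits$s)
  late_only <- setdiff(seq_len(nrow(late)), matched_late)
  late_rows <- data.frame(dmr_id = late$dmr_id[late_only],
                          contrast = rep(attr(late, "contrast") %||% NA_character_,
                                         length(late_only)),
                          chrom = late$chrom[late_only],
                          start = late$start[late_only],
                          end = late$end[late_only],
                          direction = late$direction[late_only],
                          category = rep("late_single", length(late_only)),
                          partner_ids = rep("", length(late_only)),
                          stringsAsFactors = FALSE)
  out <- rbind(early_rows, late_rows)
  rownames(out) <- NULL
  out
}

#' Cross regeneration and aging DMR catalogs
#'
#' Emits one record per overlapping (regeneration DMR, aging DMR) pair,
#' labelled `synchronous` when the two directions agree (hyper/hyper or
#' hypo/hypo) and `inverse` otherwise. A regeneration DMR overlapping
#' several aging DMRs yields several records.
#'
#' @param regen `dmr_catalog` from a regeneration contrast (R1:R0, R2:R0,
#'   R4:R0).
#' @param aging `dmr_catalog` from an aging contrast (A8:A2, A16:A8,
#'   A16:A2).
#' @param params A [compare_params()] object.
#' @return Data frame: `regen_id`, `aging_id`, `regen_contrast`,
#'   `aging_contrast`, `regen_direction`, `aging_direction`, `relation`.
#' @export
cross_regeneration <- function(regen, aging, params = compare_params()) {
  hits <- .overlap_hits(regen, aging, params)
  data.frame(regen_id = regen$dmr_id[hits$q],
             aging_id = aging$dmr_id[hits$s],
             regen_contrast = rep(attr(regen, "contrast") %||% NA_character_, nrow(hits)),
             aging_contrast = rep(attr(aging, "contrast") %||% NA_character_, nrow(hits)),
             regen_direction = regen$direction[hits$q],
             aging_direction = aging$direction[hits$s],
             relation = ifelse(regen$direction[hits$q] == aging$direction[hits$s],
                               "synchronous", "inverse"),
             stringsAsFactors = FALSE)
}

# Union-find over overlap hits among pooled records. Returns integer
# component id per row of `pooled`.
.overlap_components <- function(pooled, params) {
  n <- nrow(pooled)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  hits <- .overlap_hits(pooled, pooled, params)
  hits <- hits[hits$q < hits$s, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    rq <- find(hits$q[i]); rs <- find(hits$s[i])
    if (rq != rs) parent[rs] <- rq
  }
  vapply(seq_len(n), find, integer(1))
}

#' Three-set Venn accounting over overlap-connected components
#'
#' DMRs from three same-direction catalogs are clustered into connected
#' components under the at-least-`min_overlap_bp` overlap relation; every
#' Venn quantity is counted over components, so a DMR overlapping two DMRs
#' of another catalog is not double-counted. A component belongs to every
#' catalog that contributes at least one DMR to it. Pairwise intersection
#' counts include triple-overlap components, so the three-set
#' inclusion-exclusion identity `union = sum(sizes) - sum(pairs) + triple`
#' holds exactly.
#'
#' @param catalogs List of exactly three `dmr_catalog`s of one direction.
#' @param params A [compare_params()] object.
#' @param labels Labels for the three sets; defaults to the catalogs'
#'   contrast attributes.
#' @return A `venn_summary` list: `set_sizes`, `pair_intersections`,
#'   `triple_intersection`, `union_size`, `exclusive_counts`.
#' @export
venn_summary <- function(catalogs, params = compare_params(), labels = NULL) {
  if (length(catalogs) != 3L)
    .stopf("venn_summary: exactly three catalogs are required")
  dirs <- unique(unlist(lapply(catalogs, function(x) unique(x$direction))))
  if (length(dirs) > 1L)
    .stopf("venn_summary: catalogs must share a single direction")
  if (is.null(labels))
    labels <- vapply(seq_along(catalogs), function(i) {
      attr(catalogs[[i]], "contrast") %||% paste0("set", i)
    }, character(1))
  pooled <- do.call(rbind, lapply(seq_along(catalogs), function(i) {
    data.frame(chrom = catalogs[[i]]$chrom, start = catalogs[[i]]$start,
               end = catalogs[[i]]$end, set = i, stringsAsFactors = FALSE)
  }))
  if (!nrow(pooled)) {
    zero3 <- stats::setNames(rep(0L, 3L), labels)
    pair_names <- c(paste(labels[1], labels[2], sep = "&"),
                    paste(labels[1], labels[3], sep = "&"),
                    paste(labels[2], labels[3], sep = "&"))
    return(structure(list(set_sizes = zero3,
                          pair_intersections = stats::setNames(rep(0L, 3L), pair_names),
                          triple_intersection = 0L, union_size = 0L,
                          exclusive_counts = stats::setNames(rep(0L, 7L),
                            c(labels, pair_names, paste(labels, collapse = "&")))),
                     class = "venn_summary"))
  }
  comp <- .overlap_components(pooled, params)
  membership <- vapply(1:3, function(i) {
    as.integer(unique(comp) %in% comp[pooled$set == i])
  }, integer(length(unique(comp))))
  # rows of `membership` follow unique(comp)
  m1 <- membership[, 1L] == 1L
  m2 <- membership[, 2L] == 1L
  m3 <- membership[, 3L] == 1L
  sizes <- stats::setNames(c(sum(m1), sum(m2), sum(m3)), labels)
  pairs <- stats::setNames(c(sum(m1 & m2), sum(m1 & m3), sum(m2 & m3)),
                           c(paste(labels[1], labels[2], sep = "&"),
                             paste(labels[1], labels[3], sep = "&"),
                             paste(labels[2], labels[3], sep = "&")))
  triple <- sum(m1 & m2 & m3)
  excl <- stats::setNames(
    c(sum(m1 & !m2 & !m3), sum(!m1 & m2 & !m3), sum(!m1 & !m2 & m3),
      sum(m1 & m2 & !m3), sum(m1 & !m2 & m3), sum(!m1 & m2 & m3), triple),
    c(labels, names(pairs), paste(labels, collapse = "&")))
  structure(list(set_sizes = sizes, pair_intersections = pairs,
                 triple_intersection = triple,
                 union_size = length(unique(comp)),
                 exclusive_counts = excl),
            class = "venn_summary")
}
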