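# End-to-end orchestration: simulate/load -> call -> classify -> annotate
# -> link -> summarise.

#' Subset a DMR catalog to one direction
#'
#' @param catalog A `dmr_catalog`.
#' @param direction `"hyper"` or `"hypo"`.
#' @return A `dmr_catalog` holding only that direction, same contrast.
#' @export
subset_direction <- function(catalog, direction) {
  df <- as.data.frame(catalog)[catalog$direction == direction, , drop = FALSE]
  new_dmr_catalog(df[, c("chrom", "start", "end", "direction", "dmc_count",
                         "mean_delta", "min_p")],
                  attr(catalog, "contrast"))
}

#' Pipeline configuration
#'
#' @param simulation A [sim_config()]; when supplied the run is
#'   simulation-backed. Otherwise `inputs` must name on-disk tables.
#' @param inputs Named list for file-backed runs: `samples` (named list of
#'   condition -> character vector of CpG TSV paths), `genes`, `repeats`,
#'   `cgi`, `chrom_sizes` (2-column TSV), `degs` (file paths).
#' @param dmc,dmr,compare,gene_map,deg Stage parameter objects.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            dmc = dmc_params(), dmr = dmr_params(),
                            compare = compare_params(),
                            gene_map = gene_map_params(), deg = deg_params()) {
  if (is.null(simulation) && is.null(inputs))
    .stopf("pipeline_config: supply either a simulation config or file inputs")
  structure(list(simulation = simulation, inputs = inputs, dmc = dmc,
                 dmr = dmr, compare = compare, gene_map = gene_map,
                 deg = deg),
            class = "pipeline_config")
}

.load_inputs <- function(inputs) {
  samples <- lapply(inputs$samples, function(paths) {
    lapply(seq_along(paths), function(i)
      read_cpg_table(paths[i], sub("\\.tsv$", "", basename(paths[i]))))
  })
  cs <- utils::read.table(inputs$chrom_sizes, sep = "\t",
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  list(samples = samples,
       genes = read_gene_models(inputs$genes),
       repeats = read_region_track(inputs$repeats),
       cgi = read_region_track(inputs$cgi, "cgi"),
       chrom_sizes = stats::setNames(as.integer(cs$size), cs$chrom),
       degs = read_deg_table(inputs$degs),
       truth = NULL)
}

#' Run the full differential-methylation pipeline
#'
#' Executes every stage on a simulated or file-backed study: pools
#' replicates, calls DMCs and DMRs for the six standard contrasts (three
#' aging, three regeneration), classifies aging DMRs into temporal
#' categories, crosses regeneration against aging catalogs, computes
#' three-set Venn accounting over the regeneration catalogs per direction,
#' derives hotspot tracks and reports, maps DMRs to genes, links them to
#' DEGs with direction matching, finds flip genes, and (for simulations)
#' scores recovery against planted truth.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Optional output directory; when given, all stage outputs
#'   (DMR BEDs, TSVs, JSON summary, manifest) are written beneath it.
#' @return A `regenmeth_run` list: `catalogs`, `temporal`, `cross`, `venn`,
#'   `hotspot`, `genemaps`, `degs`, `linked`, `flip_genes`, `recovery`
#'   (simulation only), and `summary` (the machine-readable run summary).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  data <- if (!is.null(config$simulation)) {
    stage("simulate", simulate_methylomes(config$simulation))
  } else {
    stage("load", .load_inputs(config$inputs))
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pooled <- stage("pool", lapply(data$samples, pool_group))
  contrasts <- .SIM_CONTRASTS
  catalogs <- list()
  dmc_counts <- list()
  for (nm in names(contrasts)) {
    pair <- contrasts[[nm]]
    if (!all(pair %in% names(pooled))) next
    dmcs <- stage(paste0("call ", nm),
                  call_dmcs(pooled[[pair["test"]]], pooled[[pair["ref"]]],
                            config$dmc, quiet = TRUE))
    catalogs[[nm]] <- stage(paste0("assemble ", nm),
                            assemble_dmrs(dmcs, config$dmr, contrast = nm))
    dmc_counts[[nm]] <- c(n_tested = attr(dmcs, "n_tested"),
                          hyper = sum(dmcs$direction == "hyper"),
                          hypo = sum(dmcs$direction == "hypo"))
  }

  temporal <- stage("classify-aging",
                    classify_temporal(catalogs[["A8:A2"]], catalogs[["A16:A8"]],
                                      config$compare))
  cross <- stage("cross", do.call(rbind, lapply(
    c("R1:R0", "R2:R0", "R4:R0"), function(r) {
      do.call(rbind, lapply(c("A8:A2", "A16:A8", "A16:A2"), function(a)
        cross_regeneration(catalogs[[r]], catalogs[[a]], config$compare)))
    })))
  venn <- stage("venn", lapply(stats::setNames(c("hyper", "hypo"), c("hyper", "hypo")),
                               function(dir) {
    venn_summary(lapply(c("R1:R0", "R2:R0", "R4:R0"), function(r)
      subset_direction(catalogs[[r]], dir)), config$compare)
  }))

  tracks <- stage("tracks", suppressWarnings(
    derive_region_tracks(data$genes, data$repeats, data$cgi, data$chrom_sizes)))
  hotspot <- stage("hotspot", hotspot_report(catalogs[["R2:R0"]], tracks,
                                             config$compare))
  genemaps <- stage("genemap", lapply(catalogs, map_dmrs_to_genes,
                                      genes = data$genes,
                                      map_params = config$gene_map,
                                      params = config$compare))
  degs <- stage("degs", filter_degs(data$degs, config$deg))
  linked <- stage("map-deg", lapply(
    stats::setNames(c("R1:R0", "R2:R0", "R4:R0"), c("R1:R0", "R2:R0", "R4:R0")),
    function(r) link_dmrs_to_degs(genemaps[[r]], degs, "promoter")))
  flip <- stage("flip-genes",
                find_flip_genes(genemaps[["A8:A2"]], genemaps[["A16:A8"]], degs))
  recovery <- if (!is.null(data$truth))
    stage("score", score_recovery(data$truth, catalogs)) else NULL

  count_by_dir <- function(cat) c(hyper = sum(cat$direction == "hyper"),
                                  hypo = sum(cat$direction == "hypo"))
  summary <- list(
    tool = "regenmeth",
    version = as.character(utils::packageVersion("regenmeth")),
    seed = if (!is.null(config$simulation)) config$simulation$seed else NA,
    params = list(dmc = unclass(config$dmc), dmr = unclass(config$dmr),
                  compare = unclass(config$compare),
                  gene_map = unclass(config$gene_map),
                  deg = unclass(config$deg)),
    dmc_counts = dmc_counts,
    dmr_counts = lapply(catalogs, count_by_dir),
    temporal_counts = as.list(table(temporal$category)),
    cross_counts = as.list(table(cross$relation)),
    venn = lapply(venn, function(v) list(
      set_sizes = as.list(v$set_sizes),
      pair_intersections = as.list(v$pair_intersections),
      triple_intersection = v$triple_intersection,
      union_size = v$union_size)),
    linked_counts = lapply(linked, function(l) list(
      dmr_level = attr(l, "n_dmrs"), gene_level = attr(l, "n_genes"))),
    flip_gene_count = nrow(flip),
    recovery = if (!is.null(recovery))
      list(sensitivity = recovery$sensitivity,
           precision = recovery$precision) else NULL)

  run <- structure(list(catalogs = catalogs, temporal = temporal,
                        cross = cross, venn = venn, hotspot = hotspot,
                        genemaps = genemaps, degs = degs, linked = linked,
                        flip_genes = flip, recovery = recovery,
                        tracks = tracks, data = data, summary = summary),
                   class = "regenmeth_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

.write_run <- function(run, out_dir) {
  manifest <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest <<- c(manifest, name)
  }
  for (nm in names(run$catalogs)) {
    safe <- gsub(":", "_", nm, fixed = TRUE)
    emit(sprintf("dmrs_%s.bed", safe),
         function(p) write_dmr_bed(run$catalogs[[nm]], p))
  }
  tsv <- function(df) function(p) utils::write.table(
    df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("temporal.tsv", tsv(run$temporal))
  emit("cross.tsv", tsv(run$cross))
  emit("hotspot_R2_R0.tsv", tsv(run$hotspot))
  emit("degs_classified.tsv", tsv(run$degs))
  for (nm in names(run$linked)) {
    safe <- gsub(":", "_", nm, fixed = TRUE)
    emit(sprintf("linked_%s.tsv", safe), tsv(as.data.frame(run$linked[[nm]])))
  }
  emit("flip_genes.tsv", tsv(run$flip_genes))
  emit("summary.json", function(p)
    jsonlite::write_json(run$summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null"))
  writeLines(manifest, file.path(out_dir, "MANIFEST"))
  invisible(out_dir)
}
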