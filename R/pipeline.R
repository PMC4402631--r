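#' Assemble a pipeline run configuration
#'
#' A run is driven either by input files (genotypes, IBD segments,
#' genetic map, phenotypes) or by a \code{\link{sim_spec}} that generates
#' them; exactly one of the two must be given. Every stage's parameters
#' live here so a run is auditable from one object.
#'
#' @param sim a \code{\link{sim_spec}}, or NULL when reading files.
#' @param input NULL, or a list with paths: \code{ped_prefix} (or
#'   \code{vcf}), \code{segments}, \code{genetic_map}, \code{phenotypes}.
#' @param qc a \code{\link{qc_thresholds}}.
#' @param outlier an \code{\link{outlier_params}}.
#' @param filter a \code{\link{segment_filter_params}}.
#' @param mapping a \code{\link{mapping_params}}.
#' @param out_dir output directory for stage reports (created on run).
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, input = NULL,
                       qc = qc_thresholds(),
                       outlier = outlier_params(),
                       filter = segment_filter_params(),
                       mapping = mapping_params(),
                       out_dir = tempfile("ibdmapr_run_"),
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  structure(list(sim = sim, input = input, qc = qc, outlier = outlier,
                 filter = filter, mapping = mapping, out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every parameter block against its invariants and reports the
#' defaults in force. Returns a report rather than throwing, so a caller
#' can display all problems at once.
#'
#' @param config a \code{\link{run_config}}.
#' @return list with \code{ok} (logical), \code{issues} (character
#'   vector of violations) and \code{defaults} (named list of the
#'   parameter values in force).
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (!inherits(config, "run_config")) add("not a run_config object")
  has_sim <- !is.null(config$sim)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    add("exactly one of sim / input must be given")
  if (has_sim && !inherits(config$sim, "sim_spec"))
    add("sim must be a sim_spec")
  if (has_input) {
    paths <- unlist(config$input[setdiff(names(config$input), "ped_prefix")])
    if (!is.null(config$input$ped_prefix))
      paths <- c(paths, paste0(config$input$ped_prefix, c(".ped", ".map")))
    missing <- paths[!file.exists(paths)]
    for (p in missing) add(paste("input file does not exist:", p))
  }
  for (blk in c("qc", "outlier", "filter", "mapping")) {
    cls <- c(qc = "qc_thresholds", outlier = "outlier_params",
             filter = "segment_filter_params", mapping = "mapping_params")[blk]
    if (!inherits(config[[blk]], cls))
      add(paste0(blk, " must be a ", cls, " object"))
  }
  if (inherits(config$mapping, "mapping_params") &&
      config$mapping$n_permutations < 1)
    add("n_permutations must be >= 1")
  defaults <- list(
    maf_min = config$qc$maf_min, hwe_p_min = config$qc$hwe_p_min,
    ind_missing_max = config$qc$ind_missing_max,
    marker_missing_max = config$qc$marker_missing_max,
    n_pcs = config$outlier$n_pcs, n_neighbors = config$outlier$n_neighbors,
    density_cutoff = config$outlier$density_cutoff,
    interior_min = config$outlier$interior_min,
    lod_min = config$filter$lod_min,
    length_min_cm = config$filter$length_min_cm,
    fwer_level = config$mapping$fwer_level,
    coverage_fraction = config$mapping$coverage_fraction,
    n_permutations = config$mapping$n_permutations)
  list(ok = length(issues) == 0L, issues = issues, defaults = defaults)
}

#' Run the full IBD mapping pipeline
#'
#' Stage order: acquire inputs (simulate or read) -> genotype QC ->
#' genotype PCA and two-stage outlier removal (samples removed there are
#' dropped from the labels and their segments discarded) -> genetic-map
#' annotation and LOD/length filtering of segments -> permutation mapping
#' with the low-coverage filter -> significant-marker report. Each stage
#' writes a tab-separated report under \code{config$out_dir} and a
#' manifest records parameters and seeds; re-running the same config is
#' byte-identical.
#'
#' @param config a \code{\link{run_config}}; must validate.
#' @return the \code{\link{ibd_map}} fit, with attribute \code{files}
#'   naming the written artifacts.
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (!v$ok)
    stop2("invalid configuration:\n  ", paste(v$issues, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$log_level == "info")
    message("[ibdmapr] ", ...)
  out <- function(name) file.path(config$out_dir, name)
  stage <- "input"
  files <- character(0)
  tryCatch({
    if (!is.null(config$sim)) {
      say("simulating panel, segments and map (seed ", config$sim$seed, ")")
      simp <- simulate_panel(config$sim)
      panel <- simp$panel
      segments <- simulate_ibd_segments(config$sim,
                                        panel_phenotypes(panel))$segments
      gmap <- sim_genetic_map(config$sim)
    } else {
      inp <- config$input
      panel <- if (!is.null(inp$ped_prefix)) read_ped(inp$ped_prefix)
               else read_vcf_panel(inp$vcf, read_phenotypes(inp$phenotypes))
      if (!is.null(inp$phenotypes)) {
        ph <- read_phenotypes(inp$phenotypes)
        hit <- match(panel$sample_ids, names(ph))
        panel$phenotype[!is.na(hit)] <- ph[hit[!is.na(hit)]]
      }
      segments <- read_refined_ibd(inp$segments)
      gmap <- read_genetic_map(inp$genetic_map)
    }

    stage <- "qc"
    say("genotype QC")
    qc <- apply_qc(panel, config$qc)
    n_ri <- nrow(qc$removed_individuals)
    n_rm <- nrow(qc$removed_markers)
    utils::write.table(
      data.frame(id = c(qc$removed_individuals$id, qc$removed_markers$id),
                 type = rep(c("individual", "marker"), c(n_ri, n_rm)),
                 reason = c(rep("ind_missing", n_ri),
                            qc$removed_markers$reason),
                 value = c(qc$removed_individuals$missing_rate,
                           qc$removed_markers$value)),
      out("qc_report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, out("qc_report.tsv"))
    if (qc$empty) stop2("QC removed all samples or markers")

    stage <- "outliers"
    say("genotype PCA and two-stage outlier removal")
    n_pcs <- min(config$outlier$n_pcs, length(qc$panel$sample_ids),
                 nrow(qc$panel$markers))
    emb <- compute_pcs(qc$panel, n_pcs)
    opar <- config$outlier
    if (n_pcs != opar$n_pcs)
      opar <- outlier_params(opar$n_neighbors, opar$density_cutoff,
                             opar$interior_min, n_pcs, opar$stage2_neighbors)
    outl <- two_stage_outlier_removal(emb, opar)
    utils::write.table(outl$diagnostics, out("outlier_diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, out("outlier_diagnostics.tsv"))
    kept_panel <- subset_panel(qc$panel, samples = outl$kept)
    ph <- panel_phenotypes(kept_panel)
    drop_seg <- !(segments$sample1 %in% outl$kept &
                    segments$sample2 %in% outl$kept)
    say(sum(drop_seg), " segments dropped with removed samples")
    segments <- segments[!drop_seg, , drop = FALSE]

    stage <- "segment_filter"
    say("annotating and filtering segments")
    segments <- annotate_segments(segments, gmap)
    flt <- filter_segments(segments, config$filter)
    utils::write.table(flt$segments, out("segments_kept.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, out("segments_kept.tsv"))

    stage <- "mapping"
    say("permutation mapping (", config$mapping$n_permutations,
        " permutations)")
    fit <- ibd_map(flt$segments, ph, kept_panel$markers, config$mapping)
    utils::write.table(fit$results, out("mapping_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hits <- significant_markers(fit)
    utils::write.table(hits, out("significant_markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, out("mapping_results.tsv"),
               out("significant_markers.tsv"))

    manifest <- list(
      package_version = as.character(utils::packageVersion("ibdmapr")),
      seed_sim = if (!is.null(config$sim)) config$sim$seed else NULL,
      seed_mapping = config$mapping$seed,
      parameters = validate_config(config)$defaults,
      n_samples_post_qc = length(qc$panel$sample_ids),
      n_samples_post_outliers = length(kept_panel$sample_ids),
      n_segments_kept = flt$report$n_kept,
      segment_exclusions = flt$report[c("n_lod", "n_length", "n_excluded")])
    yaml::write_yaml(manifest, out("manifest.yaml"))
    files <- c(files, out("manifest.yaml"))

    attr(fit, "files") <- files
    fit
  }, error = function(e) {
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
}

#' Read a pipeline configuration from YAML
#'
#' Mirrors \code{\link{run_config}}: top-level blocks \code{sim},
#' \code{input}, \code{qc}, \code{outlier}, \code{filter},
#' \code{mapping}, \code{out_dir}; missing blocks take the package
#' defaults.
#'
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(block, fn) {
    if (is.null(y[[block]])) fn() else do.call(fn, y[[block]])
  }
  sim <- if (!is.null(y$sim)) {
    args <- y$sim
    if (!is.null(args$chromosomes))
      args$chromosomes <- as.data.frame(lapply(args$chromosomes, unlist),
                                        stringsAsFactors = FALSE)
    do.call(sim_spec, args)
  } else NULL
  run_config(sim = sim, input = y$input,
             qc = build("qc", qc_thresholds),
             outlier = build("outlier", outlier_params),
             filter = build("filter", segment_filter_params),
             mapping = build("mapping", mapping_params),
             out_dir = y$out_dir %||% tempfile("ibdmapr_run_"),
             log_level = y$log_level %||% "info")
}
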