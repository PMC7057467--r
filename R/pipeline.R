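#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis with its default. Any
#' argument can instead be supplied through a YAML file via `yaml_path`
#' (explicit arguments win over the file).
#'
#' @param matrix_path,meta_path Input expression matrix and metadata (see
#'   [load_expression()]).
#' @param out_dir Output directory; created if absent.
#' @param species Character vector of species to scan; `NULL` = every
#'   species with enough young samples.
#' @param max_age Age cutoff in years for the infant course (default 1).
#' @param window_size,step,min_size,max_size,kme_threshold,z_threshold,permutations
#'   DNB-scan parameters, see [dnb_scan()]; `z_threshold = NULL` uses the
#'   multiplicity-calibrated default.
#' @param fdr_threshold,fc_threshold DEG thresholds, see [call_degs()].
#' @param cutoff_age Cutoff for the first-axis change fraction (default 1).
#' @param seed Master seed; per-stage seeds are derived as
#'   `seed + 1000 * stage_rank` so stages rerun standalone reproducibly.
#' @param plots Write PNG plots of the CI trajectory and MDS axis.
#' @param yaml_path Optional YAML file with any of the above fields.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, meta_path = NULL,
                            out_dir = NULL, species = NULL, max_age = 1,
                            window_size = 4, step = 1, min_size = 5,
                            max_size = NULL, kme_threshold = 0.9,
                            z_threshold = NULL,
                            permutations = 0, fdr_threshold = 0.01,
                            fc_threshold = 2, cutoff_age = 1, seed = 1,
                            plots = FALSE, yaml_path = NULL) {
  cfg <- list(
    matrix_path = matrix_path, meta_path = meta_path, out_dir = out_dir,
    species = species, max_age = max_age, window_size = window_size,
    step = step, min_size = min_size, max_size = max_size,
    kme_threshold = kme_threshold,
    z_threshold = z_threshold, permutations = permutations,
    fdr_threshold = fdr_threshold, fc_threshold = fc_threshold,
    cutoff_age = cutoff_age, seed = seed, plots = plots
  )
  if (!is.null(yaml_path)) {
    file_cfg <- yaml::read_yaml(yaml_path)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    supplied <- names(as.list(match.call())[-1])
    for (nm in setdiff(names(file_cfg), supplied)) cfg[[nm]] <- file_cfg[[nm]]
  }
  for (nm in c("max_age", "window_size", "step", "min_size", "kme_threshold",
               "fdr_threshold", "fc_threshold", "cutoff_age")) {
    if (cfg[[nm]] <= 0) stop("`", nm, "` must be positive")
  }
  if (!is.null(cfg$z_threshold) && cfg$z_threshold <= 0) {
    stop("`z_threshold` must be positive")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full tipping-point pipeline
#'
#' Executes load -> normalize -> exploratory ordination -> per-species
#' age filter -> DNB scan -> DEG calling around the tipping age ->
#' cross-species overlaps, writing per-stage TSV artifacts and a single
#' JSON report into `config$out_dir`. Reruns with the same config and
#' inputs reproduce the report byte for byte.
#'
#' @param config A [pipeline_config()] (or a list of its fields, or a
#'   path to a YAML file).
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(yaml_path = config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  if (is.null(config$matrix_path) || is.null(config$meta_path) ||
      is.null(config$out_dir)) {
    stop("[config] matrix_path, meta_path and out_dir are required")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ds <- pipeline_stage("data_io", {
    normalize_uniform(load_expression(config$matrix_path, config$meta_path,
                                      quiet = TRUE))
  })

  explore <- pipeline_stage("exploratory", {
    n_species <- length(unique(ds$meta$species))
    cl <- cluster_samples(ds, "average", "euclidean",
                          k = if (n_species > 1) n_species else NULL)
    pca <- pca_scores(ds, k = min(2, ncol(ds$values) - 1))
    mds <- mds_axis(ds)
    frac <- fraction_change_by_age(mds, ds$meta$age_years, config$cutoff_age)
    coords <- data.frame(
      sample_id = ds$meta$sample_id, species = ds$meta$species,
      age_years = ds$meta$age_years,
      pc1 = pca$coordinates[, 1],
      pc2 = if (ncol(pca$coordinates) > 1) pca$coordinates[, 2] else NA_real_,
      mds1 = mds$coordinates[, 1]
    )
    utils::write.table(coords, file.path(config$out_dir, "ordination.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (isTRUE(config$plots)) {
      grDevices::png(file.path(config$out_dir, "mds_vs_age.png"), 600, 480)
      plot_mds_age(mds, ds$meta$age_years, ds$meta$species)
      grDevices::dev.off()
    }
    list(frac = frac, pca_var = pca$variance_explained, labels = cl$labels)
  })

  sp_list <- config$species
  if (is.null(sp_list)) {
    tab <- table(ds$meta$species[ds$meta$age_years <= config$max_age])
    sp_list <- names(tab)[tab >= max(3, config$window_size)]
  }
  if (length(sp_list) == 0) stop("[config] no species with enough young samples")

  species_reports <- list()
  dnb_sets <- list()
  deg_sets <- list()
  for (i in seq_along(sp_list)) {
    sp <- sp_list[[i]]
    sub <- pipeline_stage("data_io", filter_by_age(ds, sp, config$max_age))
    scan <- pipeline_stage("dnb_core", {
      dnb_scan(sub, window_size = config$window_size, step = config$step,
               min_size = config$min_size, max_size = config$max_size,
               kme_threshold = config$kme_threshold,
               z_threshold = config$z_threshold,
               permutations = config$permutations,
               seed = config$seed + 1000L * i)
    })
    utils::write.table(scan$scores,
                       file.path(config$out_dir, sprintf("dnb_windows_%s.tsv", sp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(scan$dnb_genes,
               file.path(config$out_dir, sprintf("dnb_genes_%s.txt", sp)))
    if (isTRUE(config$plots)) {
      grDevices::png(file.path(config$out_dir, sprintf("ci_trajectory_%s.png", sp)),
                     600, 480)
      plot_ci_trajectory(scan)
      grDevices::dev.off()
    }
    degs <- pipeline_stage("degs", {
      differential_expression(sub, split_age = scan$tipping_age,
                              fdr_threshold = config$fdr_threshold,
                              fc_threshold = config$fc_threshold)
    })
    utils::write.table(degs,
                       file.path(config$out_dir, sprintf("degs_%s.tsv", sp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dnb_sets[[sp]] <- scan$dnb_genes
    deg_sets[[sp]] <- degs$gene_id[degs$is_deg]
    species_reports[[sp]] <- list(
      n_samples = ncol(sub$values),
      tipping_age = scan$tipping_age,
      tipping_window = scan$tipping_index,
      peak_z = scan$z,
      significant = scan$significant,
      permutation_p = scan$perm_p,
      n_dnb_genes = length(scan$dnb_genes),
      n_degs = length(deg_sets[[sp]])
    )
  }

  report <- list(
    parameters = unclass(config),
    exploratory = list(
      first_axis_change_fraction = explore$frac,
      cutoff_age = config$cutoff_age,
      pca_variance_explained = explore$pca_var
    ),
    species = species_reports
  )
  if (length(sp_list) >= 2) {
    ov_dnb <- overlap_sets(dnb_sets[[1]], dnb_sets[[2]])
    ov_deg <- overlap_sets(deg_sets[[1]], deg_sets[[2]])
    report$overlap <- list(
      species = sp_list[1:2],
      dnb = as.list(ov_dnb$sizes),
      dnb_shared_genes = ov_dnb$intersection,
      deg = as.list(ov_deg$sizes),
      deg_shared_genes = ov_deg$intersection
    )
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
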