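#' Annotate cells: signature scores, hypoxia class, state, coordinates
#'
#' Convenience composition of the per-cell stages: scores the hypoxia
#' signature, calibrates (or accepts) the hypoxia threshold against the
#' marker guide, classifies cells, scores and assigns the six Neftel state
#' sets, and computes the 2D state-plot coordinates.
#'
#' @param cells a [cell_matrix()] with `lognorm` present.
#' @param hypoxia_sig [gene_signature()] scored for hypoxia.
#' @param neftel_sets list of the six state signatures (see
#'   [score_states()]).
#' @param params a [score_params()].
#' @param marker_gene marker gene symbol for threshold calibration.
#' @param grid candidate threshold grid (see [calibrate_threshold()]).
#' @param threshold optional fixed threshold overriding calibration.
#' @return list with `annotation` (per-cell data.frame: id/patient/IDH,
#'   `hypoxia_score`, `hypoxic`, six state scores, `state_raw`, `state`,
#'   `coord_x`, `coord_y`) and `calibration` (the
#'   `threshold_calibration`).
#' @export
annotate_cells <- function(cells, hypoxia_sig, neftel_sets,
                           params = score_params(), marker_gene = "VEGFA",
                           grid = seq(0.05, 0.95, by = 0.05), threshold = NULL) {
  hyp_score <- module_score(cells, hypoxia_sig, params)
  marker <- marker_positive(cells, marker_gene)
  calib <- calibrate_threshold(hyp_score, marker, grid, override = threshold)
  hypoxic <- classify_hypoxic(hyp_score, calib$chosen)
  st <- score_states(cells, neftel_sets, params)
  coords <- state_coordinates(st$scores)
  ann <- data.frame(cells$cell_meta[, c("cell_id", "patient", "idh_status")],
                    hypoxia_score = unname(hyp_score),
                    marker_positive = unname(marker),
                    hypoxic = unname(hypoxic),
                    st$scores,
                    state_raw = st$state_raw, state = st$state,
                    coords, stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  list(annotation = ann, calibration = calib)
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full pipeline over a configuration
#'
#' Executes the stages in order — input (simulate, or read an MTX triplet
#' directory), QC filtering, log-normalization, hypoxia-signature scoring,
#' threshold calibration and classification, state scoring, and the
#' IDH-stratified shift report — and writes every stage's output under
#' `out_dir` together with a config echo (including the package version and
#' seed) and an MD5 manifest.  Two runs with the same config produce
#' byte-identical CSVs.
#'
#' Config fields (all optional except `out_dir`): `seed`; `sim` (list of
#' [sim_config()] overrides) or `mtx_dir` (input triplet directory, in
#' which case `signatures_gmt` must name a GMT file holding the hypoxia
#' signature named in `hypoxia_sig` plus the six state sets); `qc`
#' ([qc_thresholds()] overrides); `score` ([score_params()] overrides);
#' `grid`; `threshold` (fixed override); `marker_gene`.
#'
#' @param config a named list or path to a JSON config file.
#' @return list of in-memory results (`cells`, `annotation`, `calibration`,
#'   `shift`, `report`, `out_dir`), invisibly.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$out_dir)) stop("config must name out_dir")
  if (!is.null(config$mtx_dir)) {
    if (!dir.exists(config$mtx_dir))
      stop("validation error: mtx_dir does not exist: ", config$mtx_dir)
    if (is.null(config$signatures_gmt) || !file.exists(config$signatures_gmt))
      stop("validation error: signatures_gmt missing or not found")
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    outputs[[length(outputs) + 1]] <<- path
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- data.frame(file = basename(outputs),
                             md5 = unname(tools::md5sum(outputs)))
      utils::write.csv(manifest, file.path(config$out_dir, "partial_manifest.csv"),
                       row.names = FALSE)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- input ------------------------------------------------------------
  input <- stage("input", {
    if (!is.null(config$mtx_dir)) {
      sigs <- read_gmt(config$signatures_gmt)
      hyp_name <- if (is.null(config$hypoxia_sig)) "hypoxia" else config$hypoxia_sig
      if (!hyp_name %in% names(sigs)) stop("hypoxia signature '", hyp_name, "' not in GMT")
      list(cells = read_mtx_triplet(config$mtx_dir),
           hyp_sig = sigs[[hyp_name]],
           sets = sigs[c("MES1", "MES2", "AC", "OPC", "NPC1", "NPC2")])
    } else {
      scfg <- do.call(sim_config, c(config$sim, if (is.null(config$sim$seed)) list(seed = seed)))
      sim <- simulate_cells(scfg)
      emit(sim$truth$cell, "sim_truth.csv")
      list(cells = sim$cells,
           hyp_sig = gene_signature("hypoxia",
                                    sim$truth$gene$gene[sim$truth$gene$program == "hypoxia"]),
           sets = state_signatures(sim$truth$gene))
    }
  })
  cells <- input$cells; hyp_sig <- input$hyp_sig; sets <- input$sets

  ann <- stage("qc", {
    thr <- do.call(qc_thresholds, as.list(config$qc))
    filtered <- filter_cells(cells, thr)
    emit(attr(filtered, "qc_report"), "qc_report.csv")
    filtered
  })
  ann <- stage("normalize", log_normalize(ann))
  res <- stage("score", {
    params <- do.call(score_params, c(as.list(config$score),
                                      if (is.null(config$score$seed)) list(seed = seed)))
    annotate_cells(ann, hyp_sig, sets, params,
                   marker_gene = if (is.null(config$marker_gene)) "VEGFA" else config$marker_gene,
                   grid = if (is.null(config$grid)) seq(0.05, 0.95, by = 0.05) else config$grid,
                   threshold = config$threshold)
  })
  stage("report", {
    emit(res$calibration$table, "calibration.csv")
    emit(res$annotation, "cell_annotations.csv")
    shift <- state_composition(res$annotation, by_patient = TRUE)
    emit(as.data.frame(shift), "shift_table.csv")
    rpt <- idh_shift_report(shift)
    emit(rpt$tests, "group_tests.csv")
    emit(rpt$patients, "patient_summary.csv")
    echo <- config
    echo$package_version <- as.character(utils::packageVersion("hypoxiaShift"))
    echo$seed <- seed
    echo$chosen_threshold <- res$calibration$chosen
    jsonlite::write_json(echo, file.path(config$out_dir, "config_echo.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest <- data.frame(file = basename(outputs), md5 = unname(tools::md5sum(outputs)))
    utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"), row.names = FALSE)
    invisible(list(cells = ann, annotation = res$annotation,
                   calibration = res$calibration, shift = shift, report = rpt,
                   out_dir = config$out_dir))
  })
}
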