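#' @include reconstruction.R
NULL

## per-stage allowed keys and defaults; `stage` is the discriminator key
.stageSchema <- list(
  flat = list(method = "conventional", n_components = 3L,
              estimation_region = NULL, eps_factor = 1e-6, clip_max = 10),
  geometry = list(axis = "auto", overlap_blend = "ramp"),
  ring = list(method = "raven", placement = "pre_phase", u0 = 0.05,
              order = 4L, n_angular_lines = 2L, smoothing_width = 9L),
  phase = list(method = "paganin", delta_beta_ratio = 100,
               regularization = 1e-4, response_clamp = pi / 2,
               padding = 64L, mu = NULL, delta = NULL),
  recon = list(algorithm = "fbp", filter = "shepp_logan", iterations = 100L,
               nonneg = TRUE, supersample = 2L, output_size = NULL)
)

.stageOrder <- c(flat = 1L, geometry = 2L, ring = 3L, phase = 3L, recon = 4L)

.validChoices <- list(
  flat = list(method = c("conventional", "dynamic")),
  geometry = list(overlap_blend = c("ramp", "cut", "cosine")),
  ring = list(method = c("raven", "column_norm", "none"),
              placement = c("pre_phase", "post_phase", "both")),
  phase = list(method = c("paganin", "ctf_pure_phase", "projected_ctf", "none")),
  recon = list(algorithm = c("fbp", "sirt"),
               filter = c("ramlak", "shepp_logan", "hann"))
)

.expandStage <- function(st) {
  if (is.null(st$stage)) stop("every stage entry needs a 'stage' key")
  name <- st$stage
  if (!(name %in% names(.stageSchema)))
    stop("unknown stage '", name, "'")
  schema <- .stageSchema[[name]]
  extra <- setdiff(names(st), c("stage", names(schema)))
  if (length(extra))
    stop("unknown key(s) in stage '", name, "': ",
         paste(extra, collapse = ", "))
  out <- schema
  for (k in names(st)) if (k != "stage") out[[k]] <- st[[k]]
  out <- out[!vapply(out, is.null, TRUE)]
  for (k in names(.validChoices[[name]])) {
    val <- out[[k]]
    if (!is.null(val) && is.character(val) && k != "axis" &&
        !(val %in% .validChoices[[name]][[k]]))
      stop("stage '", name, "': '", k, "' must be one of ",
           paste(.validChoices[[name]][[k]], collapse = "|"))
  }
  out$stage <- name
  out
}

#' Parse and validate a workflow parameter file
#'
#' The parameter file is human-editable YAML with an ordered `stages`
#' list plus `input`, `output`, `slices` and `seed` sections. Validation
#' fills stage defaults (so every run is reproducible from the expanded
#' spec alone), rejects unknown stages or keys, and enforces the stage
#' dependencies: flat fielding first, stitching before ring/phase
#' stages, reconstruction last.
#'
#' @param path path to a YAML workflow file.
#' @return a validated list of class \code{"WorkflowSpec"}.
#' @export
parseWorkflow <- function(path) {
  if (!file.exists(path)) stop("workflow file not found: ", path)
  validateWorkflow(yaml::read_yaml(path))
}

#' @rdname parseWorkflow
#' @param spec a raw workflow list (as read from YAML).
#' @export
validateWorkflow <- function(spec) {
  known <- c("stages", "input", "output", "slices", "seed", "simulate")
  extra <- setdiff(names(spec), known)
  if (length(extra))
    stop("unknown top-level key(s): ", paste(extra, collapse = ", "))
  if (is.null(spec$stages) || !length(spec$stages))
    stop("a workflow needs a non-empty 'stages' list")
  stages <- lapply(spec$stages, .expandStage)
  names(stages) <- vapply(stages, `[[`, "", "stage")
  if (anyDuplicated(names(stages)))
    stop("duplicated stage: ", names(stages)[duplicated(names(stages))][1L])
  ord <- .stageOrder[names(stages)]
  if (any(diff(ord) < 0)) {
    i <- which(diff(ord) < 0)[1L]
    stop("stage ordering violation: '", names(stages)[i + 1L],
         "' cannot come after '", names(stages)[i], "'")
  }
  if (names(stages)[1L] != "flat")
    stop("stage ordering violation: the first stage must be 'flat' (found '",
         names(stages)[1L], "')")
  if (!("recon" %in% names(stages)))
    stop("a workflow needs a 'recon' stage")
  if (tail(names(stages), 1L) != "recon")
    stop("stage ordering violation: 'recon' must be the last stage")
  out <- list(
    stages = stages,
    input = {
      inp <- spec$input
      if (is.null(inp)) inp <- list()
      defaults <- list(container = "tiff_sequence", data = "tomo",
                       white = "flat", dark = "dark", theta = "geometry.yaml")
      extraI <- setdiff(names(inp), names(defaults))
      if (length(extraI))
        stop("unknown input key(s): ", paste(extraI, collapse = ", "))
      utils::modifyList(defaults, inp)
    },
    output = {
      o <- spec$output
      if (is.null(o)) o <- list()
      extraO <- setdiff(names(o), "dir")
      if (length(extraO))
        stop("unknown output key(s): ", paste(extraO, collapse = ", "))
      if (is.null(o$dir)) o$dir <- "recon_out"
      o
    },
    slices = if (is.null(spec$slices)) "middle" else unlist(spec$slices),
    seed = if (is.null(spec$seed)) 1L else as.integer(spec$seed)
  )
  if (!is.null(spec$simulate)) out$simulate <- spec$simulate
  class(out) <- c("WorkflowSpec", "list")
  out
}

#' Serialize a workflow spec to YAML
#'
#' \code{parseWorkflow(serializeWorkflow(spec))} reproduces the spec.
#'
#' @param spec a \code{"WorkflowSpec"}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
serializeWorkflow <- function(spec, path) {
  x <- unclass(spec)
  x$stages <- unname(x$stages)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

.pairIndices <- function(angs) {
  i0 <- which.min(abs(angs - angs[1L]))
  i180 <- which.min(abs(angs - (angs[1L] + 180)))
  c(i0, i180)
}

.applyRing <- function(stack, geom, ringCfg, axis) {
  h <- dim(stack)[2L]
  for (r in seq_len(h)) {
    sg <- sinogram(stack[, r, ], geom$angles, axis, geom$pixelSize)
    sg <- switch(ringCfg$method,
      raven = ravenFilter(sg, ringCfg$u0, ringCfg$order,
                          ringCfg$n_angular_lines),
      column_norm = columnNormalizationFilter(sg, ringCfg$smoothing_width),
      none = sg)
    stack[, r, ] <- sg@values
  }
  stack
}

#' Execute a reconstruction workflow on one dataset
#'
#' Runs the validated stage chain over the requested slice range: flat
#' fielding, optional rotation-axis estimation and half-acquisition
#' stitching, ring removal (before and/or after phase retrieval), phase
#' retrieval, and slice reconstruction. Slices are written as 32-bit
#' float TIFFs; a structured report (per-stage parameters, timings,
#' warnings, output checksums) plus the default-expanded spec are
#' written next to them, so any run is replayable from its own log.
#' Identical spec + dataset + seed give bit-identical outputs.
#'
#' @param spec a \code{"WorkflowSpec"} from [parseWorkflow()] /
#'   [validateWorkflow()].
#' @param dataset a dataset directory (read with the spec's input
#'   layout) or a [ProjectionSet-class].
#' @param outputDir overrides the spec's output directory.
#' @param writeOutputs set \code{FALSE} to skip writing files (the
#'   report then carries the slices only in memory).
#' @return a list of class \code{"runReport"}: stages, timings (s),
#'   warnings, metrics (axis estimate, etc.), reconstructed slices and
#'   output paths.
#' @export
runWorkflow <- function(spec, dataset, outputDir = NULL, writeOutputs = TRUE) {
  stopifnot(inherits(spec, "WorkflowSpec"))
  t0 <- Sys.time()
  warnings_ <- character()
  note <- function(w) warnings_ <<- c(warnings_, w)
  withCallingHandlers(
    report <- .runWorkflowImpl(spec, dataset, outputDir, writeOutputs, note),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  report$warnings <- warnings_
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report
}

.runWorkflowImpl <- function(spec, dataset, outputDir, writeOutputs, note) {
  st <- spec$stages
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t, name) timings[[name]] <<- round(
    as.numeric(difftime(Sys.time(), t, units = "secs")), 3)
  set.seed(spec$seed)

  stageFail <- function(name, e, slice = NA)
    stop("stage '", name, "'",
         if (!is.na(slice)) paste0(" (slice ", slice, ")") else "",
         " failed: ", conditionMessage(e), call. = FALSE)

  ps <- if (is(dataset, "ProjectionSet")) dataset else {
    lay <- datasetLayout(spec$input$container, spec$input$data,
                         spec$input$white, spec$input$dark, spec$input$theta)
    readProjectionSet(dataset, lay)
  }
  geom <- ps@geometry
  metrics <- list()

  ## --- flat fielding -------------------------------------------------
  t <- tic()
  fcfg <- st$flat
  stack <- tryCatch(
    flatFieldStack(ps, method = fcfg$method, nComponents = fcfg$n_components,
                   estimationRegion = fcfg$estimation_region,
                   epsFactor = fcfg$eps_factor, clipMax = fcfg$clip_max),
    error = function(e) stageFail("flat", e))
  toc(t, "flat")
  curAngles <- geom@angles
  curAxis <- geom@axisPosition
  p <- geom@pixelSize

  ## --- geometry: axis assessment + stitching -------------------------
  if (!is.null(st$geometry)) {
    t <- tic()
    gcfg <- st$geometry
    if (identical(gcfg$axis, "auto")) {
      idx <- .pairIndices(curAngles)
      est <- tryCatch(
        estimateAxisPosition(stack[idx[1L], , ], stack[idx[2L], , ]),
        error = function(e) stageFail("geometry", e))
      curAxis <- as.numeric(est)
      metrics$axis_estimate <- curAxis
      metrics$axis_peak_correlation <- attr(est, "peak")
    } else {
      curAxis <- as.numeric(gcfg$axis)
      metrics$axis_estimate <- curAxis
    }
    if (geom@scanMode == "full_turn_360_offset") {
      h <- dim(stack)[2L]
      stitched <- NULL
      for (r in seq_len(h)) {
        sg <- sinogram(stack[, r, ], curAngles, curAxis, p)
        sg2 <- tryCatch(stitchHalfAcquisition(sg, blend = gcfg$overlap_blend),
                        error = function(e) stageFail("geometry", e, r - 1L))
        if (is.null(stitched))
          stitched <- array(0, c(nrow(sg2@values), h, ncol(sg2@values)))
        stitched[, r, ] <- sg2@values
        if (r == h) {
          curAngles <- sg2@angles
          curAxis <- sg2@axisPosition
        }
      }
      stack <- stitched
      metrics$stitched_width <- dim(stack)[3L]
    }
    toc(t, "geometry")
  } else if (geom@scanMode == "full_turn_360_offset") {
    stop("a full-turn offset scan requires a 'geometry' stage for stitching")
  }
  gWork <- geometry(geom@energy, p, geom@distance, curAngles,
                    detectorWidth = dim(stack)[3L], axisPosition = curAxis,
                    scanMode = "half_turn_180")
  gList <- list(angles = curAngles, pixelSize = p)

  ## --- ring removal (pre) --------------------------------------------
  ringCfg <- st$ring
  if (!is.null(ringCfg) && ringCfg$method != "none" &&
      ringCfg$placement %in% c("pre_phase", "both")) {
    t <- tic()
    stack <- tryCatch(.applyRing(stack, gList, ringCfg, curAxis),
                      error = function(e) stageFail("ring", e))
    toc(t, "ring_pre")
  }

  ## --- phase retrieval ------------------------------------------------
  quantity <- "attenuation_coefficient"
  pcfg <- st$phase
  if (!is.null(pcfg) && pcfg$method != "none") {
    t <- tic()
    cfg <- retrievalConfig(method = pcfg$method,
                           deltaBetaRatio = pcfg$delta_beta_ratio,
                           regularization = pcfg$regularization,
                           responseClamp = pcfg$response_clamp,
                           padding = pcfg$padding)
    np <- dim(stack)[1L]
    for (i in seq_len(np)) {
      img <- matrix(stack[i, , ], dim(stack)[2L], dim(stack)[3L])
      out <- tryCatch(
        if (pcfg$method == "paganin")
          paganinRetrieve(img, gWork, cfg, mu = pcfg$mu,
                          delta = pcfg$delta)$pseudoAbsorption
        else ctfRetrieve(img, gWork, cfg),
        error = function(e) stageFail("phase", e, i - 1L))
      stack[i, , ] <- out
    }
    quantity <- "delta"
    toc(t, "phase")
  }

  ## --- ring removal (post) --------------------------------------------
  if (!is.null(ringCfg) && ringCfg$method != "none" &&
      ringCfg$placement %in% c("post_phase", "both")) {
    t <- tic()
    stack <- tryCatch(.applyRing(stack, gList, ringCfg, curAxis),
                      error = function(e) stageFail("ring", e))
    toc(t, "ring_post")
  }

  ## --- reconstruction --------------------------------------------------
  t <- tic()
  rcfg <- st$recon
  h <- dim(stack)[2L]
  sliceRows <- spec$slices
  if (identical(sliceRows, "middle")) sliceRows <- (h - 1L) %/% 2L
  sliceRows <- as.integer(sliceRows)
  if (any(sliceRows < 0L | sliceRows > h - 1L))
    stop("stage 'recon' failed: slice index outside [0, ", h - 1L, "]")
  outDir <- if (!is.null(outputDir)) outputDir else spec$output$dir
  if (writeOutputs) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  slices <- list()
  paths <- character()
  for (r in sliceRows) {
    sg <- sinogram(stack[, r + 1L, ], curAngles, curAxis, p)
    sl <- tryCatch(
      if (rcfg$algorithm == "fbp")
        fbp(sg, filterName = rcfg$filter, quantity = quantity,
            outputSize = rcfg$output_size, supersample = rcfg$supersample)
      else
        sirt(sg, nIterations = rcfg$iterations, nonneg = isTRUE(rcfg$nonneg),
             quantity = quantity, outputSize = rcfg$output_size,
             supersample = rcfg$supersample),
      error = function(e) stageFail("recon", e, r))
    slices[[as.character(r)]] <- sl
    if (writeOutputs) {
      f <- file.path(outDir, sprintf("slice_%04d.tif", r))
      writeSlice(sl, f)
      paths <- c(paths, f)
    }
  }
  toc(t, "recon")

  report <- list(
    stages = lapply(spec$stages, function(s) s[!vapply(s, is.null, TRUE)]),
    slices_reconstructed = sliceRows,
    metrics = metrics,
    timings_s = timings,
    slices = slices,
    output_files = paths,
    output_md5 = if (length(paths)) as.list(tools::md5sum(paths)) else list()
  )
  class(report) <- c("runReport", "list")
  if (writeOutputs) {
    serializeWorkflow(spec, file.path(outDir, "workflow_expanded.yaml"))
    rep2 <- report
    rep2$slices <- NULL
    yaml::write_yaml(rep2, file.path(outDir, "run_report.yaml"))
  }
  report
}

#' @export
print.runReport <- function(x, ...) {
  cat("Workflow run:", length(x$stages), "stage(s),",
      length(x$slices_reconstructed), "slice(s)\n")
  cat("  stages:", paste(names(x$stages), collapse = " -> "), "\n")
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  for (nm in names(x$timings_s))
    cat(sprintf("  %-10s %8.3f s\n", nm, x$timings_s[[nm]]))
  invisible(x)
}

#' Apply one workflow to a sequence of datasets
#'
#' Batch counterpart of [runWorkflow()]: each dataset is processed
#' independently, a failure in one does not abort the rest, and a
#' summary table is attached.
#'
#' @param spec a \code{"WorkflowSpec"}.
#' @param datasetPaths character vector (or list) of dataset paths /
#'   [ProjectionSet-class] objects; must be non-empty.
#' @param outputDirs optional per-dataset output directories.
#' @return list of run reports (a failed run holds the error message);
#'   attribute \code{"summary"} is a data.frame of per-dataset status.
#' @export
runBatch <- function(spec, datasetPaths, outputDirs = NULL) {
  if (length(datasetPaths) < 1L) stop("at least one dataset is required")
  if (is.character(datasetPaths)) datasetPaths <- as.list(datasetPaths)
  reports <- vector("list", length(datasetPaths))
  status <- character(length(datasetPaths))
  for (i in seq_along(datasetPaths)) {
    od <- if (!is.null(outputDirs)) outputDirs[[i]] else
      file.path(spec$output$dir, sprintf("dataset_%02d", i))
    reports[[i]] <- tryCatch({
      r <- runWorkflow(spec, datasetPaths[[i]], outputDir = od)
      status[i] <- "ok"
      r
    }, error = function(e) {
      status[i] <<- "failed"
      structure(list(error = conditionMessage(e)), class = "runReport")
    })
  }
  attr(reports, "summary") <- data.frame(
    dataset = seq_along(datasetPaths), status = status,
    stringsAsFactors = FALSE)
  reports
}
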