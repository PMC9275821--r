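# Mesh and table I/O: ASCII OBJ/PLY with a chart sidecar CSV, and tidy CSV
# helpers shared by the pipeline runner.

#' Write and read tube surfaces
#'
#' Meshes are written as ASCII OBJ or PLY (chosen from the file
#' extension); the chart travels in a sidecar CSV `<path>.chart.csv` with
#' columns `vertex_id`, `s`, `phi`. Round-trips preserve vertices, faces
#' and chart to full printed precision.
#'
#' @param surface a [tube_surface()].
#' @param path output file (`.obj` or `.ply`).
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` a
#'   [tube_surface()].
#' @export
write_mesh <- function(surface, path) {
  ext <- tolower(tools::file_ext(path))
  v <- surface$vertices
  f <- surface$faces
  if (ext == "obj") {
    con <- file(path, "w")
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
    close(con)
  } else if (ext == "ply") {
    con <- file(path, "w")
    writeLines(c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    close(con)
  } else {
    stop("unsupported mesh format: ", ext)
  }
  if (!is.null(surface$chart)) {
    utils::write.csv(surface$chart, paste0(path, ".chart.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @param require_chart error if the chart sidecar is missing?
#' @export
read_mesh <- function(path, require_chart = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    if (length(vl) == 0 || length(fl) == 0) {
      stop("malformed OBJ (no vertices or faces): ", path)
    }
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
      as.integer(sub("/.*", "", x[2:4]))
    }))
  } else if (ext == "ply") {
    hdr_end <- which(lines == "end_header")
    if (length(hdr_end) != 1) stop("malformed PLY header: ", path)
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    body <- lines[(hdr_end + 1):length(lines)]
    v <- do.call(rbind, lapply(strsplit(body[seq_len(nv)], "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(body[nv + seq_len(nf)], "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
  } else {
    stop("unsupported mesh format: ", ext)
  }
  chart_path <- paste0(path, ".chart.csv")
  chart <- NULL
  if (file.exists(chart_path)) {
    chart <- tibble::as_tibble(utils::read.csv(chart_path))
  } else if (require_chart) {
    stop("chart required: sidecar not found at ", chart_path)
  }
  tube_surface(v, f, chart)
}

#' Run the analysis pipeline on a synthetic dataset
#'
#' Convenience end-to-end driver: generates a constricting tube, runs the
#' incompressibility analysis, the shear kymograph, the cell-shape
#' pipeline on a synthetic tessellation, and the nuclei-pair analysis, and
#' writes tidy CSV outputs plus a JSON summary. Every stochastic stage is
#' seeded from `config$seed`; reruns with the same config are
#' byte-identical.
#'
#' @param config list with optional entries `seed` (default 1), `out_dir`
#'   (default `tempdir()`), `stages` (subset of
#'   `c("simulate", "kinematics", "shear", "cells", "pairs")`), `tube`
#'   (arguments to [tube_spec()]), `cells` (arguments to
#'   [cell_field_spec()]), `patch_grid` (`c(n_s, n_phi)` bins).
#' @return list of stage results (invisibly writes CSVs and
#'   `summary.json` under `out_dir`).
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempdir()
  stages <- config$stages %||% c("simulate", "kinematics", "shear", "cells", "pairs")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list(seed = seed)
  spec <- do.call(tube_spec, c(config$tube %||% list(), list(seed = seed)))
  seq <- make_constricting_tube(spec)
  res$tube <- seq
  if ("kinematics" %in% stages) {
    pg <- config$patch_grid %||% c(20, 16)
    fields <- incompressibility_fields_sequence(seq, pg[1], pg[2])
    fit <- incompressibility_correlation(fields)
    utils::write.csv(fields, file.path(out_dir, "kinematics_patches.csv"),
                     row.names = FALSE)
    res$kinematics <- fit
  }
  if ("shear" %in% stages) {
    mc <- material_chart(seq)
    ky <- shear_kymograph(seq, mc)
    utils::write.csv(ky, file.path(out_dir, "shear_kymograph.csv"),
                     row.names = FALSE)
    res$shear <- ky
  }
  if ("cells" %in% stages) {
    cspec <- do.call(cell_field_spec, c(config$cells %||% list(),
                                        list(seed = seed + 1L)))
    tess <- make_cell_tessellation(cspec, seq$surfaces[[1]])
    rec <- embed_and_measure(tess$polygons, seq$surfaces[[1]])
    utils::write.csv(rec, file.path(out_dir, "cell_shapes.csv"),
                     row.names = FALSE)
    res$cells <- list(records = rec,
                      mean_aspect = weighted_mean_aspect(rec),
                      se = as.numeric(bootstrap_se(rec$aspect, rec$area,
                                                   seed = seed + 2L)))
  }
  if ("pairs" %in% stages) {
    tracks <- make_nuclei_pairs(seed = seed + 3L)
    pm <- nuclei_pair_motion(tracks)
    utils::write.csv(pm$separation, file.path(out_dir, "pair_separation.csv"),
                     row.names = FALSE)
    res$pairs <- pm
  }
  summary <- list(seed = seed)
  if (!is.null(res$kinematics)) {
    summary$incompressibility_r <- res$kinematics$r
    summary$incompressibility_slope <- res$kinematics$slope
  }
  if (!is.null(res$cells)) summary$mean_cell_aspect <- res$cells$mean_aspect
  if (!is.null(res$pairs)) summary$pair_drift_um_per_h <- res$pairs$rate_um_per_h
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
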