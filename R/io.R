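#' Read and write ROI time-series tables
#'
#' Time series travel as tab-delimited text: a header row of node ids, then
#' one row per volume. `read_timeseries()` validates shape strictly — ragged
#' rows, non-numeric cells, and duplicate node ids are parse errors naming
#' the offending line — and reorders columns to atlas order when an atlas is
#' supplied.
#'
#' @param path File path.
#' @param atlas Optional atlas tibble (`node_id`, `system`); column order of
#'   the result follows it.
#' @return `read_timeseries()`: numeric T x R matrix with node-id column
#'   names. `write_timeseries()`: `path`, invisibly.
#' @export
read_timeseries <- function(path, atlas = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("parse error: need a header row and data rows")
  split <- strsplit(lines, "\t", fixed = TRUE)
  ids <- split[[1]]
  if (anyDuplicated(ids))
    abort("parse error (line 1): duplicate node ids")
  R <- length(ids)
  body <- split[-1]
  n_fields <- lengths(body)
  if (any(n_fields != R)) {
    bad <- which(n_fields != R)[1]
    abort(sprintf("parse error (line %d): %d fields, expected %d",
                  bad + 1, n_fields[bad], R))
  }
  vals <- suppressWarnings(as.numeric(unlist(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(matrix(vals, ncol = R, byrow = TRUE)), arr.ind = TRUE)[1, 1]
    abort(sprintf("parse error (line %d): non-numeric cell", bad + 1))
  }
  m <- matrix(vals, ncol = R, byrow = TRUE, dimnames = list(NULL, ids))
  if (!is.null(atlas)) {
    missing <- setdiff(atlas$node_id, ids)
    if (length(missing) > 0)
      abort(sprintf("atlas nodes missing from file: %s",
                    paste(head(missing, 5), collapse = ", ")))
    m <- m[, atlas$node_id, drop = FALSE]
  }
  m
}

#' @rdname read_timeseries
#' @param ts T x R numeric matrix with node-id column names.
#' @export
write_timeseries <- function(ts, path) {
  ids <- colnames(ts)
  if (is.null(ids)) ids <- node_ids(ncol(ts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  body <- apply(matrix(sprintf("%.17g", ts), nrow(ts)), 1, paste,
                collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read and write atlas mappings (TSV: node_id, system)
#'
#' @param path File path.
#' @return `read_atlas()`: tibble with unique `node_id` and one `system`
#'   per node.
#' @export
read_atlas <- function(path) {
  atlas <- readr::read_tsv(path, col_types = readr::cols(
    node_id = readr::col_character(), system = readr::col_character()))
  if (anyDuplicated(atlas$node_id)) abort("parse error: duplicate node ids in atlas")
  if (anyNA(atlas$system)) abort("parse error: node missing a system label")
  atlas
}

#' @rdname read_atlas
#' @param atlas Atlas tibble.
#' @export
write_atlas <- function(atlas, path) {
  readr::write_tsv(atlas[, c("node_id", "system")], path)
  invisible(path)
}

#' Read and write subject metadata tables (CSV)
#'
#' @param path File path.
#' @return `read_subjects()`: subject tibble as produced by
#'   [simulate_cohort()].
#' @export
read_subjects <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), group = readr::col_character(),
    medication = readr::col_character(), sex = readr::col_character(),
    site = readr::col_character(), .default = readr::col_double()))
}

#' @rdname read_subjects
#' @param subjects Subject tibble.
#' @export
write_subjects <- function(subjects, path) {
  readr::write_csv(subjects, path)
  invisible(path)
}

#' Read and write generator / pipeline configuration as YAML
#'
#' The structured-text dialect for configuration files is YAML.
#'
#' @param path File path.
#' @return `read_synth_config()`: a validated [synth_config()].
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$n_per_group <- unlist(raw$n_per_group)
  raw$switch_rate <- unlist(raw$switch_rate)
  do.call(synth_config, raw)
}

#' @rdname read_synth_config
#' @param config A `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  out <- unclass(config)
  out$n_per_group <- as.list(out$n_per_group)
  out$switch_rate <- as.list(out$switch_rate)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Per-subject time series as tab-delimited text, the subject table as CSV,
#' the atlas as TSV, and the generator configuration as YAML.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$timeseries))
    write_timeseries(cohort$timeseries[[id]],
                     file.path(dir, paste0(id, "_timeseries.tsv")))
  write_subjects(cohort$subjects, file.path(dir, "subjects.csv"))
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  write_synth_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Serialize community assignments
#'
#' Each repetition is written as a compact R x W integer table
#' (`rep###.tsv`, node ids in the first column) next to a `runs.json`
#' metadata record (seed, gamma, omega, quality per repetition).
#'
#' @param detection A `community_detection`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_assignments <- function(detection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(seq_along(detection), function(r) {
    a <- detection[[r]]
    file <- sprintf("rep%03d.tsv", r)
    df <- data.frame(node_id = rownames(a$labels), a$labels,
                     check.names = FALSE)
    names(df)[-1] <- paste0("w", seq_len(ncol(a$labels)))
    readr::write_tsv(df, file.path(dir, file))
    list(file = file, seed = a$seed, quality = a$quality,
         n_communities = a$n_communities)
  })
  jsonlite::write_json(
    list(master_seed = attr(detection, "master_seed"),
         gamma = attr(detection, "gamma"), omega = attr(detection, "omega"),
         runs = meta),
    file.path(dir, "runs.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "runs.json"),
                              simplifyVector = TRUE)
  runs <- lapply(seq_len(nrow(meta$runs)), function(r) {
    df <- readr::read_tsv(file.path(dir, meta$runs$file[r]),
                          col_types = readr::cols(
                            node_id = readr::col_character(),
                            .default = readr::col_integer()))
    lab <- as.matrix(df[, -1])
    rownames(lab) <- df$node_id
    structure(list(labels = lab, quality = meta$runs$quality[r],
                   n_communities = meta$runs$n_communities[r],
                   seed = meta$runs$seed[r]),
              class = "community_assignment")
  })
  structure(runs, class = "community_detection",
            master_seed = meta$master_seed, gamma = meta$gamma,
            omega = meta$omega)
}

#' Serialize a layer stack as plain text
#'
#' The container is a directory with `meta.json` (dimensions, window
#' parameters, FDR level, negative-weight policy) and `edges.csv` (retained
#' edges: `window`, `from`, `to`, `weight`); all non-listed entries are
#' zero. Round-trips exactly through [read_layer_stack()].
#'
#' @param stack A [build_layer_stack()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_layer_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(node_ids = stack$node_ids, n_windows = dim(stack$layers)[3],
         width = stack$width, step = stack$step, alpha = stack$alpha,
         negatives = stack$negatives, n_pairs_tested = stack$n_pairs_tested,
         subject_id = stack$subject_id),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(tidy.layer_stack(stack), file.path(dir, "edges.csv"))
  invisible(dir)
}

#' @rdname write_layer_stack
#' @export
read_layer_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  edges <- readr::read_csv(file.path(dir, "edges.csv"),
                           col_types = readr::cols(
                             window = readr::col_integer(),
                             from = readr::col_character(),
                             to = readr::col_character(),
                             weight = readr::col_double()))
  R <- length(meta$node_ids); W <- meta$n_windows
  layers <- array(0, dim = c(R, R, W))
  retained <- array(FALSE, dim = c(R, R, W))
  if (nrow(edges) > 0) {
    i <- match(edges$from, meta$node_ids)
    j <- match(edges$to, meta$node_ids)
    idx <- cbind(i, j, edges$window)
    layers[idx] <- edges$weight
    layers[idx[, c(2, 1, 3)]] <- edges$weight
    retained[idx] <- TRUE
    retained[idx[, c(2, 1, 3)]] <- TRUE
  }
  win <- sliding_windows(meta$width + (W - 1) * meta$step, meta$width,
                         meta$step)
  structure(list(layers = layers, retained = retained, windows = win,
                 node_ids = meta$node_ids, width = meta$width,
                 step = meta$step, alpha = meta$alpha,
                 negatives = meta$negatives,
                 n_pairs_tested = meta$n_pairs_tested,
                 subject_id = meta$subject_id),
            class = "layer_stack")
}
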