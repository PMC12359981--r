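#' Read and write feature matrices
#'
#' Feature matrices are stored feature-major (features as rows) in
#' CSV/TSV: first column feature ids, header row of observation ids. The
#' delimiter is sniffed from the file extension (`.tsv`/`.txt` tab,
#' otherwise comma). Round-tripping preserves values to better than 1e-12.
#'
#' @param path File path.
#' @param scale Scale tag to attach on read (`"beta"`, `"M"`, `"normal"`).
#' @param matrix A [feature_matrix] to write.
#' @return `read_feature_matrix` returns a [feature_matrix];
#'   `write_feature_matrix` returns `path` invisibly.
#' @export
read_feature_matrix <- function(path, scale = c("beta", "M", "normal")) {
  scale <- match.arg(scale)
  if (!file.exists(path) || file.size(path) == 0) {
    stop_depfdr(sprintf("empty or missing file: %s", path),
                "depfdr_parse_error")
  }
  dt <- data.table::fread(path, sep = io_sep(path), header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2L) {
    stop_depfdr("matrix file needs a feature-id column and >= 1 observation",
                "depfdr_parse_error")
  }
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop_depfdr(sprintf("duplicate feature id: %s", dup), "depfdr_parse_error")
  }
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[-1L], is.numeric, TRUE))[1L] + 1L
    stop_depfdr(sprintf("non-numeric values in column %d", bad),
                "depfdr_parse_error")
  }
  feature_matrix(vals, scale = scale, feature_ids = ids,
                 obs_ids = colnames(dt)[-1L])
}

#' @rdname read_feature_matrix
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- data.frame(feature_id = rownames(matrix),
                   unclass(matrix)[, , drop = FALSE],
                   check.names = FALSE)
  colnames(df) <- c("feature_id", colnames(matrix))
  data.table::fwrite(df, path, sep = io_sep(path))
  invisible(path)
}

io_sep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read and write group labels
#'
#' Two-column TSV/CSV (`observation_id`, `group`). On read, labels are
#' aligned to a matrix's observation ids by id, never by position.
#'
#' @param path File path.
#' @param obs_ids Observation ids (e.g. `colnames(matrix)`) to align to.
#' @param labels A labelled factor/vector to write, named by observation id
#'   or accompanied by `obs_ids`.
#' @return `read_group_labels` returns a factor aligned to `obs_ids`.
#' @export
read_group_labels <- function(path, obs_ids) {
  dt <- data.table::fread(path, sep = io_sep(path), header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2L) {
    stop_depfdr("labels file needs observation_id and group columns",
                "depfdr_parse_error")
  }
  found <- match(obs_ids, as.character(dt[[1L]]))
  if (any(is.na(found))) {
    stop_depfdr(sprintf("observation id %s not found in labels file",
                        obs_ids[which(is.na(found))[1L]]),
                "depfdr_parse_error")
  }
  factor(dt[[2L]][found])
}

#' @rdname read_group_labels
#' @export
write_group_labels <- function(labels, path, obs_ids = names(labels)) {
  if (is.null(obs_ids)) obs_ids <- paste0("obs", seq_along(labels))
  data.table::fwrite(data.frame(observation_id = obs_ids,
                                group = as.character(labels)),
                     path, sep = io_sep(path))
  invisible(path)
}

#' Write a run's provenance block
#'
#' Every analysis run records its resolved configuration, master seed,
#' package version and timestamp as YAML next to its outputs, so any output
#' row can be regenerated from the provenance alone.
#'
#' @param config Named list of resolved settings (an [experiment_spec()]
#'   works directly; dependence configs are flattened).
#' @param path Output file (YAML).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, path) {
  flat <- rapply(unclass(config), f = function(x) x, how = "replace")
  block <- list(
    package = "depfdr",
    version = as.character(utils::packageVersion("depfdr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = flat
  )
  yaml::write_yaml(block, path)
  invisible(path)
}

#' Read an experiment configuration file
#'
#' YAML with the fields of [experiment_spec()]; a `dependence` mapping (with
#' `bin_size`, `corr_range`, `prop_correlated`) is promoted to a
#' [dependence_config()].
#'
#' @param path YAML file path.
#' @return An [experiment_spec()].
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$dependence)) {
    cfg$dependence <- do.call(dependence_config, cfg$dependence)
  }
  do.call(experiment_spec, cfg)
}
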