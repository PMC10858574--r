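#' Read a patient-level CSV
#'
#' Expects a headered CSV with covariate columns `x1..xK` (contiguous
#' numbering from 1) and, for an index-study file, binary columns `trt`
#' and `y`. Missing values anywhere are rejected with the offending row
#' and column named: the methods assume complete data.
#'
#' @param path Path to the CSV file.
#' @param require_outcome If `TRUE`, require `trt` and `y` and return an
#'   `mim_trial`; otherwise return an `mim_target` from the covariate
#'   columns alone.
#' @return An `mim_trial` or `mim_target`.
#' @export
read_patient_csv <- function(path, require_outcome = TRUE) {
  if (!file.exists(path)) {
    stop_mim("mim_io_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path)
  xcols <- paste0("x", seq_len(sum(grepl("^x[0-9]+$", names(df)))))
  if (length(xcols) == 0 || !all(xcols %in% names(df))) {
    stop_mim("mim_io_error",
             "covariate columns x1..xK (contiguous) are required")
  }
  check_cols <- c(xcols, if (require_outcome) c("trt", "y"))
  if (require_outcome && !all(c("trt", "y") %in% names(df))) {
    stop_mim("mim_io_error", "columns trt and y are required")
  }
  for (cl in check_cols) {
    if (!is.numeric(df[[cl]])) {
      stop_mim("mim_io_error",
               sprintf("column %s is not numeric", cl))
    }
    bad <- which(is.na(df[[cl]]))
    if (length(bad) > 0) {
      stop_mim("mim_io_error", sprintf(
        "missing value in column %s, row %d", cl, bad[1]))
    }
  }
  x <- as.matrix(df[xcols])
  if (!require_outcome) {
    return(structure(list(covariates = x), class = "mim_target"))
  }
  if (!all(df$trt %in% c(0, 1))) {
    stop_mim("mim_io_error", "column trt must be binary 0/1")
  }
  if (!all(df$y %in% c(0, 1))) {
    stop_mim("mim_io_error", "column y must be binary 0/1")
  }
  structure(list(covariates = x, treatment = as.integer(df$trt),
                 outcomes = as.integer(df$y)),
            class = "mim_trial")
}

#' Write a patient-level CSV
#'
#' Writes an `mim_trial` as columns `x1..xK, trt, y`, or an `mim_target`
#' as `x1..xK` only, with 15 significant digits so a round trip preserves
#' values.
#'
#' @param x An `mim_trial` or `mim_target`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(x, path) {
  df <- as.data.frame(x$covariates)
  names(df) <- paste0("x", seq_len(ncol(df)))
  if (inherits(x, "mim_trial")) {
    df$trt <- x$treatment
    df$y <- x$outcomes
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 15)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a flat YAML run configuration
#'
#' Reads a flat YAML file whose keys mirror [dgp_config()] and
#' [outcome_model_spec()] arguments plus run settings (`pooling`,
#' `n_boot`, `seed`, ...). Unknown keys are retained for the caller to
#' interpret.
#'
#' @param path Path to the YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_mim("mim_io_error", sprintf("config file not found: %s", path))
  }
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) {
    stop_mim("mim_io_error", "config file must contain a mapping")
  }
  cfg
}

# Machine-readable provenance block attached to CLI outputs.
provenance_block <- function(seed, extra = list()) {
  cfg_json <- jsonlite::toJSON(extra, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(as.character(cfg_json), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  c(list(seed = seed, config_hash = hash,
         package_version = as.character(utils::packageVersion("mimstd"))),
    extra)
}
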