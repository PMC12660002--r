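#' Read a manifest-variable data matrix
#'
#' Delimited text with a header row of variable names and a numeric body.
#' The delimiter is auto-detected (comma vs tab) from the header line.
#' Missing or non-numeric values are a hard error (listwise deletion is
#' deliberately not offered), with the offending row and column named.
#'
#' @param path File path.
#' @return Numeric matrix with column names.
#' @export
read_fa_data <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  x <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (is.null(dim(x))) x <- matrix(x, nrow = nrow(df),
                                   dimnames = list(NULL, names(df)))
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("missing or non-numeric value at row ", bad[1, 1], ", column '",
         colnames(x)[bad[1, 2]], "'", call. = FALSE)
  x
}

#' Read a model specification from a config file
#'
#' YAML or JSON file with keys `m`, `d`, `pattern` (list of 0/1 rows),
#' `identification`, and `mean_structure`, mapped onto [fa_model_spec()].
#'
#' @param path File path (`.yaml`/`.yml` parsed as YAML, `.json` as JSON,
#'   anything else tried as YAML, which subsumes JSON for these files).
#' @return An [fa_model_spec()].
#' @export
read_fa_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$m) || is.null(cfg$d))
    stop("model config must contain 'm' and 'd'", call. = FALSE)
  pattern <- if (!is.null(cfg$pattern))
    do.call(rbind, lapply(cfg$pattern, as.numeric)) else NULL
  fa_model_spec(m = cfg$m, d = cfg$d, pattern = pattern,
                identification = cfg$identification %||%
                  "unit_factor_variance",
                mean_structure = cfg$mean_structure %||% TRUE)
}
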