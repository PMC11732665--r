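# Lossless round-tripping of a cohort as a directory of delimited text
# tables plus a JSON schema/config file. Doubles are written with 17
# significant digits so read-back reproduces them bit-for-bit.

cohort_table_names <- function() {
  c("participants", "influence_trials", "dictator", "mcq", "cyberball",
    "questionnaires", "outcomes", "truth", "scenario_pool")
}

write_table_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Write a synthetic cohort to a directory of text tables
#'
#' Each component table is written as a tab-separated file; column classes
#' and the generating configuration are stored in `schema.json` so
#' [read_cohort()] restores the object losslessly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stop_if_not(inherits(cohort, "synthetic_cohort"), "not a synthetic_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schema <- list(tables = list())
  for (nm in cohort_table_names()) {
    df <- cohort[[nm]]
    write_table_precise(df, file.path(dir, paste0(nm, ".tsv")))
    schema$tables[[nm]] <- as.list(vapply(df, function(col) class(col)[1],
                                          character(1)))
  }
  schema$config <- serialize_config(cohort$config)
  jsonlite::write_json(schema, file.path(dir, "schema.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic cohort back from a directory
#'
#' @param dir directory written by [write_cohort()].
#' @return a `synthetic_cohort`.
#' @export
read_cohort <- function(dir) {
  schema <- jsonlite::read_json(file.path(dir, "schema.json"),
                                simplifyVector = FALSE)
  out <- list()
  for (nm in cohort_table_names()) {
    classes <- unlist(schema$tables[[nm]])
    df <- utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                            header = TRUE, sep = "\t", na.strings = "NA",
                            colClasses = unname(classes),
                            stringsAsFactors = FALSE)
    names(df) <- names(classes)
    out[[nm]] <- df
  }
  out$config <- deserialize_config(schema$config)
  structure(out, class = "synthetic_cohort")
}

# Doubles are stringified at 17 significant digits (JSON numeric output
# would round to 15); names on atomic vectors are preserved by listifying
# (jsonlite drops them otherwise).
serialize_value <- function(x) {
  if (is.list(x)) return(lapply(x, serialize_value))
  if (is.double(x)) {
    s <- sprintf("%.17g", x)
    if (is.null(names(x))) return(as.list(s))
    return(as.list(stats::setNames(s, names(x))))
  }
  if (is.atomic(x)) return(as.list(x))
  x
}

deserialize_value <- function(x) {
  if (!is.list(x)) return(x)
  leaf <- all(vapply(x, function(e) is.atomic(e) && length(e) == 1,
                     logical(1)))
  if (!leaf) return(lapply(x, deserialize_value))
  v <- unlist(x)
  if (is.character(v)) {
    num <- suppressWarnings(as.numeric(v))
    if (!any(is.na(num) & !is.na(v))) return(stats::setNames(num, names(v)))
  }
  v
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$factor_loading_matrix <- list(
    values = as.vector(config$factor_loading_matrix),
    nrow = nrow(config$factor_loading_matrix),
    rownames = as.list(rownames(config$factor_loading_matrix)),
    colnames = as.list(colnames(config$factor_loading_matrix)))
  cfg$questionnaire_scales <- as.list(config$questionnaire_scales)
  lapply(cfg, serialize_value)
}

deserialize_config <- function(cfg) {
  cfg <- lapply(cfg, deserialize_value)
  L <- cfg$factor_loading_matrix
  cfg$factor_loading_matrix <- matrix(
    as.numeric(unlist(L$values)), nrow = as.integer(L$nrow),
    dimnames = list(as.character(unlist(L$rownames)),
                    as.character(unlist(L$colnames))))
  qs <- as.data.frame(cfg$questionnaire_scales, stringsAsFactors = FALSE)
  qs$n_items <- as.integer(qs$n_items)
  qs$factor <- as.integer(qs$factor)
  cfg$questionnaire_scales <- qs
  for (nm in c("n_participants", "n_trials_per_timepoint",
               "n_scenario_pool", "seed")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}
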