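#' Sample-by-metabolite abundance table
#'
#' The central data container of the package: a numeric matrix of abundances
#' (samples in rows, metabolites in columns) together with sample metadata
#' (day after inoculation, biological replicate), metabolite annotation
#' (name, chemical class, identification level), and a processing-stage tag.
#'
#' The stage tag encodes the preprocessing state machine. Stages advance only
#' forward: `raw` -> `normalized` (sample-median normalization) -> `logged`
#' (natural log) -> `scaled` (per-metabolite autoscaling). Each preprocessing
#' function checks the stage of its input, so the chain cannot be applied out
#' of order.
#'
#' @param values Numeric matrix, samples x metabolites.
#' @param samples `data.frame` with columns `sample_id`, `day`, `replicate`.
#' @param metabolites `data.frame` with columns `name`, `class`, `id_level`
#'   (`id_level` one of `"identified"`, `"class-annotated"`, `"unknown"`).
#' @param stage Processing stage, one of `"raw"`, `"normalized"`, `"logged"`,
#'   `"scaled"`.
#' @return An object of class `metab_table`.
#' @export
metab_table <- function(values, samples, metabolites, stage = "raw") {
  values <- as.matrix(values)
  stages <- c("raw", "normalized", "logged", "scaled")
  if (!stage %in% stages) stopf("unknown stage '%s'", stage)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  need_s <- c("sample_id", "day", "replicate")
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) stopf("sample metadata lacks column(s): %s", paste(miss, collapse = ", "))
  need_m <- c("name", "class", "id_level")
  miss <- setdiff(need_m, names(metabolites))
  if (length(miss)) stopf("metabolite annotation lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) {
    stopf("duplicate sample_id: %s",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  if (anyDuplicated(metabolites$name)) {
    stopf("duplicate metabolite name: %s",
          paste(unique(metabolites$name[duplicated(metabolites$name)]), collapse = ", "))
  }
  if (nrow(values) != nrow(samples)) stopf("values has %d rows but %d samples declared",
                                           nrow(values), nrow(samples))
  if (ncol(values) != nrow(metabolites)) stopf("values has %d columns but %d metabolites declared",
                                               ncol(values), nrow(metabolites))
  rownames(values) <- samples$sample_id
  colnames(values) <- metabolites$name
  if (stage == "raw" && any(values[!is.na(values)] < 0)) {
    stopf("raw abundances must be non-negative")
  }
  structure(
    list(values = values, samples = samples, metabolites = metabolites,
         stage = stage, flags = list()),
    class = "metab_table"
  )
}

stage_index <- function(stage) match(stage, c("raw", "normalized", "logged", "scaled"))

require_stage <- function(table, stage, op) {
  if (!inherits(table, "metab_table")) stopf("%s() expects a metab_table", op)
  if (!identical(table$stage, stage)) {
    stopf("%s() requires a table at stage '%s' (got '%s')", op, stage, table$stage)
  }
  invisible(table)
}

#' @export
print.metab_table <- function(x, ...) {
  cat(sprintf("metab_table: %d samples x %d metabolites [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  days: %s\n", paste(sort(unique(x$samples$day)), collapse = ", ")))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf("  missing cells: %d (%.2f%%)\n", nmiss,
                             100 * nmiss / length(x$values)))
  if (length(x$flags$constant_metabolites)) {
    cat(sprintf("  constant metabolites (zeroed at scaling): %d\n",
                length(x$flags$constant_metabolites)))
  }
  invisible(x)
}

#' @export
dim.metab_table <- function(x) dim(x$values)

#' Read a feature table and its metabolite annotation from disk
#'
#' The feature table is CSV with columns `sample_id`, `day`, `replicate`
#' followed by one column per metabolite; the annotation is TSV with columns
#' `metabolite`, `class`, `id_level`. Unparseable or negative abundance cells
#' become missing with a warning.
#'
#' @param path Path to the CSV feature table.
#' @param annotation_path Path to the TSV metabolite annotation.
#' @return A raw-stage [metab_table()].
#' @export
read_feature_table <- function(path, annotation_path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "day", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("feature table lacks mandatory column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stopf("duplicate sample_id in %s: %s", path,
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  day <- suppressWarnings(as.integer(df$day))
  repl <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(day)) stopf("column 'day' is not integer-parseable")
  if (anyNA(repl)) stopf("column 'replicate' is not integer-parseable")
  met_cols <- setdiff(names(df), need)
  vals <- as.matrix(as.data.frame(lapply(df[met_cols], function(col) {
    suppressWarnings(as.numeric(col))
  }), check.names = FALSE))
  orig <- vapply(df[met_cols], as.character, character(nrow(df)))
  if (is.null(dim(orig))) orig <- matrix(orig, nrow = nrow(df))
  empty <- is.na(orig) | trimws(orig) == ""
  unparse <- is.na(vals) & !empty
  if (any(unparse)) warnf("%d unparseable abundance cell(s) set to missing", sum(unparse))
  bad <- !is.na(vals) & vals < 0
  if (any(bad)) {
    warnf("%d negative abundance cell(s) set to missing", sum(bad))
    vals[bad] <- NA_real_
  }

  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need_a <- c("metabolite", "class", "id_level")
  miss <- setdiff(need_a, names(ann))
  if (length(miss)) stopf("annotation lacks column(s): %s", paste(miss, collapse = ", "))
  ann <- ann[match(met_cols, ann$metabolite), , drop = FALSE]
  if (anyNA(ann$metabolite)) stopf("annotation does not cover all metabolites in the table")
  metab_table(
    values = vals,
    samples = data.frame(sample_id = df$sample_id, day = day, replicate = repl,
                         stringsAsFactors = FALSE),
    metabolites = data.frame(name = ann$metabolite, class = ann$class,
                             id_level = ann$id_level, stringsAsFactors = FALSE),
    stage = "raw"
  )
}

#' Write a feature table (and annotation) to disk
#'
#' Inverse of [read_feature_table()]. Values are written at full double
#' precision so a write/read round trip reproduces them exactly.
#'
#' @param table A [metab_table()].
#' @param path Output CSV path for the abundance table.
#' @param annotation_path Optional output TSV path for the annotation.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, annotation_path = NULL) {
  stopifnot(inherits(table, "metab_table"))
  meta <- table$samples[c("sample_id", "day", "replicate")]
  vals <- table$values
  df <- cbind(meta, as.data.frame(apply(vals, 2, full_precision),
                                  check.names = FALSE, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(annotation_path)) {
    ann <- table$metabolites
    names(ann)[names(ann) == "name"] <- "metabolite"
    utils::write.table(ann, annotation_path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
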