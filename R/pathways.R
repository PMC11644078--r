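#' Pathway membership annotation
#'
#' A named collection of metabolite sets (KEGG-style pathways), used by the
#' enrichment and pair-correlation analyses. Sets are stored as character
#' vectors of metabolite names with a one-line description each.
#'
#' @param sets Named list of character vectors (pathway id -> members).
#' @param descriptions Optional named character vector of descriptions.
#' @return An object of class `pathway_annotation`.
#' @export
pathway_annotation <- function(sets, descriptions = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stopf("'sets' must be a non-empty named list")
  }
  if (any(lengths(sets) == 0)) {
    stopf("empty pathway set(s): %s", paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    descriptions[is.na(descriptions)] <- names(sets)[is.na(descriptions)]
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "pathway_annotation")
}

#' @export
print.pathway_annotation <- function(x, ...) {
  cat(sprintf("pathway_annotation: %d sets, sizes %d-%d (median %.0f)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              stats::median(lengths(x$sets))))
  invisible(x)
}

#' Read pathway sets from a GMT-like TSV file
#'
#' Each line is `pathway_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path File path.
#' @return A [pathway_annotation()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("no pathway records in %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stopf("GMT line(s) with fewer than 3 fields: %s",
                      paste(which(bad), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- stats::setNames(vapply(parts, `[[`, character(1), 2), ids)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  pathway_annotation(sets, desc)
}

#' Write pathway sets as a GMT-like TSV file
#'
#' @param annotation A [pathway_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "pathway_annotation"))
  lines <- vapply(names(annotation$sets), function(id) {
    paste(c(id, annotation$descriptions[[id]], annotation$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Apply manual corrections to pathway membership
#'
#' Mirrors the hand-curation step of KEGG-derived metabolite sets: an
#' override table with columns `action` (`add` or `remove`), `pathway_id`,
#' `metabolite` is merged onto the base annotation. Adding to an unknown
#' pathway creates it; class-annotated compounds can thus be placed into
#' class-level pathways.
#'
#' @param annotation A [pathway_annotation()].
#' @param overrides A `data.frame` with columns `action`, `pathway_id`,
#'   `metabolite`, or a path to a TSV file with those columns.
#' @return The corrected [pathway_annotation()].
#' @export
apply_pathway_overrides <- function(annotation, overrides) {
  stopifnot(inherits(annotation, "pathway_annotation"))
  if (is.character(overrides) && length(overrides) == 1L) {
    overrides <- utils::read.delim(overrides, stringsAsFactors = FALSE)
  }
  need <- c("action", "pathway_id", "metabolite")
  miss <- setdiff(need, names(overrides))
  if (length(miss)) stopf("override table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!all(overrides$action %in% c("add", "remove"))) {
    stopf("override action must be 'add' or 'remove'")
  }
  sets <- annotation$sets
  desc <- annotation$descriptions
  for (i in seq_len(nrow(overrides))) {
    act <- overrides$action[i]; pid <- overrides$pathway_id[i]; m <- overrides$metabolite[i]
    if (act == "add") {
      if (is.null(sets[[pid]])) {
        sets[[pid]] <- m
        desc[pid] <- pid
      } else {
        sets[[pid]] <- union(sets[[pid]], m)
      }
    } else {
      if (!is.null(sets[[pid]])) sets[[pid]] <- setdiff(sets[[pid]], m)
    }
  }
  keep <- lengths(sets) > 0
  pathway_annotation(sets[keep], desc[names(sets)[keep]])
}
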