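#' Catalogs of coded model records
#'
#' A catalog is a data frame of coded model records: one row per record with
#' a unique `record_id`, the canonical `code`, and the free-text metadata
#' fields of the national database (`name`, `english_name`,
#' `disease_description`, `cooperation`, `date`, `preservation`,
#' `keywords`). Several records may share one code: classification codes
#' are categories, not identifiers.
#'
#' @param records Data frame with at least `record_id` and `code`; missing
#'   metadata columns are added as empty strings.
#' @param registry Optional `amr_registry`; when given, every code is
#'   validated against it and the first violation raises an error.
#' @return An object of classes `amr_catalog` and `data.frame`.
#' @export
#' @examples
#' cat6 <- amr_catalog(data.frame(record_id = "m1",
#'                                code = "CSTR09:A0101B1111001C01D122"))
#' nrow(cat6)
amr_catalog <- function(records, registry = NULL) {
  stopifnot(is.data.frame(records))
  if (!all(c("record_id", "code") %in% names(records))) {
    stop("records must have columns record_id and code", call. = FALSE)
  }
  records$record_id <- as.character(records$record_id)
  records$code <- canonicalize_code(as.character(records$code))
  if (anyDuplicated(records$record_id)) {
    stop(sprintf("duplicate record_id '%s'",
                 records$record_id[duplicated(records$record_id)][1]),
         call. = FALSE)
  }
  for (f in catalog_metadata_fields()) {
    if (is.null(records[[f]])) records[[f]] <- rep("", nrow(records))
    records[[f]] <- as.character(records[[f]])
  }
  if (!is.null(registry)) {
    for (i in seq_len(nrow(records))) {
      v <- validate_code(registry, records$code[i])
      if (nrow(v)) {
        stop(sprintf("record '%s' has invalid code '%s': %s",
                     records$record_id[i], records$code[i], v$message[1]),
             call. = FALSE)
      }
    }
  }
  keep <- c("record_id", "code", catalog_metadata_fields())
  records <- records[, keep, drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("amr_catalog", "data.frame")
  records
}

catalog_metadata_fields <- function() {
  c("name", "english_name", "disease_description", "cooperation", "date",
    "preservation", "keywords")
}

# Metadata fields matched as substrings vs whole-value equality in the
# keyword baseline (the national database's advanced retrieval).
partial_match_fields <- function() c("name", "english_name", "disease_description")
exact_match_fields <- function() c("cooperation", "date", "preservation")

#' Read and write catalogs
#'
#' Catalogs round-trip through CSV (one header row) and JSON-lines (one
#' object per line) with keys `record_id`, `code`, `name`, `english_name`,
#' `disease_description`, `cooperation`, `date`, `preservation`,
#' `keywords`.
#'
#' @param path File path; format inferred from the extension (`.csv` vs
#'   `.jsonl`/`.ndjson`/`.json`) unless `format` is given.
#' @param format `"csv"`, `"jsonl"`, or `NULL` to infer.
#' @param registry Optional registry for code validation on read.
#' @return `read_catalog()` an `amr_catalog`; `write_catalog()` the path,
#'   invisibly.
#' @export
read_catalog <- function(path, format = NULL, registry = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE))
      "jsonl" else "csv"
  }
  df <- switch(format,
    csv = read.csv(path, colClasses = "character", stringsAsFactors = FALSE),
    jsonl = {
      lines <- readLines(path, encoding = "UTF-8")
      lines <- lines[nzchar(trimws(lines))]
      do.call(rbind, lapply(lines, function(l) {
        as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
      }))
    },
    stop(sprintf("unknown catalog format '%s'", format), call. = FALSE))
  amr_catalog(df, registry = registry)
}

#' @param catalog An `amr_catalog`.
#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path, format = NULL) {
  stopifnot(inherits(catalog, "amr_catalog"))
  if (is.null(format)) {
    format <- if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE))
      "jsonl" else "csv"
  }
  df <- as.data.frame(catalog)
  switch(format,
    csv = write.csv(df, path, row.names = FALSE),
    jsonl = {
      con <- file(path, open = "w", encoding = "UTF-8")
      on.exit(close(con))
      for (i in seq_len(nrow(df))) {
        writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE),
                   con)
      }
    },
    stop(sprintf("unknown catalog format '%s'", format), call. = FALSE))
  invisible(path)
}

#' @export
print.amr_catalog <- function(x, ...) {
  cat("<amr_catalog> ", nrow(x), " records, ",
      length(unique(x$code)), " distinct codes\n", sep = "")
  if (nrow(x)) print(head(as.data.frame(x)[, c("record_id", "code", "name")]))
  invisible(x)
}
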