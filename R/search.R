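#' Code-pattern queries
#'
#' A query pattern constrains each of the four code segments: a segment is
#' either the full wildcard `"*"` or a string of the segment's exact width
#' in which every position is a literal digit or the single-position
#' wildcard `"?"`. A fully literal pattern pins one exact code.
#'
#' @param a,b,c,d Segment patterns (default `"*"`).
#' @param profile `"paper"` (default) or `"extended"`; fixes the segment
#'   widths.
#' @return An object of class `amr_query_pattern`.
#' @export
#' @examples
#' query_pattern(a = "0101", c = "01")
query_pattern <- function(a = "*", b = "*", c = "*", d = "*",
                          profile = c("paper", "extended")) {
  profile <- match.arg(profile)
  widths <- cached_widths(profile)
  pats <- list(A = a, B = b, C = c, D = d)
  for (seg in names(pats)) {
    p <- pats[[seg]]
    if (!is.character(p) || length(p) != 1L) {
      stop(sprintf("pattern for segment %s must be a single string", seg),
           call. = FALSE)
    }
    if (p == "*") next
    if (nchar(p) != widths[[seg]]) {
      stop(sprintf("pattern '%s' for segment %s has width %d, expected %d",
                   p, seg, nchar(p), widths[[seg]]), call. = FALSE)
    }
    if (!grepl("^[0-9?]+$", p)) {
      stop(sprintf("pattern '%s' for segment %s may contain only digits and '?'",
                   p, seg), call. = FALSE)
    }
  }
  structure(list(segments = pats, profile = profile),
            class = "amr_query_pattern")
}

#' @export
print.amr_query_pattern <- function(x, ...) {
  cat("<query pattern> ",
      paste(names(x$segments), unlist(x$segments), sep = "=", collapse = " "),
      " (", x$profile, " profile)\n", sep = "")
  invisible(x)
}

parse_code_bodies <- function(codes, profile) {
  widths <- cached_widths(profile)
  pat <- sprintf("^CSTR09:A([0-9]{%d})B([0-9]{%d})C([0-9]{%d})D([0-9]{%d})$",
                 widths[["A"]], widths[["B"]], widths[["C"]], widths[["D"]])
  m <- regmatches(codes, regexec(pat, codes))
  ok <- lengths(m) == 5L
  segs <- matrix(NA_character_, nrow = length(codes), ncol = 4,
                 dimnames = list(NULL, c("A", "B", "C", "D")))
  segs[ok, ] <- t(vapply(m[ok], function(g) g[2:5], character(4)))
  segs
}

match_segment <- function(values, pattern) {
  if (pattern == "*") return(!is.na(values))
  hit <- !is.na(values)
  chars <- strsplit(pattern, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "?") next
    hit <- hit & substr(values, i, i) == chars[i]
  }
  hit
}

retrieval_result <- function(catalog, idx) {
  ord <- order(catalog$code[idx], catalog$record_id[idx], method = "radix")
  ids <- catalog$record_id[idx][ord]
  structure(list(record_ids = ids, candidate_count = length(ids)),
            class = "amr_retrieval")
}

#' @export
print.amr_retrieval <- function(x, ...) {
  cat("<retrieval result> ", x$candidate_count, " candidate(s)\n", sep = "")
  if (x$candidate_count) {
    print(head(x$record_ids, 20))
    if (x$candidate_count > 20) cat("  ...\n")
  }
  invisible(x)
}

#' Retrieve records by code pattern
#'
#' The code-based retrieval: returns exactly the records whose code matches
#' every literal digit of the pattern, ordered lexicographically by
#' (code, record_id). Records whose code does not parse under the pattern's
#' profile never match.
#'
#' @param catalog An `amr_catalog`.
#' @param pattern An [query_pattern()].
#' @return An `amr_retrieval` with `record_ids` and `candidate_count`.
#' @export
#' @examples
#' cat6 <- amr_catalog(data.frame(
#'   record_id = c("m1", "m2"),
#'   code = c("CSTR09:A0101B1111001C01D122", "CSTR09:A0103B1111001C02D121")))
#' search_by_code_pattern(cat6, query_pattern(a = "0101"))$record_ids
search_by_code_pattern <- function(catalog, pattern) {
  stopifnot(inherits(catalog, "amr_catalog"),
            inherits(pattern, "amr_query_pattern"))
  segs <- parse_code_bodies(catalog$code, pattern$profile)
  hit <- rep(TRUE, nrow(catalog))
  for (seg in c("A", "B", "C", "D")) {
    hit <- hit & match_segment(segs[, seg], pattern$segments[[seg]])
  }
  retrieval_result(catalog, which(hit))
}

# Digit spans of the addressable layers, for neighbor expansion: names are
# "<dimension>.<layer>" (e.g. "A.intermediate", "D.cooperation").
expansion_layers <- function(profile) {
  lays <- profile_layers(profile)
  unlist(lapply(names(lays), function(d) {
    setNames(lapply(lays[[d]], function(l) layer_digit_span(d, l, profile)),
             paste(d, lays[[d]], sep = "."))
  }), recursive = FALSE)
}

#' Relevance expansion around a base code
#'
#' Retrieves the "neighbors" of a coded model: records whose code agrees
#' with `base_code` everywhere except in the varied layers, which are
#' wildcarded. This realizes related-model search by modifying one or
#' several classification or attribute data in the code. Records carrying
#' the base code itself are excluded.
#'
#' @param catalog An `amr_catalog`.
#' @param base_code A valid canonical code (or printed form).
#' @param vary Nonempty character vector of layer identifiers of the form
#'   `"A.intermediate"`, `"B.strain"`, `"C.category"`, `"D.cooperation"`,
#'   ...
#' @return An `amr_retrieval`.
#' @export
#' @examples
#' cat6 <- amr_catalog(data.frame(
#'   record_id = c("m1", "m2"),
#'   code = c("CSTR09:A0101B1111001C01D122", "CSTR09:A0101B1111001C01D312")))
#' neighbor_expansion(cat6, "CSTR09:A0101B1111001C01D122",
#'                    c("D.cooperation", "D.sharing"))$record_ids
neighbor_expansion <- function(catalog, base_code, vary) {
  stopifnot(inherits(catalog, "amr_catalog"))
  if (!length(vary)) stop("vary must be nonempty", call. = FALSE)
  base <- canonicalize_code(base_code)
  segs <- code_segments(sub("^CSTR09:", "", base))
  if (is.null(segs) || !grepl("^CSTR09:", base)) {
    stop(sprintf("invalid base code '%s'", base_code), call. = FALSE)
  }
  profile <- detect_profile(segs)
  if (is.null(profile)) {
    stop(sprintf("base code '%s' matches no profile's segment widths", base_code),
         call. = FALSE)
  }
  spans <- expansion_layers(profile)
  unknown <- setdiff(vary, names(spans))
  if (length(unknown)) {
    stop(sprintf("unknown layer identifier(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(spans), collapse = ", ")), call. = FALSE)
  }
  pats <- segs
  for (v in vary) {
    d <- sub("\\..*$", "", v)
    span <- spans[[v]]
    p <- pats[[d]]
    substr(p, span[1], span[2]) <- strrep("?", span[2] - span[1] + 1L)
    pats[[d]] <- p
  }
  pattern <- query_pattern(a = pats$A, b = pats$B, c = pats$C, d = pats$D,
                           profile = profile)
  segs_all <- parse_code_bodies(catalog$code, profile)
  hit <- catalog$code != base
  for (seg in c("A", "B", "C", "D")) {
    hit <- hit & match_segment(segs_all[, seg], pattern$segments[[seg]])
  }
  retrieval_result(catalog, which(hit))
}

#' Keyword field-AND retrieval (the baseline)
#'
#' Emulates the national database's retrieval: every supplied field must
#' match — as a substring for the long free-text fields (`name`,
#' `english_name`, `disease_description`), as whole-value equality for the
#' short fields (`cooperation`, `date`, `preservation`). Matching is
#' case-sensitive on trimmed values; fields combine with Boolean AND. The
#' result cannot be refined further, which is exactly the inefficiency the
#' code-based retrieval removes.
#'
#' @param catalog An `amr_catalog`.
#' @param field_terms Named list/vector mapping field name to search term.
#' @return An `amr_retrieval`.
#' @export
#' @examples
#' cat1 <- amr_catalog(data.frame(record_id = "m1",
#'                                code = "CSTR09:A0101B1111001C01D122",
#'                                name = "BALB/c myocarditis model"))
#' keyword_search(cat1, list(name = "myocarditis"))$candidate_count
keyword_search <- function(catalog, field_terms) {
  stopifnot(inherits(catalog, "amr_catalog"))
  field_terms <- as.list(field_terms)
  if (!length(field_terms) || is.null(names(field_terms)) ||
      any(!nzchar(names(field_terms)))) {
    stop("field_terms must be a nonempty named list", call. = FALSE)
  }
  known <- c(partial_match_fields(), exact_match_fields())
  unknown <- setdiff(names(field_terms), known)
  if (length(unknown)) {
    stop(sprintf("unknown field(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  hit <- rep(TRUE, nrow(catalog))
  for (f in names(field_terms)) {
    term <- trimws(as.character(field_terms[[f]]))
    values <- trimws(catalog[[f]])
    hit <- hit & if (f %in% partial_match_fields()) {
      grepl(term, values, fixed = TRUE)
    } else {
      values == term
    }
  }
  retrieval_result(catalog, which(hit))
}

#' Benchmark one-shot retrieval: code patterns vs keyword baseline
#'
#' Runs each query of a query set through both retrieval methods and
#' summarizes their one-shot efficiency. A query is a one-shot hit for a
#' method when the method returns exactly the target record as its sole
#' candidate — no secondary visual search needed.
#'
#' @param catalog An `amr_catalog`.
#' @param query_set List of queries, each a list with `target_id`, `terms`
#'   (named list for [keyword_search()]) and `pattern` (an
#'   [query_pattern()]); typically built by [make_query_set()].
#' @return An object of class `amr_benchmark`: per method the one-shot hit
#'   rate and the mean/max candidate-list size, plus `n_queries`. Rates are
#'   `NA` for an empty query set.
#' @export
benchmark_one_shot <- function(catalog, query_set) {
  stopifnot(inherits(catalog, "amr_catalog"))
  n <- length(query_set)
  methods <- c("old_method", "new_method")
  sizes <- matrix(NA_real_, nrow = n, ncol = 2,
                  dimnames = list(NULL, methods))
  hits <- matrix(NA, nrow = n, ncol = 2, dimnames = list(NULL, methods))
  for (i in seq_len(n)) {
    q <- query_set[[i]]
    if (!q$target_id %in% catalog$record_id) {
      stop(sprintf("unknown target record_id '%s'", q$target_id),
           call. = FALSE)
    }
    old <- keyword_search(catalog, q$terms)
    new <- search_by_code_pattern(catalog, q$pattern)
    sizes[i, ] <- c(old$candidate_count, new$candidate_count)
    hits[i, ] <- c(identical(old$record_ids, q$target_id),
                   identical(new$record_ids, q$target_id))
  }
  summarize <- function(j) {
    list(one_shot_rate = if (n) mean(hits[, j]) else NA_real_,
         mean_candidates = if (n) mean(sizes[, j]) else NA_real_,
         max_candidates = if (n) max(sizes[, j]) else NA_real_)
  }
  structure(list(n_queries = n,
                 old_method = summarize("old_method"),
                 new_method = summarize("new_method")),
            class = "amr_benchmark")
}

#' @export
print.amr_benchmark <- function(x, ...) {
  cat("<retrieval benchmark> ", x$n_queries, " queries\n", sep = "")
  cat(sprintf("  %-22s %12s %12s\n", "", "old (keyword)", "new (code)"))
  row <- function(label, f, fmt = "%12.3f") {
    cat(sprintf(paste0("  %-22s ", fmt, " ", fmt, "\n"), label,
                x$old_method[[f]], x$new_method[[f]]))
  }
  row("one-shot hit rate", "one_shot_rate")
  row("mean candidate size", "mean_candidates")
  row("max candidate size", "max_candidates", "%12.0f")
  invisible(x)
}
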