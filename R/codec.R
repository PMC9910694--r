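#' Construct a model record
#'
#' A model record carries the classification label paths along the three
#' trunk dimensions, the essential-attribute values, and free-text metadata.
#' Label paths are given outermost-first and may stop above the deepest
#' layer (the remaining layers encode as the supplementary zeros).
#'
#' @param disease Character vector: disease major, intermediate, optional
#'   minor labels.
#' @param species Character vector: animal major (laboratory animal),
#'   species, optional strain labels.
#' @param modeling Character vector: modeling category, optional subcategory
#'   labels.
#' @param cooperation,sharing,preservation Attribute value labels (see
#'   [amr_attribute_levels()]); `NA` or `"missing"` for a missing attribute.
#' @param metadata Named list of free-text fields (`name`, `english_name`,
#'   `disease_description`, `date`, `keywords`, ...).
#' @return An object of class `amr_record`.
#' @export
#' @examples
#' amr_record(disease = c("cardiovascular disease", "myocarditis"),
#'            species = c("laboratory animal", "mouse", "BALB/c"),
#'            modeling = "spontaneous",
#'            cooperation = "independence", sharing = "free",
#'            preservation = "frozen")
amr_record <- function(disease, species, modeling,
                       cooperation = NA_character_, sharing = NA_character_,
                       preservation = NA_character_, metadata = list()) {
  attr_val <- function(x, which) {
    if (length(x) != 1L) {
      stop(sprintf("%s must be a single value", which), call. = FALSE)
    }
    if (is.na(x)) x <- "missing"
    levels <- amr_attribute_levels()[[which]]
    if (!x %in% names(levels)) {
      stop(sprintf("invalid %s value '%s' (one of: %s)", which, x,
                   paste(names(levels), collapse = ", ")), call. = FALSE)
    }
    x
  }
  structure(list(disease = as.character(disease),
                 species = as.character(species),
                 modeling = as.character(modeling),
                 attributes = list(
                   cooperation = attr_val(cooperation, "cooperation"),
                   sharing = attr_val(sharing, "sharing"),
                   preservation = attr_val(preservation, "preservation")),
                 metadata = metadata),
            class = "amr_record")
}

#' @export
print.amr_record <- function(x, ...) {
  cat("<amr_record>\n")
  cat("  disease:      ", paste(x$disease, collapse = " / "), "\n", sep = "")
  cat("  species:      ", paste(x$species, collapse = " / "), "\n", sep = "")
  cat("  modeling:     ", paste(x$modeling, collapse = " / "), "\n", sep = "")
  cat("  attributes:   ", paste(names(x$attributes),
                                unlist(x$attributes),
                                sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Canonicalize a code string
#'
#' The canonical form is `CSTR09:` followed by the four lettered segments
#' with upper-case letters and no internal whitespace. Printed forms with a
#' space after the colon or lower-case letters are accepted and normalized;
#' canonicalization is idempotent. No structural validation is performed
#' beyond whitespace/case cleanup.
#'
#' @param code_text Character vector of code strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' canonicalize_code("cstr09: A0101B1111001C01D122")
canonicalize_code <- function(code_text) {
  x <- trimws(code_text)
  x <- sub("^([A-Za-z0-9]+):\\s+", "\\1:", x)
  toupper(x)
}

code_segments <- function(body) {
  m <- regexec("^A([0-9]+)B([0-9]+)C([0-9]+)D([0-9]+)$", body)
  g <- regmatches(body, m)[[1]]
  if (!length(g)) return(NULL)
  setNames(as.list(g[2:5]), c("A", "B", "C", "D"))
}

detect_profile <- function(segs) {
  for (p in c("paper", "extended")) {
    w <- cached_widths(p)
    if (all(nchar(unlist(segs)) == w)) return(p)
  }
  NULL
}

split_segment <- function(dimension, segment, profile) {
  lays <- profile_layers(profile)[[dimension]]
  spec <- dim_specs()[[dimension]]
  widths <- spec$layers$width[match(lays, spec$layers$layer)]
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  setNames(substring(segment, starts, ends), lays)
}

#' Encode a model record to its canonical code
#'
#' Resolves the record's label paths in the registry and assembles the
#' canonical code string `CSTR09:A..B..C..D..`. Layers absent from the
#' record encode as the supplementary zeros; under the `"paper"` profile the
#' optional disease-minor and modeling-subcategory layers are not part of
#' the code at all, under `"extended"` they are zero-filled when absent.
#' Missing attributes encode as digit 0.
#'
#' @param registry An `amr_registry`.
#' @param record An [amr_record()].
#' @param profile `"paper"` (default) or `"extended"`.
#' @return The canonical code string.
#' @export
#' @examples
#' reg <- amr_fixture_registry()
#' rec <- amr_record(c("cardiovascular disease", "myocarditis"),
#'                   c("laboratory animal", "mouse", "BALB/c"),
#'                   "spontaneous", "independence", "free", "frozen")
#' encode_record(reg, rec)  # "CSTR09:A0101B1111001C01D122"
encode_record <- function(registry, record, profile = c("paper", "extended")) {
  profile <- match.arg(profile)
  stopifnot(inherits(record, "amr_record"))
  lays <- profile_layers(profile)
  specs <- registry$dimensions
  trunk_part <- function(dimension, labels) {
    layers <- lays[[dimension]]
    if (length(labels) > length(layers)) {
      stop(sprintf("dimension %s path has %d layers but the %s profile encodes only %s",
                   dimension, length(labels), profile,
                   paste(layers, collapse = "+")), call. = FALSE)
    }
    codes <- resolve_label_path(registry, dimension, labels)
    ldf <- specs[[dimension]]$layers
    widths <- ldf$width[match(layers, ldf$layer)]
    fill <- vapply(widths, zero_code, character(1))
    fill[seq_along(codes)] <- codes
    paste(fill, collapse = "")
  }
  levels <- amr_attribute_levels()
  d_part <- paste(vapply(names(levels), function(a) {
    as.character(levels[[a]][[record$attributes[[a]]]])
  }, character(1)), collapse = "")
  paste0("CSTR09:",
         "A", trunk_part("A", record$disease),
         "B", trunk_part("B", record$species),
         "C", trunk_part("C", record$modeling),
         "D", d_part)
}

#' Decode a code string to its classification and attributes
#'
#' Parses and canonicalizes `code_text`, resolves every trunk segment to
#' registry labels and every attribute digit to its value, and returns the
#' record skeleton. `decode_code(encode_record(r))` reproduces `r`'s
#' classification and attributes exactly. An extended-profile code whose
#' minor/subcategory segments are all zeros decodes against a paper-profile
#' registry by dropping them.
#'
#' @inheritParams encode_record
#' @param code_text One code string.
#' @return An [amr_record()] (metadata empty) with an attribute `profile`.
#' @export
#' @examples
#' reg <- amr_fixture_registry()
#' decode_code(reg, "CSTR09: A0103B1111001C02D311")$disease
decode_code <- function(registry, code_text) {
  stopifnot(length(code_text) == 1L)
  x <- canonicalize_code(code_text)
  if (!startsWith(x, "CSTR09:")) {
    stop(sprintf("code '%s' lacks the 'CSTR09:' identification prefix",
                 code_text), call. = FALSE)
  }
  segs <- code_segments(sub("^CSTR09:", "", x))
  if (is.null(segs)) {
    stop(sprintf("code '%s' does not match A<digits>B<digits>C<digits>D<digits>",
                 code_text), call. = FALSE)
  }
  profile <- detect_profile(segs)
  if (is.null(profile)) {
    stop(sprintf("code '%s' matches no profile's segment widths", code_text),
         call. = FALSE)
  }
  trunk_labels <- function(dimension) {
    parts <- split_segment(dimension, segs[[dimension]], profile)
    keep <- !vapply(parts, is_all_zero, logical(1))
    labs <- character(0)
    if (any(keep)) {
      node <- lookup_by_code(registry, dimension, parts[seq_len(max(which(keep)))])
      labs <- node$labels
    }
    labs
  }
  levels <- amr_attribute_levels()
  digits <- as.integer(strsplit(segs$D, "")[[1]])
  attrs <- lapply(seq_along(levels), function(i) {
    if (!digits[i] %in% levels[[i]]) {
      stop(sprintf("invalid %s digit %d in '%s'", names(levels)[i],
                   digits[i], code_text), call. = FALSE)
    }
    names(levels[[i]])[match(digits[i], levels[[i]])]
  })
  rec <- amr_record(disease = trunk_labels("A"), species = trunk_labels("B"),
                    modeling = trunk_labels("C"),
                    cooperation = attrs[[1]], sharing = attrs[[2]],
                    preservation = attrs[[3]])
  attr(rec, "profile") <- profile
  rec
}

#' Validate a code string
#'
#' Checks a code string against the grammar and the registry and returns all
#' violations as data, not as errors: the identification prefix, the segment
#' grammar and widths, every nonzero trunk code's presence in the registry,
#' zero-layer placement, and the attribute digit ranges.
#'
#' @inheritParams encode_record
#' @param code_text One code string.
#' @return Data frame with columns `component`, `layer`, `message`; zero
#'   rows for a valid code.
#' @export
#' @examples
#' reg <- amr_fixture_registry()
#' nrow(validate_code(reg, "CSTR09:A0101B1111001C01D122"))  # 0
#' validate_code(reg, "CSTR08:A0101B1111001C01D122")$component
validate_code <- function(registry, code_text) {
  stopifnot(length(code_text) == 1L)
  viol <- function(component, layer, message) {
    data.frame(component = component, layer = layer, message = message,
               stringsAsFactors = FALSE)
  }
  out <- empty_viol <- viol(character(0), character(0), character(0))
  x <- canonicalize_code(code_text)
  m <- regexec("^([A-Z0-9]+):(.*)$", x)
  g <- regmatches(x, m)[[1]]
  if (!length(g)) {
    return(viol("identification", NA_character_,
                sprintf("code '%s' lacks the 'CSTR09:' identification prefix", code_text)))
  }
  if (g[2] != "CSTR09") {
    out <- rbind(out, viol("identification", NA_character_,
                           sprintf("identification code is '%s', expected 'CSTR09'", g[2])))
  }
  segs <- code_segments(g[3])
  if (is.null(segs)) {
    return(rbind(out, viol("grammar", NA_character_,
                           sprintf("body '%s' does not match A<digits>B<digits>C<digits>D<digits>", g[3]))))
  }
  profile <- detect_profile(segs)
  if (is.null(profile)) {
    w <- cached_widths("paper")
    bad <- names(segs)[nchar(unlist(segs)) != w]
    return(rbind(out, viol(bad, NA_character_,
                           sprintf("segment %s has width %d, expected %d (paper profile) ",
                                   bad, nchar(unlist(segs))[nchar(unlist(segs)) != w],
                                   w[bad]))))
  }
  for (dimension in c("A", "B", "C")) {
    parts <- split_segment(dimension, segs[[dimension]], profile)
    res <- tryCatch(lookup_by_code(registry, dimension, parts),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out <- rbind(out, viol(dimension, NA_character_, conditionMessage(res)))
    }
  }
  levels <- amr_attribute_levels()
  digits <- as.integer(strsplit(segs$D, "")[[1]])
  for (i in seq_along(levels)) {
    if (!digits[i] %in% levels[[i]]) {
      out <- rbind(out, viol("D", names(levels)[i],
                             sprintf("invalid %s digit %d (allowed: %s)",
                                     names(levels)[i], digits[i],
                                     paste(sort(unname(levels[[i]])), collapse = ", "))))
    }
  }
  out
}

#' Parse a national science-and-technology resource identifier
#'
#' National identifiers have the form
#' `resource:institution.type.unit` with component widths 4, 5, 2 and 10
#' characters (21 content characters in total), e.g.
#' `CSTR:16397.09.0C01001234`.
#'
#' @param text One identifier string.
#' @return An object of class `amr_national_id` with fields
#'   `resource_code`, `institution_code`, `resource_type`, `unit_code`.
#' @export
#' @examples
#' id <- parse_national_identifier("CSTR:16397.09.0C01001234")
#' id$institution_code
#' format(id)
parse_national_identifier <- function(text) {
  stopifnot(length(text) == 1L)
  x <- trimws(text)
  m <- regexec("^([^:.]+):([^.]+)\\.([^.]+)\\.([^.]+)$", x)
  g <- regmatches(x, m)[[1]]
  if (!length(g)) {
    stop(sprintf("'%s' is not of the form resource:institution.type.unit", text),
         call. = FALSE)
  }
  widths <- c(resource_code = 4L, institution_code = 5L, resource_type = 2L,
              unit_code = 10L)
  parts <- setNames(as.list(g[2:5]), names(widths))
  got <- nchar(unlist(parts))
  bad <- got != widths
  if (any(bad)) {
    stop(sprintf("component %s has width %d, expected %d",
                 names(widths)[bad][1], got[bad][1], widths[bad][1]),
         call. = FALSE)
  }
  structure(parts, class = "amr_national_id")
}

#' @export
format.amr_national_id <- function(x, ...) {
  paste0(x$resource_code, ":", x$institution_code, ".", x$resource_type,
         ".", x$unit_code)
}

#' @export
print.amr_national_id <- function(x, ...) {
  cat("<national identifier> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Combinatorial capacity of a flat classification
#'
#' Number of leaf cells a purely combinatorial classification admits: the
#' product of the per-dimension category counts. With 10 disease majors, 6
#' species and 3 modeling methods a flat three-dimension classification
#' yields at most 180 cells — the motivation for subdividing each dimension
#' into more layers.
#'
#' @param major_counts Vector of positive integer category counts.
#' @return The product, as a double (counts can overflow integer range).
#' @export
#' @examples
#' combinatorial_capacity(c(10, 6, 3))  # 180
combinatorial_capacity <- function(major_counts) {
  if (!length(major_counts)) {
    stop("major_counts must be non-empty", call. = FALSE)
  }
  counts <- as.numeric(major_counts)
  if (any(is.na(counts)) || any(counts < 1) || any(counts != floor(counts))) {
    stop("major_counts must be positive integers", call. = FALSE)
  }
  prod(counts)
}
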