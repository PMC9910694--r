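#' Dimension specifications of the coding scheme
#'
#' The code body has four lettered parts. A, B and C are the trunk: layered
#' hierarchies of system disease (major, intermediate, optional minor),
#' animal species (major, species, strain) and modeling method (category,
#' optional subcategory). D is the branch: three parallel one-digit
#' essential-attribute positions (cooperation, sharing, preservation). Each
#' layer has a fixed zero-padded digit width; the all-zeros code of a layer
#' is reserved as the supplementary "empty" code and never carries a label.
#'
#' @return Named list of four dimension specs (`A`, `B`, `C`, `D`), each with
#'   `letter`, `name`, `trunk` flag and a `layers` data frame of
#'   `layer`, `width`, `optional`.
#' @export
#' @examples
#' amr_dimension_specs()$A$layers
amr_dimension_specs <- function() {
  layer_df <- function(layer, width, optional) {
    data.frame(layer = layer, width = width, optional = optional,
               stringsAsFactors = FALSE)
  }
  list(
    A = list(letter = "A", name = "system disease", trunk = TRUE,
             layers = layer_df(c("major", "intermediate", "minor"),
                               c(2L, 2L, 2L), c(FALSE, FALSE, TRUE))),
    B = list(letter = "B", name = "animal species", trunk = TRUE,
             layers = layer_df(c("major", "species", "strain"),
                               c(2L, 2L, 3L), c(FALSE, FALSE, FALSE))),
    C = list(letter = "C", name = "modeling method", trunk = TRUE,
             layers = layer_df(c("category", "subcategory"),
                               c(2L, 2L), c(FALSE, TRUE))),
    D = list(letter = "D", name = "essential attributes", trunk = FALSE,
             layers = layer_df(c("cooperation", "sharing", "preservation"),
                               c(1L, 1L, 1L), c(FALSE, FALSE, FALSE)))
  )
}

#' Essential-attribute digit vocabularies
#'
#' Positional one-digit vocabularies of the branch (D) part. Digit 0 is the
#' supplementary code for a missing attribute in every position.
#'
#' @return Named list mapping each attribute to a named integer vector of
#'   digit values (names are the attribute value labels).
#' @export
#' @examples
#' amr_attribute_levels()$cooperation
amr_attribute_levels <- function() {
  list(
    cooperation  = c(missing = 0L, independence = 1L, cooperation = 2L,
                     outsourcing = 3L),
    sharing      = c(missing = 0L, paid = 1L, free = 2L),
    preservation = c(missing = 0L, live = 1L, frozen = 2L)
  )
}

# Cached copies of the (immutable) dimension specs and per-profile segment
# widths, so hot codec paths don't rebuild data frames.
dim_specs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- amr_dimension_specs()
    cache
  }
})

cached_widths <- local({
  cache <- list()
  function(profile) {
    if (is.null(cache[[profile]])) cache[[profile]] <<- profile_widths(profile)
    cache[[profile]]
  }
})

# Which layers of each dimension a profile encodes. The paper profile codes
# A major+intermediate, B all three, C category, D all three; the extended
# profile adds the optional A minor and C subcategory layers (00-filled when
# absent).
profile_layers <- function(profile = c("paper", "extended")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    list(A = c("major", "intermediate"),
         B = c("major", "species", "strain"),
         C = "category",
         D = c("cooperation", "sharing", "preservation"))
  } else {
    list(A = c("major", "intermediate", "minor"),
         B = c("major", "species", "strain"),
         C = c("category", "subcategory"),
         D = c("cooperation", "sharing", "preservation"))
  }
}

# Segment widths (total digits per lettered part) for a profile.
profile_widths <- function(profile = c("paper", "extended")) {
  profile <- match.arg(profile)
  specs <- dim_specs()
  lays <- profile_layers(profile)
  vapply(names(lays), function(d) {
    ldf <- specs[[d]]$layers
    sum(ldf$width[ldf$layer %in% lays[[d]]])
  }, integer(1))
}

# Digit offsets of one layer inside its segment, for a profile.
# Returns c(start, end), 1-based within the segment.
layer_digit_span <- function(dimension, layer, profile = "paper") {
  specs <- dim_specs()
  lays <- profile_layers(profile)[[dimension]]
  if (is.null(lays) || !(layer %in% lays)) {
    stop(sprintf("layer '%s' is not encoded in dimension %s under the %s profile",
                 layer, dimension, profile), call. = FALSE)
  }
  ldf <- specs[[dimension]]$layers
  widths <- ldf$width[match(lays, ldf$layer)]
  i <- match(layer, lays)
  start <- if (i == 1L) 1L else sum(widths[seq_len(i - 1L)]) + 1L
  c(start, start + widths[i] - 1L)
}

zero_code <- function(width) strrep("0", width)

is_all_zero <- function(code) grepl("^0+$", code)
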