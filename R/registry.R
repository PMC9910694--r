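#' @title Taxonomy registry
#' @description
#' An `amr_registry` holds the controlled vocabulary of the coding scheme:
#' one labeled node per (dimension, layer, parent, code). Codes are
#' zero-padded digit strings of the layer's width; the all-zeros code is
#' reserved as the supplementary "empty" code and can never be assigned to a
#' labeled node. Within one parent both codes and labels are unique.
#' @name amr_registry
NULL

new_registry <- function(nodes = empty_nodes()) {
  structure(list(dimensions = dim_specs(), nodes = nodes),
            class = "amr_registry")
}

empty_nodes <- function() {
  df <- data.frame(dimension = character(), layer = character(),
                   parent_path = character(), label = character(),
                   code = character(), provenance = character(),
                   label_path = character(), stringsAsFactors = FALSE)
  # full label vector per node, kept separately because labels themselves
  # may contain the "/" path separator (e.g. the BALB/c strain)
  df$labels <- I(list())
  df
}

path_depth <- function(path) {
  ifelse(path == "", 0L, lengths(strsplit(path, "/", fixed = TRUE)))
}

join_path <- function(parent_path, label) {
  ifelse(parent_path == "", label, paste(parent_path, label, sep = "/"))
}

# Validate and append one node row; returns the updated registry.
# Trunk layers must nest (parent at the layer above); D layers are parallel
# with an empty parent path.
add_node <- function(registry, dimension, layer, parent_path, label, code,
                     provenance = "stated") {
  spec <- registry$dimensions[[dimension]]
  if (is.null(spec)) {
    stop(sprintf("unknown dimension '%s'", dimension), call. = FALSE)
  }
  ldf <- spec$layers
  li <- match(layer, ldf$layer)
  if (is.na(li)) {
    stop(sprintf("unknown layer '%s' for dimension %s", layer, dimension),
         call. = FALSE)
  }
  width <- ldf$width[li]
  if (!grepl("^[0-9]+$", code) || nchar(code) != width) {
    stop(sprintf("code '%s' does not match width %d of %s/%s",
                 code, width, dimension, layer), call. = FALSE)
  }
  if (is_all_zero(code)) {
    stop(sprintf("code '%s' is the reserved supplementary code of %s/%s and cannot label a node",
                 code, dimension, layer), call. = FALSE)
  }
  parent_labels <- character(0)
  if (spec$trunk) {
    if (li == 1L && parent_path != "") {
      stop(sprintf("top layer '%s' of %s takes no parent path", layer,
                   dimension), call. = FALSE)
    }
    if (li > 1L) {
      nd <- registry$nodes
      hit <- which(nd$dimension == dimension & nd$layer == ldf$layer[li - 1L] &
                     nd$label_path == parent_path)
      if (!length(hit)) {
        stop(sprintf("unknown parent path '%s' for %s/%s node '%s'",
                     parent_path, dimension, layer, label), call. = FALSE)
      }
      parent_labels <- nd$labels[[hit[1]]]
    }
  } else if (parent_path != "") {
    stop(sprintf("branch dimension %s layers take no parent path", dimension),
         call. = FALSE)
  }
  sib <- registry$nodes[registry$nodes$dimension == dimension &
                          registry$nodes$layer == layer &
                          registry$nodes$parent_path == parent_path, ,
                        drop = FALSE]
  if (code %in% sib$code) {
    stop(sprintf("duplicate code '%s' under %s/%s parent '%s'",
                 code, dimension, layer, parent_path), call. = FALSE)
  }
  if (label %in% sib$label) {
    stop(sprintf("duplicate label '%s' under %s/%s parent '%s'",
                 label, dimension, layer, parent_path), call. = FALSE)
  }
  row <- data.frame(dimension = dimension, layer = layer,
                    parent_path = parent_path, label = label, code = code,
                    provenance = provenance,
                    label_path = join_path(parent_path, label),
                    stringsAsFactors = FALSE)
  row$labels <- I(list(c(parent_labels, label)))
  registry$nodes <- rbind(registry$nodes, row)
  registry
}

#' Load a taxonomy registry from tabular or structured-document rows
#'
#' Accepts a tab-separated file (columns `dimension`, `layer`, `parent_path`,
#' `label`, `code`, optional `provenance`), a YAML file holding the same rows
#' as a list of mappings, or an equivalent data frame. Parents must appear
#' before their children. Rows with an empty `code` receive the next
#' incremental code under their parent (see [assign_next_code()]).
#'
#' @param source Path to a `.tsv`/`.tab` or `.yml`/`.yaml` file, or a data
#'   frame of rows.
#' @param format `"tsv"`, `"yaml"`, or `NULL` to infer from the file
#'   extension.
#' @return An `amr_registry`.
#' @export
#' @examples
#' reg <- load_registry(data.frame(
#'   dimension = "A", layer = "major", parent_path = "",
#'   label = "cardiovascular disease", code = "01"))
#' registry_stats(reg)
load_registry <- function(source, format = NULL) {
  if (is.character(source) && length(source) == 1L) {
    if (is.null(format)) {
      format <- if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) "yaml" else "tsv"
    }
    rows <- switch(format,
      tsv = read.delim(source, colClasses = "character",
                       stringsAsFactors = FALSE),
      yaml = {
        lst <- yaml::read_yaml(source)
        do.call(rbind, lapply(lst, function(r) {
          data.frame(dimension = r$dimension, layer = r$layer,
                     parent_path = if (is.null(r$parent_path)) "" else r$parent_path,
                     label = r$label,
                     code = if (is.null(r$code)) "" else as.character(r$code),
                     provenance = if (is.null(r$provenance)) "stated" else r$provenance,
                     stringsAsFactors = FALSE)
        }))
      },
      stop(sprintf("unknown registry format '%s'", format), call. = FALSE))
  } else if (is.data.frame(source)) {
    rows <- source
  } else {
    stop("source must be a file path or a data frame", call. = FALSE)
  }
  needed <- c("dimension", "layer", "parent_path", "label")
  miss <- setdiff(needed, names(rows))
  if (length(miss)) {
    stop(sprintf("registry rows lack column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (is.null(rows$code)) rows$code <- rep("", nrow(rows))
  if (is.null(rows$provenance)) rows$provenance <- rep("stated", nrow(rows))
  rows$parent_path[is.na(rows$parent_path)] <- ""
  rows$code[is.na(rows$code)] <- ""
  registry <- new_registry()
  for (i in seq_len(nrow(rows))) {
    code <- rows$code[i]
    if (code == "") {
      code <- assign_next_code(registry, rows$dimension[i],
                               rows$parent_path[i], layer = rows$layer[i])
    }
    registry <- add_node(registry, rows$dimension[i], rows$layer[i],
                         rows$parent_path[i], rows$label[i], code,
                         rows$provenance[i])
  }
  registry
}

#' Bundled reference registry
#'
#' Loads the registry of classification nodes shipped with the package: the
#' 16 system-disease major categories, the cardiovascular intermediate
#' categories, the laboratory-animal species and strains, the three modeling
#' methods, and the essential-attribute vocabularies. Nodes whose codes are
#' inferred from printed full codes rather than stated directly carry
#' `provenance = "inferred"`.
#'
#' @param format `"tsv"` (default) or `"yaml"`; both bundled forms load to
#'   the same registry.
#' @return An `amr_registry`.
#' @export
#' @examples
#' reg <- amr_fixture_registry()
#' registry_stats(reg)
amr_fixture_registry <- function(format = c("tsv", "yaml")) {
  format <- match.arg(format)
  file <- system.file("extdata",
                      paste0("taxonomy_fixture.",
                             if (format == "tsv") "tsv" else "yaml"),
                      package = "amrcode", mustWork = TRUE)
  load_registry(file, format = format)
}

#' Next incremental code under a parent
#'
#' Sequence codes are generated dynamically by incremental number: the
#' smallest unused nonzero code under the parent, zero-padded to the layer's
#' width. The all-zeros code is reserved and never emitted.
#'
#' @param registry An `amr_registry`.
#' @param dimension_letter `"A"`, `"B"`, `"C"` or `"D"`.
#' @param parent_path Label path of the parent joined with `/` (`""` for a
#'   top layer).
#' @param layer Layer name; inferred from the parent depth for trunk
#'   dimensions, required for the branch dimension `D`.
#' @return A digit string.
#' @export
#' @examples
#' reg <- amr_fixture_registry()
#' assign_next_code(reg, "A", "")                      # "17"
#' assign_next_code(reg, "B", "laboratory animal/mouse") # "004"
assign_next_code <- function(registry, dimension_letter, parent_path = "",
                             layer = NULL) {
  spec <- registry$dimensions[[dimension_letter]]
  if (is.null(spec)) {
    stop(sprintf("unknown dimension '%s'", dimension_letter), call. = FALSE)
  }
  ldf <- spec$layers
  if (is.null(layer)) {
    if (!spec$trunk) {
      stop("layer must be given for the branch dimension", call. = FALSE)
    }
    depth <- path_depth(parent_path)
    if (depth + 1L > nrow(ldf)) {
      stop(sprintf("parent path '%s' is already at the deepest layer of %s",
                   parent_path, dimension_letter), call. = FALSE)
    }
    layer <- ldf$layer[depth + 1L]
  }
  li <- match(layer, ldf$layer)
  if (is.na(li)) {
    stop(sprintf("unknown layer '%s' for dimension %s", layer,
                 dimension_letter), call. = FALSE)
  }
  if (spec$trunk && li > 1L) {
    nd <- registry$nodes
    ok <- any(nd$dimension == dimension_letter &
                nd$layer == ldf$layer[li - 1L] &
                nd$label_path == parent_path)
    if (!ok) {
      stop(sprintf("unknown parent path '%s' in dimension %s", parent_path,
                   dimension_letter), call. = FALSE)
    }
  }
  width <- ldf$width[li]
  used <- registry$nodes$code[registry$nodes$dimension == dimension_letter &
                                registry$nodes$layer == layer &
                                registry$nodes$parent_path == parent_path]
  capacity <- 10^width - 1L
  free <- setdiff(seq_len(capacity), as.integer(used))
  if (!length(free)) {
    stop(sprintf("capacity exhausted under %s/%s parent '%s': all codes %s-%s in use",
                 dimension_letter, layer, parent_path,
                 sprintf("%0*d", width, 1L), strrep("9", width)),
         call. = FALSE)
  }
  sprintf("%0*d", width, min(free))
}

#' Resolve a code path to a taxonomy node
#'
#' Walks the layers of a trunk dimension down the given code path. A trailing
#' run of all-zeros segments is the supplementary "empty layer" marker and
#' resolves to an object of class `amr_empty_layer` rather than an error. For
#' the branch dimension `D` the positions are parallel: each digit is
#' resolved independently and a list of nodes/markers is returned.
#'
#' @param registry An `amr_registry`.
#' @param dimension_letter `"A"`, `"B"`, `"C"` or `"D"`.
#' @param code_path Character vector of per-layer digit strings, outermost
#'   first.
#' @return A node (named list), an `amr_empty_layer` marker, or for `D` a
#'   list of those.
#' @export
#' @examples
#' reg <- amr_fixture_registry()
#' lookup_by_code(reg, "A", c("01", "01"))$label  # "myocarditis"
#' lookup_by_code(reg, "A", c("01", "00"))        # empty-layer marker
lookup_by_code <- function(registry, dimension_letter, code_path) {
  spec <- registry$dimensions[[dimension_letter]]
  if (is.null(spec)) {
    stop(sprintf("unknown dimension '%s'", dimension_letter), call. = FALSE)
  }
  ldf <- spec$layers
  if (length(code_path) > nrow(ldf)) {
    stop(sprintf("code path longer than the %d layers of dimension %s",
                 nrow(ldf), dimension_letter), call. = FALSE)
  }
  widths <- ldf$width[seq_along(code_path)]
  bad <- nchar(code_path) != widths | !grepl("^[0-9]+$", code_path)
  if (any(bad)) {
    stop(sprintf("segment '%s' does not match width %d of %s/%s",
                 code_path[which(bad)[1]], widths[which(bad)[1]],
                 dimension_letter, ldf$layer[which(bad)[1]]), call. = FALSE)
  }
  if (!spec$trunk) {
    return(lapply(seq_along(code_path), function(i) {
      find_node(registry, dimension_letter, ldf$layer[i], "", code_path[i])
    }))
  }
  parent <- ""
  node <- NULL
  for (i in seq_along(code_path)) {
    seg <- code_path[i]
    if (is_all_zero(seg)) {
      rest <- code_path[seq_along(code_path) >= i]
      if (!all(is_all_zero(rest))) {
        stop(sprintf("nonzero code '%s' below an empty %s layer",
                     rest[which(!is_all_zero(rest))[1]], ldf$layer[i]),
             call. = FALSE)
      }
      return(structure(list(dimension = dimension_letter,
                            layer = ldf$layer[i], parent_path = parent),
                       class = "amr_empty_layer"))
    }
    node <- find_node(registry, dimension_letter, ldf$layer[i], parent, seg)
    parent <- node$label_path
  }
  node
}

find_node <- function(registry, dimension, layer, parent_path, code) {
  if (is_all_zero(code)) {
    return(structure(list(dimension = dimension, layer = layer,
                          parent_path = parent_path),
                     class = "amr_empty_layer"))
  }
  nd <- registry$nodes
  hit <- which(nd$dimension == dimension & nd$layer == layer &
                 nd$parent_path == parent_path & nd$code == code)
  if (!length(hit)) {
    stop(sprintf("unknown code '%s' at %s/%s under '%s'",
                 code, dimension, layer, parent_path), call. = FALSE)
  }
  i <- hit[1]
  list(dimension = nd$dimension[i], layer = nd$layer[i],
       parent_path = nd$parent_path[i], label = nd$label[i],
       code = nd$code[i], provenance = nd$provenance[i],
       label_path = nd$label_path[i], labels = nd$labels[[i]])
}

# Label-path resolution used by the encoder; returns the per-layer codes.
resolve_label_path <- function(registry, dimension, labels) {
  spec <- registry$dimensions[[dimension]]
  ldf <- spec$layers
  if (length(labels) > nrow(ldf)) {
    stop(sprintf("label path longer than the %d layers of dimension %s",
                 nrow(ldf), dimension), call. = FALSE)
  }
  nd <- registry$nodes
  parent <- ""
  codes <- character(length(labels))
  for (i in seq_along(labels)) {
    hit <- which(nd$dimension == dimension & nd$layer == ldf$layer[i] &
                   nd$parent_path == parent & nd$label == labels[i])
    if (!length(hit)) {
      stop(sprintf("unresolvable label '%s' at %s/%s under '%s'",
                   labels[i], dimension, ldf$layer[i], parent), call. = FALSE)
    }
    codes[i] <- nd$code[hit[1]]
    parent <- nd$label_path[hit[1]]
  }
  codes
}

#' Labeled-node counts per dimension and layer
#'
#' Counts the labeled nodes of a registry by dimension and layer.
#' Supplementary (all-zeros) codes are not nodes and are never counted.
#'
#' @param registry An `amr_registry`.
#' @return Data frame with columns `dimension`, `layer`, `n`, one row per
#'   layer of every dimension (zero counts included).
#' @export
#' @examples
#' registry_stats(amr_fixture_registry())
registry_stats <- function(registry) {
  out <- do.call(rbind, lapply(registry$dimensions, function(spec) {
    data.frame(dimension = spec$letter, layer = spec$layers$layer,
               n = 0L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (nrow(registry$nodes)) {
    tab <- table(paste(registry$nodes$dimension, registry$nodes$layer,
                       sep = "\r"))
    key <- paste(out$dimension, out$layer, sep = "\r")
    out$n <- as.integer(ifelse(key %in% names(tab), tab[key], 0L))
  }
  out
}

#' @export
print.amr_registry <- function(x, ...) {
  cat("<amr_registry> ", nrow(x$nodes), " labeled nodes\n", sep = "")
  st <- registry_stats(x)
  st <- st[st$n > 0L, , drop = FALSE]
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %s %-13s %d\n", st$dimension[i], st$layer[i], st$n[i]))
  }
  invisible(x)
}

#' @export
print.amr_empty_layer <- function(x, ...) {
  cat(sprintf("<empty %s layer of dimension %s>\n", x$layer, x$dimension))
  invisible(x)
}
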