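#' Configuration for the synthetic catalog generator
#'
#' The generator emulates the structure of the national animal-model
#' database: records fall into (disease x species x modeling) leaf cells
#' with heavily skewed occupancy — a few hotspot cells (e.g. induced and
#' genetically engineered tumor mouse models) hold a large share of all
#' records, the rest scatter thinly. Defaults are calibrated to the
#' database's anecdotal shape (865 records of which 181 are mouse tumor
#' models) but are explicitly fictional: the real per-cell distribution is
#' unpublished.
#'
#' @param total_records Number of records to generate (default 865).
#' @param seed Integer RNG seed.
#' @param cell_skew Dirichlet concentration for the non-hotspot cells;
#'   smaller values give stronger skew (default 0.5).
#' @param hotspot_cells List of hotspot overrides, each a list with label
#'   paths `disease`, `species`, `modeling` (joined with `/`) and an
#'   absolute probability `weight`; weights must sum to at most 1.
#' @param attribute_missing_rate Per-attribute probability of a missing
#'   value, in \[0, 1\] (default 0.1).
#' @return An object of class `amr_generator_config`.
#' @export
#' @examples
#' generator_config(total_records = 100, seed = 7)
generator_config <- function(total_records = 865L, seed = 1L,
                             cell_skew = 0.5,
                             hotspot_cells = default_hotspots(),
                             attribute_missing_rate = 0.1) {
  if (!is.numeric(total_records) || total_records < 1) {
    stop("total_records must be >= 1", call. = FALSE)
  }
  if (!is.numeric(cell_skew) || cell_skew <= 0) {
    stop("cell_skew must be > 0", call. = FALSE)
  }
  if (attribute_missing_rate < 0 || attribute_missing_rate > 1) {
    stop("attribute_missing_rate must be in [0, 1]", call. = FALSE)
  }
  w <- vapply(hotspot_cells, function(h) as.numeric(h$weight), numeric(1))
  if (any(w < 0) || sum(w) > 1) {
    stop("hotspot weights must be >= 0 and sum to at most 1", call. = FALSE)
  }
  structure(list(total_records = as.integer(total_records),
                 seed = as.integer(seed), cell_skew = cell_skew,
                 hotspot_cells = hotspot_cells,
                 attribute_missing_rate = attribute_missing_rate),
            class = "amr_generator_config")
}

#' @rdname generator_config
#' @export
default_hotspots <- function() {
  list(
    list(disease = "tumor", species = "laboratory animal/mouse/C57",
         modeling = "induced", weight = 0.11),
    list(disease = "tumor", species = "laboratory animal/mouse/C57",
         modeling = "genetic engineering", weight = 0.10)
  )
}

# Deepest labeled paths per trunk dimension within the paper profile:
# majors without intermediates count as leaves, intermediates are leaves,
# species without strains are leaves, strains are leaves. Returns the label
# vectors plus their joined display keys.
leaf_paths <- function(registry, dimension) {
  lays <- profile_layers("paper")[[dimension]]
  nd <- registry$nodes[registry$nodes$dimension == dimension, , drop = FALSE]
  nd <- nd[nd$layer %in% lays, , drop = FALSE]
  has_child <- nd$label_path %in% nd$parent_path
  list(labels = nd$labels[!has_child], key = nd$label_path[!has_child])
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a seeded synthetic catalog
#'
#' Draws each record's leaf cell from the skewed cell distribution defined
#' by the config (fixed hotspot weights, Dirichlet-weighted remainder),
#' draws its attributes (each independently missing with
#' `attribute_missing_rate`), encodes the canonical code, and assembles
#' label-derived metadata text with a noise token. Byte-identical output
#' for identical `registry` and `config`.
#'
#' @param registry An `amr_registry` with at least one labeled leaf per
#'   trunk dimension.
#' @param config An [generator_config()].
#' @return An `amr_catalog` of `config$total_records` records, with an
#'   attribute `cell_weights` (data frame of cell key, drawn probability and
#'   realized count) describing the cell distribution used.
#' @export
#' @examples
#' cat <- generate_catalog(amr_fixture_registry(),
#'                         generator_config(total_records = 50, seed = 1))
#' nrow(cat)
generate_catalog <- function(registry, config) {
  stopifnot(inherits(config, "amr_generator_config"))
  leaves <- list(A = leaf_paths(registry, "A"), B = leaf_paths(registry, "B"),
                 C = leaf_paths(registry, "C"))
  cells <- expand.grid(disease = seq_along(leaves$A$key),
                       species = seq_along(leaves$B$key),
                       modeling = seq_along(leaves$C$key))
  if (!nrow(cells)) {
    stop("registry has no labeled leaf in some trunk dimension", call. = FALSE)
  }
  cell_key <- paste(leaves$A$key[cells$disease], leaves$B$key[cells$species],
                    leaves$C$key[cells$modeling], sep = "|")
  hot_w <- numeric(nrow(cells))
  for (h in config$hotspot_cells) {
    k <- paste(h$disease, h$species, h$modeling, sep = "|")
    i <- match(k, cell_key)
    if (is.na(i)) {
      stop(sprintf("hotspot cell '%s' is not a leaf cell of this registry", k),
           call. = FALSE)
    }
    hot_w[i] <- hot_w[i] + h$weight
  }
  levels <- amr_attribute_levels()
  with_seed(config$seed, {
    rest <- hot_w == 0
    w <- hot_w
    if (any(rest)) {
      g <- rgamma(sum(rest), shape = config$cell_skew)
      w[rest] <- (1 - sum(hot_w)) * g / sum(g)
    }
    n <- config$total_records
    cell_idx <- sample.int(nrow(cells), n, replace = TRUE, prob = w)
    draw_attr <- function(which) {
      vals <- setdiff(names(levels[[which]]), "missing")
      out <- sample(vals, n, replace = TRUE)
      out[runif(n) < config$attribute_missing_rate] <- "missing"
      out
    }
    coop <- draw_attr("cooperation")
    shar <- draw_attr("sharing")
    pres <- draw_attr("preservation")
    dates <- sprintf("%04d-%02d-%02d", sample(2013:2022, n, replace = TRUE),
                     sample(12L, n, replace = TRUE),
                     sample(28L, n, replace = TRUE))
    noise <- sprintf("lot-%05d", sample.int(99999L, n, replace = TRUE))
    # trunk code prefix and label-derived text are constant per cell
    used <- sort(unique(cell_idx))
    prefix <- name_head <- descr <- keyw <- character(max(used))
    for (ci in used) {
      dis <- leaves$A$labels[[cells$disease[ci]]]
      spe <- leaves$B$labels[[cells$species[ci]]]
      mod <- leaves$C$labels[[cells$modeling[ci]]]
      rec <- amr_record(disease = dis, species = spe, modeling = mod)
      prefix[ci] <- sub("D000$", "D",
                        encode_record(registry, rec, profile = "paper"))
      # "BALB/c mouse", "New Zealand rabbit", or plain "guinea pig"
      animal <- if (length(spe) == 3L) paste(spe[3], spe[2]) else spe[length(spe)]
      name_head[ci] <- paste(animal, dis[length(dis)], mod[1], "model")
      descr[ci] <- paste(paste(dis, collapse = " "), "model of human disease")
      keyw[ci] <- paste(c(dis, spe, mod), collapse = ", ")
    }
    levmap <- function(which, vals) {
      as.character(amr_attribute_levels()[[which]][vals])
    }
    d_part <- paste0(levmap("cooperation", coop), levmap("sharing", shar),
                     levmap("preservation", pres))
    name <- paste(name_head[cell_idx], noise)
    out <- amr_catalog(data.frame(
      record_id = sprintf("AM%05d", seq_len(n)),
      code = paste0(prefix[cell_idx], d_part),
      name = name,
      english_name = name,
      disease_description = descr[cell_idx],
      cooperation = ifelse(coop == "missing", "", coop),
      date = dates,
      preservation = ifelse(pres == "missing", "", pres),
      keywords = keyw[cell_idx],
      stringsAsFactors = FALSE))
    # realized cell distribution, for goodness-of-fit checks
    attr(out, "cell_weights") <- data.frame(cell = cell_key,
                                            weight = w / sum(w),
                                            count = tabulate(cell_idx,
                                                             nrow(cells)),
                                            stringsAsFactors = FALSE)
    out
  })
}

#' Build a benchmark query set from a catalog
#'
#' Samples `n_queries` target records without replacement. For each target
#' it builds the keyword-baseline query (one word drawn from the target's
#' `name`, searched in the `name` field — it always matches the target,
#' possibly among many others) and the code-based query (the fully literal
#' pattern of the target's own code).
#'
#' @param catalog An `amr_catalog`.
#' @param n_queries Number of queries, at most `nrow(catalog)`.
#' @param seed Integer RNG seed.
#' @return List of queries for [benchmark_one_shot()].
#' @export
make_query_set <- function(catalog, n_queries, seed = 1L) {
  stopifnot(inherits(catalog, "amr_catalog"))
  if (n_queries > nrow(catalog)) {
    stop(sprintf("n_queries (%d) exceeds the %d catalog records",
                 n_queries, nrow(catalog)), call. = FALSE)
  }
  with_seed(seed, {
    targets <- sample.int(nrow(catalog), n_queries)
    lapply(targets, function(i) {
      tokens <- strsplit(trimws(catalog$name[i]), "\\s+")[[1]]
      tokens <- tokens[nchar(tokens) >= 3]
      term <- if (length(tokens)) sample(tokens, 1) else catalog$name[i]
      segs <- code_segments(sub("^CSTR09:", "", catalog$code[i]))
      profile <- detect_profile(segs)
      list(target_id = catalog$record_id[i],
           terms = list(name = term),
           pattern = query_pattern(a = segs$A, b = segs$B, c = segs$C,
                                   d = segs$D, profile = profile))
    })
  })
}
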