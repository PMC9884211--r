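#' Read a respondent-by-item response matrix from CSV
#'
#' Reads a CSV with one header row of item ids, one row per respondent, and
#' (optionally) a `diagnosis` column carrying a per-respondent group label.
#' Every item cell must be an integer within `0:likert_max`; missing or
#' out-of-range cells are reported with their row and column.
#'
#' @param path Path to a CSV file.
#' @param likert_max Largest admissible ordinal code (default 4, i.e. a
#'   five-point 0--4 Likert scale).
#' @param item_pattern Optional regular expression; when supplied, only the
#'   columns matching it (plus `diagnosis`) are kept. Useful when the raw
#'   file carries extra administrative columns.
#'
#' @return A tibble with one integer column per item and, if present in the
#'   file, a character `diagnosis` column.
#' @export
load_responses <- function(path, likert_max = 4, item_pattern = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) < 1) abort("response file has no rows")
  if (!is.null(item_pattern)) {
    keep <- union(grep(item_pattern, names(raw), value = TRUE),
                  intersect(names(raw), "diagnosis"))
    raw <- raw[keep]
  }
  validate_responses(raw, likert_max = likert_max)
}

#' Validate a response tibble
#'
#' Checks the invariants expected of ordinal questionnaire data: unique item
#' ids, no missing cells, every value an integer inside the declared range.
#'
#' @param data A data frame of item columns (plus optional `diagnosis`).
#' @inheritParams load_responses
#' @return The validated tibble, item columns coerced to integer.
#' @export
validate_responses <- function(data, likert_max = 4) {
  raw_items <- names(data)[!names(data) %in% ITEM_RESERVED]
  if (anyDuplicated(raw_items) > 0) {
    abort(paste0("duplicate item id: ", raw_items[duplicated(raw_items)][1]))
  }
  data <- tibble::as_tibble(data)
  items <- item_cols(data)
  if (length(items) == 0) abort("no item columns found")
  for (it in items) {
    v <- data[[it]]
    if (!is.numeric(v)) abort(paste0("item ", it, " is not numeric"))
    if (anyNA(v)) {
      abort(paste0("missing value at row ", which(is.na(v))[1],
                   ", item ", it))
    }
    if (any(v != round(v))) {
      abort(paste0("non-integer value at row ", which(v != round(v))[1],
                   ", item ", it))
    }
    if (any(v < 0 | v > likert_max)) {
      bad <- which(v < 0 | v > likert_max)[1]
      abort(paste0("value out of range [0,", likert_max, "] at row ", bad,
                   ", item ", it))
    }
    data[[it]] <- as.integer(v)
  }
  if ("diagnosis" %in% names(data)) {
    data$diagnosis <- as.character(data$diagnosis)
  }
  data
}

#' Read an item key (item to subscale to composite map) from YAML
#'
#' The key lists, per subscale code, its item ids, and per composite score,
#' its subscale codes. Items absent from every subscale are treated as
#' unscored (the EDI-3 has one such item). A template ships in
#' `inst/extdata/item_key_template.yaml`; the true EDI-3 key is manual
#' content and must be supplied by the user.
#'
#' @param path Path to a YAML file with top-level maps `subscales` and
#'   `composites`.
#' @param items Optional character vector of all item ids in the data; items
#'   not covered by the key are returned in `$unscored`.
#' @return An object of class `netpsy_key`: list with `item_subscale`
#'   (named character), `subscale_composite` (named list), `subscales`,
#'   `composites`, `unscored`.
#' @export
load_item_key <- function(path, items = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$subscales) || is.null(cfg$composites)) {
    abort("item key must define `subscales` and `composites`")
  }
  item_key(subscales = cfg$subscales, composites = cfg$composites,
           items = items)
}

#' Construct an item key from in-memory maps
#'
#' @param subscales Named list: subscale code -> character vector of item ids.
#' @param composites Named list: composite name -> character vector of
#'   subscale codes.
#' @param items Optional universe of item ids (to flag unscored items).
#' @param allowed_subscales Admissible subscale codes; defaults to the 12
#'   EDI-3 codes. Pass `NULL` to accept any code (synthetic keys).
#' @return A `netpsy_key` object.
#' @export
item_key <- function(subscales, composites, items = NULL,
                     allowed_subscales = edi3_subscales()) {
  sub_codes <- names(subscales)
  if (!is.null(allowed_subscales)) {
    bad <- setdiff(sub_codes, allowed_subscales)
    if (length(bad) > 0) {
      abort(paste0("unknown subscale code: ", paste(bad, collapse = ", ")))
    }
  }
  item_subscale <- character(0)
  for (sc in sub_codes) {
    its <- as.character(subscales[[sc]])
    dup <- intersect(its, names(item_subscale))
    if (length(dup) > 0) {
      abort(paste0("item mapped to two subscales: ", dup[1], " (",
                   item_subscale[dup[1]], " and ", sc, ")"))
    }
    item_subscale[its] <- sc
  }
  comp_map <- purrr::map(composites, as.character)
  covered <- unique(unlist(comp_map))
  uncovered <- setdiff(sub_codes, covered)
  if (length(uncovered) > 0) {
    abort(paste0("subscale in no composite: ", paste(uncovered, collapse = ", ")))
  }
  unknown <- setdiff(covered, sub_codes)
  if (length(unknown) > 0) {
    abort(paste0("composite references unknown subscale: ",
                 paste(unknown, collapse = ", ")))
  }
  unscored <- if (is.null(items)) character(0) else
    setdiff(items, names(item_subscale))
  structure(
    list(item_subscale = item_subscale,
         subscale_composite = comp_map,
         subscales = sub_codes,
         composites = names(comp_map),
         unscored = unscored),
    class = "netpsy_key"
  )
}

#' The 12 EDI-3 subscale codes
#' @return Character vector of the canonical subscale codes.
#' @export
edi3_subscales <- function() {
  c("DT", "B", "BD", "LSE", "PA", "II", "IA", "ID", "ED", "P", "A", "MF")
}

#' Items belonging to a composite score
#'
#' @param key A `netpsy_key`.
#' @param composite Composite name present in the key.
#' @return Character vector of item ids of all subscales in the composite.
#' @export
composite_items <- function(key, composite) {
  stopifnot(inherits(key, "netpsy_key"))
  if (!composite %in% key$composites) {
    abort(paste0("unknown composite: ", composite))
  }
  subs <- key$subscale_composite[[composite]]
  names(key$item_subscale)[key$item_subscale %in% subs]
}

#' Export a network to GraphML and an edge-list CSV
#'
#' Writes `<path>.graphml` (all nodes declared, weighted edges) and
#' `<path>_edges.csv` with columns `node_i, node_j, weight`, excluding
#' zero-weight pairs.
#'
#' @param network A `netpsy_network` (see [estimate_network()]) or a
#'   symmetric weight matrix with dimnames.
#' @param path Output path stem (no extension).
#' @return Invisibly, the two file paths written.
#' @export
export_network <- function(network, path) {
  w <- network_weights(network)
  stop_if_asymmetric(w, "network weight matrix")
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  graphml <- paste0(path, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  edges <- tidy_network_edges(w)
  csv <- paste0(path, "_edges.csv")
  readr::write_csv(edges, csv)
  invisible(c(graphml = graphml, edges = csv))
}

#' Read a network back from an exported edge list
#'
#' @param path The path stem used in [export_network()].
#' @param node_ids Node ids (order) of the network; when `NULL` they are
#'   read from the GraphML file.
#' @return A symmetric weight matrix.
#' @export
read_network <- function(path, node_ids = NULL) {
  graphml <- paste0(path, ".graphml")
  csv <- paste0(path, "_edges.csv")
  if (is.null(node_ids)) {
    if (!file.exists(graphml)) abort(paste0("file not found: ", graphml))
    g <- igraph::read_graph(graphml, format = "graphml")
    node_ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  }
  edges <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             node_i = readr::col_character(),
                             node_j = readr::col_character(),
                             weight = readr::col_double()))
  p <- length(node_ids)
  w <- matrix(0, p, p, dimnames = list(node_ids, node_ids))
  if (nrow(edges) > 0) {
    w[cbind(edges$node_i, edges$node_j)] <- edges$weight
    w[cbind(edges$node_j, edges$node_i)] <- edges$weight
  }
  w
}

# long edge tibble from a weight matrix (upper triangle, nonzero)
tidy_network_edges <- function(w) {
  ids <- colnames(w) %||% as.character(seq_len(ncol(w)))
  ut <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  tibble::tibble(node_i = ids[ut[, 1]], node_j = ids[ut[, 2]],
                 weight = w[ut])
}

#' Write / read a partition as JSON
#'
#' Serialized as a flat `{node: label}` object.
#'
#' @param partition A `netpsy_partition` or named integer vector.
#' @param path Output (input) JSON path.
#' @return `write_partition()` returns the path invisibly;
#'   `read_partition()` returns a named integer vector.
#' @export
write_partition <- function(partition, path) {
  lab <- partition_labels(partition)
  jsonlite::write_json(as.list(lab), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  x <- jsonlite::read_json(path)
  setNames(as.integer(unlist(x)), names(x))
}
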