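#' Network loadings: standardized within-community node strength
#'
#' Raw loading of node `i` on community `c` is \eqn{\sum_{j \in c} |w_{ij}|}
#' (`signed = TRUE` drops the absolute value); each column is standardized
#' by \eqn{\sqrt{\sum_{j \in c} NL_{jc}}}, the network analogue of a factor
#' loading. Raw loadings decompose node strength exactly:
#' \eqn{\sum_c NL_{ic} = s_i}.
#'
#' @param network A `netpsy_network` or weight matrix.
#' @param partition Partition over the network's nodes.
#' @param signed Use signed weights instead of absolute values.
#' @return A `netpsy_loadings`: list with `raw` and `standardized`
#'   node-by-community matrices and the partition labels.
#' @export
network_loadings <- function(network, partition, signed = FALSE) {
  w <- network_weights(network)
  lab <- partition_labels(partition)
  lab <- lab[colnames(w)]
  if (anyNA(lab)) abort("partition does not cover all network nodes")
  if (any(table(lab) == 0)) abort("empty community")
  a <- if (signed) w else abs(w)
  comms <- sort(unique(lab))
  raw <- vapply(comms, function(cc) {
    rowSums(a[, lab == cc, drop = FALSE])
  }, numeric(nrow(a)))
  dimnames(raw) <- list(colnames(w), as.character(comms))
  denom <- vapply(comms, function(cc) {
    s <- sum(raw[lab == cc, as.character(cc)])
    if (s > 0) sqrt(s) else 1
  }, numeric(1))
  std <- sweep(raw, 2, denom, "/")
  structure(list(raw = raw, standardized = std, assignment = lab,
                 signed = signed),
            class = "netpsy_loadings")
}

#' @export
print.netpsy_loadings <- function(x, ...) {
  cat("<netpsy_loadings> ", nrow(x$raw), " nodes x ", ncol(x$raw),
      " communities (", if (x$signed) "signed" else "absolute", ")\n",
      sep = "")
  invisible(x)
}

#' Strength centrality
#'
#' \eqn{s_i = \sum_j |w_{ij}|}: the summed absolute weight of all edges
#' extending from a node.
#'
#' @param network A `netpsy_network` or weight matrix.
#' @return Tibble with `item`, `strength`, `rank` (1 = strongest).
#' @export
node_strength <- function(network) {
  w <- network_weights(network)
  s <- rowSums(abs(w))
  tibble::tibble(item = colnames(w), strength = as.numeric(s),
                 rank = rank(-s, ties.method = "min"))
}

#' One-step and two-step expected influence
#'
#' \eqn{EI^{(1)}_i = \sum_j w_{ij}} (signed) and
#' \eqn{EI^{(2)}_i = EI^{(1)}_i + \sum_j w_{ij} EI^{(1)}_j}: the node's
#' direct signed influence plus, at two steps, the weight-propagated
#' influence of its neighbors.
#'
#' @param network A `netpsy_network` or weight matrix.
#' @param steps 1 or 2.
#' @return Tibble with `item`, `ei`, `rank`.
#' @export
expected_influence <- function(network, steps = 1) {
  if (!steps %in% c(1, 2)) abort("steps must be 1 or 2")
  w <- network_weights(network)
  ei1 <- rowSums(w)
  ei <- if (steps == 1) ei1 else ei1 + as.numeric(w %*% ei1)
  tibble::tibble(item = colnames(w), ei = as.numeric(ei),
                 rank = rank(-ei, ties.method = "min"))
}

#' Full centrality table
#'
#' Strength, one-step and two-step expected influence, with per-metric
#' ranks.
#'
#' @param network A `netpsy_network` or weight matrix.
#' @return Tibble with `item`, `strength`, `ei1`, `ei2` and
#'   `rank_strength`, `rank_ei1`, `rank_ei2`.
#' @export
centrality_table <- function(network) {
  s <- node_strength(network)
  e1 <- expected_influence(network, 1)
  e2 <- expected_influence(network, 2)
  tibble::tibble(item = s$item, strength = s$strength, ei1 = e1$ei,
                 ei2 = e2$ei, rank_strength = s$rank, rank_ei1 = e1$rank,
                 rank_ei2 = e2$rank)
}

#' Top and bottom nodes per metric
#'
#' @param table A centrality tibble (from [centrality_table()],
#'   [node_strength()], or [expected_influence()]).
#' @param metric Column to rank on.
#' @param k Number of nodes at each end.
#' @return List with `top` and `bottom` tibbles (ties broken by item id).
#' @export
top_bottom_nodes <- function(table, metric = "strength", k = 5) {
  if (!metric %in% names(table)) abort(paste0("no column ", metric))
  if (k > nrow(table)) abort("k exceeds the number of nodes")
  ord <- order(-table[[metric]], table$item)
  list(top = table[head(ord, k), ], bottom = table[rev(tail(ord, k)), ])
}

#' Agreement between a partition and the questionnaire's subscales
#'
#' Assigns each subscale to the community holding the plurality of its
#' items (Jaccard similarity breaks ties), then reports, per community: the
#' matched subscales, the items of those subscales landing elsewhere
#' (missing), the community members whose own subscale matched elsewhere
#' (foreign, with their true subscale), and the composite score(s) the
#' matched subscales belong to. Unscored items (in no subscale) are listed
#' separately and never counted as foreign.
#'
#' @param partition Partition over original item ids (expand composites
#'   first with [expand_partition()]).
#' @param key A `netpsy_key`.
#' @return A `netpsy_agreement`: tibble with `community`, `subscales`,
#'   `missing_items`, `foreign_items`, `composite`, `n_items`; attribute
#'   `"unscored"` lists unscored items and their communities.
#' @export
subscale_agreement <- function(partition, key) {
  stopifnot(inherits(key, "netpsy_key"))
  lab <- partition_labels(partition)
  scored <- names(lab)[names(lab) %in% names(key$item_subscale)]
  unscored <- setdiff(names(lab), scored)
  unknown <- setdiff(unscored, key$unscored)
  if (length(key$unscored) > 0 && length(unknown) > 0) {
    abort(paste0("item missing from key and not flagged unscored: ",
                 unknown[1]))
  }
  subs <- unique(key$item_subscale[scored])
  comms <- sort(unique(lab))
  # subscale -> community by plurality, Jaccard tie-break
  sub_comm <- vapply(subs, function(sc) {
    its <- scored[key$item_subscale[scored] == sc]
    ov <- vapply(comms, function(cc) sum(lab[its] == cc), numeric(1))
    best <- which(ov == max(ov))
    if (length(best) > 1) {
      jac <- vapply(comms[best], function(cc) {
        cs <- names(lab)[lab == cc]
        length(intersect(cs, its)) / length(union(cs, its))
      }, numeric(1))
      best <- best[which.max(jac)]
    }
    comms[best[1]]
  }, numeric(1))
  rows <- purrr::map_dfr(comms, function(cc) {
    members <- names(lab)[lab == cc]
    matched <- subs[sub_comm == cc]
    matched_items <- scored[key$item_subscale[scored] %in% matched]
    missing <- setdiff(matched_items, members)
    foreign <- setdiff(intersect(members, scored), matched_items)
    comp <- unique(unlist(purrr::map(matched, function(sc) {
      key$composites[purrr::map_lgl(key$subscale_composite,
                                    function(x) sc %in% x)]
    })))
    fmt <- function(its) {
      if (length(its) == 0) return("")
      paste0(its, " (", key$item_subscale[its], ")", collapse = ", ")
    }
    tibble::tibble(
      community = as.integer(cc),
      subscales = paste(sort(matched), collapse = " + "),
      missing_items = fmt(sort(missing)),
      foreign_items = fmt(sort(foreign)),
      composite = paste(sort(comp), collapse = " + "),
      n_items = length(members))
  })
  attr(rows, "unscored") <-
    tibble::tibble(item = unscored, community = as.integer(lab[unscored]))
  class(rows) <- c("netpsy_agreement", class(rows))
  rows
}
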