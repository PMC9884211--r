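new_partition <- function(labels, energy = NA_real_, seed = NA_integer_,
                          method = "spinglass") {
  labels <- relabel_dense(labels)
  structure(list(assignment = labels, energy = energy, seed = seed,
                 method = method),
            class = "netpsy_partition")
}

# dense integer labels starting at 1, order of first appearance
relabel_dense <- function(labels) {
  setNames(as.integer(match(labels, unique(labels))), names(labels))
}

partition_labels <- function(p) {
  if (inherits(p, "netpsy_partition")) return(p$assignment)
  if (is.numeric(p) || is.integer(p)) {
    if (is.null(names(p))) abort("partition vector must be named by node id")
    return(setNames(as.integer(p), names(p)))
  }
  abort("not a partition: expected netpsy_partition or named integer vector")
}

#' @export
print.netpsy_partition <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat("<netpsy_partition> ", length(x$assignment), " nodes, ", k,
      " communities (", x$method, ")",
      if (is.finite(x$energy)) paste0(", energy = ", signif(x$energy, 5)),
      "\n", sep = "")
  invisible(x)
}

#' Signed Potts Hamiltonian of a partition
#'
#' Evaluates
#' \eqn{H(\sigma) = -\sum_{i<j}(w^+_{ij} - \gamma^+ p^+_{ij})\,\delta(\sigma_i,\sigma_j)
#'  + \sum_{i<j}(w^-_{ij} - \gamma^- p^-_{ij})\,\delta(\sigma_i,\sigma_j)}
#' with configuration-model null expectations
#' \eqn{p^{\pm}_{ij} = k^{\pm}_i k^{\pm}_j / (2 m^{\pm})} computed on the
#' positive and negative subgraphs. This is the objective the signed
#' spinglass algorithm minimizes; lower is better.
#'
#' @param network A `netpsy_network` or symmetric weight matrix.
#' @param partition A partition over the network's nodes.
#' @param gamma_pos,gamma_neg Resolution parameters of the positive and
#'   negative null terms.
#' @return The Hamiltonian value (finite).
#' @export
partition_energy <- function(network, partition, gamma_pos = 1,
                             gamma_neg = 1) {
  w <- network_weights(network)
  lab <- partition_labels(partition)
  lab <- lab[colnames(w)]
  if (anyNA(lab)) abort("partition does not cover all network nodes")
  wp <- pmax(w, 0)
  wn <- pmax(-w, 0)
  same <- outer(lab, lab, "==")
  h_part <- function(ws, gamma) {
    m2 <- sum(ws)                       # = 2m on a symmetric matrix
    if (m2 == 0) return(matrix(0, nrow(ws), ncol(ws)))
    k <- rowSums(ws)
    ws - gamma * tcrossprod(k) / m2
  }
  hp <- h_part(wp, gamma_pos)
  hn <- h_part(wn, gamma_neg)
  contrib <- (-hp + hn) * same
  sum(contrib[upper.tri(contrib)])
}

#' Spinglass community detection on a signed weighted network
#'
#' Minimizes the signed Potts Hamiltonian (see [partition_energy()]) by
#' simulated annealing, as implemented in igraph's negative-weight spinglass
#' variant. The optimizer is stochastic: `restarts` independent annealing
#' runs are performed (child seeds derived from `seed`) and the
#' lowest-energy solution kept, which stabilizes the reported partition.
#' Nodes isolated on the nonzero subgraph get singleton communities, and
#' disconnected blocks are partitioned separately (the configuration null is
#' per-component).
#'
#' @param network A `netpsy_network` or symmetric weight matrix.
#' @param gamma_pos,gamma_neg Resolution parameters.
#' @param max_spins Upper bound on the number of communities.
#' @param t_start,t_stop,cooling Annealing schedule.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param restarts Annealing runs to take the best of.
#' @return A `netpsy_partition` with the realized energy and seed.
#' @export
spinglass_partition <- function(network, gamma_pos = 1, gamma_neg = 1,
                                max_spins = 25, t_start = 1, t_stop = 0.01,
                                cooling = 0.99, seed = 1, restarts = 10) {
  w <- network_weights(network)
  stop_if_asymmetric(w, "network weight matrix")
  ids <- colnames(w)
  if (all(w == 0)) abort("no structure: all network weights are zero")
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  labels <- setNames(integer(length(ids)), ids)
  energy <- 0
  offset <- 0L
  for (ci in seq_len(comp$no)) {
    members <- ids[comp$membership == ci]
    if (length(members) == 1) {
      labels[members] <- offset + 1L
      offset <- offset + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, members)
    spins <- min(max_spins, length(members))
    best <- NULL
    for (r in seq_len(restarts)) {
      set.seed(seed * 1000L + r)
      cl <- igraph::cluster_spinglass(
        sub, weights = igraph::E(sub)$weight, spins = spins,
        implementation = "neg", gamma = gamma_pos, gamma.minus = gamma_neg,
        start.temp = t_start, stop.temp = t_stop, cool.fact = cooling)
      memb <- setNames(igraph::membership(cl), members)
      en <- partition_energy(w[members, members, drop = FALSE], memb,
                             gamma_pos, gamma_neg)
      if (is.null(best) || en < best$energy) best <- list(memb = memb,
                                                          energy = en)
    }
    labels[members] <- offset + as.integer(best$memb)
    offset <- offset + max(best$memb)
    energy <- energy + best$energy
  }
  new_partition(labels, energy = energy, seed = seed, method = "spinglass")
}

# contingency table of two label vectors over the same nodes
partition_contingency <- function(p1, p2) {
  l1 <- partition_labels(p1)
  l2 <- partition_labels(p2)
  if (length(l1) != length(l2) ||
      !setequal(names(l1), names(l2))) {
    abort("partitions are over different node sets")
  }
  l2 <- l2[names(l1)]
  table(l1, l2)
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

mutual_information <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[idx]
  sum(nij / n * log(n * nij / (a[idx[, 1]] * b[idx[, 2]])))
}

#' Normalized mutual information of two partitions
#'
#' Arithmetic normalization \eqn{2 I(P_1;P_2) / (H(P_1) + H(P_2))}; 1 iff
#' the partitions coincide up to relabeling. Two all-in-one-cluster
#' partitions (both entropies zero) count as identical, hence 1.
#'
#' @param p1,p2 Partitions over the same node set.
#' @return A value in `[0, 1]`.
#' @export
nmi <- function(p1, p2) {
  tab <- partition_contingency(p1, p2)
  h1 <- entropy_nats(rowSums(tab))
  h2 <- entropy_nats(colSums(tab))
  if (h1 + h2 == 0) return(1)
  2 * mutual_information(tab) / (h1 + h2)
}

#' Adjusted mutual information of two partitions
#'
#' \eqn{(I - E[I]) / (\bar H - E[I])} with \eqn{\bar H} the arithmetic mean
#' of the two entropies and \eqn{E[I]} the expected mutual information under
#' the permutation (hypergeometric) model with fixed marginals. 1 iff the
#' partitions coincide up to relabeling; near 0 for independent partitions.
#'
#' @inheritParams nmi
#' @return A value `<= 1` (can be slightly negative by chance).
#' @export
ami <- function(p1, p2) {
  tab <- partition_contingency(p1, p2)
  h1 <- entropy_nats(rowSums(tab))
  h2 <- entropy_nats(colSums(tab))
  if (h1 + h2 == 0) return(1)
  mi <- mutual_information(tab)
  emi <- expected_mi(rowSums(tab), colSums(tab))
  denom <- (h1 + h2) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  (mi - emi) / denom
}

# E[I] under the hypergeometric model with fixed marginals (exact sum)
expected_mi <- function(a, b) {
  n <- sum(a)
  lfact <- lgamma(seq_len(n + 1))       # lfact[k+1] = log(k!)
  lf <- function(k) lfact[k + 1]
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lf(ai) + lf(bj) + lf(n - ai) + lf(n - bj) - lf(n) -
          lf(nij) - lf(ai - nij) - lf(bj - nij) - lf(n - ai - bj + nij)
        emi <- emi + exp(lp) * (nij / n) * log(n * nij / (ai * bj))
      }
    }
  }
  emi
}

#' Expand a partition on reduced items to the original items
#'
#' Every source item of a composite inherits the composite's community
#' label; untouched items keep theirs. Used to compare cohort partitions on
#' the common original item set after cohort-specific redundancy merges.
#'
#' @param partition Partition over reduced (possibly composite) item ids.
#' @param merge_map Named list: composite id -> character vector of source
#'   item ids (as in a `netpsy_uva_report`).
#' @return A `netpsy_partition` over the original items.
#' @export
expand_partition <- function(partition, merge_map) {
  lab <- partition_labels(partition)
  composites <- names(lab)[grepl("_", names(lab))]
  uncovered <- setdiff(composites, names(merge_map))
  if (length(uncovered) > 0) {
    abort(paste0("composite missing from merge_map: ", uncovered[1]))
  }
  out <- integer(0)
  for (node in names(lab)) {
    src <- merge_map[[node]] %||% node
    out[src] <- lab[node]
  }
  method <- if (inherits(partition, "netpsy_partition")) partition$method
            else "expanded"
  new_partition(out, energy = NA_real_, seed = NA_integer_, method = method)
}
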