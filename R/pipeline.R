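#' Run the full network-based validation for one or more cohorts
#'
#' Per cohort (the full sample plus each selected `diagnosis` label):
#' redundancy reduction ([run_uva()]), bootstrap exploratory graph analysis
#' ([bootstrap_ega()]), the median network and its spinglass partition,
#' stability summaries ([item_stability()], [structural_consistency()],
#' [ncomm_distribution()]), node metrics ([centrality_table()],
#' [network_loadings()]) and, when an item key is given, the
#' subscale-agreement table. All seeds derive from `seed` and every stage's
#' settings are recorded, so a run is a pure function of (data, config).
#'
#' @param data Response tibble; a `diagnosis` column selects cohorts.
#' @param key Optional `netpsy_key`.
#' @param cohorts Character vector of diagnosis labels to analyze
#'   separately; `NULL` analyzes only the full sample. The full sample is
#'   always included, labeled `"cross-sample"`.
#' @param corr_method,gamma,n_lambda,lambda_min_ratio Estimation settings.
#' @param uva Named list of overrides for [run_uva()].
#' @param spinglass Named list of overrides for [spinglass_partition()].
#' @param B Bootstrap replicates per cohort.
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, all reports are written
#'   there as CSV/JSON (one subdirectory per cohort).
#' @return A named list of cohort bundles (class `netpsy_validation`), each
#'   with `uva`, `ensemble`, `median_network`, `partition`, `stability`,
#'   `consistency`, `ncomm`, `centrality`, `loadings`, `agreement`,
#'   `expanded_partition`, `config`.
#' @export
run_validation <- function(data, key = NULL, cohorts = NULL,
                           corr_method = c("polychoric", "pearson"),
                           gamma = 0.5, n_lambda = 100,
                           lambda_min_ratio = 0.01,
                           uva = list(), spinglass = list(),
                           B = 500, seed = 1, out_dir = NULL) {
  corr_method <- match.arg(corr_method)
  data <- validate_responses(data, likert_max = max(response_values(data)))
  sets <- list("cross-sample" = data)
  for (lb in cohorts) {
    if (!"diagnosis" %in% names(data)) {
      abort("cohorts requested but `data` has no diagnosis column")
    }
    sub <- dplyr::filter(data, .data$diagnosis == lb)
    if (nrow(sub) == 0) abort(paste0("no respondents with diagnosis ", lb))
    sets[[lb]] <- sub
  }
  bundles <- purrr::imap(sets, function(d, label) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort(paste0("[", label, "/", what, "] ", conditionMessage(e)))
      })
    }
    cohort_seed <- seed + match(label, names(sets)) - 1L
    red <- stage("uva", do.call(run_uva, c(
      list(data = d, corr_method = corr_method, gamma = gamma,
           n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio), uva)))
    ens <- stage("bootstrap", do.call(bootstrap_ega, c(
      list(data = red$data, B = B, seed = cohort_seed,
           corr_method = corr_method, gamma = gamma, n_lambda = n_lambda,
           lambda_min_ratio = lambda_min_ratio, spinglass = spinglass))))
    med <- stage("median_network", median_network(ens))
    part <- stage("partition", do.call(spinglass_partition, c(
      list(network = med, seed = cohort_seed), spinglass)))
    # stability is judged against the median-network partition
    ens_med <- ens
    ens_med$empirical <- list(network = med$weights, partition = part,
                              n_communities = length(unique(part$assignment)))
    stab <- stage("item_stability", item_stability(ens_med))
    cons <- stage("structural_consistency", structural_consistency(ens_med))
    ncd <- stage("ncomm", ncomm_distribution(ens))
    cent <- stage("centrality", centrality_table(med))
    loads <- stage("loadings", network_loadings(med, part))
    expanded <- stage("expand", expand_partition(part, red$report$merge_map))
    agree <- if (!is.null(key)) {
      stage("agreement", subscale_agreement(expanded, key))
    }
    structure(
      list(label = label, uva = red$report, data_reduced = red$data,
           ensemble = ens, median_network = med, partition = part,
           expanded_partition = expanded, stability = stab,
           consistency = cons, ncomm = ncd, centrality = cent,
           loadings = loads, agreement = agree,
           config = list(corr_method = corr_method, gamma = gamma,
                         n_lambda = n_lambda,
                         lambda_min_ratio = lambda_min_ratio, B = B,
                         seed = cohort_seed)),
      class = "netpsy_bundle")
  })
  out <- structure(bundles, class = "netpsy_validation")
  if (!is.null(out_dir)) write_validation(out, out_dir)
  out
}

#' @export
print.netpsy_bundle <- function(x, ...) {
  cat("<netpsy_bundle> ", x$label, ": ", x$uva$n_items_in, " -> ",
      x$uva$n_items_out, " items, ",
      length(unique(x$partition$assignment)), " communities, B = ",
      x$ensemble$B, "\n", sep = "")
  invisible(x)
}

#' @export
print.netpsy_validation <- function(x, ...) {
  cat("<netpsy_validation> ", length(x), " cohort(s): ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  for (b in x) print(b)
  invisible(x)
}

# write one validation's reports as plain CSV/JSON
write_validation <- function(validation, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (b in validation) {
    d <- file.path(out_dir, gsub("[^A-Za-z0-9_-]", "_", b$label))
    dir.create(d, showWarnings = FALSE)
    readr::write_csv(uva_merge_table(b$uva), file.path(d, "merged_items.csv"))
    export_network(b$median_network, file.path(d, "median_network"))
    write_partition(b$partition, file.path(d, "partition.json"))
    write_partition(b$expanded_partition,
                    file.path(d, "partition_expanded.json"))
    readr::write_csv(b$stability, file.path(d, "item_stability.csv"))
    readr::write_csv(b$consistency,
                     file.path(d, "structural_consistency.csv"))
    readr::write_csv(b$ncomm, file.path(d, "ncomm_distribution.csv"))
    readr::write_csv(b$centrality, file.path(d, "centrality.csv"))
    readr::write_csv(tibble::as_tibble(b$loadings$standardized,
                                       rownames = "item"),
                     file.path(d, "loadings.csv"))
    if (!is.null(b$agreement)) {
      readr::write_csv(b$agreement, file.path(d, "subscale_agreement.csv"))
    }
    jsonlite::write_json(
      list(label = b$label, config = b$config,
           merge_map = b$uva$merge_map,
           n_items_out = b$uva$n_items_out),
      file.path(d, "bundle.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Compare cohort community structures on the original item set
#'
#' Expands every cohort's partition back to the original items through its
#' own merge map, then reports pairwise normalized and adjusted mutual
#' information plus a per-item label table flagging items that migrate
#' between cohorts.
#'
#' @param validation A `netpsy_validation` (>= 2 cohorts), or a list of
#'   `netpsy_bundle`s.
#' @return List with `agreement` (tibble: cohort_1, cohort_2, nmi, ami) and
#'   `items` (tibble: item, one aligned-label column per cohort,
#'   `migrating`).
#' @export
run_comparison <- function(validation) {
  bundles <- unclass(validation)
  if (length(bundles) < 2) abort("need at least two cohorts to compare")
  parts <- purrr::map(bundles, "expanded_partition")
  item_sets <- purrr::map(parts, function(p) sort(names(p$assignment)))
  if (length(unique(item_sets)) != 1) {
    abort("cohorts do not share the original item set")
  }
  labels <- names(bundles)
  pairs <- combn(labels, 2)
  agreement <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble::tibble(cohort_1 = a, cohort_2 = b,
                   nmi = nmi(parts[[a]], parts[[b]]),
                   ami = ami(parts[[a]], parts[[b]]))
  })
  ref <- parts[[1]]
  aligned <- purrr::map(parts, function(p) {
    align_labels(p, ref)[sort(names(ref$assignment))]
  })
  items <- tibble::tibble(item = sort(names(ref$assignment)))
  for (lb in labels) items[[lb]] <- as.integer(aligned[[lb]])
  items$migrating <- apply(items[labels], 1,
                           function(r) length(unique(r)) > 1)
  list(agreement = agreement, items = items)
}
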