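# Clonal diversity from liquid-culture phenotypes: isolates are clustered on
# their absorbance/fluorescence channels by agglomerative clustering, the
# dendrogram is cut at a fixed linkage-distance cutoff, and each population's
# diversity score is the percentage of distinct clusters among its isolates.

#' Cluster isolates by phenotype
#'
#' Agglomerative (hierarchical) clustering of isolates on their measurement
#' channels; clusters are the groups that remain connected after removing all
#' merges whose linkage distance exceeds `cutoff`. The clustering source did
#' not name a linkage or metric, so both are explicit arguments recorded in
#' the result; the defaults (single linkage, Euclidean distance) match the
#' Matlab `linkage` defaults. Channels are z-scored per feature by default
#' because they live on wildly different scales; the fixed default cutoff
#' 1.12 is only meaningful on the scale the features are in.
#'
#' @param x a `phenotype_panel` / data frame with an `isolate` column,
#'   optional `population` column and numeric channel columns, or a plain
#'   numeric matrix (rows = isolates).
#' @param cutoff linkage-distance cutoff (default 1.12).
#' @param linkage_method agglomeration method for [stats::hclust()]
#'   (default `"single"`).
#' @param distance_metric metric for [stats::dist()] (default `"euclidean"`).
#' @param standardize z-score each channel before computing distances
#'   (default `TRUE`); constant channels are left at 0.
#' @return object of class `cluster_assignment`: list with `assignment`
#'   (data frame `isolate`, `population`, `cluster`), `cutoff`,
#'   `linkage_method`, `distance_metric`, `standardize`, `n_clusters`, and
#'   the underlying `hclust` tree. Cluster ids are contiguous from 1 in
#'   order of first appearance.
#' @export
hierarchical_clusters <- function(x, cutoff = 1.12,
                                  linkage_method = "single",
                                  distance_metric = "euclidean",
                                  standardize = TRUE) {
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  if (is.data.frame(x)) {
    iso <- if ("isolate" %in% names(x)) as.character(x$isolate) else
      sprintf("isolate%d", seq_len(nrow(x)))
    pop <- if ("population" %in% names(x)) x$population else NA
    drop <- intersect(c("isolate", "population", "true_cluster"), names(x))
    mat <- as.matrix(x[, setdiff(names(x), drop), drop = FALSE])
  } else {
    mat <- as.matrix(x)
    iso <- rownames(mat) %||% sprintf("isolate%d", seq_len(nrow(mat)))
    pop <- NA
  }
  if (!is.numeric(mat)) stop("channel columns must be numeric", call. = FALSE)
  if (nrow(mat) < 2L) stop("need at least 2 isolates to cluster", call. = FALSE)
  if (anyNA(mat)) stop("phenotype matrix contains missing values", call. = FALSE)
  if (standardize) {
    mat <- apply(mat, 2L, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
  }
  rownames(mat) <- iso
  d <- stats::dist(mat, method = distance_metric)
  tree <- stats::hclust(d, method = linkage_method)
  raw <- stats::cutree(tree, h = cutoff)
  # renumber contiguously in order of first appearance
  ids <- match(raw, unique(raw))
  structure(list(
    assignment = data.frame(isolate = iso, population = pop, cluster = ids,
                            stringsAsFactors = FALSE),
    cutoff = cutoff,
    linkage_method = linkage_method,
    distance_metric = distance_metric,
    standardize = standardize,
    n_clusters = length(unique(ids)),
    tree = tree
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d isolates in %d clusters (%s linkage, %s distance, cutoff %.3g%s)\n",
              nrow(x$assignment), x$n_clusters, x$linkage_method,
              x$distance_metric, x$cutoff,
              if (x$standardize) ", z-scored channels" else ""))
  invisible(x)
}

#' Per-population clonal diversity score
#'
#' For each population, `100 * (number of distinct clusters represented) /
#' (number of isolates sampled)`. With the standard 8 isolates per population
#' the score ranges from 12.5% (all isolates in one cluster) to 100% (every
#' isolate its own cluster) in steps of 12.5. Populations with a different
#' isolate count are scored with their own count as denominator and flagged.
#'
#' @param assignment a [hierarchical_clusters()] result, or a data frame with
#'   columns `isolate` and `cluster`.
#' @param populations optional isolate -> population mapping (named vector or
#'   data frame with `isolate`, `population`); defaults to the populations
#'   stored in the assignment.
#' @param expected_n the per-population sample size the score was designed
#'   for (default 8).
#' @return data frame of class `diversity_report`: `population`,
#'   `n_isolates`, `n_clusters`, `score` (percent), `nonstandard_n`.
#' @export
diversity_score <- function(assignment, populations = NULL, expected_n = 8L) {
  df <- if (inherits(assignment, "cluster_assignment")) assignment$assignment
        else as.data.frame(assignment)
  stop_missing_cols(df, c("isolate", "cluster"), "cluster assignment")
  if (!is.null(populations)) {
    if (is.data.frame(populations)) {
      stop_missing_cols(populations, c("isolate", "population"), "population mapping")
      pop <- stats::setNames(populations$population, populations$isolate)
    } else {
      pop <- populations
    }
    df$population <- pop[as.character(df$isolate)]
  }
  if (!"population" %in% names(df) || all(is.na(df$population))) {
    stop("no population mapping available for the isolates", call. = FALSE)
  }
  if (anyNA(df$population)) {
    stop("isolates without a population: ",
         paste(df$isolate[is.na(df$population)], collapse = ", "), call. = FALSE)
  }
  pops <- unique(df$population)
  rows <- lapply(pops, function(p) {
    sub <- df[df$population == p, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) stop("population ", p, " has no isolates", call. = FALSE)
    k <- length(unique(sub$cluster))
    data.frame(population = p, n_isolates = n, n_clusters = k,
               score = 100 * k / n, nonstandard_n = n != expected_n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_report", "data.frame")
  out
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report> percent of distinct phenotype clusters per population\n")
  print.data.frame(x, row.names = FALSE)
  if (any(x$nonstandard_n)) {
    cat("note: populations flagged nonstandard_n do not have the standard sample size\n")
  }
  invisible(x)
}

#' Serialize a dendrogram to Newick
#'
#' Exports the clustering tree of a [hierarchical_clusters()] result (or any
#' `hclust` object) as a Newick string, optionally writing it to a file.
#'
#' @param x a `cluster_assignment`, `clustergram` component, or `hclust`.
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
dendrogram_newick <- function(x, file = NULL) {
  tree <- if (inherits(x, "cluster_assignment")) x$tree else x
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
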