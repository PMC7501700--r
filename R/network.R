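# Global bipartite drug-target network: assembly, degree statistics,
# herb overlap analysis, common-target cores and subnetwork extraction.

# Half-up rounding to `digits` decimals (round() in R rounds half to even;
# reported network means use the conventional half-up).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Assemble the global drug-target network
#'
#' Unions known and predicted DTI records into one bipartite network,
#' keeping per-edge provenance. When the same (compound, target) edge
#' appears in both lists, the known record wins.
#'
#' @param known data.frame of known DTI records.
#' @param predicted data.frame of predicted DTI records (may be `NULL`).
#' @return a `dti_network` object: `edges` data.frame (`compound_id`,
#'   `target`, `provenance`, `score`), plus compound and target node lists.
#' @export
assemble_network <- function(known, predicted = NULL) {
  cols <- c("compound_id", "target", "provenance", "score")
  tidy <- function(df, prov) {
    if (is.null(df) || nrow(as.data.frame(df)) == 0)
      return(data.frame(compound_id = character(), target = character(),
                        provenance = character(), score = numeric(),
                        stringsAsFactors = FALSE))
    df <- as.data.frame(df)
    if (!"provenance" %in% names(df)) df$provenance <- prov
    if (!"score" %in% names(df)) df$score <- NA_real_
    df$target <- normalize_gene_symbols(df$target)
    df[, cols]
  }
  edges <- rbind(tidy(known, "known"), tidy(predicted, "predicted"))
  bad <- setdiff(unique(edges$provenance), c("known", "predicted"))
  if (length(bad) > 0)
    stop("unknown provenance value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  # known records first, so duplicated() on the pair key resolves a
  # known/predicted collision to known
  edges <- edges[order(edges$provenance != "known"), , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$compound_id, edges$target,
                                   sep = "\r")), , drop = FALSE]
  edges <- edges[order(edges$compound_id, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 compounds = sort(unique(edges$compound_id)),
                 targets = sort(unique(edges$target))),
            class = "dti_network")
}

#' @export
print.dti_network <- function(x, ...) {
  tab <- table(x$edges$provenance)
  cat("<dti_network> ", nrow(x$edges), " DTIs connecting ",
      length(x$compounds), " compounds with ", length(x$targets),
      " targets\n", sep = "")
  cat("  provenance:",
      paste(sprintf("%s = %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.dti_network <- function(object, ...) degree_summary(object)

#' Degree statistics of a drug-target network
#'
#' Computes per-node degrees and the two global means: the average target
#' degree of a compound (`edges / compounds`) and the average compound
#' degree of a target (`edges / targets`). Means are reported half-up
#' rounded to one decimal; full precision is retained in the returned
#' object.
#'
#' @param network a `dti_network`.
#' @param provenance optional filter: `"known"` or `"predicted"` to count
#'   only edges of that provenance (default: both).
#' @return a `degree_summary` object: `mean_compound_degree`,
#'   `mean_target_degree` (exact), the rounded values, per-node degree
#'   tables, and top-degree lists.
#' @export
degree_summary <- function(network, provenance = NULL) {
  stopifnot(inherits(network, "dti_network"))
  edges <- network$edges
  if (!is.null(provenance))
    edges <- edges[edges$provenance %in% provenance, , drop = FALSE]
  if (nrow(edges) == 0) stop("empty network", call. = FALSE)
  cdeg <- sort(table(edges$compound_id), decreasing = TRUE)
  tdeg <- sort(table(edges$target), decreasing = TRUE)
  n_edges <- nrow(edges)
  res <- list(
    n_edges = n_edges,
    n_compounds = length(cdeg),
    n_targets = length(tdeg),
    mean_compound_degree = n_edges / length(cdeg),
    mean_target_degree = n_edges / length(tdeg),
    compound_degrees = stats::setNames(as.integer(cdeg), names(cdeg)),
    target_degrees = stats::setNames(as.integer(tdeg), names(tdeg)))
  res$mean_compound_degree_1dp <- round_half_up(res$mean_compound_degree, 1)
  res$mean_target_degree_1dp <- round_half_up(res$mean_target_degree, 1)
  class(res) <- "degree_summary"
  res
}

#' @export
print.degree_summary <- function(x, n_top = 10, ...) {
  cat("<degree_summary> ", x$n_edges, " edges, ", x$n_compounds,
      " compounds, ", x$n_targets, " targets\n", sep = "")
  cat(sprintf("  mean target degree per compound (D): %.1f\n",
              x$mean_compound_degree_1dp))
  cat(sprintf("  mean compound degree per target (K): %.1f\n",
              x$mean_target_degree_1dp))
  top <- utils::head(x$compound_degrees, n_top)
  cat("  top compounds:",
      paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  top <- utils::head(x$target_degrees, n_top)
  cat("  top targets:  ",
      paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

# Target set of a herb: union of its compounds' neighbors in the network.
.herb_targets <- function(compound_ids, network) {
  e <- network$edges
  unique(e$target[e$compound_id %in% compound_ids])
}

#' Pairwise herb overlap matrix
#'
#' Counts shared items between every pair of herbs. With
#' `item = "compounds"` the items are the herbs' own compound sets; with
#' `item = "targets"` each herb's item set is the union of its compounds'
#' neighbors in `network`. The diagonal holds each herb's item-set size.
#'
#' @param herbs long-format herb membership data.frame (`herb_id`,
#'   `compound_id`).
#' @param item `"compounds"` or `"targets"`.
#' @param network a `dti_network` (required for `item = "targets"`).
#' @return symmetric integer matrix, herbs x herbs.
#' @export
herb_overlap <- function(herbs, item = c("compounds", "targets"),
                         network = NULL) {
  item <- match.arg(item)
  sets <- herb_compound_sets(herbs)
  if (item == "targets") {
    if (is.null(network)) stop("item = 'targets' needs a network",
                               call. = FALSE)
    sets <- lapply(sets, .herb_targets, network = network)
  }
  sets <- lapply(sets, unique)
  ids <- names(sets)
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids))
    for (j in seq_len(i))
      m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]]))
  m
}

#' Targets common to every herb
#'
#' Intersection of all herbs' target sets (each herb's target set being the
#' union of its compounds' neighbors in the network).
#'
#' @param herbs long-format herb membership data.frame with at least two
#'   herbs.
#' @param network a `dti_network`.
#' @return sorted character vector of gene symbols.
#' @export
common_targets <- function(herbs, network) {
  sets <- herb_compound_sets(herbs)
  if (length(sets) < 2) stop("need at least 2 herbs", call. = FALSE)
  tsets <- lapply(sets, .herb_targets, network = network)
  sort(Reduce(intersect, tsets))
}

#' Extract the induced subnetwork of a compound set
#'
#' Restricts the bipartite network to the listed compounds and their
#' targets, preserving edge provenance.
#'
#' @param network a `dti_network`.
#' @param compound_ids non-empty character vector of compound ids, all
#'   present in the network.
#' @return a `dti_network`.
#' @export
extract_subnetwork <- function(network, compound_ids) {
  stopifnot(inherits(network, "dti_network"))
  if (length(compound_ids) == 0)
    stop("empty compound id list", call. = FALSE)
  bad <- setdiff(compound_ids, network$compounds)
  if (length(bad) > 0)
    stop("compound id(s) not in network: ", paste(bad, collapse = ", "),
         call. = FALSE)
  e <- network$edges[network$edges$compound_id %in% compound_ids, ,
                     drop = FALSE]
  rownames(e) <- NULL
  structure(list(edges = e,
                 compounds = sort(unique(e$compound_id)),
                 targets = sort(unique(e$target))),
            class = "dti_network")
}

#' High-degree nodes
#'
#' Nodes on one side of the bipartite network whose degree strictly exceeds
#' a threshold, sorted by degree descending then id.
#'
#' @param network a `dti_network`.
#' @param side `"compounds"` or `"targets"`.
#' @param threshold nonnegative degree threshold (strict).
#' @return data.frame with columns `node`, `degree`.
#' @export
high_degree_nodes <- function(network, side = c("compounds", "targets"),
                              threshold = 0) {
  side <- match.arg(side)
  stopifnot(threshold >= 0)
  deg <- if (side == "compounds") table(network$edges$compound_id)
         else table(network$edges$target)
  deg <- deg[deg > threshold]
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
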