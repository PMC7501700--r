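# Compound-disease prioritization (Fisher's exact, right tail, BH-corrected)
# and generic hypergeometric over-representation analysis for annotation
# gene sets.

#' Right-tail Fisher's exact probability of a 2x2 table
#'
#' Exact enrichment p-value with both margins fixed:
#' `P(X >= a)` for `X ~ Hypergeometric`, where the table is
#' `a` = query-and-annotated, `b` = query-only, `c` = annotated-only,
#' `d` = neither. One-sided in the enrichment direction.
#'
#' @param a,b,c,d nonnegative integer cell counts (vectorized).
#' @return numeric vector of exact right-tail probabilities.
#' @export
fisher_right_tail <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  if (any(c(a, b, c, d) != round(c(a, b, c, d))))
    stop("cell counts must be integers", call. = FALSE)
  # X ~ Hyper(m = a+b draws-of-interest, n = c+d, k = a+c sampled)
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted values (`stats::p.adjust(method = "BH")`), clipped
#' at 1 and returned in the input order, after validating that every input
#' lies in `[0,1]`.
#'
#' @param pvals numeric vector of raw p-values in `[0,1]`.
#' @return numeric vector of adjusted values (q), same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Compound-disease enrichment across a drug-target network
#'
#' The network-based prioritization: for every compound with at least one
#' target in the universe, tests whether its target profile is enriched for
#' disease genes by a right-tail Fisher's exact test on the 2x2 table
#' (targets vs non-targets, disease vs non-disease over the universe), then
#' adjusts across all tested compounds by Benjamini-Hochberg. Compounds
#' with zero in-universe targets are excluded from the family (they cannot
#' be enriched and would distort the correction).
#'
#' @param network a `dti_network` ([assemble_network()]).
#' @param disease a `gene_set` or character vector of disease gene symbols.
#' @param universe `"network"` (the network's target genes; default) or
#'   `"union"` (network targets plus disease genes).
#' @param q_star significance level on the adjusted value (default 0.05).
#' @return an `enrichment_result` data.frame, one row per tested compound:
#'   `compound_id`, cells `a`,`b`,`c`,`d`, `p`, `q`, `significant`; sorted
#'   by `q` then `p`. Attributes record the universe size and policy.
#' @export
compound_disease_enrichment <- function(network, disease,
                                        universe = c("network", "union"),
                                        q_star = 0.05) {
  stopifnot(inherits(network, "dti_network"))
  universe <- match.arg(universe)
  disease_genes <- .as_genes(disease)
  uni <- network$targets
  if (universe == "union") uni <- sort(union(uni, disease_genes))
  dis <- intersect(disease_genes, uni)
  if (length(dis) == 0)
    stop("no disease genes in the chosen universe", call. = FALSE)

  e <- network$edges[network$edges$target %in% uni, , drop = FALSE]
  tsets <- split(e$target, e$compound_id)
  tsets <- lapply(tsets, unique)
  if (length(tsets) == 0) stop("no compound has targets in the universe",
                               call. = FALSE)
  N <- length(uni); K <- length(dis)
  a <- vapply(tsets, function(t) length(intersect(t, dis)), integer(1))
  n_t <- vapply(tsets, length, integer(1))
  b <- n_t - a
  c_ <- K - a
  d <- N - K - b
  p <- fisher_right_tail(a, b, c_, d)
  q <- bh_adjust(p)
  out <- data.frame(compound_id = names(tsets),
                    a = a, b = b, c = c_, d = d,
                    n_targets = n_t, p = p, q = q,
                    significant = q < q_star,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$q, out$p, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe_size") <- N
  attr(out, "n_disease_in_universe") <- K
  attr(out, "universe_policy") <- universe
  attr(out, "q_star") <- q_star
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat("<enrichment_result> ", nrow(x), " compounds tested against ",
      attr(x, "n_disease_in_universe"), "/", attr(x, "universe_size"),
      " disease genes in the universe; ", sum(x$significant),
      " significant at q < ", attr(x, "q_star"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric enrichment of a query gene list against
#' annotation gene sets over a fixed universe, with BH adjustment across
#' sets. Query genes outside the universe are dropped with a warning.
#'
#' @param query_genes character vector (or `gene_set`) of query genes.
#' @param annotations list of `gene_set` objects (e.g.
#'   [read_gene_sets_gmt()]).
#' @param universe character vector of background gene symbols.
#' @param q_star significance level on the adjusted value.
#' @return data.frame, one row per annotation set, sorted by `q`:
#'   `set_id`, `overlap`, `set_size`, `query_size`, `universe_size`, `p`,
#'   `q`, `significant`.
#' @export
ora_hypergeometric <- function(query_genes, annotations, universe,
                               q_star = 0.05) {
  universe <- unique(normalize_gene_symbols(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- .as_genes(query_genes)
  out_q <- setdiff(query, universe)
  if (length(out_q) > 0) {
    warning("dropping ", length(out_q), " query gene(s) outside the universe",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stop("no query genes in universe", call. = FALSE)
  rows <- lapply(annotations, function(s) {
    set <- intersect(s$genes, universe)
    ov <- length(intersect(query, set))
    p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set_id = s$set_id, overlap = ov, set_size = length(set),
               query_size = length(query), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_star
  out <- out[order(out$q, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
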