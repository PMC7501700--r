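# Substructure-drug-target resource diffusion for target prediction.
#
# The tripartite graph has three node layers: drugs, substructure bits and
# protein targets. Drug-substructure edges come from fingerprint bits equal
# to 1; drug-target edges from known DTIs. There are no within-layer or
# substructure-target edges. A unit of resource placed around a drug is
# diffused for k rounds; the final mass on target nodes ranks candidate
# targets. Node names are prefixed internally ("d:", "s:", "t:") so the
# three layers can never collide.

#' Diffusion parameters
#'
#' Parameters of the network-based inference: `alpha` balances the initial
#' resource between the substructure and target sides of a drug, `beta`
#' weights the two edge types during spreading, `gamma` is the hub-degree
#' exponent (negative values penalize hubs), `k` the number of diffusion
#' rounds and `top_n` the number of ranked predictions kept per drug.
#' Defaults are alpha = beta = 0.1, gamma = -0.5, k = 2, top_n = 20.
#'
#' @param alpha initial-resource balance, in `[0,1]`.
#' @param beta edge-type weight during spreading, in `[0,1]`.
#' @param gamma hub-degree exponent (unbounded; typically `<= 0`).
#' @param k integer number of diffusion rounds, `>= 1`.
#' @param top_n ranked predictions kept per drug, `>= 1`.
#' @return a `diffusion_params` list.
#' @export
diffusion_params <- function(alpha = 0.1, beta = 0.1, gamma = -0.5,
                             k = 2, top_n = 20) {
  stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1,
            is.numeric(beta), beta >= 0, beta <= 1,
            is.numeric(gamma), length(gamma) == 1)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be an integer >= 1", call. = FALSE)
  if (!is.numeric(top_n) || top_n < 1)
    stop("top_n must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 k = as.integer(k), top_n = as.integer(top_n)),
            class = "diffusion_params")
}

# paste0 recycles zero-length arguments to "", which would fabricate a
# phantom node name for an empty layer
.pfx <- function(prefix, x) if (length(x)) paste0(prefix, x) else character(0)

#' Build the tripartite substructure-drug-target graph
#'
#' Compounds whose fingerprint row is all zero carry no substructure
#' information and are excluded (with a warning); DTI rows for compounds
#' absent from the fingerprint table are likewise dropped with a warning.
#' An empty DTI list is allowed (new-chemical-entity mode: predictions are
#' driven by substructure sharing alone).
#'
#' @param fingerprints a [fingerprint_table()].
#' @param known_dtis data.frame of known DTI records (may be `NULL` or
#'   empty).
#' @return a `tripartite_graph`: drug/substructure/target node ids, sparse
#'   drug-substructure and drug-target incidence matrices, and the static
#'   total-degree index used for hub weighting.
#' @export
build_tripartite <- function(fingerprints, known_dtis = NULL) {
  stopifnot(inherits(fingerprints, "fingerprint_table"))
  bits <- fingerprints$bits
  zero <- rowSums(bits) == 0
  if (any(zero)) {
    warning("excluding ", sum(zero),
            " compound(s) with all-zero fingerprints: ",
            paste(utils::head(rownames(bits)[zero], 10), collapse = ", "),
            call. = FALSE)
    bits <- bits[!zero, , drop = FALSE]
  }
  if (nrow(bits) == 0) stop("no usable drugs (all fingerprints empty)",
                            call. = FALSE)
  bits <- bits[, colSums(bits) > 0, drop = FALSE]
  drugs <- rownames(bits)
  subs <- colnames(bits)

  if (is.null(known_dtis) || nrow(as.data.frame(known_dtis)) == 0) {
    dti <- data.frame(compound_id = character(), target = character(),
                      stringsAsFactors = FALSE)
  } else {
    dti <- as.data.frame(known_dtis)[, c("compound_id", "target")]
    dti$target <- normalize_gene_symbols(dti$target)
    unknown <- setdiff(unique(dti$compound_id), drugs)
    if (length(unknown) > 0) {
      warning("dropping DTIs for ", length(unknown),
              " compound(s) absent from the fingerprint table",
              call. = FALSE)
      dti <- dti[dti$compound_id %in% drugs, , drop = FALSE]
    }
    dti <- dti[!duplicated(paste(dti$compound_id, dti$target, sep = "\r")), ,
               drop = FALSE]
  }
  targets <- sort(unique(dti$target))

  A_ds <- Matrix::Matrix(bits, sparse = TRUE)
  A_dt <- Matrix::sparseMatrix(
    i = match(dti$compound_id, drugs),
    j = match(dti$target, targets),
    x = 1, dims = c(length(drugs), length(targets)),
    dimnames = list(drugs, targets))

  deg <- c(Matrix::rowSums(A_ds) + Matrix::rowSums(A_dt),
           Matrix::colSums(A_ds),
           Matrix::colSums(A_dt))
  names(deg) <- c(.pfx("d:", drugs), .pfx("s:", subs),
                  .pfx("t:", targets))

  structure(list(drugs = drugs, substructures = subs, targets = targets,
                 A_ds = A_ds, A_dt = A_dt, degree = deg,
                 excluded = rownames(fingerprints$bits)[zero]),
            class = "tripartite_graph")
}

#' @export
print.tripartite_graph <- function(x, ...) {
  cat("<tripartite_graph> ", length(x$drugs), " drugs, ",
      length(x$substructures), " substructure bits, ",
      length(x$targets), " targets; ",
      Matrix::nnzero(x$A_ds), " drug-substructure edges, ",
      Matrix::nnzero(x$A_dt), " drug-target edges\n", sep = "")
  if (length(x$excluded) > 0)
    cat("  (", length(x$excluded), " compounds excluded: empty fingerprints)\n",
        sep = "")
  invisible(x)
}

# Row-normalize a sparse matrix, leaving all-zero rows zero.
.row_norm <- function(m) {
  rs <- Matrix::rowSums(m)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% m
}

# The two half-round operators.
#  R_mat ((S+T) x D): substructure/target nodes return mass evenly to their
#    neighboring drugs.
#  S_mat (D x (S+T)): each drug sends beta of its mass to its substructure
#    neighbors and (1-beta) to its target neighbors (all to the side that
#    exists when the other is empty), within a side proportionally to
#    (static total degree)^gamma.
.half_rounds <- function(graph, beta, gamma) {
  nd <- length(graph$drugs); ns <- length(graph$substructures)
  nt <- length(graph$targets)
  R_mat <- rbind(.row_norm(Matrix::t(graph$A_ds)),
                 if (nt > 0) .row_norm(Matrix::t(graph$A_dt))
                 else Matrix::Matrix(0, 0, nd, sparse = TRUE))

  deg_s <- graph$degree[paste0("s:", graph$substructures)]
  W_s <- .row_norm(graph$A_ds %*% Matrix::Diagonal(x = deg_s^gamma))
  if (nt > 0) {
    deg_t <- graph$degree[.pfx("t:", graph$targets)]
    W_t <- .row_norm(graph$A_dt %*% Matrix::Diagonal(x = deg_t^gamma))
  } else {
    W_t <- Matrix::Matrix(0, nd, 0, sparse = TRUE)
  }
  has_t <- Matrix::rowSums(graph$A_dt) > 0
  b_s <- ifelse(has_t, beta, 1)       # side weight when target side exists
  b_t <- ifelse(has_t, 1 - beta, 0)
  S_mat <- cbind(Matrix::Diagonal(x = b_s) %*% W_s,
                 Matrix::Diagonal(x = b_t) %*% W_t)
  list(R_mat = R_mat, S_mat = S_mat)
}

#' Initial resource allocation for one drug
#'
#' Places a unit of resource around `drug`: a fraction `alpha` is split
#' evenly over the drug's substructure neighbors and `1 - alpha` evenly over
#' its known-target neighbors. A drug without known targets sends all mass
#' to its substructure neighbors.
#'
#' @param graph a `tripartite_graph`.
#' @param drug drug (compound) id present in the graph.
#' @param alpha initial-resource balance in `[0,1]`.
#' @return named numeric vector over all graph nodes (names prefixed
#'   `d:`/`s:`/`t:`), summing to 1.
#' @export
initial_resource <- function(graph, drug, alpha = 0.1) {
  stopifnot(inherits(graph, "tripartite_graph"))
  i <- match(drug, graph$drugs)
  if (is.na(i)) stop("drug '", drug, "' not in graph", call. = FALSE)
  r <- stats::setNames(numeric(length(graph$degree)), names(graph$degree))
  srow <- graph$A_ds[i, ]
  trow <- if (length(graph$targets) > 0) graph$A_dt[i, ] else numeric(0)
  ns <- sum(srow); nt <- sum(trow)
  a <- if (nt > 0) alpha else 1
  r[paste0("s:", graph$substructures)] <- a * srow / ns
  if (nt > 0)
    r[.pfx("t:", graph$targets)] <- (1 - alpha) * trow / nt
  r
}

#' Run k rounds of resource diffusion
#'
#' Each round first returns the mass held on substructure and target nodes
#' evenly to their neighboring drugs, then lets every drug spread its mass
#' to its two sides as described in [diffusion_params()]. Mass already
#' sitting on a drug node simply joins the spread step. With `gamma = 0`
#' total mass is conserved exactly; with `gamma != 0` the within-side
#' degree weighting still normalizes each drug's outflow, so conservation
#' holds as well — only the allocation changes.
#'
#' @param graph a `tripartite_graph`.
#' @param resource named numeric vector over graph nodes (as produced by
#'   [initial_resource()]).
#' @param params a [diffusion_params()] object.
#' @return named numeric vector: the resource after `k` rounds.
#' @export
propagate <- function(graph, resource, params = diffusion_params()) {
  stopifnot(inherits(graph, "tripartite_graph"))
  if (params$k < 1) stop("k must be >= 1", call. = FALSE)
  nodes <- names(graph$degree)
  if (!setequal(names(resource), nodes))
    stop("resource vector does not match graph nodes", call. = FALSE)
  r <- resource[nodes]
  hr <- .half_rounds(graph, params$beta, params$gamma)
  nd <- length(graph$drugs)
  for (round in seq_len(params$k)) {
    r_d <- r[seq_len(nd)]
    r_st <- r[-seq_len(nd)]
    on_drugs <- r_d + as.numeric(r_st %*% hr$R_mat)
    r_st_new <- as.numeric(on_drugs %*% hr$S_mat)
    r <- stats::setNames(c(numeric(nd), r_st_new), nodes)
  }
  r
}

#' Fit a substructure-drug-target diffusion model
#'
#' Builds the tripartite graph from a fingerprint table and known DTIs and
#' precomputes the k-round diffusion operator, ready for target prediction.
#'
#' @param fingerprints a [fingerprint_table()].
#' @param known_dtis data.frame of known DTI records (may be empty).
#' @param params a [diffusion_params()] object.
#' @return an object of class `sdtnbi` with `graph`, `params` and the
#'   per-drug score matrix over targets (raw final resource masses; only
#'   ranks are contractually meaningful).
#' @seealso [predict.sdtnbi()], [evaluate_auc()]
#' @export
sdtnbi <- function(fingerprints, known_dtis = NULL,
                   params = diffusion_params()) {
  graph <- build_tripartite(fingerprints, known_dtis)
  hr <- .half_rounds(graph, params$beta, params$gamma)
  P <- hr$R_mat %*% hr$S_mat            # one full round on the (S+T) space
  Pk <- P
  if (params$k > 1)
    for (i in seq_len(params$k - 1)) Pk <- Pk %*% P

  # initial resources for every drug at once: alpha split over
  # substructures, (1-alpha) over known targets (all to substructures when
  # a drug has none)
  has_t <- Matrix::rowSums(graph$A_dt) > 0
  a_s <- ifelse(has_t, params$alpha, 1)
  R0 <- cbind(Matrix::Diagonal(x = a_s) %*% .row_norm(graph$A_ds),
              Matrix::Diagonal(x = ifelse(has_t, 1 - params$alpha, 0)) %*%
                .row_norm(graph$A_dt))
  final <- R0 %*% Pk
  nt <- length(graph$targets)
  scores <- if (nt > 0) {
    m <- as.matrix(final[, length(graph$substructures) + seq_len(nt),
                         drop = FALSE])
    dimnames(m) <- list(graph$drugs, graph$targets)
    m
  } else {
    matrix(numeric(0), nrow = length(graph$drugs), ncol = 0,
           dimnames = list(graph$drugs, NULL))
  }
  structure(list(graph = graph, params = params, scores = scores),
            class = "sdtnbi")
}

#' @export
print.sdtnbi <- function(x, ...) {
  p <- x$params
  cat("<sdtnbi> diffusion model: ", length(x$graph$drugs), " drugs, ",
      length(x$graph$substructures), " substructure bits, ",
      length(x$graph$targets), " targets\n", sep = "")
  cat(sprintf("  alpha = %g, beta = %g, gamma = %g, k = %d, top_n = %d\n",
              p$alpha, p$beta, p$gamma, p$k, p$top_n))
  invisible(x)
}

#' @export
summary.sdtnbi <- function(object, ...) {
  g <- object$graph
  out <- list(
    n_drugs = length(g$drugs),
    n_substructures = length(g$substructures),
    n_targets = length(g$targets),
    n_ds_edges = Matrix::nnzero(g$A_ds),
    n_dt_edges = Matrix::nnzero(g$A_dt),
    n_excluded = length(g$excluded),
    params = object$params)
  class(out) <- "summary.sdtnbi"
  out
}

#' @export
print.summary.sdtnbi <- function(x, ...) {
  cat("Substructure-drug-target diffusion model\n")
  cat("  drugs:         ", x$n_drugs, "\n")
  cat("  substructures: ", x$n_substructures,
      " (", x$n_ds_edges, " edges)\n", sep = "")
  cat("  targets:       ", x$n_targets,
      " (", x$n_dt_edges, " known DTI edges)\n", sep = "")
  if (x$n_excluded > 0)
    cat("  excluded drugs (empty fingerprints): ", x$n_excluded, "\n")
  p <- x$params
  cat(sprintf("  alpha = %g, beta = %g, gamma = %g, k = %d, top_n = %d\n",
              p$alpha, p$beta, p$gamma, p$k, p$top_n))
  invisible(x)
}

# Rank one drug's score row: known targets removed unless exclude_known is
# FALSE; descending score with ties broken by gene symbol.
.rank_row <- function(fit, drug, top_n, exclude_known) {
  g <- fit$graph
  sc <- fit$scores[drug, ]
  if (exclude_known && length(g$targets) > 0) {
    known <- g$targets[as.numeric(g$A_dt[match(drug, g$drugs), ]) > 0]
    sc <- sc[setdiff(names(sc), known)]
  }
  if (length(sc) == 0)
    return(data.frame(target = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  ord <- order(-sc, names(sc))
  sc <- sc[ord]
  n <- min(top_n, length(sc))
  data.frame(target = names(sc)[seq_len(n)],
             score = unname(sc[seq_len(n)]),
             stringsAsFactors = FALSE)
}

#' Predict putative targets from a fitted diffusion model
#'
#' Ranks candidate targets for each drug by final diffusion mass. Known
#' targets are removed ("putative" = not already known) unless
#' `exclude_known = FALSE` (used by the AUC harness); ties are broken by
#' gene symbol so top lists are reproducible.
#'
#' @param object a fitted [sdtnbi()] model.
#' @param compounds drug ids to predict for (default: all drugs in the
#'   graph).
#' @param top_n maximum predictions per drug (default from the fit params).
#' @param exclude_known drop each drug's known targets from its ranking.
#' @param type `"list"` for a named list of per-drug data.frames,
#'   `"edges"` for one combined data.frame of predicted DTI records,
#'   `"scores"` for the raw drug x target score matrix.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.sdtnbi <- function(object, compounds = NULL,
                           top_n = object$params$top_n,
                           exclude_known = TRUE,
                           type = c("list", "edges", "scores"), ...) {
  type <- match.arg(type)
  if (type == "scores") return(object$scores)
  if (is.null(compounds)) compounds <- object$graph$drugs
  bad <- setdiff(compounds, object$graph$drugs)
  if (length(bad) > 0)
    stop("unknown or unusable drug(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  preds <- lapply(compounds, function(d)
    .rank_row(object, d, top_n, exclude_known))
  names(preds) <- compounds
  if (type == "list") return(preds)
  n_each <- vapply(preds, nrow, integer(1))
  data.frame(compound_id = rep(compounds, n_each),
             target = unlist(lapply(preds, `[[`, "target"), use.names = FALSE),
             provenance = "predicted",
             score = unlist(lapply(preds, `[[`, "score"), use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Ranked putative targets for one drug
#'
#' Convenience wrapper around [sdtnbi()] + [predict.sdtnbi()] for a single
#' compound.
#'
#' @param graph a `tripartite_graph` or a fitted `sdtnbi` model.
#' @param drug drug id.
#' @param params a [diffusion_params()] (ignored when `graph` is already a
#'   fit).
#' @return data.frame with columns `target`, `score`, ordered by
#'   nonincreasing score.
#' @export
predict_targets <- function(graph, drug, params = diffusion_params()) {
  fit <- if (inherits(graph, "sdtnbi")) graph
         else structure(list(graph = graph, params = params,
                             scores = sdtnbi_scores_from_graph(graph, params)),
                        class = "sdtnbi")
  predict(fit, compounds = drug)[[1]]
}

# Score matrix for an existing graph (used when the caller holds a
# tripartite_graph rather than a fingerprint table).
sdtnbi_scores_from_graph <- function(graph, params) {
  hr <- .half_rounds(graph, params$beta, params$gamma)
  P <- hr$R_mat %*% hr$S_mat
  Pk <- P
  if (params$k > 1) for (i in seq_len(params$k - 1)) Pk <- Pk %*% P
  has_t <- Matrix::rowSums(graph$A_dt) > 0
  R0 <- cbind(Matrix::Diagonal(x = ifelse(has_t, params$alpha, 1)) %*%
                .row_norm(graph$A_ds),
              Matrix::Diagonal(x = ifelse(has_t, 1 - params$alpha, 0)) %*%
                .row_norm(graph$A_dt))
  final <- R0 %*% Pk
  nt <- length(graph$targets)
  if (nt == 0)
    return(matrix(numeric(0), nrow = length(graph$drugs), ncol = 0,
                  dimnames = list(graph$drugs, NULL)))
  m <- as.matrix(final[, length(graph$substructures) + seq_len(nt),
                       drop = FALSE])
  dimnames(m) <- list(graph$drugs, graph$targets)
  m
}

# Rank-based (Mann-Whitney) AUC; ties count one half.
.auc <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Hold-out AUC of known-DTI recovery
#'
#' Hides a random fraction of the known DTIs (seeded), refits the diffusion
#' model on the rest, scores every (drug, target) pair not retained in
#' training, and computes the AUC with the held-out edges as positives and
#' never-known pairs as negatives. Targets that lose all their training
#' edges receive score zero (they attract no mass).
#'
#' @param fingerprints a [fingerprint_table()].
#' @param known_dtis data.frame of known DTI records (`>= 10` rows).
#' @param holdout_fraction fraction of known DTIs to hide, in `(0,1)`.
#' @param params a [diffusion_params()].
#' @param seed integer seed for the hold-out draw.
#' @return an `sdtnbi_eval` object: `auc`, `holdout_fraction`, `seed`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_auc <- function(fingerprints, known_dtis, holdout_fraction = 0.2,
                         params = diffusion_params(), seed = 1) {
  dti <- as.data.frame(known_dtis)
  dti <- dti[dti$compound_id %in% fingerprints$compound_ids, , drop = FALSE]
  usable <- fingerprints$compound_ids[rowSums(fingerprints$bits) > 0]
  dti <- dti[dti$compound_id %in% usable, , drop = FALSE]
  if (nrow(dti) < 10)
    stop("need at least 10 known DTIs on usable drugs", call. = FALSE)
  sp <- holdout_split(dti, holdout_fraction, seed)
  fit <- suppressWarnings(sdtnbi(fingerprints, sp$train, params))
  g <- fit$graph
  universe <- sort(unique(dti$target))
  scores <- matrix(0, nrow = length(g$drugs), ncol = length(universe),
                   dimnames = list(g$drugs, universe))
  common <- intersect(universe, colnames(fit$scores))
  scores[, common] <- fit$scores[, common]

  key <- function(d, t) paste(d, t, sep = "\r")
  train_keys <- key(sp$train$compound_id, sp$train$target)
  known_keys <- key(dti$compound_id, dti$target)
  all_pairs <- expand.grid(compound_id = g$drugs, target = universe,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  all_keys <- key(all_pairs$compound_id, all_pairs$target)
  sc <- scores[cbind(match(all_pairs$compound_id, g$drugs),
                     match(all_pairs$target, universe))]
  is_train <- all_keys %in% train_keys
  is_pos <- all_keys %in% key(sp$test$compound_id, sp$test$target)
  is_neg <- !(all_keys %in% known_keys)
  structure(list(auc = .auc(sc[is_pos & !is_train], sc[is_neg]),
                 holdout_fraction = holdout_fraction, seed = seed,
                 n_pos = sum(is_pos & !is_train), n_neg = sum(is_neg)),
            class = "sdtnbi_eval")
}

#' @export
print.sdtnbi_eval <- function(x, ...) {
  cat(sprintf(
    "<sdtnbi_eval> AUC = %.3f (%d positives, %d negatives, holdout %.0f%%, seed %d)\n",
    x$auc, x$n_pos, x$n_neg, 100 * x$holdout_fraction, x$seed))
  invisible(x)
}
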