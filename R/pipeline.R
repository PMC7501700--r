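# End-to-end orchestration: load -> diffuse/predict -> assemble network ->
# degree/overlap analysis -> compound-disease prioritization -> four-step
# screen, with a reproducible run manifest. Stages are a thin, logged
# composition of the exported functions; all randomness flows from the
# single config seed.

#' Pipeline configuration
#'
#' Collects the file paths and parameters of a full analysis run. Defaults
#' follow the package-wide conventions: diffusion alpha = beta = 0.1,
#' gamma = -0.5, k = 2, top 20 predictions per compound, network-target
#' universe for enrichment, HIA/BBB threshold 0.5 and q* = 0.05.
#'
#' @param compounds,herbs,fingerprints,dti,disease input file paths
#'   (compound CSV, herb TSV, fingerprint CSV, known-DTI TSV, disease
#'   GMT).
#' @param main_components optional path to a plain-text file of main-
#'   component compound ids (one per line); when `NULL`, every compound is
#'   treated as a main component (step 1 always passes).
#' @param out_dir output directory for the stage TSVs and manifest.
#' @param alpha,beta,gamma,k,top_n diffusion parameters
#'   ([diffusion_params()]).
#' @param universe enrichment universe policy, `"network"` or `"union"`.
#' @param admet_threshold HIA/BBB positive-call cutoff.
#' @param q_star enrichment significance level.
#' @param seed integer seed for every stochastic step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(compounds, herbs, fingerprints, dti, disease,
                            main_components = NULL, out_dir = "netpharm_out",
                            alpha = 0.1, beta = 0.1, gamma = -0.5, k = 2,
                            top_n = 20, universe = "network",
                            admet_threshold = 0.5, q_star = 0.05, seed = 1) {
  structure(list(
    paths = list(compounds = compounds, herbs = herbs,
                 fingerprints = fingerprints, dti = dti, disease = disease,
                 main_components = main_components),
    out_dir = out_dir,
    params = diffusion_params(alpha, beta, gamma, k, top_n),
    universe = match.arg(universe, c("network", "union")),
    admet_threshold = admet_threshold, q_star = q_star,
    seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; file paths live under
#' a `paths:` mapping.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  p <- y$paths
  do.call(pipeline_config, c(
    list(compounds = p$compounds, herbs = p$herbs,
         fingerprints = p$fingerprints, dti = p$dti, disease = p$disease,
         main_components = p$main_components),
    y[setdiff(names(y), "paths")]))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order and writes `predicted.tsv`, `network.tsv`,
#' `degrees.tsv`, `overlaps.tsv`, `enrich.tsv`, `report.tsv` and
#' `manifest.yaml` into the configured output directory. Stage outputs are
#' pure functions of (inputs, config, seed); re-running with identical
#' inputs reproduces identical TSVs.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param quiet suppress progress messages.
#' @return a `run_manifest` (invisibly): config snapshot, input digests,
#'   per-stage counts, seed, package version, timestamp.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage diffusion: fingerprints + known DTIs -> predicted targets")
  fit <- .stage("diffusion", {
    fp <- read_fingerprint_table(config$paths$fingerprints)
    known <- read_dti_table(config$paths$dti)
    suppressWarnings(sdtnbi(fp, known, config$params))
  })
  known <- read_dti_table(config$paths$dti)
  predicted <- .stage("diffusion",
    predict(fit, type = "edges", top_n = config$params$top_n))
  write_dti_table(predicted, file.path(config$out_dir, "predicted.tsv"))

  say("stage network: assemble known + predicted DTIs")
  network <- .stage("network", assemble_network(known, predicted))
  write_network_tsv(network, file.path(config$out_dir, "network.tsv"))
  degs <- .stage("network", degree_summary(network))
  deg_df <- rbind(
    data.frame(node = names(degs$compound_degrees), side = "compound",
               degree = unname(degs$compound_degrees),
               stringsAsFactors = FALSE),
    data.frame(node = names(degs$target_degrees), side = "target",
               degree = unname(degs$target_degrees),
               stringsAsFactors = FALSE))
  utils::write.table(deg_df, file.path(config$out_dir, "degrees.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage overlap: herb compound/target overlap matrices")
  herbs <- .stage("overlap", read_herb_table(config$paths$herbs))
  ov <- .stage("overlap", {
    oc <- herb_overlap(herbs, "compounds")
    ot <- herb_overlap(herbs, "targets", network)
    rbind(
      data.frame(herb_i = rep(rownames(oc), ncol(oc)),
                 herb_j = rep(colnames(oc), each = nrow(oc)),
                 item = "compounds", count = as.vector(oc),
                 stringsAsFactors = FALSE),
      data.frame(herb_i = rep(rownames(ot), ncol(ot)),
                 herb_j = rep(colnames(ot), each = nrow(ot)),
                 item = "targets", count = as.vector(ot),
                 stringsAsFactors = FALSE))
  })
  utils::write.table(ov, file.path(config$out_dir, "overlaps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage enrichment: compound-disease prioritization")
  enrich <- .stage("enrichment", {
    disease <- read_gene_sets_gmt(config$paths$disease)[[1]]
    compound_disease_enrichment(network, disease,
                                universe = config$universe,
                                q_star = config$q_star)
  })
  utils::write.table(as.data.frame(enrich),
                     file.path(config$out_dir, "enrich.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage screening: four-step simplification")
  report <- .stage("screening", {
    compounds <- read_compound_table(config$paths$compounds)
    mc <- if (is.null(config$paths$main_components)) compounds$compound_id
          else readLines(config$paths$main_components, warn = FALSE)
    mc <- trimws(mc); mc <- mc[nzchar(mc)]
    four_step_screen(mc, compounds, enrich,
                     admet_threshold = config$admet_threshold,
                     q_star = config$q_star)
  })
  utils::write.table(as.data.frame(report),
                     file.path(config$out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  in_paths <- unlist(config$paths[!vapply(config$paths, is.null,
                                          logical(1))])
  manifest <- structure(list(
    tool = "netpharm",
    version = as.character(utils::packageVersion("netpharm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = list(
      params = unclass(config$params), universe = config$universe,
      admet_threshold = config$admet_threshold, q_star = config$q_star,
      out_dir = config$out_dir),
    input_digests = as.list(tools::md5sum(in_paths)),
    counts = list(
      compounds_usable = length(fit$graph$drugs),
      compounds_excluded = length(fit$graph$excluded),
      known_dtis = nrow(known),
      predicted_dtis = nrow(predicted),
      network_edges = nrow(network$edges),
      network_compounds = length(network$compounds),
      network_targets = length(network$targets),
      compounds_tested = nrow(enrich),
      compounds_significant = sum(enrich$significant),
      compounds_retained = sum(report$retained))),
    class = "run_manifest")
  yaml::write_yaml(unclass(manifest),
                   file.path(config$out_dir, "manifest.yaml"))
  say("done: ", config$out_dir)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> netpharm ", x$version, " (seed ", x$seed, ")\n",
      sep = "")
  for (n in names(x$counts))
    cat(sprintf("  %-22s %d\n", n, x$counts[[n]]))
  invisible(x)
}
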