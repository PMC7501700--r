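# Synthetic formula datasets with the statistical structure the analysis
# assumes: several herbs drawing compounds from a shared pool, sparse
# binary fingerprints coupled to a sparse known-DTI network, a disease
# gene subset of the target universe, and a planted subset of active
# compounds whose target profiles are enriched for disease genes at a
# controllable strength.
#
# Coupling design: compounds belong to latent scaffold modules. Each
# module owns a target profile; each target owns a few "driver" bits.
# A compound draws most of its targets from its module's profile and
# carries the driver bits of its targets, so compounds sharing a module
# share both targets and substructures — similar chemistry hits similar
# proteins, which is what makes held-out interactions recoverable by
# resource diffusion through either channel.

# Deterministic per-component sub-stream: adding a component never perturbs
# the draws of another.
.substream <- function(seed, component) {
  set.seed((as.integer(seed) %% 1000003L) * 97L + component)
}

#' Synthetic dataset configuration
#'
#' Defaults describe the benchmark regime used throughout the package's
#' tests: 6 herbs over a shared pool of 400 compounds, 200 targets, 300
#' substructure bits, 30 disease genes and 20 planted active compounds
#' whose target profiles contain at least a fraction
#' `planting_strength = 0.6` of disease genes (background disease fraction
#' 30/200 = 0.15). Fingerprint-target coupling wires DTIs to compounds
#' carrying each target's driver bits, making held-out interactions
#' recoverable by diffusion.
#'
#' @param n_herbs number of herbs.
#' @param n_compounds total compound pool size.
#' @param compounds_per_herb compounds sampled per herb from the shared
#'   pool (overlap between herbs arises from the shared pool).
#' @param n_targets size of the target (gene) universe.
#' @param n_bits number of substructure fingerprint bits.
#' @param targets_per_compound mean known targets per compound (Poisson,
#'   truncated at 1); the known-DTI density is
#'   `targets_per_compound / n_targets`.
#' @param n_modules number of latent scaffold modules.
#' @param module_size targets in each module's profile.
#' @param target_noise fraction of a compound's targets drawn uniformly
#'   from outside its module (0 = perfectly modular).
#' @param drivers_per_target driver bits assigned to each target.
#' @param coupling probability a compound carries each driver bit of its
#'   targets (signal strength for diffusion recoverability), in `[0,1]`.
#' @param bit_noise_density background probability of a non-driver bit.
#' @param n_disease_genes disease genes (subset of the target universe).
#' @param n_planted planted active compounds.
#' @param planting_strength minimum fraction of a planted compound's
#'   targets drawn from disease genes; must exceed the background disease
#'   fraction.
#' @param seed integer random seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_herbs = 6, n_compounds = 400,
                             compounds_per_herb = 100,
                             n_targets = 200, n_bits = 300,
                             targets_per_compound = 8,
                             n_modules = 40, module_size = 15,
                             target_noise = 0.15,
                             drivers_per_target = 3,
                             coupling = 0.9,
                             bit_noise_density = 0.02,
                             n_disease_genes = 30, n_planted = 20,
                             planting_strength = 0.6,
                             seed = 1) {
  cfg <- list(n_herbs = n_herbs, n_compounds = n_compounds,
              compounds_per_herb = compounds_per_herb,
              n_targets = n_targets, n_bits = n_bits,
              targets_per_compound = targets_per_compound,
              n_modules = n_modules, module_size = module_size,
              target_noise = target_noise,
              drivers_per_target = drivers_per_target,
              coupling = coupling, bit_noise_density = bit_noise_density,
              n_disease_genes = n_disease_genes, n_planted = n_planted,
              planting_strength = planting_strength,
              seed = as.integer(seed))
  counts <- c("n_herbs", "n_compounds", "compounds_per_herb", "n_targets",
              "n_bits", "drivers_per_target", "n_modules", "module_size")
  for (f in counts)
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop(f, " must be a positive integer", call. = FALSE)
  if (cfg$module_size > cfg$n_targets)
    stop("module_size exceeds the target universe", call. = FALSE)
  for (f in c("coupling", "bit_noise_density", "planting_strength",
              "target_noise"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0,1]", call. = FALSE)
  if (cfg$n_disease_genes > cfg$n_targets)
    stop("more disease genes than targets", call. = FALSE)
  if (cfg$n_planted > cfg$n_compounds)
    stop("more planted actives than compounds", call. = FALSE)
  if (cfg$compounds_per_herb > cfg$n_compounds)
    stop("compounds_per_herb exceeds the pool", call. = FALSE)
  if (cfg$n_planted > 0 &&
      cfg$planting_strength <= cfg$n_disease_genes / cfg$n_targets)
    stop("planting_strength must exceed the background disease fraction ",
         signif(cfg$n_disease_genes / cfg$n_targets, 3), call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

.zero_pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), seq_len(n))
}

# Draw a compound's target set.
#   coupled, background: mostly from the compound's module profile, a
#     target_noise fraction uniformly from outside it.
#   coupled, planted: ceil(s * n) targets from the disease genes, the rest
#     from the module's non-disease targets, so the realized disease
#     fraction is >= s by construction.
#   uncoupled (null): uniform over the target universe.
.draw_targets <- function(n, targets, disease, module, planted, s,
                          target_noise, coupled) {
  if (!coupled) return(sample(targets, min(n, length(targets))))
  if (planted) {
    nd <- min(ceiling(s * n), length(disease))
    pool <- setdiff(module, disease)
    nm <- min(n - nd, length(pool))
    return(c(sample(disease, nd), sample(pool, nm)))
  }
  nn <- stats::rbinom(1, n, target_noise)
  nm <- min(n - nn, length(module))
  out <- sample(module, nm)
  extra <- setdiff(targets, out)
  unique(c(out, sample(extra, min(nn, length(extra)))))
}

.generate_impl <- function(config, coupled) {
  cfg <- config
  compound_ids <- .zero_pad_ids("C", cfg$n_compounds)
  target_ids <- toupper(.zero_pad_ids("G", cfg$n_targets))
  bit_names <- .zero_pad_ids("FP", cfg$n_bits)

  # disease genes
  .substream(cfg$seed, 1L)
  disease <- sort(sample(target_ids, cfg$n_disease_genes))

  # planted actives
  .substream(cfg$seed, 2L)
  planted <- if (cfg$n_planted > 0) sort(sample(compound_ids, cfg$n_planted))
             else character(0)

  # driver bits per target (only used when coupled)
  .substream(cfg$seed, 3L)
  drivers <- stats::setNames(
    lapply(seq_len(cfg$n_targets),
           function(i) sample(bit_names, cfg$drivers_per_target)),
    target_ids)

  # latent scaffold modules and known targets per compound; background
  # modules live on the non-disease targets — engaging the disease
  # neighborhood is the planted actives' signature (background compounds
  # reach disease genes only through the uniform target_noise channel)
  .substream(cfg$seed, 4L)
  module_pool <- setdiff(target_ids, disease)
  modules <- lapply(seq_len(cfg$n_modules),
                    function(i) sample(module_pool, cfg$module_size))
  module_of <- sample.int(cfg$n_modules, cfg$n_compounds, replace = TRUE)
  n_t <- pmax(1L, stats::rpois(cfg$n_compounds, cfg$targets_per_compound))
  tsets <- lapply(seq_len(cfg$n_compounds), function(i)
    .draw_targets(n_t[i], target_ids, disease, modules[[module_of[i]]],
                  coupled && compound_ids[i] %in% planted,
                  cfg$planting_strength, cfg$target_noise, coupled))
  names(tsets) <- compound_ids
  dtis <- data.frame(
    compound_id = rep(compound_ids, lengths(tsets)),
    target = unlist(tsets, use.names = FALSE),
    provenance = "known", score = NA_real_,
    stringsAsFactors = FALSE)

  # fingerprints
  .substream(cfg$seed, 5L)
  noise_density <- if (coupled) cfg$bit_noise_density else
    min(0.5, cfg$targets_per_compound * cfg$drivers_per_target *
          cfg$coupling / cfg$n_bits + cfg$bit_noise_density)
  bits <- matrix(stats::rbinom(cfg$n_compounds * cfg$n_bits, 1,
                               noise_density),
                 nrow = cfg$n_compounds,
                 dimnames = list(compound_ids, bit_names))
  if (coupled) {
    for (i in seq_len(cfg$n_compounds)) {
      db <- unique(unlist(drivers[tsets[[i]]], use.names = FALSE))
      keep <- db[stats::runif(length(db)) < cfg$coupling]
      bits[i, keep] <- 1L
    }
  }
  empty <- rowSums(bits) == 0
  if (any(empty))    # guarantee every compound is usable for diffusion
    bits[cbind(which(empty),
               sample.int(cfg$n_bits, sum(empty), replace = TRUE))] <- 1L

  # herbs drawn from the shared pool; uncovered compounds get a herb
  .substream(cfg$seed, 6L)
  herb_ids <- paste0("H", seq_len(cfg$n_herbs))
  memb <- lapply(herb_ids, function(h)
    sample(compound_ids, cfg$compounds_per_herb))
  names(memb) <- herb_ids
  uncovered <- setdiff(compound_ids, unlist(memb))
  if (length(uncovered) > 0) {
    assign_to <- sample(herb_ids, length(uncovered), replace = TRUE)
    for (h in herb_ids)
      memb[[h]] <- union(memb[[h]], uncovered[assign_to == h])
  }
  role <- ifelse(seq_len(cfg$n_herbs) <= ceiling(cfg$n_herbs / 2),
                 "JunChen", "ZuoShi")
  herbs <- data.frame(
    herb_id = rep(herb_ids, lengths(memb)),
    name = rep(herb_ids, lengths(memb)),
    compound_id = unlist(memb, use.names = FALSE),
    role_class = rep(role, lengths(memb)),
    stringsAsFactors = FALSE)
  herbs <- herbs[order(herbs$herb_id, herbs$compound_id), , drop = FALSE]
  rownames(herbs) <- NULL

  # physicochemical + ADMET profiles (placeholder chemistry)
  .substream(cfg$seed, 7L)
  compounds <- data.frame(
    compound_id = compound_ids,
    name = paste0("compound-", compound_ids),
    smiles = NA_character_,
    mw = round(exp(stats::rnorm(cfg$n_compounds, log(300), 0.35)), 2),
    alogp = round(stats::rnorm(cfg$n_compounds, 2.5, 1.5), 2),
    hbd = stats::rpois(cfg$n_compounds, 2),
    hba = stats::rpois(cfg$n_compounds, 5),
    hia_prob = round(stats::runif(cfg$n_compounds), 3),
    bbb_prob = round(stats::runif(cfg$n_compounds), 3),
    stringsAsFactors = FALSE)

  structure(list(config = cfg,
                 compounds = compounds,
                 herbs = herbs,
                 fingerprints = fingerprint_table(bits),
                 dtis = dtis,
                 disease = gene_set("DISEASE", "synthetic disease gene set",
                                    disease),
                 planted = planted,
                 drivers = if (coupled) drivers else NULL,
                 modules = if (coupled) modules else NULL,
                 module_of = if (coupled)
                   stats::setNames(module_of, compound_ids) else NULL),
            class = "synthetic_dataset")
}

#' Generate a synthetic formula dataset
#'
#' Produces a complete dataset (herbs, compounds, fingerprints, known DTIs,
#' disease gene set, planted-active labels and the ground-truth
#' fingerprint-target driver map) satisfying every loader invariant, fully
#' reproducible from the config seed.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` object.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  .generate_impl(config, coupled = TRUE)
}

#' Generate a null (structureless) dataset
#'
#' As [generate_synthetic()] but with zero planted actives and no
#' fingerprint-target coupling: targets are assigned uniformly at random
#' and fingerprints are pure noise at the matched marginal density. Used
#' for type-I-error and AUC-near-0.5 checks.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` with an empty planted set.
#' @export
null_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  cfg$n_planted <- 0L
  .generate_impl(cfg, coupled = FALSE)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_dataset> ", cfg$n_herbs, " herbs, ",
      nrow(x$compounds), " compounds, ", cfg$n_targets, " targets, ",
      cfg$n_bits, " bits; ", nrow(x$dtis), " known DTIs; ",
      length(x$disease$genes), " disease genes; ",
      length(x$planted), " planted actives (seed ", cfg$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Seeded train/test split of a DTI edge list
#'
#' Disjoint partition with `ceiling(fraction * n)` test edges, drawn with a
#' seeded RNG.
#'
#' @param dtis data.frame of DTI records with at least 2 rows.
#' @param fraction test fraction in `(0,1)`.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
holdout_split <- function(dtis, fraction, seed = 1) {
  dtis <- as.data.frame(dtis)
  if (nrow(dtis) < 2) stop("need at least 2 DTIs to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0,1)", call. = FALSE)
  set.seed(as.integer(seed))
  n_test <- ceiling(fraction * nrow(dtis))
  idx <- sample.int(nrow(dtis), n_test)
  list(train = dtis[-idx, , drop = FALSE],
       test = dtis[idx, , drop = FALSE])
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the external formats the loaders read (self-hosting
#' fixtures): `compounds.csv`, `herbs.tsv`, `fingerprints.csv`, `dti.tsv`,
#' `disease.gmt` and `truth.tsv` (planted-active labels).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$compounds, file.path(dir, "compounds.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$herbs, file.path(dir, "herbs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fingerprint_table(dataset$fingerprints,
                          file.path(dir, "fingerprints.csv"))
  write_dti_table(dataset$dtis, file.path(dir, "dti.tsv"))
  write_gene_sets_gmt(list(dataset$disease), file.path(dir, "disease.gmt"))
  truth <- data.frame(compound_id = dataset$compounds$compound_id,
                      planted = dataset$compounds$compound_id %in%
                        dataset$planted,
                      stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
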