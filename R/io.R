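# Readers/writers and validation for every file the pipeline touches.
# Delimiter is auto-detected from the extension (.tsv -> tab, .csv -> comma);
# a header line is mandatory everywhere.

.delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = .delim_for(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "")
}

.num_col <- function(df, col, path) {
  if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
  raw <- trimws(df[[col]])
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & nzchar(raw) & is.na(out))
  if (length(bad) > 0)
    stop(sprintf("non-numeric value '%s' in column '%s' of %s (row %d)",
                 raw[bad[1]], col, path, bad[1]), call. = FALSE)
  out
}

#' Normalize gene symbols
#'
#' Uppercases and trims gene symbols. Gene identity throughout the package is
#' the uppercased symbol string; no alias mapping is attempted.
#'
#' @param x character vector of gene symbols.
#' @return character vector, uppercased and trimmed.
#' @export
normalize_gene_symbols <- function(x) toupper(trimws(as.character(x)))

#' Read a compound table
#'
#' Reads a CSV/TSV compound table with mandatory `compound_id` and `name`
#' columns and optional physicochemical (`mw`, `alogp`, `hbd`, `hba`) and
#' ADMET (`hia_prob`, `bbb_prob`) columns. Missing optional values are kept
#' as `NA` (absent), never coerced to zero, so downstream gates can
#' distinguish "ineligible" from "fail".
#'
#' @param path path to a `.csv` or `.tsv` file with a header.
#' @return data.frame with columns `compound_id`, `name`, `smiles`, `mw`,
#'   `alogp`, `hbd`, `hba`, `hia_prob`, `bbb_prob`.
#' @export
read_compound_table <- function(path) {
  df <- .read_table(path)
  req <- c("compound_id", "name")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("compound table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  id <- trimws(df$compound_id)
  if (any(!nzchar(id))) stop("empty compound_id in ", path, call. = FALSE)
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0)
    stop("duplicate compound_id in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  out <- data.frame(
    compound_id = id,
    name = trimws(df$name),
    smiles = if ("smiles" %in% names(df)) trimws(df$smiles)
             else rep(NA_character_, nrow(df)),
    mw = .num_col(df, "mw", path),
    alogp = .num_col(df, "alogp", path),
    hbd = .num_col(df, "hbd", path),
    hba = .num_col(df, "hba", path),
    hia_prob = .num_col(df, "hia_prob", path),
    bbb_prob = .num_col(df, "bbb_prob", path),
    stringsAsFactors = FALSE
  )
  bad_mw <- which(!is.na(out$mw) & out$mw <= 0)
  if (length(bad_mw) > 0)
    stop("non-positive molecular weight at row ", bad_mw[1], " of ", path,
         call. = FALSE)
  for (p in c("hia_prob", "bbb_prob")) {
    bad <- which(!is.na(out[[p]]) & (out[[p]] < 0 | out[[p]] > 1))
    if (length(bad) > 0)
      stop(p, " outside [0,1] at row ", bad[1], " of ", path, call. = FALSE)
  }
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are uppercased and
#' deduplicated.
#'
#' @param path path to a GMT file.
#' @return named list of `gene_set` objects (`set_id`, `description`,
#'   `genes`).
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, " in ", path,
           " (need name, description and at least one gene)", call. = FALSE)
    genes <- unique(normalize_gene_symbols(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      stop("GMT line ", i, " in ", path, " has no genes", call. = FALSE)
    sets[[i]] <- gene_set(f[1], f[2], genes)
  }
  names(sets) <- vapply(sets, function(s) s$set_id, character(1))
  sets
}

#' Construct a gene set
#'
#' @param set_id identifier.
#' @param description free-text description.
#' @param genes character vector of gene symbols (normalized on input).
#' @return a `gene_set` object.
#' @export
gene_set <- function(set_id, description = "", genes = character()) {
  genes <- unique(normalize_gene_symbols(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop("gene set ", set_id, " is empty", call. = FALSE)
  structure(list(set_id = as.character(set_id),
                 description = as.character(description),
                 genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$set_id, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

# Accept a gene_set or a bare character vector of symbols.
.as_genes <- function(x) {
  if (inherits(x, "gene_set")) return(x$genes)
  unique(normalize_gene_symbols(x))
}

#' Read a drug-target interaction (DTI) edge list
#'
#' Columns: `compound_id`, `target`, optional `provenance`
#' (`known`/`predicted`, default `known`) and optional `score`. Gene symbols
#' are uppercased.
#'
#' @param path path to a `.tsv`/`.csv` edge list with header.
#' @return data.frame with columns `compound_id`, `target`, `provenance`,
#'   `score`.
#' @export
read_dti_table <- function(path) {
  df <- .read_table(path)
  req <- c("compound_id", "target")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("DTI table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  prov <- if ("provenance" %in% names(df)) trimws(df$provenance) else "known"
  prov[!nzchar(prov)] <- "known"
  bad <- setdiff(unique(prov), c("known", "predicted"))
  if (length(bad) > 0)
    stop("unknown DTI provenance value(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- data.frame(
    compound_id = trimws(df$compound_id),
    target = normalize_gene_symbols(df$target),
    provenance = prov,
    score = .num_col(df, "score", path),
    stringsAsFactors = FALSE
  )
  key <- paste(out$compound_id, out$target, out$provenance, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (compound, target, provenance) row in ", path,
         call. = FALSE)
  out
}

#' Write a DTI edge list to TSV
#'
#' @param dtis data.frame of DTI records (or a [assemble_network()] result).
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_dti_table <- function(dtis, path) {
  if (inherits(dtis, "dti_network")) dtis <- dtis$edges
  df <- dtis[, c("compound_id", "target", "provenance", "score")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dti_table
#' @param network a `dti_network` object.
#' @export
write_network_tsv <- function(network, path) write_dti_table(network, path)

#' Read a herb membership table
#'
#' Long format, one row per herb-compound membership: columns `herb_id`,
#' `name` (optional), `compound_id`, optional `role_class`
#' (`JunChen`/`ZuoShi`).
#'
#' @param path path to a `.tsv`/`.csv` file with header.
#' @return data.frame with columns `herb_id`, `name`, `compound_id`,
#'   `role_class`.
#' @export
read_herb_table <- function(path) {
  df <- .read_table(path)
  req <- c("herb_id", "compound_id")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("herb table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  role <- if ("role_class" %in% names(df)) trimws(df$role_class)
          else NA_character_
  badrole <- setdiff(unique(role[!is.na(role) & nzchar(role)]),
                     c("JunChen", "ZuoShi"))
  if (length(badrole) > 0)
    stop("unknown role_class value(s) in ", path, ": ",
         paste(badrole, collapse = ", "), call. = FALSE)
  out <- data.frame(
    herb_id = trimws(df$herb_id),
    name = if ("name" %in% names(df)) trimws(df$name) else trimws(df$herb_id),
    compound_id = trimws(df$compound_id),
    role_class = role,
    stringsAsFactors = FALSE
  )
  out[!duplicated(paste(out$herb_id, out$compound_id, sep = "\r")), ,
      drop = FALSE]
}

#' Compound sets per herb
#'
#' @param herbs long-format herb membership data.frame.
#' @return named list, herb_id -> character vector of compound ids.
#' @export
herb_compound_sets <- function(herbs) {
  split(herbs$compound_id, herbs$herb_id)
}

#' Construct a fingerprint table
#'
#' @param bits binary (0/1) matrix, compounds in rows (rownames =
#'   compound ids), substructure bits in columns.
#' @return a `fingerprint_table` object.
#' @export
fingerprint_table <- function(bits) {
  bits <- as.matrix(bits)
  if (is.null(rownames(bits)) || is.null(colnames(bits)))
    stop("fingerprint matrix needs compound rownames and bit colnames",
         call. = FALSE)
  if (!all(bits %in% c(0, 1)))
    stop("fingerprint entries must be 0 or 1", call. = FALSE)
  storage.mode(bits) <- "double"
  structure(list(compound_ids = rownames(bits),
                 bit_names = colnames(bits),
                 bits = bits),
            class = "fingerprint_table")
}

#' @export
print.fingerprint_table <- function(x, ...) {
  cat("<fingerprint_table> ", length(x$compound_ids), " compounds x ",
      length(x$bit_names), " bits (density ",
      signif(mean(x$bits), 3), ")\n", sep = "")
  invisible(x)
}

#' Read a fingerprint bit table
#'
#' CSV/TSV with first column `compound_id` and remaining columns 0/1
#' substructure bits.
#'
#' @param path path to the file.
#' @return a [fingerprint_table()] object.
#' @export
read_fingerprint_table <- function(path) {
  df <- .read_table(path)
  if (names(df)[1] != "compound_id")
    stop("fingerprint table ", path, " must start with a compound_id column",
         call. = FALSE)
  ids <- trimws(df$compound_id)
  if (anyDuplicated(ids))
    stop("duplicate compound_id in fingerprint table ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mn <- suppressWarnings(apply(m, 2, as.numeric))
  mn <- matrix(mn, nrow = nrow(df),
               dimnames = list(ids, names(df)[-1]))
  if (any(is.na(mn)) || !all(mn %in% c(0, 1)))
    stop("fingerprint table ", path, " has entries outside {0,1}",
         call. = FALSE)
  fingerprint_table(mn)
}

#' Write a fingerprint table
#'
#' @param fp a `fingerprint_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_table <- function(fp, path) {
  df <- data.frame(compound_id = fp$compound_ids,
                   fp$bits, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets list of `gene_set` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$set_id, s$description, s$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a loaded dataset
#'
#' Cross-checks the loaded components and reports (never errors on)
#' inconsistencies: orphan references, compounds without usable fingerprints
#' (excluded from diffusion), disease genes outside the target universe.
#'
#' @param compounds compound data.frame ([read_compound_table()]).
#' @param herbs herb membership data.frame (optional).
#' @param fingerprints a `fingerprint_table` (optional).
#' @param dtis DTI data.frame (optional).
#' @param gene_sets list of `gene_set` objects (optional).
#' @return a `validation_report` object: list with `errors`, `warnings`,
#'   `notes` character vectors and `ok` flag.
#' @export
validate_dataset <- function(compounds, herbs = NULL, fingerprints = NULL,
                             dtis = NULL, gene_sets = NULL) {
  errors <- character(); warnings <- character(); notes <- character()
  ids <- compounds$compound_id
  if (!is.null(herbs)) {
    orphan <- setdiff(unique(herbs$compound_id), ids)
    if (length(orphan) > 0)
      warnings <- c(warnings, paste0(
        "herb membership references unknown compound(s): ",
        paste(orphan, collapse = ", ")))
  }
  if (!is.null(fingerprints)) {
    nofp <- setdiff(ids, fingerprints$compound_ids)
    if (length(nofp) > 0)
      warnings <- c(warnings, paste0(
        length(nofp), " compound(s) lack fingerprints; unusable for diffusion: ",
        paste(utils::head(nofp, 10), collapse = ", ")))
    zero <- fingerprints$compound_ids[rowSums(fingerprints$bits) == 0]
    if (length(zero) > 0)
      warnings <- c(warnings, paste0(
        "compound(s) with all-zero fingerprint row, no substructures; ",
        "excluded from diffusion: ", paste(zero, collapse = ", ")))
  }
  if (!is.null(dtis)) {
    orphan <- setdiff(unique(dtis$compound_id), ids)
    if (length(orphan) > 0)
      warnings <- c(warnings, paste0(
        "DTI edge(s) reference unknown compound(s): ",
        paste(orphan, collapse = ", ")))
  }
  if (!is.null(gene_sets) && !is.null(dtis)) {
    universe <- unique(dtis$target)
    for (s in gene_sets) {
      out <- setdiff(s$genes, universe)
      if (length(out) > 0)
        notes <- c(notes, paste0(
          "gene set '", s$set_id, "': ", length(out),
          " gene(s) not targeted by any compound"))
    }
  }
  structure(list(errors = errors, warnings = warnings, notes = notes,
                 ok = length(errors) == 0),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", if (x$ok) "OK" else "FAILED", "\n", sep = "")
  for (e in x$errors) cat("  error:   ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  for (n in x$notes) cat("  note:    ", n, "\n", sep = "")
  invisible(x)
}
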