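# Shared readers and writers: TSV matrices (NA token "NA"), compendium
# bundles, toy-organism FASTA + TSV, ML dataset tables, and run
# configuration.  Genome coordinates in TSV maps are 1-based inclusive.

#' Write / read a numeric matrix as TSV
#'
#' Row names go into a leading `id` column; missing cells use the token
#' `NA`.  Values print at full precision so identical runs produce
#' byte-identical files.
#'
#' @param mat numeric matrix.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a compendium bundle to a directory
#'
#' Writes `values.tsv`, `missing_mask.tsv`, `outlier_mask.tsv`,
#' `array_meta.tsv` and, when given, `report.json`.
#'
#' @param comp an `expression_compendium`.
#' @param dir output directory (created).
#' @param report optional `normalization_report`.
#' @return `dir`, invisibly.
#' @export
write_compendium <- function(comp, dir, report = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(comp$values, file.path(dir, "values.tsv"))
  write_matrix_tsv(comp$missing_mask * 1, file.path(dir, "missing_mask.tsv"))
  write_matrix_tsv(comp$outlier_mask * 1, file.path(dir, "outlier_mask.tsv"))
  utils::write.table(comp$array_meta, file.path(dir, "array_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report)) {
    rep_l <- unclass(report)
    rep_l$scale_params <- NULL
    jsonlite::write_json(rep_l, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(dir) {
  values <- read_matrix_tsv(file.path(dir, "values.tsv"))
  meta <- utils::read.delim(file.path(dir, "array_meta.tsv"),
                            stringsAsFactors = FALSE)
  rownames(meta) <- meta$array_id
  mm <- read_matrix_tsv(file.path(dir, "missing_mask.tsv")) > 0
  om <- read_matrix_tsv(file.path(dir, "outlier_mask.tsv")) > 0
  structure(list(values = values, gene_ids = rownames(values),
                 array_meta = meta, missing_mask = mm, outlier_mask = om,
                 provenance = NULL),
            class = "expression_compendium")
}

#' Write / read a toy organism (FASTA + TSV + JSON constants)
#'
#' @param org a `toy_organism`.
#' @param dir directory.
#' @return `dir` / the organism.
#' @export
write_organism <- function(org, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(unlist(org$sequences))
  Biostrings::writeXStringSet(seqs, file.path(dir, "genes.fasta"))
  utils::write.table(org$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  core_ser <- lapply(org$core, function(cr)
    list(id = cr$id, stoich = as.list(cr$stoich),
         enzyme = if (is.na(cr$enzyme)) NULL else cr$enzyme,
         lb = cr$lb, ub = if (is.finite(cr$ub)) cr$ub else NULL,
         spontaneous = isTRUE(cr$spontaneous)))
  consts <- list(biomass = org$biomass,
                 uptake_reaction = org$uptake_reaction,
                 machinery_ceiling = if (is.finite(org$machinery_ceiling))
                   org$machinery_ceiling else NULL,
                 enzyme_copies = org$enzyme_copies,
                 kcat_table = org$kcat_table,
                 core = core_ser, seed = org$seed)
  jsonlite::write_json(consts, file.path(dir, "constants.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_organism
#' @export
read_organism <- function(dir) {
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genes.fasta"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  consts <- jsonlite::fromJSON(file.path(dir, "constants.json"),
                               simplifyVector = FALSE)
  core <- lapply(consts$core, function(cr)
    list(id = cr$id,
         stoich = unlist(cr$stoich),
         enzyme = cr$enzyme %||% NA_character_,
         lb = cr$lb, ub = cr$ub %||% Inf,
         spontaneous = isTRUE(cr$spontaneous)))
  kcat <- if (length(consts$kcat_table) == 0)
    data.frame(reaction = character(0), kcat = numeric(0)) else
      data.frame(
        reaction = vapply(consts$kcat_table, `[[`, character(1), "reaction"),
        kcat = vapply(consts$kcat_table, `[[`, numeric(1), "kcat"),
        stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 sequences = stats::setNames(as.character(fa), names(fa)),
                 core = core,
                 biomass = consts$biomass,
                 uptake_reaction = consts$uptake_reaction,
                 machinery_ceiling = consts$machinery_ceiling %||% Inf,
                 enzyme_copies = consts$enzyme_copies,
                 kcat_table = kcat,
                 seed = consts$seed),
            class = "toy_organism")
}

#' Write / read an ML dataset as TSV
#'
#' Columns: `array_id`, features, `y`, `view`, `origin`.
#' @param ds an [ml_dataset()]. @param path file path.
#' @return `path` / the dataset.
#' @export
write_ml_dataset <- function(ds, path) {
  df <- data.frame(array_id = rownames(ds$X) %||%
                     sprintf("arr%04d", seq_len(nrow(ds$X))),
                   ds$X, y = ds$y, view = ds$view, origin = ds$origin,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ml_dataset
#' @export
read_ml_dataset <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  feat <- setdiff(colnames(df), c("array_id", "y", "view", "origin"))
  X <- as.matrix(df[, feat, drop = FALSE])
  rownames(X) <- df$array_id
  ml_dataset(X, df$y, view = df$view[1], origin = df$origin)
}

OMEGROW_CONFIG_DEFAULTS <- list(
  seed = 0,
  k_orders = 2, n_trees = 100, min_obs = 3,          # compendium
  conf_threshold = 0.95,                             # regnet
  k_ribo = 12, k_rnap = 55, k_deg_mrna = 8,          # ME model
  default_kcat = 65, unmodeled_protein_fraction = 0.2,
  bisect_tol = 1e-6,
  train_frac = 0.8, n_repeats = 100,                 # featml
  hdmppk_var_frac = 0.95, hdmppk_top_m = 200,
  em_bounds = c(0.2, 5), accuracy_tol = 0.2)         # integrate

#' Load and validate a run configuration
#'
#' @param x `NULL` (defaults), a named list of overrides, or a YAML file
#'   path.  Unknown keys are rejected.
#' @return full configuration list.
#' @export
omegrow_config <- function(x = NULL) {
  ov <- if (is.null(x)) list() else if (is.character(x))
    yaml::read_yaml(x) else x
  unknown <- setdiff(names(ov), names(OMEGROW_CONFIG_DEFAULTS))
  if (length(unknown) > 0)
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(OMEGROW_CONFIG_DEFAULTS, ov)
}

#' Write the effective configuration into an output directory
#' @param config list from [omegrow_config()]. @param dir output directory.
#' @return invisible path.
#' @export
write_config_copy <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}
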