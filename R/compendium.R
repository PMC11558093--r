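# Expression-compendium assembly: identifier harmonization, per-gene min-max
# scaling, magnitude-outlier flagging, random-forest imputation, and the
# descriptive analyses run on the finished compendium (group correlation,
# differential expression, PCA scores).

#' Construct a raw expression table
#'
#' A raw table is one source's gene-by-array matrix plus per-array metadata.
#' Missing cells are `NA`, never 0.
#'
#' @param values numeric gene x array matrix; `NA` marks missing cells.
#' @param gene_ids character vector of source-native gene identifiers.
#' @param array_meta data.frame of per-array metadata (one row per array);
#'   expected columns include strain, medium, temperature, pH, stress and
#'   perturbation, but any columns are carried through.
#' @param source_id single string naming the source.
#' @return object of class `raw_expression_table`.
#' @export
raw_expression_table <- function(values, gene_ids, array_meta,
                                 source_id = "source") {
  values <- as.matrix(values)
  if (length(gene_ids) != nrow(values))
    stopf("gene_ids length (%d) != rows (%d)", length(gene_ids), nrow(values))
  if (nrow(array_meta) != ncol(values))
    stopf("array_meta rows (%d) != arrays (%d)", nrow(array_meta), ncol(values))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate array identifiers within table '%s'", source_id)
  rownames(values) <- gene_ids
  structure(list(source_id = source_id, values = values,
                 gene_ids = gene_ids, array_meta = array_meta),
            class = "raw_expression_table")
}

#' Harmonize gene identifiers across source tables
#'
#' Maps every source identifier to a canonical (BSU-style) identifier and
#' merges all tables into one matrix.  Rows whose identifier is absent from
#' the map are dropped and counted; when two source rows map to one canonical
#' identifier and both carry a value in the same array, the cell is marked
#' conflicting and set missing.
#'
#' @param tables list of [raw_expression_table()] objects.
#' @param id_map data.frame with columns `source_id`, `canonical_id`
#'   (`NA`/empty canonical id marks an identifier as unmapped).
#' @return a merged `raw_expression_table` whose `gene_ids` are canonical and
#'   sorted; attribute `"harmonize_log"` records dropped ids and conflicts.
#' @export
harmonize_gene_ids <- function(tables, id_map) {
  stopifnot(is.list(tables), length(tables) > 0)
  all_arrays <- unlist(lapply(tables, function(t) colnames(t$values)))
  dup <- all_arrays[duplicated(all_arrays)]
  if (length(dup) > 0)
    stopf("duplicate array identifiers across tables: %s",
          paste(unique(dup), collapse = ", "))
  map <- stats::setNames(as.character(id_map$canonical_id), id_map$source_id)
  map[map %in% c("", "NA")] <- NA_character_

  dropped <- character(0)
  canon_all <- character(0)
  per_table <- vector("list", length(tables))
  for (ti in seq_along(tables)) {
    tb <- tables[[ti]]
    canon <- unname(map[tb$gene_ids])
    unseen <- !(tb$gene_ids %in% names(map))
    canon[unseen] <- NA_character_
    dropped <- c(dropped, tb$gene_ids[is.na(canon)])
    per_table[[ti]] <- canon
    canon_all <- c(canon_all, canon[!is.na(canon)])
  }
  genes <- sort(unique(canon_all))
  merged <- matrix(NA_real_, length(genes), length(all_arrays),
                   dimnames = list(genes, all_arrays))
  contrib <- matrix(0L, length(genes), length(all_arrays),
                    dimnames = list(genes, all_arrays))
  provenance <- matrix(NA_character_, length(genes), length(all_arrays),
                       dimnames = list(genes, all_arrays))
  meta <- do.call(rbind, lapply(tables, function(t) t$array_meta))
  for (ti in seq_along(tables)) {
    tb <- tables[[ti]]
    canon <- per_table[[ti]]
    for (ri in which(!is.na(canon))) {
      g <- canon[ri]
      vals <- tb$values[ri, ]
      ok <- !is.na(vals)
      cols <- colnames(tb$values)[ok]
      contrib[g, cols] <- contrib[g, cols] + 1L
      merged[g, cols] <- vals[ok]
      provenance[g, cols] <- tb$source_id
    }
  }
  conflict <- contrib > 1L
  merged[conflict] <- NA_real_
  provenance[conflict] <- NA_character_
  out <- raw_expression_table(merged, genes, meta, source_id = "merged")
  attr(out, "harmonize_log") <- list(
    n_dropped = length(dropped), dropped_ids = dropped,
    n_conflicts = sum(conflict))
  out$provenance <- provenance
  out
}

#' Per-gene min-max rescaling to [0, 1]
#'
#' Each row is mapped by `x -> (x - min) / (max - min)` over its non-missing
#' cells.  Constant rows map to 0 (a degenerate case, logged via the
#' `"degenerate_genes"` attribute); missing cells stay missing.
#'
#' @param mat numeric gene x array matrix (`NA` = missing).
#' @return rescaled matrix with attributes `"scale_params"` (per-gene min and
#'   max) and `"degenerate_genes"`.
#' @export
minmax_rescale <- function(mat) {
  mat <- as.matrix(mat)
  nobs <- rowSums(!is.na(mat))
  if (any(nobs == 0))
    stopf("all-missing row(s): %s",
          paste(rownames(mat)[nobs == 0] %||% which(nobs == 0), collapse = ", "))
  mn <- apply(mat, 1, min, na.rm = TRUE)
  mx <- apply(mat, 1, max, na.rm = TRUE)
  rng <- mx - mn
  degen <- rng == 0
  rng[degen] <- 1                      # constant rows -> 0 by convention
  out <- (mat - mn) / rng
  out[degen, ][!is.na(out[degen, ])] <- 0
  attr(out, "scale_params") <- data.frame(gene = rownames(mat) %||%
                                            as.character(seq_len(nrow(mat))),
                                          min = mn, max = mx,
                                          row.names = NULL)
  attr(out, "degenerate_genes") <- (rownames(mat) %||%
                                      as.character(seq_len(nrow(mat))))[degen]
  out
}

#' Flag order-of-magnitude outliers
#'
#' A cell is flagged when its log10 value deviates from its gene's median
#' log10 value by more than `k_orders` orders of magnitude.  Applied to the
#' original (strictly positive) scale, before rescaling.
#'
#' @param mat strictly positive gene x array matrix (`NA` = missing).
#' @param k_orders threshold in orders of magnitude (default 2).
#' @return logical outlier mask of the same shape (missing cells `FALSE`).
#' @export
flag_magnitude_outliers <- function(mat, k_orders = 2) {
  mat <- as.matrix(mat)
  stopifnot(is.numeric(k_orders), k_orders > 0)
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-positive value at gene %s, array %s: log scale undefined",
          rownames(mat)[bad[1, 1]] %||% bad[1, 1],
          colnames(mat)[bad[1, 2]] %||% bad[1, 2])
  lx <- log10(mat)
  med <- apply(lx, 1, stats::median, na.rm = TRUE)
  mask <- abs(lx - med) > k_orders
  mask[is.na(mask)] <- FALSE
  mask
}

#' Impute missing cells by per-gene random-forest regression
#'
#' Each missing cell is predicted by a random forest regressing its gene on
#' all other genes; training arrays are those where the gene is observed,
#' with remaining predictor gaps filled by gene means (a single pass, not
#' chained iteration).  Deterministic given `seed`.
#'
#' @param mat gene x array matrix with `NA` missing cells.
#' @param n_trees trees per forest (default 100).
#' @param seed integer RNG seed (default 0).
#' @param min_obs minimum observed arrays required per gene (default 3).
#' @return completed matrix; attribute `"n_imputed"` counts filled cells.
#' @export
impute_missing <- function(mat, n_trees = 100, seed = 0, min_obs = 3) {
  mat <- as.matrix(mat)
  if (!anyNA(mat)) {
    attr(mat, "n_imputed") <- 0L
    return(mat)
  }
  nobs <- rowSums(!is.na(mat))
  if (any(nobs < min_obs))
    stopf("gene(s) with fewer than %d observed arrays: %s", min_obs,
          paste(rownames(mat)[nobs < min_obs], collapse = ", "))
  filled <- mat
  gmean <- rowMeans(mat, na.rm = TRUE)
  for (i in seq_len(nrow(filled)))
    filled[i, is.na(filled[i, ])] <- gmean[i]
  out <- mat
  n_imp <- 0L
  with_seed(seed, {
    targets <- which(rowSums(is.na(mat)) > 0)
    for (g in targets) {
      obs <- which(!is.na(mat[g, ]))
      mis <- which(is.na(mat[g, ]))
      xtr <- t(filled[-g, obs, drop = FALSE])
      xte <- t(filled[-g, mis, drop = FALSE])
      fit <- randomForest::randomForest(x = xtr, y = mat[g, obs],
                                        ntree = n_trees)
      out[g, mis] <- stats::predict(fit, xte)
      n_imp <- n_imp + length(mis)
    }
  })
  attr(out, "n_imputed") <- n_imp
  out
}

#' Run the five-stage compendium normalization pipeline
#'
#' Stages, in order: identifier harmonization, min-max rescaling,
#' order-of-magnitude outlier flagging (computed on the pre-rescale positive
#' scale), random-forest imputation, and a final min-max rescaling.
#'
#' @param tables list of [raw_expression_table()] objects.
#' @param id_map identifier map, as in [harmonize_gene_ids()].
#' @param config list overriding defaults `k_orders = 2`, `n_trees = 100`,
#'   `min_obs = 3`.
#' @param seed RNG seed for the imputation stage (default 0).
#' @return list with `compendium` (class `expression_compendium`) and
#'   `report` (class `normalization_report`).
#' @export
normalize_pipeline <- function(tables, id_map, config = list(), seed = 0) {
  cfg <- utils::modifyList(list(k_orders = 2, n_trees = 100, min_obs = 3),
                           config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s': %s", name, conditionMessage(e)))
  }
  merged <- stage("harmonize_gene_ids", harmonize_gene_ids(tables, id_map))
  hlog <- attr(merged, "harmonize_log")
  raw <- merged$values
  missing_mask <- is.na(raw)
  scaled <- stage("minmax_rescale", minmax_rescale(raw))
  omask <- stage("flag_magnitude_outliers",
                 flag_magnitude_outliers(raw, cfg$k_orders))
  scaled[omask] <- NA_real_
  imputed <- stage("impute_missing",
                   impute_missing(scaled, n_trees = cfg$n_trees, seed = seed,
                                  min_obs = cfg$min_obs))
  n_imputed <- attr(imputed, "n_imputed")
  final <- stage("minmax_rescale", minmax_rescale(imputed))
  comp <- structure(list(
    values = unclass_matrix(final),
    gene_ids = rownames(raw),
    array_meta = merged$array_meta,
    missing_mask = missing_mask,
    outlier_mask = omask,
    provenance = merged$provenance),
    class = "expression_compendium")
  report <- structure(list(
    n_outliers_removed = sum(omask),
    n_imputed = n_imputed,
    n_dropped_ids = hlog$n_dropped,
    n_conflicts = hlog$n_conflicts,
    scale_params = attr(final, "scale_params"),
    stage_order = c("harmonize_gene_ids", "minmax_rescale",
                    "flag_magnitude_outliers", "impute_missing",
                    "minmax_rescale")),
    class = "normalization_report")
  list(compendium = comp, report = report)
}

unclass_matrix <- function(m) {
  attr(m, "scale_params") <- NULL
  attr(m, "degenerate_genes") <- NULL
  attr(m, "n_imputed") <- NULL
  m
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("Expression compendium: %d genes x %d arrays\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  originally missing: %d cells; flagged outliers: %d cells\n",
              sum(x$missing_mask), sum(x$outlier_mask)))
  cat(sprintf("  metadata fields: %s\n",
              paste(colnames(x$array_meta), collapse = ", ")))
  invisible(x)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("Normalization report\n")
  cat(sprintf("  stages: %s\n", paste(x$stage_order, collapse = " -> ")))
  cat(sprintf("  outliers removed: %d; cells imputed: %d; ids dropped: %d; conflicts: %d\n",
              x$n_outliers_removed, x$n_imputed, x$n_dropped_ids,
              x$n_conflicts))
  invisible(x)
}

#' Correlation of group mean profiles with a reference group
#'
#' Computes the Pearson correlation between the mean expression profile of
#' each level of a metadata field and that of a reference level, over shared
#' non-missing genes, and flags groups with PCC >= 0.8.
#'
#' @param comp an `expression_compendium`.
#' @param group_key metadata column name (e.g. `"strain"` or `"medium"`).
#' @param reference reference group label.
#' @return data.frame with columns `group`, `n_arrays`, `n_genes`, `pcc`,
#'   `flag` (PCC >= 0.8).
#' @export
condition_correlation <- function(comp, group_key, reference) {
  stopifnot(inherits(comp, "expression_compendium"))
  grp <- comp$array_meta[[group_key]]
  if (is.null(grp)) stopf("metadata field '%s' not found", group_key)
  if (!(reference %in% grp)) stopf("reference group '%s' not found", reference)
  prof <- function(label) {
    cols <- which(grp == label)
    rowMeans(comp$values[, cols, drop = FALSE], na.rm = TRUE)
  }
  ref <- prof(reference)
  out <- lapply(setdiff(unique(grp), reference), function(label) {
    p <- prof(label)
    shared <- which(!is.na(p) & !is.na(ref))
    if (length(shared) < 3) {
      warnf("group '%s' skipped: fewer than 3 usable genes", label)
      return(NULL)
    }
    pcc <- stats::cor(p[shared], ref[shared])
    data.frame(group = label, n_arrays = sum(grp == label),
               n_genes = length(shared), pcc = pcc, flag = pcc >= 0.8)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Differential expression between two array sets
#'
#' Welch two-sample t-test on log2 values per gene with Benjamini-Hochberg
#' adjustment.  A gene is `up` when its mean log2 fold change is at least
#' `lfc_min` and the adjusted p-value is below `alpha`; `down` is symmetric;
#' everything else is `unchanged`.
#'
#' @param comp an `expression_compendium` or a positive gene x array matrix.
#' @param set_a,set_b array identifiers (or column indices) of the two
#'   groups; must be disjoint, each of size >= 2.
#' @param lfc_min minimum |log2 fold change| (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param pseudo pseudocount added before log2 (default 1e-6).
#' @return data.frame with `gene_id`, `lfc`, `p`, `padj`, `class`.
#' @export
differential_expression <- function(comp, set_a, set_b, lfc_min = 1,
                                    alpha = 0.05, pseudo = 1e-6) {
  vals <- if (inherits(comp, "expression_compendium")) comp$values else
    as.matrix(comp)
  if (is.character(set_a)) set_a <- match(set_a, colnames(vals))
  if (is.character(set_b)) set_b <- match(set_b, colnames(vals))
  if (anyNA(set_a) || anyNA(set_b)) stopf("unknown array identifiers")
  if (length(intersect(set_a, set_b)) > 0)
    stopf("degenerate contrast: array sets overlap")
  if (length(set_a) < 2 || length(set_b) < 2)
    stopf("both array sets need at least 2 arrays")
  la <- log2(vals[, set_a, drop = FALSE] + pseudo)
  lb <- log2(vals[, set_b, drop = FALSE] + pseudo)
  lfc <- rowMeans(la, na.rm = TRUE) - rowMeans(lb, na.rm = TRUE)
  p <- vapply(seq_len(nrow(vals)), function(i) {
    a <- la[i, ]; b <- lb[i, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (stats::var(a) + stats::var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  class <- rep("unchanged", nrow(vals))
  class[!is.na(padj) & padj < alpha & lfc >= lfc_min] <- "up"
  class[!is.na(padj) & padj < alpha & lfc <= -lfc_min] <- "down"
  data.frame(gene_id = rownames(vals) %||% as.character(seq_len(nrow(vals))),
             lfc = lfc, p = p, padj = padj, class = class, row.names = NULL)
}

#' Principal-component scores of a compendium
#'
#' Arrays are observations, genes are variables (completed values).
#'
#' @param comp an `expression_compendium`.
#' @param n_components number of components to return (default 2).
#' @return list with `scores` (array x component matrix) and
#'   `variance_explained` (fractions).
#' @export
compendium_pca <- function(comp, n_components = 2) {
  stopifnot(inherits(comp, "expression_compendium"))
  pc <- stats::prcomp(t(comp$values), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}
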