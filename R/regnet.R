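# TF-operon-target regulatory networks and the per-edge confidence /
# multiple-linear-regression analysis: each target gene is regressed on the
# expression of all its annotated regulators across arrays; per-regulator
# coefficients (beta), t-test p-values and confidence = 1 - p classify edges
# as activation or repression.

NET_COLS <- c("tf_id", "operon_id", "target_gene_id", "sign")

#' Construct a validated regulatory network
#'
#' @param edges data.frame with columns `tf_id`, `operon_id`,
#'   `target_gene_id`, `sign` (one of `+`, `-`, `unknown`); an optional
#'   `evidence` column is carried through.  Duplicate (tf, target) pairs are
#'   collapsed with a warning.
#' @param sigma_factors character vector of tf ids that are sigma factors.
#' @param stress_map named list mapping stress labels to tf id sets.
#' @return object of class `regulatory_network`.
#' @export
regulatory_network <- function(edges, sigma_factors = character(0),
                               stress_map = list()) {
  missing_cols <- setdiff(NET_COLS, colnames(edges))
  if (length(missing_cols) > 0)
    stopf("edge table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  bad_sign <- !(edges$sign %in% c("+", "-", "unknown"))
  if (any(bad_sign)) stopf("invalid sign in edge row(s): %s",
                           paste(which(bad_sign), collapse = ", "))
  key <- paste(edges$tf_id, edges$target_gene_id)
  if (anyDuplicated(key)) {
    warnf("%d duplicate (tf, target) edge(s) collapsed",
          sum(duplicated(key)))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  self <- edges$tf_id == edges$target_gene_id
  if (any(self))
    message(sprintf("note: %d self-regulation edge(s) retained", sum(self)))
  unknown_sf <- setdiff(sigma_factors, edges$tf_id)
  if (length(unknown_sf) > 0)
    warnf("sigma factor(s) not present as tf: %s",
          paste(unknown_sf, collapse = ", "))
  rownames(edges) <- NULL
  structure(list(edges = edges, sigma_factors = sigma_factors,
                 stress_map = stress_map),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Regulatory network: %d edges, %d TFs, %d target genes\n",
              nrow(x$edges), length(unique(x$edges$tf_id)),
              length(unique(x$edges$target_gene_id))))
  invisible(x)
}

#' Read a regulatory network from a TSV edge list
#'
#' Expected columns: `tf_id`, `operon_id`, `target_gene_id`, `sign`
#' (optionally `evidence`).
#'
#' @param path TSV file path.
#' @return a [regulatory_network()].
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stopf("network file not found: %s", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0)
    return(regulatory_network(stats::setNames(
      as.data.frame(matrix(character(0), 0, 4)), NET_COLS)))
  incomplete <- which(apply(raw[, intersect(NET_COLS, colnames(raw)),
                                drop = FALSE],
                            1, function(r) any(is.na(r) | r == "")))
  if (length(incomplete) > 0)
    stopf("malformed edge at line %d of %s", incomplete[1] + 1L, path)
  regulatory_network(raw)
}

#' Write a regulatory network edge list to TSV
#' @param net a [regulatory_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fit per-target multiple linear regressions over the network
#'
#' For each target gene, ordinary least squares of its expression on the
#' expression of all annotated regulator TFs across arrays; per-regulator
#' coefficients, standard errors, two-sided t-test p-values and confidence
#' `1 - p`.  Collinear (aliased) regressors flag the fit unstable and leave
#' the affected edges unclassified.
#'
#' @param comp an `expression_compendium` or gene x array matrix containing
#'   every tf and target.
#' @param net a [regulatory_network()].
#' @param adjust also report Benjamini-Hochberg adjusted p-values
#'   (default TRUE; the headline confidence stays unadjusted).
#' @return data.frame of edge fits: `tf_id`, `target_gene_id`, `beta`,
#'   `stderr`, `p_value`, `confidence`, `class`, `padj`.
#' @export
fit_tf_gene_regression <- function(comp, net, adjust = TRUE) {
  vals <- if (inherits(comp, "expression_compendium")) comp$values else
    as.matrix(comp)
  edges <- net$edges
  ids <- unique(c(edges$tf_id, edges$target_gene_id))
  absent <- setdiff(ids, rownames(vals))
  if (length(absent) > 0)
    stopf("gene(s) absent from expression data: %s",
          paste(absent, collapse = ", "))
  n_arr <- ncol(vals)
  out <- lapply(split(edges, edges$target_gene_id), function(ed) {
    tfs <- ed$tf_id
    if (n_arr < length(tfs) + 2)
      stopf("target %s: %d arrays < %d regulators + 2",
            ed$target_gene_id[1], n_arr, length(tfs))
    df <- data.frame(t(vals[c(ed$target_gene_id[1], tfs), , drop = FALSE]))
    colnames(df) <- c(".y", make.names(tfs))
    fit <- stats::lm(.y ~ ., data = df)
    cf <- suppressWarnings(stats::coef(summary(fit)))
    unstable <- any(is.na(stats::coef(fit)[-1]))
    rows <- lapply(seq_along(tfs), function(j) {
      nm <- make.names(tfs[j])
      if (unstable || !(nm %in% rownames(cf))) {
        data.frame(tf_id = tfs[j], target_gene_id = ed$target_gene_id[1],
                   beta = NA_real_, stderr = NA_real_, p_value = NA_real_,
                   confidence = NA_real_, class = "unclassified",
                   stringsAsFactors = FALSE)
      } else {
        b <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
        p <- cf[nm, "Pr(>|t|)"]
        data.frame(tf_id = tfs[j], target_gene_id = ed$target_gene_id[1],
                   beta = b, stderr = se, p_value = p, confidence = 1 - p,
                   class = if (unstable) "unclassified" else
                     if (b > 0) "activation" else "repression",
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  })
  fits <- do.call(rbind, out)
  rownames(fits) <- NULL
  if (adjust) fits$padj <- stats::p.adjust(fits$p_value, method = "BH")
  fits
}

#' Select confident edges and count activation/repression
#'
#' @param fits edge-fit data.frame from [fit_tf_gene_regression()].
#' @param conf_threshold keep edges with confidence strictly above this
#'   (default 0.95).
#' @return list with `edges` (the confident subnetwork), `n_activation`,
#'   `n_repression`.
#' @export
classify_confident_edges <- function(fits, conf_threshold = 0.95) {
  stopifnot(nrow(fits) > 0)
  keep <- !is.na(fits$confidence) & fits$confidence > conf_threshold &
    fits$class != "unclassified"
  sub <- fits[keep, , drop = FALSE]
  list(edges = sub,
       n_activation = sum(sub$class == "activation"),
       n_repression = sum(sub$class == "repression"))
}
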