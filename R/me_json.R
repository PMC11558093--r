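# ME-model serialization: a COBRA-style JSON document extended with growth-
# rate-dependent coefficients.  Schema (version 1.0):
#   {
#     "schema_version": "1.0",
#     "params": {...},                     # me_params() fields
#     "uptake_reaction": "GLC_upt",
#     "metabolites": [{"id", "class"}],
#     "genes": [...] | null,
#     "reactions": [{
#        "id", "lb", "ub",                 # ub null encodes +Inf
#        "type", "enzyme", "k_eff", "gene", "growth_coupled",
#        "stoich": [{"met", "const", "mu"}]  # coefficient = const + mu * mu
#     }]
#   }
# Re-serialization of a read model is byte-identical.

#' Write an ME model to JSON
#'
#' @param model an `me_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_me_model <- function(model, path) {
  doc <- list(
    schema_version = "1.0",
    params = model$params,
    uptake_reaction = model$uptake_reaction,
    metabolites = model$metabolites,
    genes = model$genes,
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, lb = r$lb,
           ub = if (is.finite(r$ub)) r$ub else NULL,
           type = r$type,
           enzyme = if (is.na(r$enzyme)) NULL else r$enzyme,
           k_eff = if (is.na(r$k_eff)) NULL else r$k_eff,
           gene = if (is.na(r$gene)) NULL else r$gene,
           growth_coupled = isTRUE(r$growth_coupled),
           stoich = lapply(r$stoich, function(e)
             list(met = e$met, const = e$const, mu = e$mu)))
    }))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read an ME model from JSON
#'
#' Validates the schema version and every coefficient entry; a malformed
#' entry raises an error naming its JSON path.
#'
#' @param path JSON file written by [write_me_model()].
#' @return an `me_model`.
#' @export
read_me_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema_version, "1.0"))
    stopf("unsupported schema_version '%s' (expected 1.0)",
          doc$schema_version %||% "<missing>")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = m$id, class = m$class, stringsAsFactors = FALSE)))
  genes <- if (is.null(doc$genes)) NULL else rows_to_df(doc$genes)
  rxns <- lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    st <- lapply(seq_along(r$stoich), function(j) {
      e <- r$stoich[[j]]
      if (!is.numeric(e$const %||% NULL) || !is.numeric(e$mu %||% NULL) ||
          !is.character(e$met %||% NULL))
        stopf("schema error at reactions[%d].stoich[%d]: need met/const/mu",
              i, j)
      list(met = e$met, const = as.numeric(e$const), mu = as.numeric(e$mu))
    })
    list(id = r$id, lb = as.numeric(r$lb),
         ub = as.numeric(r$ub %||% Inf), type = r$type,
         enzyme = r$enzyme %||% NA_character_,
         k_eff = as.numeric(r$k_eff %||% NA_real_),
         gene = r$gene %||% NA_character_,
         growth_coupled = isTRUE(r$growth_coupled),
         stoich = st)
  })
  me_model(mets, rxns, params = doc$params,
           uptake_reaction = doc$uptake_reaction, genes = genes)
}

# list of row objects (possibly with NA fields dropped by the writer)
# back to a data.frame with NA fill
rows_to_df <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cl) {
    vals <- lapply(rows, function(r) r[[cl]] %||% NA)
    unlist(lapply(vals, function(v) if (is.null(v)) NA else v))
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}
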