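# Process-data records: the nine structured inputs from which the
# expression half of an ME model is mechanically assembled.

pd_new <- function(subclass, id, fields) {
  structure(c(list(id = id), fields),
            class = c(subclass, "process_data"))
}

#' Process-data constructors
#'
#' Nine record types describing everything the builder needs to mechanize
#' gene expression: metabolic stoichiometries, enzyme complex composition,
#' machinery sub-reactions, transcription units, translation, tRNA charging,
#' translocation, post-translational processing, and generic groupings.
#'
#' @param id unique identifier of the record.
#' @param stoichiometry named numeric vector (metabolite -> coefficient).
#' @param reversible logical, for metabolic reactions.
#' @param subunits named numeric vector (protein id -> copy number).
#' @param modifications character vector of modification labels.
#' @param machinery enzyme/complex ids carrying out a sub-reaction.
#' @param tu_id,sequence,rna_products,sigma_factor,rna_type transcription
#'   unit fields; `sequence` is the DNA template (A/C/G/T).
#' @param gene_id,mrna_id,protein_id translation fields; `sequence` is the
#'   coding DNA sequence.
#' @param codon,amino_acid,trna_id tRNA fields.
#' @param pathway,k_eff,enzymes translocation fields.
#' @param members member ids of a generic component.
#' @return an object of class `process_data` (plus the subclass).
#' @name process_data
NULL

#' @rdname process_data
#' @export
stoichiometric_data <- function(id, stoichiometry, reversible = FALSE) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  pd_new("stoichiometric_data", id,
         list(stoichiometry = stoichiometry, reversible = reversible))
}

#' @rdname process_data
#' @export
complex_data <- function(id, subunits, modifications = character(0)) {
  stopifnot(is.numeric(subunits), !is.null(names(subunits)),
            all(subunits > 0))
  pd_new("complex_data", id,
         list(subunits = subunits, modifications = modifications))
}

#' @rdname process_data
#' @export
subreaction_data <- function(id, stoichiometry, machinery = character(0)) {
  pd_new("subreaction_data", id,
         list(stoichiometry = stoichiometry, machinery = machinery))
}

check_seq <- function(sequence, alphabet, id) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0) stopf("%s: empty sequence", id)
  bad <- which(!(chars %in% alphabet))
  if (length(bad) > 0)
    stopf("%s: invalid character '%s' at position %d", id, chars[bad[1]],
          bad[1])
  paste(chars, collapse = "")
}

#' @rdname process_data
#' @export
transcription_data <- function(tu_id, sequence, rna_products,
                               sigma_factor = "sigA",
                               rna_type = c("mRNA", "rRNA", "tRNA")) {
  rna_type <- match.arg(rna_type)
  if (length(rna_products) == 0)
    stopf("%s: transcription unit with empty product list", tu_id)
  sequence <- check_seq(sequence, c("A", "C", "G", "T"), tu_id)
  pd_new("transcription_data", tu_id,
         list(sequence = sequence, rna_products = rna_products,
              sigma_factor = sigma_factor, rna_type = rna_type))
}

#' @rdname process_data
#' @export
translation_data <- function(gene_id, mrna_id, sequence, protein_id) {
  sequence <- check_seq(sequence, c("A", "C", "G", "T"), gene_id)
  if (nchar(sequence) %% 3 != 0)
    stopf("%s: coding sequence length %d not divisible by 3", gene_id,
          nchar(sequence))
  pd_new("translation_data", gene_id,
         list(mrna_id = mrna_id, sequence = sequence,
              protein_id = protein_id))
}

#' @rdname process_data
#' @export
trna_data <- function(id, codon, amino_acid, trna_id,
                      modifications = character(0)) {
  pd_new("trna_data", id,
         list(codon = codon, amino_acid = amino_acid, trna_id = trna_id,
              modifications = modifications))
}

#' @rdname process_data
#' @export
translocation_data <- function(id, pathway, k_eff, enzymes = character(0),
                               stoichiometry = numeric(0)) {
  pd_new("translocation_data", id,
         list(pathway = pathway, k_eff = k_eff, enzymes = enzymes,
              stoichiometry = stoichiometry))
}

#' @rdname process_data
#' @export
post_translation_data <- function(id, pathway, modifications = character(0)) {
  pd_new("post_translation_data", id,
         list(pathway = pathway, modifications = modifications))
}

#' @rdname process_data
#' @export
generic_data <- function(id, members) {
  stopifnot(length(members) > 0)
  pd_new("generic_data", id, list(members = members))
}

#' Translate a coding sequence to residues
#'
#' Drops a trailing stop codon; errors on internal stops or invalid codons,
#' naming the offending position.
#' @param sequence coding DNA sequence.
#' @param id identifier used in error messages.
#' @return character vector of one-letter amino-acid codes.
#' @keywords internal
translate_cds <- function(sequence, id = "sequence") {
  codons <- substring(sequence, seq(1, nchar(sequence) - 2, 3),
                      seq(3, nchar(sequence), 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  bad <- which(is.na(aa))
  if (length(bad) > 0)
    stopf("%s: invalid codon '%s' at codon position %d", id,
          codons[bad[1]], bad[1])
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  internal_stop <- which(aa == "*")
  if (length(internal_stop) > 0)
    stopf("%s: internal stop codon at position %d", id, internal_stop[1])
  unname(aa)
}

#' Expression reaction stoichiometry from a process-data record
#'
#' Transcription consumes one NTP per template base (T read as U) and
#' releases one pyrophosphate per base, producing the RNA product.
#' Translation consumes one charged tRNA per residue and 2 GTP-equivalents
#' per residue (peptide-bond plus initiation cost), producing the protein.
#' Machinery (RNA polymerase, ribosome, mRNA) coupling coefficients are
#' added by the model builder, not here.
#'
#' @param td a [transcription_data()] or [translation_data()] record.
#' @param trna_set named map from amino-acid one-letter code to the charged
#'   tRNA metabolite id (required for translation).
#' @return named numeric stoichiometry (negative = consumed).
#' @export
expression_stoichiometry <- function(td, trna_set = NULL) {
  if (inherits(td, "transcription_data")) {
    chars <- strsplit(td$sequence, "")[[1]]
    counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
    st <- c(atp_c = -as.numeric(counts["A"]),
            utp_c = -as.numeric(counts["T"]),
            gtp_c = -as.numeric(counts["G"]),
            ctp_c = -as.numeric(counts["C"]),
            ppi_c = nchar(td$sequence))
    st <- st[st != 0]
    prod <- stats::setNames(rep(1, length(td$rna_products)),
                            td$rna_products)
    c(st, prod)
  } else if (inherits(td, "translation_data")) {
    aa <- translate_cds(td$sequence, td$id)
    counts <- table(aa)
    missing_aa <- setdiff(names(counts), names(trna_set %||% character(0)))
    if (length(missing_aa) > 0)
      stopf("%s: no charged tRNA for amino acid '%s' (first at residue %d)",
            td$id, missing_aa[1], which(aa == missing_aa[1])[1])
    st <- stats::setNames(-as.numeric(counts), trna_set[names(counts)])
    c(st, gtp_c = -2 * length(aa),
      stats::setNames(1, td$protein_id))
  } else {
    stopf("expression_stoichiometry: unsupported process-data class '%s'",
          class(td)[1])
  }
}
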