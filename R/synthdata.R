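# Synthetic-data generators with recorded ground truth: a toy organism for
# the ME model, multi-source expression compendia, sparse growth mappings,
# and planted regulatory networks.  Every generator is deterministic per
# seed and returns the planted truth alongside the data.

#' Generate a toy organism for desk-scale ME modelling
#'
#' The organism has a ribosomal-RNA gene, a ribosomal-protein gene, an
#' RNA-polymerase gene, a structural biomass-protein gene, and one or more
#' enzyme genes catalyzing a small glucose-to-biomass core (precursor branch,
#' energy branch, optional parallel precursor path and byproduct route).
#' Gene sequences are random valid ORFs (ATG start, sense codons, stop).
#' The stoichiometric glucose yield of biomass is hand-computable from the
#' recorded constants (see `$biomass` and the `yield_oracle()` helper).
#'
#' @param n_genes number of protein-coding genes (>= 3; the first three are
#'   the biomass protein, ribosomal protein and RNA-polymerase protein, the
#'   rest are enzymes).  An rRNA gene is always added.
#' @param n_enzymes number of enzyme genes (default `n_genes - 3`, capped).
#' @param include_machinery_ceiling bound the ribosome-formation flux so a
#'   batch growth region exists (default TRUE).
#' @param seed RNG seed.
#' @return object of class `toy_organism`.
#' @export
make_toy_organism <- function(n_genes = 7, n_enzymes = NULL,
                              include_machinery_ceiling = TRUE, seed = 0) {
  stopifnot(n_genes >= 3)
  n_enzymes <- min(n_enzymes %||% (n_genes - 3L), n_genes - 3L)
  with_seed(seed, {
    sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
    random_orf <- function() {
      n_cod <- sample(10:33, 1)  # 90-305 nt window, incl. start+stop
      paste0("ATG", paste(sample(sense, n_cod - 2, replace = TRUE),
                          collapse = ""), "TAA")
    }
    roles <- c("biomass_protein", "ribosomal_protein", "rna_polymerase",
               if (n_enzymes > 0) paste0("enzyme", seq_len(n_enzymes)),
               if (n_genes - 3L - n_enzymes > 0)
                 rep("cargo", n_genes - 3L - n_enzymes))
    gene_id <- sprintf("BSU%03d0", seq_len(n_genes))
    seqs <- vapply(seq_len(n_genes), function(i) random_orf(), character(1))
    names(seqs) <- gene_id
    rrna_id <- "BSUrRNA"
    seqs[rrna_id] <- paste(sample(c("A", "C", "G", "T"), 1200,
                                  replace = TRUE), collapse = "")
    genes <- data.frame(
      gene_id = c(gene_id, rrna_id),
      tu_id = paste0("TU_", c(gene_id, rrna_id)),
      operon = paste0("op_", c(gene_id, rrna_id)),
      product = c(rep("protein", n_genes), "rRNA"),
      role = c(roles, "rRNA"),
      length_nt = unname(nchar(seqs)),
      stringsAsFactors = FALSE)

    # enzyme-to-reaction map over the metabolic core
    core_rxn <- c("R_PRE", "R_NRG", "R_PRE2", "R_BYP")
    enz_genes <- gene_id[roles %in% paste0("enzyme", seq_len(n_enzymes))]
    enzyme_of <- stats::setNames(rep(NA_character_, length(genes$gene_id)),
                                 genes$gene_id)
    for (i in seq_along(enz_genes))
      enzyme_of[enz_genes[i]] <- core_rxn[i]
    genes$enzyme_of <- unname(enzyme_of[genes$gene_id])

    core <- list(
      list(id = "GLC_upt", stoich = c(glc_c = 1), enzyme = NA, lb = 0,
           ub = 10, spontaneous = TRUE),
      list(id = "R_PRE", stoich = c(glc_c = -1, pre_c = 2),
           enzyme = enzyme_for("R_PRE", enz_genes, core_rxn),
           lb = 0, ub = Inf, spontaneous = is.na(enzyme_for("R_PRE", enz_genes, core_rxn))),
      list(id = "R_NRG", stoich = c(glc_c = -1, gtp_c = 4),
           enzyme = enzyme_for("R_NRG", enz_genes, core_rxn),
           lb = 0, ub = Inf, spontaneous = is.na(enzyme_for("R_NRG", enz_genes, core_rxn))),
      if (length(enz_genes) >= 3)
        list(id = "R_PRE2", stoich = c(glc_c = -1, pre_c = 2),
             enzyme = enzyme_for("R_PRE2", enz_genes, core_rxn),
             lb = 0, ub = Inf, spontaneous = FALSE),
      if (length(enz_genes) >= 4)
        list(id = "R_BYP", stoich = c(pre_c = -1, byp_c = 1),
             enzyme = enzyme_for("R_BYP", enz_genes, core_rxn),
             lb = 0, ub = Inf, spontaneous = FALSE),
      if (length(enz_genes) >= 4)
        list(id = "EX_byp", stoich = c(byp_c = -1), enzyme = NA, lb = 0,
             ub = Inf, spontaneous = TRUE))
    core <- core[!vapply(core, is.null, logical(1))]

    enz_rxn_ids <- stats::na.omit(vapply(core, function(cr)
      if (!is.na(cr$enzyme %||% NA)) cr$id else NA_character_,
      character(1)))
    structure(list(
      genes = genes,
      sequences = seqs,
      core = core,
      # biomass: precursor + energy demand plus structural protein content;
      # q_bio in protein units per unit biomass flux
      biomass = list(b_pre = 10, b_gtp = 20, q_bio = 0.3),
      uptake_reaction = "GLC_upt",
      machinery_ceiling = if (include_machinery_ceiling) 2.1e-5 else Inf,
      enzyme_copies = 12,                    # subunits per enzyme complex
      kcat_table = data.frame(reaction = as.character(enz_rxn_ids),
                              kcat = rep(0.3, length(enz_rxn_ids)),
                              stringsAsFactors = FALSE),
      seed = seed),
      class = "toy_organism")
  })
}

enzyme_for <- function(rxn, enz_genes, core_rxn) {
  i <- match(rxn, core_rxn)
  if (!is.na(i) && i <= length(enz_genes)) enz_genes[i] else NA_character_
}

#' @export
print.toy_organism <- function(x, ...) {
  cat(sprintf("Toy organism: %d genes (%d protein-coding), %d core reactions\n",
              nrow(x$genes), sum(x$genes$product == "protein"),
              length(x$core)))
  cat(sprintf("  machinery ceiling: %s\n",
              if (is.finite(x$machinery_ceiling))
                format(x$machinery_ceiling) else "none"))
  invisible(x)
}

#' Generate a synthetic multi-source expression compendium
#'
#' Emulates the structure of a multi-condition microarray compendium: a
#' rank-`latent_rank` latent-factor expression model on a positive
#' (log-normal) scale, condition metadata, missing cells, planted
#' order-of-magnitude outliers, and a split into two source tables with
#' synonym identifiers so harmonization is exercised.
#'
#' @param organism a `toy_organism` (gene ids reused) or an integer gene
#'   count.
#' @param n_arrays number of arrays (default 50).
#' @param noise_sd log-scale measurement noise sd (default 0.3).
#' @param missing_frac fraction of missing cells (default 0.05).
#' @param outlier_frac fraction of magnitude-outlier cells, planted at
#'   |delta log10| = 3 (default 0.02).
#' @param latent_rank rank of the latent factor structure (default 5).
#' @param seed RNG seed.
#' @return list with `tables` (two [raw_expression_table()]s), `id_map`,
#'   and `truth` (planted positions, latent parameters, seed).
#' @export
make_synthetic_compendium <- function(organism = 40, n_arrays = 50,
                                      noise_sd = 0.3, missing_frac = 0.05,
                                      outlier_frac = 0.02, latent_rank = 5,
                                      seed = 0) {
  stopifnot(missing_frac >= 0, missing_frac < 1,
            outlier_frac >= 0, outlier_frac < 1)
  gene_ids <- if (inherits(organism, "toy_organism"))
    organism$genes$gene_id else sprintf("BSU%04d", seq_len(organism))
  ng <- length(gene_ids)
  with_seed(seed, {
    media <- sample(c("LB", "M9", "SMM"), n_arrays, replace = TRUE)
    strain <- sample(c("168", "MP902", "AG174"), n_arrays, replace = TRUE)
    temp <- sample(c(22, 37, 40), n_arrays, replace = TRUE)
    stress <- sample(c("none", "salt", "metal"), n_arrays, replace = TRUE,
                     prob = c(0.6, 0.2, 0.2))
    meta <- data.frame(array_id = sprintf("arr%03d", seq_len(n_arrays)),
                       strain = strain, medium = media, temperature = temp,
                       pH = round(stats::runif(n_arrays, 6, 8), 1),
                       stress = stress, perturbation = "none",
                       stringsAsFactors = FALSE)
    rownames(meta) <- meta$array_id

    L <- matrix(stats::rnorm(ng * latent_rank, sd = 0.5), ng)
    Fmat <- matrix(stats::rnorm(latent_rank * n_arrays, sd = 1), latent_rank)
    # condition-driven shifts so metadata structure is real
    Fmat[1, ] <- Fmat[1, ] + 1.2 * (media == "M9")
    Fmat[2, ] <- Fmat[2, ] + 1.0 * (stress != "none")
    base <- stats::rnorm(ng, mean = 2, sd = 0.6)
    logx <- base + L %*% Fmat +
      matrix(stats::rnorm(ng * n_arrays, sd = noise_sd), ng)
    vals <- exp(logx)                   # positive measurement scale
    dimnames(vals) <- list(gene_ids, meta$array_id)

    ncell <- ng * n_arrays
    pos <- sample.int(ncell, size = round((missing_frac + outlier_frac) * ncell))
    n_out <- round(outlier_frac * ncell)
    out_pos <- pos[seq_len(n_out)]
    mis_pos <- setdiff(pos, out_pos)
    if (n_out > 0) {
      # plant at exactly +/- 3 orders of magnitude from the gene median
      sgn <- sample(c(-3, 3), n_out, replace = TRUE)
      med <- apply(log10(vals), 1, stats::median)
      oi <- arrayInd(out_pos, dim(vals))
      vals[out_pos] <- 10^(med[oi[, 1]] + sgn)
    }
    vals_mis <- vals
    vals_mis[mis_pos] <- NA_real_
    # keep every gene observed at least 3 times
    for (i in seq_len(ng)) {
      nas <- which(is.na(vals_mis[i, ]))
      keep_n <- ncol(vals_mis) - length(nas)
      if (keep_n < 3) {
        fixi <- nas[seq_len(3 - keep_n)]
        vals_mis[i, fixi] <- vals[i, fixi]
        mis_pos <- setdiff(mis_pos, (fixi - 1) * ng + i)
      }
    }

    split_at <- floor(n_arrays / 2)
    a1 <- seq_len(split_at); a2 <- (split_at + 1):n_arrays
    syn <- paste0(gene_ids, "_syn")
    t1 <- raw_expression_table(vals_mis[, a1, drop = FALSE], gene_ids,
                               meta[a1, , drop = FALSE], "sourceA")
    v2 <- vals_mis[, a2, drop = FALSE]
    rownames(v2) <- syn
    t2 <- raw_expression_table(v2, syn, meta[a2, , drop = FALSE], "sourceB")
    id_map <- data.frame(source_id = c(gene_ids, syn),
                         canonical_id = c(gene_ids, gene_ids),
                         stringsAsFactors = FALSE)
    truth <- list(outlier_positions = arrayInd(out_pos, dim(vals)),
                  missing_positions = arrayInd(mis_pos, dim(vals)),
                  latent = list(loadings = L, factors = Fmat, base = base),
                  clean_values = vals, gene_ids = gene_ids, seed = seed)
    list(tables = list(t1, t2), id_map = id_map, truth = truth)
  })
}

#' Generate growth-rate labels from a sparse saturating mapping
#'
#' `y = S / (1 + S / mu_sat) + N(0, sigma)` with `S` a sparse positive
#' linear combination of gene expression values.
#'
#' @param X array x gene feature matrix (or an `expression_compendium`,
#'   transposed internally).
#' @param mapping optional list with `weights` (named, sparse), `mu_sat`,
#'   `sigma`; generated when `NULL`.
#' @param n_informative number of informative genes when generating
#'   (default 20).
#' @param mu_sat saturation constant (1/h scale, default 2).
#' @param sigma label noise sd (default 0.1).
#' @param seed RNG seed.
#' @return list with `y` and `truth` (weights, informative ids, parameters).
#' @export
make_growth_truth <- function(X, mapping = NULL, n_informative = 20,
                              mu_sat = 2, sigma = 0.1, seed = 0) {
  if (inherits(X, "expression_compendium")) X <- t(X$values)
  X <- as.matrix(X)
  p <- ncol(X)
  feat <- colnames(X) %||% sprintf("f%04d", seq_len(p))
  colnames(X) <- feat
  with_seed(seed, {
    if (is.null(mapping)) {
      stopifnot(n_informative <= p)
      inf <- sort(sample.int(p, n_informative))
      w <- stats::setNames(numeric(p), feat)
      w[inf] <- stats::runif(n_informative, 0.5, 1.5) * 2 / n_informative
      mapping <- list(weights = w[w != 0], mu_sat = mu_sat, sigma = sigma)
    }
    w_full <- stats::setNames(numeric(p), feat)
    w_full[names(mapping$weights)] <- mapping$weights
    S <- as.numeric(X %*% w_full)
    y <- S / (1 + S / mapping$mu_sat) +
      stats::rnorm(nrow(X), sd = mapping$sigma)
    list(y = y,
         truth = list(weights = mapping$weights,
                      informative = names(mapping$weights),
                      mu_sat = mapping$mu_sat, sigma = mapping$sigma,
                      signal = S, seed = seed))
  })
}

#' Generate a regulatory network with planted signed effects
#'
#' TF expression is uniform on (0, 1); each target gene's expression is
#' `0.5 + sum beta_e (x_tf - 0.5) + N(0, sigma)` over its regulators.
#' The returned expression matrix is on the generator's raw scale.
#'
#' @param n_tfs number of transcription factors (default 8).
#' @param n_targets number of target genes (default 40).
#' @param n_arrays number of arrays (default 500).
#' @param beta_range magnitude range of planted coefficients (default
#'   c(1, 2)); signs are random.
#' @param sigma target noise sd (default 0.1).
#' @param max_regulators maximum regulators per target (default 2).
#' @param seed RNG seed.
#' @return list with `network` (a [regulatory_network()]), `expression`
#'   (gene x array matrix), and `truth` (planted betas per edge).
#' @export
make_regulatory_truth <- function(n_tfs = 8, n_targets = 40, n_arrays = 500,
                                  beta_range = c(1, 2), sigma = 0.1,
                                  max_regulators = 2, seed = 0) {
  stopifnot(n_tfs >= 1, n_targets >= 1)
  with_seed(seed, {
    tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
    tg_ids <- sprintf("BSUT%03d", seq_len(n_targets))
    tf_x <- matrix(stats::runif(n_tfs * n_arrays), n_tfs,
                   dimnames = list(tf_ids, sprintf("arr%03d", seq_len(n_arrays))))
    edges <- do.call(rbind, lapply(seq_len(n_targets), function(i) {
      k <- sample.int(max_regulators, 1)
      regs <- sample(tf_ids, k)
      beta <- stats::runif(k, beta_range[1], beta_range[2]) *
        sample(c(-1, 1), k, replace = TRUE)
      data.frame(tf_id = regs, operon_id = paste0("op", i),
                 target_gene_id = tg_ids[i],
                 sign = ifelse(beta > 0, "+", "-"),
                 beta_true = beta, stringsAsFactors = FALSE)
    }))
    tg_x <- matrix(0.5, n_targets, n_arrays,
                   dimnames = list(tg_ids, colnames(tf_x)))
    for (r in seq_len(nrow(edges))) {
      tg <- edges$target_gene_id[r]
      tg_x[tg, ] <- tg_x[tg, ] +
        edges$beta_true[r] * (tf_x[edges$tf_id[r], ] - 0.5)
    }
    tg_x <- tg_x + matrix(stats::rnorm(n_targets * n_arrays, sd = sigma),
                          n_targets)
    net <- regulatory_network(edges[, c("tf_id", "operon_id",
                                        "target_gene_id", "sign")])
    list(network = net,
         expression = rbind(tf_x, tg_x),
         truth = edges)
  })
}

#' Generate a complementary two-view growth benchmark
#'
#' Two feature views (transcription, translation) each carry an independent
#' sparse linear half of the growth signal, so combining views is strictly
#' better than either alone.
#'
#' @param n_arrays,p_per_view,n_informative benchmark dimensions
#'   (defaults 240, 60, 8).
#' @param sigma label noise sd (default 0.08).
#' @param seed RNG seed.
#' @return list with `transcription`, `translation` (both [ml_dataset()]s)
#'   and `truth`.
#' @export
make_two_view_benchmark <- function(n_arrays = 240, p_per_view = 60,
                                    n_informative = 8, sigma = 0.08,
                                    seed = 0) {
  with_seed(seed, {
    mk_view <- function(prefix) {
      X <- matrix(stats::runif(n_arrays * p_per_view), n_arrays,
                  dimnames = list(sprintf("arr%03d", seq_len(n_arrays)),
                                  sprintf("%s%03d", prefix, seq_len(p_per_view))))
      inf <- sort(sample.int(p_per_view, n_informative))
      w <- numeric(p_per_view); w[inf] <- stats::runif(n_informative, 0.6, 1.4)
      list(X = X, w = w, inf = colnames(X)[inf],
           s = as.numeric(scale(X %*% w)))
    }
    vt <- mk_view("tx"); vp <- mk_view("tl")
    y <- 0.5 + 0.18 * vt$s + 0.18 * vp$s + stats::rnorm(n_arrays, sd = sigma)
    list(transcription = ml_dataset(vt$X, y, view = "transcription"),
         translation = ml_dataset(vp$X, y, view = "translation"),
         truth = list(informative_transcription = vt$inf,
                      informative_translation = vp$inf,
                      sigma = sigma, seed = seed))
  })
}
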