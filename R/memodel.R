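# Desk-scale metabolism-and-expression (ME) model: reactions whose
# stoichiometric coefficients are affine functions of the growth rate mu
# (coupling constraints for enzymes, ribosome, RNA polymerase and mRNA),
# solved at fixed mu as a linear program and maximized over mu by bisection
# on LP feasibility.
#
# Units: fluxes mmol gDW^-1 h^-1 (macromolecule fluxes in arbitrary
# macromolecule units per gDW per h), mu 1/h, kcat 1/s (converted to 1/h
# internally as k_eff = kcat * 3600).

#' Construct an ME model from explicit parts
#'
#' Low-level constructor; most users should call [build_me_model()].
#'
#' @param metabolites data.frame with columns `id`, `class`.
#' @param reactions named list of reaction records (id, lb, ub, stoich as a
#'   list of `list(met, const, mu)` coefficient entries, type, and optional
#'   `enzyme`, `k_eff`, `gene`, `growth_coupled` fields).
#' @param params model parameters (see [me_params()]).
#' @param uptake_reaction id of the substrate uptake reaction.
#' @param genes optional gene table.
#' @return object of class `me_model`.
#' @export
me_model <- function(metabolites, reactions, params = me_params(),
                     uptake_reaction = NULL, genes = NULL) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  mids <- metabolites$id
  for (r in reactions) {
    mets <- vapply(r$stoich, `[[`, character(1), "met")
    missing_m <- setdiff(mets, mids)
    if (length(missing_m) > 0)
      stopf("reaction %s references unknown metabolite(s): %s", r$id,
            paste(missing_m, collapse = ", "))
  }
  structure(list(metabolites = metabolites, reactions = reactions,
                 params = params, uptake_reaction = uptake_reaction,
                 genes = genes),
            class = "me_model")
}

#' Default ME-model parameters
#'
#' @param k_ribo ribosome elongation rate (amino acids per second,
#'   default 12).
#' @param k_rnap RNA-polymerase elongation rate (nucleotides per second,
#'   default 55).
#' @param k_deg_mrna mRNA degradation rate constant (1/h, default 8).
#' @param default_kcat fallback enzyme turnover number (1/s, default 65).
#' @param unmodeled_protein_fraction proteome fraction outside the model,
#'   inflating the structural protein demand (default 0.2).
#' @param nt_mass,aa_mass average monomer masses (g/mol) for the
#'   RNA-to-protein mass ratio.
#' @return named list of parameters.
#' @export
me_params <- function(k_ribo = 12, k_rnap = 55, k_deg_mrna = 8,
                      default_kcat = 65, unmodeled_protein_fraction = 0.2,
                      nt_mass = 324, aa_mass = 110) {
  list(k_ribo = k_ribo, k_rnap = k_rnap, k_deg_mrna = k_deg_mrna,
       default_kcat = default_kcat,
       unmodeled_protein_fraction = unmodeled_protein_fraction,
       nt_mass = nt_mass, aa_mass = aa_mass)
}

coeff_entry <- function(met, const = 0, mu = 0) list(met = met, const = const,
                                                     mu = mu)

const_stoich <- function(stoich)
  lapply(seq_along(stoich), function(i)
    coeff_entry(names(stoich)[i], const = unname(stoich[i])))

make_rxn <- function(id, stoich_entries, lb = 0, ub = Inf, type = "other",
                     enzyme = NA_character_, k_eff = NA_real_,
                     gene = NA_character_, growth_coupled = FALSE) {
  list(id = id, lb = lb, ub = ub, stoich = stoich_entries, type = type,
       enzyme = enzyme, k_eff = k_eff, gene = gene,
       growth_coupled = growth_coupled)
}

#' Build an ME model from a toy organism
#'
#' Mechanically assembles, per protein-coding gene: a transcription
#' reaction (NTP consumption by base counts, RNA-polymerase coupling
#' `mu * L_nt / (k_rnap * 3600)`), a translation reaction (charged-tRNA and
#' GTP consumption, ribosome coupling `mu * L_aa / (k_ribo * 3600)`, mRNA
#' coupling `(mu + k_deg_mrna) / k_eff_mrna`), and free dilution sinks for
#' the mRNA and protein; per enzyme-catalyzed reaction: enzyme-complex
#' consumption at `mu / k_eff` with `k_eff = kcat * 3600`; aggregate tRNA
#' charging per amino acid; ribosome and RNA-polymerase complex formation;
#' and a biomass dilution reaction whose flux is pinned to mu.
#'
#' @param organism a [make_toy_organism()] spec.
#' @param process_data optional externally built process-data list
#'   (default: derived from the organism).
#' @param kcat_table data.frame (`reaction`, `kcat` in 1/s); missing
#'   reactions get `params$default_kcat` and are logged.
#' @param params [me_params()] overrides (list).
#' @return an `me_model`.
#' @export
build_me_model <- function(organism, process_data = NULL, kcat_table = NULL,
                           params = list()) {
  pars <- utils::modifyList(me_params(), params)
  genes <- organism$genes
  coding <- genes[genes$product == "protein", ]
  rrna <- genes[genes$product == "rRNA", ]

  pd <- process_data %||% derive_process_data(organism)
  tds <- Filter(function(x) inherits(x, "transcription_data"), pd)
  tls <- Filter(function(x) inherits(x, "translation_data"), pd)

  # amino-acid alphabet in use -> aggregate charging reactions
  aa_all <- sort(unique(unlist(lapply(tls, function(td)
    translate_cds(td$sequence, td$id)))))
  trna_set <- stats::setNames(paste0("ctrna_", aa_all, "_c"), aa_all)

  mets <- data.frame(id = c("glc_c", "pre_c", "gtp_c", "atp_c", "utp_c",
                            "ctp_c", "ppi_c"),
                     class = "small_molecule", stringsAsFactors = FALSE)
  add_met <- function(id, class) {
    new <- !(id %in% mets$id)
    if (any(new)) mets <<- rbind(mets, data.frame(id = id[new],
                                                  class = class))
  }
  add_met(unname(trna_set), "charged_trna")

  rxns <- list()
  addr <- function(r) rxns[[r$id]] <<- r

  kcat_tab <- kcat_table %||% organism$kcat_table %||%
    data.frame(reaction = character(0), kcat = numeric(0))
  kcat_log <- list(defaulted = character(0), provided = character(0))
  lookup_keff <- function(rxn_id) {
    i <- match(rxn_id, kcat_tab$reaction)
    if (!is.na(i)) {
      if (kcat_tab$kcat[i] <= 0)
        stopf("non-positive kcat for reaction %s", rxn_id)
      kcat_log$provided <<- c(kcat_log$provided, rxn_id)
      kcat_tab$kcat[i] * 3600
    } else {
      kcat_log$defaulted <<- c(kcat_log$defaulted, rxn_id)
      pars$default_kcat * 3600
    }
  }

  # metabolic core (+ enzyme coupling); NTP synthesis from precursor+energy
  for (cr in organism$core) {
    for (m in names(cr$stoich)) add_met(m, "small_molecule")
    entries <- const_stoich(cr$stoich)
    enzyme_met <- NA_character_; keff <- NA_real_
    if (!is.na(cr$enzyme) && !isTRUE(cr$spontaneous)) {
      enzyme_met <- paste0("cplx_", cr$enzyme)
      add_met(enzyme_met, "complex")
      keff <- lookup_keff(cr$id)
      entries <- c(entries, list(coeff_entry(enzyme_met, mu = -1 / keff)))
    } else if (!isTRUE(cr$spontaneous) && is.na(cr$enzyme)) {
      stopf("reaction %s is neither spontaneous nor enzyme-mapped", cr$id)
    }
    addr(make_rxn(cr$id, entries, lb = cr$lb, ub = cr$ub, type = "metabolic",
                  enzyme = enzyme_met, k_eff = keff, gene = cr$enzyme))
  }
  for (b in c("atp_c", "utp_c", "ctp_c"))
    addr(make_rxn(paste0("SYN_", b),
                  const_stoich(stats::setNames(c(-1, -1, 1),
                                               c("pre_c", "gtp_c", b))),
                  type = "metabolic"))
  for (aa in aa_all)
    addr(make_rxn(paste0("CHRG_", aa),
                  const_stoich(stats::setNames(
                    c(-1, -1, 1), c("pre_c", "gtp_c", trna_set[aa]))),
                  type = "trna_charging"))
  addr(make_rxn("DM_ppi", const_stoich(c(ppi_c = -1)), type = "sink"))

  # expression machinery metabolites
  add_met(c("ribosome", "rnap"), "complex")

  k_ribo_eff <- pars$k_ribo * 3600   # aa/h
  k_rnap_eff <- pars$k_rnap * 3600   # nt/h

  for (td in tds) {
    rna_id <- td$rna_products[[1]]
    add_met(rna_id, if (td$rna_type == "mRNA") "mRNA" else "rRNA")
    L_nt <- nchar(td$sequence)
    entries <- const_stoich(expression_stoichiometry(td))
    entries <- c(entries,
                 list(coeff_entry("rnap", mu = -L_nt / k_rnap_eff)))
    addr(make_rxn(paste0("TX_", td$id), entries, type = "transcription",
                  gene = sub("^TU_", "", td$id)))
    addr(make_rxn(paste0("DM_", rna_id),
                  const_stoich(stats::setNames(-1, rna_id)), type = "sink"))
  }

  for (tl in tls) {
    add_met(tl$protein_id, "protein")
    aa_seq <- translate_cds(tl$sequence, tl$id)
    L_aa <- length(aa_seq)
    k_eff_mrna <- k_ribo_eff / L_aa   # proteins per mRNA per hour
    entries <- const_stoich(expression_stoichiometry(tl, trna_set))
    entries <- c(entries,
                 list(coeff_entry("ribosome", mu = -L_aa / k_ribo_eff),
                      coeff_entry(tl$mrna_id,
                                  const = -pars$k_deg_mrna / k_eff_mrna,
                                  mu = -1 / k_eff_mrna)))
    addr(make_rxn(paste0("TL_", tl$id), entries, type = "translation",
                  gene = tl$id, k_eff = k_eff_mrna))
    addr(make_rxn(paste0("DM_", tl$protein_id),
                  const_stoich(stats::setNames(-1, tl$protein_id)),
                  type = "sink"))
  }

  # complexes: ribosome (ribosomal protein + rRNA), RNA polymerase, enzymes
  rp <- coding$gene_id[coding$role == "ribosomal_protein"][1]
  rnapg <- coding$gene_id[coding$role == "rna_polymerase"][1]
  rrna_met <- paste0("rna_", rrna$gene_id[1])
  addr(make_rxn("FORM_ribosome",
                const_stoich(stats::setNames(
                  c(-1, -1, 1), c(paste0("prot_", rp), rrna_met,
                                  "ribosome"))),
                ub = organism$machinery_ceiling %||% Inf,
                type = "complex_formation"))
  addr(make_rxn("FORM_rnap",
                const_stoich(stats::setNames(
                  c(-2, 1), c(paste0("prot_", rnapg), "rnap"))),
                type = "complex_formation"))
  addr(make_rxn("DM_ribosome", const_stoich(c(ribosome = -1)),
                type = "sink"))
  addr(make_rxn("DM_rnap", const_stoich(c(rnap = -1)), type = "sink"))
  for (eg in coding$gene_id[!is.na(coding$enzyme_of)]) {
    cplx <- paste0("cplx_", eg)
    add_met(cplx, "complex")
    addr(make_rxn(paste0("FORM_", cplx),
                  const_stoich(stats::setNames(
                    c(-organism$enzyme_copies %||% 1, 1),
                    c(paste0("prot_", eg), cplx))),
                  type = "complex_formation"))
    addr(make_rxn(paste0("DM_", cplx), const_stoich(stats::setNames(-1, cplx)),
                  type = "sink"))
  }

  # biomass dilution: precursor + energy + structural protein, flux == mu
  bio_gene <- coding$gene_id[coding$role == "biomass_protein"][1]
  q_eff <- organism$biomass$q_bio / (1 - pars$unmodeled_protein_fraction)
  addr(make_rxn("BIOMASS",
                const_stoich(stats::setNames(
                  c(-organism$biomass$b_pre, -organism$biomass$b_gtp,
                    -q_eff),
                  c("pre_c", "gtp_c", paste0("prot_", bio_gene)))),
                type = "biomass", growth_coupled = TRUE))

  model <- me_model(mets, rxns, pars,
                    uptake_reaction = organism$uptake_reaction,
                    genes = genes)
  model$kcat_log <- kcat_log
  model$organism_biomass <- organism$biomass
  model$q_eff <- q_eff
  model
}

# derive per-gene transcription/translation records from a toy organism
derive_process_data <- function(organism) {
  genes <- organism$genes
  pd <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    seqg <- organism$sequences[[g]]
    if (genes$product[i] == "protein") {
      pd[[paste0("TU_", g)]] <- transcription_data(
        paste0("TU_", g), seqg, rna_products = paste0("mrna_", g),
        rna_type = "mRNA")
      pd[[g]] <- translation_data(g, paste0("mrna_", g), seqg,
                                  paste0("prot_", g))
    } else {
      pd[[paste0("TU_", g)]] <- transcription_data(
        paste0("TU_", g), seqg, rna_products = paste0("rna_", g),
        rna_type = "rRNA")
    }
  }
  pd
}

#' @export
print.me_model <- function(x, ...) {
  cat(sprintf("ME model: %d metabolites, %d reactions\n",
              nrow(x$metabolites), length(x$reactions)))
  tys <- table(vapply(x$reactions, `[[`, character(1), "type"))
  cat("  ", paste(sprintf("%s: %d", names(tys), tys), collapse = ", "), "\n")
  if (!is.null(x$kcat_log))
    cat(sprintf("  kcat coverage: %d provided, %d defaulted\n",
                length(x$kcat_log$provided), length(x$kcat_log$defaulted)))
  invisible(x)
}

#' Replace enzyme turnover numbers from a kcat table
#'
#' Updates the `mu / k_eff` enzyme-coupling coefficient of every catalyzed
#' reaction listed in the table (`k_eff = kcat * 3600`); unknown reaction
#' ids warn and are skipped.
#'
#' @param model an `me_model`.
#' @param table data.frame with columns `reaction`, `kcat` (1/s, positive).
#' @param default_kcat optional fallback applied to catalyzed reactions not
#'   in the table (1/s); `NULL` leaves them unchanged.
#' @return updated model; `model$kcat_coverage` reports `n_provided`,
#'   `n_default`, `coverage`.
#' @export
integrate_kcats <- function(model, table, default_kcat = NULL) {
  if (nrow(table) > 0 && any(table$kcat <= 0))
    stopf("non-positive kcat for reaction %s",
          table$reaction[which(table$kcat <= 0)[1]])
  cat_rxns <- names(model$reactions)[vapply(model$reactions, function(r)
    !is.na(r$enzyme), logical(1))]
  unknown <- setdiff(table$reaction, cat_rxns)
  if (length(unknown) > 0)
    warnf("kcat entries for unknown catalyzed reaction(s): %s",
          paste(unknown, collapse = ", "))
  n_prov <- 0L
  for (rid in cat_rxns) {
    i <- match(rid, table$reaction)
    keff <- if (!is.na(i)) {
      n_prov <- n_prov + 1L
      table$kcat[i] * 3600
    } else if (!is.null(default_kcat)) default_kcat * 3600 else NA_real_
    if (is.na(keff)) next
    r <- model$reactions[[rid]]
    for (j in seq_along(r$stoich)) {
      if (identical(r$stoich[[j]]$met, r$enzyme))
        r$stoich[[j]]$mu <- -1 / keff
    }
    r$k_eff <- keff
    model$reactions[[rid]] <- r
  }
  model$kcat_coverage <- list(n_provided = n_prov,
                              n_default = length(cat_rxns) - n_prov,
                              coverage = if (length(cat_rxns) > 0)
                                n_prov / length(cat_rxns) else 0)
  model
}

# assemble S(mu) and bounds at a fixed growth rate
me_lp_parts <- function(model, mu) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  lb <- numeric(length(rids)); ub <- numeric(length(rids))
  for (j in seq_along(rids)) {
    r <- model$reactions[[j]]
    for (e in r$stoich)
      S[e$met, j] <- S[e$met, j] + e$const + mu * e$mu
    lb[j] <- r$lb; ub[j] <- r$ub
    if (isTRUE(r$growth_coupled)) { lb[j] <- mu; ub[j] <- mu }
  }
  if (any(!is.finite(S))) stopf("non-finite coefficient at mu = %g", mu)
  list(S = S, lb = lb, ub = ub, rids = rids, mids = mids)
}

#' Solve the ME model at a fixed growth rate
#'
#' Evaluates all coupling coefficients at `mu` and solves the resulting
#' linear program.  With no objective a parsimonious solution (minimum
#' total flux) over the feasible set is returned, which makes predicted
#' expression well determined; a named `objective` vector is maximized
#' instead when given.
#'
#' @param model an `me_model`.
#' @param mu growth rate (1/h, >= 0).
#' @param objective optional named numeric vector over reaction ids to
#'   maximize (e.g. `c(DM_x = 1)`).
#' @param pfba minimize total flux when no objective is given
#'   (default TRUE).
#' @return object of class `me_solution`: `status`, `mu`, `fluxes`,
#'   `duals` (per-metabolite row duals), `residual`, `objective_value`.
#' @export
solve_at_mu <- function(model, mu, objective = NULL, pfba = TRUE) {
  stopifnot(mu >= 0)
  parts <- me_lp_parts(model, mu)
  n <- length(parts$rids)
  if (is.null(objective)) {
    obj <- rep(if (pfba) 1 else 0, n)
    maximize <- FALSE
  } else {
    obj <- numeric(n)
    obj[match(names(objective), parts$rids)] <- objective
    maximize <- TRUE
  }
  sol <- lp_solve(obj, parts$S, rep(0, nrow(parts$S)), parts$lb, parts$ub,
                  maximize = maximize)
  if (sol$status != "optimal")
    return(structure(list(status = sol$status, mu = mu, fluxes = NULL,
                          duals = NULL, residual = NA_real_,
                          objective_value = NA_real_),
                     class = "me_solution"))
  fluxes <- stats::setNames(sol$x, parts$rids)
  structure(list(status = "optimal", mu = mu, fluxes = fluxes,
                 duals = stats::setNames(sol$duals, parts$mids),
                 residual = sol$residual,
                 objective_value = if (is.null(objective)) NA_real_ else
                   sol$obj),
            class = "me_solution")
}

#' @export
print.me_solution <- function(x, ...) {
  cat(sprintf("ME solution: status %s at mu = %.6g 1/h\n", x$status, x$mu))
  if (x$status == "optimal")
    cat(sprintf("  mass-balance residual %.2e; %d nonzero fluxes\n",
                x$residual, sum(abs(x$fluxes) > 1e-9)))
  invisible(x)
}

#' Maximize growth by bisection on LP feasibility
#'
#' Feasibility of the mu-parameterized LP is monotone (demands grow with
#' mu), so the largest feasible mu is found by bisection to within `tol`.
#'
#' @param model an `me_model`.
#' @param tol bisection tolerance on mu (1/h, default 1e-6).
#' @param mu_max_bracket upper bracket; an error asks for a larger bracket
#'   if the model is still feasible there (default 4).
#' @return the `me_solution` at the maximal feasible mu (parsimonious
#'   fluxes), with `n_bisect` iterations recorded.
#' @export
maximize_growth <- function(model, tol = 1e-6, mu_max_bracket = 4) {
  if (solve_at_mu(model, 0, pfba = FALSE)$status != "optimal")
    stopf("model infeasible at mu = 0")
  feasible <- function(mu)
    solve_at_mu(model, mu, pfba = FALSE)$status == "optimal"
  if (feasible(mu_max_bracket))
    stopf("still feasible at mu = %g: increase mu_max_bracket",
          mu_max_bracket)
  lo <- 0; hi <- mu_max_bracket; it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
    it <- it + 1L
  }
  sol <- solve_at_mu(model, lo)
  sol$n_bisect <- it
  sol$mu_infeasible_above <- hi
  sol
}

#' Set the substrate-uptake bound of a model
#'
#' @param model an `me_model`.
#' @param bound new upper bound (mmol gDW^-1 h^-1).
#' @param reaction uptake reaction id (default the model's).
#' @return modified model.
#' @export
set_uptake <- function(model, bound, reaction = NULL) {
  rid <- reaction %||% model$uptake_reaction
  if (is.null(rid) || !(rid %in% names(model$reactions)))
    stopf("unknown uptake reaction '%s'", rid %||% "<null>")
  model$reactions[[rid]]$ub <- bound
  model
}

#' Growth curve over a substrate-uptake grid
#'
#' For each uptake bound the maximal growth rate is found by bisection and
#' the substrate shadow price (marginal growth gain per unit uptake,
#' d mu*/d u) is computed by a forward-difference re-solve.
#'
#' @param model an `me_model`.
#' @param uptake_grid ascending numeric vector of uptake bounds
#'   (mmol gDW^-1 h^-1).
#' @param substrate_exchange uptake reaction id (default the model's).
#' @param tol bisection tolerance.
#' @param delta_frac relative step for the shadow-price difference
#'   (default 0.02).
#' @return object of class `growth_curve`: data.frame `uptake`, `mu_star`,
#'   `shadow_price`, plus region labels once [classify_regions()] is run.
#' @export
growth_curve <- function(model, uptake_grid, substrate_exchange = NULL,
                         tol = 1e-6, delta_frac = 0.02) {
  if (is.unsorted(uptake_grid)) stopf("uptake grid must be ascending")
  mu <- numeric(length(uptake_grid))
  sp <- numeric(length(uptake_grid))
  bracket <- 4
  for (i in seq_along(uptake_grid)) {
    u <- uptake_grid[i]
    sol <- tryCatch(
      maximize_growth(set_uptake(model, u, substrate_exchange), tol = tol,
                      mu_max_bracket = bracket),
      error = function(e) stopf("grid point %d (uptake %g): %s", i, u,
                                conditionMessage(e)))
    mu[i] <- sol$mu
    du <- max(delta_frac * max(u, uptake_grid[length(uptake_grid)] * 0.05),
              1e-4)
    sol2 <- maximize_growth(set_uptake(model, u + du, substrate_exchange),
                            tol = tol, mu_max_bracket = bracket)
    sp[i] <- (sol2$mu - mu[i]) / du
  }
  structure(list(curve = data.frame(uptake = uptake_grid, mu_star = mu,
                                    shadow_price = sp)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  print(x$curve)
  invisible(x)
}

#' Classify growth-curve regions
#'
#' Strictly nutrient-limited (SNL): positive substrate shadow price and
#' local slope within `slope_tol` of the initial slope; batch: shadow price
#' below `eps`; Janusian: in between.  Labels are contiguous in that order.
#'
#' @param curve a [growth_curve()].
#' @param eps dual threshold for the batch region (default 1e-6).
#' @param slope_tol relative slope tolerance for SNL (default 0.05).
#' @return the curve with a `region` column and a `boundaries` element.
#' @export
classify_regions <- function(curve, eps = 1e-6, slope_tol = 0.05) {
  cv <- curve$curve
  if (nrow(cv) < 5) stopf("need at least 5 grid points")
  if (any(diff(cv$mu_star) < -1e-7))
    stopf("non-monotone growth curve: upstream solver bug")
  n <- nrow(cv)
  slope <- c(NA, diff(cv$mu_star) / diff(cv$uptake))
  init_slope <- slope[2]
  region <- rep("janusian", n)
  snl <- cv$shadow_price > eps &
    (is.na(slope) | abs(slope - init_slope) <= slope_tol * abs(init_slope))
  batch <- cv$shadow_price < eps
  # contiguity: SNL is the maximal prefix, batch the maximal suffix
  last_snl <- if (snl[1]) max(which(cumsum(!snl) == 0)) else 0L
  first_batch <- if (batch[n]) n + 1L - max(which(cumsum(rev(!batch)) == 0))
    else n + 1L
  region[seq_len(last_snl)] <- "SNL"
  if (first_batch <= n) region[first_batch:n] <- "batch"
  cv$region <- region
  out <- curve
  out$curve <- cv
  out$boundaries <- list(snl_end = last_snl, batch_start = first_batch)
  out
}

#' RNA-to-protein mass ratio of a solution
#'
#' Steady-state amounts from the synthesis/dilution balance: mRNA amount
#' `v_tx / (mu + k_deg)`, stable RNA amount `v_tx / mu`, protein amount
#' `v_tl / mu`; masses via average monomer masses and sequence lengths.
#'
#' @param solution an optimal `me_solution` with `mu > 0`.
#' @param model the `me_model` it came from.
#' @return mass ratio (g RNA per g protein).
#' @export
rna_protein_ratio <- function(solution, model) {
  stopifnot(solution$status == "optimal")
  mu <- solution$mu
  pars <- model$params
  rna_mass <- 0; prot_mass <- 0
  for (r in model$reactions) {
    v <- solution$fluxes[[r$id]]
    if (r$type == "transcription") {
      rna_met <- vapply(r$stoich, function(e) e$met, character(1))
      rna_met <- rna_met[grepl("^(mrna_|rna_)", rna_met)][1]
      L_nt <- sum(vapply(r$stoich, function(e)
        if (e$met %in% c("atp_c", "utp_c", "gtp_c", "ctp_c"))
          -e$const else 0, numeric(1)))
      denom <- if (grepl("^mrna_", rna_met)) mu + pars$k_deg_mrna else mu
      rna_mass <- rna_mass + v / denom * L_nt * pars$nt_mass
    } else if (r$type == "translation") {
      L_aa <- sum(vapply(r$stoich, function(e)
        if (grepl("^ctrna_", e$met)) -e$const else 0, numeric(1)))
      prot_mass <- prot_mass + v / mu * L_aa * pars$aa_mass
    }
  }
  if (prot_mass <= 0) stopf("zero protein mass at mu = %g", mu)
  rna_mass / prot_mass
}

#' Flux variability at a fixed growth fraction
#'
#' Minimum and maximum of one reaction's flux with mu fixed at
#' `mu_fraction * mu_star`.
#'
#' @param model an `me_model`.
#' @param reaction reaction id.
#' @param mu_fraction fraction of the maximal growth rate (default 1).
#' @param mu_star optional precomputed maximal growth rate.
#' @return named vector `c(min, max)`.
#' @export
flux_variability <- function(model, reaction, mu_fraction = 1,
                             mu_star = NULL) {
  if (!(reaction %in% names(model$reactions)))
    stopf("unknown reaction '%s'", reaction)
  mu_star <- mu_star %||% maximize_growth(model)$mu
  mu <- mu_fraction * mu_star
  obj <- stats::setNames(1, reaction)
  up <- solve_at_mu(model, mu, objective = obj)
  dn <- solve_at_mu(model, mu, objective = stats::setNames(-1, reaction))
  if (up$status != "optimal" || dn$status != "optimal")
    stopf("infeasible at mu fraction %g (mu = %g)", mu_fraction, mu)
  c(min = dn$fluxes[[reaction]], max = up$fluxes[[reaction]])
}

#' Maximal metabolite synthesis over a substrate grid
#'
#' Adds a demand reaction for the metabolite and maximizes its flux while
#' holding mu at `mu_fraction` of the point's maximal growth rate.
#'
#' @param model an `me_model`.
#' @param metabolite metabolite id.
#' @param glucose_grid ascending substrate-uptake bounds.
#' @param mu_fraction growth-rate fraction retained (default 0.5).
#' @return data.frame `uptake`, `mu_star`, `synthesis_rate`.
#' @export
metabolite_synthesis_scan <- function(model, metabolite, glucose_grid,
                                      mu_fraction = 0.5) {
  if (!(metabolite %in% model$metabolites$id))
    stopf("unknown metabolite '%s'", metabolite)
  dm_id <- paste0("DM_scan_", metabolite)
  model$reactions[[dm_id]] <-
    make_rxn(dm_id, const_stoich(stats::setNames(-1, metabolite)),
             type = "sink")
  rate <- numeric(length(glucose_grid))
  mus <- numeric(length(glucose_grid))
  for (i in seq_along(glucose_grid)) {
    m <- set_uptake(model, glucose_grid[i])
    mus[i] <- if (glucose_grid[i] == 0) 0 else maximize_growth(m)$mu
    sol <- solve_at_mu(m, mu_fraction * mus[i],
                       objective = stats::setNames(1, dm_id))
    rate[i] <- if (sol$status == "optimal") sol$objective_value else 0
  }
  if (all(rate <= 1e-12) && any(glucose_grid > 0))
    warnf("metabolite %s unreachable: zero synthesis curve", metabolite)
  data.frame(uptake = glucose_grid, mu_star = mus, synthesis_rate = rate)
}

#' Predicted per-gene expression of a solution
#'
#' Per-gene transcription flux, min-max rescaled to [0, 1] across genes
#' (the compendium scaling convention; a constant profile maps to 0).
#'
#' @param solution an optimal `me_solution`.
#' @param model the `me_model`.
#' @return named numeric vector over genes with transcription data.
#' @export
predicted_expression <- function(solution, model) {
  stopifnot(solution$status == "optimal")
  tx <- names(model$reactions)[vapply(model$reactions, function(r)
    r$type == "transcription", logical(1))]
  v <- vapply(tx, function(rid) solution$fluxes[[rid]], numeric(1))
  names(v) <- sub("^TX_TU_", "", tx)
  rng <- max(v) - min(v)
  if (rng == 0) return(stats::setNames(rep(0, length(v)), names(v)))
  (v - min(v)) / rng
}

#' Knock a gene out of the expression machinery
#'
#' Blocks the gene's translation (protein cannot be made, so any complex
#' and catalysis depending on it carries no flux at mu > 0).
#'
#' @param model an `me_model`. @param gene gene id.
#' @return modified model.
#' @export
me_knockout <- function(model, gene) {
  rid <- paste0("TL_", gene)
  if (!(rid %in% names(model$reactions)))
    stopf("gene '%s' has no translation reaction", gene)
  model$reactions[[rid]]$ub <- 0
  model
}
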