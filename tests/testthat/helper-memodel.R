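# Hand-built minimal ME-style models with closed-form behaviour.

mini_rxn <- function(id, stoich, lb = 0, ub = Inf, type = "metabolic",
                     growth_coupled = FALSE) {
  list(id = id, lb = lb, ub = ub,
       stoich = lapply(seq_along(stoich), function(i)
         list(met = names(stoich)[i], const = unname(stoich[i]), mu = 0)),
       type = type, enzyme = NA_character_, k_eff = NA_real_,
       gene = NA_character_, growth_coupled = growth_coupled)
}

# uptake (ub u) -> R1: glc -> 2 pre -> biomass consumes 10 pre at rate mu;
# closed-form maximal growth: mu* = 2u/10 = 0.2 u
mini_linear_model <- function(u = 1, parallel = FALSE) {
  mets <- data.frame(id = c("glc_c", "pre_c"), class = "small_molecule")
  rxns <- list(
    mini_rxn("GLC_upt", c(glc_c = 1), ub = u),
    mini_rxn("R1", c(glc_c = -1, pre_c = 2)),
    mini_rxn("BIOMASS", c(pre_c = -10), type = "biomass",
             growth_coupled = TRUE))
  if (parallel)
    rxns <- append(rxns, list(mini_rxn("R1b", c(glc_c = -1, pre_c = 2))), 2)
  me_model(mets, rxns, params = me_params(), uptake_reaction = "GLC_upt")
}

# standard toy organism + model, cached per session for speed
toy_cache <- new.env(parent = emptyenv())
toy_model <- function(seed = 0, ceiling = TRUE) {
  key <- paste0("m", seed, ceiling)
  if (is.null(toy_cache[[key]])) {
    org <- make_toy_organism(include_machinery_ceiling = ceiling,
                             seed = seed)
    toy_cache[[key]] <- list(org = org, model = build_me_model(org))
  }
  toy_cache[[key]]
}

# stoichiometric glucose yield of biomass, derived by hand from the recorded
# toy constants: glc/2 per precursor, glc/4 per energy unit; protein costs
# 1 precursor + 1 energy (synthesis+charging) + 2 energy (elongation) per
# residue; unmodeled-protein inflation 1/(1-0.2)
toy_yield_oracle <- function(org, params = me_params()) {
  b <- org$biomass
  q_eff <- b$q_bio / (1 - params$unmodeled_protein_fraction)
  bio_gene <- org$genes$gene_id[org$genes$role == "biomass_protein"]
  L_aa <- nchar(org$sequences[[bio_gene]]) / 3 - 1
  glc_per_mu <- b$b_pre / 2 + b$b_gtp / 4 +
    q_eff * L_aa * (1 / 2 + 1 / 4 + 2 / 4)
  1 / glc_per_mu
}
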