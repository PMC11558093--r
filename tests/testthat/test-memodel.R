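test_that("expression stoichiometry counts bases, tRNAs and GTP", {
  td <- transcription_data("TU_x", "ATGC", rna_products = "mrna_x")
  st <- expression_stoichiometry(td)
  expect_equal(st[["atp_c"]], -1)
  expect_equal(st[["utp_c"]], -1)
  expect_equal(st[["gtp_c"]], -1)
  expect_equal(st[["ctp_c"]], -1)
  expect_equal(st[["ppi_c"]], 4)
  expect_equal(st[["mrna_x"]], 1)

  tl <- translation_data("gx", "mrna_x", "ATGAAA", "prot_x")
  trna <- c(M = "ctrna_M_c", K = "ctrna_K_c")
  st2 <- expression_stoichiometry(tl, trna)
  expect_equal(st2[["ctrna_M_c"]], -1)
  expect_equal(st2[["ctrna_K_c"]], -1)
  expect_equal(st2[["gtp_c"]], -4)   # 2 GTP-equivalents per residue
  expect_equal(st2[["prot_x"]], 1)

  expect_error(transcription_data("TU_y", "ATGC", character(0)),
               "empty product")
  expect_error(translation_data("gy", "m", "ATGA", "p"), "divisible")
  expect_error(expression_stoichiometry(
    translation_data("gz", "m", "ATGAAA", "p"), c(M = "ctrna_M_c")),
    "no charged tRNA")
})

test_that("model construction creates the full per-gene reaction set", {
  tm <- toy_model()
  m <- tm$model
  types <- vapply(m$reactions, `[[`, character(1), "type")
  expect_gte(sum(types == "transcription"), 8)   # 7 coding + rRNA
  expect_equal(sum(types == "translation"), 7)
  expect_gte(sum(types == "sink"), 15)
  expect_true("BIOMASS" %in% names(m$reactions))
  expect_gte(length(m$reactions), 6)

  # mu = 0 limit: all mu-scaled machinery coefficients vanish; the mRNA
  # degradation term stays
  tl <- m$reactions[[grep("^TL_", names(m$reactions))[1]]]
  mrna_e <- Filter(function(e) grepl("^mrna_", e$met), tl$stoich)[[1]]
  expect_lt(mrna_e$const, 0)          # degradation survives at mu = 0
  rib_e <- Filter(function(e) e$met == "ribosome", tl$stoich)[[1]]
  expect_equal(rib_e$const, 0)
  expect_lt(rib_e$mu, 0)

  # missing kcat falls back to the 65 1/s default and is logged
  org <- tm$org
  m2 <- build_me_model(org, kcat_table = data.frame(reaction = character(0),
                                                    kcat = numeric(0)))
  expect_gte(length(m2$kcat_log$defaulted), 1)
  expect_equal(m2$reactions[["R_PRE"]]$k_eff, 65 * 3600)
})

test_that("kcat integration updates coupling coefficients and coverage", {
  tm <- toy_model()
  m <- tm$model
  enz_rxns <- names(m$reactions)[vapply(m$reactions, function(r)
    !is.na(r$enzyme), logical(1))]

  m0 <- integrate_kcats(m, data.frame(reaction = character(0),
                                      kcat = numeric(0)))
  expect_equal(m0$kcat_coverage$coverage, 0)
  full <- data.frame(reaction = enz_rxns, kcat = 1)
  m1 <- integrate_kcats(m, full)
  expect_equal(m1$kcat_coverage$coverage, 1)

  # doubling one kcat halves the enzyme coupling coefficient
  tab1 <- data.frame(reaction = enz_rxns[1], kcat = 1)
  tab2 <- data.frame(reaction = enz_rxns[1], kcat = 2)
  coef_of <- function(mm) {
    r <- mm$reactions[[enz_rxns[1]]]
    Filter(function(e) identical(e$met, r$enzyme), r$stoich)[[1]]$mu
  }
  expect_equal(coef_of(integrate_kcats(m, tab1)) / 2,
               coef_of(integrate_kcats(m, tab2)), tolerance = 1e-12)

  expect_error(integrate_kcats(m, data.frame(reaction = enz_rxns[1],
                                             kcat = -1)), "non-positive")
  expect_warning(integrate_kcats(m, data.frame(reaction = "NOPE", kcat = 1)),
                 "unknown")
})

test_that("fixed-mu solves respect feasibility and the balance contract", {
  tm <- toy_model()
  m <- tm$model
  s0 <- solve_at_mu(m, 0)
  expect_equal(s0$status, "optimal")
  expect_lt(max(abs(s0$fluxes)), 1e-9)     # all-zero flux admissible
  expect_equal(solve_at_mu(m, 3.9)$status, "infeasible")
  s <- solve_at_mu(m, 0.15)
  expect_lt(s$residual, 1e-9)
})

test_that("bisection growth maximization matches the closed-form yield", {
  for (u in c(0.5, 1, 2)) {
    m <- mini_linear_model(u = u)
    s <- maximize_growth(m, tol = 1e-7)
    expect_equal(s$mu, 0.2 * u, tolerance = 1e-5)
  }
  # zero uptake -> zero growth
  expect_equal(maximize_growth(mini_linear_model(u = 0))$mu, 0,
               tolerance = 1e-6)
  # tolerance contract
  m <- mini_linear_model(u = 1)
  mu4 <- maximize_growth(m, tol = 1e-4)$mu
  mu6 <- maximize_growth(m, tol = 1e-6)$mu
  expect_lt(abs(mu4 - mu6), 1e-4)
  # feasible at bracket top asks for a larger bracket
  m_unbounded <- mini_linear_model(u = 100)
  expect_error(maximize_growth(m_unbounded, mu_max_bracket = 4),
               "bracket")
})

test_that("LP feasibility is monotone in the growth rate", {
  tm <- toy_model()
  m <- set_uptake(tm$model, 5)
  feas <- vapply(seq(0.02, 0.4, by = 0.02), function(mu)
    solve_at_mu(m, mu, pfba = FALSE)$status == "optimal", logical(1))
  expect_true(all(diff(feas) <= 0))   # once infeasible, stays infeasible
})

test_that("growth curve exhibits SNL, Janusian and batch regions", {
  tm <- toy_model()
  gc <- growth_curve(tm$model, seq(0, 10, by = 1))
  cv <- classify_regions(gc)$curve
  expect_true(all(diff(cv$mu_star) >= -1e-7))
  expect_setequal(unique(cv$region), c("SNL", "janusian", "batch"))
  # regions contiguous in order
  rle_r <- rle(cv$region)$values
  expect_equal(rle_r, c("SNL", "janusian", "batch"))
  # SNL slope matches the hand yield oracle within 2%
  slope <- (cv$mu_star[2] - cv$mu_star[1]) / (cv$uptake[2] - cv$uptake[1])
  Y <- toy_yield_oracle(tm$org)
  expect_lt(abs(slope - Y) / Y, 0.02)
  # dual signs: positive while nutrient-limited, < 1e-6 in batch
  expect_true(all(cv$shadow_price[cv$region == "SNL"] > 1e-6))
  expect_true(all(cv$shadow_price[cv$region == "batch"] < 1e-6))
  # plateau equals the uptake-unconstrained maximum
  s_unb <- maximize_growth(set_uptake(tm$model, 1e5))
  expect_equal(max(cv$mu_star), s_unb$mu, tolerance = 1e-4)
  # huge eps makes everything batch
  cv2 <- classify_regions(gc, eps = 1e9)$curve
  expect_true(all(cv2$region == "batch"))
})

test_that("removing the machinery ceiling removes the batch region", {
  tm <- toy_model(ceiling = FALSE)
  gc <- growth_curve(tm$model, seq(0, 10, by = 2))
  cv <- classify_regions(gc)$curve
  expect_false("batch" %in% cv$region)
})

test_that("RNA-to-protein ratio follows growth-law directions", {
  tm <- toy_model()
  m <- set_uptake(tm$model, 10)
  r_lo <- rna_protein_ratio(solve_at_mu(m, 0.1), m)
  r_hi <- rna_protein_ratio(solve_at_mu(m, 0.25), m)
  expect_gt(r_hi, r_lo)

  # doubling the ribosome elongation rate lowers the ratio at fixed mu
  m_fast <- build_me_model(tm$org, params = list(k_ribo = 24))
  m_fast <- set_uptake(m_fast, 10)
  expect_lt(rna_protein_ratio(solve_at_mu(m_fast, 0.15), m_fast),
            rna_protein_ratio(solve_at_mu(m, 0.15), m))

  # mu -> 0: ratio/mu approaches the symbolic single-gene limit
  org <- tm$org
  pars <- m$params
  bio <- org$genes$gene_id[org$genes$role == "biomass_protein"]
  rrna <- org$genes$gene_id[org$genes$product == "rRNA"]
  s0 <- (nchar(org$sequences[[bio]]) + nchar(org$sequences[[rrna]])) *
    pars$nt_mass / (pars$k_ribo * 3600 * pars$aa_mass)
  mu_small <- 1e-3
  r <- rna_protein_ratio(solve_at_mu(m, mu_small), m)
  expect_equal(r / mu_small, s0, tolerance = 0.02)
})

test_that("flux variability is exact on unique and parallel pathways", {
  mu_fix <- 0.1
  uni <- mini_linear_model(u = 10)
  fva <- flux_variability(uni, "R1", mu_fraction = 1, mu_star = mu_fix)
  expect_lt(fva[["max"]] - fva[["min"]], 1e-8)
  expect_equal(fva[["min"]], 10 * mu_fix / 2, tolerance = 1e-8)

  par2 <- mini_linear_model(u = 10, parallel = TRUE)
  fvap <- flux_variability(par2, "R1", mu_fraction = 1, mu_star = mu_fix)
  expect_equal(fvap[["min"]], 0, tolerance = 1e-8)
  expect_equal(fvap[["max"]], 10 * mu_fix / 2, tolerance = 1e-8)

  # relaxing mu widens (or preserves) the range; FVA brackets the FBA flux
  tm <- toy_model()
  m5 <- set_uptake(tm$model, 5)
  mu_star <- maximize_growth(m5)$mu
  for (rid in c("R_NRG", "R_PRE2")) {
    f9 <- flux_variability(m5, rid, 0.9, mu_star = mu_star)
    f2 <- flux_variability(m5, rid, 0.2, mu_star = mu_star)
    expect_lte(f9[["max"]] - f9[["min"]], f2[["max"]] - f2[["min"]] + 1e-8)
    v <- solve_at_mu(m5, 0.9 * mu_star)$fluxes[[rid]]
    expect_gte(v, f9[["min"]] - 1e-8)
    expect_lte(v, f9[["max"]] + 1e-8)
  }
})

test_that("metabolite synthesis scans saturate and respect growth demand", {
  tm <- toy_model()
  sc <- metabolite_synthesis_scan(tm$model, "pre_c", c(0, 2, 4),
                                  mu_fraction = 0.5)
  expect_equal(sc$synthesis_rate[1], 0, tolerance = 1e-9)
  expect_true(all(diff(sc$synthesis_rate) >= -1e-8))
  # at full growth demand the spare synthesis capacity collapses
  sc1 <- metabolite_synthesis_scan(tm$model, "pre_c", c(2), mu_fraction = 1)
  expect_lt(sc1$synthesis_rate, 0.05 * sc$synthesis_rate[2])
  expect_error(metabolite_synthesis_scan(tm$model, "nope_c", c(1)),
               "unknown metabolite")
})

test_that("predicted expression tracks pathway usage and knockouts", {
  tm <- toy_model()
  m <- set_uptake(tm$model, 5)
  s <- maximize_growth(m)
  pe <- predicted_expression(s, m)
  n_tx <- sum(vapply(m$reactions, function(r) r$type == "transcription",
                     logical(1)))
  expect_length(pe, n_tx)
  expect_true(all(pe >= 0 & pe <= 1))

  # the parsimonious solution uses one precursor path; knocking out the
  # active path's enzyme gene reroutes flux and silences its expression
  genes <- tm$org$genes
  e_pre2 <- genes$gene_id[!is.na(genes$enzyme_of) &
                            genes$enzyme_of == "R_PRE2"]
  active <- if (s$fluxes[["R_PRE2"]] > 1e-9) e_pre2 else
    genes$gene_id[!is.na(genes$enzyme_of) & genes$enzyme_of == "R_PRE"]
  expect_gt(pe[[active]], 0)
  m_ko <- me_knockout(m, active)
  s_ko <- solve_at_mu(m_ko, 0.5 * s$mu)
  expect_equal(s_ko$status, "optimal")
  pe_ko <- predicted_expression(s_ko, m_ko)
  expect_equal(pe_ko[[active]], 0)
})

test_that("slowing any machinery parameter lowers the maximal growth rate", {
  tm <- toy_model()
  base <- maximize_growth(set_uptake(tm$model, 10))$mu
  slow_ribo <- build_me_model(tm$org, params = list(k_ribo = 1.2))
  expect_lt(maximize_growth(set_uptake(slow_ribo, 10))$mu, base)
  slow_kcat <- integrate_kcats(
    set_uptake(tm$model, 10),
    data.frame(reaction = c("R_PRE", "R_PRE2", "R_NRG", "R_BYP"),
               kcat = 0.03))
  expect_lt(maximize_growth(slow_kcat)$mu, base)
})
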