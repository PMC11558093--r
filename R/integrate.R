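# The ME <-> ML integration loop: simulate expression/growth arrays from
# the ME model (GE-MF), extend the learners' datasets with them, update the
# ME model's expression modules from learned growth/expression targets, and
# score expression-prediction accuracy.

#' Simulate gene-expression/growth arrays from the ME model
#'
#' For each condition (a substrate-uptake bound), growth is maximized and
#' the per-gene predicted expression vector recorded; infeasible conditions
#' are skipped with a warning.
#'
#' @param model an `me_model`.
#' @param conditions data.frame with column `uptake` (mmol gDW^-1 h^-1) and
#'   optional descriptor columns (`substrate`, `temperature`, ...).
#' @param seed recorded for provenance (the simulation itself is
#'   deterministic).
#' @return object of class `simulated_array_set`: `expression`
#'   (gene x condition, values in [0, 1]), `mu`, `conditions`, `origin`.
#' @export
generate_gemf <- function(model, conditions, seed = 0) {
  stopifnot(is.data.frame(conditions), "uptake" %in% colnames(conditions))
  cols <- list(); mus <- numeric(0); kept <- integer(0)
  for (i in seq_len(nrow(conditions))) {
    sol <- tryCatch(
      maximize_growth(set_uptake(model, conditions$uptake[i])),
      error = function(e) NULL)
    if (is.null(sol) || sol$status != "optimal") {
      warnf("condition %d (uptake %g) infeasible: skipped", i,
            conditions$uptake[i])
      next
    }
    cols[[length(cols) + 1L]] <- predicted_expression(sol, model)
    mus <- c(mus, sol$mu)
    kept <- c(kept, i)
  }
  if (length(cols) == 0) stopf("no solvable condition")
  expr <- do.call(cbind, cols)
  colnames(expr) <- sprintf("sim%03d", kept)
  structure(list(expression = expr, mu = stats::setNames(mus,
                                                         colnames(expr)),
                 conditions = conditions[kept, , drop = FALSE],
                 origin = "simulated", seed = seed),
            class = "simulated_array_set")
}

#' @export
print.simulated_array_set <- function(x, ...) {
  cat(sprintf("Simulated array set: %d genes x %d conditions, mu in [%.3g, %.3g]\n",
              nrow(x$expression), ncol(x$expression), min(x$mu), max(x$mu)))
  invisible(x)
}

#' Extend an experimental ML dataset with simulated arrays
#'
#' Features are intersected (logged when columns drop); simulated arrays
#' are appended with `origin = "simulated"`.  The default placement keeps
#' them as a test-set extension.
#'
#' @param experimental an [ml_dataset()].
#' @param sim a [generate_gemf()] result.
#' @param placement `"test_extension"` (default) or `"train"`.
#' @return an [ml_dataset()] with attribute `"placement"`.
#' @export
augment_dataset <- function(experimental, sim,
                            placement = c("test_extension", "train")) {
  placement <- match.arg(placement)
  if (is.null(sim) || ncol(sim$expression) == 0) return(experimental)
  feats <- intersect(colnames(experimental$X), rownames(sim$expression))
  if (length(feats) == 0) stopf("empty feature intersection")
  if (length(feats) < ncol(experimental$X))
    message(sprintf("note: feature intersection keeps %d of %d features",
                    length(feats), ncol(experimental$X)))
  Xs <- t(sim$expression[feats, , drop = FALSE])
  out <- ml_dataset(rbind(experimental$X[, feats, drop = FALSE], Xs),
                    c(experimental$y, unname(sim$mu)),
                    view = experimental$view,
                    origin = c(experimental$origin,
                               rep("simulated", nrow(Xs))))
  attr(out, "placement") <- placement
  out
}

#' Update the ME model's expression modules toward target expression
#'
#' Per-gene bounded multipliers on the translation reaction's mRNA demand
#' (equivalently, a rescaled effective expression rate) are fitted by
#' iterated proportional updates, clamped to `bounds`, minimizing the
#' squared deviation between the model's predicted expression and the
#' targets at mu fixed to `mu_pred`.  Updates that would break feasibility
#' are reverted gene by gene and logged.  Targets equal to the current
#' predictions are a fixed point (all multipliers 1).
#'
#' @param model an `me_model`.
#' @param mu_pred growth rate at which to match expression (1/h).
#' @param expression_targets named vector in [0, 1] over model genes.
#' @param bounds multiplier bounds (default c(0.2, 5)).
#' @param max_iter proportional-update sweeps (default 4).
#' @return list of class `em_update`: `model` (updated), `multipliers`,
#'   `objective_trace`, `reverted`, `predicted`.
#' @export
update_me_model <- function(model, mu_pred, expression_targets,
                            bounds = c(0.2, 5), max_iter = 4) {
  stopifnot(all(expression_targets >= 0 & expression_targets <= 1))
  sol <- solve_at_mu(model, mu_pred)
  if (sol$status != "optimal")
    stopf("model infeasible at mu_pred = %g", mu_pred)
  pred <- predicted_expression(sol, model)
  genes <- intersect(names(expression_targets), names(pred))
  if (length(genes) == 0) stopf("no target gene matches the model")
  # only genes with a translation reaction can be retuned
  tunable <- genes[paste0("TL_", genes) %in% names(model$reactions)]
  mult <- stats::setNames(rep(1, length(tunable)), tunable)
  objective <- function(p) sum((p[genes] - expression_targets[genes])^2)
  obj_trace <- objective(pred)
  reverted <- character(0)
  eps <- 1e-6
  scale_gene <- function(mm, g, factor) {
    rid <- paste0("TL_", g)
    r <- mm$reactions[[rid]]
    for (j in seq_along(r$stoich)) {
      if (grepl("^mrna_", r$stoich[[j]]$met)) {
        r$stoich[[j]]$const <- r$stoich[[j]]$const * factor
        r$stoich[[j]]$mu <- r$stoich[[j]]$mu * factor
      }
    }
    mm$reactions[[rid]] <- r
    mm
  }
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (g in tunable) {
      ratio <- (expression_targets[[g]] + eps) / (pred[[g]] + eps)
      m_new <- min(max(mult[[g]] * ratio, bounds[1]), bounds[2])
      if (abs(m_new - mult[[g]]) < 1e-9) next
      cand <- scale_gene(model, g, m_new / mult[[g]])
      sol_c <- solve_at_mu(cand, mu_pred)
      if (sol_c$status != "optimal") {
        reverted <- union(reverted, g)
        next
      }
      model <- cand
      mult[[g]] <- m_new
      sol <- sol_c
      pred <- predicted_expression(sol, model)
      changed <- TRUE
    }
    obj_trace <- c(obj_trace, objective(pred))
    if (!changed) break
  }
  structure(list(model = model, multipliers = mult,
                 objective_trace = obj_trace, reverted = reverted,
                 predicted = pred, mu_pred = mu_pred),
            class = "em_update")
}

#' @export
print.em_update <- function(x, ...) {
  cat(sprintf("EM update at mu = %g: %d multipliers in [%.3g, %.3g], objective %.4g -> %.4g\n",
              x$mu_pred, length(x$multipliers), min(x$multipliers),
              max(x$multipliers), x$objective_trace[1],
              x$objective_trace[length(x$objective_trace)]))
  if (length(x$reverted) > 0)
    cat("  reverted (feasibility):", paste(x$reverted, collapse = ", "),
        "\n")
  invisible(x)
}

#' Score expression-prediction accuracy
#'
#' A gene counts as correctly predicted when `|pred - ref| <= tol` on the
#' normalized [0, 1] scale (rule `"band"`), or when both values fall in the
#' same tertile (rule `"tertile"`).
#'
#' @param predicted,reference named numeric vectors on [0, 1].
#' @param rule `"band"` (default) or `"tertile"`.
#' @param tol band half-width (default 0.2).
#' @return list of class `accuracy_report`: `n_correct`, `n_total`,
#'   `accuracy` (fraction), `percent`, per-gene `errors`, `rule`.
#' @export
score_expression_accuracy <- function(predicted, reference,
                                      rule = c("band", "tertile"),
                                      tol = 0.2) {
  rule <- match.arg(rule)
  genes <- intersect(names(predicted), names(reference))
  if (length(genes) == 0) stopf("empty gene intersection")
  p <- predicted[genes]; r <- reference[genes]
  errors <- abs(p - r)
  correct <- if (rule == "band") errors <= tol else {
    tert <- function(x) cut(x, c(-Inf, 1 / 3, 2 / 3, Inf), labels = FALSE)
    tert(p) == tert(r)
  }
  n_correct <- sum(correct)
  structure(list(n_correct = n_correct, n_total = length(genes),
                 accuracy = n_correct / length(genes),
                 percent = 100 * n_correct / length(genes),
                 errors = errors, correct = correct, rule = rule,
                 tol = tol),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Expression accuracy (%s rule): %d / %d correct = %.1f%%\n",
              x$rule, x$n_correct, x$n_total, x$percent))
  invisible(x)
}
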