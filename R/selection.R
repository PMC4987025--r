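#' Stepwise selection of shared-environment variance components
#'
#' Starting from a model containing only the additive-genetic component,
#' each candidate shared-environment component is added in turn; the best
#' addition is kept if it improves the criterion, and the procedure then
#' tries to add one more component, stopping when no addition improves
#' the fit. Every fitted model is retained in the trace. Under the
#' `"LRT"` criterion (REML backend) an addition improves the fit when the
#' one-degree-of-freedom likelihood-ratio test is significant at `alpha`;
#' under `"DIC"` (Gibbs backend) when DIC decreases by more than
#' `dic_tol` (default 3: by DIC conventions, smaller differences are
#' not decisive and are within Monte-Carlo noise). Candidate chains
#' within one selection run share their starting RNG state so that DIC
#' differences are not dominated by sampler noise. Ties within
#' tolerance favour the model with fewer components.
#'
#' @param spec a [mixed_model_spec()] whose `random_components` name the
#'   base model (normally just `"additive"`).
#' @param phenotypes phenotype data.frame.
#' @param structures named list of `relationship_structure`s covering the
#'   base and all candidates.
#' @param candidates character vector of structure names to consider.
#' @param criterion `"LRT"` or `"DIC"`.
#' @param alpha LRT significance level for keeping a component.
#' @param dic_tol minimum DIC decrease counted as an improvement.
#' @param boundary use the boundary-corrected LRT p-value.
#' @return list with `best_spec`, `best_fit`, `selected` (component
#'   names), and `trace` (data.frame of every model fitted, its
#'   criterion value and decision).
#' @export
stepwise_model_selection <- function(spec, phenotypes, structures,
                                     candidates = c("spouse", "sib",
                                                    "household"),
                                     criterion = c("LRT", "DIC"),
                                     alpha = 0.05, dic_tol = 3,
                                     boundary = FALSE) {
  criterion <- match.arg(criterion)
  candidates <- intersect(candidates, names(structures))
  # common random numbers across the candidate chains: every model in
  # one selection run starts its sampler from the same RNG state, so
  # DIC differences reflect the models rather than Monte-Carlo noise
  chain_seed <- sample.int(.Machine$integer.max - 1L, 1)
  prep_cache <- new.env(parent = emptyenv())
  fit_one <- function(comps) {
    sp <- spec
    sp$random_components <- comps
    if (criterion == "LRT") return(fit_reml(sp, phenotypes, structures))
    set.seed(chain_seed)
    fit_gibbs_ordinal(sp, phenotypes, structures, cache = prep_cache)
  }
  crit_of <- function(fit)
    if (criterion == "LRT") fit$log_likelihood else fit$dic

  current <- spec$random_components
  cur_fit <- fit_one(current)
  trace <- data.frame(step = 0L,
                      model = paste(current, collapse = "+"),
                      n_components = length(current),
                      criterion = criterion,
                      value = crit_of(cur_fit),
                      p_value = NA_real_, selected = TRUE)
  remaining <- candidates
  step <- 0L
  repeat {
    step <- step + 1L
    best_cand <- NULL; best_fit <- NULL; best_val <- NULL; best_p <- NA
    for (cand in remaining) {
      fit <- tryCatch(fit_one(c(current, cand)), error = function(e) {
        warning("candidate '", cand, "' skipped: ", conditionMessage(e))
        NULL
      })
      if (is.null(fit)) next
      val <- crit_of(fit)
      p <- NA_real_
      improves <- if (criterion == "LRT") {
        lrt <- tryCatch(
          likelihood_ratio_test(fit, cur_fit, df = 1, boundary = boundary),
          error = function(e) NULL)
        p <- if (is.null(lrt)) NA_real_ else lrt$p_value
        !is.null(lrt) && lrt$p_value < alpha
      } else {
        val < crit_of(cur_fit) - dic_tol
      }
      trace <- rbind(trace, data.frame(
        step = step, model = paste(c(current, cand), collapse = "+"),
        n_components = length(current) + 1L, criterion = criterion,
        value = val, p_value = p, selected = FALSE))
      if (improves) {
        better <- if (is.null(best_val)) TRUE
                  else if (criterion == "LRT") val > best_val + 1e-8
                  else val < best_val - 1e-8
        if (better) {
          best_cand <- cand; best_fit <- fit; best_val <- val; best_p <- p
        }
      }
    }
    if (is.null(best_cand)) break
    current <- c(current, best_cand)
    cur_fit <- best_fit
    trace$selected[trace$model == paste(current, collapse = "+")] <- TRUE
    remaining <- setdiff(remaining, best_cand)
    if (!length(remaining)) break
  }
  best_spec <- spec
  best_spec$random_components <- current
  list(best_spec = best_spec, best_fit = cur_fit,
       selected = current, trace = trace)
}
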