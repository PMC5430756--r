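#' End-to-end analysis pipeline
#'
#' Orchestrates the full workflow on one set of inputs: filter and
#' classify the brood table per species, then count heterogamety
#' transitions on the tree by parsimony (both coding schemes, with
#' per-direction counts over all most-parsimonious reconstructions) and by
#' maximum likelihood (ER and SYM Mk fits followed by stochastic mapping).
#' Every stage's result is written under `out_dir` as JSON/TSV, plus a
#' top-level `summary.json` that joins species calls with tree tips and
#' reports transition counts for each scheme/method; numbers in the
#' summary are copied from the stage outputs, never recomputed. Given the
#' same config and seed the JSON outputs are byte-identical.
#'
#' @param broods brood data frame or TSV path (see [read_broods()]).
#' @param tree `phylo` or Newick path; outgroups are pruned.
#' @param states an [character_states()] vector or TSV path; the coding
#'   schemes in `schemes` are applied to it.
#' @param out_dir output directory (created).
#' @param alpha,male_leak_rate classifier settings.
#' @param schemes coding schemes to run.
#' @param models Mk parameterizations to fit.
#' @param n_maps stochastic maps per fitted model.
#' @param seed integer seed for the stochastic-mapping stage.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(broods, tree, states, out_dir,
                         alpha = 0.05, male_leak_rate = 0,
                         schemes = c("two_state", "three_state"),
                         models = c("ER", "SYM"),
                         n_maps = 1000, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  broods <- stage("broods", {
    if (is.character(broods)) broods <- read_broods(broods)
    validate_broods(broods)
  })
  tree <- stage("tree", {
    if (is.character(tree)) tree <- parse_newick(path = tree)
    prune_outgroups(validate_tree(tree))
  })
  raw_states <- states

  calls <- stage("call_heterogamety",
                 call_heterogamety(broods, alpha = alpha,
                                   male_leak_rate = male_leak_rate))
  utils::write.table(calls$summary, file.path(out_dir, "species_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(calls$summary,
                       file.path(out_dir, "species_calls.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  transitions <- list()
  for (scheme in schemes) {
    st <- stage(paste0("states_", scheme), {
      if (is.character(raw_states) && !inherits(raw_states, "sd_states") &&
          length(raw_states) == 1L) read_states(raw_states, scheme)
      else character_states(stats::setNames(unclass(raw_states),
                                            names(raw_states)), scheme)
    })
    mp <- stage(paste0("parsimony_", scheme),
                parsimony_direction_counts(tree, st))
    entry <- list(parsimony = list(
      minimum = mp$total,
      n_mp_labelings = mp$n_labelings,
      direction_range = mp$range,
      profiles = mp$profiles))
    for (mod in models) {
      fit <- stage(paste0("fit_", mod, "_", scheme),
                   fit_mk(tree, st, parameterization = mod))
      sm <- stage(paste0("simmap_", mod, "_", scheme),
                  stochastic_maps(tree, st, fit, n_maps = n_maps,
                                  seed = seed))
      marg <- ancestral_marginals(tree, st, fit)
      entry[[mod]] <- list(
        rates_per_my = fit$rates, loglik = fit$loglik,
        expected_transitions = sm$total,
        by_direction = as.data.frame(as.table(sm$by_direction),
                                     stringsAsFactors = FALSE),
        node_marginals = as.data.frame(marg))
    }
    transitions[[scheme]] <- entry
  }
  jsonlite::write_json(transitions, file.path(out_dir, "transitions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  in_tree <- calls$summary$species %in% tree$tip.label
  summary <- list(
    config = list(alpha = alpha, male_leak_rate = male_leak_rate,
                  schemes = schemes, models = models, n_maps = n_maps,
                  seed = seed),
    n_broods_in = nrow(broods),
    n_broods_kept = nrow(calls$filter$kept),
    n_discarded_wolbachia =
      sum(calls$filter$discarded$reason == "wolbachia"),
    n_discarded_balanced =
      sum(calls$filter$discarded$reason == "balanced_sex_ratio"),
    species_calls = calls$summary[, c("species", "system", "ww_viability")],
    species_on_tree = calls$summary$species[in_tree],
    transitions = lapply(transitions, function(e) list(
      parsimony_minimum = e$parsimony$minimum,
      ml_expected = lapply(e[setdiff(names(e), "parsimony")],
                           function(m) m$expected_transitions))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
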