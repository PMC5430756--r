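#' Configuration for a simulated sex-reversal crossing experiment
#'
#' Mirrors the structure of the real experiments: a number of young
#' females injected with androgenic glands per species, of which some die
#' and some were in fact undifferentiated males (failed reversal, so the
#' cross is genetic male x female and yields a balanced sex ratio);
#' surviving neomales are crossed with sisters, mothers may carry
#' feminizing Wolbachia, and brood sizes follow a negative-binomial count
#' distribution. Defaults reflect the study-scale contamination: 25/135
#' failed reversals, 60/135 deaths, 5/43 Wolbachia-infected mothers, ~90%
#' Wolbachia transmission, and a mean brood of 40.
#'
#' @param true_system `"XY"` or `"ZW"`.
#' @param ww_viable logical; under ZW the neomale-cross male proportion is
#'   1/4 when WW is viable, 1/3 when not.
#' @param n_females_injected number of injected individuals.
#' @param reversal_failure_rate probability an injected individual was an
#'   undifferentiated male.
#' @param death_rate probability an injected individual dies.
#' @param wolbachia_prevalence probability a mother is infected.
#' @param wolbachia_transmission transmission rate (brood female
#'   proportion when the mother is infected).
#' @param broods_per_neomale broods obtained per surviving neomale.
#' @param brood_mean,brood_dispersion negative-binomial brood-size mean
#'   and dispersion (size) parameters.
#' @param male_leak_rate male proportion in XY neomale broods (0 = strict
#'   all-female prediction).
#' @return list of class `"sd_expconfig"`.
#' @export
experiment_config <- function(true_system = c("ZW", "XY"), ww_viable = TRUE,
                              n_females_injected = 9,
                              reversal_failure_rate = 25 / 135,
                              death_rate = 60 / 135,
                              wolbachia_prevalence = 5 / 43,
                              wolbachia_transmission = 0.9,
                              broods_per_neomale = 2,
                              brood_mean = 40, brood_dispersion = 8,
                              male_leak_rate = 0) {
  true_system <- match.arg(true_system)
  stopifnot(reversal_failure_rate >= 0, reversal_failure_rate <= 1,
            death_rate >= 0, death_rate <= 1,
            wolbachia_prevalence >= 0, wolbachia_prevalence <= 1,
            wolbachia_transmission >= 0, wolbachia_transmission <= 1,
            male_leak_rate >= 0, male_leak_rate <= 1,
            n_females_injected >= 0, broods_per_neomale >= 0,
            brood_mean > 0, brood_dispersion > 0)
  structure(as.list(environment()), class = "sd_expconfig")
}

#' Simulate a sex-reversal crossing experiment
#'
#' Draws brood sex counts binomially with the male proportion implied by
#' the true system, sire type and maternal infection: 0.5 for failed
#' reversals (genetic-male sires), 1/4 or 1/3 for ZW neomales (by WW
#' viability), `male_leak_rate` (default 0) for XY neomales, and
#' `1 - transmission` for Wolbachia-infected mothers regardless of sire.
#' Deaths and failed reversals thin the neomale pool first. The emitted
#' table has the brood-table layout consumed by [filter_broods()], with
#' `mother_wolbachia` reflecting a PCR screen of each mother; the
#' accompanying truth table records the actual sire type and expected male
#' proportion per brood for recovery tests.
#'
#' @param config an [experiment_config()].
#' @param species species name stamped on the broods.
#' @param seed integer seed; output is reproducible given
#'   `(config, species, seed)`.
#' @return list with `broods` (data frame: species, brood_id, n_male,
#'   n_female, mother_wolbachia) and `truth` (data frame: brood_id,
#'   sire_type, mother_infected, expected_male_prop). Zero surviving
#'   neomales yield empty tables with a warning.
#' @export
simulate_experiment <- function(config, species = "sim_species", seed = 1) {
  stopifnot(inherits(config, "sd_expconfig"))
  local_seed(seed, {
    n <- config$n_females_injected
    died <- stats::runif(n) < config$death_rate
    failed <- stats::runif(n) < config$reversal_failure_rate
    sires <- ifelse(failed, "genetic_male", "neomale")[!died]
    if (length(sires) == 0L) {
      warning("zero surviving sires; empty brood table", call. = FALSE)
      return(list(broods = empty_broods(), truth = empty_truth()))
    }
    rows <- list(); tr <- list(); bid <- 0L
    for (s in sires) {
      for (b in seq_len(config$broods_per_neomale)) {
        bid <- bid + 1L
        infected <- stats::runif(1) < config$wolbachia_prevalence
        p_male <-
          if (infected) 1 - config$wolbachia_transmission
          else if (s == "genetic_male") 0.5
          else if (config$true_system == "XY") config$male_leak_rate
          else if (config$ww_viable) 0.25 else 1 / 3
        size <- max(1L, stats::rnbinom(1, size = config$brood_dispersion,
                                       mu = config$brood_mean))
        m <- stats::rbinom(1, size, p_male)
        rows[[bid]] <- data.frame(
          species = species, brood_id = paste0(species, "_b", bid),
          n_male = m, n_female = size - m,
          mother_wolbachia = if (infected) "positive" else "negative")
        tr[[bid]] <- data.frame(
          brood_id = paste0(species, "_b", bid), sire_type = s,
          mother_infected = infected, expected_male_prop = p_male)
      }
    }
    list(broods = do.call(rbind, rows), truth = do.call(rbind, tr))
  })
}

empty_broods <- function()
  data.frame(species = character(0), brood_id = character(0),
             n_male = integer(0), n_female = integer(0),
             mother_wolbachia = character(0))
empty_truth <- function()
  data.frame(brood_id = character(0), sire_type = character(0),
             mother_infected = logical(0), expected_male_prop = numeric(0))

#' Simulate an Mk character history on a tree (Gillespie)
#'
#' Draws a root state from the model's root prior, then simulates the
#' continuous-time Markov chain down every branch, recording each state
#' change. Used as the ground-truth oracle for rate-recovery and
#' transition-count tests.
#'
#' @inheritParams mk_loglik
#' @param seed integer seed.
#' @return list with `tip_states` (an [character_states()] vector over the
#'   tree's tips), `node_states` (state index per node), `events` (data
#'   frame `edge`, `time`, `from`, `to`), `n_events`, `root_state`.
#' @export
simulate_mk_history <- function(tree, model, seed = 1) {
  validate_tree(tree)
  tt <- tree_traversal(tree)
  n_node <- tt$n_tip + tree$Nnode
  k <- length(model$levels)
  local_seed(seed, {
    st <- integer(n_node)
    st[tt$root] <- sample.int(k, 1, prob = model$root_prior)
    ev <- list()
    for (v in rev(tt$postorder)) {      # preorder
      ch <- tt$children[[v]]
      if (is.null(ch)) next
      for (c in ch) {
        h <- forward_path(st[v], tt$edge_len[c], model$Q)
        st[c] <- h$end
        if (length(h$time))
          ev[[length(ev) + 1]] <- data.frame(
            edge = c, time = h$time,
            from = model$levels[h$from], to = model$levels[h$to])
      }
    }
    events <- if (length(ev)) do.call(rbind, ev)
              else data.frame(edge = integer(0), time = numeric(0),
                              from = character(0), to = character(0))
    tips <- stats::setNames(model$levels[st[seq_len(tt$n_tip)]],
                            tree$tip.label)
    scheme <- if (k == 2) "two_state" else "three_state"
    list(tip_states = character_states(tips, scheme),
         node_states = st, events = events, n_events = nrow(events),
         root_state = st[tt$root])
  })
}
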