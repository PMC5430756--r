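#' Minimum number of heterogamety transitions by Sankoff parsimony
#'
#' Dynamic-programming (Sankoff) parsimony with unit cost between distinct
#' observable states. `UNKNOWN` tips carry zero cost for every state, so
#' missing data can never increase the minimum. Branch lengths are
#' ignored. On the packaged isopod phylogeny (outgroups pruned) with the
#' published heterogametic types this minimum is 3 under the two-state
#' coding and 4 under the three-state coding in which the Armadillidium
#' assimile system counts as its own state.
#'
#' @param tree a rooted `phylo`.
#' @param states an [character_states()] vector.
#' @return list of class `"sd_parsimony"`: `total` (minimum number of
#'   changes), `levels`, and the per-node Sankoff cost matrix `cost`.
#' @export
parsimony_min_transitions <- function(tree, states) {
  sk <- sankoff_costs(tree, states)
  structure(list(total = min(sk$cost[sk$tt$root, ]),
                 levels = sk$levels, cost = sk$cost),
            class = "sd_parsimony")
}

sankoff_costs <- function(tree, states) {
  validate_tree(tree)
  states <- align_states(tree, states)
  levels <- attr(states, "levels")
  if (all(unclass(states) == "UNKNOWN"))
    stop("uninformative character: all tips UNKNOWN", call. = FALSE)
  tt <- tree_traversal(tree)
  k <- length(levels)
  n_node <- tt$n_tip + tree$Nnode
  cost <- matrix(0, n_node, k, dimnames = list(NULL, levels))
  for (i in seq_len(tt$n_tip)) {
    s <- states[[tree$tip.label[i]]]
    if (s != "UNKNOWN") cost[i, ] <- ifelse(levels == s, 0, Inf)
  }
  for (v in tt$postorder) {
    ch <- tt$children[[v]]
    if (is.null(ch)) next
    for (s in seq_len(k)) {
      tot <- 0
      for (c in ch) tot <- tot + min(cost[c, ] + (seq_len(k) != s))
      cost[v, s] <- tot
    }
  }
  list(cost = cost, levels = levels, tt = tt, states = states)
}

#' Per-direction transition counts over all most-parsimonious labelings
#'
#' Enumerates every internal-node labeling that achieves the Sankoff
#' minimum and tallies transitions by direction (from, to) for each. The
#' counts are reported per distinct direction profile together with the
#' per-direction range across reconstructions; on the isopod fixture one
#' most-parsimonious reconstruction has exactly 1 XY->ZW and 2 ZW->XY
#' changes. Unknown-state tips never change state in a most-parsimonious
#' labeling and contribute no transitions.
#'
#' @inheritParams parsimony_min_transitions
#' @param max_labelings enumeration cap; if the number of most-parsimonious
#'   labelings exceeds it, a single (arbitrary) labeling is returned with
#'   `capped = TRUE`.
#' @return list of class `"sd_mpr"`: `total`, `profiles` (data frame of
#'   distinct direction-count profiles with a column per ordered state
#'   pair and `n_labelings`), `range` (min/max per direction),
#'   `n_labelings`, `capped`.
#' @export
parsimony_direction_counts <- function(tree, states, max_labelings = 1e6) {
  sk <- sankoff_costs(tree, states)
  tt <- sk$tt; k <- length(sk$levels); cost <- sk$cost
  total <- min(cost[tt$root, ])

  # count MP labelings bottom-up to decide whether enumeration is feasible
  nlab <- matrix(0, nrow(cost), k)
  for (v in tt$postorder) {
    ch <- tt$children[[v]]
    if (is.null(ch)) { nlab[v, is.finite(cost[v, ])] <- 1; next }
    for (s in seq_len(k)) {
      prod <- 1
      for (c in ch) {
        sub <- cost[c, ] + (seq_len(k) != s)
        prod <- prod * sum(nlab[c, sub == min(sub)])
      }
      nlab[v, s] <- prod
    }
  }
  root_opt <- which(cost[tt$root, ] == total)
  n_total <- sum(nlab[tt$root, root_opt])
  capped <- n_total > max_labelings

  pair_names <- outer(sk$levels, sk$levels,
                      function(a, b) paste0(a, "->", b))
  off <- which(diag(k) == 0)

  # enumerate (or pick one) labeling; accumulate direction profiles
  profiles <- new.env(parent = emptyenv())
  add_profile <- function(counts) {
    key <- paste(counts, collapse = ",")
    profiles[[key]] <- (if (is.null(profiles[[key]])) 0 else profiles[[key]]) + 1
  }
  # recursive expansion: given node v fixed to state s, return list of
  # direction-count matrices (k x k) achievable below v at minimum cost
  expand <- function(v, s, pick_one) {
    ch <- tt$children[[v]]
    if (is.null(ch)) return(list(matrix(0, k, k)))
    res <- list(matrix(0, k, k))
    for (c in ch) {
      sub <- cost[c, ] + (seq_len(k) != s)
      opts <- which(sub == min(sub))
      if (pick_one) opts <- opts[1]
      branch <- list()
      for (t in opts) {
        below <- expand(c, t, pick_one)
        for (m in below) {
          if (t != s) m[s, t] <- m[s, t] + 1
          branch <- c(branch, list(m))
        }
      }
      new <- list()
      for (a in res) for (b in branch) new <- c(new, list(a + b))
      res <- new
    }
    res
  }
  roots <- if (capped) root_opt[1] else root_opt
  for (s in roots)
    for (m in expand(tt$root, s, capped)) add_profile(m[off])

  keys <- ls(profiles)
  prof <- do.call(rbind, lapply(keys, function(key)
    as.numeric(strsplit(key, ",")[[1]])))
  prof <- as.data.frame(prof)
  names(prof) <- pair_names[off]
  prof$n_labelings <- vapply(keys, function(key) profiles[[key]], numeric(1))
  rng <- data.frame(direction = pair_names[off],
                    min = vapply(prof[pair_names[off]], min, numeric(1)),
                    max = vapply(prof[pair_names[off]], max, numeric(1)))
  rownames(rng) <- NULL
  structure(list(total = total, profiles = prof, range = rng,
                 n_labelings = n_total, capped = capped,
                 levels = sk$levels),
            class = "sd_mpr")
}

#' @export
print.sd_mpr <- function(x, ...) {
  cat("Most-parsimonious reconstructions: minimum", x$total, "changes,",
      x$n_labelings, "labeling(s)", if (x$capped) "(capped)" else "", "\n")
  print(x$profiles, row.names = FALSE)
  invisible(x)
}
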