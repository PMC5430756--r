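# Independent brute-force oracles, kept free of the implementation paths
# they check.

# enumerate the 2x2 gamete table of a cross and tally genotype frequencies
brute_cross_freqs <- function(alleles1, alleles2, ww_viable = TRUE,
                              yy_viable = TRUE) {
  tab <- list()
  for (a in alleles1) for (b in alleles2) {
    lab <- paste(sort(c(a, b)), collapse = "")
    lab <- c(WZ = "ZW")[lab] %||% lab
    tab[[lab]] <- (tab[[lab]] %||% 0) + 0.25
  }
  f <- unlist(tab)
  if (!ww_viable) f <- f[names(f) != "WW"]
  if (!yy_viable) f <- f[names(f) != "YY"]
  f / sum(f)
}
`%||%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

# exhaustive minimum-change count over all internal labelings
brute_parsimony <- function(tree, states, levels) {
  tt <- isopodSD:::tree_traversal(tree)
  n_tip <- tt$n_tip
  n_int <- tree$Nnode
  k <- length(levels)
  tips <- unclass(states)[tree$tip.label]
  parents <- integer(n_tip + n_int)
  for (p in seq_along(tt$children))
    if (!is.null(tt$children[[p]])) parents[tt$children[[p]]] <- p
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    cost <- 0
    # internal-internal edges
    for (v in seq_len(n_int - 1L) + n_tip + 1L)
      cost <- cost + (lab[v - n_tip] != lab[parents[v] - n_tip])
    # tip edges: unknown tips are free (can always match the parent)
    for (i in seq_len(n_tip)) {
      s <- tips[[i]]
      if (s == "UNKNOWN") next
      cost <- cost + (which(levels == s) != lab[parents[i] - n_tip])
    }
    best <- min(best, cost)
  }
  best
}

# exhaustive Mk likelihood: sum over all internal labelings of
# prior(root) * prod over edges of P[parent_state, child_state](t)
brute_mk_lik <- function(tree, states, model) {
  tt <- isopodSD:::tree_traversal(tree)
  n_tip <- tt$n_tip
  n_int <- tree$Nnode
  k <- length(model$levels)
  tips <- unclass(states)[tree$tip.label]
  parents <- integer(n_tip + n_int)
  for (p in seq_along(tt$children))
    if (!is.null(tt$children[[p]])) parents[tt$children[[p]]] <- p
  # tip partial indicator (columns of allowed states per tip)
  tip_states <- lapply(seq_len(n_tip), function(i) {
    s <- tips[[i]]
    if (s == "UNKNOWN") seq_len(k) else which(model$levels == s)
  })
  Pm <- lapply(seq_len(n_tip + n_int), function(v)
    if (v == tt$root) NULL
    else isopodSD:::mk_pmat(model$Q, tt$edge_len[v]))
  total <- 0
  int_grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  tip_grid <- as.matrix(expand.grid(tip_states))
  for (r in seq_len(nrow(int_grid))) {
    lab <- int_grid[r, ]
    base <- model$root_prior[lab[1]]   # root is node n_tip + 1
    for (v in seq_len(n_int - 1L) + n_tip + 1L)
      base <- base * Pm[[v]][lab[parents[v] - n_tip], lab[v - n_tip]]
    for (s in seq_len(nrow(tip_grid))) {
      term <- base
      for (i in seq_len(n_tip))
        term <- term * Pm[[i]][lab[parents[i] - n_tip], tip_grid[s, i]]
      total <- total + term
    }
  }
  total
}

# random rooted binary tree with exponential branch lengths
random_tree <- function(n_tip, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tip)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / 20) + 0.5
  tr
}

random_states <- function(tree, levels, p_unknown = 0.25, seed = 1) {
  set.seed(seed)
  s <- sample(c(levels, "UNKNOWN"), length(tree$tip.label), replace = TRUE,
              prob = c(rep((1 - p_unknown) / length(levels), length(levels)),
                       p_unknown))
  character_states(stats::setNames(s, tree$tip.label),
                   if (length(levels) == 2) "two_state" else "three_state")
}

# exhaustive likelihood with one internal node clamped to a given state
brute_mk_lik_clamped <- function(tree, states, model, node, state) {
  tt <- isopodSD:::tree_traversal(tree)
  n_tip <- tt$n_tip
  n_int <- tree$Nnode
  k <- length(model$levels)
  tips <- unclass(states)[tree$tip.label]
  parents <- integer(n_tip + n_int)
  for (p in seq_along(tt$children))
    if (!is.null(tt$children[[p]])) parents[tt$children[[p]]] <- p
  tip_states <- lapply(seq_len(n_tip), function(i) {
    s <- tips[[i]]
    if (s == "UNKNOWN") seq_len(k) else which(model$levels == s)
  })
  Pm <- lapply(seq_len(n_tip + n_int), function(v)
    if (v == tt$root) NULL
    else isopodSD:::mk_pmat(model$Q, tt$edge_len[v]))
  int_grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  tip_grid <- as.matrix(expand.grid(tip_states))
  total <- 0
  for (r in seq_len(nrow(int_grid))) {
    lab <- int_grid[r, ]
    if (lab[node - n_tip] != state) next
    base <- model$root_prior[lab[1]]
    for (v in seq_len(n_int - 1L) + n_tip + 1L)
      base <- base * Pm[[v]][lab[parents[v] - n_tip], lab[v - n_tip]]
    for (s in seq_len(nrow(tip_grid))) {
      term <- base
      for (i in seq_len(n_tip))
        term <- term * Pm[[i]][lab[parents[i] - n_tip], tip_grid[s, i]]
      total <- total + term
    }
  }
  total
}
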