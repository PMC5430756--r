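#' Mk model of discrete heterogamety-state evolution
#'
#' A continuous-time Markov (Mk) model over the observable states of a
#' coding scheme. `ER` shares one rate across all transitions; `SYM`
#' gives each unordered state pair its own rate (identical to ER when
#' k = 2). Rates are per million years, matching the chronogram branch
#' lengths. The root prior defaults to equal probabilities, the stationary
#' distribution of any ER/SYM chain and the convention used for unknown
#' sex-determination systems.
#'
#' @param levels character vector of observable states (2 or 3).
#' @param parameterization `"ER"` or `"SYM"`.
#' @param rates positive rate parameters: length 1 for ER,
#'   `k*(k-1)/2` for SYM (pair order: (1,2), (1,3), (2,3)).
#' @param root_prior probability vector over `levels` (default uniform).
#' @return list of class `"sd_mk"` with `levels`, `parameterization`,
#'   `rates`, `root_prior` and the `k x k` rate matrix `Q` (rows sum to 0).
#' @export
mk_model <- function(levels, parameterization = c("ER", "SYM"), rates,
                     root_prior = NULL) {
  parameterization <- match.arg(parameterization)
  k <- length(levels)
  stopifnot(k >= 2)
  n_par <- if (parameterization == "ER") 1L else (k * (k - 1L)) %/% 2L
  if (length(rates) != n_par || any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be ", n_par, " finite positive value(s)", call. = FALSE)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  stopifnot(length(root_prior) == k, abs(sum(root_prior) - 1) < 1e-9)
  Q <- matrix(0, k, k, dimnames = list(levels, levels))
  if (parameterization == "ER") {
    Q[] <- rates
  } else {
    idx <- which(upper.tri(Q))
    Q[idx] <- rates
    Q <- Q + t(Q)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(levels = levels, parameterization = parameterization,
                 rates = rates, root_prior = root_prior, Q = Q),
            class = "sd_mk")
}

#' @export
print.sd_mk <- function(x, ...) {
  cat("Mk model (", x$parameterization, ", ", length(x$levels),
      " states): rates ", paste(signif(x$rates, 4), collapse = ", "),
      " per My\n", sep = "")
  invisible(x)
}

# transition probability matrix exp(Q t) by eigendecomposition; ER/SYM
# rate matrices are symmetric, so the decomposition is real and stable
mk_pmat <- function(Q, t, eig = NULL) {
  if (t == 0) return(diag(nrow(Q)))
  if (is.null(eig)) eig <- eigen(Q, symmetric = TRUE)
  P <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
  # clip tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

# tip partial-likelihood matrix (n_tip x k); UNKNOWN rows are all ones
tip_partials <- function(tree, states, levels) {
  states <- align_states(tree, states)
  L <- matrix(1, length(tree$tip.label), length(levels),
              dimnames = list(tree$tip.label, levels))
  for (i in seq_along(tree$tip.label)) {
    s <- states[[tree$tip.label[i]]]
    if (s != "UNKNOWN") {
      if (!s %in% levels)
        stop("tip state ", s, " not among model levels", call. = FALSE)
      L[i, ] <- as.numeric(levels == s)
    }
  }
  L
}

# Felsenstein pruning: per-node partials with log-scaling.
# Returns list(partials = n_node x k matrix, logscale = per-node summed
# log scaling, loglik, tt, eig)
mk_prune <- function(tree, states, model) {
  validate_tree(tree)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be present and non-negative for likelihood ",
         "computation", call. = FALSE)
  tt <- tree_traversal(tree)
  k <- length(model$levels)
  n_node <- tt$n_tip + tree$Nnode
  eig <- eigen(model$Q, symmetric = TRUE)
  L <- matrix(1, n_node, k)
  L[seq_len(tt$n_tip), ] <- tip_partials(tree, states, model$levels)
  logscale <- numeric(n_node)
  for (v in tt$postorder) {
    ch <- tt$children[[v]]
    if (is.null(ch)) next
    part <- rep(1, k)
    sc <- 0
    for (c in ch) {
      P <- mk_pmat(model$Q, tt$edge_len[c], eig)
      part <- part * as.numeric(P %*% L[c, ])
      sc <- sc + logscale[c]
    }
    m <- max(part)
    if (m <= 0) { L[v, ] <- 0; logscale[v] <- -Inf; next }
    L[v, ] <- part / m
    logscale[v] <- sc + log(m)
  }
  lik <- sum(model$root_prior * L[tt$root, ])
  list(partials = L, logscale = logscale,
       loglik = if (lik <= 0) -Inf else log(lik) + logscale[tt$root],
       tt = tt, eig = eig)
}

#' Mk log-likelihood of tip states on a dated tree
#'
#' Felsenstein pruning over the Mk rate matrix, with transition
#' probabilities from the matrix exponential (eigendecomposition of the
#' symmetric rate matrix) and the root weighted by the model's root prior.
#' Tips with `UNKNOWN` state contribute all-ones partial likelihoods,
#' i.e. equal probability across systems.
#'
#' @inheritParams parsimony_min_transitions
#' @param model an [mk_model()].
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, states, model) {
  mk_prune(tree, states, model)$loglik
}

#' Maximum-likelihood fit of an Mk model
#'
#' Maximizes [mk_loglik()] over positive rates, log-parameterized with a
#' bounded deterministic search (golden-section for the single ER rate,
#' L-BFGS-B from the ER solution for SYM). With two states SYM is
#' identical to ER.
#'
#' @inheritParams mk_loglik
#' @param parameterization `"ER"` or `"SYM"`.
#' @param root_prior passed to [mk_model()]; default uniform.
#' @param log_bounds search interval for log(rate per My).
#' @return the fitted [mk_model()] with extra fields `loglik`,
#'   `convergence` (`TRUE`/`FALSE`) and `flags` (e.g.
#'   `monotone_likelihood` when the optimum sits on the lower bound, as
#'   happens when all observed tips share one state).
#' @export
fit_mk <- function(tree, states, parameterization = c("ER", "SYM"),
                   root_prior = NULL, log_bounds = c(-12, 4)) {
  parameterization <- match.arg(parameterization)
  states <- align_states(tree, states)
  levels <- attr(states, "levels")
  k <- length(levels)
  obj_er <- function(lq)
    -mk_loglik(tree, states, mk_model(levels, "ER", exp(lq), root_prior))
  opt <- stats::optimize(obj_er, interval = log_bounds, tol = 1e-8)
  rates <- exp(opt$minimum)
  loglik <- -opt$objective
  conv <- TRUE
  if (parameterization == "SYM" && k > 2) {
    obj <- function(lq)
      -mk_loglik(tree, states, mk_model(levels, "SYM", exp(lq), root_prior))
    o <- stats::optim(rep(opt$minimum, k * (k - 1) / 2), obj,
                      method = "L-BFGS-B",
                      lower = log_bounds[1], upper = log_bounds[2],
                      control = list(maxit = 500))
    rates <- exp(o$par)
    loglik <- -o$value
    conv <- o$convergence == 0
    if (!conv)
      warning("SYM optimization did not fully converge; returning ",
              "best-so-far rates", call. = FALSE)
  } else if (parameterization == "SYM") {
    rates <- rep(rates, 1)  # k = 2: SYM has a single pair rate == ER
  }
  flags <- character(0)
  if (any(abs(log(rates) - log_bounds[1]) < 0.05))
    flags <- c(flags, "monotone_likelihood")
  m <- mk_model(levels, parameterization, rates, root_prior)
  m$loglik <- loglik
  m$convergence <- conv
  m$flags <- flags
  m
}

#' Marginal ancestral state probabilities under an Mk model
#'
#' Standard two-pass (down then up) computation of the marginal posterior
#' probability of each state at every internal node, conditional on the
#' tip data and the model -- the quantities drawn as pie charts on
#' ancestral-state figures. Each row sums to 1.
#'
#' @inheritParams mk_loglik
#' @return matrix (internal nodes x states); row names are the phylo node
#'   numbers.
#' @export
ancestral_marginals <- function(tree, states, model) {
  pr <- mk_prune(tree, states, model)
  tt <- pr$tt
  k <- length(model$levels)
  n_node <- tt$n_tip + tree$Nnode
  # outside (up-pass) partials, renormalized per node
  U <- matrix(NA_real_, n_node, k)
  U[tt$root, ] <- model$root_prior
  for (v in rev(tt$postorder)) {       # preorder
    ch <- tt$children[[v]]
    if (is.null(ch)) next
    msgs <- lapply(ch, function(c)
      as.numeric(mk_pmat(model$Q, tt$edge_len[c], pr$eig) %*%
                   pr$partials[c, ]))
    for (i in seq_along(ch)) {
      sib <- rep(1, k)
      for (j in seq_along(ch)) if (j != i) sib <- sib * msgs[[j]]
      P <- mk_pmat(model$Q, tt$edge_len[ch[i]], pr$eig)
      u <- as.numeric(t(P) %*% (U[v, ] * sib))
      U[ch[i], ] <- u / sum(u)
    }
  }
  nodes <- (tt$n_tip + 1L):n_node
  marg <- U[nodes, , drop = FALSE] * pr$partials[nodes, , drop = FALSE]
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list(nodes, model$levels)
  marg
}
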