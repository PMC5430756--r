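#' Stochastic character mapping of heterogamety transitions
#'
#' Samples full character histories on the tree conditional on the tip
#' data and an Mk model, and tallies state transitions by direction.
#' Internal node states are drawn jointly from their conditional
#' distribution (root from prior x partial likelihood, then each child
#' given its parent); substitution histories along each branch are then
#' drawn conditional on the branch endpoints by uniformization (an exact
#' endpoint-conditioned sampler with bounded runtime; rejection sampling
#' is available via `method = "rejection"` and falls back to
#' uniformization automatically if a branch exceeds the retry cap).
#'
#' @inheritParams mk_loglik
#' @param n_maps number of stochastic maps.
#' @param seed integer seed; the run is reproducible given
#'   `(tree, states, model, n_maps, seed)`.
#' @param method `"uniformization"` (default) or `"rejection"`.
#' @param keep_histories logical; retain the full event list of each map.
#' @return list of class `"sd_simmap"`: `total` (mean transition count
#'   over maps), `by_direction` (mean k x k count matrix), `n_maps`,
#'   `per_map_total`, and (optionally) `histories` -- per map, a data
#'   frame `edge`, `time` (from the parent end), `from`, `to`.
#' @export
stochastic_maps <- function(tree, states, model, n_maps = 1000, seed = 1,
                            method = c("uniformization", "rejection"),
                            keep_histories = FALSE) {
  method <- match.arg(method)
  stopifnot(n_maps >= 1)
  pr <- mk_prune(tree, states, model)
  if (!is.finite(pr$loglik))
    stop("tip data have zero likelihood under this model", call. = FALSE)
  tt <- pr$tt
  k <- length(model$levels)
  n_node <- tt$n_tip + tree$Nnode
  preorder <- rev(tt$postorder)
  Pm <- lapply(seq_len(n_node), function(v)
    if (v == tt$root) NULL else mk_pmat(model$Q, tt$edge_len[v], pr$eig))
  parents <- integer(n_node)
  for (p in seq_len(n_node))
    if (!is.null(tt$children[[p]])) parents[tt$children[[p]]] <- p

  dir_sum <- matrix(0, k, k, dimnames = list(model$levels, model$levels))
  per_map_total <- numeric(n_maps)
  histories <- if (keep_histories) vector("list", n_maps) else NULL

  local_seed(seed, {
    for (mi in seq_len(n_maps)) {
      # joint draw of node states
      st <- integer(n_node)
      w <- model$root_prior * pr$partials[tt$root, ]
      st[tt$root] <- sample.int(k, 1, prob = w)
      for (v in preorder) {
        ch <- tt$children[[v]]
        for (c in ch) {
          w <- Pm[[c]][st[v], ] * pr$partials[c, ]
          st[c] <- sample.int(k, 1, prob = w)
        }
      }
      # branch histories conditional on endpoints
      dmat <- matrix(0, k, k)
      ev <- if (keep_histories) list() else NULL
      for (v in seq_len(n_node)) {
        if (v == tt$root) next
        path <- sample_branch_history(st[parents[v]], st[v], tt$edge_len[v],
                                      model$Q, method)
        if (length(path$from)) {
          for (j in seq_along(path$from))
            dmat[path$from[j], path$to[j]] <- dmat[path$from[j], path$to[j]] + 1
          if (keep_histories)
            ev[[length(ev) + 1]] <- data.frame(
              edge = v, time = path$time,
              from = model$levels[path$from], to = model$levels[path$to])
        }
      }
      dir_sum <- dir_sum + dmat
      per_map_total[mi] <- sum(dmat)
      if (keep_histories)
        histories[[mi]] <- if (length(ev)) do.call(rbind, ev)
                           else data.frame(edge = integer(0), time = numeric(0),
                                           from = character(0), to = character(0))
    }
  })
  by_dir <- dir_sum / n_maps
  structure(list(total = sum(by_dir), by_direction = by_dir,
                 n_maps = n_maps, per_map_total = per_map_total,
                 histories = histories, levels = model$levels),
            class = "sd_simmap")
}

#' @export
print.sd_simmap <- function(x, ...) {
  cat("Stochastic mapping over", x$n_maps, "maps: mean",
      round(x$total, 2), "transitions\n")
  print(round(x$by_direction, 3))
  invisible(x)
}

# endpoint-conditioned history of a CTMC on one branch.
# Returns list(time, from, to) of true (non-virtual) jumps, times measured
# from the parent end of the branch.
sample_branch_history <- function(a, b, t, Q, method = "uniformization",
                                  max_tries = 100L) {
  if (method == "rejection") {
    for (i in seq_len(max_tries)) {
      h <- forward_path(a, t, Q)
      if (h$end == b)
        return(list(time = h$time, from = h$from, to = h$to))
    }
    # retry cap exceeded (likely endpoints forced through unlikely paths):
    # switch to uniformization, which is exact and bounded
    method <- "uniformization"
  }
  uniformization_path(a, b, t, Q)
}

# unconditional forward simulation (Gillespie) on one branch
forward_path <- function(a, t, Q) {
  k <- nrow(Q)
  s <- a; tau <- 0
  time <- from <- to <- numeric(0)
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) break
    tau <- tau + stats::rexp(1, rate)
    if (tau >= t) break
    nxt <- sample.int(k, 1, prob = pmax(Q[s, ], 0))
    time <- c(time, tau); from <- c(from, s); to <- c(to, nxt)
    s <- nxt
  }
  list(time = time, from = from, to = to, end = s)
}

uniformization_path <- function(a, b, t, Q, max_jumps = 10000L) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0) {
    if (a != b) stop("endpoints differ under a zero-rate model")
    return(list(time = numeric(0), from = numeric(0), to = numeric(0)))
  }
  R <- diag(k) + Q / mu
  Pt <- mk_pmat(Q, t)
  p_ab <- Pt[a, b]
  if (p_ab <= 0) stop("impossible endpoint pair on branch", call. = FALSE)
  # sample number of uniformized jumps N: P(N=n) = dpois(n, mu t) R^n[a,b]/p_ab
  u <- stats::runif(1)
  Rpow <- list(diag(k))            # R^0
  cum <- stats::dpois(0, mu * t) * Rpow[[1]][a, b] / p_ab
  n <- 0L
  while (u > cum && n < max_jumps) {
    n <- n + 1L
    Rpow[[n + 1L]] <- Rpow[[n]] %*% R
    cum <- cum + stats::dpois(n, mu * t) * Rpow[[n + 1L]][a, b] / p_ab
  }
  if (n == 0L) return(list(time = numeric(0), from = numeric(0), to = numeric(0)))
  # sample the jump chain s_0 = a, ..., s_n = b
  chain <- integer(n + 1L); chain[1] <- a; chain[n + 1L] <- b
  if (n > 1L) for (i in seq_len(n - 1L)) {
    prev <- chain[i]
    w <- R[prev, ] * Rpow[[n - i + 1L]][, b]   # R^(n-i)[j, b]
    chain[i + 1L] <- sample.int(k, 1, prob = w)
  }
  jump_times <- sort(stats::runif(n, 0, t))
  keep <- chain[-length(chain)] != chain[-1]   # drop virtual self-jumps
  list(time = jump_times[keep],
       from = chain[-length(chain)][keep],
       to = chain[-1][keep])
}
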