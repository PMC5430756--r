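test_that("two-state pruning matches the single-branch closed form", {
  # P(stay) over a branch of length t under ER rate q is 1/2 + e^{-2qt}/2
  tr <- parse_newick(text = "(A:1,B:1);")
  m <- mk_model(c("XY", "ZW"), "ER", 0.5)
  st <- character_states(c(A = "XY", B = "XY"), "two_state")
  # both tips same state, branches 1 each from the root:
  # L = sum_r pi_r P_r,XY(1)^2
  p_stay <- 0.5 + 0.5 * exp(-2 * 0.5 * 1)
  p_flip <- 1 - p_stay
  expect_equal(mk_loglik(tr, st, m),
               log(0.5 * p_stay^2 + 0.5 * p_flip^2), tolerance = 1e-10)
  expect_equal(p_stay, 0.6839397, tolerance = 1e-6)
})

test_that("pruning equals exhaustive enumeration on random 4- and 5-tip trees", {
  for (seed in 1:8) {
    n_tip <- 4 + seed %% 2
    tr <- random_tree(n_tip, seed)
    for (k in 2:3) {
      lv <- c("XY", "ZW", "OTHER")[seq_len(k)]
      st <- random_states(tr, lv, p_unknown = 0.2, seed = seed + 7 * k)
      set.seed(seed)
      rates <- if (k == 2) runif(1, 0.005, 0.05) else runif(3, 0.005, 0.05)
      m <- mk_model(lv, if (k == 2) "ER" else "SYM",
                    if (k == 2) rates else rates)
      expect_equal(mk_loglik(tr, st, m), log(brute_mk_lik(tr, st, m)),
                   tolerance = 1e-9, info = paste("seed", seed, "k", k))
    }
  }
})

test_that("likelihood is invariant to child order and to re-rooting", {
  tr <- fixture_isopod_tree()
  st <- fixture_state_table("two_state")
  m <- mk_model(c("XY", "ZW"), "ER", 0.012)
  base <- mk_loglik(tr, st, m)
  expect_equal(mk_loglik(ape::rotateConstr(tr, rev(tr$tip.label)), st, m),
               base, tolerance = 1e-9)
  # reversible model + stationary root prior: position of the root on an
  # internal edge does not change the likelihood
  rerooted <- ape::root(ape::unroot(tr), node = 30, resolve.root = TRUE)
  expect_equal(mk_loglik(rerooted, st, m), base, tolerance = 1e-6)
})

test_that("rate towards zero drives the likelihood of variable data to -Inf", {
  tr <- parse_newick(text = "((A:1,B:1):1,C:2);")
  st <- character_states(c(A = "XY", B = "ZW", C = "ZW"), "two_state")
  lls <- vapply(c(1e-2, 1e-4, 1e-6, 1e-8), function(q)
    mk_loglik(tr, st, mk_model(c("XY", "ZW"), "ER", q)), numeric(1))
  expect_true(all(diff(lls) < 0))
  expect_lt(lls[4], -15)
})

test_that("ER fit matches an independent Mk implementation on the fixture", {
  skip_if_not_installed("phytools")
  tr <- fixture_isopod_tree()
  st <- fixture_state_table("two_state")
  fit <- fit_mk(tr, st, "ER")
  x <- unclass(st)[tr$tip.label]
  known <- x != "UNKNOWN"
  m <- matrix(0.5, length(x), 2, dimnames = list(names(x), c("XY", "ZW")))
  m[known, ] <- t(vapply(x[known], function(s) as.numeric(c("XY", "ZW") == s),
                         numeric(2)))
  ref <- phytools::fitMk(tr, m, model = "ER", pi = c(0.5, 0.5))
  expect_equal(unname(fit$rates), unname(ref$rates[1]), tolerance = 1e-4)
  # phytools scales unknown tips by 1/2 each: a constant offset of
  # n_unknown * log(2)
  expect_equal(fit$loglik - sum(!known) * log(2), as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)
})

test_that("SYM reduces to ER for two states and fits per-pair rates for three", {
  tr <- fixture_isopod_tree()
  st <- fixture_state_table("two_state")
  er <- fit_mk(tr, st, "ER")
  sym <- fit_mk(tr, st, "SYM")
  expect_equal(er$loglik, sym$loglik, tolerance = 1e-6)
  expect_equal(unname(er$rates), unname(sym$rates), tolerance = 1e-4)

  st3 <- fixture_state_table("three_state")
  sym3 <- fit_mk(tr, st3, "SYM")
  expect_length(sym3$rates, 3)
  expect_gte(sym3$loglik, fit_mk(tr, st3, "ER")$loglik - 1e-6)
})

test_that("constant characters push the ER rate to the lower bound", {
  tr <- random_tree(6, 2)
  st <- character_states(stats::setNames(rep("ZW", 6), tr$tip.label),
                         "two_state")
  fit <- fit_mk(tr, st, "ER")
  expect_true("monotone_likelihood" %in% fit$flags)
})

test_that("simulated ER data recover the generating rate", {
  # median MLE over replicates on 100-tip trees within [q/2, 2q]
  q <- 0.02
  est <- vapply(1:50, function(r) {
    tr <- random_tree(100, r)
    h <- simulate_mk_history(tr, mk_model(c("XY", "ZW"), "ER", q), seed = r)
    if (length(unique(unclass(h$tip_states))) < 2) return(NA_real_)
    fit_mk(tr, h$tip_states, "ER")$rates
  }, numeric(1))
  expect_true(median(est, na.rm = TRUE) >= q / 2 &&
              median(est, na.rm = TRUE) <= 2 * q)
})

test_that("ancestral marginals are valid, symmetric and match enumeration", {
  # symmetric two-tip tree with opposite states: root is 50/50
  tr <- parse_newick(text = "(A:2,B:2);")
  st <- character_states(c(A = "XY", B = "ZW"), "two_state")
  m <- mk_model(c("XY", "ZW"), "ER", 0.1)
  marg <- ancestral_marginals(tr, st, m)
  expect_equal(unname(marg[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  # very fast evolution: every node's marginal approaches the root prior
  fast <- mk_model(c("XY", "ZW"), "ER", 100)
  tr4 <- random_tree(4, 4)
  st4 <- character_states(stats::setNames(c("XY", "ZW", "XY", "ZW"),
                                          tr4$tip.label), "two_state")
  mfast <- ancestral_marginals(tr4, st4, fast)
  expect_true(all(abs(mfast - 0.5) < 1e-6))

  # exhaustive-oracle check of each internal node's marginal: P(node = s)
  # proportional to the enumerated likelihood with that node clamped
  m4 <- mk_model(c("XY", "ZW"), "ER", 0.03)
  marg4 <- ancestral_marginals(tr4, st4, m4)
  expect_equal(unname(rowSums(marg4)), rep(1, nrow(marg4)), tolerance = 1e-9)
  tt <- isopodSD:::tree_traversal(tr4)
  full <- brute_mk_lik(tr4, st4, m4)
  for (v in (tt$n_tip + 1):(tt$n_tip + tr4$Nnode)) {
    for (s in 1:2) {
      # clamp node v to state s by zeroing the prior/transition mass of
      # the other state via direct enumeration
      clamped <- brute_mk_lik_clamped(tr4, st4, m4, v, s)
      expect_equal(marg4[as.character(v), s], clamped / full,
                   tolerance = 1e-9)
    }
  }
})
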