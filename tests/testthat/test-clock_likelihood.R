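# partitioned GTR+Gamma(+I) pruning likelihood, clock and tree priors

jc_model <- function() substitution_model(rep(1, 6), rep(0.25, 4),
                                          gamma_shape = Inf)

test_that("pruning matches closed forms on tiny trees", {
  phy <- ape::read.tree(text = "(a:1,b:1);")
  jc <- jc_model()

  # all tips share a base on a zero-length tree: log(pi_base)
  aln_same <- aln_from_strings(c(a = "A", b = "A"))
  st0 <- dating_state(phy, ages = 1e-9, branch_rates = c(1e-9, 1e-9),
                      models = jc)
  expect_equal(pruning_loglik(st0, aln_same), log(0.25), tolerance = 1e-6)

  # two tips under JC: log(pi_x P_xy(d)) with the JC transition closed form
  aln_diff <- aln_from_strings(c(a = "A", b = "G"))
  st <- dating_state(phy, ages = 2, branch_rates = c(0.05, 0.05),
                     models = jc)
  d <- 0.05 * 2 * 2
  pxy <- 0.25 - 0.25 * exp(-4 / 3 * d)
  expect_equal(pruning_loglik(st, aln_diff), log(0.25 * pxy))
})

test_that("pruning equals exhaustive state summation on a 4-tip GTR+G+I tree", {
  phy <- ape::read.tree(text = "((a,b),(c,d));")
  m <- substitution_model(rates = c(1.3, 4, 0.7, 1.1, 5, 1),
                          base_freqs = c(0.35, 0.15, 0.2, 0.3),
                          gamma_shape = 0.7, n_cat = 4, p_inv = 0.2)
  aln <- aln_from_strings(c(a = "ACT", b = "GA-", c = "GAC", d = "T?C"))
  ages <- c(1, 0.5, 0.4)
  rates <- c(0.6, 1.1, 0.3, 0.8, 0.9, 0.4)
  st <- dating_state(phy, ages, rates, m)

  # independent oracle: sum over all 4^3 internal state assignments
  allages <- c(0, 0, 0, 0, ages)
  blen <- rates * (allages[phy$edge[, 1]] - allages[phy$edge[, 2]])
  Pm_for <- function(t) {
    P <- m$evec %*% diag(exp(m$eval * t)) %*% m$ievec
    P
  }
  codes <- c(A = 1, C = 2, G = 3, T = 4)
  obs <- rbind(codes[strsplit("ACT", "")[[1]]],
               c(codes["G"], codes["A"], NA),
               codes[strsplit("GAC", "")[[1]]],
               c(codes["T"], NA, codes["C"]))
  bf_site <- function(s) {
    tot <- 0
    for (k in seq_along(m$catrate)) {
      Pm <- lapply(blen * m$catrate[k], Pm_for)
      acc <- 0
      for (x in 1:4) for (y in 1:4) for (z in 1:4) {
        stv <- c(NA, NA, NA, NA, x, y, z)
        pr <- m$base_freqs[x]
        for (e in seq_len(nrow(phy$edge))) {
          par <- stv[phy$edge[e, 1]]
          ch <- phy$edge[e, 2]
          pr <- pr * if (ch <= 4) {
            if (is.na(obs[ch, s])) 1 else Pm[[e]][par, obs[ch, s]]
          } else Pm[[e]][par, stv[ch]]
        }
        acc <- acc + pr
      }
      tot <- tot + m$catw[k] * acc
    }
    log(tot)
  }
  expect_equal(pruning_loglik(st, aln),
               sum(vapply(1:3, bf_site, 0)), tolerance = 1e-10)
})

test_that("likelihood invariances hold (site order, duplication, scaling)", {
  set.seed(5)
  phy <- sim_yule_tree(6, 0.3)
  rates <- sim_branch_rates(phy, 0.05, 0.2)
  m <- substitution_model(gamma_shape = 1)
  aln <- sim_alignment(phy, rates, list(g = list(length = 40, model = m)))
  ages <- node_ages(phy)[7:11]
  st <- dating_state(phy, ages, rates, m)
  base <- pruning_loglik(st, aln)

  perm <- aln
  perm$g <- perm$g[, sample(ncol(perm$g)), drop = FALSE]
  expect_equal(pruning_loglik(st, perm), base)

  dup <- aln
  dup$g <- dup$g[, c(1, 1:ncol(dup$g)), drop = FALSE]
  expect_equal(pruning_loglik(st, dup), base +
                 pruning_loglik(st, partitioned_alignment(
                   list(g = aln$g[, 1, drop = FALSE]))))

  # rate-time confounding: rates * c with durations / c is invariant
  st2 <- dating_state(phy, ages / 3, rates * 3, m)
  expect_equal(pruning_loglik(st2, aln), base, tolerance = 1e-9)
})

test_that("pruning agrees with an independent likelihood engine", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  phy <- sim_yule_tree(7, 0.3)
  rates <- rep(0.04, nrow(phy$edge))
  m <- substitution_model(gamma_shape = Inf)
  aln <- sim_alignment(phy, rates, list(g = list(length = 60, model = m)))
  st <- dating_state(phy, node_ages(phy)[8:13], rates, m)
  dat <- phangorn::phyDat(aln$g, type = "DNA")
  tr <- phy
  tr$edge.length <- tr$edge.length * 0.04
  fit <- phangorn::pml(tr, dat, k = 1)
  expect_equal(pruning_loglik(st, aln), fit$logLik, tolerance = 1e-6)
})

test_that("discrete gamma converges to the rate-homogeneous model", {
  phy <- ape::read.tree(text = "(a:1,(b:1,c:1):1);")
  aln <- aln_from_strings(c(a = "ACGTAA", b = "ACGTCA", c = "AGGTAA"))
  mk <- function(shape) substitution_model(rep(1, 6), rep(0.25, 4),
                                           gamma_shape = shape)
  st <- function(m) dating_state(phy, c(2, 1), rep(0.1, 4), m)
  ll_inf <- pruning_loglik(st(mk(Inf)), aln)
  expect_equal(pruning_loglik(st(mk(1e6)), aln), ll_inf, tolerance = 1e-6)
  expect_gt(abs(pruning_loglik(st(mk(0.5)), aln) - ll_inf), 1e-3)
})

test_that("Yule prior follows its closed forms and peaks near truth", {
  # 2-tip: exponential no-split term
  expect_equal(yule_log_prior(7, 0.3), -2 * 0.3 * 7)
  # density decreases in the root age (mass toward younger ages), and the
  # effect strengthens with the birth rate
  expect_gt(yule_log_prior(5, 0.3), yule_log_prior(6, 0.3))
  d1 <- yule_log_prior(5, 0.3) - yule_log_prior(6, 0.3)
  d2 <- yule_log_prior(5, 0.6) - yule_log_prior(6, 0.6)
  expect_gt(d2, d1)

  # Monte-Carlo: mean log-prior over simulated trees is maximized near the
  # generating rate
  set.seed(13)
  lam0 <- 0.25
  ages <- replicate(150, {
    phy <- sim_yule_tree(10, lam0)
    node_ages(phy)[11:19]
  }, simplify = FALSE)
  grid <- lam0 * c(0.4, 0.6, 0.8, 1, 1.25, 1.6, 2.5)
  meanlp <- vapply(grid, function(l)
    mean(vapply(ages, yule_log_prior, 0, birth_rate = l)), 0)
  expect_equal(grid[which.max(meanlp)], lam0, tolerance = 0.3)
})

test_that("lognormal rate prior has the stated parameterization", {
  # single branch matches the textbook density
  expect_equal(rates_log_prior(0.02, ucld_mean = 0.01, ucld_sd = 0.5),
               dlnorm(0.02, log(0.01) - 0.125, 0.5, log = TRUE))
  # real-space mean parameterization: sampled mean matches ucld_mean
  set.seed(3)
  r <- rlnorm(1e5, log(0.01) - 0.3^2 / 2, 0.3)
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 0.01), 3 * se)
  # strict-clock limit concentrates
  expect_gt(rates_log_prior(0.01, 0.01, 1e-4),
            rates_log_prior(0.01, 0.01, 0.5))
})
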