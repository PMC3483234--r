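# simulators: Yule trees, branch rates, sequences, fossil preservation

test_that("Yule simulator matches its conditioning closed form", {
  # n = 2: root age is Exp(2 lambda), mean 1/(2 lambda)
  set.seed(61)
  lam <- 0.4
  roots <- replicate(4000, max(node_ages(sim_yule_tree(2, lam))))
  se <- sd(roots) / sqrt(length(roots))
  expect_lt(abs(mean(roots) - 1 / (2 * lam)), 4 * se)

  # determinism under a seed
  t1 <- sim_yule_tree(9, 0.2, seed = 123)
  t2 <- sim_yule_tree(9, 0.2, seed = 123)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  # trees are valid, ultrametric, with the requested tip count
  for (n in c(2, 5, 12)) {
    phy <- sim_yule_tree(n, 0.3, seed = n)
    expect_equal(ape::Ntip(phy), n)
    expect_true(ape::is.ultrametric(phy, tol = 1e-8))
    expect_true(ape::is.binary(phy))
  }

  # growth consistency: mean root age scales like sum_{k=2..n} 1/(k lambda)
  set.seed(62)
  n <- 8
  roots8 <- replicate(1500, max(node_ages(sim_yule_tree(n, lam))))
  expected <- sum(1 / ((2:n) * lam))
  se8 <- sd(roots8) / sqrt(length(roots8))
  expect_lt(abs(mean(roots8) - expected), 4 * se8)
})

test_that("sequence simulator respects frozen and saturated limits", {
  set.seed(63)
  phy <- sim_yule_tree(5, 0.3)
  m <- substitution_model(base_freqs = c(0.4, 0.3, 0.2, 0.1),
                          gamma_shape = Inf)

  # rate ~ 0: all sequences identical to the root draw
  aln0 <- sim_alignment(phy, 1e-12, list(g = list(length = 50, model = m)))
  expect_true(all(apply(aln0$g, 2, function(cl) length(unique(cl)) == 1)))

  # saturation: pairwise identity approaches sum(pi^2)
  phy2 <- ape::read.tree(text = "(a:1,b:1);")
  phy2$edge.length <- c(25, 25)  # far past 10 expected subs/site at rate 1
  aln2 <- sim_alignment(phy2, 1, list(g = list(length = 4000, model = m)))
  ident <- mean(aln2$g["a", ] == aln2$g["b", ])
  expect_lt(abs(ident - sum(m$base_freqs^2)), 0.025)

  # self-consistency: generating parameters beat perturbed ones on average
  set.seed(64)
  wins <- 0
  for (r in 1:20) {
    phy3 <- sim_yule_tree(6, 0.3)
    rates <- rep(0.1, nrow(phy3$edge))
    aln3 <- sim_alignment(phy3, rates, list(g = list(length = 150,
                                                     model = m)))
    ages3 <- node_ages(phy3)[7:11]
    ll_true <- pruning_loglik(dating_state(phy3, ages3, rates, m), aln3)
    ll_off <- pruning_loglik(dating_state(phy3, ages3, rates * 2.5, m), aln3)
    if (ll_true > ll_off) wins <- wins + 1
  }
  expect_gte(wins, 16)
})

# deep pectinate tree whose terminal branches all span the older SALMA
# bins (node ages a1 > ... > a9, extant tips at 0)
deep_pectinate <- function(node_age = seq(26, 18, by = -1)) {
  k <- length(node_age)
  cur <- sprintf("(t%d:%g,t%d:%g)", k, node_age[k], k + 1, node_age[k])
  for (j in (k - 1):1)
    cur <- sprintf("(t%d:%g,%s:%g)", j, node_age[j], cur,
                   node_age[j] - node_age[j + 1])
  ape::read.tree(text = paste0(cur, ";"))
}

test_that("fossil preservation is Poisson-thinned per bin with causal FADs", {
  ts <- salma_timescale()
  phy <- deep_pectinate()

  # zero preservation: empty record
  none <- sim_fossil_record(phy, 0, ts, seed = 65)
  expect_equal(nrow(none$occ), 0)
  expect_length(none$unsampled, 10)

  # FAD cannot predate the lineage origin (bin age_min <= origin age)
  rec <- sim_fossil_record(phy, 0.2, ts, seed = 66)
  ages <- node_ages(phy)
  for (i in seq_len(nrow(rec$occ))) {
    tip <- match(rec$occ$taxon[i], phy$tip.label)
    origin <- ages[phy$edge[phy$edge[, 2] == tip, 1]]
    expect_lte(rec$occ$fad_min[i], origin + 1e-9)
  }

  # a Lagerstaetten bin concentrates first appearances: every terminal
  # branch crosses the hot Santacrucian bin, whose rate dwarfs the rest
  pres <- stats::setNames(rep(0.03, nrow(ts)), ts$name)
  pres["Santacrucian"] <- 8
  hot_wins <- 0
  for (r in 1:10) {
    rec2 <- sim_fossil_record(phy, pres, ts, seed = 200 + r)
    if (!nrow(rec2$occ)) next
    tab <- table(factor(rec2$occ$interval, levels = ts$name))
    if (tab["Santacrucian"] >= max(tab)) hot_wins <- hot_wins + 1
  }
  expect_gte(hot_wins, 9)
})

test_that("more preservation means fewer implied ghost lineages", {
  ts <- salma_timescale()
  phy <- deep_pectinate()
  rates <- c(0.05, 0.15, 0.4, 1, 4)
  mean_mig <- numeric(length(rates))
  for (k in seq_along(rates)) {
    migs <- c()
    for (r in 1:8) {
      rec <- sim_fossil_record(phy, rates[k], ts, seed = 500 + 31 * k + r)
      if (nrow(rec$occ) < 3) next
      sub <- ape::keep.tip(phy, rec$occ$taxon)
      ch <- strat_calibrate(sub, rec$occ)
      migs <- c(migs, sum(ghost_lineages(ch)$duration_min))
    }
    mean_mig[k] <- mean(migs)
  }
  expect_false(anyNA(mean_mig))
  expect_lt(cor(rates, mean_mig, method = "spearman"), 0)
})

test_that("the default scenario mirrors the published data shape", {
  sc <- sim_scenario()
  expect_equal(sc$n_tips, 12)
  expect_equal(sc$ucld_sd, 0.3)
  lens <- vapply(sc$partitions, `[[`, 0, "length")
  expect_equal(unname(lens), c(961, 1140, 1099, 814))
  expect_equal(sum(lens), 4014)
  expect_gt(sc$partitions$cyb$model$p_inv, 0)    # cyb runs GTR+I+G
  expect_equal(sc$partitions$`12s`$model$p_inv, 0)

  sim <- simulate_scenario(sim_scenario(n_tips = 6), seed = 99)
  expect_equal(ape::Ntip(sim$tree), 6)
  expect_length(sim$rates, nrow(sim$tree$edge))
  expect_equal(nrow(sim$alignment$cyb), 6)
  # same seed regenerates identical data end to end
  sim2 <- simulate_scenario(sim_scenario(n_tips = 6), seed = 99)
  expect_identical(sim$alignment, sim2$alignment)
  expect_identical(ape::write.tree(sim$tree), ape::write.tree(sim2$tree))
})

test_that("cavioid bookkeeping matches the published matrix sizes", {
  expect_equal(unname(cavioid_partitions()),
               c(961L, 1140L, 1099L, 814L))
  ms <- cavioid_matrix_size()
  expect_equal(ms$n_molecular, 4014L)
  expect_equal(ms$n_total, 4110L)
  fx <- cavioid_fixture()
  expect_true(all(c("Chubutomys_simpsoni", "Prodolichotis_pridiana") %in%
                    fx$tree$tip.label))
  # P. pridiana is binned to the Laventan (13.5-11.8 Ma)
  pp <- fx$occurrences[fx$occurrences$taxon == "Prodolichotis_pridiana", ]
  expect_equal(pp$interval, "Laventan")
  expect_equal(pp$fad_max, 13.5)
  expect_equal(pp$fad_min, 11.8)
})
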