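# sensitivity design enumeration, LTT curves, gap report

test_that("the analysis design enumerates subsets in the published order", {
  cfgs <- enumerate_analyses()
  expect_length(cfgs, 30)
  # structure: sizes 4,3,2,1; normal before gamma; lexicographic subsets
  sizes <- vapply(cfgs, function(cf) length(cf$calibrated_nodes), 0L)
  expect_equal(sizes, rep(c(4, 3, 3, 3, 3, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1),
                          each = 2))
  expect_equal(cfgs[[3]]$family, "normal")
  expect_equal(cfgs[[3]]$calibrated_nodes, c(1L, 2L, 3L))
  expect_equal(cfgs[[5]]$calibrated_nodes, c(1L, 2L, 4L))
  expect_equal(cfgs[[29]]$calibrated_nodes, 4L)
  # bijection: id -> config -> id round-trips
  for (id in c(1, 7, 18, 30))
    expect_equal(analysis_config(id)$analysis_id, id)
  # count law (2^k - 1) * 2
  for (k in 1:4)
    expect_length(enumerate_analyses(k), (2^k - 1) * 2)
  expect_length(enumerate_analyses(1), 2)
})

test_that("fossil LTT counts lineages from their inferred origins", {
  # single cherry steps 1 -> 2 at the root age
  phy <- ape::read.tree(text = "(A,B);")
  occ <- occurrences(c("A", "B"), fad_max = 12, fad_min = 10)
  lt <- ltt_fossil(strat_calibrate(phy, occ))
  expect_equal(lt$n_min[lt$age == 10], 2L)

  # worked example: 6 cavioid lineages by the end of the Deseadan
  fx <- cavioid_fixture()
  ch <- strat_calibrate(fx$tree, fx$occurrences)
  lt2 <- ltt_fossil(ch)
  expect_equal(lt2$n_min[lt2$age == 24.5], 6L)

  # envelope: the max-age curve never lags the min-age curve, both
  # non-decreasing toward the present
  expect_true(all(diff(lt2$n_min) >= 0))
  expect_true(all(diff(lt2$n_max) >= 0))
  expect_true(all(lt2$n_max >= lt2$n_min))

  # random chronogram: counts match an independent edge-crossing recount
  set.seed(41)
  phy6 <- ape::rtree(6)
  fmin <- runif(6, 0, 20)
  occ6 <- occurrences(phy6$tip.label, fad_max = fmin + runif(6, 0, 2),
                      fad_min = fmin)
  ch6 <- strat_calibrate(phy6, occ6)
  lt6 <- ltt_fossil(ch6)
  probes <- seq(0, max(ch6$age_lo), length.out = 100)
  for (t in probes) {
    nodes <- 7:11
    expected <- 1L + sum(ch6$age_lo[nodes] >= t)  # binary: each split +1
    rows <- which(lt6$age >= t)  # events at or before (older than) t
    got <- if (length(rows)) lt6$n_min[max(rows)] else 1L
    expect_equal(got, expected, info = t)
  }
})

test_that("clock LTT steps at mean ages and matches the fossil curve", {
  phy <- ape::read.tree(text = "((a,b),(c,d));")
  # equal means jump together, curve non-decreasing toward present
  lt <- ltt_clock(c(5, 2, 2), phy)
  expect_equal(lt$n[lt$age == 2], 4L)
  expect_true(all(diff(lt$n) >= 0))
  expect_error(ltt_clock(c(5, 2), phy), "every internal node")

  # consistency: equals ltt_fossil's min curve when means equal age_lo
  occ <- occurrences(c("a", "b", "c", "d"),
                     fad_max = c(4, 1, 2, 3), fad_min = c(4, 1, 2, 3))
  ch <- strat_calibrate(phy, occ)
  ltf <- ltt_fossil(ch)
  ltc <- ltt_clock(ch$age_lo[5:7], phy)
  for (a in ltc$age)
    expect_equal(ltc$n[ltc$age == a], ltf$n_min[ltf$age == a], info = a)
})

test_that("gap_report measures the minimum demonstrable hiatus", {
  ts <- salma_timescale()
  # Laventan record followed by Chasicoan record: 11.8 - 9.07 = 2.73 Myr
  occ <- occurrences(c("old", "young"), interval = c("Laventan", "Chasicoan"),
                     ts = ts)
  g <- gap_report(occ, ts)
  expect_equal(g$gap_min, 2.73)
  expect_equal(g$from, "Laventan")

  # contiguous intervals have no demonstrable gap
  occ2 <- occurrences(c("a", "b"), interval = c("Chasicoan", "Huayquerian"),
                      ts = ts)
  expect_equal(gap_report(occ2, ts)$gap_min, 0)

  # a missing middle bin spans the gap, verified by direct subtraction
  occ3 <- occurrences(c("a", "b"), interval = c("Chasicoan", "Montehermosan"),
                      ts = ts)
  expect_equal(gap_report(occ3, ts)$gap_min, 6.1 - 5.3)

  # fewer than two occupied intervals: empty report
  expect_equal(nrow(gap_report(occ[1, ], ts)), 0)
})

test_that("the sensitivity driver fills the design table deterministically", {
  set.seed(55)
  phy <- sim_yule_tree(8, 0.15)
  rates <- sim_branch_rates(phy, 0.02, 0.2)
  m <- substitution_model(gamma_shape = Inf)
  aln <- sim_alignment(phy, rates, list(g = list(length = 150, model = m)))
  tra <- node_ages(phy)
  # two candidate nodes: root and one cherry
  cherry <- phy$tip.label[phy$edge[phy$edge[, 1] ==
                                     max(phy$edge[, 1]), 2][1:2]]
  cherry_node <- mrca_node(phy, cherry)
  node_tips <- list(node1 = phy$tip.label, node2 = cherry)
  node_priors <- list(
    node1 = list(normal = normal_prior(max(tra) * 0.85, max(tra) * 1.15),
                 gamma = gamma_prior(max(tra) * 0.9, max(tra) * 1.4,
                                     shape = 2)),
    node2 = list(normal = normal_prior(tra[cherry_node] * 0.7,
                                       tra[cherry_node] * 1.3 + 0.1),
                 gamma = gamma_prior(max(tra[cherry_node] * 0.8, 0.01),
                                     tra[cherry_node] * 1.5 + 0.2,
                                     shape = 2)))
  s <- mcmc_settings(iterations = 2000, thin = 10, n_runs = 1, seed = 9)
  res <- run_sensitivity(phy, aln, node_tips, node_priors, settings = s,
                         models = m)
  expect_equal(nrow(res), 6)  # (2^2 - 1) * 2
  expect_true(all(c("node1_mean", "node2_hpd_hi") %in% names(res)))
  expect_true(all(is.finite(res$node1_mean)))
  # bit-reproducible under the same master seed
  res2 <- run_sensitivity(phy, aln, node_tips, node_priors, settings = s,
                          models = m)
  expect_identical(res, res2)
})
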