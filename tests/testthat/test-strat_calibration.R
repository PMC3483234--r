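# stratigraphic calibration, ghost lineages and congruence metrics

test_that("calibration propagates running maxima of descendant FADs", {
  # single cherry: two tips with FAD [10, 12] -> root [10, 12]
  phy <- ape::read.tree(text = "(A,B);")
  occ <- occurrences(c("A", "B"), fad_max = 12, fad_min = 10)
  ch <- strat_calibrate(phy, occ)
  expect_equal(ch$age_lo[3], 10)
  expect_equal(ch$age_hi[3], 12)

  # 5-tip pectinate with FADs 1..5: node age_lo is the running max of
  # descendant fad_min, checked by direct recomputation
  phy5 <- ape::read.tree(text = "(t1,(t2,(t3,(t4,t5))));")
  occ5 <- occurrences(paste0("t", 1:5), fad_max = 1:5 + 0.5, fad_min = 1:5)
  ch5 <- strat_calibrate(phy5, occ5)
  for (nd in 6:9) {
    tips <- ape::extract.clade(phy5, nd)$tip.label
    expect_equal(ch5$age_lo[nd],
                 max(occ5$fad_min[occ5$taxon %in% tips]), info = nd)
    expect_equal(ch5$age_hi[nd],
                 max(occ5$fad_max[occ5$taxon %in% tips]), info = nd)
  }
  expect_error(strat_calibrate(phy5, occ5[-2, ]), "t2")
})

test_that("monotonicity: an older FAD never decreases an ancestor age_lo", {
  set.seed(11)
  for (rep in 1:5) {
    phy <- ape::rtree(7)
    base <- runif(7, 1, 10)
    occ1 <- occurrences(phy$tip.label, fad_max = base + 1, fad_min = base)
    ch1 <- strat_calibrate(phy, occ1)
    i <- sample(7, 1)
    base2 <- base
    base2[i] <- base2[i] + runif(1, 0, 10)
    occ2 <- occurrences(phy$tip.label, fad_max = base2 + 1, fad_min = base2)
    ch2 <- strat_calibrate(phy, occ2)
    expect_true(all(ch2$age_lo >= ch1$age_lo - 1e-12))
  }
})

test_that("ghost lineage durations equal per-tip recomputation", {
  # Colhuehuapian tip under a Deseadan-constrained node: at least 4 Myr
  fx <- cavioid_fixture()
  ch <- strat_calibrate(fx$tree, fx$occurrences)
  g <- ghost_lineages(ch)
  for (tx in c("Luantus_initialis", "Luantus_minor", "Chubutomys_leucoreios"))
    expect_equal(g$duration_min[g$taxon == tx], 24.5 - 20.5, info = tx)

  # tip whose FAD equals its parent interval has no minimum gap (the
  # maximum gap spans the interval width, so the tips stay flagged)
  phy <- ape::read.tree(text = "(A,B);")
  occ <- occurrences(c("A", "B"), fad_max = 12, fad_min = 10)
  g2 <- ghost_lineages(strat_calibrate(phy, occ))
  expect_equal(g2$duration_min, c(0, 0))
  expect_equal(g2$duration_max, c(2, 2))
  # only a fully degenerate gap ([0, 0] both ways) is non-ghost
  occ0 <- occurrences(c("A", "B"), fad_max = 10, fad_min = 10)
  g0 <- ghost_lineages(strat_calibrate(phy, occ0))
  expect_false(any(g0$is_ghost))

  # random chronogram: durations equal independent subtraction
  set.seed(21)
  phy6 <- ape::rtree(6)
  fmin <- runif(6, 0, 20)
  occ6 <- occurrences(phy6$tip.label, fad_max = fmin + runif(6, 0, 2),
                      fad_min = fmin)
  ch6 <- strat_calibrate(phy6, occ6)
  g6 <- ghost_lineages(ch6)
  for (i in 1:6) {
    par <- phy6$edge[phy6$edge[, 2] == i, 1]
    expect_equal(g6$duration_min[g6$taxon == phy6$tip.label[i]],
                 max(0, ch6$age_lo[par] - occ6$fad_max[occ6$taxon ==
                                                         phy6$tip.label[i]]))
  }
  # MIG additivity: total equals the per-tip sum
  expect_equal(sum(g6$duration_min),
               sum(pmax(0, ch6$age_lo[phy6$edge[phy6$edge[, 2] <= 6, 1]][
                 order(phy6$edge[phy6$edge[, 2] <= 6, 2])] -
                   ch6$age_hi[1:6])))
})

test_that("ghost-origin counts work on intervals and edge cases", {
  fx <- cavioid_fixture()
  ch <- strat_calibrate(fx$tree, fx$occurrences)
  expect_identical(count_ghost_origins(ch, "Deseadan"), 4L)
  expect_identical(count_ghost_origins(ch, "Santacrucian"), 3L)
  # an interval older than the root yields none
  expect_identical(count_ghost_origins(ch, c(60, 40)), 0L)
})

test_that("stratigraphic debt matches exhaustive Sankoff on all 4-tip trees", {
  ages <- c(A = 1, B = 2, C = 3, D = 4)
  tops <- all_rooted_topologies(names(ages))
  expect_length(tops, 15)
  for (tr in tops) {
    phy <- ape::read.tree(text = oracle_newick(tr))
    expect_equal(strat_debt(phy, ages), oracle_debt(tr, ages),
                 info = oracle_newick(tr))
  }
  # congruent pectinate attains the range; equal ages cost nothing
  phy <- ape::read.tree(text = "(D,(C,(B,A)));")
  expect_equal(strat_debt(phy, ages), 3)
  expect_equal(strat_debt(phy, c(A = 2, B = 2, C = 2, D = 2)), 0)
})

test_that("metric extremes and ratios match exhaustive enumeration", {
  # congruent pectinate: GER = 1, MSM* = 1
  phy <- ape::read.tree(text = "(D,(C,(B,A)));")
  ages <- c(A = 1, B = 2, C = 3, D = 4)
  m <- strat_metrics(phy, ages)
  expect_equal(m$ger, 1)
  expect_equal(m$msm_star, 1)

  # anti-ordered pectinate (oldest most nested): GER = 0, and its MIG is
  # the enumerated maximum
  anti <- ape::read.tree(text = "(A,(B,(C,D)));")
  m2 <- strat_metrics(anti, ages)
  rng <- oracle_mig_range(ages)
  expect_equal(m2$ger, 0)
  expect_equal(m2$mig, unname(rng["g_max"]))

  # n <= 5 random cases: (mig, g_min, g_max) equal brute force over all
  # rooted binary topologies
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(4:5, 1)
    ages <- round(runif(n, 0, 10), 2)
    names(ages) <- letters[1:n]
    rng <- oracle_mig_range(ages)
    tops <- all_rooted_topologies(names(ages))
    tr <- tops[[sample(length(tops), 1)]]
    phy <- ape::read.tree(text = oracle_newick(tr))
    m <- strat_metrics(phy, ages)
    expect_equal(m$g_min, unname(rng["g_min"]), info = rep)
    expect_equal(m$g_max, unname(rng["g_max"]), info = rep)
    expect_equal(m$mig, oracle_mig(tr, ages), info = rep)
    expect_gte(m$ger, 0); expect_lte(m$ger, 1)
    expect_gt(m$msm_star, 0); expect_lte(m$msm_star, 1)
  }

  # degenerate: all FADs identical -> both ratios 1 by convention
  star <- ape::read.tree(text = "((a,b),(c,d));")
  same <- c(a = 3, b = 3, c = 3, d = 3)
  md <- strat_metrics(star, same)
  expect_equal(md$ger, 1)
  expect_equal(md$msm_star, 1)
})

test_that("calibrated NEXUS round-trips node intervals (incl. polytomies)", {
  fx <- cavioid_fixture()  # contains polytomies
  ch <- strat_calibrate(fx$tree, fx$occurrences)
  f <- withr::local_tempfile(fileext = ".nex")
  write_calibrated_nexus(ch, f)

  # still a readable tree through the plain reader
  plain <- read_tree(f)
  expect_true(ape::all.equal.phylo(fx$tree, plain, use.edge.length = FALSE))

  back <- read_calibrated_nexus(f)
  # node intervals survive; compare via matched clades
  for (nd in (ape::Ntip(fx$tree) + 1L):(ape::Ntip(fx$tree) + fx$tree$Nnode)) {
    tips <- ape::extract.clade(fx$tree, nd)$tip.label
    nd2 <- if (length(tips) == ape::Ntip(back$phy))
      ape::Ntip(back$phy) + 1L else mrca_node(back$phy, tips)
    expect_equal(back$age_lo[nd2], ch$age_lo[nd], info = nd)
    expect_equal(back$age_hi[nd2], ch$age_hi[nd], info = nd)
  }
  # degenerate interval [a, a] round-trips too
  phy <- ape::read.tree(text = "(A,B);")
  occ <- occurrences(c("A", "B"), fad_max = 7, fad_min = 7)
  f2 <- withr::local_tempfile(fileext = ".nex")
  write_calibrated_nexus(strat_calibrate(phy, occ), f2)
  b2 <- read_calibrated_nexus(f2)
  expect_equal(b2$age_lo[3], 7)
  expect_equal(b2$age_hi[3], 7)
})
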