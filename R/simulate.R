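# Generators for the statistical structure the dating analysis assumes:
# Yule trees, lognormal branch rates, partitioned GTR+Gamma(+I) sequences,
# and binned Poisson fossil preservation.

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Forward simulation from two lineages at the root: with `k` lineages the
#' waiting time to the next split is Exp(`k * birth_rate`); after the
#' `n`-th lineage appears, the present is placed at the (exponential)
#' moment the `n+1`-th split would have occurred, so tip count is exactly
#' `n_tips`. Under this conditioning the 2-tip root age is Exp(2 *
#' birth_rate) with mean `1/(2 birth_rate)`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate birth rate (1/Myr).
#' @param seed optional integer seed (set for a reproducible tree).
#' @return An ultrametric [ape::phylo] with edge lengths in Myr; node ages
#'   are recoverable with [ape::branching.times()].
#' @export
sim_yule_tree <- function(n_tips, birth_rate, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rexp(n_tips - 1L, rate = (2:n_tips) * birth_rate)
  split_times <- cumsum(d)[-(n_tips - 1L)]  # forward times of splits 3..n
  Tpres <- sum(d)

  n_int <- n_tips - 1L
  int_time <- numeric(n_int); int_time[1] <- 0
  # lineages: parent internal node (package-local index) per active lineage
  lin_parent <- c(1L, 1L)
  edges <- matrix(0L, 0, 2)  # internal-index -> internal-index
  for (j in seq_along(split_times)) {
    m <- j + 1L
    int_time[m] <- split_times[j]
    i <- sample.int(length(lin_parent), 1L)
    edges <- rbind(edges, c(lin_parent[i], m))
    lin_parent <- c(lin_parent[-i], m, m)
  }
  ntot <- n_tips + n_int
  edge <- rbind(
    cbind(n_tips + edges[, 1], n_tips + edges[, 2]),
    cbind(n_tips + lin_parent, seq_len(n_tips)))
  node_time <- c(rep(Tpres, n_tips), int_time)
  phy <- structure(list(
    edge = edge,
    edge.length = node_time[edge[, 2]] - node_time[edge[, 1]],
    tip.label = paste0("t", seq_len(n_tips)),
    Nnode = n_int), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Draw uncorrelated lognormal branch rates
#'
#' One independent lognormal rate per edge, with real-space mean
#' `ucld_mean` and log-space sd `ucld_sd`; optionally, every edge inside a
#' clade (including its stem edge) is multiplied by `multiplier` to
#' emulate clade-specific rate elevation.
#'
#' @param phy an [ape::phylo].
#' @param ucld_mean real-space mean rate (substitutions/site/Myr).
#' @param ucld_sd log-space sd (0 gives a strict clock).
#' @param clade optional character vector of tip labels; the MRCA's stem
#'   edge and all descendant edges get the multiplier.
#' @param multiplier rate factor for `clade`.
#' @param seed optional integer seed.
#' @return Numeric vector of rates in `phy$edge` row order.
#' @export
sim_branch_rates <- function(phy, ucld_mean, ucld_sd = 0.3, clade = NULL,
                             multiplier = 1, seed = NULL) {
  stopifnot(ucld_mean > 0, ucld_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  nedge <- nrow(phy$edge)
  r <- if (ucld_sd > 0)
    stats::rlnorm(nedge, log(ucld_mean) - ucld_sd^2 / 2, ucld_sd)
  else rep(ucld_mean, nedge)
  if (!is.null(clade) && multiplier != 1) {
    node <- mrca_node(phy, clade)
    in_clade <- clade_edges(phy, node)
    r[in_clade] <- r[in_clade] * multiplier
  }
  r
}

# edge rows whose child is the clade node or below it (stem included)
clade_edges <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  desc <- node
  repeat {
    more <- phy$edge[phy$edge[, 1] %in% desc, 2]
    new <- setdiff(more, desc)
    if (!length(new)) break
    desc <- c(desc, new)
  }
  which(phy$edge[, 2] %in% desc)
}

#' Simulate a partitioned alignment down a tree
#'
#' Sites evolve independently under each partition's GTR+Gamma(+I) model;
#' the expected substitutions on an edge are `branch_rate * duration *
#' category_rate`. Partitions are independent.
#'
#' @param phy an [ape::phylo] with edge lengths in Myr.
#' @param branch_rates one rate per edge (substitutions/site/Myr), in
#'   `phy$edge` order; a scalar is recycled.
#' @param partitions named list; each element a list with `length` (sites)
#'   and `model` (a [substitution_model]).
#' @param seed optional integer seed.
#' @return A [partitioned_alignment].
#' @export
sim_alignment <- function(phy, branch_rates, partitions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_topology(phy)
  if (is.null(phy$edge.length)) stop("tree needs edge lengths (Myr)")
  nedge <- nrow(phy$edge)
  branch_rates <- rep_len(branch_rates, nedge)
  ntip <- ape::Ntip(phy)
  bases <- c("A", "C", "G", "T")
  pre <- ape::reorder.phylo(phy, "cladewise")  # parents before children
  rate_map <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                    paste(phy$edge[, 1], phy$edge[, 2]))
  out <- lapply(partitions, function(pt) {
    model <- pt$model
    L <- pt$length
    cat_of_site <- sample.int(length(model$catrate), L, replace = TRUE,
                              prob = model$catw)
    states <- matrix(0L, ntip + phy$Nnode, L)
    states[ntip + 1L, ] <- sample.int(4L, L, replace = TRUE,
                                      prob = model$base_freqs)
    for (k in seq_len(nrow(pre$edge))) {
      par <- pre$edge[k, 1]; chd <- pre$edge[k, 2]
      b0 <- branch_rates[rate_map[k]] * pre$edge.length[k]
      for (cc in unique(cat_of_site)) {
        P <- transition_matrix(model, b0 * model$catrate[cc])
        idx <- which(cat_of_site == cc)
        for (st in 1:4) {
          jj <- idx[states[par, idx] == st]
          if (length(jj))
            states[chd, jj] <- sample.int(4L, length(jj), replace = TRUE,
                                          prob = P[st, ])
        }
      }
    }
    m <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], nrow = ntip,
                dimnames = list(phy$tip.label, NULL))
    m
  })
  partitioned_alignment(out)
}

# P(t) from the model's eigendecomposition (rows: from-state)
transition_matrix <- function(model, t) {
  P <- model$evec %*% (exp(model$eval * t) * model$ievec)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate binned fossil preservation along terminal branches
#'
#' Occurrences are Poisson-sampled on each terminal branch (fossil taxa
#' are treated as sampled ancestors simplified to tips, so internal
#' branches are not sampled), with a per-interval preservation rate
#' (occurrences/lineage/Myr) over a [timescale]. A tip's first appearance
#' datum is its oldest occurrence, reported as the containing bin's
#' bounds. Raising one bin's rate emulates a Lagerstaetten effect.
#'
#' @param phy ultrametric [ape::phylo] with edge lengths in Myr (extant
#'   tips at age 0).
#' @param preservation a single rate, or a named vector with one rate per
#'   interval of `ts`.
#' @param ts a [timescale]; every interval overlapping the tree's span
#'   should have a rate.
#' @param seed optional integer seed.
#' @return A list: `occ` (a [occurrences] table for sampled tips, FADs at
#'   bin bounds), `unsampled` (tip labels with no occurrence), and
#'   `n_by_interval` (occurrence counts per bin).
#' @export
sim_fossil_record <- function(phy, preservation, ts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(ts, "timescale"))
  if (is.null(names(preservation)))
    preservation <- stats::setNames(rep_len(preservation, nrow(ts)), ts$name)
  miss <- setdiff(ts$name, names(preservation))
  if (length(miss)) stop("no preservation rate for interval(s): ",
                         paste(miss, collapse = ", "))
  ntip <- ape::Ntip(phy)
  ages <- node_ages(phy)
  taxon <- character(0); fmax <- fmin <- numeric(0); ivl <- character(0)
  counts <- stats::setNames(numeric(nrow(ts)), ts$name)
  for (i in seq_len(ntip)) {
    e <- which(phy$edge[, 2] == i)
    a0 <- ages[i]                      # tip age (0 if extant)
    a1 <- ages[phy$edge[e, 1]]         # origin (parent node age)
    best <- -Inf; best_iv <- NA_character_
    for (b in seq_len(nrow(ts))) {
      lo <- max(a0, ts$age_min[b]); hi <- min(a1, ts$age_max[b])
      if (hi <= lo) next
      n <- stats::rpois(1, preservation[[ts$name[b]]] * (hi - lo))
      if (n > 0) {
        counts[b] <- counts[b] + n
        omax <- max(stats::runif(n, lo, hi))
        if (omax > best) { best <- omax; best_iv <- ts$name[b] }
      }
    }
    if (is.finite(best)) {
      taxon <- c(taxon, phy$tip.label[i])
      bb <- interval_bounds(ts, best_iv)
      fmax <- c(fmax, bb[["age_max"]]); fmin <- c(fmin, bb[["age_min"]])
      ivl <- c(ivl, best_iv)
    }
  }
  occ <- if (length(taxon))
    occurrences(taxon, fmax, fmin, ivl, ts = ts)
  else occurrences(character(0))
  list(occ = occ, unsampled = setdiff(phy$tip.label, taxon),
       n_by_interval = counts)
}

#' Node ages (Ma) of an ultrametric tree
#'
#' @param phy ultrametric [ape::phylo].
#' @return Numeric vector over all nodes (tips then internals), ages
#'   before present.
#' @export
node_ages <- function(phy) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  depth <- numeric(nn)
  pre <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(pre$edge)))
    depth[pre$edge[k, 2]] <- depth[pre$edge[k, 1]] + pre$edge.length[k]
  tot <- max(depth[seq_len(ntip)])
  pmax(tot - depth, 0)
}

#' Default simulation scenario
#'
#' The stated world of the package's simulations: 12 extant tips, Yule
#' birth rate 0.12/Myr (root ages around the mid-Miocene scale of the
#' worked example), relaxed clock with mean rate 0.01
#' substitutions/site/Myr and log-sd 0.3, and four partitions of the
#' published lengths (961, 1140, 1099, 814 bp) under GTR+Gamma, the
#' cytochrome-b-like partition adding invariant sites.
#'
#' @param n_tips,birth_rate,ucld_mean,ucld_sd scenario parameters.
#' @param preservation per-interval preservation rate(s),
#'   occurrences/lineage/Myr.
#' @param clade_multiplier optional list(tips = , factor = ) for
#'   clade-specific rate elevation.
#' @return A `sim_scenario` list understood by [simulate_scenario()].
#' @export
sim_scenario <- function(n_tips = 12, birth_rate = 0.12, ucld_mean = 0.01,
                         ucld_sd = 0.3, preservation = 0.05,
                         clade_multiplier = NULL) {
  gtr <- function(pinv = 0, name = NULL)
    substitution_model(rates = c(1.5, 6, 1.2, 0.9, 8, 1),
                       base_freqs = c(0.31, 0.26, 0.17, 0.26),
                       gamma_shape = 0.5, p_inv = pinv, name = name)
  structure(list(
    n_tips = n_tips, birth_rate = birth_rate,
    ucld_mean = ucld_mean, ucld_sd = ucld_sd,
    partitions = list(
      `12s` = list(length = 961, model = gtr(name = "12s")),
      cyb = list(length = 1140, model = gtr(pinv = 0.3, name = "cyb")),
      Tth = list(length = 1099, model = gtr(name = "Tth")),
      Ghr = list(length = 814, model = gtr(name = "Ghr"))),
    preservation = preservation,
    clade_multiplier = clade_multiplier),
    class = "sim_scenario")
}

#' Generate a full synthetic data set from a scenario
#'
#' Tree, branch rates, alignment and fossil record in one deterministic
#' draw: the single `seed` drives all stages through one RNG stream.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @param ts a [timescale] for fossil preservation (default SALMA).
#' @return A list: `tree` (ultrametric phylo, Myr), `ages` (true node
#'   ages), `rates` (true branch rates), `alignment`, `fossils` (see
#'   [sim_fossil_record()]).
#' @export
simulate_scenario <- function(scenario, seed, ts = salma_timescale()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  phy <- sim_yule_tree(scenario$n_tips, scenario$birth_rate)
  clade <- scenario$clade_multiplier
  rates <- sim_branch_rates(phy, scenario$ucld_mean, scenario$ucld_sd,
                            clade = clade$tips,
                            multiplier = if (is.null(clade)) 1 else
                              clade$factor)
  aln <- sim_alignment(phy, rates, scenario$partitions)
  fos <- sim_fossil_record(phy, scenario$preservation, ts)
  list(tree = phy, ages = node_ages(phy), rates = rates,
       alignment = aln, fossils = fos)
}
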