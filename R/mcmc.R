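#' MCMC settings for the dating engine
#'
#' Desk-scale defaults (200,000 generations, sampling every 1000, 10%
#' burn-in, four independent runs); the published protocol's scale
#' (10,000,000 generations) is reachable by raising `iterations`.
#'
#' @param iterations generations per run.
#' @param thin sampling interval (generations).
#' @param burnin_frac fraction of each run discarded before summarizing.
#' @param n_runs number of independent runs to integrate.
#' @param seed master seed; each run uses a stream derived from
#'   `(seed, run index)` by a fixed splitting rule.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(iterations = 200000, thin = 1000,
                          burnin_frac = 0.10, n_runs = 4, seed = 1) {
  stopifnot(iterations >= 1, thin >= 1, burnin_frac >= 0, burnin_frac < 1,
            n_runs >= 1)
  n_samp <- floor(iterations / thin)
  if (n_samp * (1 - burnin_frac) < 100)
    stop("settings yield fewer than 100 post-burn-in samples per run; ",
         "increase iterations or decrease thin")
  structure(list(iterations = as.integer(iterations), thin = as.integer(thin),
                 burnin_frac = burnin_frac, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# documented seed-splitting rule: one stream per (seed, run)
run_seed <- function(seed, run) {
  s <- (as.numeric(seed) * 7919 + run * 104729) %% 2147483646
  as.integer(s) + 1L
}

#' Define a node calibration
#'
#' @param tips character vector (>= 2) of tip labels whose MRCA is the
#'   calibrated node; the set must be monophyletic on the fixed topology.
#' @param prior a [prior_spec] (normal or gamma).
#' @return A `calibration` list.
#' @export
calibration <- function(tips, prior) {
  stopifnot(inherits(prior, "prior_spec"), length(tips) >= 2)
  if (prior$family == "tree_prior")
    stop("a 'tree_prior' spec is the absence of a calibration")
  structure(list(tips = as.character(tips), prior = prior),
            class = "calibration")
}

# ---- internal posterior machinery -----------------------------------------

# precompute everything the per-iteration likelihood needs
likelihood_prep <- function(phy, alignment, models) {
  if (is.null(alignment)) return(NULL)
  stopifnot(inherits(alignment, "partitioned_alignment"))
  if (inherits(models, "substitution_model")) models <- list(models)
  if (length(models) == 1L && length(alignment) > 1L)
    models <- rep(models, length(alignment))
  if (length(models) != length(alignment))
    stop("number of models does not match number of partitions")
  po <- ape::reorder.phylo(phy, "postorder")
  rate_map <- match(paste(po$edge[, 1], po$edge[, 2]),
                    paste(phy$edge[, 1], phy$edge[, 2]))
  list(edge = po$edge, ntip = ape::Ntip(phy), rate_map = rate_map,
       enc = lapply(alignment, encode_partition,
                    tip_labels = phy$tip.label),
       models = models)
}

# fast total log-likelihood; -Inf on numerical failure (MCMC rejects)
prep_loglik <- function(prep, ages, rates) {
  if (is.null(prep)) return(0)
  allages <- c(numeric(prep$ntip), ages)
  dur <- allages[prep$edge[, 1]] - allages[prep$edge[, 2]]
  blen <- rates[prep$rate_map] * dur
  tot <- 0
  for (k in seq_along(prep$enc)) {
    m <- prep$models[[k]]
    ll <- peel_loglik_cpp(prep$edge, prep$ntip, blen, prep$enc[[k]]$tipdat,
                          m$evec, m$ievec, m$eval, m$base_freqs,
                          m$catrate, m$catw)
    v <- sum(prep$enc[[k]]$wts * ll)
    if (!is.finite(v)) return(-Inf)
    tot <- tot + v
  }
  tot
}

# joint log prior of ages/rates/hyperparameters
log_prior <- function(ages, rates, ucld_mean, ucld_sd, yule_rate,
                      cal_nodes, cal_priors, ntip, tree_prior,
                      hyper_max = c(ucld_mean = 100, ucld_sd = 5,
                                    yule = 10)) {
  if (ucld_mean <= 0 || ucld_mean > hyper_max["ucld_mean"] ||
      ucld_sd <= 0 || ucld_sd > hyper_max["ucld_sd"] ||
      yule_rate <= 0 || yule_rate > hyper_max["yule"]) return(-Inf)
  lp <- 0
  if (tree_prior == "yule") {
    lp <- lp + yule_log_prior(ages, yule_rate)
  } else {
    # flat tree prior: each uncalibrated non-root age uniform on
    # (0, root age), normalized -- without the 1/root terms the ordering
    # volume tilts calibrated marginals away from their priors
    n_uncal <- (length(ages) - 1L) - sum(cal_nodes != ntip + 1L)
    if (n_uncal > 0) lp <- lp - n_uncal * log(ages[1L])
  }
  lp <- lp + rates_log_prior(rates, ucld_mean, ucld_sd)
  for (i in seq_along(cal_nodes)) {
    lp <- lp + prior_logpdf(cal_priors[[i]], ages[cal_nodes[i] - ntip])
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

# initial internal node ages: proportional node heights stretched to a
# root age compatible with the calibrations, then calibrated nodes pulled
# to their prior medians and order repaired in postorder
init_ages <- function(phy, cal_nodes, cal_priors) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  h <- numeric(nn)
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge)))
    h[po$edge[k, 1]] <- max(h[po$edge[k, 1]], h[po$edge[k, 2]] + 1)
  med <- vapply(cal_priors, function(p)
    switch(p$family,
           normal = p$params[["mean"]],
           gamma = p$params[["offset"]] +
             stats::qgamma(0.5, p$params[["shape"]],
                           scale = p$params[["scale"]])), 0)
  root_age <- if (length(med)) max(med) * 1.25 else 10
  ages <- h[(ntip + 1L):nn] / h[ntip + 1L] * root_age
  if (length(cal_nodes))
    ages[cal_nodes - ntip] <- pmax(ages[cal_nodes - ntip], med)
  allages <- c(numeric(ntip), ages)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    allages[p] <- max(allages[p], allages[ch] + 0.05)
  }
  allages[(ntip + 1L):nn]
}

#' Run one Metropolis-Hastings chain of the dating model
#'
#' Samples internal node ages, branch rates and the clock/tree-prior
#' hyperparameters on a fixed topology. The move set (fixed weights,
#' logged in the result) is: single node-age slide within its
#' parent/children bracket, root-age scale, whole-tree age scale, a
#' compensating age-up/rates-down scale (exploits rate--time confounding),
#' single branch-rate scale, and scale moves on `ucld_mean`, `ucld_sd` and
#' the Yule birth rate. With a `NULL` alignment the chain samples the
#' joint prior.
#'
#' @param state0 a [dating_state()] supplying topology and initial values,
#'   or a list with at least `phy` and `models` (ages/rates then
#'   auto-initialized).
#' @param alignment a [partitioned_alignment], or `NULL` for priors-only.
#' @param calibrations list of [calibration()]s.
#' @param settings an [mcmc_settings()]; only this run's `iterations`,
#'   `thin` and `seed` are used.
#' @param tree_prior `"yule"` or `"none"` (uniform over valid orderings).
#' @param fix character vector among `"ages"`, `"rates"`, `"ucld_mean"`,
#'   `"ucld_sd"`, `"yule_rate"` to hold at initial values.
#' @return An `mcmc_trace`: samples matrix (one row per `thin`
#'   generations) with columns `age_<node>` for every internal node,
#'   `ucld_mean`, `ucld_sd`, `yule_rate`, `log_likelihood`,
#'   `log_posterior`; acceptance rates per move class as an attribute.
#' @export
run_mcmc <- function(state0, alignment = NULL, calibrations = list(),
                     settings = mcmc_settings(), tree_prior = c("yule", "none"),
                     fix = character()) {
  tree_prior <- match.arg(tree_prior)
  phy <- state0$phy
  validate_topology(phy)
  if (!ape::is.binary(phy)) stop("dating requires a binary topology")
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  nedge <- nrow(phy$edge)

  cal_nodes <- vapply(calibrations, function(cl)
    mrca_node(phy, cl$tips, monophyletic = TRUE), 0L)
  cal_priors <- lapply(calibrations, `[[`, "prior")

  ages <- state0$ages
  if (is.null(ages)) ages <- init_ages(phy, cal_nodes, cal_priors)
  ucld_mean <- if (!is.null(state0$ucld_mean)) state0$ucld_mean else 0.01
  ucld_sd <- if (!is.null(state0$ucld_sd)) state0$ucld_sd else 0.3
  yule_rate <- if (!is.null(state0$yule_rate)) state0$yule_rate else
    min(10, max(0.05, (nnode - 1) / max(1e-8, max(ages))))
  rates <- state0$branch_rates
  if (is.null(rates)) rates <- rep(ucld_mean, nedge)

  prep <- likelihood_prep(phy, alignment, state0$models)

  # parent and children lookup for the age slide
  parent <- integer(ntip + nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  root <- ntip + 1L
  internal <- (ntip + 1L):(ntip + nnode)

  allage <- function(a) c(numeric(ntip), a)
  cur_ll <- prep_loglik(prep, ages, rates)
  cur_lp <- log_prior(ages, rates, ucld_mean, ucld_sd, yule_rate,
                      cal_nodes, cal_priors, ntip, tree_prior)
  if (!is.finite(cur_ll + cur_lp))
    stop("initial state has zero posterior density; supply valid ",
         "initial ages/rates")

  moves <- c(age_slide = 30, cal_prior_draw = 10, root_scale = 5,
             tree_scale = 5, rate_time_scale = 5, rate_scale = 30,
             ucld_mean_scale = 5, ucld_sd_scale = 5, yule_scale = 3)
  if (!length(cal_nodes)) moves["cal_prior_draw"] <- 0
  if ("ages" %in% fix)
    moves[c("age_slide", "cal_prior_draw", "root_scale", "tree_scale",
            "rate_time_scale")] <- 0
  if ("rates" %in% fix) moves[c("rate_scale", "rate_time_scale")] <- 0
  if ("ucld_mean" %in% fix) moves["ucld_mean_scale"] <- 0
  if ("ucld_sd" %in% fix) moves["ucld_sd_scale"] <- 0
  if ("yule_rate" %in% fix || tree_prior != "yule") moves["yule_scale"] <- 0
  if (all(moves == 0)) stop("all moves disabled by 'fix'")
  mprob <- moves / sum(moves)
  n_prop <- n_acc <- stats::setNames(numeric(length(moves)), names(moves))

  n_samp <- floor(settings$iterations / settings$thin)
  cn <- c(paste0("age_", internal), "ucld_mean", "ucld_sd", "yule_rate",
          "log_likelihood", "log_posterior")
  out <- matrix(NA_real_, n_samp, length(cn), dimnames = list(NULL, cn))

  set.seed(settings$seed)
  eps <- list(slide = 1, scale = 0.4, rate = 0.8, hyper = 0.5)
  isamp <- 0L
  for (it in seq_len(settings$iterations)) {
    mv <- sample.int(length(moves), 1L, prob = mprob)
    mname <- names(moves)[mv]
    n_prop[mv] <- n_prop[mv] + 1
    a2 <- ages; r2 <- rates
    um2 <- ucld_mean; us2 <- ucld_sd; yr2 <- yule_rate
    lhast <- 0; need_ll <- FALSE; ok <- TRUE

    if (mname == "age_slide") {
      nd <- internal[sample.int(nnode, 1L)]
      aa <- allage(ages)
      lo <- max(aa[kids[[as.character(nd)]]])
      need_ll <- TRUE
      if (nd == root) {
        # symmetric window slide; below-children proposals rejected
        prop <- ages[nd - ntip] + eps$slide * 2 * (stats::runif(1) - 0.5)
        if (prop <= lo) ok <- FALSE else a2[nd - ntip] <- prop
      } else {
        # uniform redraw in the parent/children bracket (bracket does not
        # depend on the current value, so the proposal is symmetric)
        hi <- aa[parent[nd]]
        if (hi <= lo) ok <- FALSE
        else a2[nd - ntip] <- stats::runif(1, lo, hi)
      }
    } else if (mname == "cal_prior_draw") {
      # independence proposal from a calibration prior; the proposal
      # density cancels against the target's calibration factor, so this
      # mixes calibrated nodes rapidly wherever the marginal tracks the
      # prior
      i <- sample.int(length(cal_nodes), 1L)
      nd <- cal_nodes[i]
      new_age <- prior_sample(cal_priors[[i]], 1L)
      lhast <- prior_logpdf(cal_priors[[i]], ages[nd - ntip]) -
        prior_logpdf(cal_priors[[i]], new_age)
      if (!is.finite(lhast) || new_age <= 0) ok <- FALSE
      else a2[nd - ntip] <- new_age
      need_ll <- TRUE
    } else if (mname == "root_scale") {
      c0 <- exp(eps$scale * (stats::runif(1) - 0.5))
      aa <- allage(ages)
      lo <- max(aa[kids[[as.character(root)]]])
      a2[root - ntip] <- ages[root - ntip] * c0
      if (a2[root - ntip] <= lo) ok <- FALSE
      lhast <- log(c0)
      need_ll <- TRUE
    } else if (mname == "tree_scale") {
      c0 <- exp(eps$scale * (stats::runif(1) - 0.5))
      a2 <- ages * c0
      lhast <- nnode * log(c0)
      need_ll <- TRUE
    } else if (mname == "rate_time_scale") {
      c0 <- exp(eps$scale * (stats::runif(1) - 0.5))
      a2 <- ages * c0
      r2 <- rates / c0
      lhast <- (nnode - nedge) * log(c0)
      # branch lengths unchanged: likelihood identical by construction
    } else if (mname == "rate_scale") {
      ed <- sample.int(nedge, 1L)
      c0 <- exp(eps$rate * (stats::runif(1) - 0.5))
      r2[ed] <- rates[ed] * c0
      lhast <- log(c0)
      need_ll <- TRUE
    } else if (mname == "ucld_mean_scale") {
      c0 <- exp(eps$hyper * (stats::runif(1) - 0.5))
      um2 <- ucld_mean * c0
      lhast <- log(c0)
    } else if (mname == "ucld_sd_scale") {
      c0 <- exp(eps$hyper * (stats::runif(1) - 0.5))
      us2 <- ucld_sd * c0
      lhast <- log(c0)
    } else if (mname == "yule_scale") {
      c0 <- exp(eps$hyper * (stats::runif(1) - 0.5))
      yr2 <- yule_rate * c0
      lhast <- log(c0)
    }

    if (ok) {
      aa2 <- allage(a2)
      if (any(aa2[phy$edge[, 1]] <= aa2[phy$edge[, 2]])) ok <- FALSE
    }
    if (ok) {
      lp2 <- log_prior(a2, r2, um2, us2, yr2, cal_nodes, cal_priors,
                       ntip, tree_prior)
      if (is.finite(lp2)) {
        ll2 <- if (need_ll) prep_loglik(prep, a2, r2) else cur_ll
        if (is.finite(ll2) &&
            log(stats::runif(1)) < (ll2 + lp2) - (cur_ll + cur_lp) + lhast) {
          ages <- a2; rates <- r2
          ucld_mean <- um2; ucld_sd <- us2; yule_rate <- yr2
          cur_ll <- ll2; cur_lp <- lp2
          n_acc[mv] <- n_acc[mv] + 1
        }
      }
    }

    if (it %% settings$thin == 0L) {
      isamp <- isamp + 1L
      out[isamp, ] <- c(ages, ucld_mean, ucld_sd, yule_rate,
                        cur_ll, cur_ll + cur_lp)
    }
  }

  structure(out, class = c("mcmc_trace", "matrix"),
            acceptance = ifelse(n_prop > 0, n_acc / n_prop, NA),
            settings = settings, tree_prior = tree_prior,
            cal_nodes = cal_nodes, ntip = ntip)
}

#' Shortest (highest posterior density) interval of a sample
#'
#' The shortest contiguous interval over the sorted samples containing
#' `ceiling(mass * n)` of them.
#'
#' @param samples numeric vector (>= 20 values).
#' @param mass interval mass, default 0.95.
#' @return `c(lo, hi)`.
#' @export
hpd <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 20) stop("need at least 20 samples for an HPD interval")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lo = x[1], hi = x[n]))
  w <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(w)
  c(lo = x[i], hi = x[i + m - 1])
}

#' Effective sample size of an MCMC trace
#'
#' `n / (1 + 2 * sum(rho_k))` with empirical autocorrelations summed up to
#' (excluding) the first non-positive term (initial positive sequence
#' rule). A zero-variance series has ESS `n` by convention.
#'
#' @param samples numeric vector (>= 20 values).
#' @return Effective sample size (> 0).
#' @export
ess <- function(samples) {
  n <- length(samples)
  if (n < 20) stop("need at least 20 samples")
  if (stats::var(samples) == 0) return(n)
  rho <- stats::acf(samples, lag.max = min(n - 1, 2000),
                    plot = FALSE)$acf[-1]
  stop_at <- which(rho <= 0)
  if (length(stop_at)) rho <- rho[seq_len(stop_at[1] - 1L)]
  max(n / (1 + 2 * sum(rho)), 1)
}

#' Integrate several MCMC runs into a posterior summary
#'
#' Removes burn-in per run, pools the remaining samples, and reports the
#' pooled mean and 95% HPD per parameter. ESS is the sum of per-run ESS
#' values (autocorrelation is a within-run property).
#'
#' @param traces list of `mcmc_trace` objects with identical columns.
#' @param burnin_frac fraction of each run discarded.
#' @param mass HPD mass.
#' @return A `posterior_summary` data frame: `param`, `mean`, `hpd_lo`,
#'   `hpd_hi`, `ess`.
#' @export
combine_runs <- function(traces, burnin_frac = 0.10, mass = 0.95) {
  stopifnot(length(traces) >= 1)
  cn <- colnames(traces[[1]])
  for (tr in traces)
    if (!identical(colnames(tr), cn))
      stop("runs have different parameter schemas")
  post <- lapply(traces, function(tr) {
    nb <- floor(nrow(tr) * burnin_frac)
    tr[(nb + 1):nrow(tr), , drop = FALSE]
  })
  pooled <- do.call(rbind, post)
  keep <- setdiff(cn, c("log_likelihood", "log_posterior"))
  res <- data.frame(
    param = keep,
    mean = colMeans(pooled[, keep, drop = FALSE]),
    hpd_lo = NA_real_, hpd_hi = NA_real_, ess = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(keep)) {
    h <- hpd(pooled[, keep[i]], mass)
    res$hpd_lo[i] <- h[1]; res$hpd_hi[i] <- h[2]
    res$ess[i] <- sum(vapply(post, function(m) ess(m[, keep[i]]), 0))
  }
  class(res) <- c("posterior_summary", "data.frame")
  res
}

#' Bayesian relaxed-clock divergence dating on a fixed topology
#'
#' The package's model-fitting entry point: runs `settings$n_runs`
#' independent MCMC chains of the uncorrelated-lognormal relaxed clock
#' with partitioned GTR+Gamma(+I) likelihoods, a Yule tree prior, and
#' fossil calibration priors on named clades, then integrates the runs
#' into per-node posterior mean ages, 95% HPD intervals and ESS.
#'
#' @param phy rooted binary topology over the alignment's taxa (fixed).
#' @param alignment a [partitioned_alignment] (or `NULL` to sample the
#'   prior).
#' @param calibrations list of [calibration()]s.
#' @param models a [substitution_model] or list, one per partition.
#' @param settings an [mcmc_settings()].
#' @param tree_prior `"yule"` or `"none"`.
#' @param fix parameters to hold fixed (see [run_mcmc()]).
#' @param init optional named list of initial values (`ages`,
#'   `branch_rates`, `ucld_mean`, `ucld_sd`, `yule_rate`).
#' @return A `clock_date` object with elements `summary` (a
#'   [combine_runs()] posterior summary with clade labels), `traces`,
#'   `phy`, `calibrations`, `settings`; methods: `print`, `summary`,
#'   `coef` (posterior mean node ages), `plot`.
#' @export
clock_date <- function(phy, alignment, calibrations = list(),
                       models = substitution_model(),
                       settings = mcmc_settings(),
                       tree_prior = c("yule", "none"), fix = character(),
                       init = list()) {
  tree_prior <- match.arg(tree_prior)
  state0 <- list(phy = phy, models = models,
                 ages = init$ages, branch_rates = init$branch_rates,
                 ucld_mean = init$ucld_mean, ucld_sd = init$ucld_sd,
                 yule_rate = init$yule_rate)
  traces <- lapply(seq_len(settings$n_runs), function(r) {
    s <- settings
    s$seed <- run_seed(settings$seed, r)
    run_mcmc(state0, alignment, calibrations, s, tree_prior, fix)
  })
  smry <- combine_runs(traces, settings$burnin_frac)
  ntip <- ape::Ntip(phy)
  smry$label <- NA_character_
  for (cl in calibrations) {
    nd <- mrca_node(phy, cl$tips)
    lbl <- cl$prior$node_label
    if (!is.null(lbl))
      smry$label[smry$param == paste0("age_", nd)] <- lbl
  }
  structure(list(summary = smry, traces = traces, phy = phy,
                 calibrations = calibrations, settings = settings,
                 tree_prior = tree_prior),
            class = "clock_date")
}

#' @export
print.clock_date <- function(x, ...) {
  cat("Relaxed-clock dating:", ape::Ntip(x$phy), "tips,",
      length(x$traces), "runs x", x$settings$iterations, "generations",
      "(thin", x$settings$thin, ")\n")
  cat("Calibrations:", length(x$calibrations),
      " Tree prior:", x$tree_prior, "\n")
  ages <- x$summary[startsWith(x$summary$param, "age_"), ]
  cat("Posterior node ages (Ma):\n")
  print.data.frame(
    data.frame(node = sub("age_", "", ages$param),
               label = ifelse(is.na(ages$label), "", ages$label),
               mean = round(ages$mean, 3),
               hpd95 = sprintf("[%.3f, %.3f]", ages$hpd_lo, ages$hpd_hi),
               ess = round(ages$ess)),
    row.names = FALSE)
  invisible(x)
}

#' @export
summary.clock_date <- function(object, ...) object$summary

#' @export
coef.clock_date <- function(object, ...) {
  ages <- object$summary[startsWith(object$summary$param, "age_"), ]
  stats::setNames(ages$mean, sub("age_", "", ages$param))
}

#' Plot a fitted dating model
#'
#' `type = "trace"` draws the pooled root-age trace per run;
#' `type = "ltt"` the clock lineage-through-time curve at posterior mean
#' ages.
#'
#' @param x a `clock_date`.
#' @param type `"trace"` or `"ltt"`.
#' @param ... graphics arguments.
#' @export
plot.clock_date <- function(x, type = c("trace", "ltt"), ...) {
  type <- match.arg(type)
  if (type == "ltt") {
    m <- coef(x)
    names(m) <- sub("age_", "", names(m))
    plot(ltt_clock(m, x$phy), ...)
    return(invisible(x))
  }
  root_col <- paste0("age_", ape::Ntip(x$phy) + 1L)
  ys <- lapply(x$traces, function(tr) tr[, root_col])
  graphics::plot(ys[[1]], type = "l", xlab = "Sample",
                 ylab = "Root age (Ma)", ...)
  if (length(ys) > 1)
    for (i in 2:length(ys)) graphics::lines(ys[[i]], col = i)
  invisible(x)
}
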