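#' GTR+Gamma(+I) substitution model for one partition
#'
#' General time-reversible model with discrete-gamma among-site rate
#' variation and an optional invariant-sites class. Exchangeabilities are
#' relative (GT conventionally fixed at 1); the rate matrix is scaled to a
#' mean rate of 1 so branch lengths are in expected substitutions per site.
#'
#' The discrete gamma uses `n_cat` equal-probability categories represented
#' by their conditional means (so the category rates average 1). When
#' `p_inv > 0` an additional zero-rate class of weight `p_inv` is mixed in
#' and the gamma classes carry the remaining weight; the gamma category
#' rates are left on their mean-1 scale, so the model's overall mean rate
#' is `1 - p_inv` (the common "+I+G" parameterization pitfall is
#' documented rather than hidden: rates and `p_inv` are confounded and the
#' likelihood, not the scale convention, identifies them).
#'
#' @param rates named or ordered numeric of 6 exchangeabilities in the
#'   order `AC, AG, AT, CG, CT, GT`.
#' @param base_freqs numeric(4) equilibrium frequencies `A, C, G, T`
#'   (normalized; must be positive).
#' @param gamma_shape gamma shape (> 0); `Inf` disables rate variation.
#' @param n_cat number of gamma categories (default 4).
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @param name optional partition name.
#' @return A `substitution_model` with the scaled rate matrix `Q`, its
#'   eigendecomposition, and the category rates/weights.
#' @examples
#' jc <- substitution_model(rep(1, 6), rep(0.25, 4), gamma_shape = Inf)
#' @export
substitution_model <- function(rates = rep(1, 6),
                               base_freqs = rep(0.25, 4),
                               gamma_shape = 1, n_cat = 4L, p_inv = 0,
                               name = NULL) {
  if (length(rates) != 6 || any(rates <= 0))
    stop("need 6 positive exchangeabilities (AC, AG, AT, CG, CT, GT)")
  if (length(base_freqs) != 4 || any(base_freqs <= 0))
    stop("need 4 positive base frequencies (A, C, G, T)")
  base_freqs <- base_freqs / sum(base_freqs)
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  rates <- as.numeric(rates) / rates[6]

  R <- matrix(0, 4, 4)
  R[1, 2] <- R[2, 1] <- rates[1]  # AC
  R[1, 3] <- R[3, 1] <- rates[2]  # AG
  R[1, 4] <- R[4, 1] <- rates[3]  # AT
  R[2, 3] <- R[3, 2] <- rates[4]  # CG
  R[2, 4] <- R[4, 2] <- rates[5]  # CT
  R[3, 4] <- R[4, 3] <- rates[6]  # GT
  Q <- R %*% diag(base_freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu

  # symmetrize for a stable eigendecomposition
  sq <- sqrt(base_freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  evec <- diag(1 / sq) %*% eig$vectors
  ievec <- t(eig$vectors) %*% diag(sq)

  gr <- gamma_category_rates(gamma_shape, n_cat)
  if (p_inv > 0) {
    catrate <- c(0, gr)
    catw <- c(p_inv, rep((1 - p_inv) / n_cat, n_cat))
  } else {
    catrate <- gr
    catw <- rep(1 / n_cat, n_cat)
  }
  structure(list(name = name, rates = rates, base_freqs = base_freqs,
                 gamma_shape = gamma_shape, n_cat = as.integer(n_cat),
                 p_inv = p_inv, Q = Q, evec = evec, ievec = ievec,
                 eval = eig$values, catrate = catrate, catw = catw),
            class = "substitution_model")
}

# mean rate of each of k equal-probability discrete-gamma categories
# (mean-1 gamma; Yang's category-mean discretization)
gamma_category_rates <- function(shape, k) {
  if (!is.finite(shape)) return(rep(1, k))
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape,
                     rate = shape)
  p <- stats::pgamma(b, shape = shape + 1, rate = shape)
  r <- k * diff(p)
  r * (k / sum(r))  # keep exact mean 1 against quadrature round-off
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("GTR", if (is.finite(x$gamma_shape)) paste0("+G(", x$n_cat, ")"),
      if (x$p_inv > 0) "+I", "substitution model",
      if (!is.null(x$name)) paste0("[", x$name, "]"), "\n")
  cat("  exchangeabilities:", paste(signif(x$rates, 4), collapse = " "), "\n")
  cat("  base frequencies :", paste(signif(x$base_freqs, 4), collapse = " "),
      "\n")
  if (is.finite(x$gamma_shape))
    cat("  gamma shape:", x$gamma_shape, " p_inv:", x$p_inv, "\n")
  invisible(x)
}

#' Assemble a dating state
#'
#' The full parameter state of the dating model: a fixed, binary, rooted
#' topology over extant tips (tips at age 0), strictly ordered internal
#' node ages in Ma, one positive substitution rate per branch
#' (substitutions/site/Myr), the uncorrelated-lognormal clock
#' hyperparameters, per-partition substitution models, and the Yule birth
#' rate. Branch expected substitutions are `rate * (parent age - child
#' age)`.
#'
#' @param phy rooted, binary [ape::phylo] (topology is fixed during dating).
#' @param ages numeric internal node ages (Ma), ape order (`ntip+1`, ...).
#' @param branch_rates one positive rate per edge, in `phy$edge` row order.
#' @param models a [substitution_model] or list of them, one per partition.
#' @param ucld_mean real-space mean of the lognormal branch-rate prior.
#' @param ucld_sd log-space standard deviation of the rate prior.
#' @param yule_rate Yule birth rate (1/Myr).
#' @return A `dating_state` list.
#' @export
dating_state <- function(phy, ages, branch_rates, models,
                         ucld_mean = 0.01, ucld_sd = 0.3, yule_rate = 0.1) {
  validate_topology(phy)
  if (!ape::is.binary(phy)) stop("dating requires a binary topology")
  ntip <- ape::Ntip(phy)
  if (length(ages) != phy$Nnode) stop("need one age per internal node")
  if (length(branch_rates) != nrow(phy$edge) || any(branch_rates <= 0))
    stop("need one positive rate per branch")
  allages <- c(numeric(ntip), ages)
  dur <- allages[phy$edge[, 1]] - allages[phy$edge[, 2]]
  if (any(dur <= 0)) stop("parent ages must strictly exceed child ages")
  if (inherits(models, "substitution_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, TRUE, "substitution_model")))
  structure(list(phy = phy, ages = ages, branch_rates = branch_rates,
                 models = models, ucld_mean = ucld_mean, ucld_sd = ucld_sd,
                 yule_rate = yule_rate),
            class = "dating_state")
}

# compress one partition to site patterns; codes 0..3 = ACGT, 4 = missing
encode_partition <- function(m, tip_labels) {
  i <- match(tip_labels, rownames(m))
  if (anyNA(i))
    stop("alignment lacks tip(s): ",
         paste(tip_labels[is.na(i)], collapse = ", "))
  m <- m[i, , drop = FALSE]
  code <- matrix(match(toupper(m), c("A", "C", "G", "T")) - 1L, nrow = nrow(m))
  code[is.na(code)] <- 4L
  key <- apply(code, 2, paste, collapse = ",")
  u <- !duplicated(key)
  list(tipdat = code[, u, drop = FALSE],
       wts = as.numeric(table(key)[key[u]]),
       sites = ncol(m),
       site_of_pattern = match(key[u], key))
}

#' Partitioned pruning log-likelihood of a dating state
#'
#' Felsenstein pruning over compressed site patterns, summed across
#' partitions, with the discrete-gamma (and invariant-sites, where
#' `p_inv > 0`) mixture of each partition's model. Gaps and `?` (and any
#' non-ACGT symbol) are treated as missing data. Branch lengths are
#' `branch_rate * duration`; permutation of site order leaves the value
#' unchanged and duplicating a site doubles its contribution.
#'
#' @param state a [dating_state()].
#' @param alignment a [partitioned_alignment]; the number of partitions must
#'   match `state$models` (a single model is recycled).
#' @return Total log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(state, alignment) {
  stopifnot(inherits(state, "dating_state"),
            inherits(alignment, "partitioned_alignment"))
  models <- state$models
  if (length(models) == 1L && length(alignment) > 1L)
    models <- rep(models, length(alignment))
  if (length(models) != length(alignment))
    stop("number of models (", length(models),
         ") does not match partitions (", length(alignment), ")")
  enc <- lapply(alignment, encode_partition, tip_labels = state$phy$tip.label)
  sum(vapply(seq_along(enc), function(k)
    partition_loglik(state, enc[[k]], models[[k]],
                     part_name = names(alignment)[k]),
    0))
}

# internal: log-likelihood of one encoded partition
partition_loglik <- function(state, enc, model, part_name = "?") {
  phy <- ape::reorder.phylo(state$phy, "postorder")
  allages <- c(numeric(ape::Ntip(phy)), state$ages)
  # branch_rates follow state$phy edge order; remap to postorder rows
  key0 <- paste(state$phy$edge[, 1], state$phy$edge[, 2])
  keyp <- paste(phy$edge[, 1], phy$edge[, 2])
  rates <- state$branch_rates[match(keyp, key0)]
  blen <- rates * (allages[phy$edge[, 1]] - allages[phy$edge[, 2]])
  ll <- peel_loglik_cpp(phy$edge, ape::Ntip(phy), blen, enc$tipdat,
                        model$evec, model$ievec, model$eval,
                        model$base_freqs, model$catrate, model$catw)
  if (any(!is.finite(ll))) {
    bad <- enc$site_of_pattern[which(!is.finite(ll))[1]]
    stop("non-finite site likelihood in partition '", part_name,
         "' at site ", bad)
  }
  sum(enc$wts * ll)
}

#' Yule (pure-birth) log prior on internal node ages
#'
#' Density of the internal node ages of a binary tree for a Yule process
#' started with two lineages at the root, jointly with observing `n` tips
#' at the present:
#' `log p = (n - 2) log(lambda) - lambda * L`, where `L` is the total
#' lineage exposure `2 * t_root + sum(non-root ages)`. For two tips this is
#' the exponential no-further-split term `-2 lambda t_root`. Constants not
#' involving `lambda` or the ages are dropped.
#'
#' @param node_ages internal node ages (Ma); the oldest is the root.
#' @param birth_rate Yule birth rate (1/Myr).
#' @return Log-density (up to an additive constant).
#' @export
yule_log_prior <- function(node_ages, birth_rate) {
  if (birth_rate <= 0) stop("birth_rate must be positive")
  n_int <- length(node_ages)
  exposure <- max(node_ages) + sum(node_ages)
  (n_int - 1) * log(birth_rate) - birth_rate * exposure
}

#' Uncorrelated lognormal log prior on branch rates
#'
#' Independent lognormal densities for every branch rate, parameterized by
#' the real-space mean `ucld_mean` and the log-space standard deviation
#' `ucld_sd` (so the log-space location is
#' `log(ucld_mean) - ucld_sd^2 / 2`). As `ucld_sd` tends to 0 the prior
#' concentrates on the strict clock `rate = ucld_mean`.
#'
#' @param rates positive branch rates.
#' @param ucld_mean real-space mean rate (substitutions/site/Myr).
#' @param ucld_sd log-space standard deviation (> 0).
#' @return Sum of log-densities.
#' @export
rates_log_prior <- function(rates, ucld_mean, ucld_sd) {
  if (any(rates <= 0)) stop("rates must be positive")
  if (ucld_mean <= 0 || ucld_sd <= 0)
    stop("ucld_mean and ucld_sd must be positive")
  mu <- log(ucld_mean) - ucld_sd^2 / 2
  sum(stats::dlnorm(rates, meanlog = mu, sdlog = ucld_sd, log = TRUE))
}
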