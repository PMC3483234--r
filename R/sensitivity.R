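#' Enumerate the calibration-subset sensitivity design
#'
#' All `(2^k - 1)` non-empty subsets of `k` candidate calibration nodes,
#' each under both prior families, ordered as in the published design:
#' subsets by decreasing size, lexicographic within a size, with the normal
#' analysis (odd id) before the gamma one (even id). With the default
#' `k = 4` this yields the 30-analysis design.
#'
#' @param k number of candidate calibration nodes.
#' @return A list of analysis configurations, each a list with
#'   `analysis_id`, `family` (`"normal"`/`"gamma"`), and `calibrated_nodes`
#'   (integer subset of `1:k`).
#' @examples
#' length(enumerate_analyses())        # 30
#' enumerate_analyses()[[3]]           # normal, nodes {1,2,3}
#' @export
enumerate_analyses <- function(k = 4) {
  stopifnot(k >= 1)
  subsets <- unlist(lapply(seq(k, 1), function(sz)
    utils::combn(k, sz, simplify = FALSE)), recursive = FALSE)
  out <- vector("list", 2L * length(subsets))
  for (i in seq_along(subsets)) {
    out[[2L * i - 1L]] <- list(analysis_id = 2L * i - 1L, family = "normal",
                               calibrated_nodes = subsets[[i]])
    out[[2L * i]] <- list(analysis_id = 2L * i, family = "gamma",
                          calibrated_nodes = subsets[[i]])
  }
  out
}

#' Map an analysis id back to its configuration
#'
#' @param analysis_id integer in `1:(2*(2^k - 1))`.
#' @param k number of candidate nodes.
#' @return The matching configuration from [enumerate_analyses()].
#' @export
analysis_config <- function(analysis_id, k = 4) {
  cfgs <- enumerate_analyses(k)
  if (analysis_id < 1 || analysis_id > length(cfgs))
    stop("analysis_id out of range 1..", length(cfgs))
  cfgs[[analysis_id]]
}

#' Fossil-based lineage-through-time curve
#'
#' Cumulative number of lineages implied by the calibrated tree against
#' geological time, counting ghost lineages from their inferred origin (the
#' calibrated node age), not from their first appearance. Each internal
#' node of age `a` adds `(children - 1)` lineages at `a`; the curve starts
#' at 1 lineage (the root edge) and is non-decreasing toward the present.
#' The age uncertainty of each fossil yields two curves -- one at node
#' `age_lo`, one at `age_hi` -- forming an envelope.
#'
#' @param chron a [strat_calibrate()] chronogram.
#' @return An `ltt_curve` data frame with columns `age` (Ma, event ages,
#'   old to young), `n_min` (lineage count using minimum ages), and
#'   `n_max` (using maximum ages), evaluated so that `n_*(age)` is the
#'   count of lineages having originated at or before (i.e. at an age `>=`)
#'   that age.
#' @export
ltt_fossil <- function(chron) {
  stopifnot(inherits(chron, "chronogram"))
  phy <- chron$phy
  ntip <- ape::Ntip(phy)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  nkids <- tabulate(phy$edge[, 1], nbins = ntip + phy$Nnode)[nodes]
  ages <- sort(unique(c(chron$age_lo[nodes], chron$age_hi[nodes])),
               decreasing = TRUE)
  n_at <- function(node_age, t) 1L + sum(nkids[node_age >= t] - 1L)
  out <- data.frame(
    age = ages,
    n_min = vapply(ages, function(t) n_at(chron$age_lo[nodes], t), 1L),
    n_max = vapply(ages, function(t) n_at(chron$age_hi[nodes], t), 1L))
  class(out) <- c("ltt_curve", "data.frame")
  out
}

#' Clock-based lineage-through-time curve
#'
#' Step curve of cumulative lineages at posterior-mean node ages. Equal
#' mean ages produce a simultaneous (polytomy-like) jump.
#'
#' @param node_ages numeric vector of mean ages (Ma) for the internal nodes
#'   of `phy`, in ape node order (`ntip+1`, `ntip+2`, ...), or named by
#'   internal node id.
#' @param phy the fixed topology the means refer to.
#' @return An `ltt_curve` data frame with columns `age` and `n` (both
#'   curves coincide: `n_min = n_max = n`).
#' @export
ltt_clock <- function(node_ages, phy) {
  validate_topology(phy)
  ntip <- ape::Ntip(phy)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  if (!is.null(names(node_ages)))
    node_ages <- node_ages[as.character(nodes)]
  if (length(node_ages) != phy$Nnode || anyNA(node_ages))
    stop("need a mean age for every internal node")
  nkids <- tabulate(phy$edge[, 1], nbins = ntip + phy$Nnode)[nodes]
  ages <- sort(unique(node_ages), decreasing = TRUE)
  n <- vapply(ages, function(t) 1L + sum(nkids[node_ages >= t] - 1L), 1L)
  out <- data.frame(age = ages, n = n, n_min = n, n_max = n)
  class(out) <- c("ltt_curve", "data.frame")
  out
}

#' @export
plot.ltt_curve <- function(x, ...) {
  graphics::plot(x$age, x$n_min, type = "s", xlim = rev(range(x$age)),
                 xlab = "Age (Ma)", ylab = "Cumulative lineages", ...)
  if (!identical(x$n_min, x$n_max))
    graphics::lines(x$age, x$n_max, type = "s", lty = 2)
  invisible(x)
}

#' Report stratigraphic gaps in a clade's fossil record
#'
#' Bins a clade's occurrences into geologic intervals and reports, between
#' each pair of successive occupied intervals, the minimum demonstrable
#' hiatus: the younger bound of the older occupied interval minus the older
#' bound of the next-younger occupied interval, floored at 0 (overlapping
#' age uncertainty implies no demonstrable gap).
#'
#' @param occ a [occurrences] table (restrict it to the clade of interest
#'   before calling, e.g. by subsetting on taxon).
#' @param ts a [timescale] used to bin occurrences without an interval name.
#' @return A data frame with one row per successive pair of occupied
#'   intervals: `from`, `to` (interval names), `gap_min` (Myr). Zero rows
#'   when fewer than two intervals are occupied.
#' @examples
#' fx <- cavioid_fixture()
#' caviids <- fx$occurrences[fx$occurrences$fad_max <= 13.5, ]
#' gap_report(caviids, fx$timescale)   # Laventan -> Chasicoan: 2.73 Myr
#' @export
gap_report <- function(occ, ts = salma_timescale()) {
  stopifnot(inherits(occ, "fossil_occurrences"), inherits(ts, "timescale"))
  iv <- occ$interval
  fix <- is.na(iv)
  if (any(fix)) {
    # assign by containment of the FAD interval
    iv[fix] <- vapply(which(fix), function(i) {
      hit <- which(occ$fad_max[i] <= ts$age_max + 1e-9 &
                     occ$fad_min[i] >= ts$age_min - 1e-9)
      if (length(hit)) ts$name[hit[1]] else NA_character_
    }, "")
  }
  occupied <- ts$name[ts$name %in% iv]  # old -> young by ts order
  if (length(occupied) < 2L)
    return(data.frame(from = character(0), to = character(0),
                      gap_min = numeric(0)))
  older <- occupied[-length(occupied)]
  younger <- occupied[-1]
  gap <- pmax(0, ts$age_min[match(older, ts$name)] -
                ts$age_max[match(younger, ts$name)])
  data.frame(from = older, to = younger, gap_min = gap,
             stringsAsFactors = FALSE)
}

#' Run a calibration-subset sensitivity design
#'
#' Executes one relaxed-clock dating analysis per configuration of
#' [enumerate_analyses()]: the configuration's calibrated nodes get their
#' family's prior, uncalibrated nodes are left to the tree prior. Each
#' analysis uses a seed derived from `settings$seed` and its analysis id,
#' so the full table is reproducible under a fixed master seed.
#'
#' @param phy rooted binary topology.
#' @param alignment a [partitioned_alignment].
#' @param node_tips named list of tip sets defining the candidate
#'   calibration nodes (e.g. `cavioid_extant_tree()$node_tips`).
#' @param node_priors list parallel to `node_tips`; each element a list
#'   with `normal` and `gamma` [prior_spec]s for that node.
#' @param settings an [mcmc_settings()].
#' @param models substitution model(s) passed to [clock_date()].
#' @param monitor named list of tip sets for additional uncalibrated
#'   clades to report (e.g. a clade of interest).
#' @param designs analysis configurations; defaults to the full
#'   `(2^k - 1) * 2` design over `length(node_tips)` nodes.
#' @return A `sensitivity_result` data frame: one row per analysis with
#'   `analysis_id`, `family`, `calibrated_nodes`, and `mean`/`hpd_lo`/
#'   `hpd_hi` columns for every monitored node.
#' @export
run_sensitivity <- function(phy, alignment, node_tips, node_priors,
                            settings = mcmc_settings(), 
                            models = substitution_model(),
                            monitor = list(),
                            designs = enumerate_analyses(length(node_tips))) {
  stopifnot(length(node_tips) >= 1,
            length(node_priors) == length(node_tips))
  watch <- c(node_tips, monitor)
  watch_nodes <- vapply(watch, function(tp) mrca_node(phy, tp), 0L)
  rows <- lapply(designs, function(cfg) {
    cals <- lapply(cfg$calibrated_nodes, function(j)
      calibration(node_tips[[j]], node_priors[[j]][[cfg$family]]))
    s <- settings
    s$seed <- run_seed(settings$seed, 1000L + cfg$analysis_id)
    fit <- clock_date(phy, alignment, cals, models = models, settings = s)
    out <- data.frame(analysis_id = cfg$analysis_id, family = cfg$family,
                      calibrated_nodes = paste(cfg$calibrated_nodes,
                                               collapse = ","),
                      stringsAsFactors = FALSE)
    for (w in names(watch)) {
      r <- fit$summary[fit$summary$param == paste0("age_", watch_nodes[w]), ]
      out[[paste0(w, "_mean")]] <- r$mean
      out[[paste0(w, "_hpd_lo")]] <- r$hpd_lo
      out[[paste0(w, "_hpd_hi")]] <- r$hpd_hi
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("sensitivity_result", "data.frame")
  res
}

#' Per-node normal and gamma priors of the published design
#'
#' Convenience accessor pairing each of the four calibration nodes with
#' its normal- and gamma-family [prior_spec] from [table1_priors()].
#'
#' @return A list of four elements (`node1`..`node4`), each
#'   `list(normal = , gamma = )`.
#' @export
table1_node_priors <- function() {
  tp <- table1_priors()
  lapply(stats::setNames(1:4, paste0("node", 1:4)), function(j)
    list(normal = tp$analysis1[[j]], gamma = tp$analysis2[[j]]))
}
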