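#' Calibrate a topology against fossil first appearance data
#'
#' Produces a chronogram: the input tree with every node carrying a
#' conservative age interval `[age_lo, age_hi]` in Ma. A node must be at
#' least as old as the oldest first appearance among its descendants, so
#' `age_lo` is the running maximum of descendant `fad_min` and `age_hi` the
#' running maximum of descendant `fad_max`. Tip ages equal the tip's FAD
#' interval (extant tips: `[0, 0]`). Ages increase into the past.
#'
#' @param phy a rooted [ape::phylo]; polytomies are allowed.
#' @param occ a [occurrences] table covering every tip of `phy`.
#' @return A `chronogram`: a list with elements `phy`, `age_lo`, `age_hi`
#'   (numeric vectors indexed by ape node id, tips first), and `occ`.
#' @examples
#' fx <- cavioid_fixture()
#' ch <- strat_calibrate(fx$tree, fx$occurrences)
#' ch
#' @export
strat_calibrate <- function(phy, occ) {
  validate_topology(phy)
  stopifnot(inherits(occ, "fossil_occurrences"))
  miss <- setdiff(phy$tip.label, occ$taxon)
  if (length(miss))
    stop("no occurrence for tip(s): ", paste(miss, collapse = ", "))
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  i <- match(phy$tip.label, occ$taxon)
  age_lo <- age_hi <- numeric(nn)
  age_lo[seq_len(ntip)] <- occ$fad_min[i]
  age_hi[seq_len(ntip)] <- occ$fad_max[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    age_lo[p] <- max(age_lo[p], age_lo[ch])
    age_hi[p] <- max(age_hi[p], age_hi[ch])
  }
  structure(list(phy = phy, age_lo = age_lo, age_hi = age_hi,
                 occ = occ[i, , drop = FALSE]),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  ntip <- ape::Ntip(x$phy)
  root <- ntip + 1L
  cat("Chronogram:", ntip, "tips,", x$phy$Nnode, "internal nodes\n")
  cat("Root age interval: [", x$age_lo[root], ",", x$age_hi[root], "] Ma\n")
  g <- ghost_lineages(x)
  cat("Ghost lineages:", sum(g$duration_min > 0), "of", ntip,
      "tips with a demonstrable (minimum) gap; total MIG",
      round(sum(g$duration_min), 3), "Myr\n")
  invisible(x)
}

#' @export
summary.chronogram <- function(object, ...) {
  g <- ghost_lineages(object)
  out <- list(n_tip = ape::Ntip(object$phy),
              root_age = c(lo = object$age_lo[ape::Ntip(object$phy) + 1L],
                           hi = object$age_hi[ape::Ntip(object$phy) + 1L]),
              n_ghost = sum(g$is_ghost),
              mig = sum(g$duration_min),
              ghosts = g[g$is_ghost, , drop = FALSE])
  class(out) <- "summary.chronogram"
  out
}

#' @export
print.summary.chronogram <- function(x, ...) {
  cat("Chronogram with", x$n_tip, "tips; root [", x$root_age["lo"], ",",
      x$root_age["hi"], "] Ma\n")
  cat("Minimum implied gap (MIG):", round(x$mig, 3), "Myr over",
      x$n_ghost, "ghost lineages\n")
  if (nrow(x$ghosts)) print.data.frame(x$ghosts, row.names = FALSE)
  invisible(x)
}

#' Plot a chronogram with its node age intervals
#'
#' Draws the topology against age (Ma, increasing leftwards into the past)
#' placing each node at its `age_lo` and each tip at its `fad_min`, with
#' segments marking the `[age_lo, age_hi]` interval at internal nodes.
#'
#' @param x a `chronogram`.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.chronogram <- function(x, ...) {
  phy <- x$phy
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  phy$edge.length <- x$age_lo[phy$edge[, 1]] - x$age_lo[phy$edge[, 2]]
  # zero-length edges render invisibly; nudge for display only
  phy$edge.length[phy$edge.length <= 0] <- 1e-8
  ape::plot.phylo(phy, ...)
  lp <- get("last_plot.phylo", envir = ape::.PlotPhyloEnv)
  depth <- x$age_lo[root]
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  graphics::segments(depth - x$age_hi[nodes], lp$yy[nodes],
                     lp$xx[nodes], lp$yy[nodes], col = "grey60", lwd = 2)
  invisible(x)
}

#' Ghost lineage durations per terminal taxon
#'
#' A ghost lineage is the inferred existence of a lineage before its first
#' appearance in the fossil record, implied by the age of its sister lineage
#' on the calibrated tree. Per tip, the minimum duration is
#' `max(0, parent age_lo - fad_max)` (the least-commitment gap) and the
#' maximum is `parent age_hi - fad_min`.
#'
#' @param chron a [strat_calibrate()] chronogram.
#' @return A data frame with one row per tip: `taxon`, `duration_min`,
#'   `duration_max` (Myr), `origin_age_min`, `origin_age_max` (the
#'   attachment node's age interval, Ma), and `is_ghost` (FALSE when both
#'   durations are zero).
#' @export
ghost_lineages <- function(chron) {
  stopifnot(inherits(chron, "chronogram"))
  phy <- chron$phy
  ntip <- ape::Ntip(phy)
  parent <- integer(ntip)
  parent[phy$edge[phy$edge[, 2] <= ntip, 2]] <-
    phy$edge[phy$edge[, 2] <= ntip, 1]
  fad_max <- chron$age_hi[seq_len(ntip)]
  fad_min <- chron$age_lo[seq_len(ntip)]
  dmin <- pmax(0, chron$age_lo[parent] - fad_max)
  dmax <- chron$age_hi[parent] - fad_min
  data.frame(taxon = phy$tip.label,
             duration_min = dmin,
             duration_max = dmax,
             origin_age_min = chron$age_lo[parent],
             origin_age_max = chron$age_hi[parent],
             is_ghost = !(dmin == 0 & dmax == 0),
             stringsAsFactors = FALSE)
}

#' Count ghost lineages originating within a geologic interval
#'
#' Counts the branches (terminal or internal) whose attachment node has
#' `age_lo` within the interval while the subtended taxon or clade first
#' appears in the fossil record strictly after the interval (its oldest FAD
#' bound is younger than the interval's younger bound). Internal branches
#' count because a ghost lineage can lead to a whole later-appearing clade.
#'
#' @param chron a chronogram.
#' @param interval an interval name (resolved against `ts`) or a numeric
#'   `c(age_max, age_min)` pair in Ma.
#' @param ts a [timescale]; defaults to [salma_timescale()] when `interval`
#'   is a name.
#' @return Integer count.
#' @examples
#' fx <- cavioid_fixture()
#' ch <- strat_calibrate(fx$tree, fx$occurrences)
#' count_ghost_origins(ch, "Deseadan")
#' @export
count_ghost_origins <- function(chron, interval, ts = salma_timescale()) {
  stopifnot(inherits(chron, "chronogram"))
  if (is.character(interval)) interval <- interval_bounds(ts, interval)
  a_max <- max(interval); a_min <- min(interval)
  edge <- chron$phy$edge
  in_int <- chron$age_lo[edge[, 1]] >= a_min & chron$age_lo[edge[, 1]] <= a_max
  younger <- chron$age_hi[edge[, 2]] < a_min
  sum(in_int & younger)
}

#' Write a calibrated topology to NEXUS
#'
#' Internal node age intervals are carried as node labels of the form
#' `"<age_lo>_<age_hi>"` (a character set every Newick dialect preserves),
#' and tip FAD intervals as a bracketed comment block that standard readers
#' skip. The file round-trips through [read_tree()] (topology and labels)
#' and through [read_calibrated_nexus()] (full chronogram).
#'
#' @param chron a chronogram.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibrated_nexus <- function(chron, path) {
  stopifnot(inherits(chron, "chronogram"))
  phy <- chron$phy
  ntip <- ape::Ntip(phy)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  phy$node.label <- paste0(format_age(chron$age_lo[nodes]), "_",
                           format_age(chron$age_hi[nodes]))
  ape::write.nexus(phy, file = path)
  tip_block <- c("[&strataclock tip FAD intervals (taxon fad_min fad_max)",
                 paste(phy$tip.label,
                       format_age(chron$age_lo[seq_len(ntip)]),
                       format_age(chron$age_hi[seq_len(ntip)])),
                 "]")
  cat(tip_block, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

format_age <- function(x)
  vapply(x, function(v) format(v, digits = 15, trim = TRUE,
                               scientific = FALSE), "")

#' Read a calibrated NEXUS file back into a chronogram
#'
#' @param path a file written by [write_calibrated_nexus()].
#' @return A `chronogram`.
#' @export
read_calibrated_nexus <- function(path) {
  phy <- read_tree(path, format = "nexus")
  if (is.null(phy$node.label) ||
      !all(grepl("^[0-9.eE+-]+_[0-9.eE+-]+$", phy$node.label)))
    stop("file lacks the '<age_lo>_<age_hi>' node annotations")
  lab <- do.call(rbind, strsplit(phy$node.label, "_", fixed = TRUE))
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  age_lo <- age_hi <- numeric(nn)
  age_lo[(ntip + 1L):nn] <- as.numeric(lab[, 1])
  age_hi[(ntip + 1L):nn] <- as.numeric(lab[, 2])
  txt <- readLines(path)
  i0 <- grep("^\\[&strataclock tip FAD", txt)
  if (length(i0) != 1L)
    stop("file lacks the tip FAD comment block")
  i1 <- i0 + grep("^\\]", txt[(i0 + 1L):length(txt)])[1]
  rows <- strsplit(txt[(i0 + 1L):(i1 - 1L)], " ")
  tab <- do.call(rbind, rows)
  j <- match(phy$tip.label, tab[, 1])
  if (anyNA(j)) stop("tip FAD block does not cover all tips")
  age_lo[seq_len(ntip)] <- as.numeric(tab[j, 2])
  age_hi[seq_len(ntip)] <- as.numeric(tab[j, 3])
  phy$node.label <- NULL
  occ <- occurrences(phy$tip.label, fad_max = age_hi[seq_len(ntip)],
                     fad_min = age_lo[seq_len(ntip)])
  structure(list(phy = phy, age_lo = age_lo, age_hi = age_hi, occ = occ),
            class = "chronogram")
}
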