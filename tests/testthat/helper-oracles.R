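# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: trees are nested lists, optimization is exhaustive.

# all rooted binary topologies (nested lists) on a labeled tip set;
# (2n-3)!! trees: 15 for n = 4, 105 for n = 5
all_rooted_topologies <- function(tips) {
  n <- length(tips)
  if (n == 1) return(list(tips[[1]]))
  out <- list()
  first <- tips[1]
  rest <- tips[-1]
  # every split: first + subset of rest vs complement (complement non-empty)
  for (sz in 0:(n - 2)) {
    subs <- if (sz == 0) list(integer(0)) else
      utils::combn(seq_along(rest), sz, simplify = FALSE)
    for (s in subs) {
      left <- c(first, rest[s])
      right <- rest[setdiff(seq_along(rest), s)]
      for (lt in all_rooted_topologies(left))
        for (rt in all_rooted_topologies(right))
          out[[length(out) + 1L]] <- list(lt, rt)
    }
  }
  out
}

# oldest tip age in a nested-list tree
oracle_max_age <- function(tree, ages) {
  if (!is.list(tree)) return(ages[[tree]])
  max(vapply(tree, oracle_max_age, 0, ages = ages))
}

# per-tip minimum implied gap: sum over tips of (parent clade's oldest
# age - tip age)
oracle_mig <- function(tree, ages) {
  if (!is.list(tree)) return(0)
  m <- oracle_max_age(tree, ages)
  tot <- 0
  for (ch in tree) {
    if (!is.list(ch)) tot <- tot + (m - ages[[ch]])
    else tot <- tot + oracle_mig(ch, ages)
  }
  tot
}

# irreversible age-character length by exhaustive Sankoff: internal nodes
# take any observed age value; parent-to-child transitions may only get
# younger (cost = age drop) and cost Inf otherwise
oracle_debt <- function(tree, ages) {
  states <- sort(unique(unname(ages)))
  # bottom-up table of minimal subtree cost per candidate node state
  cost <- function(tr) {
    if (!is.list(tr)) {
      v <- rep(Inf, length(states))
      v[match(ages[[tr]], states)] <- 0
      return(v)
    }
    kid <- lapply(tr, cost)
    vapply(seq_along(states), function(i) {
      s <- states[i]
      tot <- 0
      for (kc in kid) {
        best <- Inf
        for (j in seq_along(states)) {
          if (states[j] > s) next          # child may not be older
          cand <- kc[j] + (s - states[j])  # pay the age drop
          if (cand < best) best <- cand
        }
        tot <- tot + best
      }
      tot
    }, 0)
  }
  min(cost(tree))
}

# newick serialization of a nested-list tree (for feeding the package)
oracle_newick <- function(tree) {
  go <- function(tr) {
    if (!is.list(tr)) return(tr)
    paste0("(", paste(vapply(tr, go, ""), collapse = ","), ")")
  }
  paste0(go(tree), ";")
}

# exhaustive (mig, g_min, g_max) over all rooted binary topologies
oracle_mig_range <- function(ages) {
  migs <- vapply(all_rooted_topologies(names(ages)), oracle_mig, 0,
                 ages = ages)
  c(g_min = min(migs), g_max = max(migs))
}

# shortest window containing ceiling(mass*n) sorted values, by full scan
oracle_hpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - m + 1))
    if (x[i + m - 1] - x[i] < best[2] - best[1])
      best <- c(x[i], x[i + m - 1])
  best
}

# small helper: a partitioned alignment from a character vector per taxon
aln_from_strings <- function(seqs) {
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(seqs)
  partitioned_alignment(list(p1 = m))
}
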