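#' Read a rooted tree from a Newick or NEXUS file
#'
#' Thin wrapper around [ape::read.tree()] / [ape::read.nexus()] that
#' validates the result as a usable topology: single tree, rooted, uniquely
#' labeled tips. Branch lengths, if present, are retained on the `phylo`
#' object. Underscores in labels are preserved verbatim (never converted to
#' spaces).
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.nex`/`.nexus`/`.trees` are NEXUS,
#'   anything else Newick), `"newick"`, or `"nexus"`.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|trees?)$", path, ignore.case = TRUE))
      "nexus" else "newick"
  }
  phy <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop("failed to parse '", path, "' as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("file contains ", length(phy), " trees; expected exactly one")
    phy <- phy[[1L]]
  }
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("failed to parse '", path, "': no tree found")
  validate_topology(phy)
}

#' Write a tree to Newick or NEXUS
#'
#' @param phy an [ape::phylo].
#' @param path output file path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(phy, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  validate_topology(phy)
  if (format == "nexus") ape::write.nexus(phy, file = path)
  else ape::write.tree(phy, file = path)
  invisible(path)
}

# shared validation for any tree entering the package
validate_topology <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  if (!ape::is.rooted(phy))
    stop("tree must be rooted")
  nn <- ape::Ntip(phy) + phy$Nnode
  if (any(phy$edge < 1L) || any(phy$edge > nn))
    stop("malformed edge matrix")
  phy
}

#' Node id of the most recent common ancestor of a tip set
#'
#' Calibrations address nodes by the MRCA of a named tip set, which is
#' stable under re-serialization (unlike node indices).
#'
#' @param phy an [ape::phylo].
#' @param tips character vector of two or more tip labels.
#' @param monophyletic if `TRUE`, error unless the tip set is exactly the
#'   clade subtended by the MRCA.
#' @return Internal node id (ape numbering).
#' @export
mrca_node <- function(phy, tips, monophyletic = FALSE) {
  miss <- setdiff(tips, phy$tip.label)
  if (length(miss))
    stop("tip(s) not in tree: ", paste(miss, collapse = ", "))
  if (length(tips) < 2L)
    stop("need at least two tips to define an MRCA")
  node <- as.integer(ape::getMRCA(phy, tips))
  if (monophyletic) {
    desc <- tips_below(phy, node)
    if (!setequal(desc, tips))
      stop("tip set is not monophyletic; MRCA also subtends: ",
           paste(setdiff(desc, tips), collapse = ", "))
  }
  node
}

# tip labels descending from a node (node itself if a tip)
tips_below <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- node
  out <- integer(0)
  edge <- phy$edge
  while (length(kids)) {
    ch <- edge[edge[, 1] %in% kids, 2]
    out <- c(out, ch[ch <= ntip])
    kids <- ch[ch > ntip]
  }
  phy$tip.label[out]
}

#' Assemble a partitioned alignment
#'
#' @param parts a named list; each element is a character matrix (rows =
#'   taxa, named; columns = sites) over the alphabet `A C G T - ?` (case
#'   insensitive; other IUPAC codes are treated as missing).
#' @return A `partitioned_alignment` object (the validated named list).
#' @export
partitioned_alignment <- function(parts) {
  if (!length(parts) || is.null(names(parts)) || any(names(parts) == ""))
    stop("'parts' must be a non-empty named list")
  taxa <- rownames(parts[[1]])
  for (nm in names(parts)) {
    m <- parts[[nm]]
    if (!is.matrix(m) || is.null(rownames(m)))
      stop("partition '", nm, "' must be a character matrix with taxon rownames")
    if (!setequal(rownames(m), taxa))
      stop("partition '", nm, "' has a different taxon set")
    parts[[nm]] <- toupper(m[taxa, , drop = FALSE])
  }
  structure(parts, class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat("Partitioned alignment:", length(x), "partition(s),",
      nrow(x[[1]]), "taxa\n")
  for (nm in names(x)) cat("  ", nm, ": ", ncol(x[[nm]]), " sites\n", sep = "")
  invisible(x)
}

#' Read a (possibly partitioned) alignment
#'
#' Reads FASTA (via [ape::read.dna()]) or sequential/interleaved NEXUS (via
#' [ape::read.nexus.data()]) and splits the concatenated matrix into named
#' partitions. Partition site ranges are 1-based inclusive on the
#' concatenated alignment and may be given directly or as a JSON file of the
#' form `{"gene": [start, end], ...}`.
#'
#' @param path alignment file path.
#' @param partitions `NULL` (single partition named `"all"`), a named list of
#'   `c(start, end)` integer pairs, or the path to a JSON partition file.
#' @param format `"auto"`, `"fasta"` or `"nexus"`.
#' @return A [partitioned_alignment].
#' @export
read_alignment <- function(path, partitions = NULL,
                           format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(nex|nexus)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  m <- if (format == "nexus") {
    d <- ape::read.nexus.data(path)
    do.call(rbind, lapply(d, toupper))
  } else {
    d <- ape::read.dna(path, format = "fasta", as.character = TRUE)
    toupper(as.matrix(d))
  }
  rownames(m) <- sub("\\s+$", "", rownames(m))
  if (is.null(partitions))
    return(partitioned_alignment(list(all = m)))
  if (is.character(partitions) && length(partitions) == 1L)
    partitions <- lapply(jsonlite::fromJSON(partitions), as.integer)
  parts <- lapply(partitions, function(rng) {
    if (length(rng) != 2L || rng[1] < 1L || rng[2] > ncol(m) || rng[1] > rng[2])
      stop("invalid partition range [", paste(rng, collapse = ", "), "]")
    m[, rng[1]:rng[2], drop = FALSE]
  })
  partitioned_alignment(parts)
}

#' Write an alignment to FASTA
#'
#' Partitions are concatenated in list order.
#'
#' @param aln a [partitioned_alignment].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  m <- do.call(cbind, unname(aln))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m)))
    writeLines(c(paste0(">", rownames(m)[i]),
                 paste(m[i, ], collapse = "")), con)
  invisible(path)
}
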