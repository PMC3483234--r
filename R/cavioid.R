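# The packaged caviomorph-rodent worked example: a partial Cavioidea s.s.
# topology with first appearance data binned to SALMAs. The tree encodes
# only relationships documented in the group's phylogenetic literature
# (e.g. Chubutomys simpsoni nested above the Colhuehuapian Luantus species,
# Prodolichotis pridiana sister to Hydrochoerinae); relationships without a
# documented resolution are left as polytomies, so the fixture is
# deliberately partial.

#' The caviomorph (Cavioidea s.s.) worked example
#'
#' A 32-tip partial topology of Cavioidea s.s. -- the South American clade
#' of cavies, maras and capybaras plus its extinct stem ("eocardiids") --
#' with the first appearance datum of each fossil taxon binned to a South
#' American Land Mammal Age and extant tips at the present. Calibrating
#' this tree reproduces the group's three diversification phases: a late
#' Oligocene (Deseadan) radiation revealed by four ghost lineages of taxa
#' first recorded in the Colhuehuapian, an early Miocene (Santacrucian)
#' radiation of euhypsodont forms with three ghost lineages leading to
#' Colloncuran taxa, and the diversification of crown Caviidae interrupted
#' by a late middle Miocene gap in the fossil record (the Mayoan gap).
#'
#' @return A list: `tree` ([ape::phylo]), `occurrences`
#'   (a [occurrences] table), `timescale` ([salma_timescale()]).
#' @examples
#' fx <- cavioid_fixture()
#' ch <- strat_calibrate(fx$tree, fx$occurrences)
#' count_ghost_origins(ch, "Deseadan")      # 4
#' count_ghost_origins(ch, "Santacrucian")  # 3
#' @export
cavioid_fixture <- function() {
  ts <- salma_timescale()
  tree <- read_tree(system.file("extdata", "cavioid_tree.nwk",
                                package = "strataclock", mustWork = TRUE))
  occ <- read_occurrences(system.file("extdata", "cavioid_occurrences.tsv",
                                      package = "strataclock",
                                      mustWork = TRUE), ts = ts)
  list(tree = tree, occurrences = occ, timescale = ts)
}

#' Extant-taxon cavioid topology for molecular dating
#'
#' The nine-tip extant topology used by the dating examples: Echimyidae
#' (*Proechimys*) roots the tree, then Dasyproctidae, Cuniculidae, and
#' crown Caviidae with Caviinae sister to Dolichotinae + Hydrochoerinae.
#' The four conventional calibration nodes are the MRCAs of:
#' node 1 (Cavioidea) all tips but *Proechimys*; node 2 (Cavioidea s.s. +
#' *Cuniculus*) all tips but *Proechimys* and *Dasyprocta*; node 3
#' *Kerodon* + *Hydrochoerus*; node 4 *Microcavia* + *Cavia*.
#'
#' @return A list: `tree` (binary rooted [ape::phylo]) and `node_tips`
#'   (list of the four calibration tip sets, named `node1`..`node4`).
#' @export
cavioid_extant_tree <- function() {
  tree <- ape::read.tree(text = paste0(
    "(Proechimys,(Dasyprocta,(Cuniculus_paca,((Galea_musteloides,",
    "(Cavia_aperea,Microcavia_australis)),(Dolichotis_patagonum,",
    "(Kerodon_rupestris,Hydrochoerus_hydrochaeris))))));"))
  tips <- tree$tip.label
  list(tree = tree,
       node_tips = list(
         node1 = setdiff(tips, "Proechimys"),
         node2 = setdiff(tips, c("Proechimys", "Dasyprocta")),
         node3 = c("Kerodon_rupestris", "Hydrochoerus_hydrochaeris"),
         node4 = c("Microcavia_australis", "Cavia_aperea")))
}

#' Published alignment partition lengths
#'
#' The aligned lengths of the four genes of the worked example: 961 bp
#' (12s), 1140 bp (cyb), 1099 bp (Tth), 814 bp (Ghr).
#'
#' @return Named integer vector of partition lengths.
#' @export
cavioid_partitions <- function() {
  c(`12s` = 961L, cyb = 1140L, Tth = 1099L, Ghr = 814L)
}

#' Combined-matrix bookkeeping for the worked example
#'
#' @return A list: `genes` (partition lengths), `n_morphology` (96
#'   discrete characters), `n_molecular` (sum of gene lengths) and
#'   `n_total` (molecular + morphology).
#' @export
cavioid_matrix_size <- function() {
  g <- cavioid_partitions()
  list(genes = g, n_morphology = 96L,
       n_molecular = sum(g), n_total = sum(g) + 96L)
}
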