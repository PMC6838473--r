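# Molfile fixtures built in code, a seeded random-molecule generator, and a
# small hand-built reaction database used across tests.

mol_counts_line <- function(na, nb) sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
mol_atom_line <- function(el) sprintf(
  "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0", 0, 0, 0, el)
mol_bond_line <- function(a, b, t) sprintf("%3d%3d%3d  0  0  0  0", a, b, t)

make_molfile <- function(name, elements, bonds) {
  # bonds: matrix/data.frame with 1-based a, b and numeric type
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  c(name, "  test", "",
    mol_counts_line(length(elements), nb),
    vapply(elements, mol_atom_line, character(1)),
    if (nb > 0) vapply(seq_len(nb), function(k)
      mol_bond_line(bonds[k, 1], bonds[k, 2], bonds[k, 3]), character(1)),
    "M  END")
}

methane_molfile <- function() make_molfile(
  "methane", c("C", "H", "H", "H", "H"),
  cbind(1, 2:5, 1))

ethanol_molfile <- function() make_molfile(
  "ethanol", c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
  rbind(c(1, 2, 1), c(2, 3, 1),
        c(1, 4, 1), c(1, 5, 1), c(1, 6, 1),
        c(2, 7, 1), c(2, 8, 1), c(3, 9, 1)))

benzene_molfile <- function() make_molfile(
  "benzene", rep("C", 6),
  rbind(c(1, 2, 4), c(2, 3, 4), c(3, 4, 4), c(4, 5, 4), c(5, 6, 4), c(6, 1, 4)))

ethanol_graph <- function() compound_graph(
  "eth", c("C", "C", "O"),
  data.frame(a = c(0, 1), b = c(1, 2), order = c("1", "1")))

acetaldehyde_graph <- function() compound_graph(
  "ald", c("C", "C", "O"),
  data.frame(a = c(0, 1), b = c(1, 2), order = c("1", "2")))

# random connected molecule: spanning tree + optional extra edge
random_test_graph <- function(n, id = "G") {
  elems <- sample(c("C", "C", "N", "O"), n, replace = TRUE)
  if (n == 1L) return(compound_graph(id, elems))
  a <- integer(); b <- integer(); ord <- character()
  for (k in 2:n) {
    a <- c(a, sample.int(k - 1L, 1L) - 1L); b <- c(b, k - 1L)
    ord <- c(ord, sample(c("1", "1", "2"), 1L))
  }
  if (n >= 4L && runif(1) < 0.4) {
    pr <- sort(sample.int(n, 2L)) - 1L
    if (!any(a == pr[1] & b == pr[2])) {
      a <- c(a, pr[1]); b <- c(b, pr[2]); ord <- c(ord, "1")
    }
  }
  compound_graph(id, elems, data.frame(a = a, b = b, order = ord))
}

# minimal consistent database: 3 plant-only reactions, 1 shared, 1 plant
# orphan, 1 bacteria-only reaction
tiny_db <- function() {
  cmp <- list(
    compound_graph("C1", c("C", "C", "O"),
                   data.frame(a = c(0, 1), b = c(1, 2), order = c("1", "1"))),
    compound_graph("C2", c("C", "C", "O"),
                   data.frame(a = c(0, 1), b = c(1, 2), order = c("1", "2"))))
  orgs <- list(
    organism("ath", "Arabidopsis-like plant", "plant"),
    organism("osa", "Rice-like plant", "plant"),
    organism("sco", "Streptomyces-like bacterium", "bacteria",
             lineage = c("Bacteria", "Actinobacteria", "Streptomycetaceae")),
    organism("eco", "Enteric bacterium", "bacteria"))
  cl <- list(
    ortholog_cluster("OC1", data.frame(organism = c("ath", "osa"),
                                       gene = c("ATH_1", "OSA_1")),
                     "K11111: plant oxidase"),
    ortholog_cluster("OC2", data.frame(organism = "ath", gene = "ATH_2")),
    ortholog_cluster("OC3", data.frame(organism = c("ath", "sco"),
                                       gene = c("ATH_3", "SCO_1"))),
    ortholog_cluster("OC4", data.frame(organism = c("sco", "eco"),
                                       gene = c("SCO_2", "ECO_1")),
                     "K22222: bacterial monooxygenase"))
  rx <- list(
    reaction_record("R01", "C1", "C2", ec = "1.1.1.1", cluster_ids = "OC1"),
    reaction_record("R02", "C1", "C2", cluster_ids = c("OC1", "OC2")),
    reaction_record("R03", "C2", "C1", cluster_ids = "OC2"),
    reaction_record("R04", "C1", "C2", cluster_ids = "OC3"),   # shared
    reaction_record("R05", "C2", "C1", pathway_taxa = "plant"),  # orphan
    reaction_record("R06", "C1", "C2", ec = "1.14.13.1", cluster_ids = "OC4"))
  reaction_db(cmp, rx, cl, orgs, provenance = "tiny fixture")
}
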