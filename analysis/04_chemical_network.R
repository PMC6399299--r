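#!/usr/bin/env Rscript
# Chemical similarity network: circular fingerprints over four homologue
# families, edges at Tc > 0.75, nodes colored by PFS bands (high_sim
# below -3, low_sim above -2). The families should resolve into four
# connected components.

suppressMessages(library(pocketscreen))
dir.create("results", showWarnings = FALSE)

fam <- list(
  alkane = c("CCCCCCCC", "CCCCCCCCC", "CCCCCCCCCC"),
  alcohol = c("OCCCCCCCC", "OCCCCCCCCC", "OCCCCCCCCCC"),
  diamine = c("NCCCCCCCN", "NCCCCCCCCN", "NCCCCCCCCCN"),
  thiol = c("SCCCCCCCC", "SCCCCCCCCC", "SCCCCCCCCCC")
)
cmp <- data.frame(ligand_id = paste0(rep(names(fam), each = 3), 1:3),
                  smiles = unlist(fam))
set.seed(31)
pfs_map <- setNames(runif(nrow(cmp), -4.5, -1), cmp$ligand_id)

net <- build_network(cmp, pfs_map = pfs_map, tc_threshold = 0.75)
print(net)
comp <- igraph::components(net$graph)
message("connected components: ", comp$no,
        " (planted scaffold families: ", length(fam), ")")
message("node color classes: ",
        paste(names(table(net$nodes$color_class)),
              table(net$nodes$color_class), collapse = ", "))

write_network(net, "results/compound_network.graphml", "graphml")
write_network(net, "results/compound_network_edges.tsv", "tsv")
message("wrote results/compound_network.graphml and edge/node TSVs")
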