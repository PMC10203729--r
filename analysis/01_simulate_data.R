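#!/usr/bin/env Rscript
# Generate the synthetic study data every later step consumes: a branching
# 10-timepoint differentiation time course with planted lineage truth, and
# a 3D spatially resolved reference with planted query cells.
# Outputs under results/data/.

suppressMessages(library(germmap))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

params <- synth_params(seed = 7)
message("Simulating the branching time course (",
        length(params$timepoints_h), " timepoints, ",
        params$n_lineages, " terminal lineages, ",
        params$n_cells_per_cluster, " cells/cluster) ...")
sim <- simulate_timecourse(params)
message("  ", n_cells(sim$cells), " cells x ", length(sim$cells$gene_ids),
        " genes; clusters: ",
        paste(unique(sim$cells$meta$cluster), collapse = ", "))

write_counts_mtx(sim$cells, file.path(out, "timecourse"))
write_table(sim$cells$meta, file.path(out, "timecourse_meta.tsv"))
write_embedding(sim$emb, file.path(out, "timecourse_embedding.csv"))
write_table(sim$tree$edges, file.path(out, "planted_tree_edges.tsv"))
markers <- planted_markers(sim)
write_table(data.frame(gene = unlist(markers),
                       lineage = rep(names(markers), lengths(markers))),
            file.path(out, "planted_markers.tsv"))

message("Simulating the 3D spatial reference and planted queries ...")
ref <- simulate_spatial_reference(params)
q <- plant_query(params, ref, n_per_lineage = 500)
ref_tab <- data.frame(cell_id = ref$embedding$cell_ids,
                      ref$positions, label = ref$labels,
                      ref$embedding$coords)
write_table(ref_tab, file.path(out, "spatial_reference.tsv"))
write_embedding(q$emb, file.path(out, "query_embedding.csv"))
write_table(data.frame(cell_id = q$emb$cell_ids, lineage = q$true_labels),
            file.path(out, "query_truth.tsv"))

message("Done. Planted tree has ", nrow(sim$tree$edges), " edges; ",
        "reference spans x in [", round(min(ref$positions[, 1])), ", ",
        round(max(ref$positions[, 1])), "] with domains ordered ",
        paste(rownames(ref$domain_centroids), collapse = " -> "), ".")
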