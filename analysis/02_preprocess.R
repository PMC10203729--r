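#!/usr/bin/env Rscript
# End-to-end preprocessing of the simulated counts: logCP10k normalization,
# highly-variable-gene selection and a 50-PC embedding — the expression-side
# route into the pipeline (the lineage analyses can also use the generator's
# latent embedding directly).

suppressMessages(library(germmap))

data_dir <- "results/data"
if (!file.exists(file.path(data_dir, "timecourse", "matrix.mtx")))
  stop("run analysis/01_simulate_data.R first")

cells <- read_counts_mtx(file.path(data_dir, "timecourse", "matrix.mtx"),
                         file.path(data_dir, "timecourse", "genes.tsv"),
                         file.path(data_dir, "timecourse", "barcodes.tsv"))
cells <- read_metadata(file.path(data_dir, "timecourse_meta.tsv"), cells)

message("Normalizing ", n_cells(cells), " cells (logCP10k) ...")
norm <- normalize_logcp10k(cells)
message("  ", sum(norm$zero_cells), " zero-count cells flagged")

n_hvg <- 500
hvg <- select_hvg(norm, n_hvg)
markers <- read_table_auto(file.path(data_dir, "planted_markers.tsv"))
marker_idx <- match(markers$gene, cells$gene_ids)
hit <- mean(marker_idx %in% hvg)
message("Selected ", n_hvg, " HVGs; ", round(100 * hit, 1),
        "% of planted lineage markers are among them.")

emb <- pca_embed(norm, hvg, n_pcs = 50)
ev <- attr(emb, "explained_variance")
message("PCA: first 5 components explain ",
        round(100 * sum(ev[1:5]), 1), "% of variance.")

dir.create("results", showWarnings = FALSE)
write_embedding(emb, "results/timecourse_pca50.csv")
write_table(data.frame(component = seq_along(ev), explained_variance = ev),
            "results/pca_explained_variance.csv")
write_table(data.frame(gene = cells$gene_ids[hvg]), "results/hvg_genes.csv")
message("Wrote results/timecourse_pca50.csv")
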