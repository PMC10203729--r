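#!/usr/bin/env Rscript
# Transfer reference lineage annotations onto the planted query cells by
# KNN hypergeometric enrichment, and benchmark against the held-out truth.

suppressMessages(library(germmap))

data_dir <- "results/data"
ref_tab <- read_table_auto(file.path(data_dir, "spatial_reference.tsv"))
emb_cols <- grep("^V|^X|^PC|^[0-9]", names(ref_tab), value = TRUE)
emb_cols <- setdiff(names(ref_tab), c("cell_id", "x", "y", "z", "label"))
ref_emb <- embedding(as.matrix(ref_tab[, emb_cols]), ref_tab$cell_id,
                     "aligned")
query <- read_embedding(file.path(data_dir, "query_embedding.csv"), "aligned")
truth <- read_table_auto(file.path(data_dir, "query_truth.tsv"))

message("Transferring ", length(unique(ref_tab$label)),
        " reference annotations onto ", nrow(query$coords),
        " query cells (k = 20, alpha = 0.05) ...")
out <- transfer_labels(query, ref_emb, ref_tab$label, k = 20, alpha = 0.05)

stopifnot(identical(out$cell_id, truth$cell_id))
correct <- mean(out$assigned_label == truth$lineage)
wrong <- mean(out$assigned_label != truth$lineage &
              out$assigned_label != UNASSIGNED)
unas <- mean(out$assigned_label == UNASSIGNED)
message(sprintf("  correct %.2f%%  wrong %.2f%%  unassigned %.2f%%",
                100 * correct, 100 * wrong, 100 * unas))

write_table(out, "results/label_assignments.tsv")
write_table(data.frame(metric = c("correct_pct", "wrong_pct",
                                  "unassigned_pct"),
                       value = 100 * c(correct, wrong, unas)),
            "results/label_transfer_summary.csv")
message("Wrote results/label_assignments.tsv")
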