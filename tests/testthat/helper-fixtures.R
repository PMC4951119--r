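# Small in-code fixtures shared across test files.

# write a matrix + annotation TSV pair for a hand-made dataset and return
# the two paths
write_fixture_tsvs <- function(values, regions, individual_id = "A",
                               dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "matrix.tsv")
  ap <- file.path(dir, "annotation.tsv")
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample_id = colnames(values),
                    individual_id = individual_id, region = regions)
  write.table(ann, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, annotation = ap)
}

# a dataset with given per-region counts and deterministic filler values
region_count_dataset <- function(individual_id, bs, cb, cc, n_genes = 3L) {
  S <- bs + cb + cc
  values <- matrix(seq_len(n_genes * S) / 7, n_genes, S,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("%s_s%03d", individual_id,
                                           seq_len(S))))
  expression_dataset(individual_id, values,
                     rep(c("BS", "CB", "CC"), c(bs, cb, cc)))
}

# the six-donor cohort shape used throughout
table1_counts <- function() default_cohort_counts()

# small multi-individual planted cohort for pipeline-level tests
small_cohort_config <- function(seed = 11L, n_genes = 150L,
                                n_planted = 3L, effect = 3) {
  cohort_config(
    n_genes = n_genes,
    per_individual_counts = list(A = c(8L, 8L, 8L), B = c(6L, 10L, 8L),
                                 C = c(8L, 6L, 10L)),
    n_planted_per_region = n_planted, effect_size = effect,
    batch_sd = 0.3, noise_sd = 1, seed = seed)
}
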