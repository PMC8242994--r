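# Shared fixtures, built in code at test time.

# a fully populated table of `n` drugs following the default schema
make_table_df <- function(n = 3, seed = 1, labels = NULL) {
  sc <- default_schema()
  set.seed(seed)
  df <- as.data.frame(matrix(round(rnorm(n * 47), 4), n, 47))
  names(df) <- c(sc$chemical_columns, sc$target_columns)
  df <- cbind(drug_id = sprintf("D%03d", seq_len(n)), df)
  df[[sc$label_column]] <- labels %||%
    rep(c("approved", "failed"), length.out = n)
  df
}

write_table_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# a small imputed synthetic dataset with both classes
make_small_dataset <- function(n = 120, ratio = 3, seed = 99, ...) {
  generate_bimodal(sim_config(n = n, imbalance_ratio = ratio,
                              missing_frac = 0, seed = seed, ...))
}
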