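# Small shared fixtures, generated once per test run.

shared_config <- generator_config(seed = 101)
shared_feats <- generate_feature_dataset(20, config = shared_config)
shared_weights <- relieff_weights(shared_feats, k_neighbors = 5)
shared_sel <- select_top_per_channel(shared_weights)
shared_fit <- train_bpnn(project_features(shared_feats, shared_sel),
                         iterations = 1500, seed = 7)

# Concatenate recordings end to end, keeping the first one's metadata.
concat_recordings <- function(...) {
  recs <- list(...)
  df <- dplyr::bind_rows(lapply(recs, function(r) r[-1]))
  fs <- attr(recs[[1]], "sampling_rate")
  df <- dplyr::bind_cols(tibble::tibble(t = (seq_len(nrow(df)) - 1) / fs), df)
  structure(df, sampling_rate = fs, movement = NA_character_, load = NA_real_,
            class = class(recs[[1]]))
}
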