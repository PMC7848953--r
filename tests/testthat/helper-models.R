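# Shared, lazily trained models reused across test files to keep the suite
# runtime down. Each entry is trained once per session under a fixed seed.
.model_cache <- new.env(parent = emptyenv())

cached_model <- function(name, builder) {
  if (is.null(.model_cache[[name]])) .model_cache[[name]] <- builder()
  .model_cache[[name]]
}

# A trained conditioning RNN: a 2e5-batch prefix of the reference 3e5-batch
# schedule (the learning rate must still be high when the recurrent weights
# escape their initial plateau, so the decay is truncated, not compressed).
trained_rnn <- function() {
  cached_model("rnn", function() {
    set.seed(9001)
    train_rnn(train_schedule(2e5, 1e-2, 1e-4, gamma = 0.9),
              anneal_horizon = 3e5, loss_every = 1e4L)
  })
}
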