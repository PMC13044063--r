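# Shared, lazily-built test fixtures. The smoke-training run is the expensive
# one (~1 minute); it is trained once per test session and reused by the
# training and Grad-CAM tests.

.fixture_cache <- new.env(parent = emptyenv())

smoke_dataset <- function() {
  if (is.null(.fixture_cache$ds)) {
    ds <- generate_garlic_dataset(60, image_size = 64, seed = 42)
    .fixture_cache$ds <- split_plan(ds, seed = 42)
  }
  .fixture_cache$ds
}

# Reduced-width DH-GarlicNet trained for 5 epochs on the 180-image synthetic
# set under the published optimizer settings (batch 8, SGD, lr 0.01).
smoke_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    plan <- smoke_dataset()
    net <- build_model("dh_garlicnet", num_classes = 3, width = 8,
                       input_size = 64, seed = 42)
    cfg <- train_config(input_size = 64, batch_size = 8, lr = 0.01,
                        epochs = 5, seed = 42)
    .fixture_cache$fit <- suppressWarnings(garlic_train(
      net,
      plan[plan$partition == "train", ],
      plan[plan$partition == "val", ],
      cfg
    ))
  }
  .fixture_cache$fit
}
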