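# Shared fixtures. Trained models are expensive, so they are built lazily
# once per test run and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# annotated complete wings for tier-2 training (96 x 120 canvas)
landmark_wings <- function() {
  fixture("landmark_wings", function() {
    wings <- generate_wing_batch(500, canvas = c(96, 120), p_incomplete = 0,
                                 seed = 11)
    split_dataset(wings, seed = 12)
  })
}

regression_fit <- function() {
  fixture("regression_fit", function() {
    wings <- landmark_wings()
    cfg <- landmark_config("regression", seed = 5,
                           schedule = list(list(epochs = 60, lr = 1e-3),
                                           list(epochs = 20, lr = 1e-4)))
    train_landmark_model(wings[wings$split == "train", ],
                         wings[wings$split == "val", ], cfg)
  })
}

regression_fit_noaug <- function() {
  fixture("regression_fit_noaug", function() {
    wings <- landmark_wings()
    cfg <- landmark_config("regression", seed = 5,
                           schedule = list(list(epochs = 60, lr = 1e-3),
                                           list(epochs = 20, lr = 1e-4)),
                           augment = aug_config(enabled = FALSE))
    train_landmark_model(wings[wings$split == "train", ],
                         wings[wings$split == "val", ], cfg)
  })
}

segmentation_fit <- function() {
  fixture("segmentation_fit", function() {
    wings <- landmark_wings()
    cfg <- landmark_config("segmentation", seed = 5,
                           schedule = list(list(epochs = 40, lr = 1e-3)))
    train_landmark_model(wings[wings$split == "train", ],
                         wings[wings$split == "val", ], cfg)
  })
}

# curated balanced wings for tier-1 training
classifier_wings <- function() {
  fixture("classifier_wings", function() {
    wings <- generate_wing_batch(900, canvas = c(96, 120), p_incomplete = 0.5,
                                 seed = 21)
    split_dataset(wings, stratify = "label", seed = 22)
  })
}

classifier_fit <- function() {
  fixture("classifier_fit", function() {
    wings <- classifier_wings()
    cfg <- classifier_config(input_size = 32, epochs = 40, lr = 1e-3,
                             batch_size = 16, seed = 8)
    train_classifier(build_classifier(cfg), wings[wings$split == "train", ],
                     wings[wings$split == "val", ], cfg)
  })
}

test_truth_table <- function() {
  wings <- landmark_wings()
  te <- wings[wings$split == "test", ]
  landmark_table(te$landmarks, te$name)
}

# small deterministic landmark sets for geometry tests
toy_shape <- function(seed = 1, scale = 1) {
  set.seed(seed)
  matrix(stats::rnorm(22, sd = scale), 11, 2)
}
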