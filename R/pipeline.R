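#' End-to-end two-tier workflow
#'
#' Wires the modules into the full pipeline: simulate (or load) wings,
#' train the tier-1 classifier and a tier-2 landmark head, gate landmark
#' prediction on the classifier (incomplete wings never reach tier 2),
#' evaluate pixel errors against ground truth, run the shape-bias
#' regression, and check image-to-record alignment page by page.
#'
#' @name pipeline
NULL

#' Stratified train/validation/test split
#'
#' Splits a wing table into disjoint train/validation/test sets (default
#' 60:20:20), stratified by a label column so both classes appear in every
#' split.
#'
#' @param data tibble of wings.
#' @param fractions length-3 numeric summing to 1.
#' @param stratify optional column name to stratify on.
#' @param seed integer seed.
#' @return the tibble with an added `split` factor column.
#' @export
split_dataset <- function(data, fractions = c(0.6, 0.2, 0.2),
                          stratify = NULL, seed = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stop_wingmark("split fractions must sum to 1")
  with_seed(seed, {
    assign_split <- function(n) {
      k <- c(train = floor(fractions[1] * n), val = floor(fractions[2] * n))
      k <- c(k, test = n - sum(k))
      sample(rep(c("train", "val", "test"), times = k))
    }
    if (is.null(stratify)) {
      data$split <- assign_split(nrow(data))
    } else {
      data$split <- NA_character_
      for (g in unique(data[[stratify]])) {
        idx <- which(data[[stratify]] == g)
        data$split[idx] <- assign_split(length(idx))
      }
    }
    data$split <- factor(data$split, levels = c("train", "val", "test"))
    data
  })
}

#' Two-tier gated prediction
#'
#' Classifies every image; wings scored incomplete are rejected (listed
#' with their scores, never sent to tier 2), the remainder get landmark
#' predictions. Right-wing images must be flipped to left orientation
#' before calling (both tiers see left-oriented wings only).
#'
#' @param images list of H x W image matrices.
#' @param names image names.
#' @param classifier_fit a trained `wing_classifier_fit`.
#' @param landmark_fit a trained `landmark_fit`.
#' @param threshold classifier score threshold.
#' @return list with `landmarks` (landmark table for accepted wings),
#'   `rejected` (tibble `name, score`), and `counts`
#'   (`n_total, n_accepted, n_rejected`).
#' @export
two_tier_predict <- function(images, names, classifier_fit, landmark_fit,
                             threshold = 0.5) {
  if (is.null(classifier_fit$model) || is.null(landmark_fit$model)) {
    stop_wingmark("both tier-1 and tier-2 models must be trained")
  }
  cls <- predict_classifier(classifier_fit, images, names = names,
                            threshold = threshold)
  keep <- cls$label == 0L
  landmarks <- if (any(keep)) {
    predict_landmarks(landmark_fit, images[keep], names = names[keep])
  } else {
    landmark_table(list(), character())
  }
  list(
    landmarks = landmarks,
    rejected = dplyr::select(cls[!keep, ], "name", "score"),
    counts = c(n_total = length(images), n_accepted = sum(keep),
               n_rejected = sum(!keep))
  )
}

#' Run the full desk-scale workflow on synthetic wings
#'
#' Generates a labelled synthetic wing set, trains tier 1 and a tier-2
#' head, runs the gated prediction on the test split, and returns all
#' stage outputs. Intended for demonstration and end-to-end testing at
#' reduced resolution; every stage is reproducible from `seed`.
#'
#' @param n_wings size of the annotated complete-wing set for tier-2
#'   training.
#' @param n_classifier size of the curated, class-balanced set used to
#'   train tier 1 (labelled separately from the deployment pool, as the
#'   reference workflow curates its classification training data).
#' @param n_deploy size of the unannotated deployment pool the gate runs
#'   on.
#' @param p_incomplete incomplete fraction in the deployment pool.
#' @param canvas `(H, W)` canvas size.
#' @param head tier-2 head.
#' @param seed integer seed fixing generation, splits, initialisation,
#'   augmentation and bootstrap draws.
#' @param classifier_epochs,landmark_schedule optional overrides for the
#'   desk-scale training lengths.
#' @return list with the fitted models, the test-set error summary, the
#'   baseline summary, shape-bias regression, and counts from the gate.
#' @export
run_wing_workflow <- function(n_wings = 500L, n_classifier = 900L,
                              n_deploy = 200L, p_incomplete = 0.13,
                              canvas = c(96L, 120L),
                              head = "regression", seed = 1L,
                              classifier_epochs = 40L,
                              landmark_schedule = NULL) {
  # tier 1: curated balanced training set
  cls_wings <- generate_wing_batch(n_classifier, canvas = canvas,
                                   p_incomplete = 0.5,
                                   seed = child_seed(seed, 1))
  cls_wings <- split_dataset(cls_wings, stratify = "label",
                             seed = child_seed(seed, 2))
  ccfg <- classifier_config(epochs = classifier_epochs, lr = 1e-3,
                            batch_size = 16L, seed = child_seed(seed, 3))
  cls_fit <- train_classifier(build_classifier(ccfg),
                              cls_wings[cls_wings$split == "train", ],
                              cls_wings[cls_wings$split == "val", ], ccfg)

  # tier 2: annotated complete wings only
  complete <- generate_wing_batch(n_wings, canvas = canvas, p_incomplete = 0,
                                  seed = child_seed(seed, 4))
  complete <- split_dataset(complete, seed = child_seed(seed, 5))
  lcfg <- landmark_config(head = head, seed = child_seed(seed, 6),
                          schedule = landmark_schedule)
  lmk_fit <- train_landmark_model(complete[complete$split == "train", ],
                                  complete[complete$split == "val", ], lcfg)

  # deployment pool through the two-tier gate
  deploy <- generate_wing_batch(n_deploy, canvas = canvas,
                                p_incomplete = p_incomplete,
                                seed = child_seed(seed, 7))
  gate <- two_tier_predict(deploy$image, deploy$name, cls_fit, lmk_fit)

  test_complete <- complete[complete$split == "test", ]
  pred <- predict_landmarks(lmk_fit, test_complete$image, test_complete$name)
  truth <- landmark_table(test_complete$landmarks, test_complete$name)
  errors <- distance_errors(pred, truth)

  base <- baseline_mean_location(complete$landmarks[complete$split == "train"])
  base_errors <- distance_errors(predict_baseline(base, test_complete$name), truth)

  gpa <- generalized_procrustes(truth)
  bias <- bias_regression(gpa, per_image_mean_error(pred, truth))

  list(classifier = cls_fit, landmark_model = lmk_fit, gate = gate,
       deploy = deploy, errors = errors, baseline_errors = base_errors,
       shape_bias = bias, annotated = complete)
}
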