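## domain_tuner module (part 2): fitting theta to reference frames by
## maximizing embedding cosine similarity, and the generic few-shot
## segmenter-adaptation harness.

#' Tuner configuration
#'
#' Defaults mirror the standard protocol: 1000 trials and the top
#' k = 10 retained candidates.  The shipped sampler is seeded random
#' search; the `sampler` tag exists so an adaptive (TPE-style) sampler
#' can be plugged in behind the same interface.
#'
#' @param n_trials number of objective evaluations (>= 1).
#' @param top_k candidates to retain (1 <= top_k <= n_trials).
#' @param sampler `"random"` (shipped) or a custom tag.
#' @param seed master seed for the whole run.
#' @return an object of class `tuner_config`.
#' @export
tuner_config <- function(n_trials = 1000L, top_k = 10L,
                         sampler = "random", seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (top_k < 1 || top_k > n_trials) stop("need 1 <= top_k <= n_trials")
  structure(list(n_trials = as.integer(n_trials), top_k = as.integer(top_k),
                 sampler = sampler, seed = as.integer(seed)),
            class = "tuner_config")
}

#' Embedding-similarity objective for one parameter vector
#'
#' Generates one sample image from `theta` under `seed`, embeds it and
#' every reference frame with the backend, and scores the trial as the
#' maximum cosine similarity across the references — the chosen
#' parameters must be plausible for at least one representative frame,
#' not for their average.
#'
#' @param theta a valid `theta_params`.
#' @param refs a `reference_set`.
#' @param backend an `embedding_backend`.
#' @param seed seed for the generated sample.
#' @return an object of class `trial_record`: `theta`, `objective`
#'   (= max of `similarities`), per-reference `similarities`, `seed`.
#' @export
tune_objective <- function(theta, refs, backend, seed) {
  smp <- generate_sample(theta, seed)
  e_syn <- backend$embed(smp$image)
  sims <- vapply(refs$images, function(im)
    cosine_similarity(e_syn, backend$embed(im)), numeric(1))
  structure(list(theta = theta, objective = max(sims),
                 similarities = sims, trial = NA_integer_, seed = seed),
            class = "trial_record")
}

#' Fit theta to reference frames
#'
#' Runs `n_trials` evaluations of [tune_objective()] with parameter
#' vectors drawn from the search space by the configured sampler, and
#' returns the `top_k` trial records sorted by non-increasing objective.
#' The full trial log is attached as the `"log"` attribute (and written
#' as JSON-lines when `log_path` is given).  Runs are exactly
#' reproducible under a fixed master seed.
#'
#' @param space a valid `search_space`.
#' @param refs a `reference_set`.
#' @param backend an `embedding_backend`.
#' @param config a `tuner_config`.
#' @param base_theta fixed fields for sampled vectors.
#' @param log_path optional JSON-lines trial log path.
#' @return list of `top_k` `trial_record`s, best first.
#' @export
tune <- function(space, refs, backend, config = tuner_config(),
                 base_theta = default_theta(), log_path = NULL) {
  assert_search_space(space)
  records <- vector("list", config$n_trials)
  for (t in seq_len(config$n_trials)) {
    seed_t <- derive_seed(config$seed, t)
    theta_t <- with_seed(seed_t, sample_theta(space, base = base_theta))
    rec <- tune_objective(theta_t, refs, backend, seed = seed_t)
    rec$trial <- t
    records[[t]] <- rec
  }
  if (!is.null(log_path)) {
    con <- file(log_path, open = "wt")
    for (r in records)
      writeLines(jsonlite::toJSON(list(trial = r$trial, seed = r$seed,
                                       objective = r$objective,
                                       similarities = r$similarities,
                                       theta = unclass(r$theta)),
                                  auto_unbox = TRUE, digits = NA), con)
    close(con)
  }
  obj <- vapply(records, `[[`, numeric(1), "objective")
  top <- records[order(-obj)][seq_len(config$top_k)]
  attr(top, "log") <- records
  top
}

#' Few-shot segmenter adaptation by maximizing mean SKIoU
#'
#' Generic hyperparameter-adaptation harness for an arbitrary segmenter:
#' each trial draws a parameter set from `param_space`, runs the segmenter
#' on every tuning image, normalizes and (optionally) postprocesses its
#' predictions, and scores the trial as the mean over tuning images of
#' the per-image mean SKIoU against ground truth.  A segmenter exception
#' scores that trial 0 and the run continues — third-party segmenters
#' crash, the harness must not.  Preprocessing parameters can simply be
#' part of `param_space` and consumed inside `segmenter`.
#'
#' @param segmenter function `(image, params) -> prediction_set` (or a
#'   bare list of logical masks).
#' @param param_space a `search_space`-style named list of
#'   `list(low, high, scale)` entries over the segmenter's numeric
#'   hyperparameters (names need not be theta fields).
#' @param tuning_set nonempty list of `list(image =, gt = mask_stack)`
#'   pairs (the standard protocol uses 10 images).
#' @param config a `tuner_config` (standard protocol: 1000 trials).
#' @param postprocess apply [unified_postprocess()] with thresholds pooled
#'   from the tuning-set ground truth.
#' @return list with `best_params`, `best_score`, and the trial `log`
#'   (data frame of trial, score and parameters).
#' @export
adapt_segmenter <- function(segmenter, param_space, tuning_set,
                            config = tuner_config(), postprocess = TRUE) {
  if (length(tuning_set) == 0) stop("tuning_set must be nonempty")
  thresholds <- if (postprocess) {
    pooled <- unlist(lapply(tuning_set, function(s) unclass(s$gt)),
                     recursive = FALSE)
    compute_gt_thresholds(mask_stack(pooled))
  } else NULL

  score_params <- function(params, seed) {
    scores <- vapply(seq_along(tuning_set), function(i) {
      s <- tuning_set[[i]]
      preds <- tryCatch({
        out <- with_seed(derive_seed(seed, i), segmenter(s$image, params))
        if (!inherits(out, "prediction_set"))
          out <- prediction_set(mask_stack(out), "stack", dim(to_gray(s$image)))
        if (!is.null(thresholds)) out <- unified_postprocess(out, thresholds)
        normalize_predictions(out)
      }, error = function(e) NULL)
      if (is.null(preds)) return(NA_real_)
      v <- mean_skiou(preds, s$gt)
      if (is.na(v)) 0 else v
    }, numeric(1))
    if (any(is.na(scores))) 0 else mean(scores)
  }

  log <- vector("list", config$n_trials)
  best_score <- -Inf; best_params <- NULL
  for (t in seq_len(config$n_trials)) {
    seed_t <- derive_seed(config$seed, t, 7L)
    params <- with_seed(seed_t, sample_params(param_space))
    sc <- score_params(params, seed_t)
    log[[t]] <- c(list(trial = t, score = sc), params)
    if (sc > best_score) {
      best_score <- sc
      best_params <- params
    }
  }
  list(best_params = best_params, best_score = best_score,
       log = do.call(rbind, lapply(log, as.data.frame)))
}
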