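# Trial-level CSV interchange and the end-to-end pipeline driver.

ti_csv_columns <- function() {
  c("participant_id", "condition", "block", "sub_block", "trial_index",
    "left_item", "right_item", "feedback", "phase", "correct_item",
    "chosen_item", "missed")
}

#' Write trial-level choice data to CSV
#'
#' One row per trial, UTF-8 with header, 1-based item ids and blocks:
#' `participant_id, condition, block, sub_block, trial_index, left_item,
#' right_item, feedback, phase, correct_item, chosen_item, missed`.
#' Multiple participants are stacked in one file.
#'
#' @param data a `ti_data` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_choice_csv <- function(data, path) {
  if (inherits(data, "ti_data")) data <- list(data)
  rows <- do.call(rbind, lapply(data, function(d) {
    tr <- d$session$trials
    data.frame(participant_id = d$participant_id,
               condition = d$session$condition, block = tr$block,
               sub_block = tr$sub_block, trial_index = tr$trial,
               left_item = tr$left_item, right_item = tr$right_item,
               feedback = tr$feedback, phase = tr$phase,
               correct_item = tr$correct_item,
               chosen_item = d$responses$chosen_item,
               missed = d$responses$missed)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# Reconstruct a hierarchy from the correct_item column of a block range:
# an item's rank is 1 + the number of distinct items it is recorded as
# beating.
infer_hierarchy <- function(tr, condition, changed) {
  items <- sort(unique(c(tr$left_item, tr$right_item)))
  n <- length(items)
  beats <- vapply(items, function(it) {
    rows <- tr$correct_item == it
    if (!any(rows)) return(0L)  # the bottom-ranked item never wins
    length(unique(c(tr$left_item[rows], tr$right_item[rows]))) - 1L
  }, integer(1))
  ranks <- beats + 1L
  if (!setequal(ranks, seq_len(n)))
    stop("schema error: correct_item column does not encode a strict ",
         "ranking", call. = FALSE)
  new_hierarchy(ranks, condition, changed)
}

#' Read trial-level choice data from CSV
#'
#' Inverse of [write_choice_csv()]: validates the schema, reconstructs the
#' per-participant session (hierarchies are inferred from the
#' `correct_item` pattern before and after the changepoint; the
#' changepoint block from the first `"post"` trial) and returns datasets
#' with provenance `"imported"`.  Unknown extra columns are ignored; a
#' missing required column is a schema error naming the column; item ids
#' outside `1..n_items` are rejected.
#'
#' @param path CSV file written in the package schema.
#' @return list of `ti_data`, one per participant, in file order.
#' @export
read_choice_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ti_csv_columns(), names(df))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$feedback <- as.logical(df$feedback)
  df$missed <- as.logical(df$missed)
  n_items <- max(df$left_item, df$right_item)
  bad <- c(df$left_item, df$right_item, df$correct_item) < 1 |
    c(df$left_item, df$right_item, df$correct_item) > n_items
  if (any(bad, na.rm = TRUE))
    stop("schema error: item ids must be 1-based and within 1..n_items",
         call. = FALSE)
  ids <- unique(df$participant_id)
  lapply(ids, function(id) {
    sub <- df[df$participant_id == id, , drop = FALSE]
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    condition <- sub$condition[1L]
    has_post <- any(sub$phase == "post")
    cb <- if (has_post) min(sub$block[sub$phase == "post"]) else NA_integer_
    pre_tr <- if (has_post) sub[sub$block < cb, , drop = FALSE] else sub
    h_pre <- infer_hierarchy(pre_tr, "none", FALSE)
    h_post <- if (has_post)
      infer_hierarchy(sub[sub$block >= cb, , drop = FALSE], condition, TRUE)
    else h_pre
    trials <- data.frame(block = sub$block, sub_block = sub$sub_block,
                         trial = sub$trial_index,
                         left_item = sub$left_item,
                         right_item = sub$right_item,
                         feedback = sub$feedback,
                         correct_item = sub$correct_item,
                         phase = sub$phase)
    session <- structure(
      list(trials = trials, condition = condition,
           n_items = as.integer(n_items),
           changepoint_block = as.integer(cb),
           hierarchy_pre = h_pre, hierarchy_post = h_post, seed = NA),
      class = "ti_session")
    new_ti_data(session, id, "imported",
                chosen_item = sub$chosen_item, missed = sub$missed)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Simulate a synthetic cohort, apply the inclusion filter, fit the
#' candidate models to every retained participant, run random-effects
#' model selection per condition, and compute the behavioural metrics.
#' All stage outputs are written under `out_dir` as CSV/JSON; a rerun with
#' the same configuration reproduces identical payloads.
#'
#' @param out_dir output directory (created if needed).
#' @param config named list (or path to a YAML file holding one) with any
#'   of: `n_up`, `n_down`, `model`, `preset`, `miss_rate`, `models`,
#'   `maxiter`, `popsize`, `criterion`, `window`.  Unknown model names are
#'   rejected before any computation.
#' @param seed master seed (overrides a `seed` entry in `config`).
#' @return invisibly, a list with the cohort, fits, BMS results, metric
#'   table and output paths.
#' @export
run_pipeline <- function(out_dir, config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n_up = 5, n_down = 5, model = "qasymm",
                   preset = "winner", miss_rate = 0, models = ti_models(),
                   maxiter = 60, popsize = 16, criterion = "aic",
                   window = 70, seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(seed)) cfg$seed <- seed
  bad <- setdiff(c(cfg$model, cfg$models), ti_models())
  if (length(bad))
    stop("unknown model name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(cohort_config(
    n_up = cfg$n_up, n_down = cfg$n_down, model = cfg$model,
    sampler = param_preset(cfg$preset, cfg$model), seed = cfg$seed,
    miss_rate = cfg$miss_rate))
  paths <- list(
    choices = file.path(out_dir, "choices.csv"),
    manifest = file.path(out_dir, "cohort_manifest.csv"),
    inclusion = file.path(out_dir, "inclusion.csv"),
    fits = file.path(out_dir, "fits.csv"),
    bms = file.path(out_dir, "bms.json"),
    metrics = file.path(out_dir, "metrics.csv"),
    config = file.path(out_dir, "config.json"))
  write_choice_csv(cohort, paths$choices)
  write.csv(cohort_manifest(cohort), paths$manifest, row.names = FALSE)

  incl <- do.call(rbind, lapply(cohort, function(d) {
    f <- inclusion_filter(d)
    data.frame(participant_id = d$participant_id, include = f$include,
               n_pre = f$n_pre, n_correct_pre = f$n_correct_pre,
               threshold = f$threshold, miss_prop = f$miss_prop)
  }))
  write.csv(incl, paths$inclusion, row.names = FALSE)
  kept <- cohort[incl$include]
  if (!length(kept))
    stop("pipeline halt at filter stage: no participant passed inclusion",
         call. = FALSE)

  fits <- lapply(kept, function(d)
    fit_models(d, cfg$models, maxiter = cfg$maxiter, popsize = cfg$popsize,
               seed = cfg$seed))
  ids <- vapply(kept, function(d) d$participant_id, character(1))
  ftab <- fit_table(fits, ids)
  write.csv(ftab, paths$fits, row.names = FALSE)

  conds <- vapply(kept, function(d) d$session$condition, character(1))
  bms <- lapply(split(seq_along(kept), conds), function(idx) {
    if (length(idx) < 2L) return(NULL)
    res <- rfx_bms(evidence_from_aic(
      criterion_matrix(fits[idx], cfg$criterion)), seed = cfg$seed)
    res[c("models", "alpha", "expected_freq", "xp", "bor", "pxp")]
  })
  jsonlite::write_json(bms, paths$bms, auto_unbox = TRUE, digits = NA)

  metrics <- do.call(rbind, lapply(kept, function(d) {
    data.frame(participant_id = d$participant_id,
               condition = d$session$condition,
               asymmetry_slope = asymmetry_slope(d, "pre")$slope,
               distance_slope = distance_effect(d, "pre")$slope)
  }))
  write.csv(metrics, paths$metrics, row.names = FALSE)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, inclusion = incl, fits = fits,
                 bms = bms, metrics = metrics, paths = paths))
}
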