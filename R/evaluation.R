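#' Train/test split of a cohort manifest
#'
#' Assigns each subject's captures to enrollment (train) or probe (test)
#' roles. By default the first half of a subject's captures (by
#' `capture_index`, minimum one) enrolls and the remainder probe — with four
#' captures per subject this is the two-enroll/two-probe protocol, and with
#' two captures the classic first-enrolls/last-probes rule. With
#' `by_side = TRUE` the first capture of each ear side enrolls (one left +
#' one right) and the remaining captures probe, the protocol used for infant
#' cohorts where left and right ear images are combined into the composite.
#'
#' @param manifest A manifest `data.frame` (see [read_manifest()]).
#' @param n_train Number of enrollment captures per subject; `NULL` for the
#'   half-split default.
#' @param by_side Use the one-per-side enrollment rule.
#' @return A `data.frame` with columns `image_path`, `subject_id`, `role`.
#' @export
split_spec <- function(manifest, n_train = NULL, by_side = FALSE) {
  out <- do.call(rbind, lapply(split(manifest, manifest$subject_id), function(mm) {
    mm <- mm[order(mm$capture_index, mm$image_path), , drop = FALSE]
    if (isTRUE(by_side)) {
      first_of_side <- !duplicated(mm$side)
      role <- ifelse(first_of_side, "train", "test")
      if (!any(role == "test")) role[length(role)] <- "test"
    } else {
      k <- if (is.null(n_train)) max(1L, nrow(mm) %/% 2L) else min(n_train, nrow(mm) - 1L)
      k <- max(1L, k)
      role <- c(rep("train", k), rep("test", nrow(mm) - k))
    }
    data.frame(image_path = mm$image_path, subject_id = mm$subject_id,
               role = role, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!all(c("train", "test") %in% out$role)) {
    stop("split must assign at least one train and one test image")
  }
  out
}

#' Closed-set rank-1..rank-10 recognition evaluation
#'
#' Enrolls every subject's training captures into a gallery under `config`,
#' then presents each probe (a single test capture, or the composite of a
#' subject's test captures when concatenation is enabled), ranks the gallery
#' with [rank_matches()] and classifies each outcome. Probes that yield zero
#' descriptors are counted as "no match" outcomes, never dropped silently.
#'
#' @param manifest Manifest `data.frame` (see [read_manifest()]).
#' @param rois Named list of [crop_roi()] keyed by image path (required when
#'   `config$use_crop`).
#' @param split A [split_spec()] `data.frame`; defaults to the half-split.
#' @param config A [pipeline_config()].
#' @param cache Optional [descriptor_cache()].
#' @param image_dir Directory that manifest image paths are relative to.
#' @return An `evaluation_result`: `n_probes`, `hits_at_k`, `rate_at_k`
#'   (k = 1..10), `per_probe` data frame and the strategy label.
#' @export
evaluate_cohort <- function(manifest, rois = NULL, split = NULL,
                            config = pipeline_config(), cache = NULL,
                            image_dir = NULL) {
  if (is.null(split)) split <- split_spec(manifest)
  bad <- setdiff(split$image_path, manifest$image_path)
  if (length(bad)) stop("split references images absent from the manifest")
  test_subjects <- unique(split$subject_id[split$role == "test"])
  train_subjects <- unique(split$subject_id[split$role == "train"])
  if (!all(test_subjects %in% train_subjects)) {
    stop("every probed subject must be enrolled")
  }
  images <- load_manifest_images(manifest, image_dir)
  roi_for <- function(path) {
    if (!config$use_crop) return(NULL)
    roi <- rois[[path]]
    if (is.null(roi)) stop(sprintf("no ROI for image '%s'", path))
    roi
  }

  gallery <- ear_gallery(config)
  subj_meta <- manifest[!duplicated(manifest$subject_id),
                        c("subject_id", "gender"), drop = FALSE]
  genders <- stats::setNames(subj_meta$gender, subj_meta$subject_id)
  for (sid in sort(train_subjects)) {
    paths <- split$image_path[split$subject_id == sid & split$role == "train"]
    if (!config$use_concatenation) paths <- paths[1L]
    gallery <- enroll_subject(
      gallery, sid, genders[[sid]],
      images = images[paths],
      rois = lapply(paths, roi_for),
      cache = cache
    )
  }

  probe_sets <- list()
  for (sid in sort(test_subjects)) {
    paths <- split$image_path[split$subject_id == sid & split$role == "test"]
    sets <- lapply(paths, function(p) {
      extract_cached(images[[p]], config, roi = roi_for(p), cache = cache)
    })
    if (config$use_concatenation) {
      usable <- Filter(Negate(is_unmatchable), sets)
      composite <- if (length(usable)) concatenate_descriptors(usable) else sets[[1L]]
      probe_sets[[paste0(sid, "/composite")]] <-
        list(set = composite, true_id = sid)
    } else {
      for (i in seq_along(sets)) {
        probe_sets[[paths[i]]] <- list(set = sets[[i]], true_id = sid)
      }
    }
  }

  per_probe <- do.call(rbind, lapply(names(probe_sets), function(pid) {
    p <- probe_sets[[pid]]
    if (is_unmatchable(p$set)) {
      message(sprintf("probe '%s' yielded no descriptors; counted as no match", pid))
      return(data.frame(probe_id = pid, true_id = p$true_id,
                        rank = NA_integer_, outcome = "none",
                        stringsAsFactors = FALSE))
    }
    ranked <- rank_matches(p$set, gallery, config,
                           probe_gender = genders[[p$true_id]])
    oc <- classify_outcome(ranked, p$true_id)
    data.frame(probe_id = pid, true_id = p$true_id, rank = oc$rank,
               outcome = oc$outcome, stringsAsFactors = FALSE)
  }))

  hits <- vapply(1:10, function(k) sum(!is.na(per_probe$rank) & per_probe$rank <= k),
                 integer(1))
  structure(
    list(n_probes = nrow(per_probe), hits_at_k = hits,
         rate_at_k = hits / nrow(per_probe), per_probe = per_probe,
         strategy = config$label,
         width = if (config$use_resize) config$target_width else NA_integer_),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result %s> n=%d top-1 %.2f%% top-10 %.2f%%\n",
              x$strategy, x$n_probes, 100 * x$rate_at_k[1], 100 * x$rate_at_k[10]))
  invisible(x)
}

#' Strategy presets for the ablation grid
#'
#' `"table5"` returns the six-strategy grid used on the museum cohort
#' (resize only; resize + HE without crop; crop + resize; crop + resize +
#' HE; + concatenation; + gender filter). `"table6"` returns the
#' five-strategy grid used on the infant cohort (crop + resize; + HE;
#' + gender filter; + HE + gender filter; all five techniques).
#'
#' @param name `"table5"` or `"table6"`.
#' @param target_width Resize width shared by all presets.
#' @param top_k Ranked-list length shared by all presets.
#' @return A named list of [pipeline_config()] objects.
#' @export
strategy_presets <- function(name = c("table5", "table6"), target_width = 150L,
                             top_k = 10L) {
  name <- match.arg(name)
  mk <- function(label, crop, he, concat, gender) {
    pipeline_config(use_crop = crop, use_resize = TRUE,
                    target_width = target_width, use_hist_eq = he,
                    use_concatenation = concat, use_gender_filter = gender,
                    top_k = top_k, label = label)
  }
  if (name == "table5") {
    list(
      one   = mk("one",   crop = FALSE, he = FALSE, concat = FALSE, gender = FALSE),
      two   = mk("two",   crop = FALSE, he = TRUE,  concat = FALSE, gender = FALSE),
      three = mk("three", crop = TRUE,  he = FALSE, concat = FALSE, gender = FALSE),
      four  = mk("four",  crop = TRUE,  he = TRUE,  concat = FALSE, gender = FALSE),
      five  = mk("five",  crop = TRUE,  he = TRUE,  concat = TRUE,  gender = FALSE),
      six   = mk("six",   crop = TRUE,  he = TRUE,  concat = TRUE,  gender = TRUE)
    )
  } else {
    list(
      crop_resize        = mk("crop_resize",        TRUE, FALSE, FALSE, FALSE),
      crop_resize_he     = mk("crop_resize_he",     TRUE, TRUE,  FALSE, FALSE),
      crop_resize_gender = mk("crop_resize_gender", TRUE, FALSE, FALSE, TRUE),
      crop_resize_he_gender = mk("crop_resize_he_gender", TRUE, TRUE, FALSE, TRUE),
      all_techniques     = mk("all_techniques",     TRUE, TRUE,  TRUE,  TRUE)
    )
  }
}

#' Run an ablation grid of strategies over one split
#'
#' Evaluates every strategy on the same train/test split so differences in
#' rates are attributable to the techniques alone.
#'
#' @inheritParams evaluate_cohort
#' @param strategies A named list of [pipeline_config()] objects, e.g. from
#'   [strategy_presets()].
#' @return A list with `summary` (one row per strategy: label, width,
#'   n_probes, rank1..rank10) and `results` (the `evaluation_result`s).
#' @export
run_ablation <- function(manifest, rois = NULL, split = NULL,
                         strategies = strategy_presets("table5"),
                         cache = NULL, image_dir = NULL) {
  stopifnot(length(strategies) >= 1L)
  if (is.null(split)) split <- split_spec(manifest)
  results <- lapply(strategies, function(cfg) {
    evaluate_cohort(manifest, rois = rois, split = split, config = cfg,
                    cache = cache, image_dir = image_dir)
  })
  list(summary = summarize_results(results), results = results)
}

summarize_results <- function(results) {
  out <- do.call(rbind, lapply(results, function(r) {
    rates <- as.list(stats::setNames(r$rate_at_k, paste0("rank", 1:10)))
    cbind(data.frame(strategy = r$strategy, width = r$width,
                     n_probes = r$n_probes, stringsAsFactors = FALSE),
          as.data.frame(rates))
  }))
  rownames(out) <- NULL
  out
}

#' Recognition rates across resize widths
#'
#' Evaluates a crop + resize pipeline at each target width, mirroring the
#' resize-parameter sweep used to select the 150 px ear width.
#'
#' @inheritParams evaluate_cohort
#' @param widths Integer vector of target widths.
#' @return As [run_ablation()], one row/result per width.
#' @export
resize_sweep <- function(manifest, rois = NULL, split = NULL,
                         widths = c(75L, 100L, 125L, 150L, 175L, 200L),
                         cache = NULL, image_dir = NULL) {
  stopifnot(length(widths) >= 1L)
  strategies <- lapply(widths, function(w) {
    pipeline_config(use_crop = TRUE, use_resize = TRUE, target_width = w,
                    use_hist_eq = FALSE, use_concatenation = FALSE,
                    use_gender_filter = FALSE, label = sprintf("width%d", w))
  })
  names(strategies) <- sprintf("width%d", widths)
  run_ablation(manifest, rois = rois, split = split, strategies = strategies,
               cache = cache, image_dir = image_dir)
}

#' Write evaluation results to CSV
#'
#' The summary CSV has columns `strategy`, `width`, `n_probes`,
#' `rank1`..`rank10` with rates rounded to two decimals; the optional
#' per-probe CSV has `probe_id`, `true_id`, `rank`, `outcome` at full
#' precision.
#'
#' @param results A single `evaluation_result` or list of them.
#' @param path Summary CSV path.
#' @param per_probe_path Optional per-probe CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation_csv <- function(results, path, per_probe_path = NULL) {
  if (inherits(results, "evaluation_result")) results <- list(results)
  summary <- summarize_results(results)
  summary[paste0("rank", 1:10)] <- round(summary[paste0("rank", 1:10)], 2)
  utils::write.csv(summary, path, row.names = FALSE)
  if (!is.null(per_probe_path)) {
    pp <- do.call(rbind, lapply(results, function(r) {
      cbind(strategy = r$strategy, r$per_probe)
    }))
    utils::write.csv(pp, per_probe_path, row.names = FALSE)
  }
  invisible(path)
}
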