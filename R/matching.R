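#' Average nearest-neighbour squared Euclidean distance
#'
#' The identification score between a probe vector map and one gallery
#' entry: for every probe descriptor find its nearest neighbour among the
#' entry's descriptors under squared Euclidean distance, then average those
#' minima over the probe. Small scores indicate strong matches; a probe
#' scored against an entry containing the identical descriptors scores 0.
#' The score is asymmetric (the probe side is averaged).
#'
#' Exact brute-force nearest-neighbour search is the reference semantics;
#' the default `"compiled"` path runs that double loop in C so scores are
#' exact (never approximated by an index), and a probe scored against an
#' entry holding identical descriptors is exactly 0. `method = "loop"` is
#' the same sweep in plain R.
#'
#' @param probe,entry Non-empty [descriptor_set()] objects.
#' @param method Computation path; `"compiled"` (default) or `"loop"`.
#' @return A non-negative scalar score.
#' @export
distance_score <- function(probe, entry, method = c("compiled", "loop")) {
  method <- match.arg(method)
  stopifnot(inherits(probe, "descriptor_set"), inherits(entry, "descriptor_set"))
  if (is_unmatchable(probe) || is_unmatchable(entry)) {
    stop("distance_score requires non-empty probe and gallery descriptor sets")
  }
  P <- probe$descriptors
  E <- entry$descriptors
  mins <- if (method == "compiled") {
    nn_min_sq(t(P), t(E))
  } else {
    vapply(seq_len(nrow(P)), function(i) {
      min(colSums((t(E) - P[i, ])^2))
    }, numeric(1))
  }
  mean(mins)
}

#' Narrow a gallery by gender label
#'
#' Before scoring, the searchable database can be restricted to records
#' whose recorded gender equals the probe's label, reducing the number of
#' candidates and with it the chance of a false positive. An unknown
#' (`NA`) probe label disables the filter so identification degrades
#' gracefully to the unfiltered search.
#'
#' @param records A list of subject records (see [enroll_subject()]).
#' @param label Gender label of the probe, or `NA`.
#' @return The filtered list of records.
#' @export
apply_gender_filter <- function(records, label) {
  if (is.null(label) || is.na(label)) return(records)
  Filter(function(r) identical(r$gender, as.character(label)), records)
}

#' Rank gallery candidates for a probe
#'
#' Scores the probe against every (optionally gender-filtered) gallery
#' record with [distance_score()] and returns the `top_k` smallest scores in
#' ascending order. Ties are broken lexicographically by subject ID so
#' rankings are deterministic across platforms. If filtering empties the
#' gallery the list is empty; if fewer than `top_k` candidates survive the
#' list is simply shorter.
#'
#' @param probe A non-empty [descriptor_set()].
#' @param gallery An [ear_gallery()] or plain list of subject records.
#' @param config A [pipeline_config()]; `use_gender_filter` and `top_k` are
#'   consulted.
#' @param probe_gender Gender label of the probe, or `NA` when unknown.
#' @return A `data.frame` with columns `subject_id`, `score`, `rank`.
#' @export
rank_matches <- function(probe, gallery, config = pipeline_config(),
                         probe_gender = NA_character_) {
  stopifnot(inherits(probe, "descriptor_set"))
  if (is_unmatchable(probe)) stop("probe has no descriptors and cannot be matched")
  records <- if (inherits(gallery, "ear_gallery")) gallery$records else gallery
  if (config$use_gender_filter) {
    records <- apply_gender_filter(records, probe_gender)
  }
  records <- Filter(function(r) !is_unmatchable(r$composite), records)
  if (length(records) == 0L) {
    return(data.frame(subject_id = character(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  ids <- vapply(records, function(r) r$subject_id, character(1))
  scores <- vapply(records, function(r) distance_score(probe, r$composite),
                   numeric(1))
  ord <- order(scores, ids)
  keep <- ord[seq_len(min(config$top_k, length(ord)))]
  data.frame(subject_id = ids[keep], score = scores[keep],
             rank = seq_along(keep), stringsAsFactors = FALSE)
}

#' Classify an identification outcome
#'
#' A probe whose true subject heads the ranked list is a top-1 (and hence
#' also top-10) match; one found lower in the top-10 list is a top-10 match;
#' one absent from the list is designated "no match".
#'
#' @param ranked A ranked match `data.frame` from [rank_matches()].
#' @param true_id The probe's true subject ID.
#' @return A list with `outcome` (`"top1"`, `"top10"` or `"none"`) and
#'   `rank` (integer, `NA` when absent).
#' @export
classify_outcome <- function(ranked, true_id) {
  pos <- match(true_id, ranked$subject_id)
  if (is.na(pos)) {
    list(outcome = "none", rank = NA_integer_)
  } else if (pos == 1L) {
    list(outcome = "top1", rank = 1L)
  } else {
    list(outcome = "top10", rank = as.integer(pos))
  }
}
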