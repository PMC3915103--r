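#' Label propagation and weighted majority voting
#'
#' Each selected exemplar's label map is warped onto the subject grid with
#' the exemplar-to-subject field (nearest-neighbour, so no new label values
#' appear), then the candidate segmentations are fused per voxel: the score
#' of label L is the sum of the voting weights of the templates voting L
#' (background 0 votes like any other label, which prevents foreground
#' bleeding where most templates see background), and the label with the
#' highest score wins, ties going to the smallest label value.
#'
#' @name fusion
NULL

#' Construct a vote stack
#'
#' @param warped_labels list of [label_volume]s on the subject grid.
#' @param weights numeric voting weights in `[0,1]`, one per volume.
#' @return a `vote_stack`.
#' @export
vote_stack <- function(warped_labels, weights) {
  if (length(warped_labels) < 1L)
    validation_error("vote_stack needs at least one label volume")
  if (length(weights) != length(warped_labels))
    validation_error("weights and labels must have the same length")
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1))
    validation_error("weights must be finite and in [0,1]")
  d <- grid_dim(warped_labels[[1L]])
  for (l in warped_labels) {
    if (!inherits(l, "label_volume"))
      validation_error("vote_stack entries must be label_volumes")
    if (!identical(grid_dim(l), d))
      validation_error("vote_stack label volumes must share one grid")
  }
  structure(list(warped_labels = warped_labels, weights = as.numeric(weights)),
            class = "vote_stack")
}

#' Propagate exemplar labels to the subject grid
#'
#' @param selection a `selection_result` from [select_exemplars].
#' @param atlas_labels named list of [label_volume]s covering every exemplar.
#' @param registrations named list (`"<atlas>__to__<subject>"` keys) of
#'   `registration_result`s or [displacement_field]s.
#' @return a `vote_stack` of warped exemplar labels paired with their
#'   voting weights.
#' @export
propagate_labels <- function(selection, atlas_labels, registrations) {
  ex <- selection$exemplars
  missing_lab <- setdiff(ex, names(atlas_labels))
  if (length(missing_lab) > 0L)
    validation_error("missing label volumes for exemplar(s): %s",
                     paste(missing_lab, collapse = ", "))
  keys <- reg_key(ex, selection$subject_id)
  missing_reg <- keys[!keys %in% names(registrations)]
  if (length(missing_reg) > 0L)
    validation_error("missing registrations: %s", paste(missing_reg, collapse = ", "))
  warped <- vector("list", length(ex))
  for (i in seq_along(ex)) {
    r <- registrations[[keys[i]]]
    fld <- if (inherits(r, "registration_result")) r$field else r
    warped[[i]] <- warp(atlas_labels[[ex[i]]], fld, "nearest")
  }
  names(warped) <- ex
  vote_stack(warped, as.numeric(selection$weights[ex]))
}

vote_engine <- function(stack, weights) {
  labs <- sort(unique(unlist(lapply(stack$warped_labels,
                                    function(l) unique(as.vector(l$data))))))
  d <- grid_dim(stack$warped_labels[[1L]])
  best_score <- array(-Inf, dim = d)
  best_label <- array(labs[1L], dim = d)
  for (L in labs) {          # ascending: strict > keeps the smallest label on ties
    score <- array(0, dim = d)
    for (t in seq_along(stack$warped_labels))
      score <- score + weights[t] * (stack$warped_labels[[t]]$data == L)
    upd <- score > best_score
    best_label[upd] <- L
    best_score[upd] <- score[upd]
  }
  ref <- stack$warped_labels[[1L]]
  list(labels = label_volume(best_label, ref$spacing, ref$origin),
       confidence = volume_image(best_score, ref$spacing, ref$origin))
}

#' Weighted majority-vote label fusion
#'
#' @param stack a `vote_stack`.
#' @param return_confidence if `TRUE`, also return the per-voxel winning
#'   vote score as a [volume_image].
#' @return a [label_volume], or a list `(labels, confidence)`.
#' @export
weighted_majority_vote <- function(stack, return_confidence = FALSE) {
  if (!inherits(stack, "vote_stack"))
    validation_error("weighted_majority_vote expects a vote_stack")
  if (all(stack$weights == 0))
    validation_error("weighted_majority_vote: all voting weights are zero")
  out <- vote_engine(stack, stack$weights)
  if (return_confidence) out else out$labels
}

#' Unweighted (simple) majority-vote label fusion
#'
#' Baseline fusion that weights every candidate segmentation equally;
#' identical to [weighted_majority_vote] with equal weights.
#'
#' @inheritParams weighted_majority_vote
#' @return a [label_volume], or a list `(labels, confidence)`.
#' @export
unweighted_majority_vote <- function(stack, return_confidence = FALSE) {
  if (!inherits(stack, "vote_stack"))
    validation_error("unweighted_majority_vote expects a vote_stack")
  out <- vote_engine(stack, rep(1, length(stack$warped_labels)))
  if (return_confidence) out else out$labels
}
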