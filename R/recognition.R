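## Applying a trained network: the result matrix, label decoding and
## recognition rates.

#' Run recognition on unlabeled windows
#'
#' Each column of the 800 x n recognition input is passed through the
#' trained network; the raw linear outputs are clamped into `[0, 1]` so
#' every entry is a recognition index (the bound is part of the result
#' contract; clamping does not change the decoded argmax).
#'
#' @param model a trained `bpnn_model`.
#' @param input an 800 x n matrix of window columns, or a `motion_windows`
#'   object.
#' @return a 6 x n `result_matrix` of recognition indices in `[0, 1]`.
#' @export
recognize <- function(model, input) {
  if (!isTRUE(model$trained))
    stop_contract("recognize requires a trained model")
  x <- if (inherits(input, "motion_windows")) input$values else as.matrix(input)
  r <- forward(model, x)
  r <- pmin(pmax(r, 0), 1)
  structure(r, class = c("result_matrix", class(r)))
}

#' Decode exercise labels from a result matrix
#'
#' Per column, the exercise whose recognition index is largest (the closer
#' an index is to 1, the more the window is recognized as that exercise).
#' Exact ties are broken toward the lowest exercise number, with a warning.
#'
#' @param r a 6 x n result matrix.
#' @return integer vector of exercise labels (1--6), one per column.
#' @export
decode <- function(r) {
  r <- unclass(r)
  if (ncol(r) == 0L) return(integer(0))
  lab <- apply(r, 2L, which.max)
  ties <- vapply(seq_len(ncol(r)), function(j)
    sum(r[, j] == max(r[, j])) > 1L, logical(1L))
  if (any(ties))
    warning(sum(ties), " column(s) with tied recognition indices; ",
            "lowest exercise index chosen")
  as.integer(lab)
}

#' Recognition rates per exercise and overall
#'
#' The per-exercise rate is the fraction of windows whose true label is
#' that exercise that were decoded correctly.  An exercise absent from the
#' truth (as in blind tests where participants may omit exercises) yields
#' `NaN`, not 0.
#'
#' @param decoded integer labels from [decode()].
#' @param truth ground-truth labels, same length.
#' @return list with `per_exercise` (named numeric of length 6) and
#'   `overall` (scalar fraction correct).
#' @export
recognition_rate <- function(decoded, truth) {
  if (length(decoded) != length(truth))
    stop_contract("decoded and truth must have equal length")
  if (!length(truth))
    return(list(per_exercise = stats::setNames(rep(NaN, N_EXERCISES),
                                               paste0("Ex", 1:N_EXERCISES)),
                overall = NaN))
  per <- vapply(seq_len(N_EXERCISES), function(k) {
    sel <- truth == k
    if (!any(sel)) return(NaN)
    mean(decoded[sel] == k)
  }, numeric(1L))
  names(per) <- paste0("Ex", seq_len(N_EXERCISES))
  list(per_exercise = per, overall = mean(decoded == truth))
}

#' Held-out recognition rates of a trained model
#'
#' Convenience wrapper: recognizes the test-set columns recorded in the
#' model's split and scores them against the true labels.
#'
#' @param model a trained `bpnn_model` (from [train_bpnn()]).
#' @param M the `motion_matrix` the model was trained on.
#' @return as [recognition_rate()], plus `n_test`.
#' @export
held_out_rates <- function(model, M) {
  fm <- flatten_cells(M)
  idx <- unlist(model$split$test)
  pred <- decode(recognize(model, fm$mat[, idx, drop = FALSE]))
  out <- recognition_rate(pred, fm$label[idx])
  out$n_test <- length(idx)
  out
}
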