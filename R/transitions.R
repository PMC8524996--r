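#' Standalone CAD case outcomes
#'
#' Classifies the CAD's own marks with the identical matching rule and case
#' definitions used for readers, so standalone CAD metrics and the
#' transition analysis share one code path.
#'
#' @inheritParams classify_study
#' @param cad_annotations Box table of CAD marks (with `image_id`).
#' @return A case-outcome tibble, one row per image.
#' @export
cad_case_outcomes <- function(images, lesions, cad_annotations,
                              policy = match_policy()) {
  classify_study(images, lesions, cad_annotations, policy)
}

transition_cells <- tibble::tibble(
  cad_state = c("TP", "TN", "FN", "FP"),
  before_state = c("FN", "FP", "TP", "TN"),
  flip_to = c("TP", "TN", "FN", "FP")
)

#' Per-reader decision-transition table
#'
#' Tabulates how one reader's case-level decisions changed between the
#' without-CAD and with-CAD reads, conditioned on the CAD's own case-level
#' correctness. Only the four discordant combinations are tracked — (CAD
#' TP, before FN), (CAD TN, before FP), (CAD FN, before TP), (CAD FP,
#' before TN) — where "changed" means the case state flipped (FN to TP, FP
#' to TN, TP to FN, TN to FP respectively). Cases whose before-state agrees
#' with the CAD are tallied in a single `concordant` count so that every
#' image is accounted for.
#'
#' @param pre,post,cad Case-outcome tibbles (from [classify_study()]) for
#'   the reader's without-CAD arm, with-CAD arm, and the CAD, covering the
#'   identical image set.
#' @param reader_id Identifier recorded in the result.
#' @return An object of class `transition_table`: list with `reader_id`,
#'   `cells` (tibble `cad_state`, `before_state`, `changed`, `unchanged`),
#'   `concordant` and `n_images`.
#' @export
transition_table <- function(pre, post, cad, reader_id = NA_character_) {
  ids <- sort(pre$image_id)
  if (!identical(ids, sort(post$image_id)) || !identical(ids, sort(cad$image_id))) {
    stop("pre, post and cad outcomes must cover the identical image set",
      call. = FALSE
    )
  }
  pre <- pre[order(pre$image_id), ]
  post <- post[order(post$image_id), ]
  cad <- cad[order(cad$image_id), ]
  # a case can only move within its label's state pair
  pos_pair <- pre$state %in% c("TP", "FN") & post$state %in% c("TP", "FN")
  neg_pair <- pre$state %in% c("TN", "FP") & post$state %in% c("TN", "FP")
  if (!all(pos_pair | neg_pair)) {
    stop("inconsistent outcomes: a case changed between malignant and normal state pairs",
      call. = FALSE
    )
  }
  cells <- transition_cells
  cells$changed <- NA_integer_
  cells$unchanged <- NA_integer_
  in_cell <- rep(FALSE, length(ids))
  for (k in seq_len(nrow(cells))) {
    sel <- cad$state == cells$cad_state[k] & pre$state == cells$before_state[k]
    in_cell <- in_cell | sel
    cells$changed[k] <- sum(sel & post$state == cells$flip_to[k])
    cells$unchanged[k] <- sum(sel & post$state == cells$before_state[k])
  }
  structure(
    list(
      reader_id = reader_id,
      cells = cells[c("cad_state", "before_state", "changed", "unchanged")],
      concordant = sum(!in_cell),
      n_images = length(ids)
    ),
    class = "transition_table"
  )
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf(
    "<transition_table> reader %s (%d images, %d concordant)\n",
    x$reader_id, x$n_images, x$concordant
  ))
  print(x$cells)
  invisible(x)
}

#' Group switch rates from transition tables
#'
#' Sums transition counts over the readers of each group and reports, for
#' each of the four tracked cells, the proportion of opportunities on which
#' the reader's decision flipped: `changed / (changed + unchanged)`. A cell
#' with an empty denominator is reported as `NA`.
#'
#' @param tables A list of [transition_table()] objects.
#' @param groups Data frame `reader_id`, `group`; defaults to a single
#'   group `"all"`.
#' @param digits Display rounding for the proportion (default 2).
#' @return A tibble `group`, `cad_state`, `before_state`, `changed`,
#'   `unchanged`, `proportion`.
#' @export
switch_rates <- function(tables, groups = NULL, digits = 2) {
  if (length(tables) == 0) stop("no transition tables supplied", call. = FALSE)
  rows <- dplyr::bind_rows(lapply(tables, function(t) {
    dplyr::mutate(t$cells, reader_id = t$reader_id, .before = 1)
  }))
  if (is.null(groups)) {
    groups <- tibble::tibble(
      reader_id = unique(rows$reader_id), group = "all"
    )
  }
  rows <- dplyr::left_join(rows, groups, by = "reader_id")
  if (any(is.na(rows$group))) {
    stop("every reader_id must appear in the group assignment", call. = FALSE)
  }
  rows |>
    dplyr::group_by(.data$group, .data$cad_state, .data$before_state) |>
    dplyr::summarise(
      changed = sum(.data$changed), unchanged = sum(.data$unchanged),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      proportion = ifelse(
        .data$changed + .data$unchanged > 0,
        round_half_up(.data$changed / (.data$changed + .data$unchanged), digits),
        NA_real_
      )
    )
}

#' Transition analysis of a study bundle
#'
#' Convenience wrapper: classifies every arm of a bundle, builds one
#' transition table per reader, and returns the per-reader eight-cell
#' counts together with group switch rates.
#'
#' @param bundle A `study_bundle`.
#' @param policy A [match_policy()].
#' @return A list with `tables` (per-reader `transition_table`s), `counts`
#'   (tibble, one row per reader, eight count columns plus concordant) and
#'   `rates` (group switch-rate tibble, including group totals).
#' @export
transition_analysis <- function(bundle, policy = match_policy()) {
  outcomes <- classify_bundle(bundle, policy)
  transition_analysis_outcomes(outcomes, bundle$readers)
}

transition_analysis_outcomes <- function(outcomes, readers) {
  cad <- outcomes[outcomes$arm == "cad", ]
  tables <- lapply(readers$reader_id, function(r) {
    pre <- outcomes[outcomes$arm == "pre_cad" & outcomes$reader_id %in% r, ]
    post <- outcomes[outcomes$arm == "post_cad" & outcomes$reader_id %in% r, ]
    transition_table(pre, post, cad, reader_id = r)
  })
  counts <- dplyr::bind_rows(lapply(tables, function(t) {
    wide <- t$cells
    out <- tibble::tibble(reader_id = t$reader_id)
    for (k in seq_len(nrow(wide))) {
      out[[sprintf("cad%s_%s_changed", wide$cad_state[k], wide$before_state[k])]] <-
        wide$changed[k]
      out[[sprintf("cad%s_%s_unchanged", wide$cad_state[k], wide$before_state[k])]] <-
        wide$unchanged[k]
    }
    out$concordant <- t$concordant
    out
  }))
  groups <- readers[c("reader_id", "group")]
  list(
    tables = tables,
    counts = counts,
    rates = switch_rates(tables, groups)
  )
}
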