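#' Construct a table of axis-aligned bounding boxes
#'
#' Boxes are the unit of annotation throughout the package: ground-truth
#' lesions, reader marks, and CAD output are all axis-aligned rectangles in
#' continuous pixel coordinates (origin top-left, x rightward, y downward),
#' stored corner-wise as `(x_min, y_min, x_max, y_max)`.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of equal length (recycled
#'   by the usual rules) giving the box corners in pixels.
#' @return A tibble with columns `x_min`, `y_min`, `x_max`, `y_max`, one row
#'   per box.
#' @examples
#' bbox(0, 0, 2, 2)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  out <- tibble::tibble(
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max)
  )
  validate_boxes(out)
  out
}

box_cols <- c("x_min", "y_min", "x_max", "y_max")

#' Validate a box table
#'
#' Checks that all four corner columns are present and finite and that every
#' box has strictly positive width and height. Called internally by every
#' geometric operation; exported so that readers of annotation files can
#' fail fast.
#'
#' @param boxes A data frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @param what Label used in error messages.
#' @return `boxes`, invisibly.
#' @export
validate_boxes <- function(boxes, what = "box") {
  if (!all(box_cols %in% names(boxes))) {
    stop(sprintf(
      "%s table must have columns %s", what,
      paste(box_cols, collapse = ", ")
    ), call. = FALSE)
  }
  if (nrow(boxes) == 0L) return(invisible(boxes))
  m <- as.matrix(boxes[box_cols])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop(sprintf("%s coordinates must all be finite numbers", what),
      call. = FALSE
    )
  }
  bad <- boxes$x_max <= boxes$x_min | boxes$y_max <= boxes$y_min
  if (any(bad)) {
    stop(sprintf(
      "%s rows with non-positive extent (x_max <= x_min or y_max <= y_min): %s",
      what, paste(which(bad), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(boxes)
}

#' Box area in squared pixels
#'
#' @param boxes A box table (see [bbox()]).
#' @return Numeric vector of areas, one per row.
#' @examples
#' box_area(bbox(0, 0, 1, 3))
#' @export
box_area <- function(boxes) {
  validate_boxes(boxes)
  (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
}

#' Intersection over union of box pairs
#'
#' `box_iou()` computes the IoU elementwise between two box tables of equal
#' length (or with one of them a single row, which is recycled).
#' `iou_matrix()` computes the full cross table. IoU uses continuous
#' (closed-rectangle) areas, the standard reading of the overlap criterion;
#' disjoint boxes have IoU 0 and identical boxes IoU 1.
#'
#' @param a,b Box tables.
#' @return `box_iou()`: a numeric vector in `[0, 1]`. `iou_matrix()`: a
#'   `nrow(a)` by `nrow(b)` matrix.
#' @examples
#' box_iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3)) # 1/7
#' @export
box_iou <- function(a, b) {
  validate_boxes(a)
  validate_boxes(b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1) a <- a[rep(1L, nrow(b)), ]
    else if (nrow(b) == 1) b <- b[rep(1L, nrow(a)), ]
    else stop("a and b must have the same number of rows (or one row)",
      call. = FALSE
    )
  }
  ix <- pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min)
  iy <- pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

#' @rdname box_iou
#' @export
iou_matrix <- function(a, b) {
  validate_boxes(a)
  validate_boxes(b)
  na <- nrow(a)
  nb <- nrow(b)
  out <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(out)
  for (j in seq_len(nb)) {
    out[, j] <- box_iou(a, b[j, ])
  }
  out
}

#' Matching policy for the box correctness judgment
#'
#' An annotation is judged correct when its IoU with a ground-truth lesion
#' reaches the threshold; the threshold comparison is inclusive (`>=`), so a
#' box at exactly the threshold matches. The study regime has at most one
#' lesion per image, where any reasonable assignment coincides; for
#' multi-lesion inputs the policy chooses between a deterministic greedy
#' assignment by descending IoU and an optimal assignment that maximizes the
#' number of matched pairs, then total IoU.
#'
#' @param iou_threshold Fraction in `(0, 1]`; default 0.3.
#' @param assignment `"greedy_desc_iou"` (default) or `"optimal"`.
#' @return An object of class `match_policy`.
#' @export
match_policy <- function(iou_threshold = 0.3,
                         assignment = c("greedy_desc_iou", "optimal")) {
  assignment <- match.arg(assignment)
  if (!is.numeric(iou_threshold) || length(iou_threshold) != 1 ||
    !is.finite(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1) {
    stop("iou_threshold must be a single number in (0, 1]", call. = FALSE)
  }
  structure(
    list(iou_threshold = iou_threshold, assignment = assignment),
    class = "match_policy"
  )
}

#' @export
print.match_policy <- function(x, ...) {
  cat(sprintf(
    "<match_policy> IoU >= %g, assignment = %s\n",
    x$iou_threshold, x$assignment
  ))
  invisible(x)
}

#' One-to-one matching of annotations to lesions
#'
#' Pairs annotation boxes with ground-truth lesion boxes so that each box
#' appears in at most one pair and every accepted pair has IoU at or above
#' the policy threshold. Annotations left unmatched are false-positive
#' lesions; lesions left unmatched are misses.
#'
#' @param annotations,lesions Box tables (possibly zero rows).
#' @param policy A [match_policy()].
#' @return A list of class `match_result` with elements `matched_pairs`
#'   (tibble with columns `annotation`, `lesion`, `iou`),
#'   `unmatched_annotations` and `unmatched_lesions` (integer row indices).
#' @examples
#' match_boxes(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3), match_policy(0.1))
#' @export
match_boxes <- function(annotations, lesions, policy = match_policy()) {
  stopifnot(inherits(policy, "match_policy"))
  validate_boxes(annotations, "annotation")
  validate_boxes(lesions, "lesion")
  na <- nrow(annotations)
  nl <- nrow(lesions)
  empty <- tibble::tibble(
    annotation = integer(), lesion = integer(), iou = numeric()
  )
  if (na == 0L || nl == 0L) {
    return(new_match_result(empty, seq_len(na), seq_len(nl)))
  }
  iou <- iou_matrix(annotations, lesions)
  cand <- which(iou >= policy$iou_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(new_match_result(empty, seq_len(na), seq_len(nl)))
  }
  cand <- tibble::tibble(
    annotation = as.integer(cand[, 1]),
    lesion = as.integer(cand[, 2]),
    iou = iou[cand]
  )
  pairs <- switch(policy$assignment,
    greedy_desc_iou = greedy_match(cand),
    optimal = optimal_match(cand)
  )
  new_match_result(
    pairs,
    setdiff(seq_len(na), pairs$annotation),
    setdiff(seq_len(nl), pairs$lesion)
  )
}

new_match_result <- function(pairs, un_ann, un_les) {
  structure(
    list(
      matched_pairs = pairs,
      unmatched_annotations = as.integer(un_ann),
      unmatched_lesions = as.integer(un_les)
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d matched, %d unmatched annotations (FP lesions), %d missed lesions\n",
    nrow(x$matched_pairs), length(x$unmatched_annotations),
    length(x$unmatched_lesions)
  ))
  invisible(x)
}

# Greedy acceptance by descending IoU; ties broken by lower annotation
# index, then lower lesion index, so results are reproducible.
greedy_match <- function(cand) {
  ord <- order(-cand$iou, cand$annotation, cand$lesion)
  cand <- cand[ord, ]
  taken_a <- logical(max(cand$annotation))
  taken_l <- logical(max(cand$lesion))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    a <- cand$annotation[k]
    l <- cand$lesion[k]
    if (!taken_a[a] && !taken_l[l]) {
      keep[k] <- TRUE
      taken_a[a] <- TRUE
      taken_l[l] <- TRUE
    }
  }
  cand[keep, ]
}

# Maximizes the number of matched pairs, then total IoU, by depth-first
# search over the candidate pair list with simple pruning. Candidate lists
# are tiny in practice (a handful of boxes per image).
optimal_match <- function(cand) {
  n <- nrow(cand)
  best_pairs <- integer(0)
  best_count <- -1L
  best_iou <- -Inf
  ord <- order(cand$annotation, cand$lesion)
  cand <- cand[ord, ]
  recurse <- function(k, chosen, used_a, used_l, tot) {
    if (k > n) {
      cnt <- length(chosen)
      if (cnt > best_count || (cnt == best_count && tot > best_iou)) {
        best_pairs <<- chosen
        best_count <<- cnt
        best_iou <<- tot
      }
      return(invisible(NULL))
    }
    # upper bound on remaining pairs cannot beat best: prune
    if (length(chosen) + (n - k + 1L) < best_count) return(invisible(NULL))
    a <- cand$annotation[k]
    l <- cand$lesion[k]
    if (!(a %in% used_a) && !(l %in% used_l)) {
      recurse(k + 1L, c(chosen, k), c(used_a, a), c(used_l, l),
        tot + cand$iou[k])
    }
    recurse(k + 1L, chosen, used_a, used_l, tot)
  }
  recurse(1L, integer(0), integer(0), integer(0), 0)
  cand[best_pairs, ]
}
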