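#' A numeral form and its compositional decomposition
#'
#' Represents one numeral of a language: its meaning (\code{value}) and, if
#' non-atomic, the atomic summands it is built from. For example a language
#' where 'four' is expressed by repeating the word for 'two' has the form
#' \code{numeral_form(4, c(2, 2))}; an atomic 'five' is
#' \code{numeral_form(5)}. Parts that are known loans can be flagged so that
#' anchor detection can restrict itself to the native system.
#'
#' @param value positive integer, the numeral's meaning.
#' @param parts integer vector of atomic summands (empty for an atomic form);
#'   must sum to \code{value} when non-empty.
#' @param borrowed_parts subset of \code{parts} flagged as borrowed material.
#' @return an object of class \code{numeral_form}.
#' @export
numeral_form <- function(value, parts = integer(), borrowed_parts = integer()) {
  value <- as.integer(value)
  parts <- as.integer(parts)
  borrowed_parts <- as.integer(borrowed_parts)
  if (length(value) != 1L || is.na(value) || value < 1L)
    stop("value must be a single positive integer")
  if (length(parts) && any(parts < 1L)) stop("parts must be positive")
  if (length(parts) && sum(parts) != value)
    stop("inconsistent decomposition for value ", value, ": parts sum to ",
         sum(parts), ", not ", value)
  extra <- setdiff(borrowed_parts, parts)
  if (length(extra)) stop("borrowed_parts not among parts for value ", value,
                          ": ", paste(extra, collapse = ", "))
  structure(list(value = value, parts = parts, borrowed_parts = borrowed_parts),
            class = "numeral_form")
}

#' @export
print.numeral_form <- function(x, ...) {
  if (length(x$parts) == 0L) cat(x$value, "(atomic)\n")
  else cat(x$value, "=", paste(x$parts, collapse = " + "), "\n")
  invisible(x)
}

#' Detect compositional anchors in a set of numeral forms
#'
#' An anchor is any atomic numeral actively used to compose non-atomic
#' numerals: every value that appears as a summand of at least one non-atomic
#' form. The profile also records whether an anchor-2 system is "proper" (the
#' term for 2 forms all low composites, with no atomic 3 or 4 standing
#' outside the system) or "non-proper" (an atomic 3 or 4 exists that is not
#' itself an anchor), the distinction used for the Papuan codings.
#'
#' @param forms list of [numeral_form] objects (non-empty).
#' @param include_borrowed if \code{FALSE} (default), summands flagged as
#'   borrowed are ignored when collecting anchors, so that the profile
#'   describes the native system.
#' @return an object of class \code{anchor_profile}: \code{anchors} (sorted
#'   integer set), \code{smallest_anchor} (integer or \code{NA}),
#'   \code{max_value}, and \code{proper2} (\code{"proper"},
#'   \code{"non-proper"} or \code{"not-applicable"}).
#' @examples
#' # 'four' as two-plus-two makes 2 an anchor
#' detect_anchors(list(numeral_form(1), numeral_form(2), numeral_form(4, c(2, 2))))
#' @export
detect_anchors <- function(forms, include_borrowed = FALSE) {
  if (!length(forms)) stop("forms must be non-empty")
  stopifnot(all(vapply(forms, inherits, TRUE, "numeral_form")))
  values <- vapply(forms, `[[`, 1L, "value")
  atomic_values <- values[vapply(forms, function(f) length(f$parts) == 0L, TRUE)]
  anchors <- integer()
  for (f in forms) {
    if (length(f$parts) == 0L) next
    p <- f$parts
    if (!include_borrowed) p <- setdiff(p, f$borrowed_parts)
    anchors <- union(anchors, p)
  }
  # the unit is not an anchor: every additive composite uses 1, so treating
  # it as an anchor would make the notion vacuous (2 + 1 evidences anchor 2)
  anchors <- sort(setdiff(anchors, 1L))
  proper2 <- if (!(2L %in% anchors)) "not-applicable" else {
    stray_atomic <- setdiff(intersect(atomic_values, c(3L, 4L)), anchors)
    if (length(stray_atomic)) "non-proper" else "proper"
  }
  structure(list(anchors = anchors,
                 smallest_anchor = if (length(anchors)) min(anchors) else NA_integer_,
                 max_value = max(values),
                 proper2 = proper2),
            class = "anchor_profile")
}

#' @export
print.anchor_profile <- function(x, ...) {
  cat("Anchor profile: anchors {", paste(x$anchors, collapse = ", "),
      "}, max value ", x$max_value, ", anchor-2 status ", x$proper2, "\n",
      sep = "")
  invisible(x)
}

#' Classify an anchor profile into a numeral-system state label
#'
#' Deterministic, total mapping from a detected [anchor_profile] to the
#' discrete state used in phylogenetic analysis: \code{"restricted"} for
#' anchorless systems; \code{"anchor 2 (proper)"} / \code{"anchor 2
#' (non-proper)"} when 2 is the primary anchor; \code{"anchor N"} otherwise.
#' Multi-anchor systems keep their full anchor set in the profile; the single
#' phylogenetic label is chosen by \code{policy} — the default
#' \code{"smallest"} matches the convention of coding a system by its
#' smallest anchor, while \code{"largest"} codes by the most extensive one.
#'
#' @param profile an [anchor_profile].
#' @param policy \code{"smallest"} (default) or \code{"largest"}.
#' @return a single state label string.
#' @export
classify_system <- function(profile, policy = c("smallest", "largest")) {
  stopifnot(inherits(profile, "anchor_profile"))
  policy <- match.arg(policy)
  if (!length(profile$anchors)) return("restricted")
  primary <- if (policy == "smallest") min(profile$anchors) else max(profile$anchors)
  if (primary == 2L) {
    status <- if (profile$proper2 == "non-proper") "non-proper" else "proper"
    paste0("anchor 2 (", status, ")")
  } else {
    paste0("anchor ", primary)
  }
}
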