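#' Construct a state space of anchor-system types
#'
#' A state space is an ordered set of discrete character states (anchor-system
#' types such as "restricted", "anchor 2", "anchor 5", "anchor 10") together
#' with one-letter codes \code{A, B, C, ...} assigned in order. The order is
#' canonical: it fixes the row/column indexing of every Q matrix built over
#' this space and the ordering of transition-rate parameters \code{qAB, qAC,
#' ...}.
#'
#' @param labels character vector of state names, in canonical order.
#' @param codes optional character vector of unique one-letter codes; defaults
#'   to \code{LETTERS} in order.
#' @return an object of class \code{state_space} with elements \code{labels},
#'   \code{codes} and \code{k} (number of states).
#' @examples
#' state_space(c("restricted", "anchor 2", "anchor 5", "anchor 10"))
#' @export
state_space <- function(labels, codes = LETTERS[seq_along(labels)]) {
  labels <- as.character(labels)
  codes <- as.character(codes)
  if (length(labels) == 0L) stop("state space needs at least one state")
  if (anyDuplicated(labels)) stop("duplicate state labels: ",
    paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(codes) != length(labels)) stop("codes and labels differ in length")
  if (anyDuplicated(codes)) stop("duplicate state codes")
  if (any(nchar(codes) != 1L)) stop("codes must be single characters")
  structure(list(labels = labels, codes = codes, k = length(labels)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space with", x$k, "states:\n")
  cat(paste0("  ", x$codes, " = ", x$labels, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
format.state_space <- function(x, ...) paste0(x$codes, "=", x$labels)

state_index <- function(space, code) {
  i <- match(code, space$codes)
  if (anyNA(i)) stop("unknown state code(s): ",
    paste(code[is.na(i)], collapse = ", "))
  i
}

#' Construct a trait matrix of tip states
#'
#' Binds taxon identifiers (e.g. glottocodes) to anchor-system states over a
#' given state space. A taxon may carry a single state code, an ambiguity set
#' of codes (observed but not resolvable between several types), or
#' \code{NA}/empty for missing data; missing data are treated as ambiguous
#' over all states in the likelihood, the standard Mk convention.
#'
#' @param taxa character vector of unique taxon identifiers.
#' @param states character vector, same length: a single code (\code{"B"}), a
#'   \code{"|"}-joined ambiguity set (\code{"B|C"}), or \code{NA}/\code{""}
#'   for missing.
#' @param space a [state_space].
#' @param family optional family name attached to the matrix.
#' @return an object of class \code{trait_matrix}: a list with \code{taxa},
#'   \code{states} (list of integer state-index vectors), \code{space},
#'   \code{family}.
#' @export
trait_matrix <- function(taxa, states, space, family = NA_character_) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon identifiers: ",
    paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (length(states) != length(taxa)) stop("taxa and states differ in length")
  stopifnot(inherits(space, "state_space"))
  st <- lapply(as.character(states), function(s) {
    if (is.na(s) || !nzchar(s)) return(seq_len(space$k))  # missing = fully ambiguous
    codes <- strsplit(s, "|", fixed = TRUE)[[1]]
    sort(unique(state_index(space, codes)))
  })
  names(st) <- taxa
  structure(list(taxa = taxa, states = st, space = space, family = family),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Trait matrix:", length(x$taxa), "taxa over", x$space$k, "states")
  if (!is.na(x$family)) cat(" (", x$family, ")", sep = "")
  cat("\n")
  tab <- table(vapply(x$states, function(i)
    paste(x$space$codes[i], collapse = "|"), ""))
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  invisible(x)
}

# state strings ("B", "B|C", "" for fully ambiguous) from the index lists
trait_state_strings <- function(matrix) {
  vapply(matrix$states, function(i) {
    if (length(i) == matrix$space$k) "" else
      paste(matrix$space$codes[i], collapse = "|")
  }, "")
}

#' Merge or rename states of a trait matrix
#'
#' Applies a label-level merge map (old label -> new label) to a trait
#' matrix, producing a new matrix over the reduced state space. Merging
#' similar categories keeps the number of transition-rate parameters -- which
#' grows as k^2 - k -- manageable for small families. No records are dropped;
#' ambiguity sets are mapped element-wise and deduplicated.
#'
#' @param matrix a [trait_matrix].
#' @param merge_map named character vector: \code{c("old label" = "new
#'   label", ...)}; must cover every label of the matrix's state space.
#' @return a [trait_matrix] over the merged [state_space]; the new space
#'   keeps the canonical order in which new labels first appear.
#' @export
recode_states <- function(matrix, merge_map) {
  stopifnot(inherits(matrix, "trait_matrix"))
  old <- matrix$space$labels
  missing <- setdiff(old, names(merge_map))
  if (length(missing)) stop("merge_map is missing label(s): ",
    paste(missing, collapse = ", "))
  new_labels <- unique(unname(merge_map[old]))  # canonical order of appearance
  new_space <- state_space(new_labels)
  old_to_new <- match(unname(merge_map[old]), new_labels)
  st <- lapply(matrix$states, function(i) sort(unique(old_to_new[i])))
  out <- matrix
  out$space <- new_space
  out$states <- st
  out
}

#' Read a trait table from TSV/CSV
#'
#' Expects a header with columns \code{taxon}, \code{state} and optionally
#' \code{family}. The state column holds a code, a \code{"|"}-joined
#' ambiguity set, or an empty field for missing data.
#'
#' @param path file path.
#' @param space a [state_space]; if \code{NULL}, one is built from the single
#'   codes observed in the file (in sorted order), which only works when every
#'   state field is a plain code.
#' @param sep field separator; \code{"\t"} (default) or \code{","}.
#' @param exclude_dialects if \code{TRUE}, rows whose optional
#'   \code{is_dialect} column is true are dropped.
#' @return a [trait_matrix].
#' @export
read_trait_table <- function(path, space = NULL, sep = "\t",
                             exclude_dialects = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, quote = "")
  need <- c("taxon", "state")
  if (!all(need %in% names(df))) stop("trait table must have columns: ",
    paste(need, collapse = ", "))
  if (exclude_dialects && "is_dialect" %in% names(df)) {
    df <- df[!(tolower(df$is_dialect) %in% c("true", "1", "yes")), , drop = FALSE]
  }
  if (anyDuplicated(df$taxon)) stop("duplicate taxon identifiers in ", path, ": ",
    paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  if (is.null(space)) {
    codes <- sort(unique(unlist(strsplit(df$state[nzchar(df$state)], "|",
                                         fixed = TRUE))))
    space <- state_space(codes, codes)
  } else {
    seen <- unique(unlist(strsplit(df$state[nzchar(df$state)], "|", fixed = TRUE)))
    bad <- setdiff(seen, space$codes)
    if (length(bad)) stop("unknown state label(s) in ", path, ": ",
      paste(bad, collapse = ", "))
  }
  fam <- if ("family" %in% names(df) && nrow(df) > 0) df$family[1] else NA_character_
  trait_matrix(df$taxon, df$state, space, family = fam)
}

#' Write a trait table to TSV/CSV
#'
#' Inverse of [read_trait_table()]: writing then reading reproduces the
#' records exactly.
#'
#' @param matrix a [trait_matrix].
#' @param path file path.
#' @param sep field separator.
#' @export
write_trait_table <- function(matrix, path, sep = "\t") {
  stopifnot(inherits(matrix, "trait_matrix"))
  df <- data.frame(taxon = matrix$taxa,
                   family = ifelse(is.na(matrix$family), "", matrix$family),
                   state = trait_state_strings(matrix),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
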