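#' Ordered state pairs of a state space
#'
#' The canonical ordering of the k^2 - k off-diagonal transition-rate
#' parameters: row-major over the Q matrix, i.e. \code{qAB, qAC, ..., qBA,
#' qBC, ...}.
#'
#' @param space a [state_space].
#' @return data frame with columns \code{from}, \code{to} (state indices) and
#'   \code{name} (e.g. \code{"qAB"}).
#' @export
rate_pairs <- function(space) {
  k <- space$k
  from <- rep(seq_len(k), each = k)
  to <- rep(seq_len(k), k)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  data.frame(from = from, to = to,
             name = if (length(from))
               paste0("q", space$codes[from], space$codes[to])
             else character(),
             stringsAsFactors = FALSE)
}

#' Construct a transition-rate configuration
#'
#' A rate configuration fixes which of the k^2 - k directed transition-rate
#' parameters are turned on, and how the "on" parameters are partitioned into
#' shared-rate bins. The reversible-jump sampler moves through this space;
#' fixed analyses use a single configuration. Bin identities are
#' canonicalized by first appearance in parameter order, so two configurations
#' with the same partition always compare equal.
#'
#' @param space a [state_space].
#' @param mask logical vector over the ordered pairs of [rate_pairs()]
#'   (default all on).
#' @param bins integer vector: 0 for "off" parameters, a positive bin id for
#'   "on" parameters (default: singleton bins, one free rate per on
#'   parameter).
#' @return an object of class \code{rate_config} with elements \code{space},
#'   \code{pairs}, \code{mask}, \code{bins}, \code{n_bins}.
#' @export
rate_config <- function(space, mask = NULL, bins = NULL) {
  stopifnot(inherits(space, "state_space"))
  pairs <- rate_pairs(space)
  m <- nrow(pairs)
  if (is.null(mask)) mask <- rep(TRUE, m)
  if (length(mask) != m) stop("mask must have length ", m)
  mask <- as.logical(mask)
  if (is.null(bins)) {
    bins <- integer(m)
    bins[mask] <- seq_len(sum(mask))
  }
  bins <- as.integer(bins)
  if (length(bins) != m) stop("bins must have length ", m)
  if (any(bins[!mask] != 0L)) stop("off parameters must have bin 0")
  if (any(bins[mask] <= 0L)) stop("every on parameter needs a positive bin id")
  bins <- canonicalize_bins(bins)
  structure(list(space = space, pairs = pairs, mask = mask, bins = bins,
                 n_bins = length(unique(bins[bins > 0L]))),
            class = "rate_config")
}

# renumber bins 1..B in order of first appearance
canonicalize_bins <- function(bins) {
  on <- bins > 0L
  ids <- unique(bins[on])
  bins[on] <- match(bins[on], ids)
  bins
}

#' @export
print.rate_config <- function(x, ...) {
  cat("Rate configuration over", x$space$k, "states:",
      sum(x$mask), "of", nrow(x$pairs), "parameters on,",
      x$n_bins, "free rate bin(s)\n")
  on <- which(x$mask)
  if (length(on)) {
    for (b in seq_len(x$n_bins)) {
      members <- x$pairs$name[x$bins == b]
      cat("  bin", b, ":", paste(members, collapse = " "), "\n")
    }
  }
  invisible(x)
}

#' Number of free rate parameters of a configuration
#'
#' The dimension of the rate vector: the number of shared-rate bins. For the
#' fully unconstrained configuration with singleton bins this is k^2 - k
#' (e.g. 12 for a 4-state space, 30 for a 6-state space).
#'
#' @param config a [rate_config].
#' @return integer count of free parameters.
#' @examples
#' sp <- state_space(c("restricted", "anchor 2", "anchor 5", "anchor 10"))
#' count_free_parameters(rate_config(sp))  # 12
#' @export
count_free_parameters <- function(config) {
  stopifnot(inherits(config, "rate_config"))
  config$n_bins
}

#' Build a minimal cyclical rate configuration
#'
#' In a cyclical model each anchor type can change into exactly one other,
#' following a stated order around a cycle — e.g. restricted > anchor 2 >
#' anchor 5 > anchor 10 > restricted for a 4-state space — or its reverse.
#' Exactly k parameters are on, each in its own bin.
#'
#' @param space a [state_space].
#' @param state_order permutation of the space's labels (or codes) giving the
#'   cycle order.
#' @param orientation \code{"forward"} (s1 -> s2 -> ... -> sk -> s1) or
#'   \code{"reverse"}.
#' @return a [rate_config] with k on-parameters.
#' @export
build_cyclical_config <- function(space, state_order = space$labels,
                                  orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  idx <- if (all(state_order %in% space$labels)) match(state_order, space$labels)
         else match(state_order, space$codes)
  if (anyNA(idx) || !setequal(idx, seq_len(space$k)))
    stop("state_order must be a permutation of the state space")
  from <- idx
  to <- c(idx[-1], idx[1])
  if (orientation == "reverse") { tmp <- from; from <- to; to <- tmp }
  pairs <- rate_pairs(space)
  mask <- rep(FALSE, nrow(pairs))
  for (i in seq_along(from)) {
    mask[pairs$from == from[i] & pairs$to == to[i]] <- TRUE
  }
  rate_config(space, mask = mask)
}

#' Build a Q matrix from per-bin rates
#'
#' Fills the off-diagonal entries of the k x k generator from the
#' configuration's bins (masked-off entries are 0) and sets each diagonal to
#' minus its row sum, so every row sums to zero.
#'
#' @param rates non-negative numeric vector, one value per bin of
#'   \code{config}.
#' @param config a [rate_config].
#' @return k x k generator matrix with dimnames from the state codes.
#' @export
build_q <- function(rates, config) {
  stopifnot(inherits(config, "rate_config"))
  if (length(rates) != config$n_bins)
    stop("need ", config$n_bins, " rate(s), got ", length(rates))
  if (any(rates < 0)) stop("rates must be non-negative")
  k <- config$space$k
  Q <- matrix(0, k, k, dimnames = list(config$space$codes, config$space$codes))
  on <- which(config$mask)
  if (length(on)) {
    Q[cbind(config$pairs$from[on], config$pairs$to[on])] <-
      rates[config$bins[on]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# expand per-bin rates to the full per-parameter rate vector (0 where off)
expand_rates <- function(rates, config) {
  out <- numeric(nrow(config$pairs))
  on <- which(config$mask)
  out[on] <- rates[config$bins[on]]
  names(out) <- config$pairs$name
  out
}

#' Root prior over states
#'
#' The distribution assumed for the state at the tree's root: uniform over
#' states (default, making the fixed-root mixture identity the definitional
#' cross-check), fossilized to one state (for root-restriction tests),
#' stationary under a given generator, or a custom simplex.
#'
#' @param kind \code{"uniform"}, \code{"fixed"}, \code{"stationary"} or
#'   \code{"custom"}.
#' @param space a [state_space].
#' @param state state code or label (for \code{kind = "fixed"}).
#' @param Q generator matrix (for \code{kind = "stationary"}).
#' @param probs probability vector over states (for \code{kind = "custom"}).
#' @return numeric probability vector of length k, named by state codes.
#' @export
root_prior <- function(kind = c("uniform", "fixed", "stationary", "custom"),
                       space, state = NULL, Q = NULL, probs = NULL) {
  kind <- match.arg(kind)
  k <- space$k
  p <- switch(kind,
    uniform = rep(1 / k, k),
    fixed = {
      i <- if (state %in% space$labels) match(state, space$labels)
           else state_index(space, state)
      v <- numeric(k); v[i] <- 1; v
    },
    stationary = stationary_dist(Q),
    custom = {
      if (length(probs) != k || any(probs < 0)) stop("invalid custom prior")
      probs / sum(probs)
    })
  names(p) <- space$codes
  p
}

#' Stationary distribution of a generator
#'
#' The left null vector of Q normalized to sum to one: the limiting state
#' frequencies of the continuous-time Markov process (requires an
#' irreducible Q).
#'
#' @param Q generator matrix.
#' @return probability vector.
#' @export
stationary_dist <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(numeric(k), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  if (any(pi_hat < 0)) stop("Q appears reducible; no valid stationary distribution")
  pi_hat / sum(pi_hat)
}
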