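#' @keywords internal
CULTURES <- c("A", "B")

#' @keywords internal
DOMAINS <- c("friend", "colleague", "unspecified")

# Display aliases for the two culture labels; the dynamics never use them.
CULTURE_ALIASES <- c(A = "Latino", B = "European-American")

normalize_culture <- function(x, what = "culture") {
  x <- as.character(x)
  x[x %in% CULTURE_ALIASES] <- names(CULTURE_ALIASES)[match(
    x[x %in% CULTURE_ALIASES], CULTURE_ALIASES
  )]
  bad <- !(x %in% CULTURES)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s label(s): %s (expected 'A', 'B' or aliases %s)",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(sprintf("'%s'", CULTURE_ALIASES), collapse = ", ")
    ), call. = FALSE)
  }
  x
}

normalize_ties <- function(ties, n) {
  if (is.null(ties) || (is.matrix(ties) && nrow(ties) == 0) ||
      (!is.matrix(ties) && length(ties) == 0)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("source", "target"))))
  }
  if (is.list(ties)) ties <- do.call(rbind, lapply(ties, as.integer))
  ties <- matrix(as.integer(ties), ncol = 2,
                 dimnames = list(NULL, c("source", "target")))
  if (any(is.na(ties))) stop("ties contain non-integer entries", call. = FALSE)
  if (any(ties < 0L | ties >= n)) {
    stop(sprintf("tie endpoints must be alter ids in [0, %d]", n - 1L),
         call. = FALSE)
  }
  if (any(ties[, 1] == ties[, 2])) {
    i <- which(ties[, 1] == ties[, 2])[1]
    stop(sprintf("self-tie [%d,%d] is not allowed", ties[i, 1], ties[i, 2]),
         call. = FALSE)
  }
  # canonical form: smaller id first, sorted lexicographically
  flip <- ties[, 1] > ties[, 2]
  ties[flip, ] <- ties[flip, c(2, 1)]
  ties <- ties[order(ties[, 1], ties[, 2]), , drop = FALSE]
  key <- ties[, 1] * n + ties[, 2]
  if (anyDuplicated(key)) {
    d <- ties[which(duplicated(key))[1], ]
    stop(sprintf("duplicate tie [%d,%d]", d[1], d[2]), call. = FALSE)
  }
  ties
}

#' Construct an ego network
#'
#' An ego network is a fixed roster of `n` alters (ids `0..n-1`), each labeled
#' with one of exactly two cultures (`"A"`/`"B"`, display aliases "Latino" and
#' "European-American") and optionally a relational domain (`"friend"`,
#' `"colleague"`, `"unspecified"`), together with a set of undirected ties
#' among the alters. Ego is implicitly tied to every alter and is not part of
#' the roster; domains are used only by composition/structure metrics, never
#' by the identification dynamics.
#'
#' Ties are stored canonically (smaller id first, sorted lexicographically);
#' self-ties and duplicates are rejected. For `n` alters the tie count lies in
#' `[0, n(n-1)/2]` -- `[0, 28]` for the default eight-alter roster.
#'
#' @param cultures character vector of per-alter culture labels, length `n`.
#' @param ties two-column matrix (or list of length-2 vectors) of 0-based
#'   alter-id pairs; `NULL` for a tie-free network.
#' @param domains optional character vector of relational domains, length `n`;
#'   default `"unspecified"` for every alter.
#' @return an object of class `ego_network` with fields `cultures`, `domains`,
#'   `ties` (canonical integer matrix) and `n_alters`.
#' @seealso [generate_network()], [same_culture_degree()], [group_size()],
#'   [interclass_tie_weight()], [read_network()]
#' @examples
#' net <- ego_network(c("A", "A", "B"), ties = rbind(c(0, 1), c(0, 2)))
#' same_culture_degree(net, 0)
#' @export
ego_network <- function(cultures, ties = NULL, domains = NULL) {
  cultures <- normalize_culture(cultures)
  n <- length(cultures)
  if (n < 1L) stop("a network needs at least one alter", call. = FALSE)
  if (is.null(domains)) {
    domains <- rep("unspecified", n)
  } else {
    domains <- as.character(domains)
    if (length(domains) != n) {
      stop("domains must have one entry per alter", call. = FALSE)
    }
    bad <- !(domains %in% DOMAINS)
    if (any(bad)) {
      stop(sprintf("invalid domain label(s): %s",
                   paste(unique(domains[bad]), collapse = ", ")), call. = FALSE)
    }
  }
  ties <- normalize_ties(ties, n)
  max_ties <- n * (n - 1L) / 2L
  if (nrow(ties) > max_ties) {
    stop(sprintf("tie count %d exceeds maximum %d for %d alters",
                 nrow(ties), max_ties, n), call. = FALSE)
  }
  structure(
    list(cultures = cultures, domains = domains, ties = ties,
         n_alters = n),
    class = "ego_network"
  )
}

#' @export
print.ego_network <- function(x, ...) {
  cat(sprintf("<ego_network: %d alters (A:%d, B:%d), %d ties>\n",
              x$n_alters, sum(x$cultures == "A"), sum(x$cultures == "B"),
              nrow(x$ties)))
  invisible(x)
}

#' @export
format.ego_network <- function(x, ...) {
  sprintf("ego_network(%d alters, %d ties)", x$n_alters, nrow(x$ties))
}

all_pairs <- function(n) {
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2))
  }
  t(combn(0:(n - 1L), 2L))
}

#' Generate a random ego network
#'
#' Builds an `n_alters` network with exactly `n_culture_a` alters of culture A
#' and exactly `n_ties` ties drawn uniformly at random, without replacement,
#' from all unordered alter pairs. This mirrors the simulation design of the
#' underlying model: eight alters, a culture ratio from 0:8 to 8:0, and 0--28
#' uniformly placed ties.
#'
#' By default the first `n_culture_a` roster slots carry culture A: the
#' dynamics depend only on culture counts and tie placement, not on which
#' roster slot holds which label. `random_labels = TRUE` shuffles label
#' placement (for fixture realism); `domains = TRUE` marks the first half of
#' the roster `"friend"` and the second half `"colleague"`, mirroring a
#' four-friends-plus-four-colleagues elicitation.
#'
#' Draws come from R's global random stream; pass `seed` for a self-contained
#' reproducible draw.
#'
#' @param n_alters positive integer roster size (default 8).
#' @param n_culture_a integer in `[0, n_alters]`: alters of culture A.
#' @param n_ties integer in `[0, n_alters(n_alters-1)/2]`.
#' @param domains logical: assign friend/colleague domains (default FALSE).
#' @param random_labels logical: shuffle culture placement (default FALSE).
#' @param seed optional integer seed.
#' @return an [ego_network()].
#' @examples
#' generate_network(8, 4, 12, seed = 1)
#' @export
generate_network <- function(n_alters = 8L, n_culture_a, n_ties,
                             domains = FALSE, random_labels = FALSE,
                             seed = NULL) {
  n_alters <- as.integer(n_alters)
  if (is.na(n_alters) || n_alters < 1L) {
    stop("n_alters must be a positive integer", call. = FALSE)
  }
  if (n_culture_a < 0 || n_culture_a > n_alters) {
    stop(sprintf("n_culture_a = %s out of bounds [0, %d]",
                 format(n_culture_a), n_alters), call. = FALSE)
  }
  max_ties <- n_alters * (n_alters - 1L) / 2L
  if (n_ties < 0 || n_ties > max_ties) {
    stop(sprintf("n_ties = %s out of bounds [0, %d]",
                 format(n_ties), max_ties), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cultures <- rep(c("A", "B"), c(n_culture_a, n_alters - n_culture_a))
  if (random_labels) cultures <- sample(cultures)
  pairs <- all_pairs(n_alters)
  idx <- if (n_ties > 0L) sample.int(nrow(pairs), as.integer(n_ties)) else integer(0)
  dom <- NULL
  if (isTRUE(domains)) {
    half <- ceiling(n_alters / 2)
    dom <- rep(c("friend", "colleague"), c(half, n_alters - half))
  }
  ego_network(cultures, ties = pairs[idx, , drop = FALSE], domains = dom)
}

check_alter_id <- function(network, alter_id) {
  alter_id <- as.integer(alter_id)
  if (is.na(alter_id) || alter_id < 0L || alter_id >= network$n_alters) {
    stop(sprintf("unknown alter id %s (valid ids: 0..%d)",
                 format(alter_id), network$n_alters - 1L), call. = FALSE)
  }
  alter_id
}

#' Same-culture degree centrality of an alter
#'
#' The number of ties an alter has to alters sharing its culture -- the degree
#' centrality that scales that alter's influence on ego in the dynamics. For
#' an eight-alter network it ranges from 0 to 7.
#'
#' @param network an [ego_network()].
#' @param alter_id 0-based alter id.
#' @return integer count in `[0, n_alters - 1]`.
#' @seealso [same_culture_degrees()] for all alters at once.
#' @export
same_culture_degree <- function(network, alter_id) {
  alter_id <- check_alter_id(network, alter_id)
  same_culture_degrees(network)[alter_id + 1L]
}

#' Same-culture degrees of every alter
#'
#' @param network an [ego_network()].
#' @return integer vector of length `n_alters`, indexed by alter id + 1.
#' @export
same_culture_degrees <- function(network) {
  ties <- network$ties
  cu <- network$cultures
  if (nrow(ties) == 0L) {
    return(integer(network$n_alters))
  }
  same <- cu[ties[, 1] + 1L] == cu[ties[, 2] + 1L]
  tabulate(c(ties[same, 1], ties[same, 2]) + 1L, nbins = network$n_alters)
}

#' Group size of a culture
#'
#' Compositional measure: the absolute count of alters carrying the given
#' culture label; for an eight-alter roster it takes values 0--8 and the two
#' group sizes sum to the roster size.
#'
#' @param network an [ego_network()].
#' @param culture `"A"` or `"B"` (or a display alias).
#' @return integer count.
#' @export
group_size <- function(network, culture) {
  culture <- normalize_culture(culture)
  if (length(culture) != 1L) stop("culture must be a single label", call. = FALSE)
  sum(network$cultures == culture)
}

#' Inter-class tie weight between two alter groups
#'
#' Structural measure of how well two disjoint groups of alters are connected,
#' normalized by group size: `omega(F, C) = e(F, C) / (|F| * |C|)`, where
#' `e(F, C)` counts ties with one endpoint in each group. Under this formula
#' the weight lies in `[0, 1]`: 0 exactly when no cross-group tie exists and 1
#' exactly when the bipartite graph between the groups is complete. Typical
#' use pairs same-culture friends with same-culture colleagues.
#'
#' When either group is empty the measure is undefined (the denominator is 0)
#' and `NA_real_` is returned rather than 0, so "no members" stays
#' distinguishable from "members but no ties". Note that some survey uses of
#' same-named interconnection measures report values above 1, implying a
#' different denominator; this function implements the product-of-group-sizes
#' normalization only.
#'
#' @param network an [ego_network()].
#' @param group_f,group_c disjoint vectors of 0-based alter ids.
#' @return numeric weight in `[0, 1]`, or `NA_real_` if a group is empty.
#' @examples
#' net <- ego_network(rep("A", 4), ties = rbind(c(0, 2), c(0, 3)))
#' interclass_tie_weight(net, c(0, 1), c(2, 3))  # 2 / (2*2)
#' @export
interclass_tie_weight <- function(network, group_f, group_c) {
  group_f <- vapply(group_f, function(i) check_alter_id(network, i), integer(1))
  group_c <- vapply(group_c, function(i) check_alter_id(network, i), integer(1))
  group_f <- unique(group_f)
  group_c <- unique(group_c)
  if (length(intersect(group_f, group_c)) > 0L) {
    stop("group_f and group_c must be disjoint", call. = FALSE)
  }
  if (length(group_f) == 0L || length(group_c) == 0L) {
    return(NA_real_)
  }
  ties <- network$ties
  if (nrow(ties) == 0L) {
    return(0)
  }
  cross <- (ties[, 1] %in% group_f & ties[, 2] %in% group_c) |
    (ties[, 1] %in% group_c & ties[, 2] %in% group_f)
  sum(cross) / (length(group_f) * length(group_c))
}
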