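#' Enumerate unordered event pairs
#'
#' All n(n-1)/2 unordered pairs in lexicographic order (i < j). With 16
#' events this yields the familiar 120 pairings of a pairwise photo-ID
#' rating task.
#'
#' @param events either a positive integer n (pairs of indices 1..n) or a
#'   character vector of event ids (pairs of sorted ids).
#' @return data.frame with columns `event_a`, `event_b`.
#' @examples
#' nrow(enumerate_pairs(16))  # 120
#' @export
enumerate_pairs <- function(events) {
  if (is.numeric(events) && length(events) == 1L) {
    if (events < 1 || events != round(events)) {
      stop_input("enumerate_pairs: n must be a positive integer")
    }
    ids <- seq_len(events)
  } else {
    ids <- sort(unique(as.character(events)))
    if (length(ids) < 1L) stop_input("enumerate_pairs: no events")
  }
  n <- length(ids)
  if (n == 1L) {
    return(data.frame(event_a = ids[0], event_b = ids[0]))
  }
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(event_a = ids[i], event_b = ids[j], stringsAsFactors = FALSE)
}

#' Construct a pairwise rating set
#'
#' Bundles the verdicts of R raters over all unordered pairs of n events
#' into a validated object. Pairs are canonicalized (event_a < event_b
#' lexicographically) on ingestion; the constructor rejects duplicate,
#' missing, or off-domain cells so downstream agreement statistics can
#' assume a complete n(n-1)/2 x R verdict matrix.
#'
#' @param ratings long-format data.frame with columns `event_a`, `event_b`,
#'   `rater`, `verdict` ("same"/"different").
#' @return object of class `pair_rating_set`: list with `event_ids`,
#'   `raters`, `pairs` (data.frame) and `verdicts` (n_pairs x R character
#'   matrix, rows aligned with `pairs`).
#' @export
pair_rating_set <- function(ratings) {
  need <- c("event_a", "event_b", "rater", "verdict")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) {
    stop_input(paste("pair_rating_set: missing column(s):", paste(miss, collapse = ", ")))
  }
  a <- as.character(ratings$event_a); b <- as.character(ratings$event_b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  if (any(a == b)) stop_input("pair_rating_set: self-pairings present")
  v <- as.character(ratings$verdict)
  if (!all(v %in% c("same", "different"))) {
    stop_input(paste("pair_rating_set: verdicts outside {same, different}:",
                     paste(setdiff(unique(v), c("same", "different")), collapse = ", ")))
  }
  event_ids <- sort(unique(c(a, b)))
  raters <- sort(unique(as.character(ratings$rater)))
  pairs <- enumerate_pairs(event_ids)
  key <- paste(a, b, sep = "\r")
  pkey <- paste(pairs$event_a, pairs$event_b, sep = "\r")
  cell <- paste(key, ratings$rater, sep = "\r")
  if (anyDuplicated(cell)) {
    stop_input(paste("pair_rating_set: duplicate cell(s), e.g.",
                     cell[duplicated(cell)][1]))
  }
  verdicts <- matrix(NA_character_, nrow(pairs), length(raters),
                     dimnames = list(NULL, raters))
  verdicts[cbind(match(key, pkey), match(as.character(ratings$rater), raters))] <- v
  if (anyNA(verdicts)) {
    holes <- which(is.na(verdicts), arr.ind = TRUE)
    ex <- paste0("(", pairs$event_a[holes[, 1]], ",", pairs$event_b[holes[, 1]],
                 ") by ", raters[holes[, 2]])
    stop_input(paste0("pair_rating_set: ", nrow(holes), " missing cell(s): ",
                      paste(utils::head(ex, 5), collapse = "; ")))
  }
  structure(list(event_ids = event_ids, raters = raters,
                 pairs = pairs, verdicts = verdicts),
            class = "pair_rating_set")
}

#' @export
print.pair_rating_set <- function(x, ...) {
  cat("pair_rating_set:", length(x$event_ids), "events,",
      nrow(x$pairs), "pairings,", length(x$raters), "raters\n")
  invisible(x)
}

#' One rater's identity partition
#'
#' Treats the rater's "same" verdicts as edges of a graph over events; the
#' connected components are the rater's implied individual identities
#' (transitive closure, exactly as an interactive network plot would group
#' them). Pairs the rater marked "different" that nevertheless end up inside
#' one component are reported as contradictions -- they are never resolved
#' automatically.
#'
#' @param ratings a `pair_rating_set`.
#' @param rater rater id.
#' @return list with `rater`, `components` (list of character vectors),
#'   `n_individuals`, and `contradictions` (data.frame of conflicted pairs).
#' @export
partition_from_ratings <- function(ratings, rater) {
  stopifnot(inherits(ratings, "pair_rating_set"))
  if (!rater %in% ratings$raters) {
    stop_input(paste("partition_from_ratings: unknown rater", rater))
  }
  v <- ratings$verdicts[, rater]
  g <- igraph::graph_from_data_frame(
    ratings$pairs[v == "same", , drop = FALSE],
    directed = FALSE, vertices = ratings$event_ids)
  comp <- igraph::components(g)
  membership <- comp$membership[ratings$event_ids]
  components <- unname(split(ratings$event_ids, membership))
  contr_idx <- which(v == "different" &
    membership[ratings$pairs$event_a] == membership[ratings$pairs$event_b])
  list(rater = rater,
       components = components,
       n_individuals = as.integer(comp$no),
       contradictions = ratings$pairs[contr_idx, , drop = FALSE])
}

#' Individuals identified per rater
#'
#' @param ratings a `pair_rating_set`.
#' @return list with `per_rater` (named integer vector of component counts)
#'   and `summary` (mean, min, max, sd; sample SD with n-1 denominator).
#' @export
count_individuals <- function(ratings) {
  stopifnot(inherits(ratings, "pair_rating_set"))
  counts <- vapply(ratings$raters,
                   function(r) partition_from_ratings(ratings, r)$n_individuals,
                   integer(1))
  list(per_rater = counts,
       summary = c(mean = mean(counts), min = min(counts),
                   max = max(counts), sd = stats::sd(counts)))
}

#' Adjust singleton disagreements to the consensus
#'
#' A "singleton" pairing is one where exactly one rater dissents from the
#' unanimous verdict of all the others (an R-1 vs 1 split). This operation
#' flips each such lone verdict to the consensus, leaving every other cell
#' untouched, and reports what fraction of the pairings with any
#' disagreement were singletons.
#'
#' @param ratings a `pair_rating_set` with at least 3 raters.
#' @return list with `adjusted` (a new `pair_rating_set`), `n_flipped`, and
#'   `singleton_fraction` (singleton pairings / disagreeing pairings;
#'   NA when there is no disagreement at all).
#' @export
singleton_adjust <- function(ratings) {
  stopifnot(inherits(ratings, "pair_rating_set"))
  R <- length(ratings$raters)
  if (R < 3) stop_input("singleton_adjust: needs >= 3 raters for a consensus")
  v <- ratings$verdicts
  n_same <- rowSums(v == "same")
  disagree <- n_same > 0 & n_same < R
  singleton <- n_same == 1L | n_same == R - 1L
  flip <- which(disagree & singleton)
  for (i in flip) {
    maj <- if (n_same[i] == 1L) "different" else "same"
    v[i, v[i, ] != maj] <- maj
  }
  adjusted <- ratings
  adjusted$verdicts <- v
  list(adjusted = adjusted,
       n_flipped = length(flip),
       singleton_fraction = if (any(disagree)) sum(disagree & singleton) / sum(disagree)
                            else NA_real_)
}
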