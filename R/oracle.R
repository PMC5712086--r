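#' Create a simulated domain-expert oracle
#'
#' The oracle answers mapping-validity questions from a reference alignment
#' (a consensus alignment in the interactive track setting): the true
#' answer is membership of the canonicalized (source, target, relation)
#' triple in the reference, flipped independently with probability
#' \code{error_rate} the first time a mapping is asked. Answers are cached
#' per mapping — a human expert answers the same question consistently —
#' while every call, repeated or not, increments the request counter. All
#' randomness lives in a private RNG stream, so transcripts are
#' reproducible for a seed regardless of the caller's RNG use.
#'
#' @param reference [alignment()] used as ground truth.
#' @param error_rate probability in \eqn{[0,1]} of answering incorrectly;
#'   0 is the perfect user.
#' @param seed integer seed for the flip stream.
#' @param relation_sensitive if \code{FALSE}, membership is judged on the
#'   (source, target) pair only.
#' @return an oracle state object (mutable environment) of class
#'   \code{oracle}.
#' @export
make_oracle <- function(reference, error_rate = 0, seed = 1,
                        relation_sensitive = TRUE) {
  stopifnot(inherits(reference, "alignment"))
  if (!is.numeric(error_rate) || length(error_rate) != 1 ||
      is.na(error_rate) || error_rate < 0 || error_rate > 1)
    stop("error_rate must be a single number in [0, 1]", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$keys <- if (relation_sensitive) mapping_key(reference$mappings)
    else paste(reference$mappings$source, reference$mappings$target,
               sep = "\r")
  st$relation_sensitive <- relation_sensitive
  st$error_rate <- error_rate
  st$rng <- with_local_seed(seed, {
    stats::runif(1)  # advance once so the stored state is seed-derived
    get(".Random.seed", globalenv())
  })
  st$n_requests <- 0L
  st$cache <- new.env(parent = emptyenv())
  st$transcript <- list()
  class(st) <- "oracle"
  st
}

#' @export
print.oracle <- function(x, ...) {
  cat(sprintf("<oracle> error_rate=%.2f, %d reference mappings, %d requests\n",
              x$error_rate, length(x$keys), x$n_requests))
  invisible(x)
}

#' Ask the oracle whether a mapping is valid
#'
#' @param state an [make_oracle()] state.
#' @param source,target,relation the queried mapping (vectorized; one
#'   answer per element).
#' @return logical vector of answers.
#' @export
ask <- function(state, source, target, relation = "=") {
  stopifnot(inherits(state, "oracle"))
  m <- mapping_set(source, target, relation)
  if (nrow(m) != length(source))
    stop("duplicate mappings in one ask() call; query them separately",
         call. = FALSE)
  keys <- if (state$relation_sensitive) mapping_key(m)
    else paste(m$source, m$target, sep = "\r")
  # preserve caller order (mapping_set sorts)
  ord <- order(order(paste(trimws(source), trimws(target),
                           normalize_relation(relation), sep = "\r")))
  keys <- keys[ord]; m <- m[ord, , drop = FALSE]
  out <- logical(length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    state$n_requests <- state$n_requests + 1L
    hit <- state$cache[[k]]
    if (is.null(hit)) {
      truth <- k %in% state$keys
      flip <- if (state$error_rate == 0) FALSE else {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
          get(".Random.seed", globalenv()) else NULL
        assign(".Random.seed", state$rng, envir = globalenv())
        f <- stats::runif(1) < state$error_rate
        state$rng <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
        f
      }
      hit <- xor(truth, flip)
      assign(k, hit, envir = state$cache)
    }
    state$transcript[[length(state$transcript) + 1]] <-
      list(source = m$source[i], target = m$target[i],
           relation = m$relation[i], answer = hit)
    out[i] <- hit
  }
  out
}

#' Number of oracle requests issued so far
#' @param state an oracle state.
#' @export
n_requests <- function(state) state$n_requests

#' Oracle transcript as a data frame
#' @param state an oracle state.
#' @export
oracle_transcript <- function(state) {
  if (length(state$transcript) == 0)
    return(data.frame(source = character(), target = character(),
                      relation = character(), answer = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(state$transcript, function(t)
    data.frame(t, stringsAsFactors = FALSE)))
}

#' Interaction gain summary
#'
#' F-measure gain of an interactive run over its non-interactive baseline,
#' together with the number of oracle requests spent to obtain it (the two
#' axes the interactive track reports).
#'
#' @param before,after \code{metrics_report}s against the same reference.
#' @param state the oracle consulted between the two runs.
#' @return a list with \code{f_measure}, \code{gain} and \code{requests}.
#' @export
gain_report <- function(before, after, state) {
  if (!identical(before$reference_name, after$reference_name))
    stop("reports are against different references", call. = FALSE)
  list(f_measure = after$f_measure,
       gain = after$f_measure - before$f_measure,
       requests = n_requests(state))
}
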