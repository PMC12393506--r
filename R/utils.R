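#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`, then
#' restores the previous generator state so callers never observe a side
#' effect. With `seed = NULL` the expression runs against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Every stochastic stage draws from a generator seeded deterministically from
#' the master seed, the stage name, and an entity id, so independent stages do
#' not share (or perturb) one RNG stream. The derived value is always a valid
#' 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param ... Labels (stage name, entity id, ...) coerced to character.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

## counts-per-million on rows (cells or samples); zero rows stay zero
cpm_rows <- function(m, target = 1e6) {
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  m * (target / tot)
}

#' Cosine similarity of two numeric vectors
#'
#' @param a,b Numeric vectors of equal length; neither may be all-zero.
#' @return The cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) cosine_vec(a, b)

cosine_vec <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
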