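#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with an arbitrary set of string labels into a
#' 31-bit integer seed. Used to give every (region, pool) combination its own
#' random substream so that results do not depend on processing order.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric labels identifying the substream.
#' @return A single integer in \code{[0, 2^31 - 2]}.
#' @examples
#' substreamSeed(1L, "R01", "GLOBAL_NAT")
#' @export
substreamSeed <- function(master, ...) {
  labels <- paste(c(format(master, scientific = FALSE), unlist(list(...))),
                  collapse = "/")
  codes <- utf8ToInt(labels)
  h <- as.numeric(master) %% 2147483647
  for (k in codes) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded by `seed`; the caller's RNG
# stream is restored afterwards, so library code never perturbs user RNG.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# stopifnot-style assertion with sprintf message
assertThat <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# sample that never does the "x is scalar" surprise
sampleExact <- function(x, size) {
  x[sample.int(length(x), size)]
}
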